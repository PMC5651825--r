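#' Read a genome FASTA and optional GFF3 annotation
#'
#' @param fasta Path to a single-sequence genome FASTA.
#' @param gff3 Optional path to a GFF3 file; `CDS` features with `ID`
#'   attributes become the gene table.
#' @param circular Treat the chromosome as circular (default `TRUE`).
#' @return A [genome_record()].
#' @export
read_genome <- function(fasta, gff3 = NULL, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1) abort("Expected exactly one sequence in the genome FASTA.")
  genes <- if (!is.null(gff3)) read_annotation(gff3) else NULL
  genome_record(as.character(seqs[[1]]), genes, circular = circular)
}

#' Read CDS features from a GFF3 file
#'
#' @param gff3 Path to a GFF3 file.
#' @return Tibble with `gene_id`, `start`, `end`, `strand`.
#' @export
read_annotation <- function(gff3) {
  gr <- rtracklayer::import(gff3, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) abort("No CDS features found in the GFF3 file.")
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) ids <- sprintf("cds%04d", seq_along(gr))
  tibble(
    gene_id = as.character(ids),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr))
  )
}

#' Load per-position 5'-end counts from a bedGraph file
#'
#' bedGraph intervals are 0-based half-open; an interval `chrom 9 12 4`
#' therefore assigns count 4 to 1-based positions 10, 11 and 12. Positions
#' absent from the file are zero.
#'
#' @param path bedGraph file with one value column.
#' @param genome_length Genome length in bases.
#' @return Numeric count vector of length `genome_length`.
#' @export
load_end_counts <- function(path, genome_length) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) abort(sprintf("Failed to parse bedGraph '%s': %s",
                                      path, conditionMessage(e)))
  )
  counts <- numeric(genome_length)
  if (length(gr) > 0) {
    starts <- BiocGenerics::start(gr)
    ends <- BiocGenerics::end(gr)
    if (any(starts < 1) || any(ends > genome_length)) {
      abort(sprintf("bedGraph '%s' has intervals outside the genome.", path))
    }
    vals <- gr$score
    if (any(vals < 0)) abort(sprintf("bedGraph '%s' contains negative values.", path))
    for (i in seq_along(gr)) {
      counts[starts[i]:ends[i]] <- vals[i]
    }
  }
  counts
}

write_bedgraph <- function(counts, path, chrom = "chr") {
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
    score = r$values[keep]
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a simulated data set to disk
#'
#' Emits the genome FASTA, a GFF3 of CDS features, four bedGraph files
#' (`TEXplus`/`TEXminus` x `fwd`/`rev`) and a ground-truth TSV; all files
#' round-trip losslessly through [read_genome()] and [load_end_counts()].
#'
#' @param sim Output of [simulate_genome()] (list with `genome`, `truth`).
#' @param profiles Output of [simulate_end_profiles()].
#' @param dir Output directory (created if missing).
#' @param chrom Sequence name used in all files.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixtures <- function(sim, profiles, dir, chrom = "chr") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genome <- sim$genome
  paths <- c(
    genome = file.path(dir, "genome.fasta"),
    annotation = file.path(dir, "annotation.gff3"),
    TEXplus_fwd = file.path(dir, "TEXplus_fwd.bedgraph"),
    TEXplus_rev = file.path(dir, "TEXplus_rev.bedgraph"),
    TEXminus_fwd = file.path(dir, "TEXminus_fwd.bedgraph"),
    TEXminus_rev = file.path(dir, "TEXminus_rev.bedgraph"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  dna <- Biostrings::DNAStringSet(stats::setNames(genome$seq, chrom))
  Biostrings::writeXStringSet(dna, paths["genome"])

  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = genome$genes$start, end = genome$genes$end),
    strand = genome$genes$strand,
    type = "CDS",
    phase = 0L,
    ID = genome$genes$gene_id
  )
  rtracklayer::export(gr, paths["annotation"], format = "gff3")

  write_bedgraph(profiles$tex_plus$fwd, paths["TEXplus_fwd"], chrom)
  write_bedgraph(profiles$tex_plus$rev, paths["TEXplus_rev"], chrom)
  write_bedgraph(profiles$tex_minus$fwd, paths["TEXminus_fwd"], chrom)
  write_bedgraph(profiles$tex_minus$rev, paths["TEXminus_rev"], chrom)

  readr::write_tsv(sim$truth$tss, paths["truth"])
  invisible(paths)
}

#' Write proteome FASTA files, one per genome
#'
#' @param proteomes Named list of [Biostrings::AAStringSet] as produced by
#'   [simulate_proteomes()].
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_proteomes <- function(proteomes, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(proteomes), function(g) {
    p <- file.path(dir, paste0(g, ".faa"))
    Biostrings::writeXStringSet(proteomes[[g]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Read per-genome proteome FASTA files
#'
#' @param paths Character vector of protein FASTA paths; genome names are
#'   taken from the file names.
#' @return Named list of [Biostrings::AAStringSet].
#' @export
read_proteomes <- function(paths) {
  out <- lapply(paths, Biostrings::readAAStringSet)
  names(out) <- sub("\\.(fa|faa|fasta)$", "", basename(paths))
  out
}
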