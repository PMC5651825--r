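#' Pipeline configuration
#'
#' Collects the input paths and stage parameters for [run_pipeline()].
#' Accepts a YAML file or arguments; referenced files are checked at
#' validation time, before any stage runs.
#'
#' @param genome_fasta,gff3 Genome sequence and annotation paths.
#' @param tex_plus_fwd,tex_plus_rev,tex_minus_fwd,tex_minus_rev bedGraph
#'   paths of 5'-end counts for the two libraries, per strand.
#' @param proteome_dir Optional directory of per-genome protein FASTAs
#'   (`*.faa`/`*.fasta`); enables the pan-genome stage.
#' @param detection [detection_params()].
#' @param windows [classification_windows()].
#' @param motif_width Promoter motif width (default 6).
#' @param n_restarts EM restarts (default 20).
#' @param n_permutations Permutations for motif significance; 0 skips the
#'   test (default 0, since it dominates runtime).
#' @param out_dir Output directory.
#' @param seed Seed propagated to every stochastic stage.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta, gff3,
                            tex_plus_fwd, tex_plus_rev,
                            tex_minus_fwd, tex_minus_rev,
                            proteome_dir = NULL,
                            detection = detection_params(),
                            windows = classification_windows(),
                            motif_width = 6L, n_restarts = 20L,
                            n_permutations = 0L,
                            out_dir = tempfile("drnatss_out"), seed = 1L) {
  cfg <- list(
    genome_fasta = genome_fasta, gff3 = gff3,
    bedgraphs = c(tex_plus_fwd = unname(tex_plus_fwd),
                  tex_plus_rev = unname(tex_plus_rev),
                  tex_minus_fwd = unname(tex_minus_fwd),
                  tex_minus_rev = unname(tex_minus_rev)),
    proteome_dir = proteome_dir, detection = detection, windows = windows,
    motif_width = as.integer(motif_width), n_restarts = as.integer(n_restarts),
    n_permutations = as.integer(n_permutations),
    out_dir = out_dir, seed = as.integer(seed)
  )
  missing <- c(cfg$genome_fasta, cfg$gff3, cfg$bedgraphs)
  missing <- missing[!file.exists(missing)]
  if (length(missing) > 0) {
    abort(paste0("Input file(s) not found: ", paste(missing, collapse = ", ")))
  }
  if (!is.null(proteome_dir) && !dir.exists(proteome_dir)) {
    abort(paste0("Proteome directory not found: ", proteome_dir))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  det <- do.call(detection_params, y$detection %||% list())
  win <- do.call(classification_windows, y$windows %||% list())
  pipeline_config(
    genome_fasta = y$genome_fasta, gff3 = y$gff3,
    tex_plus_fwd = y$tex_plus_fwd, tex_plus_rev = y$tex_plus_rev,
    tex_minus_fwd = y$tex_minus_fwd, tex_minus_rev = y$tex_minus_rev,
    proteome_dir = y$proteome_dir,
    detection = det, windows = win,
    motif_width = y$motif_width %||% 6L,
    n_restarts = y$n_restarts %||% 20L,
    n_permutations = y$n_permutations %||% 0L,
    out_dir = y$out_dir %||% tempfile("drnatss_out"),
    seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full primary-transcriptome pipeline
#'
#' Genome statistics, TSS detection, positional classification,
#' promoter/5'UTR/RBS analysis and (when proteomes are supplied) the
#' pan-genome stage, writing per-stage TSVs plus one JSON report to
#' `out_dir`. Runs are deterministic under a fixed seed.
#'
#' @param config A `pipeline_config`.
#' @return The report list, invisibly; stage outputs are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- read_genome(config$genome_fasta, config$gff3)
  gstats <- genome_summary(genome)
  skew <- cumulative_gc_skew(genome)
  readr::write_tsv(as_tibble(skew), file.path(config$out_dir, "gc_skew.tsv"))

  L <- genome$length
  tex_plus <- end_profile(
    "TEXplus",
    load_end_counts(config$bedgraphs[["tex_plus_fwd"]], L),
    load_end_counts(config$bedgraphs[["tex_plus_rev"]], L)
  )
  tex_minus <- end_profile(
    "TEXminus",
    load_end_counts(config$bedgraphs[["tex_minus_fwd"]], L),
    load_end_counts(config$bedgraphs[["tex_minus_rev"]], L)
  )
  pair <- normalize_pair(tex_plus, tex_minus)
  tss <- call_tss(pair, config$detection)
  classified <- classify_tss(tss, genome, config$windows)
  readr::write_tsv(classified, file.path(config$out_dir, "tss.tsv"))
  write_tss_bed(classified, file.path(config$out_dir, "tss.bed"))
  cls <- summarize_classes(classified, genome)

  promoters <- discover_promoters(classified, genome, width = config$motif_width,
                                  n_restarts = config$n_restarts,
                                  seed = config$seed)
  if (config$n_permutations >= 99) {
    promoters$minus10 <- motif_significance(
      promoters$minus10, promoters$minus10_windows,
      config$n_permutations, seed = config$seed
    )
    promoters$minus35 <- motif_significance(
      promoters$minus35, promoters$minus35_windows,
      config$n_permutations, seed = config$seed + 1L
    )
  }
  arch <- promoter_architecture(promoters, classified)
  readr::write_tsv(arch$per_tss, file.path(config$out_dir, "promoters.tsv"))
  write_motif_meme(list(minus10 = promoters$minus10,
                        minus35 = promoters$minus35),
                   file.path(config$out_dir, "motifs.meme"))
  comp <- composition_at_tss(classified, genome)
  utr <- compute_utrs(classified)
  rbs <- find_rbs(classified, genome)
  readr::write_tsv(rbs, file.path(config$out_dir, "rbs.tsv"))

  pan <- NULL
  if (!is.null(config$proteome_dir)) {
    paths <- list.files(config$proteome_dir, "\\.(fa|faa|fasta)$",
                        full.names = TRUE)
    proteomes <- read_proteomes(paths)
    graph <- score_pairs(proteomes)
    fams <- mcl_cluster(graph)
    pan <- categorize_families(fams)
    readr::write_tsv(pan$families, file.path(config$out_dir, "families.tsv"))
    writeLines(pan_tree(pan)$newick, file.path(config$out_dir, "pan_tree.nwk"))
  }

  report <- build_report(gstats, cls, promoters, arch, comp, utr, rbs, pan)
  write_report(report, file.path(config$out_dir, "report.json"))
  invisible(report)
}

build_report <- function(gstats, cls, promoters, arch, comp, utr, rbs, pan) {
  counts <- stats::setNames(as.list(cls$n), cls$class)
  rbs_hits <- rbs[rbs$hit %in% TRUE, ]
  report <- list(
    genome = as.list(gstats),
    tss = c(
      list(total = sum(cls$n)), counts,
      list(
        genes_with_primary = attr(cls, "n_genes_with_primary"),
        fraction_genes_with_primary = attr(cls, "fraction_genes_with_primary")
      )
    ),
    promoters = list(
      minus10_consensus = promoters$minus10$consensus,
      minus35_consensus = promoters$minus35$consensus,
      minus10_fraction = promoters$minus10$occupancy,
      minus35_fraction = promoters$minus35$occupancy,
      minus10_p_value = promoters$minus10$p_value,
      minus35_p_value = promoters$minus35$p_value,
      spacer_histogram = stats::setNames(
        as.list(arch$spacer_histogram$n),
        as.character(arch$spacer_histogram$spacer)
      ),
      architecture_fractions = as.list(arch$fractions)
    ),
    composition = list(
      pyrimidine_minus1 = attr(comp, "pyrimidine_minus1"),
      purine_plus1 = attr(comp, "purine_plus1")
    ),
    utr = as.list(glance(utr)),
    rbs = list(
      n_scanned = nrow(rbs), n_hits = nrow(rbs_hits),
      fraction_spacer_5_10 = if (nrow(rbs_hits) > 0) {
        mean(rbs_hits$spacer >= 5 & rbs_hits$spacer <= 10)
      } else NA_real_
    )
  )
  if (!is.null(pan)) report$pangenome <- as.list(glance(pan))
  report
}

#' Write the pipeline report as JSON
#'
#' @param report Report list from [run_pipeline()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write motifs in MEME minimal text format
#'
#' @param motifs Named list of `motif_model`s.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_motif_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- motifs[[1]]$background
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "", "strands: +", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg["A"], bg["C"], bg["G"], bg["T"]),
    ""
  ), con)
  for (nm in names(motifs)) {
    m <- motifs[[nm]]
    writeLines(sprintf("MOTIF %s %s", nm, m$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= %g",
      m$width, nrow(m$sites),
      if (is.na(m$p_value)) 1 else m$p_value
    ), con)
    for (k in seq_len(m$width)) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         m$ppm["A", k], m$ppm["C", k],
                         m$ppm["G", k], m$ppm["T", k]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
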