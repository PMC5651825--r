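#' Positional classification windows
#'
#' @param upstream Window upstream of the start codon in which a
#'   sense-strand TSS can be primary/secondary, nt (default 300).
#' @param downstream Window downstream of the start codon, nt (default 100;
#'   set 150 to reproduce the wider convention some studies use).
#' @param antisense_flank Extra flank around an ORF for the antisense
#'   class, nt (default 0).
#' @return A `classification_windows` list.
#' @export
classification_windows <- function(upstream = 300L, downstream = 100L,
                                   antisense_flank = 0L) {
  if (upstream < 0 || downstream < 0 || antisense_flank < 0) {
    abort("Window sizes must be non-negative.")
  }
  structure(
    list(upstream = as.integer(upstream), downstream = as.integer(downstream),
         antisense_flank = as.integer(antisense_flank)),
    class = "classification_windows"
  )
}

#' Classify TSSs by position relative to annotated ORFs
#'
#' Each TSS receives exactly one of five labels with precedence
#' P > S > I > A > N. Sense-strand TSSs inside a gene's window (from
#' `upstream` nt before to `downstream` nt after its start codon) compete:
#' the one with the highest TEX+ count is primary (P), the rest secondary
#' (S). A TSS inside the window of two genes is assigned to the gene with
#' the nearer start codon (tie: the upstream gene). Remaining TSSs inside
#' an ORF on the sense strand are internal (I); on the opposite strand of
#' an ORF (plus `antisense_flank`) antisense (A); all others intergenic (N).
#'
#' The 5'UTR length of a P/S TSS is the distance in nt from the TSS to the
#' base preceding the start codon; a TSS exactly at the start codon is
#' leaderless (length 0) and a TSS downstream of it gets a negative length.
#'
#' @param tss TSS tibble from [call_tss()] (needs `position`, `strand`,
#'   `tex_plus_count`).
#' @param genes Gene tibble (`gene_id`, `start`, `end`, `strand`) or a
#'   [genome_record()].
#' @param windows [classification_windows()].
#' @return The input tibble plus `class`, `gene_id` and `utr_length`.
#' @export
classify_tss <- function(tss, genes, windows = classification_windows()) {
  if (inherits(genes, "genome_record")) genes <- genes$genes
  genes <- as_tibble(genes)
  tss <- as_tibble(tss)
  n <- nrow(tss)
  class <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n)
  utr <- rep(NA_integer_, n)
  if (n == 0) {
    return(dplyr::mutate(tss, class = character(), gene_id = character(),
                         utr_length = integer()))
  }

  codon <- ifelse(genes$strand == "+", genes$start, genes$end)
  win_lo <- ifelse(genes$strand == "+", genes$start - windows$upstream,
                   genes$end - windows$downstream)
  win_hi <- ifelse(genes$strand == "+", genes$start + windows$downstream,
                   genes$end + windows$upstream)

  # P/S: for every TSS find its window genes, keep the nearest start codon
  assigned_gene <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hit <- which(genes$strand == tss$strand[i] &
                   tss$position[i] >= win_lo & tss$position[i] <= win_hi)
    if (length(hit) == 0) next
    d <- abs(tss$position[i] - codon[hit])
    best <- hit[d == min(d)]
    if (length(best) > 1) {
      # tie: the upstream gene, strand-aware
      best <- if (tss$strand[i] == "+") best[which.min(genes$start[best])]
              else best[which.max(genes$end[best])]
    }
    assigned_gene[i] <- best
  }
  for (gi in unique(stats::na.omit(assigned_gene))) {
    members <- which(assigned_gene == gi)
    cnt <- tss$tex_plus_count[members]
    ord <- members[order(-cnt,
                         if (genes$strand[gi] == "+") tss$position[members]
                         else -tss$position[members])]
    class[ord[1]] <- "P"
    if (length(ord) > 1) class[ord[-1]] <- "S"
    gene_id[members] <- genes$gene_id[gi]
    utr[members] <- if (genes$strand[gi] == "+") {
      genes$start[gi] - tss$position[members]
    } else {
      tss$position[members] - genes$end[gi]
    }
  }

  # I / A / N for everything left
  fl <- windows$antisense_flank
  for (i in which(is.na(class))) {
    ins <- which(tss$position[i] >= genes$start & tss$position[i] <= genes$end)
    sense <- ins[genes$strand[ins] == tss$strand[i]]
    if (length(sense) > 0) {
      class[i] <- "I"
      gene_id[i] <- genes$gene_id[pick_nearest(sense, tss$position[i], codon)]
      next
    }
    anti <- which(tss$position[i] >= genes$start - fl &
                    tss$position[i] <= genes$end + fl &
                    genes$strand != tss$strand[i])
    if (length(anti) > 0) {
      class[i] <- "A"
      gene_id[i] <- genes$gene_id[pick_nearest(anti, tss$position[i], codon)]
      next
    }
    class[i] <- "N"
  }
  dplyr::mutate(tss, class = class, gene_id = gene_id, utr_length = utr)
}

pick_nearest <- function(idx, pos, codon) {
  idx[which.min(abs(pos - codon[idx]))]
}

#' Summarize TSS classes
#'
#' @param classified Output of [classify_tss()].
#' @param genes Gene tibble or [genome_record()] (for the gene fraction).
#' @return Tibble with one row per class (`P`, `S`, `I`, `A`, `N`) and
#'   count `n`; attributes `n_genes_with_primary` and
#'   `fraction_genes_with_primary` carry the gene-level summary.
#' @export
summarize_classes <- function(classified, genes = NULL) {
  if (inherits(genes, "genome_record")) genes <- genes$genes
  if (any(is.na(classified$class))) abort("Unlabelled TSS in input.")
  lv <- c("P", "S", "I", "A", "N")
  counts <- table(factor(classified$class, levels = lv))
  out <- tibble(class = lv, n = as.integer(counts))
  if (!is.null(genes)) {
    gp <- unique(classified$gene_id[classified$class == "P"])
    attr(out, "n_genes_with_primary") <- length(gp)
    attr(out, "fraction_genes_with_primary") <- length(gp) / nrow(genes)
  }
  out
}
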