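#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a motif model into per-position base probabilities
#'
#' @param x A `motif_model`.
#' @param ... Unused.
#' @return Tibble: `position`, `base`, `count`, `prob`, `ic`.
#' @export
tidy.motif_model <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$width), each = 4L),
    base = rep(BASES, x$width),
    count = as.numeric(x$pfm),
    prob = as.numeric(x$ppm),
    ic = rep(x$information_content, each = 4L)
  )
}

#' One-row summary of a motif model
#'
#' @param x A `motif_model`.
#' @param ... Unused.
#' @return Tibble: `width`, `consensus`, `n_sites`, `n_sequences`,
#'   `occupancy`, `total_ic`, `log_likelihood`, `p_value`.
#' @export
glance.motif_model <- function(x, ...) {
  tibble(
    width = x$width, consensus = x$consensus,
    n_sites = nrow(x$sites), n_sequences = x$n_sequences,
    occupancy = x$occupancy,
    total_ic = sum(x$information_content),
    log_likelihood = x$log_likelihood,
    p_value = x$p_value
  )
}

#' Tidy 5'UTR statistics into the binned histogram
#'
#' @param x A `utr_stats`.
#' @param ... Unused.
#' @return The 10-nt-bin histogram tibble.
#' @export
tidy.utr_stats <- function(x, ...) x$histogram

#' One-row summary of 5'UTR statistics
#'
#' @param x A `utr_stats`.
#' @param ... Unused.
#' @export
glance.utr_stats <- function(x, ...) {
  tibble(
    n = length(x$lengths), median = x$median,
    fraction_lt_100 = x$fraction_lt_100,
    n_long = nrow(x$long_utrs),
    n_flagged_negative = x$n_flagged_negative
  )
}

#' Tidy a pan-genome result into the per-protein family table
#'
#' @param x A `pan_genome`.
#' @param ... Unused.
#' @export
tidy.pan_genome <- function(x, ...) x$families

#' One-row summary of a pan-genome result
#'
#' @param x A `pan_genome`.
#' @param ... Unused.
#' @return Tibble with family and gene counts per category; the totals
#'   satisfy sum(families) = n_families and sum(genes) = n_proteins.
#' @export
glance.pan_genome <- function(x, ...) {
  fs <- x$family_summary
  cat_fam <- table(factor(fs$category, c("core", "dispensable", "unique")))
  cat_gene <- tapply(fs$n_proteins,
                     factor(fs$category, c("core", "dispensable", "unique")),
                     sum, default = 0L)
  tibble(
    n_genomes = x$n_genomes,
    n_families = nrow(fs),
    n_proteins = nrow(x$families),
    core_families = as.integer(cat_fam["core"]),
    dispensable_families = as.integer(cat_fam["dispensable"]),
    unique_families = as.integer(cat_fam["unique"]),
    core_genes = as.integer(cat_gene["core"]),
    dispensable_genes = as.integer(cat_gene["dispensable"]),
    unique_genes = as.integer(cat_gene["unique"])
  )
}
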