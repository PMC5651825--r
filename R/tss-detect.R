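#' TSS detection parameters
#'
#' @param min_count Minimum raw TEX+ 5'-end count at a candidate (default 10).
#' @param min_enrichment Minimum TEX+/TEX- fold enrichment after library-size
#'   normalization, with pseudocounts (default 2).
#' @param cluster_window Candidates within this many nt on the same strand
#'   are merged into one TSS (default 5).
#' @param pseudocount Added to both normalized counts before the ratio
#'   (default 1).
#' @return A `detection_params` list.
#' @export
detection_params <- function(min_count = 10, min_enrichment = 2,
                             cluster_window = 5L, pseudocount = 1) {
  if (min_count < 1) abort("`min_count` must be at least 1.")
  if (min_enrichment <= 0) abort("`min_enrichment` must be positive.")
  if (cluster_window < 0) abort("`cluster_window` must be non-negative.")
  structure(
    list(min_count = min_count, min_enrichment = min_enrichment,
         cluster_window = as.integer(cluster_window), pseudocount = pseudocount),
    class = "detection_params"
  )
}

#' Library-size normalization of a TEX+/TEX- profile pair
#'
#' Scales each library to counts per million of its own total; raw counts
#' are retained alongside. Enrichment in [call_tss()] is computed on
#' counts rescaled to the mean depth of the two libraries so that the
#' pseudocount acts on the raw-count scale.
#'
#' @param plus,minus [end_profile()]s of equal genome length.
#' @return A `profile_pair` list with cpm vectors and library totals.
#' @export
normalize_pair <- function(plus, minus) {
  stopifnot(inherits(plus, "end_profile"), inherits(minus, "end_profile"))
  if (length(plus$fwd) != length(minus$fwd)) {
    abort("Profiles cover genomes of different lengths.")
  }
  if (plus$total == 0 || minus$total == 0) {
    abort("Zero-total library; normalization is undefined.")
  }
  structure(
    list(
      plus = plus, minus = minus,
      plus_cpm = list(fwd = plus$fwd / plus$total * 1e6,
                      rev = plus$rev / plus$total * 1e6),
      minus_cpm = list(fwd = minus$fwd / minus$total * 1e6,
                       rev = minus$rev / minus$total * 1e6)
    ),
    class = "profile_pair"
  )
}

#' Call transcription start sites from a TEX+/TEX- pair
#'
#' A position is a candidate TSS when its raw TEX+ count reaches
#' `min_count` and the pseudocounted ratio of library-size-corrected TEX+
#' to TEX- counts reaches `min_enrichment` (TEX treatment degrades
#' processed, monophosphorylated 5' ends, so genuine initiation sites are
#' enriched in TEX+). Candidates within `cluster_window` nt on the same
#' strand are merged and the position with the highest TEX+ count is kept
#' (ties resolve to the most-upstream position, strand-aware). Clusters may
#' wrap around the circular chromosome.
#'
#' @param pair A `profile_pair` from [normalize_pair()].
#' @param params [detection_params()].
#' @param circular Merge clusters across the origin (default `TRUE`).
#' @return Tibble: `position`, `strand`, `tex_plus_count`,
#'   `tex_minus_count`, `tex_plus_cpm`, `tex_minus_cpm`, `enrichment`.
#' @export
call_tss <- function(pair, params = detection_params(), circular = TRUE) {
  stopifnot(inherits(pair, "profile_pair"))
  L <- length(pair$plus$fwd)
  ref <- (pair$plus$total + pair$minus$total) / 2
  out <- list()
  for (s in c("+", "-")) {
    sl <- if (s == "+") "fwd" else "rev"
    raw_p <- pair$plus[[sl]]
    raw_m <- pair$minus[[sl]]
    eff_p <- raw_p * ref / pair$plus$total
    eff_m <- raw_m * ref / pair$minus$total
    enr <- (eff_p + params$pseudocount) / (eff_m + params$pseudocount)
    cand <- which(raw_p >= params$min_count & enr >= params$min_enrichment)
    if (length(cand) == 0) next
    cl <- cluster_positions(cand, params$cluster_window, L, circular)
    keep <- vapply(cl, function(idx) {
      cnt <- raw_p[idx]
      best <- idx[cnt == max(cnt)]
      if (s == "+") min(best) else max(best)
    }, numeric(1))
    keep <- as.integer(keep)
    out[[s]] <- tibble(
      position = keep, strand = s,
      tex_plus_count = raw_p[keep], tex_minus_count = raw_m[keep],
      tex_plus_cpm = pair$plus_cpm[[sl]][keep],
      tex_minus_cpm = pair$minus_cpm[[sl]][keep],
      enrichment = enr[keep]
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(position = integer(), strand = character(),
                  tex_plus_count = numeric(), tex_minus_count = numeric(),
                  tex_plus_cpm = numeric(), tex_minus_cpm = numeric(),
                  enrichment = numeric()))
  }
  dplyr::arrange(res, .data$position)
}

# Single-linkage clustering of sorted positions with gap <= window,
# optionally joining the first and last cluster across the origin.
cluster_positions <- function(pos, window, genome_length, circular) {
  pos <- sort(pos)
  if (length(pos) == 1) return(list(pos))
  gaps <- diff(pos)
  grp <- cumsum(c(1L, gaps > window))
  cl <- split(pos, grp)
  if (circular && length(cl) > 1) {
    wrap_gap <- pos[1] + genome_length - pos[length(pos)]
    if (wrap_gap <= window) {
      cl[[1]] <- c(cl[[length(cl)]], cl[[1]])
      cl[[length(cl)]] <- NULL
    }
  }
  unname(cl)
}

#' Export a TSS table as BED6
#'
#' Score is the TEX+ count capped at 1000, per BED convention.
#'
#' @param tss TSS tibble from [call_tss()].
#' @param path Output path.
#' @param chrom Chromosome name.
#' @return Invisibly, `path`.
#' @export
write_tss_bed <- function(tss, path, chrom = "chr") {
  bed <- data.frame(
    chrom = chrom,
    start = tss$position - 1L,
    end = tss$position,
    name = sprintf("TSS_%d", seq_len(nrow(tss))),
    score = pmin(round(tss$tex_plus_count), 1000),
    strand = tss$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
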