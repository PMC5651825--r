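check_dna_alphabet <- function(s) {
  bad <- gsub("[ACGTN]", "", s)
  if (nchar(bad) > 0) {
    abort(sprintf("Sequence contains unsupported characters ('%s'); only A/C/G/T/N are accepted.",
                  substr(bad, 1, 5)))
  }
}

#' GC content of a genome
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` bases are excluded from both the
#' numerator and the denominator.
#'
#' @param genome A [genome_record()], [Biostrings::DNAString] or character.
#' @return GC fraction in `[0, 1]`.
#' @export
#' @examples
#' gc_content("ATGC")
gc_content <- function(genome) {
  s <- toupper(seq_as_chr(genome))
  if (nchar(s) == 0) abort("Empty sequence.")
  check_dna_alphabet(s)
  f <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) abort("Sequence contains no unambiguous bases.")
  unname((f[["C"]] + f[["G"]]) / denom)
}

#' Coding density of an annotated genome
#'
#' Fraction of the genome covered by the union of CDS intervals on either
#' strand; bases covered by several (or overlapping) CDS count once.
#'
#' @param genome A [genome_record()] with a gene table.
#' @return Fraction in `[0, 1]`.
#' @export
coding_density <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  if (is.null(genome$genes) || nrow(genome$genes) == 0) {
    abort("No CDS annotation present.")
  }
  if (any(genome$genes$end > genome$length)) {
    abort("CDS features extend beyond the genome.")
  }
  ir <- IRanges::reduce(IRanges::IRanges(genome$genes$start, genome$genes$end))
  sum(IRanges::width(ir)) / genome$length
}

#' Windowed and cumulative GC skew
#'
#' Computes `(G - C) / (G + C)` in windows tiled from position 1 at the
#' given step (the final window wraps around the circular chromosome) and
#' the running sum of those values. The extrema of the cumulative curve
#' mark the replication origin and terminus.
#'
#' @param genome A [genome_record()] or sequence.
#' @param window Window size, bases (default 1000).
#' @param step Step between window starts, bases (default `window`).
#' @return A `skew_profile` tibble: `start`, `midpoint`, `skew`,
#'   `cumulative`, with `window` and `step` attributes.
#' @export
cumulative_gc_skew <- function(genome, window = 1000L, step = window) {
  s <- toupper(seq_as_chr(genome))
  L <- nchar(s)
  if (window <= 0 || step <= 0) abort("`window` and `step` must be positive.")
  if (window > L) abort("`window` exceeds the genome length.")
  check_dna_alphabet(s)
  b <- strsplit(s, "")[[1]]
  isg <- cumsum(b == "G")
  isc <- cumsum(b == "C")
  starts <- seq.int(1L, L, by = step)
  count_in <- function(cum, from, to) {
    # circular window [from, to] with to possibly > L
    if (to <= L) {
      cum[to] - (if (from > 1) cum[from - 1] else 0)
    } else {
      (cum[L] - (if (from > 1) cum[from - 1] else 0)) + cum[to - L]
    }
  }
  gs <- vapply(starts, function(x) count_in(isg, x, x + window - 1L), numeric(1))
  cs <- vapply(starts, function(x) count_in(isc, x, x + window - 1L), numeric(1))
  tot <- gs + cs
  skew <- ifelse(tot == 0, 0, (gs - cs) / tot)
  out <- tibble(
    start = starts,
    midpoint = wrap_pos(as.integer(starts + window %/% 2L), L),
    skew = skew,
    cumulative = cumsum(skew)
  )
  attr(out, "window") <- as.integer(window)
  attr(out, "step") <- as.integer(step)
  class(out) <- c("skew_profile", class(out))
  out
}

#' Locate the replication origin and terminus from cumulative GC skew
#'
#' The origin is reported at the window midpoint of the global minimum of
#' the cumulative skew curve and the terminus at the global maximum
#' (leading-strand guanine excess accumulates from the origin onwards).
#'
#' @param skew A `skew_profile` from [cumulative_gc_skew()].
#' @return One-row tibble with `origin` and `terminus` positions.
#' @export
locate_origin_terminus <- function(skew) {
  stopifnot(inherits(skew, "skew_profile"))
  if (diff(range(skew$cumulative)) == 0) {
    abort("Cumulative skew is constant; origin/terminus are undefined.")
  }
  tibble(
    origin = skew$midpoint[which.min(skew$cumulative)],
    terminus = skew$midpoint[which.max(skew$cumulative)]
  )
}

#' Table-1-style genome summary
#'
#' @param genome An annotated [genome_record()].
#' @param window,step Passed to [cumulative_gc_skew()].
#' @return One-row tibble: genome size, gene count, GC and coding-density
#'   percentages, origin and terminus positions.
#' @export
genome_summary <- function(genome, window = 1000L, step = window) {
  ot <- locate_origin_terminus(cumulative_gc_skew(genome, window, step))
  tibble(
    genome_size_bp = genome$length,
    n_genes = if (is.null(genome$genes)) 0L else nrow(genome$genes),
    gc_percent = round(100 * gc_content(genome), 1),
    coding_density_percent = round(100 * coding_density(genome), 1),
    origin = ot$origin,
    terminus = ot$terminus
  )
}
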