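#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Map an arbitrary integer position onto a circular genome of length `len`.
wrap_pos <- function(pos, len) {
  ((pos - 1L) %% len) + 1L
}

# Promoter-style offsets relative to a +1 anchor: there is no offset 0, so
# offset -1 is the base immediately 5' of the anchor and +1 the anchor itself.
offsets_to_positions <- function(anchor, strand, from, to, len) {
  stopifnot(from <= to)
  offs <- setdiff(seq.int(from, to), 0L)
  rel <- ifelse(offs > 0L, offs - 1L, offs)
  if (strand == "+") wrap_pos(anchor + rel, len) else wrap_pos(anchor - rel, len)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

seq_as_chr <- function(x) {
  if (inherits(x, "genome_record")) x <- x$seq
  if (inherits(x, "XString") || inherits(x, "XStringSet")) {
    x <- as.character(x)
  }
  unname(x)[1]
}

#' Percentage formatter used in reports
#'
#' Computes `100 * numerator / denominator` rounded to `digits` decimal
#' places, the convention used for every percentage the summary report
#' prints (fraction of genes with a primary TSS, motif conservation, GC
#' content, coding density, ...).
#'
#' @param numerator,denominator Non-negative numbers.
#' @param digits Decimal places to keep (default 1, the reporting convention).
#' @return A single number, e.g. `pct_of(1, 3)` is `33.3`.
#' @export
#' @examples
#' pct_of(1253, 4090)
pct_of <- function(numerator, denominator, digits = 1) {
  if (denominator <= 0) abort("`denominator` must be positive.")
  round(100 * numerator / denominator, digits)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
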