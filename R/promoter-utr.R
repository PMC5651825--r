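#' Discover -10 and -35 promoter motifs around a TSS set
#'
#' Extracts the 20 bases upstream of every TSS (offsets -20..-1) to find
#' the -10 element, and offsets -50..-21 to find the -35 element, each by
#' ZOOPS EM ([discover_motif()]).
#'
#' @param tss TSS tibble (`position`, `strand`).
#' @param genome A [genome_record()].
#' @param width Motif width (default 6).
#' @param ... Passed to [discover_motif()].
#' @return A `promoter_motifs` list: `minus10`, `minus35` (motif models),
#'   the window offset ranges, and the windows themselves.
#' @export
discover_promoters <- function(tss, genome, width = 6L, ...) {
  w10 <- extract_windows(tss, genome, -20L, -1L)
  w35 <- extract_windows(tss, genome, -50L, -21L)
  structure(
    list(
      minus10 = discover_motif(w10, width, ...),
      minus35 = discover_motif(w35, width, ...),
      minus10_range = c(-20L, -1L), minus35_range = c(-50L, -21L),
      minus10_windows = w10, minus35_windows = w35
    ),
    class = "promoter_motifs"
  )
}

#' Per-TSS promoter architecture and -35/-10 spacer distribution
#'
#' Converts motif site offsets back to TSS-relative coordinates and, for
#' every TSS carrying both elements, computes the spacer as the number of
#' nt strictly between the -35 and the -10 box. A negative spacer
#' (overlapping boxes) is kept and flagged.
#'
#' @param promoters A `promoter_motifs` from [discover_promoters()], or a
#'   list with `minus10`/`minus35` motif models and window ranges.
#' @param tss The TSS tibble the motifs were discovered on.
#' @return A list of class `promoter_architecture`: `per_tss` tibble
#'   (`position`, `strand`, `minus10_offset`, `minus35_offset`, `spacer`,
#'   `architecture`, `spacer_flagged`), `spacer_histogram` tibble and
#'   `fractions` (both / minus10_only / minus35_only / neither).
#' @export
promoter_architecture <- function(promoters, tss) {
  n <- nrow(tss)
  w <- promoters$minus10$width
  site10 <- promoters$minus10$sites
  site35 <- promoters$minus35$sites
  off10 <- rep(NA_integer_, n)
  off35 <- rep(NA_integer_, n)
  # window position j (1-based) starts at the range lower offset
  off10[site10$seq] <- promoters$minus10_range[1] + site10$offset - 1L
  off35[site35$seq] <- promoters$minus35_range[1] + site35$offset - 1L
  spacer <- off10 - (off35 + w - 1L) - 1L
  arch <- dplyr::case_when(
    !is.na(off10) & !is.na(off35) ~ "both",
    !is.na(off10) ~ "minus10_only",
    !is.na(off35) ~ "minus35_only",
    TRUE ~ "neither"
  )
  per_tss <- tibble(
    position = tss$position, strand = tss$strand,
    minus10_offset = off10, minus35_offset = off35,
    spacer = ifelse(arch == "both", spacer, NA_integer_),
    architecture = arch,
    spacer_flagged = !is.na(spacer) & arch == "both" & spacer < 0
  )
  sp <- per_tss$spacer[!is.na(per_tss$spacer)]
  hist <- dplyr::count(tibble(spacer = sp), .data$spacer, name = "n")
  fr <- prop.table(table(factor(arch, c("both", "minus10_only",
                                        "minus35_only", "neither"))))
  structure(
    list(per_tss = per_tss, spacer_histogram = hist,
         fractions = stats::setNames(as.numeric(fr), names(fr))),
    class = "promoter_architecture"
  )
}

#' Base composition around the TSS
#'
#' Per-offset A/C/G/T frequencies at offsets -2, -1, +1, +2, +3 (two bases
#' either side of the initiating +1 base), with the pyrimidine fraction at
#' -1 and purine fraction at +1 attached — bacterial promoters typically
#' initiate on a purine preceded by a pyrimidine.
#'
#' @param tss TSS tibble (`position`, `strand`).
#' @param genome A [genome_record()].
#' @return Tibble `offset` x `A`,`C`,`G`,`T` frequencies; attributes
#'   `pyrimidine_minus1` and `purine_plus1`.
#' @export
composition_at_tss <- function(tss, genome) {
  wins <- extract_windows(tss, genome, -2L, 3L)   # offsets -2,-1,+1,+2,+3
  m <- do.call(rbind, strsplit(wins, ""))
  offsets <- c(-2L, -1L, 1L, 2L, 3L)
  freq <- t(apply(m, 2, function(col) {
    prop.table(table(factor(col, BASES)))
  }))
  out <- as_tibble(as.data.frame(freq))
  names(out) <- BASES
  out <- dplyr::bind_cols(tibble(offset = offsets), out)
  attr(out, "pyrimidine_minus1") <- sum(out$C[2], out$T[2])
  attr(out, "purine_plus1") <- sum(out$A[3], out$G[3])
  out
}

#' 5'UTR length statistics of primary TSSs
#'
#' @param classified Output of [classify_tss()]; rows with class `P` and a
#'   UTR length are used.
#' @param classes TSS classes to include (default `"P"`).
#' @return A `utr_stats` object: `lengths`, a 10-nt-bin `histogram`
#'   tibble (`bin_start`, `bin_end`, `n`), `median`, `fraction_lt_100`,
#'   and `long_utrs` (rows with length > 100 nt).
#' @export
compute_utrs <- function(classified, classes = "P") {
  rows <- classified[classified$class %in% classes & !is.na(classified$utr_length), ]
  neg <- rows$utr_length < 0
  if (any(neg)) {
    warn(sprintf("%d primary TSS(s) lie downstream of their start codon; negative 5'UTR lengths flagged and excluded.",
                 sum(neg)))
    rows <- rows[!neg, ]
  }
  lengths <- rows$utr_length
  if (length(lengths) == 0) {
    hist <- tibble(bin_start = integer(), bin_end = integer(), n = integer())
  } else {
    bins <- lengths %/% 10L
    tab <- table(factor(bins, levels = 0:max(bins)))
    hist <- tibble(
      bin_start = as.integer(names(tab)) * 10L,
      bin_end = as.integer(names(tab)) * 10L + 9L,
      n = as.integer(tab)
    )
  }
  structure(
    list(
      lengths = lengths,
      histogram = hist,
      median = if (length(lengths)) stats::median(lengths) else NA_real_,
      fraction_lt_100 = if (length(lengths)) mean(lengths < 100) else NA_real_,
      long_utrs = rows[rows$utr_length > 100, ],
      n_flagged_negative = sum(neg)
    ),
    class = "utr_stats"
  )
}

#' @export
print.utr_stats <- function(x, ...) {
  cat(sprintf("<utr_stats> %d 5'UTRs, median %.0f nt, %.1f%% < 100 nt, %d > 100 nt\n",
              length(x$lengths), x$median, 100 * x$fraction_lt_100,
              nrow(x$long_utrs)))
  invisible(x)
}

#' Search for ribosome-binding sites upstream of start codons
#'
#' Scans the window from -17 to +3 nt around each gene's start codon (the
#' region a Shine-Dalgarno element can occupy) for the best match to a
#' degenerate consensus (default `GGAGR`, `R` = A/G). Scoring is log2 odds
#' against a uniform background with near-one-hot consensus columns, and a
#' hit requires a score within 2 bits of the perfect match. The spacer is
#' the number of nt between the last base of the match and the base before
#' the start codon. Windows that would extend past the TSS (5'UTR shorter
#' than 17 nt) are truncated and flagged.
#'
#' @param classified Output of [classify_tss()]; rows of class `P` with a
#'   gene are scanned.
#' @param genome A [genome_record()] (with gene table).
#' @param consensus Degenerate consensus over A/C/G/T/R (default `"GGAGR"`).
#' @param classes Classes to scan (default `"P"`).
#' @return Tibble: `gene_id`, `tss_position`, `strand`, `rbs_seq`,
#'   `spacer`, `score_bits`, `truncated`, `hit`.
#' @export
find_rbs <- function(classified, genome, consensus = "GGAGR", classes = "P") {
  genes <- genome$genes
  rows <- classified[classified$class %in% classes & !is.na(classified$gene_id), ]
  cons <- strsplit(toupper(consensus), "")[[1]]
  k <- length(cons)
  # log2-odds column scores vs uniform background
  col_score <- function(base, cc) {
    if (cc == "R") {
      if (base %in% PURINES) log2(0.485 / 0.25) else log2(0.015 / 0.25)
    } else {
      if (base == cc) log2(0.97 / 0.25) else log2(0.01 / 0.25)
    }
  }
  perfect <- sum(vapply(seq_len(k), function(i) {
    col_score(if (cons[i] == "R") "A" else cons[i], cons[i])
  }, numeric(1)))
  threshold <- perfect - 2

  out <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    gi <- match(rows$gene_id[i], genes$gene_id)
    codon <- if (genes$strand[gi] == "+") genes$start[gi] else genes$end[gi]
    utr <- rows$utr_length[i]
    upstream <- min(17L, max(utr, 0L))
    truncated <- upstream < 17L
    if (upstream < k) {
      return(tibble(gene_id = rows$gene_id[i], tss_position = rows$position[i],
                    strand = rows$strand[i], rbs_seq = NA_character_,
                    spacer = NA_integer_, score_bits = NA_real_,
                    truncated = TRUE, hit = FALSE))
    }
    win <- extract_windows(
      tibble(position = codon, strand = genes$strand[gi]),
      genome, -upstream, 3L
    )
    b <- strsplit(win, "")[[1]]
    n_up <- upstream                       # window positions 1..n_up are upstream
    starts <- seq_len(n_up - k + 1L)       # keep the match inside the 5'UTR
    scores <- vapply(starts, function(p) {
      sum(vapply(seq_len(k), function(j) col_score(b[p + j - 1L], cons[j]),
                 numeric(1)))
    }, numeric(1))
    best <- which.max(scores)
    q <- starts[best] + k - 1L             # window position of the last RBS base
    spacer <- n_up - q
    hit <- scores[best] >= threshold
    tibble(
      gene_id = rows$gene_id[i], tss_position = rows$position[i],
      strand = rows$strand[i],
      rbs_seq = if (hit) paste(b[starts[best]:q], collapse = "") else NA_character_,
      spacer = if (hit) as.integer(spacer) else NA_integer_,
      score_bits = scores[best], truncated = truncated, hit = hit
    )
  })
  out
}
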