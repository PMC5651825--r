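#' Construct a 5'-end count profile
#'
#' Per-position, strand-resolved counts of read 5' ends for one library.
#'
#' @param library Library label, e.g. `"TEXplus"`.
#' @param fwd,rev Non-negative integer count vectors, one entry per genome
#'   position, forward and reverse strand.
#' @return An `end_profile` with fields `library`, `fwd`, `rev`, `total`.
#' @export
end_profile <- function(library, fwd, rev) {
  if (length(fwd) != length(rev)) abort("fwd and rev counts must have equal length.")
  if (any(fwd < 0) || any(rev < 0)) abort("5'-end counts must be non-negative.")
  structure(
    list(library = library, fwd = as.numeric(fwd), rev = as.numeric(rev),
         total = sum(fwd) + sum(rev)),
    class = "end_profile"
  )
}

#' @export
print.end_profile <- function(x, ...) {
  cat(sprintf("<end_profile> %s: %s positions, %s 5' ends\n",
              x$library, format(length(x$fwd), big.mark = ","),
              format(x$total, big.mark = ",")))
  invisible(x)
}

#' Simulate TEX+/TEX- 5'-end count profiles
#'
#' Draws Poisson 5'-end counts at every planted TSS (mean
#' `tss_read_mean * strength` in TEX+, divided by `tex_enrichment` in TEX-),
#' the inverted ratio at processed 5'-end sites, and a low uniform Poisson
#' background everywhere, reproducing the differential signal that TEX
#' treatment creates: triphosphorylated primary 5' ends survive the
#' exonuclease, monophosphorylated processed ends do not.
#'
#' @param genome A [genome_record()].
#' @param truth Ground truth list from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return List with `tex_plus` and `tex_minus` [end_profile()]s.
#' @export
simulate_end_profiles <- function(genome, truth, config) {
  stopifnot(inherits(genome, "genome_record"), inherits(config, "sim_config"))
  tss <- truth$tss
  if (nrow(tss) > 0 && any(tss$position < 1 | tss$position > genome$length)) {
    abort("Ground-truth TSS positions fall outside the genome.")
  }
  local_seed(config$seed + 1L, {
    L <- genome$length
    mats <- list(
      plus_fwd = numeric(L), plus_rev = numeric(L),
      minus_fwd = numeric(L), minus_rev = numeric(L)
    )
    add <- function(slot, pos, lambda) {
      mats[[slot]][pos] <<- mats[[slot]][pos] + stats::rpois(length(pos), lambda)
    }
    for (s in c("+", "-")) {
      sl <- if (s == "+") "fwd" else "rev"
      t_s <- tss[tss$strand == s, ]
      if (nrow(t_s) > 0) {
        lam <- config$tss_read_mean * t_s$strength
        add(paste0("plus_", sl), t_s$position, lam)
        add(paste0("minus_", sl), t_s$position, lam / config$tex_enrichment)
      }
      p_s <- truth$processed_sites[truth$processed_sites$strand == s, ]
      if (nrow(p_s) > 0) {
        add(paste0("minus_", sl), p_s$position, config$tss_read_mean)
        add(paste0("plus_", sl), p_s$position,
            config$tss_read_mean / config$tex_enrichment)
      }
    }
    if (config$noise_mean > 0) {
      for (slot in names(mats)) {
        mats[[slot]] <- mats[[slot]] + stats::rpois(L, config$noise_mean)
      }
    }
    list(
      tex_plus = end_profile("TEXplus", mats$plus_fwd, mats$plus_rev),
      tex_minus = end_profile("TEXminus", mats$minus_fwd, mats$minus_rev)
    )
  })
}

#' Simulate multi-genome proteomes with core/dispensable/unique families
#'
#' Each family descends from a random ancestral protein; every member genome
#' receives a copy mutated to the requested amino-acid identity. Core
#' families are present in all genomes, unique families in exactly one, and
#' dispensable families in a uniformly sampled subset of 2 to n-1 genomes.
#'
#' @param config A [sim_config()] (only the seed is used).
#' @param n_genomes Number of genomes (>= 3).
#' @param n_families Number of protein families.
#' @param category_fractions Named or positional fractions
#'   (core, dispensable, unique) summing to 1.
#' @param identity Expected amino-acid identity of members to the ancestor,
#'   in (0, 1].
#' @param protein_length Length range of ancestral proteins, residues.
#' @return List with `proteomes` (named list of [Biostrings::AAStringSet],
#'   ids `<genome>|<protein>`) and `truth` (tibble: protein_id, genome,
#'   family, category).
#' @export
simulate_proteomes <- function(config, n_genomes = 5L, n_families = 60L,
                               category_fractions = c(core = 0.35, dispensable = 0.45, unique = 0.20),
                               identity = 0.9,
                               protein_length = c(120L, 300L)) {
  stopifnot(inherits(config, "sim_config"))
  if (n_genomes < 3) abort("`n_genomes` must be at least 3.")
  if (identity <= 0 || identity > 1) abort("`identity` must lie in (0, 1].")
  if (abs(sum(category_fractions) - 1) > 1e-8) {
    abort("`category_fractions` must sum to 1.")
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  local_seed(config$seed + 2L, {
    n_cat <- round(category_fractions * n_families)
    n_cat[1] <- n_families - sum(n_cat[-1])
    categories <- rep(c("core", "dispensable", "unique"), times = n_cat)
    genomes <- sprintf("g%02d", seq_len(n_genomes))
    rows <- list()
    seqs <- stats::setNames(vector("list", n_genomes), genomes)
    for (f in seq_along(categories)) {
      len <- sample(protein_length[1]:protein_length[2], 1L)
      anc <- sample(aa, len, replace = TRUE)
      members <- switch(categories[f],
        core = seq_len(n_genomes),
        unique = sample.int(n_genomes, 1L),
        dispensable = sample.int(n_genomes, sample(2:(n_genomes - 1L), 1L))
      )
      fam_id <- sprintf("fam%04d", f)
      for (m in members) {
        p <- anc
        hit <- which(stats::runif(len) < 1 - identity)
        for (h in hit) p[h] <- sample(setdiff(aa, p[h]), 1L)
        pid <- paste0(genomes[m], "|", fam_id)
        seqs[[m]][[pid]] <- paste(p, collapse = "")
        rows[[length(rows) + 1L]] <- tibble(
          protein_id = pid, genome = genomes[m],
          family = fam_id, category = categories[f]
        )
      }
    }
    proteomes <- lapply(seqs, function(x) {
      Biostrings::AAStringSet(unlist(x))
    })
    list(proteomes = proteomes, truth = dplyr::bind_rows(rows))
  })
}
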