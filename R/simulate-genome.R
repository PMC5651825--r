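#' Simulate a bacterial genome with planted transcription architecture
#'
#' Generates a circular genome in which each gene slot carries, with the
#' configured probabilities, a primary TSS at the sampled 5'UTR distance
#' upstream of its start codon, an optional weaker secondary TSS further
#' upstream, a -10 box whose 3' end sits 7 nt upstream of the TSS
#' (canonical sigma-70 geometry), an optional -35 box at a 16-18 nt spacer,
#' a pyrimidine-biased -1 / purine-biased +1 dinucleotide, and a
#' Shine-Dalgarno element at a 5-10 nt spacer from the start codon.
#' Antisense and intergenic TSSs are planted in gene bodies (opposite
#' strand) and in gaps. Every planted element is recorded in the returned
#' ground truth.
#'
#' Genes are laid out one per equal-sized slot, alternating strand at
#' random, with enough clearance that regulatory elements of neighbouring
#' genes can never collide; the generator errors if the genome is too short
#' for the requested gene count.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` (a [genome_record()]) and `truth`,
#'   itself a list of tibbles: `tss` (position, strand, class, gene_id,
#'   strength, utr_length), `motif_sites`, `rbs_sites`, `processed_sites`.
#' @export
#' @examples
#' sim <- simulate_genome(sim_config(genome_length = 40000, n_genes = 20, seed = 1))
#' sim$genome
#' head(sim$truth$tss)
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  local_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  L <- cfg$genome_length
  margin <- 300L        # upstream clearance reserved for TSS + promoter
  gap <- 60L            # clearance left after each gene within its slot
  slot <- L %/% cfg$n_genes
  if (slot < margin + cfg$gene_length[2] + gap) {
    abort(sprintf(
      "Genome too short: %d genes of up to %d bp need at least %d bp.",
      cfg$n_genes, cfg$gene_length[2],
      cfg$n_genes * (margin + cfg$gene_length[2] + gap)
    ))
  }

  gc <- cfg$gc
  g <- sample(BASES, L, replace = TRUE,
              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  genes <- tibble(
    gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
    start = NA_integer_, end = NA_integer_,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  )
  tss_rows <- list()
  motif_rows <- list()
  rbs_rows <- list()

  mutate_bases <- function(b) {
    hit <- stats::runif(length(b)) < cfg$per_base_mutation_rate
    b[hit] <- sample(BASES, sum(hit), replace = TRUE)
    b
  }
  comp <- function(b) chartr("ACGT", "TGCA", b)

  write_sense <- function(bases, tss, strand, off_start) {
    # bases: sense-orientation characters at consecutive offsets from the TSS
    offs <- off_start + seq_along(bases) - 1L
    if (strand == "+") {
      pos <- wrap_pos(tss + offs, L)
      g[pos] <<- bases
    } else {
      pos <- wrap_pos(tss - offs, L)
      g[pos] <<- comp(bases)
    }
    pos
  }

  plant_hexamer <- function(consensus, tss, strand, off_start, element, spacer = NA_integer_) {
    b <- mutate_bases(strsplit(consensus, "")[[1]])
    pos <- write_sense(b, tss, strand, off_start)
    motif_rows[[length(motif_rows) + 1L]] <<- tibble(
      tss = tss, strand = strand, element = element,
      offset_start = off_start, offset_end = off_start + length(b) - 1L,
      genome_start = min(pos), genome_end = max(pos),
      planted_seq = paste(b, collapse = ""), spacer = spacer
    )
  }

  plant_tss_elements <- function(tss, strand) {
    # -1 pyrimidine / +1 purine biased dinucleotide, then -10 and maybe -35
    b_m1 <- if (stats::runif(1) < cfg$pyrimidine_bias) sample(PYRIMIDINES, 1) else sample(PURINES, 1)
    b_p1 <- if (stats::runif(1) < cfg$purine_bias) sample(PURINES, 1) else sample(PYRIMIDINES, 1)
    if (strand == "+") {
      g[wrap_pos(tss - 1L, L)] <<- b_m1
      g[tss] <<- b_p1
    } else {
      g[wrap_pos(tss + 1L, L)] <<- comp(b_m1)
      g[tss] <<- comp(b_p1)
    }
    plant_hexamer(cfg$minus10_consensus, tss, strand, -12L, "minus10")
    if (stats::runif(1) < cfg$p_minus35_present) {
      spacer <- sample(rep(cfg$spacer_dist, 2L), 1L)
      plant_hexamer(cfg$minus35_consensus, tss, strand, -12L - spacer - 6L,
                    "minus35", spacer = spacer)
    }
  }

  sample_utr <- function() {
    u <- if (stats::runif(1) < cfg$utr_tail_prob) {
      sample(cfg$utr_tail_range[1]:cfg$utr_tail_range[2], 1L)
    } else {
      cfg$utr_body_min + stats::rnbinom(1L, size = cfg$utr_body_size, mu = cfg$utr_body_mu)
    }
    min(u, 250L)
  }

  add_tss <- function(pos, strand, class, gene_id, strength, utr) {
    tss_rows[[length(tss_rows) + 1L]] <<- tibble(
      position = as.integer(pos), strand = strand, class = class,
      gene_id = gene_id, strength = strength, utr_length = as.integer(utr)
    )
  }

  for (i in seq_len(cfg$n_genes)) {
    lo <- (i - 1L) * slot + 1L
    hi <- i * slot
    len <- sample(cfg$gene_length[1]:cfg$gene_length[2], 1L)
    strand <- genes$strand[i]
    if (strand == "+") {
      start <- lo + margin
      end <- start + len - 1L
      g[start:(start + 2L)] <- c("A", "T", "G")
    } else {
      end <- hi - margin
      start <- end - len + 1L
      g[(end - 2L):end] <- c("C", "A", "T")
    }
    genes$start[i] <- start
    genes$end[i] <- end
    codon_pos <- if (strand == "+") start else end

    if (stats::runif(1) < cfg$p_primary_tss) {
      utr <- sample_utr()
      tss <- if (strand == "+") start - utr else end + utr
      plant_tss_elements(tss, strand)
      add_tss(tss, strand, "P", genes$gene_id[i], 1, utr)

      # Shine-Dalgarno element inside the UTR, spacer nt before the start codon
      feas <- cfg$rbs_spacer_dist[cfg$rbs_spacer_dist + 5L <= utr]
      if (length(feas) > 0) {
        r <- sample(rep(feas, 2L), 1L)
        rbs <- strsplit(cfg$rbs_consensus, "")[[1]]
        rbs[rbs == "R"] <- sample(PURINES, sum(rbs == "R"), replace = TRUE)
        rbs <- mutate_bases(rbs)
        k <- length(rbs)
        if (strand == "+") {
          pos <- (start - r - k):(start - r - 1L)
          g[pos] <- rbs
        } else {
          pos <- (end + r + 1L):(end + r + k)
          g[pos] <- rev(comp(rbs))
        }
        rbs_rows[[length(rbs_rows) + 1L]] <- tibble(
          gene_id = genes$gene_id[i], tss = tss, strand = strand,
          spacer = r, planted_seq = paste(rbs, collapse = ""),
          genome_start = min(pos), genome_end = max(pos)
        )
      }

      # Weaker secondary TSS well upstream of the primary promoter
      if (stats::runif(1) < cfg$p_secondary && utr <= 200L) {
        d <- sample(45:55, 1L)
        stss <- if (strand == "+") tss - d else tss + d
        plant_tss_elements(stss, strand)
        add_tss(stss, strand, "S", genes$gene_id[i], cfg$secondary_strength,
                utr + d)
      }
    }
  }

  # Antisense TSSs: inside a gene body, opposite strand
  if (cfg$n_antisense_tss > 0) {
    hosts <- sample(seq_len(cfg$n_genes), cfg$n_antisense_tss,
                    replace = cfg$n_antisense_tss > cfg$n_genes)
    for (i in hosts) {
      p <- sample((genes$start[i] + 45L):(genes$end[i] - 5L), 1L)
      s <- if (genes$strand[i] == "+") "-" else "+"
      plant_tss_elements(p, s)
      add_tss(p, s, "A", genes$gene_id[i], 1, NA_integer_)
    }
  }

  # Intergenic TSSs: in the gap left at the end of a slot, clear of every
  # classification window
  if (cfg$n_intergenic_tss > 0) {
    placed <- 0L
    tries <- 0L
    existing <- function() vapply(tss_rows, function(r) r$position, integer(1))
    while (placed < cfg$n_intergenic_tss && tries < 50L * cfg$n_intergenic_tss) {
      tries <- tries + 1L
      i <- sample(seq_len(cfg$n_genes), 1L)
      lo <- (i - 1L) * slot + 1L
      hi <- i * slot
      region <- if (genes$strand[i] == "+") {
        c(genes$end[i] + 45L, hi - 45L)          # after a + gene: plain gap
      } else {
        c(lo + 45L, genes$start[i] - 45L)        # before a - gene body
      }
      if (region[2] - region[1] < 10L) next
      p <- sample(region[1]:region[2], 1L)
      s <- sample(c("+", "-"), 1L)
      cls <- locate_class_simple(p, s, genes, upstream = 300L, downstream = 100L)
      if (cls != "N") next
      if (any(abs(existing() - p) < 90L)) next
      plant_tss_elements(p, s)
      add_tss(p, s, "N", NA_character_, 1, NA_integer_)
      placed <- placed + 1L
    }
    if (placed < cfg$n_intergenic_tss) {
      warn(sprintf("Placed only %d of %d intergenic TSSs.", placed,
                   cfg$n_intergenic_tss))
    }
  }

  tss <- dplyr::bind_rows(tss_rows)
  if (nrow(tss) > 0) {
    tss <- dplyr::arrange(tss, .data$position)
  } else {
    tss <- tibble(position = integer(), strand = character(),
                  class = character(), gene_id = character(),
                  strength = numeric(), utr_length = integer())
  }

  # Processed 5' ends: monophosphorylated background sites, kept clear of
  # true TSSs so detection clusters stay unambiguous
  processed <- tibble(position = integer(), strand = character())
  if (cfg$n_processed_sites > 0) {
    pool <- sample.int(L, min(L, 20L * cfg$n_processed_sites))
    keep <- integer(0)
    for (p in pool) {
      if (length(keep) >= cfg$n_processed_sites) break
      if (nrow(tss) == 0 || min(abs(tss$position - p)) > 10L) {
        keep <- c(keep, p)
      }
    }
    processed <- tibble(
      position = as.integer(keep),
      strand = sample(c("+", "-"), length(keep), replace = TRUE)
    )
  }

  genome <- genome_record(paste(g, collapse = ""), genes, circular = TRUE)
  truth <- list(
    tss = tss,
    motif_sites = dplyr::bind_rows(motif_rows),
    rbs_sites = dplyr::bind_rows(rbs_rows),
    processed_sites = processed
  )
  list(genome = genome, truth = truth)
}

# Minimal positional classifier used by the generator to certify planted
# antisense/intergenic labels under the default windows.
locate_class_simple <- function(pos, strand, genes, upstream, downstream) {
  for (i in seq_len(nrow(genes))) {
    gs <- genes$strand[i]
    win <- if (gs == "+") {
      c(genes$start[i] - upstream, genes$start[i] + downstream)
    } else {
      c(genes$end[i] - downstream, genes$end[i] + upstream)
    }
    if (strand == gs && pos >= win[1] && pos <= win[2]) return("P")
  }
  for (i in seq_len(nrow(genes))) {
    inside <- pos >= genes$start[i] && pos <= genes$end[i]
    if (inside && strand == genes$strand[i]) return("I")
    if (inside && strand != genes$strand[i]) return("A")
  }
  "N"
}
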