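#' Simulation configuration for the synthetic dRNA-seq generator
#'
#' Bundles every tunable of the synthetic-data module: genome and gene
#' geometry, promoter architecture (-10/-35 consensus, spacer distribution,
#' per-base mutation rate), 5'UTR and ribosome-binding-site spacing, the
#' TEX+/TEX- read model (Poisson site counts over uniform background), and
#' counts of antisense, intergenic and processed-5'-end sites.
#'
#' The defaults describe a 200 kb genome with 100 genes, ten-fold TEX
#' enrichment at true TSSs and canonical sigma-70 promoter geometry
#' (TATAAT/TTGACA separated by a 16-18 nt spacer); the -1 position is
#' pyrimidine-biased and the +1 position purine-biased, as observed in
#' bacterial primary transcriptomes.
#'
#' @param genome_length Genome size in bases (circular).
#' @param n_genes Number of non-overlapping protein-coding genes to place.
#' @param gene_length Length range (min, max) for genes, bases.
#' @param p_primary_tss Probability a gene receives a primary TSS.
#' @param p_secondary Probability a gene with a TSS also gets a weaker
#'   secondary TSS in its upstream window.
#' @param utr_tail_prob Probability a 5'UTR is drawn from the long tail
#'   (uniform on `utr_tail_range`) rather than the short-mode body.
#' @param utr_tail_range Long-tail 5'UTR range, nt.
#' @param utr_body_mu,utr_body_size Negative-binomial body of the 5'UTR
#'   length distribution (added to `utr_body_min`); defaults put the modal
#'   length in the low twenties of nt.
#' @param utr_body_min Minimum body 5'UTR length, nt.
#' @param minus10_consensus,minus35_consensus Planted promoter hexamers.
#' @param p_minus35_present Probability a planted promoter carries a -35 box.
#' @param spacer_dist Support of the -35/-10 spacer distribution (nt,
#'   subset of 16:18; sampled uniformly).
#' @param per_base_mutation_rate Probability each planted consensus base is
#'   replaced by a uniformly random base.
#' @param rbs_consensus Shine-Dalgarno consensus; `R` means A or G.
#' @param rbs_spacer_dist Support of the RBS-to-start-codon spacer, nt.
#' @param pyrimidine_bias Probability the -1 base is a pyrimidine (C/T).
#' @param purine_bias Probability the +1 (TSS) base is a purine (A/G).
#' @param tss_read_mean Expected TEX+ 5'-end count at a primary TSS.
#' @param secondary_strength Multiplier on `tss_read_mean` for secondary TSSs.
#' @param tex_enrichment Fold enrichment of true TSS 5' ends in TEX+ over
#'   TEX-; processed sites get the inverse ratio. Must exceed 1.
#' @param noise_mean Mean of the uniform per-position Poisson background.
#' @param n_processed_sites Number of processed 5'-end sites (TEX-enriched
#'   in the untreated library).
#' @param n_antisense_tss,n_intergenic_tss Numbers of antisense and
#'   intergenic TSSs to plant.
#' @param gc Background GC fraction of the simulated genome.
#' @param seed Integer seed; identical configs give byte-identical output.
#' @return A `sim_config` list, validated.
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 20000, n_genes = 10, seed = 1)
sim_config <- function(genome_length = 200000L,
                       n_genes = 100L,
                       gene_length = c(600L, 1500L),
                       p_primary_tss = 0.9,
                       p_secondary = 0.15,
                       utr_tail_prob = 0.12,
                       utr_tail_range = c(100L, 250L),
                       utr_body_mu = 21,
                       utr_body_size = 3,
                       utr_body_min = 12L,
                       minus10_consensus = "TATAAT",
                       minus35_consensus = "TTGACA",
                       p_minus35_present = 0.7,
                       spacer_dist = c(16L, 17L, 18L),
                       per_base_mutation_rate = 0.05,
                       rbs_consensus = "GGAGR",
                       rbs_spacer_dist = 5:10,
                       pyrimidine_bias = 0.86,
                       purine_bias = 0.94,
                       tss_read_mean = 100,
                       secondary_strength = 0.3,
                       tex_enrichment = 10,
                       noise_mean = 0.05,
                       n_processed_sites = 50L,
                       n_antisense_tss = 10L,
                       n_intergenic_tss = 10L,
                       gc = 0.472,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length), p_primary_tss = p_primary_tss,
    p_secondary = p_secondary, utr_tail_prob = utr_tail_prob,
    utr_tail_range = as.integer(utr_tail_range), utr_body_mu = utr_body_mu,
    utr_body_size = utr_body_size, utr_body_min = as.integer(utr_body_min),
    minus10_consensus = toupper(minus10_consensus),
    minus35_consensus = toupper(minus35_consensus),
    p_minus35_present = p_minus35_present,
    spacer_dist = as.integer(spacer_dist),
    per_base_mutation_rate = per_base_mutation_rate,
    rbs_consensus = toupper(rbs_consensus),
    rbs_spacer_dist = as.integer(rbs_spacer_dist),
    pyrimidine_bias = pyrimidine_bias, purine_bias = purine_bias,
    tss_read_mean = tss_read_mean, secondary_strength = secondary_strength,
    tex_enrichment = tex_enrichment, noise_mean = noise_mean,
    n_processed_sites = as.integer(n_processed_sites),
    n_antisense_tss = as.integer(n_antisense_tss),
    n_intergenic_tss = as.integer(n_intergenic_tss),
    gc = gc, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$genome_length <= 0) abort("`genome_length` must be positive.")
  for (p in c("p_primary_tss", "p_secondary", "p_minus35_present",
              "per_base_mutation_rate", "pyrimidine_bias", "purine_bias",
              "utr_tail_prob", "gc")) {
    if (!is_prob(cfg[[p]])) abort(paste0("`", p, "` must be a probability in [0, 1]."))
  }
  if (cfg$tex_enrichment <= 1) abort("`tex_enrichment` must exceed 1.")
  if (!all(cfg$spacer_dist %in% 16:18)) {
    abort("`spacer_dist` support must be a subset of {16, 17, 18} nt.")
  }
  if (length(cfg$gene_length) != 2 || cfg$gene_length[1] > cfg$gene_length[2]) {
    abort("`gene_length` must be an increasing (min, max) pair.")
  }
  if (!grepl("^[ACGTR]+$", cfg$rbs_consensus)) {
    abort("`rbs_consensus` may contain only A, C, G, T and R.")
  }
  if (!grepl("^[ACGT]{6}$", cfg$minus10_consensus) ||
      !grepl("^[ACGT]{6}$", cfg$minus35_consensus)) {
    abort("Promoter consensus sequences must be 6-mers over A/C/G/T.")
  }
  invisible(cfg)
}

#' Construct a genome record
#'
#' A circular genome sequence plus its strand-aware CDS annotation.
#'
#' @param seq Genome sequence: character string or [Biostrings::DNAString].
#' @param genes Tibble with columns `gene_id`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates; `start <= end` on both strands, with the
#'   start codon at `start` on `+` and at `end` on `-`). May be `NULL`.
#' @param circular Is the chromosome circular? Default `TRUE`.
#' @return A `genome_record`.
#' @export
genome_record <- function(seq, genes = NULL, circular = TRUE) {
  seq <- toupper(seq_as_chr(seq))
  len <- nchar(seq)
  if (len == 0) abort("Genome sequence is empty.")
  if (!is.null(genes)) {
    genes <- as_tibble(genes)
    req <- c("gene_id", "start", "end", "strand")
    if (!all(req %in% names(genes))) {
      abort("`genes` must have columns gene_id, start, end, strand.")
    }
    if (any(genes$start < 1 | genes$end > len)) {
      abort("CDS coordinates fall outside the genome.")
    }
    if (any(genes$start > genes$end)) abort("CDS start must not exceed end.")
    if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'.")
  }
  structure(
    list(seq = seq, length = len, genes = genes, circular = circular),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf(
    "<genome_record> %s bp (%s), %d genes\n",
    format(x$length, big.mark = ","),
    if (x$circular) "circular" else "linear",
    if (is.null(x$genes)) 0L else nrow(x$genes)
  ))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s bp, %d genes, TEX enrichment %gx, seed %d\n",
    format(x$genome_length, big.mark = ","), x$n_genes,
    x$tex_enrichment, x$seed
  ))
  invisible(x)
}
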