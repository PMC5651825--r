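# Shared fixtures, built once per test run.

fix_cfg <- sim_config(genome_length = 60000, n_genes = 30, seed = 7)
fix_sim <- simulate_genome(fix_cfg)
fix_prof <- simulate_end_profiles(fix_sim$genome, fix_sim$truth, fix_cfg)

# A noiseless, fully promoter-equipped simulation for exact-recovery checks
fix_clean_cfg <- sim_config(
  genome_length = 100000, n_genes = 50, p_primary_tss = 1,
  p_minus35_present = 1, per_base_mutation_rate = 0, p_secondary = 0,
  n_antisense_tss = 0, n_intergenic_tss = 0, seed = 13
)
fix_clean <- simulate_genome(fix_clean_cfg)

# Independent brute-force positional classifier: plain loops, no sharing
# with classify_tss() internals.
oracle_classify <- function(tss, genes, upstream = 300, downstream = 100) {
  n <- nrow(tss)
  out <- character(n)
  gene <- character(n)
  assigned <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best_g <- NA_integer_
    best_d <- Inf
    for (g in seq_len(nrow(genes))) {
      if (genes$strand[g] != tss$strand[i]) next
      codon <- if (genes$strand[g] == "+") genes$start[g] else genes$end[g]
      lo <- if (genes$strand[g] == "+") codon - upstream else codon - downstream
      hi <- if (genes$strand[g] == "+") codon + downstream else codon + upstream
      if (tss$position[i] < lo || tss$position[i] > hi) next
      d <- abs(tss$position[i] - codon)
      if (d < best_d) {
        best_d <- d
        best_g <- g
      } else if (d == best_d && !is.na(best_g)) {
        up_new <- if (tss$strand[i] == "+") genes$start[g] < genes$start[best_g]
                  else genes$end[g] > genes$end[best_g]
        if (up_new) best_g <- g
      }
    }
    assigned[i] <- best_g
  }
  for (g in unique(assigned[!is.na(assigned)])) {
    members <- which(assigned == g)
    cnt <- tss$tex_plus_count[members]
    strand <- genes$strand[g]
    pos <- tss$position[members]
    key <- order(-cnt, if (strand == "+") pos else -pos)
    out[members[key[1]]] <- "P"
    if (length(members) > 1) out[members[key[-1]]] <- "S"
    gene[members] <- genes$gene_id[g]
  }
  for (i in which(out == "")) {
    lab <- "N"
    best_d <- Inf
    for (g in seq_len(nrow(genes))) {
      if (tss$position[i] < genes$start[g] || tss$position[i] > genes$end[g]) next
      codon <- if (genes$strand[g] == "+") genes$start[g] else genes$end[g]
      d <- abs(tss$position[i] - codon)
      cand <- if (genes$strand[g] == tss$strand[i]) "I" else "A"
      # sense hits take precedence over antisense hits
      if (cand == "I" && lab != "I") {
        lab <- "I"; gene[i] <- genes$gene_id[g]; best_d <- d
      } else if (cand == lab && d < best_d) {
        gene[i] <- genes$gene_id[g]; best_d <- d
      } else if (cand == "A" && lab == "N") {
        lab <- "A"; gene[i] <- genes$gene_id[g]; best_d <- d
      }
    }
    out[i] <- lab
  }
  list(class = out, gene_id = gene)
}

random_layout <- function(seed, genome_length = 50000, n_genes = 8, n_tss = 12) {
  set.seed(seed)
  starts <- sort(sample.int(genome_length - 2000, n_genes))
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    start = starts,
    end = starts + sample(300:1200, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )
  tss <- tibble::tibble(
    position = sample.int(genome_length, n_tss),
    strand = sample(c("+", "-"), n_tss, replace = TRUE),
    tex_plus_count = sample(10:200, n_tss, replace = TRUE)
  )
  list(genes = genes, tss = tss)
}
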