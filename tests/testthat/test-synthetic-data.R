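test_that("identical configs give byte-identical genomes and profiles", {
  cfg <- sim_config(genome_length = 30000, n_genes = 15, seed = 42)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth, b$truth)
  pa <- simulate_end_profiles(a$genome, a$truth, cfg)
  pb <- simulate_end_profiles(b$genome, b$truth, cfg)
  expect_identical(pa$tex_plus$fwd, pb$tex_plus$fwd)
  expect_identical(pa$tex_minus$rev, pb$tex_minus$rev)
})

test_that("zero-noise planting writes exact consensus elements", {
  cfg <- sim_config(
    genome_length = 40000, n_genes = 20, p_primary_tss = 1,
    p_minus35_present = 1, per_base_mutation_rate = 0, p_secondary = 0,
    n_antisense_tss = 0, n_intergenic_tss = 0, spacer_dist = 17L, seed = 3
  )
  sim <- simulate_genome(cfg)
  ms <- sim$truth$motif_sites
  b <- strsplit(sim$genome$seq, "")[[1]]
  for (i in seq_len(nrow(ms))) {
    frag <- paste(b[ms$genome_start[i]:ms$genome_end[i]], collapse = "")
    if (ms$strand[i] == "-") {
      frag <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
    }
    expected <- if (ms$element[i] == "minus10") "TATAAT" else "TTGACA"
    expect_identical(frag, expected)
  }
  m35 <- ms[ms$element == "minus35", ]
  expect_true(all(m35$spacer == 17L))
  # every gene got exactly one primary TSS
  expect_identical(sum(sim$truth$tss$class == "P"), 20L)
})

test_that("primary TSS bookkeeping and upstream-window invariant hold", {
  cfg <- sim_config(genome_length = 100000, n_genes = 50, p_primary_tss = 1,
                    seed = 5)
  sim <- simulate_genome(cfg)
  p <- sim$truth$tss[sim$truth$tss$class == "P", ]
  expect_identical(nrow(p), 50L)
  genes <- sim$genome$genes
  for (i in seq_len(nrow(p))) {
    g <- genes[genes$gene_id == p$gene_id[i], ]
    d <- if (g$strand == "+") g$start - p$position[i] else p$position[i] - g$end
    expect_gte(d, 0)
    expect_lte(d, 300)
    expect_identical(d, as.integer(p$utr_length[i]))
  }
})

test_that("genome too short for the gene count is a sizing error", {
  expect_error(
    simulate_genome(sim_config(genome_length = 5000, n_genes = 50, seed = 1)),
    "too short"
  )
})

test_that("TEX+/TEX- ratio at true TSSs matches the configured enrichment", {
  cfg <- sim_config(
    genome_length = 1200000, n_genes = 1000, p_primary_tss = 1,
    p_secondary = 0, n_antisense_tss = 0, n_intergenic_tss = 0,
    n_processed_sites = 0, noise_mean = 0, tex_enrichment = 10,
    tss_read_mean = 100, gene_length = c(400L, 600L), seed = 21
  )
  sim <- simulate_genome(cfg)
  prof <- simulate_end_profiles(sim$genome, sim$truth, cfg)
  tss <- sim$truth$tss
  idx_f <- tss$position[tss$strand == "+"]
  idx_r <- tss$position[tss$strand == "-"]
  plus <- c(prof$tex_plus$fwd[idx_f], prof$tex_plus$rev[idx_r])
  minus <- c(prof$tex_minus$fwd[idx_f], prof$tex_minus$rev[idx_r])
  expect_identical(length(plus), 1000L)
  ratio <- mean(plus) / mean(minus)
  expect_gte(ratio, 8)
  expect_lte(ratio, 12)
  # profile mass conservation: nothing outside the planted sites
  expect_identical(sum(prof$tex_plus$fwd) + sum(prof$tex_plus$rev), sum(plus))
})

test_that("no sites and no noise give all-zero profiles", {
  cfg <- sim_config(genome_length = 20000, n_genes = 5, p_primary_tss = 0,
                    p_secondary = 0, n_antisense_tss = 0, n_intergenic_tss = 0,
                    n_processed_sites = 0, noise_mean = 0, seed = 1)
  sim <- simulate_genome(cfg)
  prof <- simulate_end_profiles(sim$genome, sim$truth, cfg)
  expect_identical(sum(prof$tex_plus$fwd) + sum(prof$tex_plus$rev), 0)
  expect_identical(sum(prof$tex_minus$fwd) + sum(prof$tex_minus$rev), 0)
})

test_that("proteome category structure follows the requested fractions", {
  cfg <- sim_config(seed = 11)
  all_core <- simulate_proteomes(cfg, n_genomes = 4, n_families = 10,
                                 category_fractions = c(1, 0, 0))
  counts <- table(all_core$truth$family)
  expect_true(all(counts == 4))
  expect_true(all(all_core$truth$category == "core"))

  all_unique <- simulate_proteomes(cfg, n_genomes = 4, n_families = 12,
                                   category_fractions = c(0, 0, 1))
  expect_identical(nrow(all_unique$truth), 12L)
  expect_true(all(table(all_unique$truth$family) == 1))
  expect_identical(sum(vapply(all_unique$proteomes, length, integer(1))), 12L)

  ident <- simulate_proteomes(cfg, n_genomes = 3, n_families = 5,
                              category_fractions = c(1, 0, 0), identity = 1)
  for (fam in unique(ident$truth$family)) {
    rows <- ident$truth[ident$truth$family == fam, ]
    seqs <- mapply(function(g, p) as.character(ident$proteomes[[g]][[p]]),
                   rows$genome, rows$protein_id)
    expect_identical(length(unique(seqs)), 1L)
  }
  expect_error(simulate_proteomes(cfg, identity = 1.2), "identity")
  expect_error(simulate_proteomes(cfg, n_genomes = 2), "at least 3")
})

test_that("fixtures round-trip losslessly and the truth TSV is complete", {
  d <- withr::local_tempdir()
  paths <- write_fixtures(fix_sim, fix_prof, d)
  g2 <- read_genome(paths["genome"], paths["annotation"])
  expect_identical(g2$seq, fix_sim$genome$seq)
  expect_identical(g2$genes$start, fix_sim$genome$genes$start)
  expect_identical(g2$genes$strand, fix_sim$genome$genes$strand)
  for (nm in c("TEXplus_fwd", "TEXplus_rev", "TEXminus_fwd", "TEXminus_rev")) {
    lib <- if (grepl("plus", nm)) fix_prof$tex_plus else fix_prof$tex_minus
    v <- load_end_counts(paths[nm], fix_sim$genome$length)
    expect_identical(v, lib[[if (grepl("fwd", nm)) "fwd" else "rev"]])
  }
  truth <- readr::read_tsv(paths["truth"], show_col_types = FALSE)
  expect_identical(nrow(truth), nrow(fix_sim$truth$tss))
})
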