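test_that("window extraction respects offsets, strand and circularity", {
  g <- genome_record("AAACCCTTTGGG")
  plus <- tibble::tibble(position = 7L, strand = "+")
  expect_identical(extract_windows(plus, g, -3, -1), "CCC")
  minus <- tibble::tibble(position = 7L, strand = "-")
  # offsets -3..-1 on the minus strand are positions 8..10, reverse-complemented
  expect_identical(extract_windows(minus, g, -3, -1), "CAA")
  # there is no offset 0: -1..+1 spans two bases around the TSS
  expect_identical(extract_windows(plus, g, -1, 1), "CT")
  # wrap across the circular origin
  expect_identical(extract_windows(tibble::tibble(position = 2L, strand = "+"),
                                   g, -3, -1), "GGA")
  expect_error(extract_windows(plus, g, -1, -3), "from")
  expect_error(extract_windows(plus, g, 0, 3), "Offset 0")
  # every upstream window of the synthetic TSS set has the full width
  w <- extract_windows(fix_sim$truth$tss, fix_sim$genome, -20, -1)
  expect_true(all(nchar(w) == 20))
})

test_that("EM recovers a planted hexamer and beats random windows", {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  planted <- vapply(1:50, function(i) {
    w <- sample(bases, 20, replace = TRUE)
    off <- sample(1:15, 1)
    w[off:(off + 5)] <- strsplit("TATAAT", "")[[1]]
    paste(w, collapse = "")
  }, character(1))
  m <- discover_motif(planted, 6, seed = 4)
  expect_identical(m$consensus, "TATAAT")
  expect_gte(m$occupancy, 0.9)
  random <- vapply(1:50, function(i) {
    paste(sample(bases, 20, replace = TRUE), collapse = "")
  }, character(1))
  m0 <- discover_motif(random, 6, seed = 4)
  expect_lt(sum(m0$information_content), sum(m$information_content))
  expect_lte(m0$occupancy, m$occupancy)
})

test_that("a degenerate single-sequence input gives a one-hot PFM", {
  w <- rep("ACGTACGTAC", 50)
  m <- discover_motif(w, 6, seed = 2, n_restarts = 5)
  # all sites at one offset: each PFM column is 50 + pseudocount at one
  # base and pseudocount elsewhere
  expect_true(all(colSums(m$pfm) == nrow(m$sites) + 4 * 0.25))
  expect_true(all(apply(m$pfm, 2, max) == nrow(m$sites) + 0.25))
  expect_identical(length(unique(m$sites$offset)), 1L)
})

test_that("PFM bookkeeping invariants hold on a real discovery run", {
  w10 <- extract_windows(fix_clean$truth$tss, fix_clean$genome, -20, -1)
  m <- discover_motif(w10, 6, seed = 9)
  expect_identical(m$consensus, "TATAAT")
  expect_equal(colSums(m$pfm), rep(nrow(m$sites) + 1, 6))
  # the PWM is recomputable from the PFM and the background
  ppm <- sweep(m$pfm, 2, colSums(m$pfm), "/")
  expect_equal(m$pwm, log2(sweep(ppm, 1, m$background, "/")))
  expect_true(all(m$information_content >= 0 & m$information_content <= 2))
  expect_true(all(is.finite(m$pwm)))
})

test_that("spacer arithmetic matches the offset definition", {
  # -35 at offsets -37..-32 and -10 at -12..-7 leave 19 nt between them
  fake <- list(
    minus10 = list(width = 6L,
                   sites = tibble::tibble(seq = 1L, offset = 9L, posterior = 1)),
    minus35 = list(width = 6L,
                   sites = tibble::tibble(seq = 1L, offset = 14L, posterior = 1)),
    minus10_range = c(-20L, -1L), minus35_range = c(-50L, -21L)
  )
  tss <- tibble::tibble(position = 100L, strand = "+")
  arch <- promoter_architecture(fake, tss)
  expect_identical(arch$per_tss$minus10_offset, -12L)
  expect_identical(arch$per_tss$minus35_offset, -37L)
  expect_identical(arch$per_tss$spacer, 19L)
  expect_identical(arch$per_tss$architecture, "both")
  # a TSS with no -35 site contributes no spacer
  fake$minus35$sites <- fake$minus35$sites[0, ]
  arch2 <- promoter_architecture(fake, tss)
  expect_identical(arch2$per_tss$architecture, "minus10_only")
  expect_identical(nrow(arch2$spacer_histogram), 0L)
})

test_that("planted spacers are recovered with support in 16-18 nt", {
  tss <- fix_clean$truth$tss
  pm <- discover_promoters(tss, fix_clean$genome, seed = 3)
  arch <- promoter_architecture(pm, tss)
  expect_true(all(arch$spacer_histogram$spacer %in% 16:18))
  expect_identical(sum(arch$spacer_histogram$n),
                   sum(arch$per_tss$architecture == "both"))
  truth35 <- fix_clean$truth$motif_sites
  truth35 <- truth35[truth35$element == "minus35", ]
  expect_setequal(unique(arch$spacer_histogram$spacer), unique(truth35$spacer))
})

test_that("composition frequencies are normalized and track the planted bias", {
  tss <- fix_clean$truth$tss
  comp <- composition_at_tss(tss, fix_clean$genome)
  expect_equal(rowSums(comp[, c("A", "C", "G", "T")]),
               rep(1, 5), ignore_attr = TRUE)
  expect_identical(comp$offset, c(-2L, -1L, 1L, 2L, 3L))
  # clean generator plants pyrimidine at -1 / purine at +1 with the
  # configured biases (0.86 / 0.94); n = 50, so allow binomial noise
  expect_gt(attr(comp, "pyrimidine_minus1"), 0.7)
  expect_gt(attr(comp, "purine_plus1"), 0.8)
  # fully deterministic case
  g <- genome_record(strrep("CA", 20))
  tss_det <- tibble::tibble(position = seq(4, 30, by = 2), strand = "+")
  cd <- composition_at_tss(tss_det, g)
  expect_equal(attr(cd, "pyrimidine_minus1"), 1)
  expect_equal(attr(cd, "purine_plus1"), 1)
})

test_that("permutation p-values are significant for planted motifs and bounded", {
  w10 <- extract_windows(fix_clean$truth$tss, fix_clean$genome, -20, -1)
  m <- discover_motif(w10, 6, seed = 9)
  m <- motif_significance(m, w10, n_permutations = 99, seed = 17)
  expect_lte(m$p_value, 0.05)
  expect_gt(m$p_value, 0)
  null_ic <- attr(m, "null_ic")
  expect_identical(length(null_ic), 99L)
  expect_true(all(null_ic < sum(m$information_content)))
  expect_error(motif_significance(m, w10, n_permutations = 50), "at least 99")
})
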