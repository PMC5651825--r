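test_that("bedGraph loading follows the 0-based half-open convention", {
  d <- withr::local_tempdir()
  p <- file.path(d, "x.bedgraph")
  writeLines("chr\t9\t12\t4", p)
  v <- load_end_counts(p, 20)
  expect_equal(v, c(rep(0, 9), 4, 4, 4, rep(0, 8)))
  # empty file -> all zeros
  writeLines(character(0), file.path(d, "e.bedgraph"))
  expect_equal(load_end_counts(file.path(d, "e.bedgraph"), 10), rep(0, 10))
  # round trip
  counts <- c(0, 0, 5, 5, 0, 2, 0, 0, 1, 0)
  drnatss:::write_bedgraph(counts, file.path(d, "r.bedgraph"))
  expect_equal(load_end_counts(file.path(d, "r.bedgraph"), 10), counts)
  writeLines("chr\t5\t100\t1", file.path(d, "oob.bedgraph"))
  expect_error(load_end_counts(file.path(d, "oob.bedgraph"), 20), "outside")
})

test_that("normalization is counts-per-million and preserves ranking", {
  a <- end_profile("A", c(10, 0, 5, 0), c(0, 0, 0, 0))
  b <- end_profile("B", c(5, 0, 5, 0), c(0, 20, 0, 0))
  pair <- normalize_pair(a, b)
  # totals 15 and 30: equal raw counts get 2x the CPM in the smaller library
  expect_equal(pair$plus_cpm$fwd[3], 2 * pair$minus_cpm$fwd[3])
  expect_equal(pair$plus_cpm$fwd, a$fwd / 15 * 1e6)
  # ranking within a library is unchanged by scaling
  set.seed(1)
  x <- end_profile("X", rpois(50, 5), rpois(50, 5))
  y <- end_profile("Y", rpois(50, 20), rpois(50, 20))
  pr <- normalize_pair(x, y)
  expect_identical(order(pr$plus_cpm$fwd), order(x$fwd))
  z <- end_profile("Z", rep(0, 4), rep(0, 4))
  expect_error(normalize_pair(a, z), "Zero-total")
  expect_error(normalize_pair(a, end_profile("W", 0:2, 0:2)), "length")
})

make_pair <- function(plus_fwd, minus_fwd, L = length(plus_fwd)) {
  normalize_pair(
    end_profile("TEXplus", plus_fwd, rep(0, L)),
    end_profile("TEXminus", minus_fwd, rep(0, L))
  )
}

test_that("call_tss applies count and enrichment thresholds", {
  plus <- rep(0, 100); minus <- rep(0, 100)
  plus[50] <- 50; minus[50] <- 5
  plus[80] <- 5                       # below min_count
  minus[20] <- 30                     # TEX- only: never a TSS
  # balance library totals so effective counts equal raw counts
  plus[1] <- 35; minus[1] <- 55
  pair <- make_pair(plus, minus)
  expect_equal(pair$plus$total, pair$minus$total)
  tss <- call_tss(pair, detection_params())
  row <- tss[tss$position == 50, ]
  expect_identical(nrow(row), 1L)
  expect_equal(row$enrichment, (50 + 1) / (5 + 1))
  expect_false(80 %in% tss$position)
  expect_false(20 %in% tss$position)
})

test_that("nearby candidates merge to the strongest position", {
  plus <- rep(0, 200); minus <- rep(0, 200)
  plus[100] <- 40; plus[103] <- 60    # within the 5-nt cluster window
  minus[150] <- 1
  pair <- make_pair(plus, minus)
  tss <- call_tss(pair)
  expect_identical(tss$position, 103L)
  # tie resolves to the most-upstream position, strand-aware
  plus2 <- rep(0, 200); minus2 <- rep(0, 200); minus2[150] <- 1
  plus2[c(100, 103)] <- 50
  tssf <- call_tss(make_pair(plus2, minus2))
  expect_identical(tssf$position, 100L)
  rev_pair <- normalize_pair(
    end_profile("TEXplus", rep(0, 200), plus2),
    end_profile("TEXminus", rep(0, 200), c(rep(0, 199), 1))
  )
  tssr <- call_tss(rev_pair)
  expect_identical(tssr$position, 103L)
})

test_that("emitted TSSs respect thresholds, spacing and monotonicity", {
  set.seed(42)
  L <- 3000
  plus <- rpois(L, 0.2); minus <- rpois(L, 0.2)
  sites <- sample.int(L, 40)
  plus[sites] <- plus[sites] + rpois(40, 60)
  pair <- make_pair(plus, minus)
  params <- detection_params()
  tss <- call_tss(pair, params)
  expect_true(all(tss$tex_plus_count >= params$min_count))
  expect_true(all(tss$enrichment >= params$min_enrichment))
  pos_by_strand <- split(tss$position, tss$strand)
  for (p in pos_by_strand) {
    if (length(p) > 1) expect_true(all(diff(sort(p)) > params$cluster_window))
  }
  # raising min_count never increases the number of calls
  n_prev <- Inf
  for (mc in c(10, 20, 40, 80)) {
    n <- nrow(call_tss(pair, detection_params(min_count = mc)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("clusters may wrap around the circular origin", {
  plus <- rep(0, 100); minus <- rep(0, 100); minus[50] <- 1
  plus[c(99, 2)] <- c(40, 60)
  tss <- call_tss(make_pair(plus, minus), detection_params())
  expect_identical(nrow(tss), 1L)
  expect_identical(tss$position, 2L)
  tss2 <- call_tss(make_pair(plus, minus), detection_params(),
                   circular = FALSE)
  expect_identical(nrow(tss2), 2L)
})
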