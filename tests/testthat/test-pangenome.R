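test_that("identical sequences score as the BLOSUM62 self-alignment", {
  s <- "MKVLAWQTENAGRCDEFHIS"
  proteomes <- list(
    g1 = Biostrings::AAStringSet(c("g1|p1" = s)),
    g2 = Biostrings::AAStringSet(c("g2|p1" = s))
  )
  gr <- score_pairs(proteomes, evalue_max = 1)
  b62 <- drnatss:::get_blosum62()
  aa <- strsplit(s, "")[[1]]
  expect_equal(gr$score, sum(b62[cbind(aa, aa)]))
  expect_identical(nrow(gr), 1L)
})

test_that("unrelated random proteins are not connected at default thresholds", {
  set.seed(77)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  hits <- vapply(1:20, function(i) {
    p <- list(
      g1 = Biostrings::AAStringSet(stats::setNames(
        paste(sample(aa, 50, TRUE), collapse = ""), "g1|p1")),
      g2 = Biostrings::AAStringSet(stats::setNames(
        paste(sample(aa, 50, TRUE), collapse = ""), "g2|p1"))
    )
    nrow(score_pairs(p))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("scores are symmetric in the pair order", {
  set.seed(5)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  s1 <- paste(sample(aa, 80, TRUE), collapse = "")
  s2 <- paste(c(sample(aa, 10, TRUE), strsplit(s1, "")[[1]][11:80]), collapse = "")
  p12 <- list(g1 = Biostrings::AAStringSet(c("g1|a" = s1)),
              g2 = Biostrings::AAStringSet(c("g2|b" = s2)))
  p21 <- list(g2 = Biostrings::AAStringSet(c("g2|b" = s2)),
              g1 = Biostrings::AAStringSet(c("g1|a" = s1)))
  expect_equal(score_pairs(p12, evalue_max = 1)$score,
               score_pairs(p21, evalue_max = 1)$score)
})

edge_graph <- function(edges, nodes) {
  g <- tibble::tibble(protein_a = edges[[1]], protein_b = edges[[2]],
                      score = edges[[3]], evalue = 0)
  attr(g, "nodes") <- nodes
  g
}

test_that("Markov clustering separates planted graph structure", {
  # two disjoint triangles -> two families
  tri <- expand.grid(a = 1:3, b = 1:3)
  tri <- tri[tri$a < tri$b, ]
  e <- list(
    c(paste0("x", tri$a), paste0("y", tri$a)),
    c(paste0("x", tri$b), paste0("y", tri$b)),
    rep(50, 2 * nrow(tri))
  )
  fams <- mcl_cluster(edge_graph(e, c(paste0("x", 1:3), paste0("y", 1:3))))
  expect_identical(dplyr::n_distinct(fams$family), 2L)
  expect_identical(dplyr::n_distinct(fams$family[grepl("^x", fams$protein)]), 1L)

  # two dense 5-cliques joined by one weak edge split at inflation 1.5
  cl <- expand.grid(a = 1:5, b = 1:5)
  cl <- cl[cl$a < cl$b, ]
  ea <- list(
    c(paste0("a", cl$a), paste0("b", cl$a), "a1"),
    c(paste0("a", cl$b), paste0("b", cl$b), "b1"),
    c(rep(50, 2 * nrow(cl)), 1)
  )
  fams2 <- mcl_cluster(edge_graph(ea, c(paste0("a", 1:5), paste0("b", 1:5))),
                       inflation = 1.5)
  expect_identical(dplyr::n_distinct(fams2$family), 2L)
  expect_identical(dplyr::n_distinct(fams2$family[grepl("^a", fams2$protein)]), 1L)

  # an isolated node is a singleton family
  fams3 <- mcl_cluster(edge_graph(list("p", "q", 50), c("p", "q", "solo")))
  expect_identical(dplyr::n_distinct(fams3$family), 2L)
  expect_identical(sum(fams3$protein == "solo"), 1L)
})

test_that("family categories and count identities are conserved", {
  fams <- tibble::tibble(
    protein = c("g1|a", "g2|a", "g3|a", "g1|b", "g2|b", "g1|c", "g1|c2"),
    family = c("f1", "f1", "f1", "f2", "f2", "f3", "f3")
  )
  pan <- categorize_families(fams, n_genomes = 3)
  summ <- pan$family_summary
  expect_identical(summ$category[summ$family == "f1"], "core")
  expect_identical(summ$category[summ$family == "f2"], "dispensable")
  expect_identical(summ$category[summ$family == "f3"], "unique")
  g <- glance(pan)
  expect_identical(g$core_families + g$dispensable_families + g$unique_families,
                   g$n_families)
  expect_identical(g$core_genes + g$dispensable_genes + g$unique_genes,
                   g$n_proteins)
  expect_identical(sum(pan$per_genome_counts$n_proteins), 7L)
  # paralogs count once for presence: f3 stays unique with two g1 members
  expect_identical(summ$n_proteins[summ$family == "f3"], 2L)
})

test_that("pan-genome distances are Jaccard on family presence", {
  fams <- tibble::tibble(
    protein = c("g1|a", "g2|a", "g1|b", "g2|c", "g3|d", "g3|e"),
    family = c("f1", "f1", "f2", "f3", "f4", "f5")
  )
  pan <- categorize_families(fams, n_genomes = 3)
  D <- pan_distance_matrix(pan)
  expect_equal(D["g1", "g2"], 1 - 1 / 3)
  expect_equal(D["g1", "g3"], 1)       # disjoint content
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  # identical content -> zero distance
  fams2 <- tibble::tibble(protein = c("g1|a", "g2|a", "g3|x"),
                          family = c("f1", "f1", "f2"))
  D2 <- pan_distance_matrix(categorize_families(fams2, n_genomes = 3))
  expect_equal(D2["g1", "g2"], 0)
})

test_that("neighbour joining reproduces additive trees exactly", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:8, 1)
    ref <- ape::rtree(n)
    D <- stats::cophenetic(ref)
    mine <- neighbor_joining(D)
    expect_identical(sort(mine$tip.label), sort(rownames(D)))
    # path distances reproduce the additive input
    got <- stats::cophenetic(mine)[rownames(D), colnames(D)]
    expect_lt(max(abs(got - D)), 1e-9)
    # topology agrees with the reference NJ implementation
    ref_nj <- ape::nj(D)
    expect_equal(as.numeric(ape::dist.topo(mine, ref_nj)), 0)
  }
})

test_that("three ultrametric taxa give a star with equal pendant branches", {
  D <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_identical(tr$Nnode, 1L)
  expect_equal(tr$edge.length, rep(1, 3))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("negative branch lengths are clamped and flagged", {
  D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 1, 9, 10, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("simulated proteomes are recovered into correct categories", {
  cfg <- sim_config(seed = 9)
  pp <- simulate_proteomes(cfg, n_genomes = 4, n_families = 25, identity = 0.9)
  gr <- score_pairs(pp$proteomes)
  pan <- categorize_families(mcl_cluster(gr))
  m <- dplyr::inner_join(pp$truth, pan$families,
                         by = c("protein_id" = "protein"))
  by_fam <- dplyr::summarise(
    dplyr::group_by(m, .data$family.y),
    ok = dplyr::n_distinct(.data$family.x) == 1 &&
      all(.data$category.x == .data$category.y),
    .groups = "drop"
  )
  expect_gte(mean(by_fam$ok), 0.95)
})
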