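#' All-vs-all protein similarity graph
#'
#' Smith-Waterman local alignment of every protein pair (BLOSUM62, gap
#' open 11 / extend 1, via [Biostrings::pairwiseAlignment]). An edge is
#' retained when the raw score reaches `score_min` and a Karlin-Altschul
#' E-value proxy (`K * m * n * exp(-lambda * S)` with gapped BLOSUM62
#' parameters lambda = 0.267, K = 0.041 and search space = query x subject
#' length) stays below `evalue_max`.
#'
#' @param proteomes Named list of [Biostrings::AAStringSet]; sequence ids
#'   must be genome-qualified (`<genome>|<protein>`).
#' @param score_min Minimum raw alignment score (default 50).
#' @param evalue_max Maximum E-value proxy (default 1e-10).
#' @param lambda,K Karlin-Altschul parameters.
#' @return A `similarity_graph`: tibble of edges (`protein_a`, `protein_b`,
#'   `score`, `evalue`) with all protein ids in attribute `"nodes"` and the
#'   genome of each node in attribute `"genome_of"`.
#' @export
score_pairs <- function(proteomes, score_min = 50, evalue_max = 1e-10,
                        lambda = 0.267, K = 0.041) {
  if (length(proteomes) < 2) abort("At least two genomes are required.")
  if (any(vapply(proteomes, length, integer(1)) == 0)) {
    abort("Empty proteome supplied.")
  }
  all_seqs <- do.call(c, unname(lapply(proteomes, as.character)))
  ids <- unlist(lapply(proteomes, names), use.names = FALSE)
  names(all_seqs) <- ids
  genome_of <- rep(names(proteomes),
                   vapply(proteomes, length, integer(1)))
  names(genome_of) <- ids
  aa <- Biostrings::AAStringSet(all_seqs)
  lens <- Biostrings::width(aa)
  n <- length(aa)
  blosum62 <- get_blosum62()
  edges <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    sc <- Biostrings::pairwiseAlignment(
      pattern = aa[rest], subject = aa[[i]],
      substitutionMatrix = blosum62, gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = TRUE
    )
    ev <- K * lens[i] * lens[rest] * exp(-lambda * sc)
    keep <- sc >= score_min & ev <= evalue_max
    if (any(keep)) {
      edges[[i]] <- tibble(
        protein_a = ids[i], protein_b = ids[rest][keep],
        score = sc[keep], evalue = ev[keep]
      )
    }
  }
  out <- dplyr::bind_rows(edges)
  attr(out, "nodes") <- ids
  attr(out, "genome_of") <- genome_of
  attr(out, "score_min") <- score_min
  attr(out, "evalue_max") <- evalue_max
  class(out) <- c("similarity_graph", class(out))
  out
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Markov clustering of a similarity graph
#'
#' Builds a column-stochastic transition matrix from the edge scores (with
#' self-loops weighted by each node's strongest edge) and iterates
#' expansion (matrix squaring) and inflation (elementwise power, column
#' renormalization, pruning of entries below `prune`) until the matrix
#' changes by less than `tol`. Families are the connected components of
#' the converged attractor structure; isolated proteins become singleton
#' families.
#'
#' @param graph A `similarity_graph` from [score_pairs()], or any tibble of
#'   weighted edges with a `"nodes"` attribute.
#' @param inflation Inflation exponent (default 1.5).
#' @param prune Entries below this are dropped after inflation (default 1e-5).
#' @param max_iter Maximum iterations (default 100).
#' @param tol Convergence threshold on the max absolute change (default 1e-6).
#' @return Tibble: `protein`, `family` (ids `fam0001`, ... by decreasing
#'   family size).
#' @export
mcl_cluster <- function(graph, inflation = 1.5, prune = 1e-5,
                        max_iter = 100L, tol = 1e-6) {
  nodes <- attr(graph, "nodes")
  if (is.null(nodes)) nodes <- sort(unique(c(graph$protein_a, graph$protein_b)))
  n <- length(nodes)
  if (n == 0) abort("Empty graph.")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph) > 0) {
    ia <- match(graph$protein_a, nodes)
    ib <- match(graph$protein_b, nodes)
    A[cbind(ia, ib)] <- graph$score
    A[cbind(ib, ia)] <- graph$score
  }
  loops <- apply(A, 2, max)
  diag(A) <- ifelse(loops > 0, loops, 1)
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                       # expansion
    M2 <- M2^inflation                  # inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    M2 <- sweep(M2, 2, ifelse(cs == 0, 1, cs), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("Markov clustering did not converge; interpreting the current state.")
  }
  # connected components of the attractor structure
  adj <- (M > 0) | (t(M) > 0)
  comp <- components_from_adjacency(adj)
  sizes <- table(comp)
  ranks <- rank(-as.integer(sizes), ties.method = "first")
  fam <- sprintf("fam%04d", ranks[match(comp, as.integer(names(sizes)))])
  tibble(protein = nodes, family = fam) %>% dplyr::arrange(.data$family)
}

components_from_adjacency <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Categorize gene families across genomes
#'
#' A family present in all genomes is core, in exactly one genome unique,
#' otherwise dispensable. A genome "has" a family when at least one of its
#' proteins belongs to it, so paralogs count once for presence but each
#' contributes to the gene totals.
#'
#' @param families Tibble `protein`, `family` from [mcl_cluster()].
#' @param genome_of Named character vector mapping protein id to genome; if
#'   `NULL`, genome is taken as the prefix of `protein` before `"|"`.
#' @param n_genomes Total number of genomes analysed; defaults to the
#'   number of distinct genomes observed.
#' @return A `pan_genome` object: `families` tibble (`protein`, `genome`,
#'   `family`, `category`), `family_summary`, `per_genome_counts`,
#'   `n_genomes`.
#' @export
categorize_families <- function(families, genome_of = NULL, n_genomes = NULL) {
  fam <- as_tibble(families)
  if (is.null(genome_of)) {
    fam$genome <- sub("\\|.*$", "", fam$protein)
  } else {
    fam$genome <- unname(genome_of[fam$protein])
    if (anyNA(fam$genome)) abort("Some proteins are not mapped to a genome.")
  }
  if (is.null(n_genomes)) n_genomes <- dplyr::n_distinct(fam$genome)
  summ <- fam %>%
    dplyr::group_by(.data$family) %>%
    dplyr::summarise(
      n_genomes_present = dplyr::n_distinct(.data$genome),
      n_proteins = dplyr::n(), .groups = "drop"
    ) %>%
    dplyr::mutate(category = dplyr::case_when(
      .data$n_genomes_present == n_genomes ~ "core",
      .data$n_genomes_present == 1L ~ "unique",
      TRUE ~ "dispensable"
    ))
  fam <- dplyr::left_join(fam, summ[, c("family", "category")], by = "family")
  per_genome <- fam %>%
    dplyr::count(.data$genome, .data$category, name = "n_proteins") %>%
    tidyr::complete(genome = unique(fam$genome),
                    category = c("core", "dispensable", "unique"),
                    fill = list(n_proteins = 0L))
  structure(
    list(
      families = fam[, c("protein", "genome", "family", "category")],
      family_summary = summ,
      per_genome_counts = per_genome,
      n_genomes = n_genomes
    ),
    class = "pan_genome"
  )
}

#' @export
print.pan_genome <- function(x, ...) {
  tab <- table(x$family_summary$category)
  cat(sprintf(
    "<pan_genome> %d genomes, %d families (%d core, %d dispensable, %d unique), %d proteins\n",
    x$n_genomes, nrow(x$family_summary),
    tab["core"] %|0|% 0, tab["dispensable"] %|0|% 0, tab["unique"] %|0|% 0,
    nrow(x$families)
  ))
  invisible(x)
}

`%|0|%` <- function(a, b) if (is.na(a)) b else a

#' Pan-genome distance matrix
#'
#' Jaccard distance on family presence/absence:
#' `1 - |shared families| / |families in either genome|`.
#'
#' @param pan A `pan_genome` from [categorize_families()].
#' @return Symmetric genome x genome distance matrix with zero diagonal.
#' @export
pan_distance_matrix <- function(pan) {
  fam <- pan$families
  genomes <- sort(unique(fam$genome))
  pres <- table(fam$genome, fam$family) > 0
  if (any(rowSums(pres) == 0)) abort("A genome has no families; distance undefined.")
  n <- length(genomes)
  D <- matrix(0, n, n, dimnames = list(genomes, genomes))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- sum(pres[i, ] & pres[j, ])
      either <- sum(pres[i, ] | pres[j, ])
      D[i, j] <- D[j, i] <- 1 - shared / either
    }
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic neighbour joining: repeatedly minimise the Q criterion, join the
#' selected pair with the standard branch-length formulas, and reduce the
#' matrix, finishing with the three-taxon star. Negative branch lengths are
#' clamped to zero and flagged via the `"negative_branches_clamped"`
#' attribute. On additive distances the tree reproduces the input path
#' lengths exactly.
#'
#' @param D Symmetric distance matrix with labelled rows, n >= 3.
#' @return An unrooted [ape] `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (!isSymmetric(unname(D))) abort("Distance matrix must be symmetric.")
  n <- nrow(D)
  if (n < 3) abort("Neighbour joining needs at least 3 taxa.")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  ids <- seq_len(n)               # current node ids; tips are 1..n
  next_id <- n + 1L
  edges <- matrix(0L, nrow = 0, ncol = 2)
  lens <- numeric(0)
  clamped <- FALSE
  add_edge <- function(parent, child, len) {
    if (len < 0) {
      clamped <<- TRUE
      len <- 0
    }
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, len)
  }
  while (length(ids) > 3) {
    m <- length(ids)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    k <- arrayInd(which.min(Q), dim(Q))
    i <- k[1]; j <- k[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    u <- next_id
    next_id <- next_id + 1L
    add_edge(u, ids[i], bi)
    add_edge(u, ids[j], bj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    D <- D2
    ids <- c(ids[keep], u)
  }
  # terminal star over the last three nodes
  u <- next_id
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  add_edge(u, ids[1], (d12 + d13 - d23) / 2)
  add_edge(u, ids[2], (d12 + d23 - d13) / 2)
  add_edge(u, ids[3], (d13 + d23 - d12) / 2)
  n_internal <- u - n
  # renumber internal nodes so the root-most (last created) comes first,
  # matching the phylo convention tips 1..n, internals n+1..n+Nnode
  remap <- c(seq_len(n), n + rev(seq_len(n_internal)))
  edges <- matrix(remap[edges], ncol = 2)
  tree <- structure(
    list(edge = edges, edge.length = lens, tip.label = labels,
         Nnode = n_internal),
    class = "phylo", order = "postorder"
  )
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "negative_branches_clamped") <- clamped
  tree
}

#' Build the full pan-genome tree
#'
#' @param pan A `pan_genome`.
#' @return List with the `phylo` `tree` and its `newick` string.
#' @export
pan_tree <- function(pan) {
  D <- pan_distance_matrix(pan)
  tree <- neighbor_joining(D)
  list(tree = tree, newick = ape::write.tree(tree))
}
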