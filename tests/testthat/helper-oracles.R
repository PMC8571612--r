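# Brute-force oracles and small fixture builders used across the suite.
# Oracles are deliberately independent of the package's implementation
# paths: exhaustive Bellman relaxation for least costs, Pruefer-sequence
# enumeration for spanning trees, pairwise tip traversal for phylogenetic
# covariance.

# resistance grid built directly from hand-set matrices (bypasses
# build_resistance so path tests control every cell cost)
manual_resistance <- function(res_mat, cell_size = 1, impassable = NULL,
                              elev = NULL, scenario = "M1") {
  if (is.null(impassable))
    impassable <- matrix(FALSE, nrow(res_mat), ncol(res_mat))
  if (is.null(elev)) elev <- matrix(-10, nrow(res_mat), ncol(res_mat))
  structure(list(res = res_mat, impassable = impassable, elev = elev,
                 cell_size = cell_size, xll = 0, yll = 0, nodata = -9999,
                 config = list(scenario = scenario,
                               depth_threshold = -150)),
            class = "resistance_grid")
}

# exhaustive Bellman iteration over the 8-connected grid; O(V^2) but exact
bellman_costs <- function(res, origins) {
  r <- res$res; nr <- nrow(r); nc <- ncol(r); cs <- res$cell_size
  pass <- !res$impassable
  cost <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(origins))) {
    if (pass[origins[k, 1], origins[k, 2]])
      cost[origins[k, 1], origins[k, 2]] <- 0
  }
  moves <- expand.grid(dr = -1:1, dc = -1:1)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!pass[i, j]) next
      for (m in seq_len(nrow(moves))) {
        pi <- i + moves$dr[m]; pj <- j + moves$dc[m]
        if (pi < 1 || pi > nr || pj < 1 || pj > nc) next
        if (!pass[pi, pj]) next
        step <- cs * sqrt(moves$dr[m]^2 + moves$dc[m]^2)
        cand <- cost[pi, pj] + step * (r[i, j] + r[pi, pj]) / 2
        if (cand < cost[i, j] - 1e-13) { cost[i, j] <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  cost[!pass] <- NA_real_
  cost
}

# decode a Pruefer sequence over n labelled vertices into its tree edges
pruefer_to_edges <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1, 2)
  for (k in seq_along(seq)) {
    leaf <- min(which(degree == 1L))
    edges[k, ] <- c(leaf, seq[k])
    degree[leaf] <- degree[leaf] - 1L
    degree[seq[k]] <- degree[seq[k]] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1, ] <- last
  edges
}

# minimum over all n^(n-2) labelled spanning trees of the summed edge length
brute_mst_total <- function(coords) {
  n <- nrow(coords)
  dm <- as.matrix(dist(coords))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- pruefer_to_edges(seqs[i, ], n)
    best <- min(best, sum(dm[e]))
  }
  best
}

# phylogenetic covariance by per-pair traversal: depth of the MRCA of each
# tip pair computed from root-to-node paths
brute_phylo_cov <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  blen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    p <- v
    while (v != root) { v <- parent[v]; p <- c(p, v) }
    p
  }
  depth <- function(v) {
    s <- 0
    while (v != root) { s <- s + blen[v]; v <- parent[v] }
    s
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    anc <- intersect(path_to_root(i), path_to_root(j))
    mrca <- anc[which.max(vapply(anc, depth, numeric(1)))]
    C[i, j] <- depth(mrca)
  }
  diag(C) <- vapply(seq_len(n), depth, numeric(1))
  C
}

# three-tip reference tree ((A:1,B:1):1,C:2)
three_tip_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

# star phylogeny of height t
star_tree <- function(n, t = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(t, nrow(tr$edge))
  tr
}

# small two-island world with a shallow channel, for barrier tests
channel_world <- function(channel_depth = -100, sea_base = -500) {
  make_world(world_config(
    n_rows = 20, n_cols = 30, cell_size = 2, mainland_width = 3,
    islands = list(island_spec(10, 12, radius = 2, peak = 100),
                   island_spec(10, 24, radius = 2, peak = 100)),
    channel_depth = channel_depth, sea_base_depth = sea_base))
}

# random small worlds for property tests (valid configs by construction)
random_world <- function(seed, channel_depth = NULL) {
  set.seed(seed)
  nr <- 24; nc <- 36
  k <- sample(2:4, 1)
  centers <- list()
  attempts <- 0
  while (length(centers) < k && attempts < 200) {
    attempts <- attempts + 1
    cand <- c(sample(5:(nr - 4), 1), sample(12:(nc - 4), 1))
    ok <- all(vapply(centers, function(ct)
      sqrt(sum((ct - cand)^2)) >= 8, logical(1)))
    if (ok) centers[[length(centers) + 1]] <- cand
  }
  if (is.null(channel_depth))
    channel_depth <- sample(c(-80, -120, -300), 1)
  isl <- lapply(centers, function(ct)
    island_spec(ct[1], ct[2], radius = sample(2:3, 1), peak = 200))
  make_world(world_config(n_rows = nr, n_cols = nc, cell_size = 3,
                          mainland_width = 4, islands = isl,
                          channel_depth = channel_depth,
                          sea_base_depth = -800))
}
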