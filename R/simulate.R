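#' Simulate a dated Yule phylogeny
#'
#' Forward pure-birth simulation: exponential waiting times with total rate
#' `k * birth_rate` for `k` extant lineages and a uniformly chosen splitting
#' lineage. After the n-th tip appears one further waiting time elapses so
#' terminal branches are positive; the tree is then rescaled to `height`
#' (Myr), giving divergence times in Mya.
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate speciation rate per lineage per Myr (> 0). Affects the
#'   pre-rescaling shape only through simulation noise; node-depth
#'   distribution is that of a Yule tree conditioned on `n_tips`.
#' @param seed integer seed; required, RNG state is restored on exit.
#' @param height tree height after rescaling (default 100 Myr).
#' @return an [ape::phylo] ultrametric rooted binary tree with tips
#'   `sp001..spN`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 0.1, seed, height = 100) {
  if (n_tips < 3) stop("n_tips must be >= 3")
  stopifnot(birth_rate > 0, height > 0)
  withr::with_seed(as.integer(seed), {
    m_max <- 2L * n_tips - 1L
    parent <- integer(m_max)
    t_start <- numeric(m_max)
    t_split <- rep(NA_real_, m_max)
    active <- 1L
    t_start[1L] <- 0
    next_id <- 2L
    t <- 0
    while (length(active) < n_tips) {
      k <- length(active)
      t <- t + stats::rexp(1L, rate = k * birth_rate)
      pos <- sample.int(k, 1L)
      i <- active[pos]
      t_split[i] <- t
      c1 <- next_id; c2 <- next_id + 1L
      next_id <- next_id + 2L
      parent[c(c1, c2)] <- i
      t_start[c(c1, c2)] <- t
      active <- c(active[-pos], c1, c2)
    }
    t_end <- t + stats::rexp(1L, rate = n_tips * birth_rate)

    ids <- seq_len(m_max)
    is_tip <- is.na(t_split)
    tip_ids <- ids[is_tip]
    int_ids <- ids[!is_tip]          # includes the root, id 1
    # ape numbering: tips 1..n, then internal nodes with the root first.
    # Internal ids are already in creation order, parents before children.
    map <- integer(m_max)
    map[tip_ids] <- seq_len(n_tips)
    map[int_ids] <- n_tips + seq_along(int_ids)

    child <- ids[ids != 1L]
    edge <- cbind(map[parent[child]], map[child])
    end_time <- ifelse(is_tip[child], t_end, t_split[child])
    len <- end_time - t_start[child]
    H <- t_end - t_split[1L]
    tr <- list(edge = edge, edge.length = len * (height / H),
               tip.label = sprintf("sp%03d", seq_len(n_tips)),
               Nnode = n_tips - 1L)
    class(tr) <- "phylo"
    attr(tr, "order") <- NULL
    ape::reorder.phylo(tr, "cladewise")
  })
}

#' Trait-simulation configuration
#'
#' @param model generating model: `"BM"` (Brownian motion), `"lambda"`
#'   (Brownian with Pagel's lambda rescaling of shared history), or `"OU"`
#'   (Ornstein-Uhlenbeck, fixed root).
#' @param sigma2 Brownian rate (trait variance per Myr, >= 0; 0 collapses
#'   every tip to `root_value`).
#' @param lambda_true Pagel's lambda of the generating process, in [0, 1].
#' @param alpha OU attraction strength (>= 0; 0 reduces to BM).
#' @param root_value trait value at the root.
#' @param seed integer seed.
#' @export
sim_trait_config <- function(model = c("BM", "lambda", "OU"), sigma2 = 1,
                             lambda_true = 1, alpha = 0, root_value = 0,
                             seed = 1L) {
  model <- match.arg(model)
  stopifnot(sigma2 >= 0, lambda_true >= 0, lambda_true <= 1, alpha >= 0)
  structure(list(model = model, sigma2 = sigma2, lambda_true = lambda_true,
                 alpha = alpha, root_value = root_value,
                 seed = as.integer(seed)),
            class = "sim_trait_config")
}

#' Simulate continuous traits on a phylogeny
#'
#' Draws one multivariate-normal trait vector with mean `root_value` and
#' covariance `sigma2 * V`, where `V` is the Brownian covariance `C` of the
#' tree, its lambda rescaling (off-diagonals multiplied by `lambda_true`),
#' or the fixed-root OU covariance, depending on the model. The standard
#' normal deviates are drawn before the model is applied, so `lambda_true =
#' 1` reproduces the BM draw for the same seed.
#'
#' @param tree an ultrametric [ape::phylo].
#' @param config a [sim_trait_config()].
#' @param n_rep number of independent replicate vectors (default 1).
#' @return named numeric vector (tip labels) or, for `n_rep > 1`, a matrix
#'   with one column per replicate.
#' @export
simulate_traits <- function(tree, config, n_rep = 1L) {
  stopifnot(inherits(config, "sim_trait_config"))
  n <- ape::Ntip(tree)
  withr::with_seed(config$seed, {
    z <- matrix(stats::rnorm(n * n_rep), n, n_rep)
    if (config$sigma2 == 0) {
      y <- matrix(config$root_value, n, n_rep)
    } else {
      C <- phylo_covariance(tree)
      V <- switch(config$model,
        BM = C,
        lambda = {
          Vl <- C * config$lambda_true
          diag(Vl) <- diag(C)
          Vl
        },
        OU = {
          if (config$alpha == 0) C
          else transform_covariance(tree, "OU1", config$alpha)
        })
      R <- chol(config$sigma2 * V)
      y <- config$root_value + crossprod(R, z)
    }
    rownames(y) <- tree$tip.label
    if (n_rep == 1L) y <- stats::setNames(drop(y), tree$tip.label)
    y
  })
}

#' Assign island occupancy to species
#'
#' Generates a binary species-by-island occupancy matrix. Each species
#' occupies each island independently with probability `p_occupy`; species
#' left without any island are given one uniformly chosen island so that
#' every species occupies at least one. A fraction `p_endemic` of species
#' are flagged endemic; their dispersal origin is the focal island (largest
#' radius, ties broken by proximity to the archipelago centroid) which they
#' are forced to occupy. The remaining, mainland-origin species disperse
#' from the mainland site.
#'
#' @param sites site table from [make_world()] (must contain >= 1 island;
#'   a mainland site is required unless `p_endemic = 1`).
#' @param tree phylogeny supplying the species ids (tip labels).
#' @param p_occupy per-island occupancy probability in (0, 1].
#' @param seed integer seed.
#' @param p_endemic probability that a species is an island endemic.
#' @return an `occupancy` object: list with `matrix` (species x island,
#'   0/1), `origin` (named character vector of origin site ids) and
#'   `is_endemic` (named logical).
#' @export
assign_occupancy <- function(sites, tree, p_occupy, seed, p_endemic = 0.3) {
  stopifnot(p_occupy > 0, p_occupy <= 1, p_endemic >= 0, p_endemic <= 1)
  isl <- sites[sites$type == "island", , drop = FALSE]
  if (nrow(isl) < 1) stop("occupancy requires at least one island site")
  main <- sites[sites$type == "mainland", , drop = FALSE]
  if (nrow(main) < 1 && p_endemic < 1)
    stop("mainland-origin species need a mainland site")
  sp <- tree$tip.label
  n <- length(sp); k <- nrow(isl)

  # focal island: largest radius, ties by distance to the island centroid
  ctr <- c(mean(isl$x), mean(isl$y))
  d_ctr <- sqrt((isl$x - ctr[1])^2 + (isl$y - ctr[2])^2)
  focal <- order(-isl$radius, d_ctr)[1]

  withr::with_seed(as.integer(seed), {
    occ <- matrix(stats::rbinom(n * k, 1L, p_occupy), n, k,
                  dimnames = list(sp, isl$site_id))
    empty <- rowSums(occ) == 0
    if (any(empty))
      occ[cbind(which(empty), sample.int(k, sum(empty), replace = TRUE))] <- 1L
    endemic <- stats::runif(n) < p_endemic
    occ[endemic, focal] <- 1L
    origin <- ifelse(endemic, isl$site_id[focal], main$site_id[1])
  })
  names(origin) <- sp
  structure(list(matrix = occ,
                 origin = origin,
                 is_endemic = stats::setNames(endemic, sp)),
            class = "occupancy")
}

#' Simulate species trait tables
#'
#' Generates the life-history/grouping table used by the regression stage:
#' snake vs lizard (snakes are a clade: the internal node whose descendant
#' count is closest to `prop_snake` of the tips), trophic preference
#' (snakes mostly vertebrate feeders), and adult total length (log-normal;
#' snakes longer than lizards).
#'
#' @param tree phylogeny.
#' @param seed integer seed.
#' @param prop_snake target proportion of snake species.
#' @return data.frame with `species`, `is_snake`, `trophic`,
#'   `total_length` (cm).
#' @export
simulate_species_traits <- function(tree, seed, prop_snake = 0.4) {
  n <- ape::Ntip(tree)
  target <- prop_snake * n
  nodes <- (n + 2L):(n + tree$Nnode)      # internal nodes except the root
  sizes <- vapply(nodes, function(nd)
    length(clade_tips(tree, nd)), integer(1))
  node <- nodes[which.min(abs(sizes - target))]
  snakes <- tree$tip.label[clade_tips(tree, node)]
  is_snake <- tree$tip.label %in% snakes
  withr::with_seed(as.integer(seed), {
    trophic <- ifelse(stats::runif(n) < ifelse(is_snake, 0.8, 0.2),
                      "vertebrates", "invertebrates")
    tl <- exp(stats::rnorm(n, mean = ifelse(is_snake, log(80), log(15)),
                           sd = 0.4))
  })
  data.frame(species = tree$tip.label, is_snake = is_snake,
             trophic = trophic, total_length = tl)
}

# tip indices descending from an internal node (iterative, no phangorn dep)
clade_tips <- function(tree, node) {
  n <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  stack <- node
  tips <- integer(0)
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    if (nd <= n) tips <- c(tips, nd)
    else stack <- c(stack, kids[[as.character(nd)]])
  }
  sort(tips)
}
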