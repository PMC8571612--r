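# match a named trait vector to tree tips, dropping NAs with the tree
match_to_tree <- function(y, tree) {
  if (is.null(names(y))) {
    if (length(y) != ape::Ntip(tree))
      stop("unnamed trait vector must have one value per tip")
    names(y) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(y))
  if (length(miss) > 0)
    stop("trait values missing for tips: ", paste(miss, collapse = ", "))
  y[tree$tip.label]
}

# constant within floating-point tolerance: no signal information
is_degenerate_trait <- function(y) {
  diff(range(y)) <= 1e-10 * (1 + abs(mean(y)))
}

#' Pagel's lambda with likelihood-ratio test
#'
#' Maximum-likelihood estimate of Pagel's lambda for one continuous trait
#' under a mean-only phylogenetic GLS: the profile log-likelihood of
#' `y ~ N(mu, sigma2 * C(lambda))` is maximized over `lambda` in [0, 1],
#' where `C(lambda)` multiplies the off-diagonal shared history by lambda.
#' The p-value is the upper chi-square (1 df) tail of
#' `2 (lnL(lambda_hat) - lnL(0))`, testing independence (lambda = 0).
#'
#' Requires an ultrametric tree (the [0, 1] bound assumes ultrametry);
#' the constant diagonal is exploited through a single eigendecomposition
#' so each profile evaluation is O(n).
#'
#' @param y named numeric trait vector (tip labels).
#' @param tree ultrametric [ape::phylo] with >= 10 tips.
#' @param tol optimization tolerance on lambda.
#' @return a `signal_estimate` data.frame row: `statistic`, `estimate`,
#'   `p_value`, `loglik`, `loglik0`, `n_species`.
#' @export
pagels_lambda <- function(y, tree, tol = 1e-6) {
  n <- ape::Ntip(tree)
  if (n < 10) stop("pagels_lambda requires >= 10 tips")
  if (!is_ultrametric(tree))
    stop("pagels_lambda requires an ultrametric tree")
  y <- match_to_tree(y, tree)
  if (is_degenerate_trait(y)) {
    return(structure(data.frame(statistic = "lambda", estimate = NA_real_,
                                p_value = NA_real_, loglik = NA_real_,
                                loglik0 = NA_real_, n_species = n),
                     class = c("signal_estimate", "data.frame")))
  }
  C <- phylo_covariance(tree)
  Tm <- max(diag(C))
  eg <- eigen(C, symmetric = TRUE)
  ty <- drop(crossprod(eg$vectors, y))
  t1 <- drop(crossprod(eg$vectors, rep(1, n)))
  # eigenvalues of C(lambda) = lambda C + (1 - lambda) T I share C's basis
  prof <- function(lam) {
    d <- lam * (eg$values - Tm) + Tm
    if (any(d <= 0)) return(-Inf)
    b <- sum(t1 * ty / d) / sum(t1^2 / d)
    rss <- sum((ty - b * t1)^2 / d)
    s2 <- rss / n
    -0.5 * (n * log(2 * pi * s2) + sum(log(d)) + n)
  }
  grid <- seq(0, 1, by = 0.05)
  ll_grid <- vapply(grid, prof, numeric(1))
  i <- which.max(ll_grid)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = tol)
  cand_lam <- c(opt$maximum, grid[i], 0, 1)
  cand_ll <- c(opt$objective, ll_grid[i], ll_grid[1], ll_grid[length(grid)])
  best <- which.max(cand_ll)
  lam_hat <- min(max(cand_lam[best], 0), 1)
  ll_hat <- cand_ll[best]
  ll0 <- ll_grid[1]
  lrt <- max(0, 2 * (ll_hat - ll0))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(data.frame(statistic = "lambda", estimate = lam_hat,
                       p_value = p, loglik = ll_hat, loglik0 = ll0,
                       n_species = n),
            class = c("signal_estimate", "data.frame"))
}

#' Blomberg's K with permutation test
#'
#' `K = (MSE0 / MSE) / E[MSE0 / MSE | BM]`, where `MSE0` is the mean
#' squared deviation of the trait from its phylogenetically corrected mean
#' and `MSE` the corresponding C-whitened mean square; the Brownian
#' expectation is `(tr(C) - n / (1' C^-1 1)) / (n - 1)`. K = 1 matches the
#' Brownian expectation, K < 1 means less signal. Significance is assessed
#' by permuting trait values across tips: p = (b + 1) / (n_perm + 1) where
#' b counts permutations with K at least the observed value.
#'
#' @param y named numeric trait vector.
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param n_perm number of permutations (default 999; 0 skips the test
#'   and returns `p_value = NA`).
#' @param seed integer seed for the permutations (required if
#'   `n_perm > 0`).
#' @return a `signal_estimate` data.frame row. Constant traits give
#'   `estimate = NA` with `degenerate = TRUE`.
#' @export
blombergs_K <- function(y, tree, n_perm = 999, seed = NULL) {
  y <- match_to_tree(y, tree)
  n <- length(y)
  C <- phylo_covariance(tree)
  Ci <- solve(C)
  w <- rowSums(Ci)                      # C^-1 1
  sw <- sum(w)
  denom <- (sum(diag(C)) - n / sw) / (n - 1)
  K_of <- function(Y) {
    a <- drop(crossprod(w, Y)) / sw
    Yc <- sweep(Y, 2, a)
    mse0 <- colSums(Yc^2) / (n - 1)
    mse <- colSums(Yc * (Ci %*% Yc)) / (n - 1)
    (mse0 / mse) / denom
  }
  if (is_degenerate_trait(y)) {
    return(structure(data.frame(statistic = "K", estimate = NA_real_,
                                p_value = NA_real_, loglik = NA_real_,
                                loglik0 = NA_real_, n_species = n,
                                degenerate = TRUE),
                     class = c("signal_estimate", "data.frame")))
  }
  K_obs <- K_of(matrix(y, n, 1))
  p <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) stop("a seed is required for the permutation test")
    perms <- withr::with_seed(as.integer(seed), {
      matrix(y[unlist(lapply(seq_len(n_perm),
                             function(i) sample.int(n)))], n, n_perm)
    })
    K_perm <- K_of(perms)
    p <- (sum(K_perm >= K_obs) + 1) / (n_perm + 1)
  }
  structure(data.frame(statistic = "K", estimate = unname(K_obs),
                       p_value = p, loglik = NA_real_, loglik0 = NA_real_,
                       n_species = n, degenerate = FALSE),
            class = c("signal_estimate", "data.frame"))
}

#' Phylogenetic signal with cost-model uncertainty
#'
#' Estimates lambda or K for each path descriptor separately under each
#' resistance scenario present in the metrics table, then summarizes the
#' scenario spread: the headline estimate is the mean of the per-scenario
#' estimates, the interval is their empirical min-max range, and the
#' p-value is the median of the per-scenario p-values. Descriptors whose
#' values are identical across scenarios (the direction-free minimum tree)
#' are reported as a single estimate without an interval.
#'
#' @param metrics data.frame with columns `species`, `scenario` and one
#'   column per descriptor.
#' @param tree ultrametric phylogeny covering the species.
#' @param statistic `"lambda"` or `"K"`.
#' @param variables descriptor columns to test (default: all numeric
#'   columns other than `species`/`scenario`).
#' @param n_perm,seed passed to [blombergs_K()].
#' @return data.frame: `variable`, `statistic`, `estimate`, `ci_low`,
#'   `ci_high`, `p_value`, `n_species`, `scenario_free`.
#' @export
signal_with_model_uncertainty <- function(metrics, tree,
                                          statistic = c("lambda", "K"),
                                          variables = NULL,
                                          n_perm = 999, seed = 1L) {
  statistic <- match.arg(statistic)
  if (is.null(variables)) {
    variables <- setdiff(names(metrics)[vapply(metrics, is.numeric,
                                               logical(1))],
                         c("species", "scenario"))
  }
  scen <- sort(unique(metrics$scenario))
  out <- lapply(variables, function(v) {
    per <- lapply(scen, function(s) {
      d <- metrics[metrics$scenario == s, ]
      y <- stats::setNames(d[[v]], d$species)
      y <- y[!is.na(y)]
      tr <- ape::keep.tip(tree, names(y))
      if (statistic == "lambda") pagels_lambda(y, tr)
      else blombergs_K(y, tr, n_perm = n_perm, seed = seed)
    })
    est <- vapply(per, function(e) e$estimate, numeric(1))
    pv <- vapply(per, function(e) e$p_value, numeric(1))
    ns <- per[[1]]$n_species
    # scenarios where the statistic is degenerate (constant descriptor,
    # e.g. every route confined to one channel depth) carry no signal
    # information; summarize over the informative scenarios
    ok <- !is.na(est)
    if (any(ok) && !all(ok)) { est <- est[ok]; pv <- pv[ok] }
    scenario_free <- length(scen) > 1 &&
      max(est) - min(est) <= 1e-12 * (1 + abs(mean(est))) &&
      is_scenario_invariant(metrics, v)
    if (scenario_free || length(scen) == 1) {
      data.frame(variable = v, statistic = statistic, estimate = est[1],
                 ci_low = NA_real_, ci_high = NA_real_, p_value = pv[1],
                 n_species = ns, scenario_free = TRUE)
    } else {
      data.frame(variable = v, statistic = statistic,
                 estimate = mean(est), ci_low = min(est),
                 ci_high = max(est), p_value = stats::median(pv),
                 n_species = ns, scenario_free = FALSE)
    }
  })
  do.call(rbind, out)
}

is_scenario_invariant <- function(metrics, v) {
  spread <- tapply(metrics[[v]], metrics$species,
                   function(x) diff(range(x, na.rm = TRUE)))
  all(spread <= 1e-12, na.rm = TRUE)
}

#' Group-wise phylogenetic signal
#'
#' Recomputes lambda and K after pruning the tree to each group (e.g.
#' snakes vs lizards). Groups with 30 or fewer species are flagged
#' low-power (both statistics are sensitive to small phylogenies) but are
#' still computed.
#'
#' @param y named trait vector.
#' @param tree ultrametric phylogeny.
#' @param groups named character/factor vector assigning each species to a
#'   group.
#' @param n_perm,seed passed to [blombergs_K()].
#' @return data.frame with one row per group x statistic, plus
#'   `low_power`.
#' @export
groupwise_signal <- function(y, tree, groups, n_perm = 999, seed = 1L) {
  y <- match_to_tree(y, tree)
  groups <- groups[tree$tip.label]
  if (anyNA(groups)) stop("every tip needs a group assignment")
  out <- lapply(sort(unique(as.character(groups))), function(gr) {
    tips <- tree$tip.label[groups == gr]
    if (length(tips) == 0) stop("group absent from the tree: ", gr)
    tr <- ape::keep.tip(tree, tips)
    yg <- y[tr$tip.label]
    lam <- pagels_lambda(yg, tr)
    K <- blombergs_K(yg, tr, n_perm = n_perm, seed = seed)
    df <- rbind(lam[, c("statistic", "estimate", "p_value", "n_species")],
                K[, c("statistic", "estimate", "p_value", "n_species")])
    df$group <- gr
    df$low_power <- length(tips) <= 30
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("group", "statistic", "estimate", "p_value", "n_species",
          "low_power")]
}
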