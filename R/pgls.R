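#' Species occurrence centroids
#'
#' Unweighted mean of the coordinates of the sites a species occupies;
#' duplicate site listings are ignored. Used as the spatial covariate in
#' the regressions (uneven island density across the basin).
#'
#' @param occupancy an `occupancy` object or a binary species x site
#'   matrix with dimnames.
#' @param sites site table with `site_id`, `lon`, `lat`.
#' @return data.frame `species`, `centroid_lon`, `centroid_lat`.
#' @export
species_centroid <- function(occupancy, sites) {
  m <- if (inherits(occupancy, "occupancy")) occupancy$matrix else occupancy
  ids <- unique(colnames(m))
  m <- m[, ids, drop = FALSE]
  pos <- match(ids, sites$site_id)
  if (anyNA(pos)) stop("occupancy columns missing from the site table")
  if (any(rowSums(m) == 0)) stop("species with empty occupancy row")
  lon <- as.vector((m %*% sites$lon[pos]) / rowSums(m))
  lat <- as.vector((m %*% sites$lat[pos]) / rowSums(m))
  data.frame(species = rownames(m), centroid_lon = lon, centroid_lat = lat)
}

#' Build the regression design matrix
#'
#' Columns: intercept, latitude, longitude, snake (0/1), endemic (0/1),
#' trophic (vertebrates = 1), 10th-percentile phylogenetic isolation, and
#' total length interacting with the snake category (`TL:no` = total
#' length within lizards, `TL:yes` = within snakes; no TL main effect, so
#' the two slopes are read directly). Continuous columns (latitude,
#' longitude, isolation and the two interactions) are standardized to mean
#' 0, sd 1 after construction. Constant columns are dropped with a
#' warning.
#'
#' @param traits data.frame with `species`, `is_snake`, `is_endemic`,
#'   `trophic`, `total_length`, `q10_divergence`, `centroid_lat`,
#'   `centroid_lon` (complete cases).
#' @param standardize standardize continuous columns (default TRUE).
#' @return numeric design matrix with rownames = species and an attribute
#'   `scaling` recording centers and sds.
#' @export
build_design <- function(traits, standardize = TRUE) {
  stopifnot(all(traits$total_length > 0),
            all(abs(traits$centroid_lat) <= 90),
            all(abs(traits$centroid_lon) <= 180))
  snake <- as.numeric(traits$is_snake)
  X <- cbind(
    "(Intercept)" = 1,
    latitude = traits$centroid_lat,
    longitude = traits$centroid_lon,
    snake = snake,
    endemic = as.numeric(traits$is_endemic),
    trophic = as.numeric(traits$trophic == "vertebrates"),
    q10_divergence = traits$q10_divergence,
    "TL:no" = traits$total_length * (1 - snake),
    "TL:yes" = traits$total_length * snake
  )
  rownames(X) <- traits$species
  continuous <- c("latitude", "longitude", "q10_divergence",
                  "TL:no", "TL:yes")
  keep <- apply(X, 2, function(x) stats::sd(x) > 0)
  keep["(Intercept)"] <- TRUE
  if (any(!keep)) {
    warning("dropping constant design columns: ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  scaling <- NULL
  if (standardize) {
    sc_cols <- intersect(continuous, colnames(X))
    ctr <- colMeans(X[, sc_cols, drop = FALSE])
    sds <- apply(X[, sc_cols, drop = FALSE], 2, stats::sd)
    X[, sc_cols] <- scale(X[, sc_cols, drop = FALSE], center = ctr,
                          scale = sds)
    scaling <- list(columns = sc_cols, center = ctr, sd = sds)
  }
  attr(X, "scaling") <- scaling
  X
}

# per-structure fitting domain; param profiled by coarse grid + bounded
# refinement. Grids for the rate-like parameters are logarithmic and
# scaled by tree height.
structure_param_grid <- function(structure, height) {
  switch(structure,
    lambda = seq(0, 1, by = 0.1),
    kappa = seq(0, 3, by = 0.25),
    delta = exp(seq(log(0.05), log(3), length.out = 14)),
    OU1 = ,
    OU2 = exp(seq(log(0.1 / height), log(500 / height), length.out = 16)),
    EB = -exp(seq(log(0.001 / height), log(10 / height),
                  length.out = 14)),
    NULL)
}

structure_param_bounds <- function(structure, height) {
  switch(structure,
    lambda = c(0, 1),
    kappa = c(0, 3),
    delta = c(0.05, 3),
    OU1 = ,
    OU2 = c(0.05 / height, 1000 / height),
    EB = c(-20 / height, -1e-4 / height),
    NULL)
}

#' Phylogenetic linear regression under one covariance structure
#'
#' ML fit of `y = X beta + e`, `e ~ N(0, sigma2 * C(structure, param))`.
#' For structures with a free parameter (lambda, kappa, delta, OU1, OU2,
#' EB) the parameter is profiled jointly with `beta` and `sigma2` over a
#' coarse grid refined by bounded search; BM and null have none.
#' Coefficient p-values come from t statistics on n - p df (p = number of
#' coefficients, with standard errors from the unbiased residual
#' variance); R-squared is computed on the whitened scale against the
#' intercept-only GLS fit with the same covariance. AIC counts the
#' coefficients, sigma2 and the structure parameter (if any).
#'
#' @param y named response vector.
#' @param X design matrix from [build_design()] (rownames = species).
#' @param tree rooted phylogeny with branch lengths.
#' @param structure one of [covariance_structures()].
#' @param param optional fixed structure parameter (skips profiling).
#' @return a `pgls_fit`: coefficients table, `structure`, `param`,
#'   `sigma2`, `logLik`, `AIC`, `R2`, `n`, `k`.
#' @export
fit_pgls <- function(y, X, tree, structure, param = NULL) {
  structure <- match.arg(structure, covariance_structures())
  y <- match_to_tree(y, tree)
  X <- X[tree$tip.label, , drop = FALSE]
  n <- length(y)
  C <- phylo_covariance(tree)
  D <- if (structure %in% c("OU1", "OU2"))
    stats::cophenetic(tree)[rownames(C), colnames(C)] else NULL
  height <- max(diag(C))

  ll_at <- function(par) {
    Cp <- transform_C(C, D, structure, par, tree = tree)
    tryCatch(gls_loglik(y, X, Cp)$loglik, error = function(e) -Inf)
  }
  has_param <- !(structure %in% c("BM", "null"))
  if (has_param && is.null(param)) {
    grid <- structure_param_grid(structure, height)
    ll <- vapply(grid, ll_at, numeric(1))
    i <- which.max(ll)
    lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
    if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
    opt <- stats::optimize(ll_at, c(lo, hi), maximum = TRUE, tol = 1e-6)
    b <- structure_param_bounds(structure, height)
    cand <- c(opt$maximum, grid[i])
    cand_ll <- c(opt$objective, ll[i])
    j <- which.max(cand_ll)
    param <- min(max(cand[j], b[1]), b[2])
    if (structure == "lambda") param <- min(max(param, 0), 1)
  } else if (!has_param) {
    param <- NA_real_
  }
  Cp <- transform_C(C, D, structure,
                    if (has_param) param else NULL, tree = tree)
  fit <- gls_loglik(y, X, Cp)
  p <- ncol(X)
  df <- n - p
  s2_unb <- fit$rss / df
  se <- sqrt(diag(fit$XtCiX_inv) * s2_unb)
  tval <- fit$beta / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  # null (intercept-only) GLS under the same covariance, for R2
  fit0 <- gls_loglik(y, NULL, Cp)
  R2 <- 1 - fit$rss / fit0$rss
  k <- p + 1L + as.integer(has_param)
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = fit$beta,
                              se = se, t = tval, p_value = pval,
                              row.names = NULL),
    structure = structure, param = param, sigma2 = fit$sigma2,
    logLik = fit$loglik, AIC = -2 * fit$loglik + 2 * k, R2 = R2,
    n = n, k = k,
    response = y),
    class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("<pgls_fit> structure %s (param %.4g), n = %d\n",
              x$structure, x$param, x$n))
  cat(sprintf("  logLik %.3f  AIC %.3f  R2 %.3f\n", x$logLik, x$AIC, x$R2))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Compare PGLS fits by AIC weight
#'
#' Delta AIC (`AIC_i - min AIC`) and Akaike weights
#' `exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` over a candidate set of
#' fits of the same data; the best structure has delta = 0. Fits on
#' different responses are rejected.
#'
#' @param fits list of `pgls_fit` objects.
#' @return a `model_comparison` data.frame: `structure`, `param`,
#'   `logLik`, `k`, `AIC`, `delta_AIC`, `AIC_weight`, ordered as given,
#'   with attribute `best`.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 2)
  y0 <- fits[[1]]$response
  same <- vapply(fits, function(f)
    length(f$response) == length(y0) &&
      isTRUE(all.equal(unname(f$response), unname(y0))), logical(1))
  if (!all(same)) stop("fits were not made on identical data")
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  delta <- aic - min(aic)
  wt <- exp(-delta / 2)
  wt <- wt / sum(wt)
  out <- data.frame(
    structure = vapply(fits, `[[`, character(1), "structure"),
    param = vapply(fits, `[[`, numeric(1), "param"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    k = vapply(fits, function(f) f$k, integer(1)),
    AIC = aic, delta_AIC = delta, AIC_weight = wt)
  attr(out, "best") <- out$structure[which.min(aic)]
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Fit all candidate covariance structures
#'
#' Convenience wrapper fitting the eight candidate structures and ranking
#' them with [select_model()].
#'
#' @inheritParams fit_pgls
#' @param structures candidate set (default all eight).
#' @return list with `fits` (named list) and `comparison`
#'   (a `model_comparison`).
#' @export
fit_pgls_set <- function(y, X, tree, structures = covariance_structures()) {
  fits <- lapply(structures, function(s) fit_pgls(y, X, tree, s))
  names(fits) <- structures
  list(fits = fits, comparison = select_model(fits))
}
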