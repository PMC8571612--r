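#' Brownian phylogenetic covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j;
#' `C[i, i]` is the root-to-tip length. For an ultrametric tree the
#' diagonal is constant and equal to the tree height.
#'
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @return symmetric positive semi-definite matrix with tip labels as
#'   dimnames, in `tree$tip.label` order.
#' @export
phylo_covariance <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  C <- ape::vcv(tree)
  C[tree$tip.label, tree$tip.label]
}

# TRUE when all root-to-tip lengths agree within rel_tol of tree height
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  d <- diag(phylo_covariance(tree))
  diff(range(d)) <= rel_tol * max(d)
}

#' Covariance-structure transforms
#'
#' Transforms the Brownian covariance of a tree into the error covariance
#' of one of eight trait-evolution structures (up to a factor absorbed by
#' the profiled variance):
#' \describe{
#'   \item{BM}{the untransformed Brownian covariance `C`.}
#'   \item{lambda}{off-diagonals multiplied by lambda in [0, 1].}
#'   \item{kappa}{every branch length raised to the power kappa (>= 0)
#'     before `C` is rebuilt.}
#'   \item{delta}{node depths raised to the power delta (> 0):
#'     `C' = C^delta * T^(1 - delta)`, rescaled so the height `T` is
#'     preserved (keeps delta identifiable separately from the rate).}
#'   \item{OU1}{Ornstein-Uhlenbeck, fixed root:
#'     `(1/(2 alpha)) exp(-alpha d_ij) (1 - exp(-2 alpha t_ij))` with
#'     `d_ij` the patristic distance and `t_ij = C[i, j]`.}
#'   \item{OU2}{Ornstein-Uhlenbeck, random (stationary) root:
#'     `(1/(2 alpha)) exp(-alpha d_ij)`.}
#'   \item{EB}{early burst with rate `r != 0`:
#'     `C' = (exp(r C) - 1) / r` (entrywise); `r -> 0` recovers `C`.}
#'   \item{null}{the identity matrix (no phylogenetic covariance).}
#' }
#' The OU stationary factor `1/(2 alpha)` is retained but is absorbed when
#' the variance is profiled, so OU likelihoods are comparable with the
#' other structures.
#'
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @param structure one of `"BM"`, `"OU1"`, `"OU2"`, `"lambda"`,
#'   `"kappa"`, `"delta"`, `"EB"`, `"null"`.
#' @param param the structure parameter (ignored for BM and null).
#' @return symmetric covariance matrix.
#' @export
transform_covariance <- function(tree, structure, param = NULL) {
  structure <- match.arg(structure, covariance_structures())
  C <- phylo_covariance(tree)
  D <- if (structure %in% c("OU1", "OU2"))
    stats::cophenetic(tree)[rownames(C), colnames(C)] else NULL
  transform_C(C, D, structure, param, tree = tree)
}

#' @rdname transform_covariance
#' @export
covariance_structures <- function() {
  c("BM", "OU1", "OU2", "lambda", "kappa", "delta", "EB", "null")
}

# core transform working from precomputed C (and patristic D for OU);
# kappa is the only structure that needs the tree itself.
transform_C <- function(C, D = NULL, structure, param = NULL, tree = NULL) {
  switch(structure,
    BM = C,
    null = diag(nrow(C)),
    lambda = {
      check_param(param, structure, param >= 0 && param <= 1, "[0, 1]")
      Cl <- C * param
      diag(Cl) <- diag(C)
      Cl
    },
    kappa = {
      check_param(param, structure, param >= 0, "[0, Inf)")
      tk <- tree
      tk$edge.length <- tk$edge.length^param
      phylo_covariance(tk)
    },
    delta = {
      check_param(param, structure, param > 0, "(0, Inf)")
      Tm <- max(diag(C))
      C^param * Tm^(1 - param)
    },
    OU1 = {
      check_param(param, structure, param > 0, "(0, Inf)")
      (1 / (2 * param)) * exp(-param * D) * (1 - exp(-2 * param * C))
    },
    OU2 = {
      check_param(param, structure, param > 0, "(0, Inf)")
      (1 / (2 * param)) * exp(-param * D)
    },
    EB = {
      check_param(param, structure, param != 0, "nonzero")
      (exp(param * C) - 1) / param
    })
}

check_param <- function(param, structure, ok, domain) {
  if (is.null(param) || length(param) != 1 || !is.finite(param) || !ok)
    stop(sprintf("parameter for structure '%s' must be in %s",
                 structure, domain))
  invisible(TRUE)
}

#' Gaussian GLS log-likelihood on a phylogenetic covariance
#'
#' Log density of `y ~ N(X beta, sigma2 * C)`. When `beta`/`sigma2` are
#' omitted they are profiled: `beta = (X' C^-1 X)^-1 X' C^-1 y` and
#' `sigma2 = (y - X beta)' C^-1 (y - X beta) / n` (ML).
#'
#' @param y numeric response vector.
#' @param X design matrix (defaults to an intercept).
#' @param C positive-definite covariance (relative scale).
#' @param sigma2,beta optional fixed parameters; both or neither.
#' @return list with `loglik`, `beta`, `sigma2`, `XtCiX_inv` (the
#'   unscaled coefficient covariance) and `rss` (the whitened residual sum
#'   of squares).
#' @export
gls_loglik <- function(y, X = NULL, C, sigma2 = NULL, beta = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  stopifnot(nrow(X) == n, nrow(C) == n, ncol(C) == n)
  R <- tryCatch(chol(C), error = function(e)
    stop(sprintf("covariance is not positive definite (rcond = %.3g)",
                 rcond(C))))
  logdet <- 2 * sum(log(diag(R)))
  yw <- backsolve(R, y, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  XtX <- crossprod(Xw)
  XtX_inv <- tryCatch(solve(XtX), error = function(e)
    stop("design matrix is rank deficient on the whitened scale"))
  if (is.null(beta)) beta <- drop(XtX_inv %*% crossprod(Xw, yw))
  resid <- yw - Xw %*% beta
  rss <- sum(resid^2)
  if (is.null(sigma2)) sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + rss / sigma2)
  list(loglik = ll, beta = stats::setNames(drop(beta), colnames(X)),
       sigma2 = sigma2, XtCiX_inv = XtX_inv, rss = rss)
}

#' Phylogenetic isolation: low-quantile divergence time
#'
#' For each tip, the q-th quantile (linear interpolation between order
#' statistics) of its divergence times to every other tip, where the
#' divergence time to another tip is the age of their MRCA (half the
#' patristic distance on an ultrametric tree). The default q = 0.10 gives
#' the 10th-percentile isolation score: large values mean the species has
#' no close relatives in the island pool.
#'
#' @param tree a dated [ape::phylo] with >= 2 tips.
#' @param q quantile in (0, 1), default 0.10.
#' @return data.frame with `species` and `q10_divergence` (Mya).
#' @export
phylo_isolation <- function(tree, q = 0.10) {
  n <- ape::Ntip(tree)
  if (n < 2) stop("phylogenetic isolation needs >= 2 tips")
  P <- stats::cophenetic(tree)[tree$tip.label, tree$tip.label] / 2
  score <- vapply(seq_len(n), function(i)
    unname(stats::quantile(P[i, -i], probs = q, type = 7)), numeric(1))
  data.frame(species = tree$tip.label, q10_divergence = score)
}
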