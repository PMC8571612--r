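make_traits <- function(tr, seed = 1) {
  tt <- simulate_species_traits(tr, seed = seed)
  n <- nrow(tt)
  set.seed(seed + 1000)
  tt$is_endemic <- runif(n) < 0.3
  tt$centroid_lat <- runif(n, 34, 40)
  tt$centroid_lon <- runif(n, 5, 25)
  tt$q10_divergence <- runif(n, 5, 60)
  tt
}

test_that("design matrix encodes interactions and standardizes columns", {
  tr <- simulate_tree(20, seed = 61)
  tt <- make_traits(tr)
  X <- build_design(tt)
  cont <- c("latitude", "longitude", "q10_divergence", "TL:no", "TL:yes")
  expect_true(all(abs(colMeans(X[, cont])) < 1e-10))
  expect_true(all(abs(apply(X[, cont], 2, sd) - 1) < 1e-10))
  # interaction columns before standardization: TL in the own group only
  Xr <- build_design(tt, standardize = FALSE)
  snake <- tt$is_snake
  expect_equal(unname(Xr[, "TL:yes"]), tt$total_length * snake)
  expect_equal(unname(Xr[, "TL:no"]), tt$total_length * (1 - snake))
  # an all-lizard table drops the all-zero snake columns with a warning
  tt_l <- tt; tt_l$is_snake <- FALSE
  expect_warning(Xl <- build_design(tt_l), "constant")
  expect_false(any(c("snake", "TL:yes") %in% colnames(Xl)))
})

test_that("null-structure PGLS equals ordinary least squares", {
  tr <- simulate_tree(40, seed = 62)
  tt <- make_traits(tr)
  X <- build_design(tt)
  y <- setNames(rnorm(40, 2), tt$species)
  fit <- fit_pgls(y, X, tr, "null")
  ref <- lm(y[rownames(X)] ~ X[, -1])
  expect_equal(unname(fit$coefficients$estimate),
               unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients$p_value),
               unname(summary(ref)$coefficients[, 4]), tolerance = 1e-8)
  expect_equal(fit$R2, summary(ref)$r.squared, tolerance = 1e-8)
})

test_that("fixed-lambda PGLS matches nlme::gls with corPagel", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(35, seed = 63)
  tt <- make_traits(tr)
  y <- simulate_traits(tr, sim_trait_config("lambda", lambda_true = 0.5,
                                            seed = 12))
  X <- build_design(tt)[, c("(Intercept)", "latitude", "TL:no")]
  fit <- fit_pgls(y, X, tr, "lambda", param = 0.5)
  df <- data.frame(y = y[tr$tip.label], X[tr$tip.label, -1])
  names(df) <- c("y", "latitude", "TLno")
  # rows are already in tip order; corPagel's covariate notice is benign
  ref <- suppressWarnings(nlme::gls(y ~ latitude + TLno, data = df,
                   correlation = ape::corPagel(0.5, phy = tr, form = ~1,
                                               fixed = TRUE),
                   method = "ML"))
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("lambda structure at the zero boundary is null plus one parameter", {
  tr <- simulate_tree(40, seed = 64)
  tt <- make_traits(tr)
  X <- build_design(tt)
  y <- setNames(rnorm(40), tt$species)      # no phylogenetic covariance
  f_null <- fit_pgls(y, X, tr, "null")
  f_lam0 <- fit_pgls(y, X, tr, "lambda", param = 0)
  expect_equal(f_lam0$logLik, f_null$logLik, tolerance = 1e-9)
  expect_equal(f_lam0$AIC, f_null$AIC + 2, tolerance = 1e-9)
  # nested structures: profiled lambda can never beat null's likelihood
  f_lam <- fit_pgls(y, X, tr, "lambda")
  expect_gte(f_lam$logLik + 1e-6, f_null$logLik)
})

test_that("AIC weights follow the delta-AIC formula", {
  tr <- simulate_tree(30, seed = 65)
  X <- matrix(1, 30, 1, dimnames = list(tr$tip.label, "(Intercept)"))
  y <- simulate_traits(tr, sim_trait_config("BM", seed = 13))
  f1 <- fit_pgls(y, X, tr, "BM")
  f2 <- fit_pgls(y, X, tr, "null")
  cmp <- select_model(list(f1, f2))
  expect_equal(sum(cmp$AIC_weight), 1, tolerance = 1e-9)
  expect_equal(min(cmp$delta_AIC), 0)
  # two fits with equal AIC split the weight; delta (0, 2) -> 0.731/0.269
  w <- exp(-c(0, 2) / 2); w <- w / sum(w)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  fits_same <- list(f1, f1)
  cmp2 <- select_model(fits_same)
  expect_equal(cmp2$AIC_weight, c(0.5, 0.5))
  # differing data rejected
  y2 <- y; y2[1] <- y2[1] + 1
  f3 <- fit_pgls(y2, X, tr, "null")
  expect_error(select_model(list(f1, f3)), "identical data")
})

test_that("BM-structure regression recovers a known slope", {
  tr <- simulate_tree(64, seed = 66)
  n <- 64
  ok <- 0
  for (rep in 1:30) {
    set.seed(700 + rep)
    x <- rnorm(n)
    noise <- simulate_traits(tr, sim_trait_config("BM", sigma2 = 0.01,
                                                  seed = 800 + rep))
    y <- setNames(2 * x + noise[tr$tip.label], tr$tip.label)
    X <- cbind("(Intercept)" = 1, x = x)
    rownames(X) <- tr$tip.label
    fit <- fit_pgls(y, X, tr, "BM")
    slope <- fit$coefficients$estimate[fit$coefficients$term == "x"]
    if (abs(slope - 2) <= 0.2) ok <- ok + 1
  }
  expect_gte(ok, 27)
})

test_that("fit_pgls is equivariant under consistent row permutation", {
  tr <- simulate_tree(25, seed = 67)
  tt <- make_traits(tr)
  X <- build_design(tt)
  y <- simulate_traits(tr, sim_trait_config("BM", seed = 14))
  f1 <- fit_pgls(y, X, tr, "lambda")
  perm <- sample(25)
  f2 <- fit_pgls(y[perm], X[perm, ], tr, "lambda")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(f1$AIC, f2$AIC, tolerance = 1e-8)
})

test_that("species centroids average occupied island coordinates", {
  sites <- data.frame(site_id = c("a", "b", "c"),
                      lon = c(0, 10, 20), lat = c(35, 37, 39))
  occ <- matrix(c(1, 0, 0,
                  1, 1, 0,
                  0, 1, 1), 3, 3, byrow = TRUE,
                dimnames = list(c("s1", "s2", "s3"), c("a", "b", "c")))
  cent <- species_centroid(occ, sites)
  expect_equal(cent$centroid_lon, c(0, 5, 15))
  expect_equal(cent$centroid_lat, c(35, 36, 38))
  # duplicate site columns are ignored
  occ_dup <- cbind(occ, a = occ[, "a"])
  expect_equal(species_centroid(occ_dup, sites)$centroid_lon, c(0, 5, 15))
  occ_bad <- occ; occ_bad[1, ] <- 0
  expect_error(species_centroid(occ_bad, sites), "empty")
})
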