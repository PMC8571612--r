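test_that("Blomberg's K is exactly 1 on star phylogenies", {
  set.seed(41)
  for (n in c(10, 25)) {
    st <- star_tree(n, t = runif(1, 0.5, 5))
    y <- setNames(rnorm(n), st$tip.label)
    K <- blombergs_K(y, st, n_perm = 0)
    expect_lt(abs(K$estimate - 1), 1e-8)
  }
})

test_that("K is scale-invariant and the identity permutation reproduces it", {
  tr <- simulate_tree(30, seed = 51)
  y <- simulate_traits(tr, sim_trait_config("BM", seed = 3))
  K1 <- blombergs_K(y, tr, n_perm = 0)
  K2 <- blombergs_K(7.3 * y, tr, n_perm = 0)
  expect_equal(K1$estimate, K2$estimate, tolerance = 1e-10)
  # identity permutation: same K (computed via the batched permuter)
  expect_equal(blombergs_K(y[tr$tip.label], tr, n_perm = 0)$estimate,
               K1$estimate)
  # constant trait flagged degenerate
  yc <- setNames(rep(1, 30), tr$tip.label)
  expect_true(blombergs_K(yc, tr, n_perm = 0)$degenerate)
})

test_that("lambda estimate is invariant to affine trait transforms", {
  tr <- simulate_tree(40, seed = 52)
  y <- simulate_traits(tr, sim_trait_config("lambda", lambda_true = 0.6,
                                            seed = 5))
  l1 <- pagels_lambda(y, tr)
  l2 <- pagels_lambda(-2.5 * y + 11, tr)
  expect_equal(l1$estimate, l2$estimate, tolerance = 1e-6)
  expect_true(l1$estimate >= 0 && l1$estimate <= 1)
  # lnL(lambda_hat) = lnL(0) gives LRT 0 and p = 1
  y0 <- simulate_traits(tr, sim_trait_config("lambda", lambda_true = 0,
                                             seed = 6))
  l0 <- pagels_lambda(y0, tr)
  if (l0$estimate == 0) expect_equal(l0$p_value, 1)
  expect_error(pagels_lambda(y[1:5], ape::keep.tip(tr, names(y)[1:5])),
               ">= 10 tips")
})

test_that("lambda and K agree with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(45, seed = 53)
  for (lam_true in c(0.2, 0.9)) {
    y <- simulate_traits(tr, sim_trait_config("lambda",
                                              lambda_true = lam_true,
                                              seed = 60 + lam_true * 10))
    ours <- pagels_lambda(y, tr)
    ref <- phytools::phylosig(tr, y, method = "lambda")
    expect_equal(ours$estimate, ref$lambda, tolerance = 0.01)
    expect_equal(ours$loglik, ref$logL, tolerance = 1e-3)
    K_ours <- blombergs_K(y, tr, n_perm = 0)
    K_ref <- phytools::phylosig(tr, y, method = "K")
    expect_equal(K_ours$estimate, unclass(K_ref)[[1]], tolerance = 1e-6)
  }
})

test_that("scenario uncertainty summarizes per-scenario estimates", {
  tr <- simulate_tree(40, seed = 54)
  y <- simulate_traits(tr, sim_trait_config("BM", seed = 7))
  # identical values across scenarios collapse to a scenario-free row
  metrics <- do.call(rbind, lapply(c("M1", "M2", "M3"), function(s)
    data.frame(species = tr$tip.label, scenario = s, v = unname(y))))
  out <- signal_with_model_uncertainty(metrics, tr, "lambda",
                                       variables = "v")
  expect_true(out$scenario_free)
  expect_true(is.na(out$ci_low))
  # differing values: headline = mean, interval = min-max of the three
  metrics2 <- metrics
  jit <- c(M1 = 0, M2 = 0.4, M3 = 0.8)
  metrics2$v <- metrics2$v + jit[metrics2$scenario] *
    as.numeric(factor(metrics2$species))
  out2 <- signal_with_model_uncertainty(metrics2, tr, "lambda",
                                        variables = "v")
  per <- vapply(c("M1", "M2", "M3"), function(s) {
    d <- metrics2[metrics2$scenario == s, ]
    pagels_lambda(setNames(d$v, d$species), tr)$estimate
  }, numeric(1))
  expect_equal(out2$estimate, mean(per), tolerance = 1e-9)
  expect_equal(out2$ci_low, min(per))
  expect_equal(out2$ci_high, max(per))
  expect_false(out2$scenario_free)
})

test_that("group-wise signal separates clades with contrasting lambda", {
  tr <- simulate_tree(80, seed = 55)
  tt <- simulate_species_traits(tr, seed = 8, prop_snake = 0.5)
  groups <- setNames(ifelse(tt$is_snake, "snakes", "lizards"), tt$species)
  snakes <- names(groups)[groups == "snakes"]
  lizards <- names(groups)[groups == "lizards"]
  tr_s <- ape::keep.tip(tr, snakes)
  tr_l <- ape::keep.tip(tr, lizards)
  # ultrametricity survives pruning
  ds <- diag(phylo_covariance(tr_s))
  expect_lt(diff(range(ds)), 1e-9 * max(ds))
  # strong signal within snakes, none within lizards
  hits <- 0
  for (rep in 1:20) {
    ys <- simulate_traits(tr_s, sim_trait_config("BM", seed = 100 + rep))
    yl <- simulate_traits(tr_l, sim_trait_config("lambda", lambda_true = 0,
                                                 seed = 200 + rep))
    y <- c(ys, yl)
    gs <- groupwise_signal(y, tr, groups, n_perm = 0)
    lam <- gs[gs$statistic == "lambda", ]
    hi <- lam$estimate[lam$group == "snakes"]
    lo <- lam$estimate[lam$group == "lizards"]
    if (hi > 0.5 && lo < 0.3) hits <- hits + 1
  }
  expect_gte(hits, 16)
  # whole-tree group equals the ungrouped estimate
  y1 <- simulate_traits(tr, sim_trait_config("BM", seed = 9))
  all_grp <- groupwise_signal(y1, tr, setNames(rep("all", 80),
                                               tr$tip.label), n_perm = 0)
  expect_equal(all_grp$estimate[all_grp$statistic == "lambda"],
               pagels_lambda(y1, tr)$estimate, tolerance = 1e-8)
  expect_error(groupwise_signal(y1, tr, groups[-(1:3)]), "group")
})
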