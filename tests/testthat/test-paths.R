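test_that("accumulated cost to an orthogonal neighbour is r * cell_size", {
  res <- manual_resistance(matrix(3, 4, 4), cell_size = 2)
  ac <- accumulate_cost(res, cbind(row = 2, col = 2))
  expect_equal(ac$cost[2, 2], 0)
  expect_equal(ac$cost[2, 3], 3 * 2)
  expect_equal(ac$cost[3, 3], 3 * 2 * sqrt(2))
  expect_equal(ac$backlink[2, 2], 0L)
})

test_that("accumulated costs equal exhaustive Bellman on a hand-set 5x5", {
  set.seed(11)
  r <- matrix(sample(1:9, 25, replace = TRUE), 5, 5)
  res <- manual_resistance(r, cell_size = 1)
  ac <- accumulate_cost(res, cbind(row = 1, col = 1))
  oracle <- bellman_costs(res, cbind(1, 1))
  expect_equal(ac$cost, oracle, tolerance = 1e-12)
  # backlinks reconstruct optimal paths: walking them reproduces the cost
  for (cell in c(25, 13, 7)) {
    i <- ((cell - 1) %% 5) + 1; j <- ((cell - 1) %/% 5) + 1
    total <- 0
    while (!(i == 1 && j == 1)) {
      prev <- ac$backlink[i, j]
      pi <- ((prev - 1) %% 5) + 1; pj <- ((prev - 1) %/% 5) + 1
      step <- sqrt((i - pi)^2 + (j - pj)^2)
      total <- total + step * (r[i, j] + r[pi, pj]) / 2
      i <- pi; j <- pj
    }
    expect_equal(total, ac$cost[((cell - 1) %% 5) + 1, ((cell - 1) %/% 5) + 1])
  }
})

test_that("multi-origin accumulation takes the nearest origin", {
  res <- manual_resistance(matrix(1, 3, 9), cell_size = 1)
  ac <- accumulate_cost(res, rbind(c(2, 1), c(2, 9)))
  expect_equal(ac$cost[2, 5], 4)
  expect_equal(ac$cost[2, 2], 1)
  expect_equal(ac$cost[2, 8], 1)
  expect_error(accumulate_cost(
    manual_resistance(matrix(1, 3, 3),
                      impassable = matrix(TRUE, 3, 3)),
    cbind(2, 2)), "impassable")
})

test_that("a ringed destination is unreachable and flagged, not an error", {
  imp <- matrix(FALSE, 5, 5)
  imp[2:4, 2] <- TRUE; imp[2:4, 4] <- TRUE; imp[2, 3] <- TRUE; imp[4, 3] <- TRUE
  res <- manual_resistance(matrix(1, 5, 5), impassable = imp)
  ac <- accumulate_cost(res, cbind(1, 1))
  expect_true(is.infinite(ac$cost[3, 3]))
  p <- least_cost_path(res, c(1, 1), c(3, 3))
  expect_false(p$reachable)
})

test_that("least-cost path realizes the accumulated-cost optimum", {
  set.seed(23)
  r <- matrix(runif(36, 1, 10), 6, 6)
  res <- manual_resistance(r, cell_size = 1.5)
  ac <- accumulate_cost(res, cbind(1, 1))
  p <- least_cost_path(res, c(1, 1), c(6, 6))
  expect_equal(p$cost, ac$cost[6, 6], tolerance = 1e-9)
  expect_equal(p$length_km, sum(p$step_km))
  # consecutive cells are 8-neighbours
  d <- abs(diff(p$cells))
  expect_true(all(pmax(d[, 1], d[, 2]) == 1))
  # identity path
  p0 <- least_cost_path(res, c(3, 3), c(3, 3))
  expect_equal(p0$cost, 0)
  expect_equal(p0$length_km, 0)
})

test_that("triangle inequality holds for least-cost distances", {
  set.seed(31)
  for (rep in 1:5) {
    r <- matrix(runif(64, 1, 8), 8, 8)
    res <- manual_resistance(r)
    pts <- list(c(1, 1), c(8, 8), c(1, 8))
    d <- function(a, b) least_cost_path(res, a, b)$cost
    ab <- d(pts[[1]], pts[[2]]); bc <- d(pts[[2]], pts[[3]])
    ac <- d(pts[[1]], pts[[3]])
    expect_lte(ac, ab + bc + 1e-9)
  }
})

test_that("M1 and M3 route choice trades distance against sea cost", {
  # two-route world: a short crossing over deep water vs a long shallow arc
  e <- matrix(-400, 6, 8)
  e[3, 2] <- 10; e[3, 7] <- 10                      # two islets
  e[3, 3:6] <- -500                                  # deep direct line
  e[6, 2:7] <- -20; e[4:5, 2] <- -20; e[4:5, 7] <- -20  # shallow detour
  g <- elevation_grid(e, cell_size = 1)
  m1 <- build_resistance(g, resistance_config("M1"))
  m3 <- build_resistance(g, resistance_config("M3"))
  p1 <- least_cost_path(m1, c(3, 2), c(3, 7))
  p3 <- least_cost_path(m3, c(3, 2), c(3, 7))
  expect_gte(p3$length_km, p1$length_km)
  # cost of the M1-optimal route evaluated under M3 is no better than the
  # M3 optimum
  reval <- function(res, cells) {
    idx <- (cells[, 2] - 1) * 6 + cells[, 1]
    k <- length(idx)
    d <- sqrt(rowSums(abs(diff(cells))^2))
    sum(d * (res$res[idx[-k]] + res$res[idx[-1]]) / 2)
  }
  expect_gte(reval(m3, p1$cells) + 1e-9, p3$cost)
})

test_that("M2 paths never dip below the depth threshold", {
  w <- channel_world(channel_depth = -100)
  res <- build_resistance(w$grid, resistance_config("M2"))
  s <- w$sites
  p <- least_cost_path(res, unlist(s[1, c("row", "col")]),
                       unlist(s[3, c("row", "col")]))
  expect_true(p$reachable)
  expect_true(all(p$elev >= -150))
  # deep channels close the route entirely
  w2 <- channel_world(channel_depth = -300)
  res2 <- build_resistance(w2$grid, resistance_config("M2"))
  p2 <- least_cost_path(res2, unlist(s[1, c("row", "col")]),
                        unlist(s[3, c("row", "col")]))
  expect_false(p2$reachable)
})

test_that("travel chains accrete islands nearest-first", {
  # three islands in a line east of the mainland
  w <- make_world(world_config(
    n_rows = 16, n_cols = 48, cell_size = 2, mainland_width = 3,
    islands = list(island_spec(8, 14, 2, 100), island_spec(8, 26, 2, 100),
                   island_spec(8, 38, 2, 100)),
    channel_depth = -80, sea_base_depth = -400))
  res <- build_resistance(w$grid, resistance_config("M1"))
  ids <- c("island_01", "island_02", "island_03")
  ch <- build_travel_chain(res, "mainland", ids, w$sites)
  expect_equal(length(ch$travels), 3L)
  hops <- t(vapply(ch$travels, function(tr) c(tr$from, tr$to), character(2)))
  expect_equal(hops[, 2], ids)                       # closest to furthest
  expect_equal(hops[, 1], c("mainland", "island_01", "island_02"))
  cache <- site_cost_cache(res, w$sites)
  # total travel equals the sum of the three pairwise least-cost lengths
  lens <- vapply(ch$travels, function(tr) tr$path$length_km, numeric(1))
  expect_equal(sum(lens),
               sum(vapply(seq_len(3), function(k) {
                 from <- c("mainland", ids)[k]
                 p <- least_cost_path(res,
                   unlist(w$sites[w$sites$site_id == from, c("row", "col")]),
                   unlist(w$sites[w$sites$site_id == ids[k], c("row", "col")]))
                 p$length_km
               }, numeric(1))))
  # single island: one travel from the origin
  ch1 <- build_travel_chain(res, "mainland", "island_01", w$sites)
  expect_equal(length(ch1$travels), 1L)
  # unreachable islands reported, not raised
  w2 <- make_world(world_config(
    n_rows = 16, n_cols = 48, cell_size = 2, mainland_width = 3,
    islands = list(island_spec(8, 30, 2, 100)),
    channel_depth = -300, sea_base_depth = -400))
  res2 <- build_resistance(w2$grid, resistance_config("M2"))
  ch2 <- build_travel_chain(res2, "mainland", "island_01", w2$sites)
  expect_equal(length(ch2$travels), 0L)
  expect_equal(ch2$unreachable, "island_01")
})
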