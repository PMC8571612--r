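#' Resistance-scenario configuration
#'
#' Parameterizes the per-cell traversal cost built by [build_resistance()].
#' The three scenarios encode increasing sea resistance:
#' \describe{
#'   \item{M1}{sea crossing is costly but feasible (`sea_multiplier = 5`).}
#'   \item{M2}{colonization during eustatic regressions only: like M1, but
#'     sea cells deeper than `depth_threshold` (default -150 m, the
#'     last-glacial minimum sea level) are impassable.}
#'   \item{M3}{sea crossing very unlikely (`sea_multiplier = 100`), so
#'     routes hug land even at a large detour cost.}
#' }
#'
#' @param scenario `"M1"`, `"M2"` or `"M3"`.
#' @param depth_threshold m (< 0); M2 barrier depth.
#' @param land_base base land cost per km (> 0).
#' @param sea_multiplier land/sea cost contrast (>= 1); defaults 5 (M1,
#'   M2) or 100 (M3).
#' @param w_dist sea-cost weight per km of distance to the coast.
#' @param w_depth sea-cost weight per m of sea-floor depth.
#' @param w_elev land-cost weight per m of terrain elevation.
#' @return a `resistance_config`.
#' @export
resistance_config <- function(scenario = c("M1", "M2", "M3"),
                              depth_threshold = -150, land_base = 1,
                              sea_multiplier = NULL,
                              w_dist = 0.02, w_depth = 0.002,
                              w_elev = 0.001) {
  scenario <- match.arg(scenario)
  if (is.null(sea_multiplier))
    sea_multiplier <- if (scenario == "M3") 100 else 5
  stopifnot(depth_threshold < 0, land_base > 0, sea_multiplier >= 1,
            w_dist >= 0, w_depth >= 0, w_elev >= 0)
  structure(list(scenario = scenario, depth_threshold = depth_threshold,
                 land_base = land_base, sea_multiplier = sea_multiplier,
                 w_dist = w_dist, w_depth = w_depth, w_elev = w_elev),
            class = "resistance_config")
}

#' Euclidean distance to the coastline
#'
#' Distance (km) from every cell centre to the nearest coastal land cell.
#' A land cell (elevation >= 0) is coastal when at least one of its
#' 4-neighbours is sea (elevation < 0); coastal land cells score 0.
#'
#' @param grid an [elevation_grid()] with at least one land and one sea
#'   cell.
#' @return numeric matrix of distances (km), same shape as the grid.
#' @export
distance_to_coast <- function(grid) {
  e <- grid$elev
  land <- e >= 0
  if (all(land) || !any(land))
    stop("coast undefined: grid must contain both land and sea cells")
  nr <- nrow(e); nc <- ncol(e)
  pad <- function(shift_r, shift_c) {
    m <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + shift_r; cs <- seq_len(nc) + shift_c
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    m[ok_r, ok_c] <- !land[rs[ok_r], cs[ok_c]]
    m
  }
  sea_adj <- pad(-1, 0) | pad(1, 0) | pad(0, -1) | pad(0, 1)
  coastal <- land & sea_adj
  if (!any(coastal))
    stop("coast undefined: no land cell borders sea in the 4-neighbourhood")
  br <- row(e)[coastal]; bc <- col(e)[coastal]
  rr <- as.vector(row(e)); cc <- as.vector(col(e))
  dmin <- rep(Inf, nr * nc)
  for (k in seq_along(br)) {
    dmin <- pmin(dmin, (rr - br[k])^2 + (cc - bc[k])^2)
  }
  matrix(sqrt(dmin) * grid$cell_size, nr, nc)
}

#' Build a resistance surface
#'
#' Per-cell traversal cost (per km) from elevation under a scenario:
#' land cells (elevation >= 0) cost
#' `land_base * (1 + w_elev * elev)`; sea cells cost
#' `land_base * sea_multiplier * (1 + w_dist * dist_coast + w_depth * depth)`
#' with `depth = -elev`. Under M2, sea cells deeper than `depth_threshold`
#' are impassable; M1 and M3 have no impassable cells. All three stated
#' resistance gradients are monotone: cost rises with distance to coast
#' and depth at sea, and with elevation on land.
#'
#' @param grid an [elevation_grid()].
#' @param cfg a [resistance_config()].
#' @return a `resistance_grid`: list with `res` (cost per km),
#'   `impassable` (logical matrix), the elevation matrix, `cell_size`,
#'   georeferencing and the config.
#' @export
build_resistance <- function(grid, cfg) {
  stopifnot(inherits(cfg, "resistance_config"))
  e <- grid$elev
  land <- e >= 0
  dc <- distance_to_coast(grid)
  res <- matrix(NA_real_, nrow(e), ncol(e))
  res[land] <- cfg$land_base * (1 + cfg$w_elev * pmax(e[land], 0))
  res[!land] <- cfg$land_base * cfg$sea_multiplier *
    (1 + cfg$w_dist * dc[!land] + cfg$w_depth * (-e[!land]))
  impassable <- matrix(FALSE, nrow(e), ncol(e))
  if (cfg$scenario == "M2") impassable <- !land & e < cfg$depth_threshold
  structure(list(res = res, impassable = impassable, elev = e,
                 cell_size = grid$cell_size, xll = grid$xll, yll = grid$yll,
                 nodata = grid$nodata, config = cfg),
            class = "resistance_grid")
}

#' @export
print.resistance_grid <- function(x, ...) {
  cat(sprintf("<resistance_grid> scenario %s, %d x %d cells, %d impassable\n",
              x$config$scenario, nrow(x$res), ncol(x$res),
              sum(x$impassable)))
  invisible(x)
}

#' Write a resistance grid as ESRI ASCII
#'
#' Impassable cells are encoded as the NODATA value.
#' @param res a `resistance_grid`.
#' @param path output file path.
#' @export
write_resistance_ascii <- function(res, path) {
  m <- res$res
  m[res$impassable] <- NA_real_
  g <- elevation_grid(m, res$cell_size, res$xll, res$yll, res$nodata)
  write_esri_ascii(g, path)
}
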