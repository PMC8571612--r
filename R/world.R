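#' Island specification
#'
#' One conical island: a circular footprint whose elevation ramps linearly
#' from just above sea level at the coastline to `peak` at the centre.
#'
#' @param row,col centre cell of the island.
#' @param radius footprint radius in cells (>= 1).
#' @param peak peak elevation in m (> 0).
#' @export
island_spec <- function(row, col, radius, peak = 400) {
  stopifnot(radius >= 1, peak > 0)
  list(row = as.integer(row), col = as.integer(col),
       radius = radius, peak = peak)
}

#' Synthetic-world configuration
#'
#' Parameters of the synthetic archipelago: a mainland strip along the
#' western edge, conical islands in a deep sea, and shallow channels carved
#' along a spanning chain of nearest-neighbour links so that, at the default
#' depths, every island is reachable during a -150 m eustatic regression.
#'
#' @param n_rows,n_cols grid dimensions (>= 8).
#' @param cell_size cell edge (km).
#' @param mainland_width width of the western mainland strip in cells
#'   (0 for a sea-only world with islands).
#' @param islands list of [island_spec()] objects.
#' @param channel_depth elevation (m, < 0) of the shallow channels.
#' @param sea_base_depth elevation (m, < 0) of the open sea floor;
#'   must be <= channel_depth.
#' @param mainland_peak peak elevation (m) of the mainland at the western
#'   edge; elevation ramps down to the coast.
#' @param seed integer seed (kept for config completeness; world generation
#'   is deterministic given the config).
#' @return a `world_config` list.
#' @export
world_config <- function(n_rows = 60, n_cols = 90, cell_size = 6,
                         mainland_width = 8,
                         islands = default_islands(),
                         channel_depth = -120, sea_base_depth = -1200,
                         mainland_peak = 300, seed = 1L) {
  stopifnot(n_rows >= 8, n_cols >= 8, cell_size > 0,
            mainland_width >= 0, channel_depth < 0, sea_base_depth < 0,
            sea_base_depth <= channel_depth, mainland_peak > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size,
                 mainland_width = as.integer(mainland_width),
                 islands = islands, channel_depth = channel_depth,
                 sea_base_depth = sea_base_depth,
                 mainland_peak = mainland_peak, seed = as.integer(seed)),
            class = "world_config")
}

#' Default island layout
#'
#' Six islands arranged as a loose west-to-east chain across the basin,
#' with radii between 2 and 5 cells, emulating an archipelago with large
#' central islands and small outliers.
#' @export
default_islands <- function() {
  list(
    island_spec(row = 22, col = 24, radius = 4, peak = 600),
    island_spec(row = 38, col = 33, radius = 5, peak = 800),
    island_spec(row = 15, col = 44, radius = 2, peak = 200),
    island_spec(row = 30, col = 55, radius = 3, peak = 450),
    island_spec(row = 44, col = 62, radius = 2, peak = 250),
    island_spec(row = 24, col = 75, radius = 4, peak = 700)
  )
}

#' Generate a synthetic archipelago
#'
#' Builds the elevation grid and the site table from a [world_config()].
#' The mainland occupies the westernmost `mainland_width` columns with a
#' linear elevation ramp toward the coast; each island is a circular cone.
#' The open sea floor lies at `sea_base_depth`; shallow channels at
#' `channel_depth` are carved along straight lines joining each island to
#' its nearest already-linked site (islands are linked in order of distance
#' from the mainland origin, the first one to the mainland itself), so the
#' channels form a spanning chain.
#'
#' @param config a [world_config()].
#' @return list with `grid` (an [elevation_grid()]) and `sites` (data.frame:
#'   `site_id`, `type` ("mainland"/"island"), `row`, `col`, `x`, `y`,
#'   `lon`, `lat`, `radius`, `peak`).
#' @export
make_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  nr <- config$n_rows; nc <- config$n_cols
  elev <- matrix(config$sea_base_depth, nr, nc)

  mw <- config$mainland_width
  mainland_mask <- matrix(FALSE, nr, nc)
  if (mw > 0) {
    for (j in seq_len(mw)) {
      elev[, j] <- config$mainland_peak * (mw - j + 1) / mw
    }
    mainland_mask[, seq_len(mw)] <- TRUE
  }

  rows <- row(elev); cols <- col(elev)
  masks <- list()
  for (i in seq_along(config$islands)) {
    isl <- config$islands[[i]]
    if (isl$row < 1 || isl$row > nr || isl$col < 1 || isl$col > nc)
      stop("island ", i, " centre lies outside the grid")
    d <- sqrt((rows - isl$row)^2 + (cols - isl$col)^2)
    mask <- d < isl$radius
    if (any(mask & mainland_mask))
      stop("island ", i, " footprint overlaps the mainland strip")
    for (k in seq_along(masks)) {
      if (any(mask & masks[[k]]))
        stop("island footprints ", k, " and ", i, " overlap")
    }
    masks[[i]] <- mask
    elev[mask] <- isl$peak * (1 - d[mask] / isl$radius)
  }

  # site table: one mainland origin (centre of the coastal edge) + centroids
  origin_row <- as.integer(ceiling(nr / 2))
  sites <- list()
  if (mw > 0) {
    sites[[1]] <- data.frame(site_id = "mainland", type = "mainland",
                             row = origin_row, col = mw,
                             radius = NA_real_, peak = NA_real_)
  }
  for (i in seq_along(config$islands)) {
    isl <- config$islands[[i]]
    sites[[length(sites) + 1L]] <-
      data.frame(site_id = sprintf("island_%02d", i), type = "island",
                 row = isl$row, col = isl$col,
                 radius = isl$radius, peak = isl$peak)
  }
  sites <- do.call(rbind, sites)

  # carve shallow channels along a spanning chain of sites
  grid <- elevation_grid(elev, cell_size = config$cell_size)
  isl_idx <- which(sites$type == "island")
  if (length(isl_idx) >= 1) {
    anchor <- if (mw > 0) which(sites$type == "mainland")[1] else isl_idx[1]
    d_anchor <- sqrt((sites$row[isl_idx] - sites$row[anchor])^2 +
                     (sites$col[isl_idx] - sites$col[anchor])^2)
    order_isl <- isl_idx[order(d_anchor)]
    linked <- anchor
    for (i in order_isl) {
      if (i == anchor) { next }
      dl <- sqrt((sites$row[linked] - sites$row[i])^2 +
                 (sites$col[linked] - sites$col[i])^2)
      j <- linked[which.min(dl)]
      cells <- grid_line_cells(sites$row[i], sites$col[i],
                               sites$row[j], sites$col[j])
      sel <- elev[cells] < 0
      elev[cells[sel, , drop = FALSE]] <- config$channel_depth
      linked <- c(linked, i)
    }
    grid$elev <- elev
  }

  xy <- grid_xy(grid, sites$row, sites$col)
  ll <- grid_lonlat(grid, sites$row, sites$col)
  sites$x <- xy$x; sites$y <- xy$y
  sites$lon <- ll$lon; sites$lat <- ll$lat
  sites <- sites[, c("site_id", "type", "row", "col", "x", "y",
                     "lon", "lat", "radius", "peak")]
  rownames(sites) <- NULL
  list(grid = grid, sites = sites)
}
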