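# --- lattice graph ---------------------------------------------------------

# Build the 8-connected lattice graph over passable cells of a resistance
# grid. Edge weight = step length (cell_size, or cell_size * sqrt(2) on
# diagonals) times the arithmetic mean of the two endpoint resistances
# (the GRASS r.cost convention). Vertices are numbered by cell index
# (column-major, as in R matrices); impassable cells keep their vertex but
# have no incident edges.
lattice_graph <- function(res) {
  r <- res$res
  nr <- nrow(r); nc <- ncol(r)
  pass <- !res$impassable
  idx <- matrix(seq_len(nr * nc), nr, nc)
  cs <- res$cell_size

  edge_set <- function(dr, dc) {
    rows <- seq_len(nr - abs(dr)); cols <- seq_len(nc - abs(dc))
    r0 <- if (dr >= 0) rows else rows + abs(dr)
    c0 <- if (dc >= 0) cols else cols + abs(dc)
    from <- idx[r0, c0, drop = FALSE]
    to <- idx[r0 + dr, c0 + dc, drop = FALSE]
    ok <- pass[as.vector(from)] & pass[as.vector(to)]
    f <- as.vector(from)[ok]; t <- as.vector(to)[ok]
    w <- cs * sqrt(dr^2 + dc^2) * (r[f] + r[t]) / 2
    list(from = f, to = t, w = w)
  }
  dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  es <- lapply(dirs, function(d) edge_set(d[1], d[2]))
  from <- unlist(lapply(es, `[[`, "from"), use.names = FALSE)
  to <- unlist(lapply(es, `[[`, "to"), use.names = FALSE)
  w <- unlist(lapply(es, `[[`, "w"), use.names = FALSE)
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  g
}

cell_index <- function(res, row, col) {
  (as.integer(col) - 1L) * nrow(res$res) + as.integer(row)
}

# --- accumulated cost ------------------------------------------------------

#' Accumulated least-cost surface
#'
#' Minimal accumulated traversal cost from the nearest of a set of origin
#' cells to every cell of the grid, under 8-connected moves whose cost is
#' the step length times the mean resistance of the two endpoint cells.
#' Backlinks record, for each reached cell, the previous cell on one
#' optimal route, allowing path reconstruction.
#'
#' @param res a `resistance_grid` from [build_resistance()].
#' @param origins matrix or data.frame with columns `row`, `col` (>= 1
#'   passable origin).
#' @return list with `cost` (matrix; 0 at origins, `Inf` where
#'   unreachable, `NA` on impassable cells) and `backlink` (matrix of
#'   predecessor cell indices; 0 at origins, `NA` elsewhere-unreached).
#' @export
accumulate_cost <- function(res, origins) {
  origins <- as.matrix(origins)
  ov <- cell_index(res, origins[, 1], origins[, 2])
  ov <- ov[!res$impassable[cbind(origins[, 1], origins[, 2])]]
  if (length(ov) == 0) stop("all origin cells are impassable")
  g <- lattice_graph(res)
  nv <- igraph::vcount(g)
  w <- igraph::E(g)$weight
  d <- rep(Inf, nv)
  dmat <- igraph::distances(g, v = ov, weights = w)
  d <- if (length(ov) == 1) dmat[1, ] else apply(dmat, 2, min)
  # backlinks: a predecessor of v is any neighbour u with d[u] + w(u,v)
  # equal to d[v]; the smallest such cell index is kept, origins get 0.
  ends <- igraph::as_edgelist(g, names = FALSE)
  u <- c(ends[, 1], ends[, 2]); v2 <- c(ends[, 2], ends[, 1])
  ww <- c(w, w)
  tol <- 1e-9 * (1 + max(d[is.finite(d)]))
  ok <- is.finite(d[u]) & abs(d[u] + ww - d[v2]) <= tol
  back <- rep(NA_integer_, nv)
  if (any(ok)) {
    cand <- data.frame(v = v2[ok], u = u[ok])
    cand <- cand[order(cand$v, cand$u), ]
    first <- !duplicated(cand$v)
    back[cand$v[first]] <- cand$u[first]
  }
  back[ov] <- 0L
  cost <- matrix(d, nrow(res$res), ncol(res$res))
  back <- matrix(back, nrow(res$res), ncol(res$res))
  back[is.infinite(cost)] <- NA_integer_
  cost[res$impassable] <- NA_real_
  back[res$impassable] <- NA_integer_
  list(cost = cost, backlink = back)
}

# --- single least-cost path ------------------------------------------------

path_from_cells <- function(res, cells) {
  nr <- nrow(res$res)
  rows <- ((cells - 1L) %% nr) + 1L
  cols <- ((cells - 1L) %/% nr) + 1L
  k <- length(cells)
  if (k >= 2) {
    dr <- diff(rows); dc <- diff(cols)
    step_km <- res$cell_size * sqrt(dr^2 + dc^2)
    cost <- sum(step_km * (res$res[cells[-k]] + res$res[cells[-1]]) / 2)
  } else {
    step_km <- numeric(0)
    cost <- 0
  }
  structure(list(cells = cbind(row = rows, col = cols),
                 step_km = step_km,
                 elev = res$elev[cells],
                 length_km = sum(step_km),
                 cost = cost,
                 reachable = TRUE),
            class = "dispersal_path")
}

#' @export
print.dispersal_path <- function(x, ...) {
  if (!x$reachable) cat("<dispersal_path> unreachable\n")
  else cat(sprintf("<dispersal_path> %d cells, %.1f km, cost %.2f\n",
                   nrow(x$cells), x$length_km, x$cost))
  invisible(x)
}

#' Least-cost path between two cells
#'
#' @param res a `resistance_grid`.
#' @param origin,dest vectors `c(row, col)` (or 1-row matrices); both must
#'   be passable.
#' @return a `dispersal_path`: cell steps, per-step lengths (km), per-cell
#'   bed elevation, total length and accumulated cost. If `dest` cannot be
#'   reached the object has `reachable = FALSE` (no error).
#' @export
least_cost_path <- function(res, origin, dest) {
  origin <- as.integer(origin); dest <- as.integer(dest)
  o <- cell_index(res, origin[1], origin[2])
  d <- cell_index(res, dest[1], dest[2])
  if (res$impassable[o] || res$impassable[d])
    stop("origin and destination must be passable cells")
  if (o == d) return(path_from_cells(res, o))
  g <- lattice_graph(res)
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = o, to = d,
                           weights = igraph::E(g)$weight))
  cells <- as.integer(sp$vpath[[1]])
  if (length(cells) == 0)
    return(structure(list(cells = NULL, step_km = numeric(0),
                          elev = numeric(0), length_km = NA_real_,
                          cost = NA_real_, reachable = FALSE),
                     class = "dispersal_path"))
  path_from_cells(res, cells)
}

# --- site-to-site cache ----------------------------------------------------

#' Least-cost distances and paths between sites
#'
#' Runs one single-source shortest-path pass per site and caches the
#' pairwise least-cost distances and cell paths. Species-level travel
#' chains reuse the cache so the grid search is done once per scenario.
#'
#' @param res a `resistance_grid`.
#' @param sites site table (`site_id`, `row`, `col`).
#' @return a `site_cost_cache`: `D` (site x site cost matrix, `Inf` when
#'   unreachable) and `paths` (list of lists of cell-index vectors).
#' @export
site_cost_cache <- function(res, sites) {
  ids <- sites$site_id
  v <- cell_index(res, sites$row, sites$col)
  if (any(res$impassable[v])) stop("site centroid on an impassable cell")
  g <- lattice_graph(res)
  n <- length(v)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  paths <- stats::setNames(vector("list", n), ids)
  w <- igraph::E(g)$weight
  for (i in seq_len(n)) {
    D[i, ] <- igraph::distances(g, v = v[i], to = v, weights = w)[1, ]
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = v[i], to = v, weights = w))
    paths[[i]] <- stats::setNames(
      lapply(sp$vpath, as.integer), ids)
  }
  structure(list(D = D, paths = paths, site_ids = ids),
            class = "site_cost_cache")
}

# --- travel chain ----------------------------------------------------------

#' Build an origin-to-islands travel chain
#'
#' Prim-style accretion: starting from the origin site, repeatedly attach
#' the not-yet-connected occupied island with the smallest least-cost
#' distance to any already-connected site, recording that least-cost path
#' as one travel. This reproduces radial colonization along an ordered
#' island chain (closest first). Islands that cannot be reached (e.g.
#' ringed by water deeper than the M2 threshold) are reported separately,
#' not as errors.
#'
#' @param res a `resistance_grid`.
#' @param origin_id site id of the dispersal origin.
#' @param island_ids character vector of occupied island site ids
#'   (excluding the origin).
#' @param sites site table.
#' @param cache optional [site_cost_cache()]; computed if missing.
#' @return a `travel_chain`: list with `origin`, `travels` (list of
#'   `list(from, to, path)`), `unreachable` (character vector) and
#'   `scenario`.
#' @export
build_travel_chain <- function(res, origin_id, island_ids, sites,
                               cache = NULL) {
  island_ids <- setdiff(island_ids, origin_id)
  used <- unique(c(origin_id, island_ids))
  if (is.null(cache))
    cache <- site_cost_cache(res, sites[sites$site_id %in% used, ,
                                        drop = FALSE])
  D <- cache$D
  connected <- origin_id
  pending <- island_ids
  travels <- list()
  unreachable <- character(0)
  while (length(pending) > 0) {
    sub <- D[connected, pending, drop = FALSE]
    k <- arrayInd(which.min(sub), dim(sub))
    if (!is.finite(sub[k])) { unreachable <- pending; break }
    from <- connected[k[1]]; to <- pending[k[2]]
    cells <- cache$paths[[from]][[to]]
    travels[[length(travels) + 1L]] <-
      list(from = from, to = to, path = path_from_cells(res, cells))
    connected <- c(connected, to)
    pending <- setdiff(pending, to)
  }
  structure(list(origin = origin_id, travels = travels,
                 unreachable = unreachable,
                 scenario = res$config$scenario),
            class = "travel_chain")
}

#' @export
print.travel_chain <- function(x, ...) {
  cat(sprintf("<travel_chain> %s from %s: %d travels, %d unreachable\n",
              x$scenario, x$origin, length(x$travels),
              length(x$unreachable)))
  invisible(x)
}

# --- minimum tree ----------------------------------------------------------

#' Minimum-cost vector network over occupied sites
#'
#' Spanning tree over the origin plus occupied island sites minimizing
#' total straight-line (planar) distance; the direction-free, resistance-
#' free estimate of the distance needed to link the island network.
#'
#' @param sites site table with `site_id`, `x`, `y` (km).
#' @param occupied_ids site ids to span (origin included); >= 2 distinct
#'   sites required.
#' @return list with `edges` (data.frame `from`, `to`, `length_km`) and
#'   `total_km`.
#' @export
minimum_tree <- function(sites, occupied_ids) {
  occupied_ids <- unique(occupied_ids)
  s <- sites[match(occupied_ids, sites$site_id), , drop = FALSE]
  if (nrow(s) < 2 || anyNA(s$site_id))
    stop("minimum_tree needs >= 2 distinct known sites")
  dm <- as.matrix(stats::dist(cbind(s$x, s$y)))
  g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # zero-length edges (duplicate coordinates) are dropped by
  # graph_from_adjacency_matrix; add them back explicitly
  zero <- which(dm == 0 & upper.tri(dm), arr.ind = TRUE)
  if (nrow(zero) > 0) {
    g <- igraph::add_edges(g, t(zero), weight = 0)
  }
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_edgelist(mst, names = FALSE)
  w <- igraph::E(mst)$weight
  list(edges = data.frame(from = s$site_id[el[, 1]],
                          to = s$site_id[el[, 2]],
                          length_km = w),
       total_km = sum(w))
}

# --- path metrics ----------------------------------------------------------

#' Path descriptors of a travel chain
#'
#' The seven descriptors of a species' dispersal network:
#' \describe{
#'   \item{minimum_tree}{total length (km) of the direction-free minimum
#'     spanning network (passed in, scenario-free).}
#'   \item{total_travel}{sum of travel lengths (km).}
#'   \item{average_travel}{total_travel / number of travels.}
#'   \item{max_single_travel}{longest single travel (km).}
#'   \item{average_depth}{length-weighted mean bed elevation (m, <= 0)
#'     over submerged steps of all travels; 0 with `all_land = TRUE` when
#'     no step is submerged.}
#'   \item{max_depth}{most negative bed elevation touched (m, <= 0).}
#'   \item{prop_travel_150}{fraction of total travel length over cells no
#'     deeper than `depth_threshold` (land or shallow sea).}
#' }
#' Each step is attributed the bed elevation of its destination cell.
#'
#' @param chain a `travel_chain` with >= 1 travel.
#' @param mst_length_km minimum-tree total from [minimum_tree()].
#' @param depth_threshold m, default -150.
#' @return one-row data.frame of the seven metrics plus `n_travels`,
#'   `n_unreachable` and `all_land`. If the chain is empty all metrics are
#'   `NA` and `empty_chain = TRUE`.
#' @export
path_metrics <- function(chain, mst_length_km, depth_threshold = -150) {
  stopifnot(inherits(chain, "travel_chain"))
  nt <- length(chain$travels)
  if (nt == 0) {
    return(data.frame(minimum_tree = mst_length_km, total_travel = NA_real_,
                      average_travel = NA_real_,
                      max_single_travel = NA_real_,
                      average_depth = NA_real_, max_depth = NA_real_,
                      prop_travel_150 = NA_real_, n_travels = 0L,
                      n_unreachable = length(chain$unreachable),
                      all_land = NA, empty_chain = TRUE))
  }
  lens <- vapply(chain$travels, function(tr) tr$path$length_km, numeric(1))
  step_km <- unlist(lapply(chain$travels, function(tr) tr$path$step_km))
  step_elev <- unlist(lapply(chain$travels,
                             function(tr) tr$path$elev[-1]))
  total <- sum(lens)
  sub <- step_elev < 0
  all_land <- !any(sub)
  if (all_land) {
    avg_depth <- 0; max_depth <- 0
  } else {
    avg_depth <- sum(step_km[sub] * step_elev[sub]) / sum(step_km[sub])
    max_depth <- min(step_elev[sub])
  }
  prop150 <- if (total > 0)
    sum(step_km[step_elev >= depth_threshold]) / total else NA_real_
  data.frame(minimum_tree = mst_length_km, total_travel = total,
             average_travel = total / nt, max_single_travel = max(lens),
             average_depth = avg_depth, max_depth = max_depth,
             prop_travel_150 = prop150, n_travels = nt,
             n_unreachable = length(chain$unreachable),
             all_land = all_land, empty_chain = FALSE)
}
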