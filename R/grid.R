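#' Elevation grid
#'
#' A rectangular, georeferenced grid of bed/terrain elevation in metres.
#' Negative values are sea-floor depth, values >= 0 are land. Row 1 is the
#' northernmost row (ESRI ASCII convention); columns run west to east.
#'
#' @param elev numeric matrix of elevations (m), row 1 = north.
#' @param cell_size cell edge length in km.
#' @param xll,yll coordinates (km) of the lower-left corner of the grid.
#' @param nodata value used for missing cells when serialized.
#' @return an object of class `elevation_grid`.
#' @export
elevation_grid <- function(elev, cell_size, xll = 0, yll = 0, nodata = -9999) {
  stopifnot(is.matrix(elev), is.numeric(elev), cell_size > 0)
  structure(
    list(elev = elev, cell_size = cell_size, xll = xll, yll = yll,
         nodata = nodata),
    class = "elevation_grid"
  )
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf("<elevation_grid> %d x %d cells, cell_size = %g km\n",
              nrow(x$elev), ncol(x$elev), x$cell_size))
  cat(sprintf("  elevation range: [%.1f, %.1f] m; land cells: %d\n",
              min(x$elev), max(x$elev), sum(x$elev >= 0)))
  invisible(x)
}

#' Planar coordinates of grid cells
#'
#' Maps (row, col) cell indices to planar x/y coordinates (km) of cell
#' centres. Row 1 is the northern edge, so y decreases with row index.
#'
#' @param grid an `elevation_grid` (or any object with `cell_size`,
#'   `xll`, `yll` and an `elev` matrix).
#' @param row,col integer vectors of equal length.
#' @return data.frame with columns `x`, `y` (km).
#' @export
grid_xy <- function(grid, row, col) {
  cs <- grid$cell_size
  data.frame(
    x = grid$xll + (col - 0.5) * cs,
    y = grid$yll + (nrow(grid$elev) - row + 0.5) * cs
  )
}

# Affine planar-km -> lon/lat mapping used for synthetic worlds. The world
# is anchored in a Mediterranean-like box; no projection is attempted
# (the synthetic grid is planar by construction).
KM_PER_DEG <- 111.32

#' @rdname grid_xy
#' @param lon0,lat0 anchor (degrees) assigned to x = 0, y = 0.
#' @export
grid_lonlat <- function(grid, row, col, lon0 = 10, lat0 = 35) {
  xy <- grid_xy(grid, row, col)
  data.frame(lon = lon0 + xy$x / KM_PER_DEG, lat = lat0 + xy$y / KM_PER_DEG)
}

#' Read and write ESRI ASCII grids
#'
#' Serializes an [elevation_grid()] in the standard ESRI ASCII raster format
#' (six-line header, row-major values, north to south).
#'
#' @param grid an `elevation_grid`.
#' @param path file path.
#' @return `write_esri_ascii` returns `path` invisibly; `read_esri_ascii`
#'   returns an `elevation_grid`.
#' @export
write_esri_ascii <- function(grid, path) {
  m <- grid$elev
  m[is.na(m)] <- grid$nodata
  header <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  rows <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  ncols <- as.integer(vals[["ncols"]])
  nrows <- as.integer(vals[["nrows"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(body) == nrows * ncols)
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  elevation_grid(m, cell_size = vals[["cellsize"]],
                 xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
                 nodata = vals[["nodata_value"]])
}

#' Cells on the straight line between two grid cells
#'
#' Rasterizes the segment joining two cell centres with Bresenham's
#' algorithm (8-connected). Used to carve shallow channels between islands
#' and to audit them.
#'
#' @param r0,c0,r1,c1 integer cell indices of the two endpoints.
#' @return integer matrix with columns `row`, `col`, one row per cell,
#'   endpoints included.
#' @export
grid_line_cells <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  r <- r0; c <- c0
  out <- matrix(NA_integer_, nrow = dr + dc + 1L, ncol = 2L)
  k <- 0L
  repeat {
    k <- k + 1L
    out[k, ] <- c(r, c)
    if (r == r1 && c == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  out <- out[seq_len(k), , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}
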