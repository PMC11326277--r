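## The artificial Visium-like array: a hexagonal lattice spanning a whole
## stitched group, onto which every spot is snapped so downstream
## neighbour-based methods (which read array_row/array_col) work unchanged.
##
## Geometry follows the Visium convention: neighbours are 100 um apart,
## array_col increments by 2 within a row (50 um per column-index unit),
## adjacent rows are 100 * sqrt(3)/2 um apart and offset by one column unit,
## so array_row + array_col is always even.

#' Estimate microns per pixel from spot geometry
#'
#' Visium spots sit 100 um from their nearest neighbours, so the scale of any
#' pixel frame holding an intact capture-area grid is `100 / median
#' nearest-neighbour distance`. With fewer than two spots the fallback
#' `55 / spot_diameter_fullres` (spot diameter 55 um) is used.
#'
#' @param spots Spot tibble with `pxl_row_in_fullres`, `pxl_col_in_fullres`.
#' @param sf Optional `scalefactors` fallback.
#' @param max_query At most this many spots (deterministically subsampled)
#'   are used as nearest-neighbour queries.
#' @return Microns per pixel (positive scalar).
#' @export
estimate_microns_per_pixel <- function(spots, sf = NULL, max_query = 2000L) {
  n <- nrow(spots)
  if (n >= 2L) {
    xy <- cbind(spots$pxl_col_in_fullres, spots$pxl_row_in_fullres)
    idx <- if (n > max_query) {
      unique(round_half_up(seq(1L, n, length.out = max_query)))
    } else {
      seq_len(n)
    }
    d <- nn_distances(xy, idx)
    med <- median(d)
    if (med <= 0) abort("median nearest-neighbour distance is zero; cannot infer scale")
    return(SPOT_SPACING_UM / med)
  }
  if (!is.null(sf)) {
    stopifnot(inherits(sf, "scalefactors"))
    return(SPOT_DIAMETER_UM / sf$spot_diameter_fullres)
  }
  abort("need at least two spots or a scalefactors fallback to estimate microns per pixel")
}

## Nearest-neighbour distance of each query point to any *other* point.
nn_distances <- function(xy, query_idx = seq_len(nrow(xy))) {
  x <- xy[, 1L]
  y <- xy[, 2L]
  vapply(query_idx, function(i) {
    d2 <- (x - x[[i]])^2 + (y - y[[i]])^2
    d2[[i]] <- Inf
    sqrt(min(d2))
  }, numeric(1L))
}

#' Build the artificial hexagonal array for a stitched group
#'
#' Anchors the lattice so the minimum `pxl_row_in_fullres` over all spots
#' maps to `array_row = 0` and the minimum `pxl_col_in_fullres` to
#' `array_col = 0`, and adds rows/columns as necessary so the lattice covers
#' the full extent of the group's spots — generally well beyond the 77/127
#' maxima of a single capture area.
#'
#' @param spots All transformed spots of the group (group fullres frame).
#' @param microns_per_pixel Physical scale of that frame.
#' @return An `artificial_array` object: origin `(x, y)` in pixels, pitches
#'   in pixels, `n_rows`, `n_cols` (counts of row / column *indices*),
#'   `microns_per_pixel`.
#' @export
build_artificial_array <- function(spots, microns_per_pixel) {
  if (nrow(spots) == 0L) abort("cannot build an array over zero spots")
  if (!is_scalar_number(microns_per_pixel) || microns_per_pixel <= 0) {
    abort("microns_per_pixel must be a positive number")
  }
  row_pitch_px <- ROW_PITCH_UM / microns_per_pixel
  col_pitch_px <- COL_PITCH_UM / microns_per_pixel
  ox <- min(spots$pxl_col_in_fullres)
  oy <- min(spots$pxl_row_in_fullres)
  span_x <- max(spots$pxl_col_in_fullres) - ox
  span_y <- max(spots$pxl_row_in_fullres) - oy
  structure(
    list(
      origin = c(x = ox, y = oy),
      microns_per_pixel = microns_per_pixel,
      row_pitch_px = row_pitch_px,
      col_pitch_px = col_pitch_px,
      n_rows = as.integer(ceiling(span_y / row_pitch_px - 1e-9)) + 1L,
      n_cols = as.integer(ceiling(span_x / col_pitch_px - 1e-9)) + 1L
    ),
    class = "artificial_array"
  )
}

#' @export
print.artificial_array <- function(x, ...) {
  cat("<artificial_array> ", x$n_rows, " rows x ", x$n_cols,
      " column indices\n", sep = "")
  cat("  origin (x, y): ", x$origin[["x"]], ", ", x$origin[["y"]], " px;  ",
      signif(x$microns_per_pixel, 6), " um/px\n", sep = "")
  invisible(x)
}

#' Pixel position of lattice points
#'
#' @param lattice An `artificial_array`.
#' @param array_row,array_col Integer vectors of lattice indices.
#' @return Tibble with columns `x`, `y` in group fullres pixels.
#' @export
array_position <- function(lattice, array_row, array_col) {
  stopifnot(inherits(lattice, "artificial_array"))
  tibble(
    x = lattice$origin[["x"]] + array_col * lattice$col_pitch_px,
    y = lattice$origin[["y"]] + array_row * lattice$row_pitch_px
  )
}

#' Snap spot coordinates to the nearest artificial lattice point
#'
#' Assigns each spot the `(array_row, array_col)` of its Euclidean-nearest
#' lattice point (only parity-valid points, `array_row + array_col` even, are
#' candidates). Exact ties go to the lexicographically smallest
#' `(array_row, array_col)`. Several spots may share one coordinate — this is
#' how overlapping capture areas coexist on the artificial array.
#'
#' For each spot only the two bracketing lattice rows and, within each, the
#' two bracketing parity-valid columns need checking; this is equivalent to
#' exhaustive search over the whole lattice.
#'
#' @param coords Data frame with `pxl_col_in_fullres` / `pxl_row_in_fullres`
#'   (or `x` / `y`) in group fullres pixels.
#' @param lattice An `artificial_array` covering the coordinates.
#' @return Tibble with integer columns `array_row`, `array_col`.
#' @export
snap_to_array <- function(coords, lattice) {
  stopifnot(inherits(lattice, "artificial_array"))
  x <- if ("pxl_col_in_fullres" %in% names(coords)) coords[["pxl_col_in_fullres"]] else coords[["x"]]
  y <- if ("pxl_row_in_fullres" %in% names(coords)) coords[["pxl_row_in_fullres"]] else coords[["y"]]
  if (is.null(x) || is.null(y)) {
    abort("coords must have pxl_col_in_fullres/pxl_row_in_fullres or x/y columns")
  }
  n <- length(x)
  u <- (x - lattice$origin[["x"]]) / lattice$col_pitch_px
  v <- (y - lattice$origin[["y"]]) / lattice$row_pitch_px
  r_lo <- pmin(pmax(floor(v), 0), lattice$n_rows - 1L)
  r_hi <- pmin(r_lo + 1, lattice$n_rows - 1L)

  ## candidate columns for a given row parity: the two parity-valid columns
  ## bracketing u, clamped into [parity, max parity-valid index]
  cand_cols <- function(r, side) {
    p <- r %% 2
    c_lo <- 2 * floor((u - p) / 2) + p
    cc <- if (side == 1L) c_lo else c_lo + 2
    hi <- lattice$n_cols - 1L
    hi <- hi - ((hi - p) %% 2)  # largest index <= n_cols-1 with parity p
    pmin(pmax(cc, p), pmax(hi, p))
  }
  R <- cbind(r_lo, r_lo, r_hi, r_hi)
  C <- cbind(cand_cols(r_lo, 1L), cand_cols(r_lo, 2L),
             cand_cols(r_hi, 1L), cand_cols(r_hi, 2L))
  D2 <- (u - C)^2 * lattice$col_pitch_px^2 + (v - R)^2 * lattice$row_pitch_px^2
  scale <- lattice$col_pitch_px^2
  dmin <- D2[cbind(seq_len(n), max.col(-D2, ties.method = "first"))]
  tol <- 1e-9 * (scale + dmin)
  ## among near-tied candidates pick the lexicographically smallest (row, col)
  key <- R * (2 * lattice$n_cols + 4) + C
  key[D2 > dmin + tol] <- Inf
  pick <- max.col(-key, ties.method = "first")
  idx <- cbind(seq_len(n), pick)
  tibble(array_row = as.integer(R[idx]), array_col = as.integer(C[idx]))
}

#' Enumerate the hexagonal neighbours of an array coordinate
#'
#' The six candidate neighbours of `(r, c)` are `(r +- 1, c +- 1)` and
#' `(r, c +- 2)`; out-of-bounds candidates are clipped. Every returned
#' position is exactly 100 um away in lattice geometry.
#'
#' @param r,c Integer array row / column (must satisfy `r + c` even).
#' @param lattice An `artificial_array`.
#' @return Tibble with columns `array_row`, `array_col`.
#' @export
array_neighbors <- function(r, c, lattice) {
  stopifnot(inherits(lattice, "artificial_array"),
            length(r) == 1L, length(c) == 1L)
  if ((r + c) %% 2 != 0) {
    abort(paste0("(", r, ", ", c, ") violates the parity convention: ",
                 "array_row + array_col must be even"))
  }
  cand <- tibble(
    array_row = as.integer(c(r - 1, r - 1, r, r, r + 1, r + 1)),
    array_col = as.integer(c(c - 1, c + 1, c - 2, c + 2, c - 1, c + 1))
  )
  cand |>
    filter(.data$array_row >= 0, .data$array_row < lattice$n_rows,
           .data$array_col >= 0, .data$array_col < lattice$n_cols) |>
    arrange(.data$array_row, .data$array_col)
}

#' Redefine array coordinates on the artificial array
#'
#' Convenience wrapper: builds (or reuses) the lattice for a stitched spot
#' table and replaces `array_row` / `array_col` with the snapped artificial
#' coordinates, keeping the originals in `array_row_original` /
#' `array_col_original`.
#'
#' @param spots Stitched spot tibble (group fullres frame).
#' @param microns_per_pixel Physical scale of the frame; estimated via
#'   [estimate_microns_per_pixel()] when `NULL`.
#' @param lattice Optional prebuilt `artificial_array`.
#' @return The spot tibble with redefined coordinates; the lattice is
#'   attached as attribute `"lattice"`.
#' @export
add_array_coords <- function(spots, microns_per_pixel = NULL, lattice = NULL) {
  if (is.null(lattice)) {
    microns_per_pixel <- microns_per_pixel %||% estimate_microns_per_pixel(spots)
    lattice <- build_artificial_array(spots, microns_per_pixel)
  }
  snapped <- snap_to_array(spots, lattice)
  if (!"array_row_original" %in% names(spots)) {
    spots$array_row_original <- spots$array_row
    spots$array_col_original <- spots$array_col
  }
  spots$array_row <- snapped$array_row
  spots$array_col <- snapped$array_col
  attr(spots, "lattice") <- lattice
  spots
}
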