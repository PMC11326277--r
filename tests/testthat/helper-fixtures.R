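# Shared fixtures, generated in code at test time. The small simulated group
# (three areas: two overlapping by ~1/3, one adjacent) is built once per run
# and cached; everything derives from seeded simulation, never from stored
# data.

.fixture_cache <- new.env(parent = emptyenv())

# small three-area group: 16 x 24 grid per area, deterministic seed
small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    dir <- file.path(tempdir(), "stitchspot-small-group")
    .fixture_cache$sim <- simulate_group(
      dir, n_rows = 16L, n_cols = 24L, h = 0.15, depth = 60,
      n_genes = 30L, seed = 42L
    )
  }
  .fixture_cache$sim
}

small_built <- function() {
  if (is.null(.fixture_cache$built)) {
    .fixture_cache$built <- build_stitched_group(
      small_sim()$sample_info, target_longest = 300L
    )
  }
  .fixture_cache$built
}

# a single tiny capture area on disk
small_area <- function(name = "tiny_A1", ...) {
  dir <- file.path(tempdir(), paste0("stitchspot-area-", name))
  if (!dir.exists(dir)) {
    simulate_capture_area(dir, area_id = name, n_rows = 8L, n_cols = 12L,
                          h = 0.2, depth = 40, n_genes = 15L, seed = 11L, ...)
  }
  read_capture_area(dir, area_id = name)
}

# in-memory capture_area with a constant image, for geometry-only tests
fake_area <- function(area_id, d, h, width = 200L, height = 160L,
                      spots = NULL) {
  structure(
    list(
      area_id = area_id,
      spots = spots %||% tibble::tibble(
        barcode = character(), in_tissue = logical(),
        array_row = integer(), array_col = integer(),
        pxl_row_in_fullres = double(), pxl_col_in_fullres = double()
      ),
      scalefactors = suppressWarnings(
        scalefactors(spot_diameter_fullres = d, tissue_hires_scalef = h)
      ),
      image = matrix(0.5, nrow = height, ncol = width),
      counts = NULL
    ),
    class = "capture_area"
  )
}

# hexagonal spot table with given pixel pitch (col pitch = half the
# neighbour spacing), origin at (x0, y0)
hex_spot_table <- function(n_rows, n_cols, col_pitch_px, x0 = 0, y0 = 0,
                           prefix = "S") {
  rows <- do.call(rbind, lapply(seq_len(n_rows) - 1L, function(r) {
    cols <- seq.int(r %% 2L, n_cols - 1L, by = 2L)
    cbind(r, cols)
  }))
  tibble::tibble(
    barcode = paste0(prefix, seq_len(nrow(rows))),
    in_tissue = TRUE,
    array_row = as.integer(rows[, 1L]),
    array_col = as.integer(rows[, 2L]),
    pxl_row_in_fullres = y0 + rows[, 1L] * col_pitch_px * sqrt(3),
    pxl_col_in_fullres = x0 + rows[, 2L] * col_pitch_px
  )
}

# exhaustive nearest-lattice-point search (the snapping oracle)
brute_force_snap <- function(coords, lattice) {
  all_pts <- do.call(rbind, lapply(seq_len(lattice$n_rows) - 1L, function(r) {
    cols <- seq.int(r %% 2L, lattice$n_cols - 1L, by = 2L)
    if (!length(cols)) return(NULL)
    cbind(r, cols)
  }))
  pos <- array_position(lattice, all_pts[, 1L], all_pts[, 2L])
  x <- if ("pxl_col_in_fullres" %in% names(coords)) coords$pxl_col_in_fullres else coords$x
  y <- if ("pxl_row_in_fullres" %in% names(coords)) coords$pxl_row_in_fullres else coords$y
  out <- t(vapply(seq_along(x), function(i) {
    d2 <- (pos$x - x[[i]])^2 + (pos$y - y[[i]])^2
    best <- which(d2 <= min(d2) + 1e-9 * (1 + min(d2)))
    # lexicographic tie-break on (row, col)
    ord <- order(all_pts[best, 1L], all_pts[best, 2L])
    all_pts[best[ord[1L]], ]
  }, numeric(2L)))
  tibble::tibble(array_row = as.integer(out[, 1L]),
                 array_col = as.integer(out[, 2L]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
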