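## Synthetic multi-capture-area Visium experiments with known ground truth.
## Everything the pipeline consumes is fabricated: SpaceRanger-style spatial
## directories, MatrixMarket counts, a Fiji-style transform XML, the stitched
## canvas image, and a table of ground-truth coincident spot pairs.
##
## The counts model is deliberately simple — independent Poisson per gene with
## an area-level depth multiplier — which is all that is needed to exercise
## mean-UMI precedence. Images are synthetic blobs with spot-scale texture
## plus one calibration disc of exactly one spot diameter; they are
## geometrically consistent with the spot positions but not tissue-realistic.

#' Simulate one Visium capture area as a SpaceRanger-style directory
#'
#' Generates a hexagonal spot grid (100 um neighbour spacing, spot diameter
#' 55 um, so the full-resolution scale is `55/d` um per pixel), an elliptical
#' "tissue" region defining `in_tissue`, a hires image with rendered tissue
#' and spot texture, and Poisson counts whose per-spot in-tissue totals have
#' mean `depth`. Defaults give the standard Visium geometry: 78 array rows x
#' 128 array column indices = 4992 spots.
#'
#' @param dir Output directory (created; SpaceRanger layout inside).
#' @param area_id Capture area identifier.
#' @param n_rows,n_cols Number of array row / column indices (>= 1).
#' @param d Spot diameter in full-resolution pixels (`spot_diameter_fullres`).
#' @param h Hires scale factor; default sized so the hires image has 2000
#'   pixels in its longest dimension, like SpaceRanger's.
#' @param depth Mean total UMIs per in-tissue spot.
#' @param n_genes Number of simulated genes.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @return Invisibly, a list with `dir`, `area_id`, `spots` (the emitted spot
#'   tibble), `scalefactors`, and the geometry parameters.
#' @export
simulate_capture_area <- function(dir, area_id = basename(dir),
                                  n_rows = 78L, n_cols = 128L,
                                  d = 55, h = NULL, depth = 1158,
                                  n_genes = 100L, seed = 1L) {
  if (n_rows < 1L || n_cols < 1L) abort("n_rows and n_cols must be >= 1")
  stopifnot(d > 0, depth > 0, n_genes >= 1L)
  set.seed(seed)
  mpp <- SPOT_DIAMETER_UM / d                   # um per fullres pixel
  col_pitch <- COL_PITCH_UM / mpp
  row_pitch <- ROW_PITCH_UM / mpp
  margin <- 400 / mpp                           # 400 um border
  grid <- expand_hex_grid(n_rows, n_cols)
  spots <- tibble(
    barcode = vapply(seq_len(nrow(grid)), spot_barcode, character(1L)),
    in_tissue = FALSE,
    array_row = grid$array_row,
    array_col = grid$array_col,
    pxl_row_in_fullres = margin + grid$array_row * row_pitch,
    pxl_col_in_fullres = margin + grid$array_col * col_pitch
  )
  width_full <- 2 * margin + (n_cols - 1L) * col_pitch
  height_full <- 2 * margin + (n_rows - 1L) * row_pitch
  h <- h %||% (2000 / max(width_full, height_full))
  ## elliptical tissue blob covering most of the grid
  cx <- width_full / 2
  cy <- height_full / 2
  rx <- 0.45 * width_full
  ry <- 0.45 * height_full
  spots$in_tissue <- ((spots$pxl_col_in_fullres - cx) / rx)^2 +
    ((spots$pxl_row_in_fullres - cy) / ry)^2 <= 1

  sf <- scalefactors(
    spot_diameter_fullres = d,
    tissue_hires_scalef = h,
    tissue_lowres_scalef = h * 600 / 2000,  # lowres is the 600 px rendering
    fiducial_diameter_fullres = d * 1.6
  )
  img <- render_area_image(spots, sf, width_full, height_full,
                           cx = cx, cy = cy, rx = rx, ry = ry, margin = margin)

  counts <- simulate_counts(spots$in_tissue, depth = depth, n_genes = n_genes)
  colnames(counts) <- spots$barcode

  spatial <- file.path(dir, "spatial")
  dir.create(spatial, recursive = TRUE, showWarnings = FALSE)
  write_tissue_positions(spots, file.path(spatial, "tissue_positions.csv"))
  write_scalefactors(sf, file.path(spatial, "scalefactors_json.json"))
  write_raster(img, file.path(spatial, "tissue_hires_image.png"))
  write_counts(counts, file.path(dir, "filtered_feature_bc_matrix"))
  invisible(list(dir = dir, area_id = area_id, spots = spots, scalefactors = sf,
                 width_full = width_full, height_full = height_full,
                 microns_per_pixel = mpp))
}

## all (row, col) with matching parity: col steps by 2 within a row
expand_hex_grid <- function(n_rows, n_cols) {
  purrr::map_dfr(seq_len(n_rows) - 1L, function(r) {
    cols <- seq.int(r %% 2L, n_cols - 1L, by = 2L)
    tibble(array_row = r, array_col = as.integer(cols))
  })
}

simulate_counts <- function(in_tissue, depth, n_genes) {
  w <- rexp(n_genes)
  rates <- depth * w / sum(w)
  t_spot <- ifelse(in_tissue, 1, 0.02)   # faint out-of-tissue background
  lam <- outer(rates, t_spot)
  m <- matrix(rpois(length(lam), lam), nrow = n_genes)
  counts <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  rownames(counts) <- sprintf("SIMG%07d", seq_len(n_genes))
  attr(counts, "features") <- tibble(
    id = rownames(counts),
    symbol = sprintf("Sim%d", seq_len(n_genes)),
    type = "Gene Expression"
  )
  counts
}

## hires raster: dark background, brighter tissue ellipse, spot-scale dots,
## and one bright calibration disc of exactly one spot diameter (d fullres px)
## centred in the top-left margin, used to verify physical-scale equalisation.
render_area_image <- function(spots, sf, width_full, height_full,
                              cx, cy, rx, ry, margin) {
  h <- sf$tissue_hires_scalef
  W <- max(1L, as.integer(round_half_up(width_full * h)))
  H <- max(1L, as.integer(round_half_up(height_full * h)))
  xs <- (seq_len(W) - 0.5) / h     # fullres x of each pixel column centre
  ys <- (seq_len(H) - 0.5) / h
  img <- matrix(0.15, nrow = H, ncol = W)
  inside <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, `+`) <= 1
  img[inside] <- 0.7
  ## spot texture: darker dots at in-tissue spot centres. One disc template
  ## (pixel offsets within r_spot of the origin) stamped at every rounded
  ## spot centre in a single indexed assignment.
  r_spot <- sf$spot_diameter_fullres * h / 2
  tmpl <- disc_template(r_spot)
  it <- which(spots$in_tissue)
  if (length(it) && nrow(tmpl)) {
    cy_px <- round_half_up(spots$pxl_row_in_fullres[it] * h)
    cx_px <- round_half_up(spots$pxl_col_in_fullres[it] * h)
    rows <- rep(cy_px, each = nrow(tmpl)) + tmpl$dr
    cols <- rep(cx_px, each = nrow(tmpl)) + tmpl$dc
    ok <- rows >= 1L & rows <= H & cols >= 1L & cols <= W
    img[cbind(rows[ok], cols[ok])] <- 0.45
  }
  ## calibration disc (diameter d fullres px = 55 um) on the dark margin
  img <- paint_disc(img, (margin / 2) * h, (margin / 2) * h, r_spot, 1.0)
  img
}

disc_template <- function(r) {
  k <- ceiling(r)
  off <- expand.grid(dr = -k:k, dc = -k:k)
  off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
}

paint_disc <- function(img, x, y, r, value) {
  rows <- max(1L, floor(y - r)):min(nrow(img), ceiling(y + r))
  cols <- max(1L, floor(x - r)):min(ncol(img), ceiling(x + r))
  if (!length(rows) || !length(cols)) return(img)
  d2 <- outer((rows - 0.5 - y)^2, (cols - 0.5 - x)^2, `+`)
  sel <- d2 <= r^2
  block <- img[rows, cols, drop = FALSE]
  block[sel] <- value
  img[rows, cols] <- block
  img
}

#' Simulate a group of capture areas with known stitching ground truth
#'
#' Emulates the three-capture-area study design: two areas partially
#' overlapping (default 30 percent along the column axis) and a third placed
#' adjacent across a gap, never overlapping. Writes per-area SpaceRanger-style
#' directories, uniformly rescaled images, a Fiji-style transform XML encoding
#' the known rigid transforms, the composited stitched canvas, a
#' `sample_info.csv`, and a ground-truth table of coincident spot pairs
#' (true positions within `eps_um`).
#'
#' The default overlap translation is an even number of column-index units,
#' so overlapping spots coincide exactly; rotations default to zero for the
#' overlapping pair (a rotation would destroy exact spot coincidence) but may
#' be set per area.
#'
#' @param out_dir Output root directory.
#' @param group_id Group identifier (becomes the stitched `sample_id`).
#' @param area_ids Three or more area identifiers.
#' @param n_rows,n_cols,d,h,n_genes Per-area geometry, as in
#'   [simulate_capture_area()] (shared by all areas).
#' @param depth Baseline mean UMIs per in-tissue spot.
#' @param depth_multipliers Per-area multipliers of `depth` (recycled);
#'   defaults make the second area the deepest, exercising mean-UMI
#'   precedence at overlaps.
#' @param overlap_frac Fraction of columns shared by areas 1 and 2, in
#'   `[0, 1)`.
#' @param gap_um Physical gap between area 2 and the adjacent area 3.
#' @param rotations_deg Per-area rotation angles (degrees, about the canvas
#'   origin, applied before translation).
#' @param eps_um Coincidence tolerance for ground-truth pairs (microns).
#' @param seed Integer seed; same seed, same bytes.
#' @return Invisibly, a list with `sample_info` (tibble), `ground_truth`
#'   (tibble of coincident pairs), `transforms`, `arrangement`, and the paths
#'   written.
#' @export
simulate_group <- function(out_dir, group_id = "sim_brain",
                           area_ids = c("sim_A1", "sim_D1", "sim_C1"),
                           n_rows = 78L, n_cols = 128L, d = 55, h = NULL,
                           n_genes = 100L,
                           depth = 1158, depth_multipliers = c(1, 1.5, 0.8),
                           overlap_frac = 0.3, gap_um = 200,
                           rotations_deg = 0, eps_um = 10, seed = 1L) {
  n_areas <- length(area_ids)
  if (n_areas < 2L) abort("simulate_group needs at least two capture areas")
  if (overlap_frac < 0 || overlap_frac >= 1) {
    abort("overlap_frac must be in [0, 1)")
  }
  depth_multipliers <- rep_len(depth_multipliers, n_areas)
  rotations_deg <- rep_len(rotations_deg, n_areas)

  ## 1. per-area SpaceRanger-style outputs
  areas <- purrr::map(seq_len(n_areas), function(i) {
    simulate_capture_area(
      dir = file.path(out_dir, "areas", area_ids[[i]]),
      area_id = area_ids[[i]], n_rows = n_rows, n_cols = n_cols,
      d = d, h = h, depth = depth * depth_multipliers[[i]],
      n_genes = n_genes, seed = seed * 1000L + i
    )
    read_capture_area(file.path(out_dir, "areas", area_ids[[i]]),
                      area_id = area_ids[[i]])
  })

  ## 2. uniform rescale + canvas scale
  plan <- compute_rescale_factors(areas)
  rescaled_dir <- file.path(out_dir, "rescaled")
  rescale_images(areas, plan, rescaled_dir)
  norm_scale <- attr(plan, "norm_scale")
  ref_id <- attr(plan, "reference_id")
  d_ref <- plan$spot_diameter_fullres[[which(plan$area_id == ref_id)]]
  mpp_canvas <- (SPOT_DIAMETER_UM / d_ref) / norm_scale
  col_pitch_cv <- COL_PITCH_UM / mpp_canvas
  row_pitch_cv <- ROW_PITCH_UM / mpp_canvas

  ## 3. known rigid transforms in canvas coordinates
  dc <- 2L * as.integer(round_half_up((1 - overlap_frac) * n_cols / 2))
  if (overlap_frac > 0 && (dc <= 0L || dc >= n_cols)) {
    abort(paste0("requested overlap_frac = ", overlap_frac,
                 " is incompatible with n_cols = ", n_cols))
  }
  adjacent_dy <- (n_rows - 1L) * row_pitch_cv + gap_um / mpp_canvas
  offsets <- purrr::map(seq_len(n_areas), function(i) {
    if (i == 1L) c(0, 0)
    else if (i == 2L) c(dc * col_pitch_cv, 0)
    else c(dc * col_pitch_cv, (i - 2L) * adjacent_dy)
  })
  transforms <- purrr::map2(offsets, rotations_deg, function(t, deg) {
    th <- deg * pi / 180
    affine2d(cos(th), sin(th), -sin(th), cos(th), t[[1L]], t[[2L]])
  })
  names(transforms) <- paste0(area_ids, ".png")

  ## shift all transforms so every image corner is non-negative, then size
  ## the canvas to the shifted bounding box
  corners <- purrr::map2(transforms, seq_len(n_areas), function(tr, i) {
    row <- plan[plan$area_id == area_ids[[i]], ]
    apply_affine(tr, rbind(c(0, 0), c(row$new_width, 0),
                           c(0, row$new_height), c(row$new_width, row$new_height)))
  })
  all_c <- do.call(rbind, corners)
  shift <- pmax(-apply(all_c, 2L, min), 0)
  transforms <- purrr::map(transforms, function(tr) {
    tr$matrix[, 3L] <- tr$matrix[, 3L] + shift
    tr
  })
  canvas_w <- as.integer(ceiling(max(all_c[, 1L] + shift[[1L]])))
  canvas_h <- as.integer(ceiling(max(all_c[, 2L] + shift[[2L]])))

  ## 4. Fiji-style XML
  fiji_dir <- file.path(out_dir, "fiji")
  dir.create(fiji_dir, recursive = TRUE, showWarnings = FALSE)
  xml_path <- file.path(fiji_dir, paste0(group_id, ".xml"))
  write_transform_xml(transforms, xml_path)

  ## 5. composite stitched canvas
  canvas <- matrix(0, nrow = canvas_h, ncol = canvas_w)
  for (i in seq_len(n_areas)) {
    img <- read_raster(file.path(rescaled_dir, paste0(area_ids[[i]], ".png")))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    m <- transforms[[i]]$matrix
    placed <- EBImage::affine(
      as_ebimage(img),
      rbind(m[, 1L], m[, 2L], m[, 3L]),
      filter = "bilinear", output.dim = c(canvas_w, canvas_h), bg.col = 0
    )
    canvas <- pmax(canvas, from_ebimage(placed))
  }
  stitched_dir <- file.path(out_dir, "stitched")
  dir.create(stitched_dir, recursive = TRUE, showWarnings = FALSE)
  stitched_path <- file.path(stitched_dir, paste0(group_id, ".png"))
  write_raster(canvas, stitched_path)

  ## 6. ground-truth coincident pairs from true geometry
  truth_coords <- purrr::map2_dfr(areas, seq_len(n_areas), function(area, i) {
    row <- plan[plan$area_id == area$area_id, ]
    xy <- cbind(area$spots$pxl_col_in_fullres, area$spots$pxl_row_in_fullres) *
      (row$tissue_hires_scalef * row$scale_factor)
    xy <- apply_affine(transforms[[i]], xy)
    tibble(key = paste(area$spots$barcode, area$area_id, sep = "_"),
           capture_area = area$area_id, x = xy[, 1L], y = xy[, 2L])
  })
  ground_truth <- coincident_pairs(truth_coords, eps_px = eps_um / mpp_canvas,
                                   mpp = mpp_canvas)
  gt_path <- file.path(out_dir, "ground_truth.csv")
  readr::write_csv(ground_truth, gt_path, progress = FALSE)

  ## 7. sample_info + arrangement record
  sample_info <- tibble(
    group_id = group_id,
    area_id = area_ids,
    spaceranger_dir = file.path(out_dir, "areas", area_ids),
    fiji_xml_path = xml_path,
    stitched_image_path = stitched_path
  )
  readr::write_csv(sample_info, file.path(out_dir, "sample_info.csv"),
                   progress = FALSE)
  arrangement <- list(
    group_id = group_id, area_ids = area_ids, n_rows = n_rows, n_cols = n_cols,
    d = d, depth = depth, depth_multipliers = depth_multipliers,
    overlap_frac = overlap_frac, overlap_col_offset = dc, gap_um = gap_um,
    rotations_deg = rotations_deg, eps_um = eps_um, seed = seed,
    transforms = purrr::map(transforms, function(tr) as.vector(t(tr$matrix)))
  )
  jsonlite::write_json(arrangement, file.path(out_dir, "arrangement.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sample_info = sample_info, ground_truth = ground_truth,
                 transforms = transforms, arrangement = arrangement,
                 plan = plan, out_dir = out_dir))
}

## pair spots from distinct areas whose true canvas positions lie within
## eps_px; binned join first, exact distance check second
coincident_pairs <- function(coords, eps_px, mpp) {
  bin <- pmax(eps_px, 1e-6) * 2.5
  binned <- coords |>
    mutate(bx = round_half_up(.data$x / bin), by = round_half_up(.data$y / bin))
  cands <- purrr::map_dfr(c(-1, 0, 1), function(ox) {
    purrr::map_dfr(c(-1, 0, 1), function(oy) {
      a <- binned |> mutate(bx = .data$bx + ox, by = .data$by + oy)
      dplyr::inner_join(
        a, binned, by = c("bx", "by"), suffix = c("_1", "_2"),
        relationship = "many-to-many"
      )
    })
  })
  cands |>
    filter(.data$capture_area_1 < .data$capture_area_2) |>
    mutate(distance_px = sqrt((.data$x_1 - .data$x_2)^2 + (.data$y_1 - .data$y_2)^2)) |>
    filter(.data$distance_px <= eps_px) |>
    dplyr::distinct(.data$key_1, .data$key_2, .keep_all = TRUE) |>
    dplyr::transmute(
      key_1 = .data$key_1, area_1 = .data$capture_area_1,
      key_2 = .data$key_2, area_2 = .data$capture_area_2,
      distance_um = .data$distance_px * mpp
    )
}

## minimal TrakEM2-style dialect: one t2_patch per image with an SVG-style
## transform attribute
write_transform_xml <- function(transforms, path) {
  doc <- xml2::xml_new_root("trakem2")
  layer <- xml2::xml_add_child(doc, "t2_layer_set")
  for (nm in names(transforms)) {
    m <- transforms[[nm]]$matrix
    xml2::xml_add_child(
      layer, "t2_patch",
      file_path = nm, title = nm,
      transform = sprintf("matrix(%.10g,%.10g,%.10g,%.10g,%.10g,%.10g)",
                          m[1, 1], m[2, 1], m[1, 2], m[2, 2], m[1, 3], m[2, 3])
    )
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
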