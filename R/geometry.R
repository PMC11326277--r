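## Coordinate frames
##
## FULLRES_i     per-area full-resolution pixel frame (tissue_positions.csv)
## NORMHIRES     the shared stitching canvas: every rescaled image lives here
##               and one pixel represents the same physical distance in all
##               areas; FULLRES_i -> NORMHIRES is multiplication by h_i * s_i
## GROUP_FULLRES the output frame: NORMHIRES divided by the reference area's
##               normalized hires scale (h_ref * s_ref), so its um-per-pixel
##               equals the reference area's full-resolution um-per-pixel
##
## The Fiji transform A_i is estimated on the canvas, so it is applied in
## NORMHIRES; the composite per-area scalar on the linear part works out to
## d_ref / d_i. Transforms operate on (x, y) = (pxl_col, pxl_row); rasters
## index [row, col].

#' Transform one capture area's spot coordinates into the group frame
#'
#' Maps each spot's full-resolution pixel coordinates into the shared
#' stitching canvas (multiplication by `h * s`), applies the area's rigid
#' affine transform there, and converts to the group full-resolution frame
#' (division by `norm_scale_ref = h_ref * s_ref`). Record order, barcodes and
#' all other columns are preserved; only `pxl_row_in_fullres` /
#' `pxl_col_in_fullres` change.
#'
#' @param spots Spot tibble with `pxl_row_in_fullres`, `pxl_col_in_fullres`.
#' @param transform The area's `affine2d` (canvas frame). Must not be `NULL`.
#' @param h The area's `tissue_hires_scalef`.
#' @param s The area's rescale factor from the plan.
#' @param norm_scale_ref The plan's `norm_scale` attribute.
#' @return The spot tibble with coordinates in the group fullres frame.
#' @export
apply_group_transform <- function(spots, transform, h, s, norm_scale_ref) {
  if (is.null(transform)) {
    abort("no affine transform supplied for this capture area")
  }
  stopifnot(inherits(transform, "affine2d"),
            is_scalar_number(h), h > 0, is_scalar_number(s), s > 0,
            is_scalar_number(norm_scale_ref), norm_scale_ref > 0)
  xy <- cbind(spots$pxl_col_in_fullres, spots$pxl_row_in_fullres) * (h * s)
  xy <- apply_affine(transform, xy) / norm_scale_ref
  spots$pxl_col_in_fullres <- xy[, 1L]
  spots$pxl_row_in_fullres <- xy[, 2L]
  spots
}

#' Resize the stitched canvas image to a lowres group image
#'
#' Resizes the stitched composite image so its longest dimension equals
#' `target_longest` pixels (default 1200, sized for a 2x2 arrangement of
#' capture areas; configure for other group compositions), preserving aspect
#' ratio. Also returns the `tissue_lowres_scalef` relating group
#' full-resolution coordinates to the lowres raster:
#' `(target_longest / longest canvas dimension) * norm_scale_ref`.
#'
#' @param image Stitched canvas raster (`[row, col(, channel)]`).
#' @param norm_scale_ref Canvas-px per group-fullres-px ratio
#'   (`h_ref * s_ref` from the rescale plan).
#' @param target_longest Longest output dimension in pixels (>= 1).
#' @return List with elements `image` (lowres raster) and
#'   `tissue_lowres_scalef`.
#' @export
resize_stitched_image <- function(image, norm_scale_ref, target_longest = 1200L) {
  dims <- dim(image)[1:2]
  if (any(dims == 0L) || is.null(dims)) abort("stitched image has zero size")
  stopifnot(is_scalar_number(target_longest), target_longest >= 1,
            is_scalar_number(norm_scale_ref), norm_scale_ref > 0)
  longest <- max(dims)
  ratio <- target_longest / longest
  if (dims[[1L]] >= dims[[2L]]) {
    new_h <- as.integer(target_longest)
    new_w <- as.integer(round_half_up(dims[[2L]] * ratio))
  } else {
    new_w <- as.integer(target_longest)
    new_h <- as.integer(round_half_up(dims[[1L]] * ratio))
  }
  list(
    image = resize_raster(image, height = new_h, width = new_w),
    tissue_lowres_scalef = ratio * norm_scale_ref
  )
}

#' Stitch all capture areas' spot tables of one group
#'
#' Applies [apply_group_transform()] per area and concatenates the results in
#' the given order, appending a `capture_area` column and replacing `barcode`
#' with the unique spot key `<barcode>_<area_id>`; the original barcode and
#' array coordinates are preserved in `barcode_original`,
#' `array_row_original`, `array_col_original`.
#'
#' @param areas List of `capture_area` objects (one group).
#' @param plan Their `rescale_plan`.
#' @param transforms Named list of `affine2d` from [parse_fiji_xml()]; matched
#'   to areas by image name `<area_id>.png` (or bare `area_id`).
#' @return One tibble of all transformed spots in the group fullres frame.
#' @export
stitch_positions <- function(areas, plan, transforms) {
  stopifnot(inherits(plan, "rescale_plan"))
  norm_scale <- attr(plan, "norm_scale")
  tables <- purrr::map(areas, function(area) {
    row <- plan[plan$area_id == area$area_id, ]
    if (nrow(row) != 1L) {
      abort(paste0("area ", area$area_id, " is not in the rescale plan"))
    }
    tr <- transforms[[paste0(area$area_id, ".png")]] %||%
      transforms[[area$area_id]]
    if (is.null(tr)) {
      abort(paste0("no affine transform found for capture area ", area$area_id))
    }
    area$spots |>
      apply_group_transform(tr, h = row$tissue_hires_scalef,
                            s = row$scale_factor, norm_scale_ref = norm_scale) |>
      mutate(
        capture_area = area$area_id,
        barcode_original = .data$barcode,
        barcode = paste(.data$barcode, area$area_id, sep = "_"),
        array_row_original = .data$array_row,
        array_col_original = .data$array_col
      )
  })
  out <- bind_rows(tables)
  if (any(out$pxl_row_in_fullres < 0 | out$pxl_col_in_fullres < 0)) {
    warn("some transformed coordinates are negative; the stitched canvas may have margins")
  }
  out
}

#' Write group-level tissue_positions.csv files
#'
#' One headered CSV per group, concatenating the transformed spot tables of
#' all constituent capture areas (extra columns `capture_area` etc.
#' included).
#'
#' @param group_tables Named list: group id -> stitched spot tibble from
#'   [stitch_positions()].
#' @param out_dir Output root; each group gets `out_dir/<group_id>/`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_group_positions <- function(group_tables, out_dir) {
  paths <- purrr::imap_chr(group_tables, function(tab, group_id) {
    dir <- file.path(out_dir, group_id)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_tissue_positions(tab, file.path(dir, "tissue_positions.csv"))
  })
  invisible(paths)
}
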