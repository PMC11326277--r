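#' Tidy a stitched group into its spot table
#'
#' @param x A `stitched_group`.
#' @param ... Unused.
#' @return Tibble with one row per spot: key, barcode, capture area, tissue
#'   and overlap flags, redefined and original array coordinates, and group
#'   full-resolution pixel coordinates.
#' @method tidy stitched_group
#' @export
tidy.stitched_group <- function(x, ...) {
  x$spots
}

#' One-row summary of a stitched group
#'
#' @param x A `stitched_group`.
#' @param ... Unused.
#' @return One-row tibble: `sample_id`, `n_areas`, `n_spots`, `n_in_tissue`,
#'   `n_excluded_overlapping`, `n_genes`, `total_umi`, `microns_per_pixel`,
#'   `tissue_lowres_scalef`.
#' @method glance stitched_group
#' @export
glance.stitched_group <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    n_areas = n_distinct(x$spots$capture_area),
    n_spots = nrow(x$spots),
    n_in_tissue = sum(x$spots$in_tissue),
    n_excluded_overlapping = sum(x$spots$exclude_overlapping),
    n_genes = nrow(x$counts),
    total_umi = sum(Matrix::colSums(x$counts)),
    microns_per_pixel = x$lattice$microns_per_pixel,
    tissue_lowres_scalef = x$scalefactors$tissue_lowres_scalef
  )
}
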