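## Assembly of the final stitched group: counts from all capture areas, spot
## annotations (transformed coordinates, redefined array coordinates, overlap
## flags), the lowres stitched image and group scale factors, in one tidy
## S3 object. One group replaces its constituent capture-area sample ids.

#' Build a stitched group-level sample
#'
#' Runs the full workflow for one group listed in `sample_info`: reads each
#' capture area's SpaceRanger outputs, computes the uniform rescale plan,
#' parses the Fiji transform XML, maps all spot coordinates into the group
#' full-resolution frame, resizes the stitched canvas to a lowres image with
#' matching scale factors, constructs the artificial hexagonal array and
#' snaps every spot to it, flags overlapping spots by mean-UMI precedence,
#' and assembles the counts of all areas (gene union, zero-filled; spot keys
#' `<barcode>_<area_id>`) into one object. No spot is ever dropped here; use
#' [filter_stitched()] for the standard analysis filters.
#'
#' @param sample_info Data frame with columns `group_id`, `area_id`,
#'   `spaceranger_dir`, `fiji_xml_path`, `stitched_image_path`.
#' @param group_id Group to build; default the first in `sample_info`.
#' @param target_longest Longest dimension of the lowres stitched image.
#' @param filter If `TRUE`, apply [filter_stitched()] before returning.
#' @param stage_hook Optional function called with each stage name
#'   (`"rescale"`, `"transform"`, `"array"`, `"overlap"`, `"assemble"`) as it
#'   starts; errors are rethrown prefixed with the stage name.
#' @return A `stitched_group` object.
#' @export
build_stitched_group <- function(sample_info, group_id = NULL,
                                 target_longest = 1200L, filter = FALSE,
                                 stage_hook = NULL) {
  info <- check_sample_info(sample_info)
  group_id <- group_id %||% info$group_id[[1L]]
  info <- info[info$group_id == group_id, ]
  if (nrow(info) == 0L) abort(paste0("group '", group_id, "' is not in sample_info"))
  stage <- make_stage_runner(stage_hook)

  ## -- rescale: read areas, compute the uniform-scale plan ------------------
  pieces <- stage("rescale", {
    areas <- purrr::map2(info$spaceranger_dir, info$area_id, read_capture_area)
    list(areas = areas, plan = compute_rescale_factors(areas))
  })
  areas <- pieces$areas
  plan <- pieces$plan
  norm_scale <- attr(plan, "norm_scale")
  ref_id <- attr(plan, "reference_id")
  d_ref <- plan$spot_diameter_fullres[[which(plan$area_id == ref_id)]]

  ## -- transform: coordinates into the group frame, lowres image -----------
  tr_piece <- stage("transform", {
    xml_path <- unique(info$fiji_xml_path)
    if (length(xml_path) != 1L) {
      abort(paste0("group '", group_id, "' lists several fiji_xml_path values"))
    }
    transforms <- parse_fiji_xml(xml_path)
    spots <- stitch_positions(areas, plan, transforms)
    img_path <- unique(info$stitched_image_path)
    if (length(img_path) != 1L) {
      abort(paste0("group '", group_id, "' lists several stitched_image_path values"))
    }
    lowres <- resize_stitched_image(read_raster(img_path), norm_scale,
                                    target_longest = target_longest)
    list(spots = spots, lowres = lowres)
  })
  spots <- tr_piece$spots
  lowres <- tr_piece$lowres

  ## -- array: artificial hexagonal lattice, redefined coordinates ----------
  arr_piece <- stage("array", {
    ## scale from the reference area's own transformed spots: at overlaps,
    ## spots from different areas sit arbitrarily close and would corrupt the
    ## nearest-neighbour median
    ref_spots <- spots[spots$capture_area == ref_id, ]
    mpp <- estimate_microns_per_pixel(
      ref_spots, sf = areas[[which(info$area_id == ref_id)]]$scalefactors
    )
    add_array_coords(spots, microns_per_pixel = mpp)
  })
  lattice <- attr(arr_piece, "lattice")
  spots <- arr_piece

  ## -- overlap: per-area depth, exclusion flags -----------------------------
  ov_piece <- stage("overlap", {
    mean_umis <- vapply(areas, function(a) {
      it <- a$spots$in_tissue[match(colnames(a$counts), a$spots$barcode)]
      capture_area_mean_umi(a$counts, it)
    }, numeric(1L))
    names(mean_umis) <- info$area_id
    list(spots = flag_excluded_overlaps(spots, mean_umis), mean_umis = mean_umis)
  })
  spots <- ov_piece$spots

  ## -- assemble: counts, scale factors, final object ------------------------
  g <- stage("assemble", {
    counts <- assemble_counts(areas)
    feats <- attr(counts, "features")
    absent <- setdiff(spots$barcode, colnames(counts))
    if (length(absent)) {
      ## spots present in tissue_positions but not in the (filtered) counts
      pad <- Matrix::sparseMatrix(i = integer(), j = integer(), x = double(),
                                  dims = c(nrow(counts), length(absent)),
                                  dimnames = list(rownames(counts), absent))
      counts <- cbind(counts, pad)
    }
    counts <- counts[, spots$barcode, drop = FALSE]
    attr(counts, "features") <- feats
    sf <- scalefactors(
      spot_diameter_fullres = d_ref,
      tissue_hires_scalef = norm_scale,
      tissue_lowres_scalef = lowres$tissue_lowres_scalef
    )
    spots <- spots[, c("barcode", "barcode_original", "capture_area",
                       "in_tissue", "exclude_overlapping",
                       "array_row", "array_col",
                       "array_row_original", "array_col_original",
                       "pxl_row_in_fullres", "pxl_col_in_fullres")]
    stopifnot(
      nrow(spots) == sum(vapply(areas, function(a) nrow(a$spots), numeric(1L))),
      !anyDuplicated(spots$barcode),
      all(is.finite(spots$pxl_row_in_fullres)),
      all(is.finite(spots$pxl_col_in_fullres)),
      !anyNA(spots$exclude_overlapping)
    )
    new_stitched_group(
      sample_id = group_id, counts = counts, spots = spots,
      image = lowres$image, scalefactors = sf, lattice = lattice,
      plan = plan, mean_umis = ov_piece$mean_umis
    )
  })
  if (filter) g <- filter_stitched(g) else g
}

make_stage_runner <- function(stage_hook) {
  function(name, expr) {
    if (!is.null(stage_hook)) stage_hook(name)
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(paste0("stage ", name, ": ", conditionMessage(e)))
      })
    )
  }
}

check_sample_info <- function(sample_info) {
  needed <- c("group_id", "area_id", "spaceranger_dir", "fiji_xml_path",
              "stitched_image_path")
  missing <- setdiff(needed, names(sample_info))
  if (length(missing)) {
    abort(paste0("sample_info lacks column(s): ", paste(missing, collapse = ", ")))
  }
  info <- as_tibble(sample_info)
  if (anyDuplicated(info[, c("group_id", "area_id")])) {
    abort("sample_info repeats an (group_id, area_id) pair")
  }
  dup <- info$area_id[duplicated(info$area_id)]
  if (length(dup)) {
    abort(paste0("capture area(s) in more than one group: ",
                 paste(unique(dup), collapse = ", ")))
  }
  info
}

## union of features across areas (first-appearance order), zero-filled;
## column keys <barcode>_<area_id>
assemble_counts <- function(areas) {
  feat_tabs <- purrr::map(areas, function(a) {
    attr(a$counts, "features") %||%
      tibble(id = rownames(a$counts), symbol = rownames(a$counts),
             type = "Gene Expression")
  })
  all_feats <- bind_rows(feat_tabs)
  conflict <- all_feats |>
    dplyr::distinct(.data$id, .data$symbol) |>
    dplyr::count(.data$id) |>
    filter(.data$n > 1L)
  if (nrow(conflict)) {
    warn(paste0(nrow(conflict), " feature id(s) carry conflicting gene symbols ",
                "across capture areas; keeping the first"))
  }
  features <- all_feats[!duplicated(all_feats$id), ]
  gene_ids <- features$id
  mats <- purrr::map(areas, function(a) {
    m <- methods::as(a$counts, "TsparseMatrix")
    out <- Matrix::sparseMatrix(
      i = match(rownames(a$counts), gene_ids)[m@i + 1L],
      j = m@j + 1L, x = m@x,
      dims = c(length(gene_ids), ncol(a$counts)),
      dimnames = list(gene_ids,
                      paste(colnames(a$counts), a$area_id, sep = "_"))
    )
    out
  })
  counts <- do.call(cbind, mats)
  attr(counts, "features") <- features
  counts
}

new_stitched_group <- function(sample_id, counts, spots, image, scalefactors,
                               lattice, plan = NULL, mean_umis = NULL) {
  structure(
    list(sample_id = sample_id, counts = counts, spots = as_tibble(spots),
         image = image, scalefactors = scalefactors, lattice = lattice,
         plan = plan, mean_umis = mean_umis),
    class = "stitched_group"
  )
}

#' @export
print.stitched_group <- function(x, ...) {
  cat("<stitched_group> ", x$sample_id, "\n", sep = "")
  cat("  ", nrow(x$counts), " genes x ", nrow(x$spots), " spots from ",
      n_distinct(x$spots$capture_area), " capture area(s)\n", sep = "")
  cat("  overlapping spots flagged: ", sum(x$spots$exclude_overlapping),
      "\n", sep = "")
  cat("  lowres image: ", raster_height(x$image), " x ",
      raster_width(x$image), " px;  array: ", x$lattice$n_rows, " rows x ",
      x$lattice$n_cols, " col indices\n", sep = "")
  invisible(x)
}

#' Apply the standard analysis filters to a stitched group
#'
#' Removes genes that were not detected (zero total counts) and spots that
#' are out of tissue or have zero counts; all spot annotations are subset
#' consistently. Filtering away everything is an error, signalling degenerate
#' input.
#'
#' @param g A `stitched_group`.
#' @return The filtered `stitched_group`.
#' @export
filter_stitched <- function(g) {
  stopifnot(inherits(g, "stitched_group"))
  gene_tot <- Matrix::rowSums(g$counts)
  spot_tot <- Matrix::colSums(g$counts)
  keep_gene <- gene_tot > 0
  keep_spot <- g$spots$in_tissue & spot_tot > 0
  if (!any(keep_gene) || !any(keep_spot)) {
    abort("filtering removed every gene or every spot; input looks degenerate")
  }
  feats <- attr(g$counts, "features")
  g$counts <- g$counts[keep_gene, keep_spot, drop = FALSE]
  if (!is.null(feats)) attr(g$counts, "features") <- feats[keep_gene, ]
  g$spots <- g$spots[keep_spot, ]
  g
}

#' Export a stitched group to disk
#'
#' `format = "dir"` writes a SpaceRanger-style spatial directory
#' (`spatial/tissue_positions.csv`, `spatial/tissue_lowres_image.png`,
#' `spatial/scalefactors_json.json`) plus MatrixMarket counts
#' (`counts/matrix.mtx` + sidecars), the full spot annotation table
#' (`spots.csv`) and a `sample.json` with the group metadata. Identical
#' inputs produce byte-identical text outputs. Re-import with
#' [import_stitched_group()].
#'
#' @param g A `stitched_group`.
#' @param dir Output directory.
#' @param format Only `"dir"` is available; anything else is an error.
#' @return `dir`, invisibly.
#' @export
export_stitched_group <- function(g, dir, format = "dir") {
  stopifnot(inherits(g, "stitched_group"))
  if (!identical(format, "dir")) {
    abort(paste0("unknown export format: ", format))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  positions <- g$spots
  write_group_spatial(file.path(dir, "spatial"), positions, g$image,
                      g$scalefactors)
  write_counts(g$counts, file.path(dir, "counts"))
  readr::write_csv(g$spots, file.path(dir, "spots.csv"), progress = FALSE)
  meta <- list(
    sample_id = g$sample_id,
    lattice = list(
      origin_x = g$lattice$origin[["x"]], origin_y = g$lattice$origin[["y"]],
      microns_per_pixel = g$lattice$microns_per_pixel,
      n_rows = g$lattice$n_rows, n_cols = g$lattice$n_cols
    ),
    mean_umis = as.list(g$mean_umis)
  )
  jsonlite::write_json(meta, file.path(dir, "sample.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Re-import an exported stitched group
#'
#' @param dir Directory written by [export_stitched_group()].
#' @return A `stitched_group`.
#' @export
import_stitched_group <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "sample.json"), simplifyVector = TRUE)
  counts <- read_counts(file.path(dir, "counts"))
  spots <- readr::read_csv(
    file.path(dir, "spots.csv"), progress = FALSE,
    col_types = readr::cols(
      barcode = "c", barcode_original = "c", capture_area = "c",
      in_tissue = "l", exclude_overlapping = "l",
      array_row = "i", array_col = "i",
      array_row_original = "i", array_col_original = "i",
      pxl_row_in_fullres = "d", pxl_col_in_fullres = "d"
    )
  )
  sf <- read_scalefactors(file.path(dir, "spatial", "scalefactors_json.json"))
  image <- read_raster(file.path(dir, "spatial", "tissue_lowres_image.png"))
  lattice <- structure(
    list(
      origin = c(x = meta$lattice$origin_x, y = meta$lattice$origin_y),
      microns_per_pixel = meta$lattice$microns_per_pixel,
      row_pitch_px = ROW_PITCH_UM / meta$lattice$microns_per_pixel,
      col_pitch_px = COL_PITCH_UM / meta$lattice$microns_per_pixel,
      n_rows = as.integer(meta$lattice$n_rows),
      n_cols = as.integer(meta$lattice$n_cols)
    ),
    class = "artificial_array"
  )
  new_stitched_group(
    sample_id = meta$sample_id, counts = counts, spots = spots,
    image = image, scalefactors = sf, lattice = lattice,
    mean_umis = unlist(meta$mean_umis)
  )
}
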