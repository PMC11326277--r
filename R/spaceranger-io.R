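## SpaceRanger-style spatial file formats: scalefactors_json.json,
## tissue_positions.csv (two dialects), MatrixMarket counts, and the
## group-level spatial directory written after stitching.

#' Read a SpaceRanger scalefactors_json.json file
#'
#' Parses the per-capture-area scaling metadata written by SpaceRanger:
#' `spot_diameter_fullres` (spot diameter in full-resolution pixels, the
#' quantity `d` used for uniform rescaling) and `tissue_hires_scalef` (the
#' ratio of hires-image pixels to full-resolution pixels, `h`), plus the
#' optional `tissue_lowres_scalef` and `fiducial_diameter_fullres`. Unknown
#' keys are retained so that [write_scalefactors()] round-trips the file.
#'
#' @param path Path to a JSON file (plain or gzip-compressed).
#' @return A `scalefactors` object: a list with elements
#'   `spot_diameter_fullres`, `tissue_hires_scalef`, `tissue_lowres_scalef`
#'   (`NULL` if absent), `fiducial_diameter_fullres` (`NULL` if absent) and
#'   `extra` (named list of unrecognised keys).
#' @export
read_scalefactors <- function(path) {
  if (!file.exists(path)) abort(paste0("scalefactors file does not exist: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) abort(paste0("not a JSON object: ", path))
  for (key in c("spot_diameter_fullres", "tissue_hires_scalef")) {
    if (is.null(raw[[key]])) {
      abort(paste0("scalefactors file is missing required key '", key, "': ", path))
    }
  }
  known <- c("spot_diameter_fullres", "tissue_hires_scalef",
             "tissue_lowres_scalef", "fiducial_diameter_fullres")
  for (key in intersect(known, names(raw))) {
    val <- raw[[key]]
    if (!is_scalar_number(val) || val <= 0) {
      abort(paste0("scalefactors key '", key, "' must be a positive number, got: ",
                   deparse(val)))
    }
  }
  sf <- scalefactors(
    spot_diameter_fullres = raw$spot_diameter_fullres,
    tissue_hires_scalef = raw$tissue_hires_scalef,
    tissue_lowres_scalef = raw$tissue_lowres_scalef,
    fiducial_diameter_fullres = raw$fiducial_diameter_fullres,
    extra = raw[setdiff(names(raw), known)]
  )
  sf
}

#' Construct a scalefactors object
#'
#' @param spot_diameter_fullres Spot diameter in full-resolution pixels (> 0).
#' @param tissue_hires_scalef Hires-px per fullres-px ratio (> 0).
#' @param tissue_lowres_scalef Optional lowres-px per fullres-px ratio (> 0).
#' @param fiducial_diameter_fullres Optional fiducial diameter, fullres pixels.
#' @param extra Named list of additional keys to preserve on write.
#' @return A `scalefactors` object.
#' @export
scalefactors <- function(spot_diameter_fullres, tissue_hires_scalef,
                         tissue_lowres_scalef = NULL,
                         fiducial_diameter_fullres = NULL,
                         extra = list()) {
  stopifnot(is_scalar_number(spot_diameter_fullres), spot_diameter_fullres > 0,
            is_scalar_number(tissue_hires_scalef), tissue_hires_scalef > 0)
  if (tissue_hires_scalef >= 1) {
    warn(paste0("tissue_hires_scalef = ", tissue_hires_scalef,
                " is >= 1; a hires image is normally smaller than fullres"))
  }
  if (!is.null(tissue_lowres_scalef)) {
    stopifnot(is_scalar_number(tissue_lowres_scalef), tissue_lowres_scalef > 0)
    if (tissue_lowres_scalef >= tissue_hires_scalef) {
      warn("tissue_lowres_scalef >= tissue_hires_scalef; lowres is normally the smaller image")
    }
  }
  if (!is.null(fiducial_diameter_fullres)) {
    stopifnot(is_scalar_number(fiducial_diameter_fullres),
              fiducial_diameter_fullres > 0)
  }
  structure(
    list(spot_diameter_fullres = spot_diameter_fullres,
         tissue_hires_scalef = tissue_hires_scalef,
         tissue_lowres_scalef = tissue_lowres_scalef,
         fiducial_diameter_fullres = fiducial_diameter_fullres,
         extra = extra),
    class = "scalefactors"
  )
}

#' @export
print.scalefactors <- function(x, ...) {
  cat("<scalefactors>\n")
  cat("  spot_diameter_fullres:", x$spot_diameter_fullres, "px\n")
  cat("  tissue_hires_scalef:  ", x$tissue_hires_scalef, "\n")
  if (!is.null(x$tissue_lowres_scalef)) {
    cat("  tissue_lowres_scalef: ", x$tissue_lowres_scalef, "\n")
  }
  if (length(x$extra)) {
    cat("  (+", length(x$extra), "extra keys preserved)\n")
  }
  invisible(x)
}

#' Write a scalefactors object as scalefactors_json.json
#'
#' @param sf A `scalefactors` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_scalefactors <- function(sf, path) {
  stopifnot(inherits(sf, "scalefactors"))
  out <- list(spot_diameter_fullres = sf$spot_diameter_fullres,
              tissue_hires_scalef = sf$tissue_hires_scalef)
  if (!is.null(sf$tissue_lowres_scalef)) {
    out$tissue_lowres_scalef <- sf$tissue_lowres_scalef
  }
  if (!is.null(sf$fiducial_diameter_fullres)) {
    out$fiducial_diameter_fullres <- sf$fiducial_diameter_fullres
  }
  out <- c(out, sf$extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tissue_positions table
#'
#' Reads either dialect of the SpaceRanger spot-position file: the headered
#' six-column `tissue_positions.csv` (SpaceRanger >= 2.0) or the headerless
#' `tissue_positions_list.csv` (SpaceRanger 1.x). The dialect is detected from
#' the first line: a line starting with `"barcode"` means headered. Gzipped
#' files are accepted transparently. Extra columns after the six standard ones
#' (e.g. `capture_area` in stitched group files) are preserved for headered
#' files.
#'
#' `pxl_row_in_fullres` is the vertical image axis (row), `pxl_col_in_fullres`
#' the horizontal axis, both 0-based full-resolution pixels.
#'
#' @param path Path to the CSV (plain or `.gz`).
#' @return A tibble with columns `barcode` (character), `in_tissue` (logical),
#'   `array_row`, `array_col` (integer), `pxl_row_in_fullres`,
#'   `pxl_col_in_fullres` (double), plus any extra columns as character.
#' @export
read_tissue_positions <- function(path) {
  if (!file.exists(path)) abort(paste0("tissue positions file does not exist: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  std_cols <- c("barcode", "in_tissue", "array_row", "array_col",
                "pxl_row_in_fullres", "pxl_col_in_fullres")
  headered <- length(lines) > 0L && startsWith(lines[[1L]], "barcode")
  if (headered) {
    header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
    if (length(header) < 6L || !identical(header[1:6], std_cols)) {
      abort(paste0("unexpected header in ", path, ": ", lines[[1L]]))
    }
    body <- lines[-1L]
    offset <- 1L
    ncol_expect <- length(header)
  } else {
    header <- std_cols
    body <- lines
    offset <- 0L
    ncol_expect <- 6L
  }
  if (length(body) == 0L) {
    out <- tibble(barcode = character(), in_tissue = logical(),
                  array_row = integer(), array_col = integer(),
                  pxl_row_in_fullres = double(), pxl_col_in_fullres = double())
    for (extra in setdiff(header, std_cols)) out[[extra]] <- character()
    return(out)
  }
  fields <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != ncol_expect)
  if (length(bad)) {
    abort(paste0("line ", bad[[1L]] + offset, " of ", path, ": expected ",
                 ncol_expect, " fields, found ", nf[[bad[[1L]]]],
                 " (", body[[bad[[1L]]]], ")"))
  }
  m <- matrix(unlist(fields), ncol = ncol_expect, byrow = TRUE)
  in_tissue_raw <- m[, 2L]
  if (!all(in_tissue_raw %in% c("0", "1"))) {
    abort(paste0("in_tissue column of ", path, " must be 0/1"))
  }
  out <- tibble(
    barcode = m[, 1L],
    in_tissue = in_tissue_raw == "1",
    array_row = as.integer(m[, 3L]),
    array_col = as.integer(m[, 4L]),
    pxl_row_in_fullres = as.double(m[, 5L]),
    pxl_col_in_fullres = as.double(m[, 6L])
  )
  if (ncol_expect > 6L) {
    for (j in 7L:ncol_expect) out[[header[[j]]]] <- m[, j]
  }
  if (anyNA(out$array_row) || anyNA(out$array_col) ||
      anyNA(out$pxl_row_in_fullres) || anyNA(out$pxl_col_in_fullres)) {
    abort(paste0("non-numeric coordinate field in ", path))
  }
  dup <- duplicated(out$barcode)
  if (any(dup)) {
    abort(paste0("duplicate barcode in ", path, ": ", out$barcode[dup][[1L]]))
  }
  out
}

#' Write a tissue_positions.csv file (headered dialect)
#'
#' `in_tissue` is written as 0/1 as SpaceRanger does. Any columns beyond the
#' six standard ones are appended after them.
#'
#' @param positions Tibble as returned by [read_tissue_positions()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tissue_positions <- function(positions, path) {
  std_cols <- c("barcode", "in_tissue", "array_row", "array_col",
                "pxl_row_in_fullres", "pxl_col_in_fullres")
  missing <- setdiff(std_cols, names(positions))
  if (length(missing)) {
    abort(paste0("positions table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  out <- positions[, c(std_cols, setdiff(names(positions), std_cols))]
  out$in_tissue <- as.integer(out$in_tissue)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a 10x-style MatrixMarket count matrix
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (optionally
#' gzipped) in `dir`. Feature files may carry one (id), two (id, symbol) or
#' three (id, symbol, type) columns.
#'
#' @param dir Directory containing the three files.
#' @return A `dgCMatrix` (genes x spots) with feature ids as rownames and
#'   barcodes as colnames; the parsed feature table is attached as attribute
#'   `"features"` (tibble with columns `id`, `symbol`, `type`).
#' @export
read_counts <- function(dir) {
  mtx <- find_variant(dir, "matrix.mtx")
  bc <- find_variant(dir, "barcodes.tsv")
  ft <- find_variant(dir, "features.tsv")
  for (x in list(c("matrix.mtx", is.null(mtx)), c("barcodes.tsv", is.null(bc)),
                 c("features.tsv", is.null(ft)))) {
    if (as.logical(x[[2L]])) {
      abort(paste0("no ", x[[1L]], "(.gz) found in ", dir))
    }
  }
  m <- if (endsWith(mtx, ".gz")) Matrix::readMM(gzfile(mtx)) else Matrix::readMM(mtx)
  barcodes <- readr::read_lines(bc)
  feat_lines <- readr::read_lines(ft)
  feat_fields <- strsplit(feat_lines, "\t", fixed = TRUE)
  features <- tibble(
    id = vapply(feat_fields, `[[`, character(1L), 1L),
    symbol = vapply(feat_fields, function(f) if (length(f) >= 2L) f[[2L]] else f[[1L]], character(1L)),
    type = vapply(feat_fields, function(f) if (length(f) >= 3L) f[[3L]] else "Gene Expression", character(1L))
  )
  if (nrow(m) != nrow(features)) {
    abort(paste0("matrix has ", nrow(m), " rows but features.tsv lists ",
                 nrow(features), " features in ", dir))
  }
  if (ncol(m) != length(barcodes)) {
    abort(paste0("matrix has ", ncol(m), " columns but barcodes.tsv lists ",
                 length(barcodes), " barcodes in ", dir))
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(features$id, barcodes)
  attr(m, "features") <- features
  m
}

#' Write a count matrix in 10x MatrixMarket layout
#'
#' @param counts Sparse genes x spots matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @param features Optional feature tibble (`id`, `symbol`, `type`); defaults
#'   to the matrix's `"features"` attribute or plain ids.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(counts, dir, features = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  features <- features %||% attr(counts, "features") %||%
    tibble(id = rownames(counts), symbol = rownames(counts),
           type = "Gene Expression")
  stopifnot(nrow(features) == nrow(counts))
  Matrix::writeMM(methods::as(counts, "TsparseMatrix"), file.path(dir, "matrix.mtx"))
  readr::write_lines(colnames(counts), file.path(dir, "barcodes.tsv"))
  readr::write_lines(paste(features$id, features$symbol, features$type, sep = "\t"),
                     file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read one capture area's SpaceRanger outputs
#'
#' Aggregates the spatial files and the filtered count matrix of a single
#' capture area. Expects `spatial/tissue_positions.csv` (either dialect),
#' `spatial/scalefactors_json.json`, `spatial/tissue_hires_image.png` and a
#' `filtered_feature_bc_matrix/` directory under `dir`.
#'
#' @param dir The capture area's SpaceRanger output directory.
#' @param area_id Identifier for the area (defaults to the directory name).
#' @param strict If `TRUE`, the barcodes of the count matrix must exactly
#'   match the spot table; if `FALSE` (default) they may be a subset of it.
#' @return A `capture_area` object: list with `area_id`, `spots` (tibble),
#'   `scalefactors`, `image` (hires raster array), `counts` (dgCMatrix).
#' @export
read_capture_area <- function(dir, area_id = basename(dir), strict = FALSE) {
  spatial <- file.path(dir, "spatial")
  if (!dir.exists(spatial)) abort(paste0("no spatial/ directory under ", dir))
  pos_path <- find_variant(spatial, "tissue_positions.csv") %||%
    find_variant(spatial, "tissue_positions_list.csv")
  if (is.null(pos_path)) abort(paste0("no tissue_positions(.csv|_list.csv) in ", spatial))
  spots <- read_tissue_positions(pos_path)
  sf <- read_scalefactors(file.path(spatial, "scalefactors_json.json"))
  img_path <- find_variant(spatial, "tissue_hires_image.png")
  if (is.null(img_path)) abort(paste0("no tissue_hires_image.png in ", spatial))
  image <- read_raster(img_path)
  counts_dir <- file.path(dir, "filtered_feature_bc_matrix")
  counts <- NULL
  if (dir.exists(counts_dir)) {
    counts <- read_counts(counts_dir)
    unknown <- setdiff(colnames(counts), spots$barcode)
    if (length(unknown)) {
      msg <- paste0(length(unknown), " barcode(s) in counts of ", area_id,
                    " are absent from tissue_positions")
      if (strict) abort(msg) else warn(msg)
    } else if (strict && !setequal(colnames(counts), spots$barcode)) {
      abort(paste0("counts barcodes of ", area_id,
                   " do not exactly match tissue_positions"))
    }
  }
  structure(
    list(area_id = area_id, spots = spots, scalefactors = sf,
         image = image, counts = counts, dir = dir),
    class = "capture_area"
  )
}

#' @export
print.capture_area <- function(x, ...) {
  cat("<capture_area> ", x$area_id, "\n", sep = "")
  cat("  spots: ", nrow(x$spots), " (", sum(x$spots$in_tissue), " in tissue)\n", sep = "")
  cat("  hires image: ", raster_height(x$image), " x ", raster_width(x$image), " px\n", sep = "")
  if (!is.null(x$counts)) {
    cat("  counts: ", nrow(x$counts), " genes x ", ncol(x$counts), " spots\n", sep = "")
  }
  invisible(x)
}

#' Write a group-level SpaceRanger-style spatial directory
#'
#' Writes `tissue_positions.csv` (headered dialect), `tissue_lowres_image.png`
#' and `scalefactors_json.json` imitating SpaceRanger's spatial outputs, but
#' describing the stitched group: positions are in the group full-resolution
#' frame and `tissue_lowres_scalef` relates that frame to the lowres raster.
#'
#' @param dir Output directory (created if needed).
#' @param positions Spot tibble in the group frame.
#' @param image Lowres raster array.
#' @param sf Group `scalefactors` object.
#' @return `dir`, invisibly.
#' @export
write_group_spatial <- function(dir, positions, image, sf) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("cannot create directory: ", dir))
  write_tissue_positions(positions, file.path(dir, "tissue_positions.csv"))
  write_raster(image, file.path(dir, "tissue_lowres_image.png"))
  write_scalefactors(sf, file.path(dir, "scalefactors_json.json"))
  invisible(dir)
}
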