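## Preparing uniformly-scaled images for external stitching in Fiji and
## parsing the per-capture-area rigid affine transforms Fiji writes back.
##
## Physical scale: in capture area i, one spot (55 um) spans d_i fullres
## pixels, so the hires image has d_i * h_i pixels per spot diameter. For
## stitching, every image must carry the same physical distance per pixel, so
## area i is rescaled by s_i = max_j(d_j * h_j) / (d_i * h_i). The area
## attaining the maximum is the reference (s = 1, never downscaled).

#' Compute per-capture-area rescale factors for stitching
#'
#' Determines the factor `s_i = max_j(d_j h_j) / (d_i h_i)` by which each
#' capture area's hires image must be upscaled so that one pixel represents
#' the same physical distance in every image of a group (`d` =
#' `spot_diameter_fullres`, `h` = `tissue_hires_scalef`). The reference area
#' (largest `d * h`, ties broken by lexicographically smallest `area_id`) gets
#' `s = 1`.
#'
#' @param areas Either a data frame with columns `area_id`,
#'   `spot_diameter_fullres`, `tissue_hires_scalef`, `width`, `height`
#'   (image dimensions in pixels), or a list of `capture_area` objects.
#' @return A `rescale_plan` tibble with columns `area_id`,
#'   `spot_diameter_fullres`, `tissue_hires_scalef`, `scale_factor`, `width`,
#'   `height`, `new_width`, `new_height`, carrying attributes
#'   `reference_id` and `norm_scale` (= `h_ref * s_ref`, the canvas-px per
#'   fullres-px ratio of the reference area).
#' @export
compute_rescale_factors <- function(areas) {
  tab <- as_area_table(areas)
  if (nrow(tab) == 0L) abort("cannot compute rescale factors for an empty group")
  if (any(tab$spot_diameter_fullres <= 0) || any(tab$tissue_hires_scalef <= 0)) {
    abort("all scale factors must be strictly positive")
  }
  prod <- tab$spot_diameter_fullres * tab$tissue_hires_scalef
  ref_idx <- order(-prod, tab$area_id)[[1L]]
  plan <- tab |>
    mutate(
      scale_factor = max(prod) / prod,
      new_width = as.integer(round_half_up(.data$width * .data$scale_factor)),
      new_height = as.integer(round_half_up(.data$height * .data$scale_factor))
    )
  attr(plan, "reference_id") <- tab$area_id[[ref_idx]]
  attr(plan, "norm_scale") <- tab$tissue_hires_scalef[[ref_idx]] *
    plan$scale_factor[[ref_idx]]
  class(plan) <- c("rescale_plan", class(plan))
  plan
}

as_area_table <- function(areas) {
  if (is.data.frame(areas)) {
    needed <- c("area_id", "spot_diameter_fullres", "tissue_hires_scalef",
                "width", "height")
    missing <- setdiff(needed, names(areas))
    if (length(missing)) {
      abort(paste0("area table lacks column(s): ", paste(missing, collapse = ", ")))
    }
    return(as_tibble(areas[, needed]))
  }
  if (is.list(areas) && all(vapply(areas, inherits, logical(1L), "capture_area"))) {
    return(purrr::map_dfr(areas, function(a) tibble(
      area_id = a$area_id,
      spot_diameter_fullres = a$scalefactors$spot_diameter_fullres,
      tissue_hires_scalef = a$scalefactors$tissue_hires_scalef,
      width = raster_width(a$image),
      height = raster_height(a$image)
    )))
  }
  abort("`areas` must be a data frame or a list of capture_area objects")
}

#' @export
print.rescale_plan <- function(x, ...) {
  cat("<rescale_plan> reference:", attr(x, "reference_id"),
      " norm_scale:", attr(x, "norm_scale"), "\n")
  NextMethod()
}

#' Rescale capture-area images to a uniform physical scale
#'
#' Resamples every hires image to the dimensions in `plan` (bilinear) and
#' writes one PNG per area, named `<area_id>.png`, into `out_dir`, plus a
#' `rescale_metadata.json` sidecar recording `s`, `d`, `h`, the new dimensions,
#' the reference area and the normalized canvas scale for later coordinate
#' work. These PNGs are what gets stitched externally.
#'
#' @param areas List of `capture_area` objects.
#' @param plan A `rescale_plan` from [compute_rescale_factors()].
#' @param out_dir Output directory (created if needed).
#' @return Tibble with columns `area_id`, `path`, invisibly.
#' @export
rescale_images <- function(areas, plan, out_dir) {
  stopifnot(inherits(plan, "rescale_plan"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  by_id <- setNames(areas, vapply(areas, `[[`, character(1L), "area_id"))
  written <- purrr::pmap_chr(plan, function(area_id, scale_factor, new_width,
                                            new_height, ...) {
    area <- by_id[[area_id]]
    if (is.null(area)) abort(paste0("no capture_area supplied for plan entry ", area_id))
    img <- resize_raster(area$image, height = new_height, width = new_width)
    write_raster(img, file.path(out_dir, paste0(area_id, ".png")))
  })
  meta <- list(
    reference_id = attr(plan, "reference_id"),
    norm_scale = attr(plan, "norm_scale"),
    areas = purrr::pmap(plan, function(area_id, spot_diameter_fullres,
                                       tissue_hires_scalef, scale_factor,
                                       new_width, new_height, ...) {
      list(area_id = area_id, spot_diameter_fullres = spot_diameter_fullres,
           tissue_hires_scalef = tissue_hires_scalef, scale_factor = scale_factor,
           width = new_width, height = new_height)
    })
  )
  jsonlite::write_json(meta, file.path(out_dir, "rescale_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(tibble(area_id = plan$area_id, path = written))
}

#' Construct a 2-D affine transform
#'
#' The transform maps `(x, y)` canvas coordinates (`x` horizontal, `y`
#' vertical) as `x' = a x + c y + e`, `y' = b x + d y + f` — the SVG
#' `matrix(a,b,c,d,e,f)` convention.
#'
#' @param a,b,c,d,e,f Transform coefficients.
#' @param name Optional source-image name.
#' @return An `affine2d` object wrapping the 2x3 matrix `[[a,c,e],[b,d,f]]`.
#' @export
affine2d <- function(a, b, c, d, e, f, name = NULL) {
  m <- matrix(c(a, c, e, b, d, f), nrow = 2L, byrow = TRUE,
              dimnames = list(c("x", "y"), c("x", "y", "t")))
  structure(list(matrix = m, name = name), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d>", if (!is.null(x$name)) x$name else "", "\n")
  print(x$matrix)
  if (is_rigid(x)) cat("  (rigid)\n")
  invisible(x)
}

#' Apply an affine transform to point coordinates
#'
#' @param transform An `affine2d` object.
#' @param xy Two-column matrix (or data frame) of `(x, y)` points.
#' @return A two-column matrix of transformed points.
#' @export
apply_affine <- function(transform, xy) {
  stopifnot(inherits(transform, "affine2d"))
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L)
  lin <- transform$matrix[, 1:2]
  tr <- transform$matrix[, 3L]
  out <- xy %*% t(lin)
  out[, 1L] <- out[, 1L] + tr[[1L]]
  out[, 2L] <- out[, 2L] + tr[[2L]]
  colnames(out) <- c("x", "y")
  out
}

#' Test whether an affine transform is rigid
#'
#' Rigid means the linear part is orthogonal with determinant +1 (rotation
#' plus translation, no scaling, shear or reflection).
#'
#' @param transform An `affine2d` object.
#' @param tol Numeric tolerance (default `1e-6`).
#' @return Logical scalar.
#' @export
is_rigid <- function(transform, tol = 1e-6) {
  lin <- transform$matrix[, 1:2]
  ortho <- max(abs(crossprod(lin) - diag(2))) <= tol
  ortho && abs(det(lin) - 1) <= tol
}

#' Parse a Fiji-style XML file of per-image affine transforms
#'
#' Reads the XML produced by interactive stitching and returns one rigid
#' affine transform per source image. The primary dialect is TrakEM2-style:
#' patch elements carrying an SVG `transform="matrix(a,b,c,d,e,f)"` attribute
#' and a file-name attribute (`file_path`, `file`, `name`, `image` or
#' `title`). A fallback dialect with explicit numeric attributes
#' `a`..`f` plus a name attribute is also accepted.
#'
#' @param path Path to the XML file.
#' @param require_rigid If `TRUE`, non-rigid transforms are an error; by
#'   default they only trigger a warning (Fiji can emit them).
#' @return Named list of `affine2d` objects, keyed by source image name.
#' @export
parse_fiji_xml <- function(path, require_rigid = FALSE) {
  if (!file.exists(path)) abort(paste0("transform XML does not exist: ", path))
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//*[@transform] | //*[@a and @b and @c and @d and @e and @f]")
  if (length(nodes) == 0L) {
    abort(paste0("no transform entries found in ", path))
  }
  out <- list()
  for (node in nodes) {
    name <- node_image_name(node)
    if (is.null(name)) {
      abort(paste0("transform entry without an image-name attribute in ", path))
    }
    tr_attr <- xml2::xml_attr(node, "transform")
    if (!is.na(tr_attr)) {
      coefs <- parse_matrix_string(tr_attr)
    } else {
      coefs <- suppressWarnings(as.numeric(vapply(
        c("a", "b", "c", "d", "e", "f"), function(k) xml2::xml_attr(node, k),
        character(1L))))
      if (anyNA(coefs)) {
        abort(paste0("non-numeric transform attributes for image '", name, "'"))
      }
    }
    if (name %in% names(out)) {
      abort(paste0("duplicate image name in ", path, ": ", name))
    }
    tr <- affine2d(coefs[[1L]], coefs[[2L]], coefs[[3L]], coefs[[4L]],
                   coefs[[5L]], coefs[[6L]], name = name)
    if (!is_rigid(tr)) {
      msg <- paste0("transform for image '", name, "' is not rigid")
      if (require_rigid) abort(msg) else warn(msg)
    }
    out[[name]] <- tr
  }
  ## entries that have a name but neither transform style -> error
  named_nodes <- xml2::xml_find_all(doc, "//*[@file_path or @file or @image or @title]")
  for (node in named_nodes) {
    nm <- node_image_name(node)
    if (!is.null(nm) && !nm %in% names(out)) {
      abort(paste0("image '", nm, "' has no transform attribute in ", path))
    }
  }
  out
}

node_image_name <- function(node) {
  for (key in c("file_path", "file", "image", "title", "name")) {
    val <- xml2::xml_attr(node, key)
    if (!is.na(val) && nzchar(val)) return(basename(val))
  }
  NULL
}

parse_matrix_string <- function(s) {
  m <- regmatches(s, regexec(
    "^\\s*matrix\\(\\s*([-+0-9.eE]+)[,\\s]+([-+0-9.eE]+)[,\\s]+([-+0-9.eE]+)[,\\s]+([-+0-9.eE]+)[,\\s]+([-+0-9.eE]+)[,\\s]+([-+0-9.eE]+)\\s*\\)\\s*$",
    s))[[1L]]
  if (length(m) != 7L) {
    abort(paste0("malformed transform matrix string: \"", s, "\""))
  }
  coefs <- suppressWarnings(as.numeric(m[-1L]))
  if (anyNA(coefs)) abort(paste0("malformed transform matrix string: \"", s, "\""))
  coefs
}
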