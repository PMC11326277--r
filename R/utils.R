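## Internal helpers: raster handling and small numerics.
##
## Raster convention throughout the package: plain R arrays indexed
## [row, col] or [row, col, channel], values in [0, 1], matching png::readPNG.
## EBImage indexes [x, y] (x horizontal), so every call into EBImage
## transposes on the way in and out.

round_half_up <- function(x) floor(x + 0.5)

raster_height <- function(img) dim(img)[1L]
raster_width <- function(img) dim(img)[2L]

#' Read a PNG or TIFF raster
#'
#' Returns an array indexed `[row, col]` or `[row, col, channel]` with values
#' in `[0, 1]`.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric array.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("image file does not exist: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported image format '.", ext, "': ", path))
  )
  ## collapse an alpha channel if present
  if (length(dim(img)) == 3L && dim(img)[3L] %in% c(2L, 4L)) {
    img <- img[, , -dim(img)[3L], drop = FALSE]
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
  }
  img
}

#' Write a raster as PNG
#'
#' @param img Array indexed `[row, col(, channel)]`, values in `[0, 1]`.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  png::writePNG(clamp01(img), path)
  invisible(path)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## [row, col(, ch)] array -> EBImage::Image and back
as_ebimage <- function(img) {
  if (length(dim(img)) == 3L) {
    EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
  } else {
    EBImage::Image(t(img), colormode = "Grayscale")
  }
}

from_ebimage <- function(eimg) {
  a <- EBImage::imageData(eimg)
  if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
}

## Bilinear resample to an exact output size (height, width in pixels).
resize_raster <- function(img, height, width) {
  height <- as.integer(height)
  width <- as.integer(width)
  if (height < 1L || width < 1L) abort("target raster dimensions must be >= 1 pixel")
  if (height == raster_height(img) && width == raster_width(img)) {
    return(img)
  }
  out <- EBImage::resize(as_ebimage(img), w = width, h = height,
                         filter = "bilinear")
  clamp01(from_ebimage(out))
}

## Find `base` or `base`.gz in `dir`; NULL if neither exists.
find_variant <- function(dir, base) {
  for (cand in file.path(dir, c(base, paste0(base, ".gz")))) {
    if (file.exists(cand)) return(cand)
  }
  NULL
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Deterministic pseudo-barcode for spot i: 16-mer over ACGT from the base-4
## expansion of i, plus the standard "-1" gem-group suffix.
spot_barcode <- function(i) {
  alphabet <- c("A", "C", "G", "T")
  chars <- character(16L)
  v <- i - 1L
  for (k in 16:1) {
    chars[k] <- alphabet[(v %% 4L) + 1L]
    v <- v %/% 4L
  }
  paste0(paste(chars, collapse = ""), "-1")
}
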