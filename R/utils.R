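## Round half away from zero (base round() is banker's); coordinates here
## are non-negative, so floor(x + 0.5) is round-half-up.
.roundHalfUp <- function(x) floor(x + 0.5)

#' Read an RGB raster image
#'
#' Reads a PNG or TIFF raster and returns a height x width x 3 numeric
#' array with channel values in 0-255. Grayscale rasters are replicated
#' across the three channels; an alpha channel is dropped.
#'
#' @param path file path; format chosen by extension (.png, .tif, .tiff).
#' @return numeric array (height, width, 3) in 0-255.
#' @export
readRasterImage <- function(path) {
    ext <- tolower(tools::file_ext(path))
    img <- switch(ext,
                  png = png::readPNG(path),
                  tif = ,
                  tiff = tiff::readTIFF(path),
                  stop("unsupported raster format: ", ext))
    if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
    round(img * 255)
}

#' Write an RGB raster image
#'
#' @param img numeric array (height, width, 3) with values in 0-255, or a
#'   matrix (written as grayscale).
#' @param path output path (.png or .tif/.tiff).
#' @return invisibly, \code{path}.
#' @export
writeRasterImage <- function(img, path) {
    ext <- tolower(tools::file_ext(path))
    x <- pmin(pmax(img / 255, 0), 1)
    switch(ext,
           png = png::writePNG(x, path),
           tif = ,
           tiff = tiff::writeTIFF(x, path),
           stop("unsupported raster format: ", ext))
    invisible(path)
}

#' Read a binary tissue mask
#'
#' Reads a PNG/TIFF raster and thresholds it at mid-intensity into a
#' logical matrix (TRUE = tissue).
#'
#' @param path file path.
#' @return logical matrix (height x width).
#' @export
readTissueMask <- function(path) {
    img <- readRasterImage(path)
    img[, , 1] >= 128
}

## Look up a logical raster at 0-based (x, y) coordinates with bounds checks.
.maskLookup <- function(mask, x, y) {
    if (any(x < 0L) || any(y < 0L) ||
        any(x >= ncol(mask)) || any(y >= nrow(mask)))
        stop("coordinate outside the tissue-mask raster")
    mask[cbind(y + 1L, x + 1L)]
}
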