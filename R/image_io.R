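#' Min-max normalize a slice to [0, 1]
#'
#' The first step of the sonification pipeline. A constant image maps to all
#' zeros.
#'
#' @param pixels Numeric matrix of intensities.
#' @return An object of class `slice_image`: list with `pixels` in `[0, 1]`,
#'   `H`, `W`.
#' @export
normalize_slice <- function(pixels) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) < 8 || ncol(pixels) < 8) {
    stop("slice must be at least 8 x 8 pixels", call. = FALSE)
  }
  if (any(!is.finite(pixels))) stop("slice contains non-finite values", call. = FALSE)
  rng <- range(pixels)
  p <- if (rng[2] > rng[1]) (pixels - rng[1]) / (rng[2] - rng[1]) else pixels * 0
  structure(list(pixels = p, H = nrow(p), W = ncol(p)), class = "slice_image")
}

#' Read a 2D slice from PNG, TIFF or NIfTI
#'
#' PNG and TIFF are read as 8/16-bit grayscale (multi-channel images are
#' averaged to luminance). For NIfTI volumes (`.nii` / `.nii.gz`) a slice
#' index and axis must be given. The result is min-max normalized.
#'
#' @param path File path.
#' @param slice For NIfTI input: 1-based slice index along `axis`.
#' @param axis For NIfTI input: 1, 2 or 3 (sagittal/coronal/axial for a
#'   canonically oriented volume).
#' @return A `slice_image`.
#' @export
read_slice_image <- function(path, slice = NULL, axis = 3) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    img <- tiff::readTIFF(path)
  } else if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI requires the 'RNifti' package", call. = FALSE)
    }
    vol <- as.array(RNifti::readNifti(path))
    if (is.null(slice)) stop("NIfTI input needs a slice index", call. = FALSE)
    img <- switch(as.character(axis),
                  "1" = vol[slice, , ],
                  "2" = vol[, slice, ],
                  "3" = vol[, , slice],
                  stop("axis must be 1, 2 or 3", call. = FALSE))
  } else {
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE)
  }
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  normalize_slice(img)
}
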