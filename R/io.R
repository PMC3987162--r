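#' Read a grayscale PNG or TIFF image
#'
#' Accepts 8- or 16-bit unsigned single-channel images (12-bit data in 16-bit
#' containers reads as values in `[0, 1]` like any other depth). Multi-channel
#' files are accepted only when all channels are identical (gray stored as
#' RGB); anything else is a format error.
#'
#' @param path image file path (.png, .tif, .tiff).
#' @return numeric matrix with intensities in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("Image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("Unsupported image format '.", ext, "' (expected PNG or TIFF): ",
         path)
  )
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3L]
    first <- img[, , 1L]
    for (k in seq_len(ch)[-1L]) {
      if (max(abs(img[, , k] - first)) > 1e-9) {
        stop("Multi-channel image is not single-channel grayscale: ", path)
      }
    }
    img <- first
  }
  if (length(dim(img)) != 2L) stop("Not a 2-D grayscale image: ", path)
  img
}

#' Write a grayscale image
#'
#' TIFF output (`.tif`/`.tiff`) is written at 16-bit depth, the container
#' used for 12-bit image data; PNG output is 8-bit (the installed PNG writer
#' has no deeper mode). Values are quantized to the container depth so
#' writes are exact and deterministic.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path output path (.png, .tif or .tiff).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(round(image * 65535) / 65535, path,
                    bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(round(image * 255) / 255, path)
  } else {
    stop("Unsupported output format '.", ext, "' (expected PNG or TIFF).")
  }
  invisible(path)
}

#' Evaluate a segmentation output against ground-truth masks on disk
#'
#' Reads per-ROI mask images (nonzero = inside ROI) with their lesion kinds,
#' checks they match the segmented image area, and scores the segmentation.
#'
#' @param run a `cmc_run` from [segment_matrix()] / [run_segment()].
#' @param mask_paths character vector of mask image paths.
#' @param kinds lesion kind per mask.
#' @return an `image_evaluation` (see [evaluate_segmentation()]).
#' @export
run_evaluate <- function(run, mask_paths, kinds) {
  stopifnot(inherits(run, "cmc_run"))
  if (length(mask_paths) != length(kinds)) {
    stop("`mask_paths` and `kinds` must have the same length.")
  }
  li <- label_image(run$segmentation)
  rois <- lapply(mask_paths, function(p) {
    m <- read_gray_image(p) > 0
    if (nrow(m) < nrow(li) || ncol(m) < ncol(li)) {
      stop("Mask size (", nrow(m), "x", ncol(m),
           ") does not cover the segmented image area (", nrow(li), "x",
           ncol(li), "): ", p)
    }
    m
  })
  truth <- structure(
    list(breast = NULL, rois = rois, kinds = as.character(kinds)),
    class = "ground_truth"
  )
  evaluate_segmentation(run$segmentation, truth)
}
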