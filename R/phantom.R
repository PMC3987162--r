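#' Specify a synthetic mammogram-like phantom
#'
#' Describes a fully synthetic test image: a half-elliptical breast-shaped
#' foreground (chest wall on the left image edge) over a dark background,
#' smooth correlated parenchyma texture, and a list of lesions. Three lesion
#' kinds mirror the regimes the method is evaluated on: `small_mass`
#' (compact bright blob, diameter <= 2 mm), `large_mass` (diffuse blob,
#' 2-30 mm), and `microcalc_cluster` (punctate high-contrast dots of
#' 0.1-0.5 mm scattered over a region whose diameter is the lesion size).
#'
#' Intensities are on `[0, 1]` and quantized to 12-bit (4096 levels), the
#' depth of presentation-intent digital mammograms; images written to disk go
#' into 16-bit containers.
#'
#' @param width,height image size in pixels (default 384 x 384).
#' @param pixel_pitch mm per pixel (default 0.1).
#' @param background_level dark background intensity (default 0.02).
#' @param parenchyma_level mean breast-tissue intensity (default 0.45).
#' @param noise_amplitude standard deviation of the correlated parenchyma
#'   texture (default 0.03).
#' @param noise_correlation_mm correlation length of the texture in mm
#'   (default 0.4; short enough that a 2 mm tile averages over many
#'   independent texture patches, so healthy tiles are statistically
#'   homogeneous).
#' @param lesions list of lesions, each a list with `kind`, `center` (pixel
#'   (row, col)), `size_mm` (diameter), `contrast` (additive intensity), and
#'   for `microcalc_cluster` an `n_dots` count (10-50).
#' @param seed RNG seed; the phantom is fully determined by the spec.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(width = 384L, height = 384L, pixel_pitch = 0.1,
                         background_level = 0.02, parenchyma_level = 0.45,
                         noise_amplitude = 0.03, noise_correlation_mm = 0.4,
                         lesions = list(), seed = 1L) {
  spec <- structure(
    list(width = as.integer(width), height = as.integer(height),
         pixel_pitch = pixel_pitch, background_level = background_level,
         parenchyma_level = parenchyma_level,
         noise_amplitude = noise_amplitude,
         noise_correlation_mm = noise_correlation_mm,
         lesions = lesions, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  mask <- breast_mask(spec)
  for (les in spec$lesions) {
    kind <- match.arg(les$kind,
                      c("small_mass", "large_mass", "microcalc_cluster"))
    if (kind == "small_mass" && les$size_mm > 2) {
      stop("small_mass diameter must be <= 2 mm (got ", les$size_mm, ").")
    }
    if (kind == "large_mass" && (les$size_mm <= 2 || les$size_mm > 30)) {
      stop("large_mass diameter must lie in (2, 30] mm (got ",
           les$size_mm, ").")
    }
    r_px <- les$size_mm / 2 / spec$pixel_pitch
    cr <- les$center[1L]; cc <- les$center[2L]
    probe <- rbind(c(cr, cc), c(cr - r_px, cc), c(cr + r_px, cc),
                   c(cr, cc - r_px), c(cr, cc + r_px))
    probe[, 1L] <- pmin(pmax(round(probe[, 1L]), 1L), spec$height)
    probe[, 2L] <- pmin(pmax(round(probe[, 2L]), 1L), spec$width)
    if (!all(mask[probe])) {
      stop("Lesion of kind ", kind, " at (", cr, ", ", cc,
           ") extends outside the breast region.")
    }
  }
  invisible(spec)
}

# half-ellipse attached to the left (chest-wall) edge; the contour stays
# strictly inside the field (as on a real mammogram) so border tiles always
# neighbor true background
breast_mask <- function(spec) {
  a <- 0.62 * spec$width        # semi-axis along columns
  b <- 0.42 * spec$height       # semi-axis along rows
  cy <- (spec$height + 1) / 2
  row <- matrix(seq_len(spec$height), spec$height, spec$width)
  col <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  ((col - 1) / a)^2 + ((row - cy) / b)^2 <= 1
}

#' Generate a phantom image and its ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: smooth correlated
#' parenchyma noise (Gaussian white noise blurred with a Gaussian kernel of
#' the stated correlation length, rescaled to the stated amplitude), lesions
#' added on top (masses as Gaussian radial profiles truncated at the stated
#' radius with sigma = radius/2; micro-calcifications as hard discs), then
#' 12-bit quantization. Identical spec and seed give bit-identical images.
#'
#' @param spec a `phantom_spec`.
#' @return list with `image` (numeric matrix in `[0, 1]`, 12-bit quantized)
#'   and `truth`, a `ground_truth` list: `breast` mask, `rois` (list of
#'   logical masks, pairwise disjoint, subsets of the breast mask), `kinds`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  h <- spec$height; w <- spec$width
  mask <- breast_mask(spec)
  img <- with_local_seed(spec$seed, {
    noise <- correlated_noise(h, w, spec$noise_correlation_mm / spec$pixel_pitch)
    base <- matrix(spec$background_level, h, w)
    base[mask] <- spec$parenchyma_level + spec$noise_amplitude * noise[mask]
    rois <- vector("list", length(spec$lesions))
    kinds <- character(length(spec$lesions))
    for (k in seq_along(spec$lesions)) {
      les <- spec$lesions[[k]]
      kinds[k] <- les$kind
      r_px <- les$size_mm / 2 / spec$pixel_pitch
      dist2 <- pixel_dist2(h, w, les$center)
      roi <- dist2 <= r_px^2
      if (les$kind == "microcalc_cluster") {
        n_dots <- if (is.null(les$n_dots)) 30L else as.integer(les$n_dots)
        if (n_dots < 10L || n_dots > 50L) {
          stop("microcalc_cluster n_dots must lie in [10, 50].")
        }
        for (d in seq_len(n_dots)) {
          # dot center uniform in the region disc; diameter 0.1-0.5 mm
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- r_px * sqrt(stats::runif(1))
          ctr <- les$center + rad * c(sin(ang), cos(ang))
          dot_r <- stats::runif(1, 0.05, 0.25) / spec$pixel_pitch
          base[pixel_dist2(h, w, ctr) <= dot_r^2] <-
            spec$parenchyma_level + les$contrast
        }
      } else {
        sigma <- r_px / 2                   # truncation at 2 sigma = radius
        prof <- les$contrast * exp(-dist2 / (2 * sigma^2))
        prof[!roi] <- 0
        base <- base + prof
      }
      rois[[k]] <- roi & mask
    }
    attr(base, "rois") <- rois
    attr(base, "kinds") <- kinds
    base
  })
  rois <- attr(img, "rois"); kinds <- attr(img, "kinds")
  attr(img, "rois") <- NULL; attr(img, "kinds") <- NULL
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 4095) / 4095           # 12-bit quantization
  truth <- structure(list(breast = mask, rois = rois, kinds = kinds),
                     class = "ground_truth")
  list(image = img, truth = truth)
}

pixel_dist2 <- function(h, w, center) {
  outer((seq_len(h) - center[1L])^2, (seq_len(w) - center[2L])^2, "+")
}

# unit-variance smooth noise: white Gaussian field blurred by a separable
# Gaussian kernel with the given sigma (px)
correlated_noise <- function(h, w, sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  kern <- stats::dnorm(-half:half, sd = sigma_px)
  kern <- kern / sum(kern)
  pad <- half
  z <- matrix(stats::rnorm((h + 2 * pad) * (w + 2 * pad)), h + 2 * pad)
  z <- apply(z, 2L, function(col) stats::filter(col, kern, sides = 2L))
  z <- t(apply(z, 1L, function(row) stats::filter(row, kern, sides = 2L)))
  z <- z[pad + seq_len(h), pad + seq_len(w)]
  z / stats::sd(as.vector(z))
}

#' Canonical phantom regression fixtures
#'
#' Six seeded phantoms covering the behaviors the pipeline must reproduce:
#' (a) uniform healthy breast; (b) one internal 2 mm small mass at least 6 mm
#' from the border; (c) a small mass adjacent to the border; (d) one 15 mm
#' large mass; (e) a dense micro-calcification cluster; (f) a sparse one.
#'
#' @param seed base RNG seed; fixture k uses `seed + k - 1`.
#' @param width,height fixture image size (default 384, within the 512 px
#'   envelope the fixtures are specified under).
#' @return list of six lists, each with `image`, `truth`, `descriptor`.
#' @export
fixture_suite <- function(seed = 1L, width = 384L, height = 384L) {
  mid <- round(height / 2)
  specs <- list(
    healthy = list(),
    small_mass_internal = list(list(kind = "small_mass",
                                    center = c(mid, round(0.22 * width)),
                                    size_mm = 2, contrast = 0.25)),
    small_mass_border = list(list(kind = "small_mass",
                                  center = c(mid, round(0.55 * width)),
                                  size_mm = 2, contrast = 0.25)),
    large_mass = list(list(kind = "large_mass",
                           center = c(mid, round(0.28 * width)),
                           size_mm = 15, contrast = 0.15)),
    microcalc_dense = list(list(kind = "microcalc_cluster",
                                center = c(round(0.40 * height),
                                           round(0.26 * width)),
                                size_mm = 10, contrast = 0.40, n_dots = 40L)),
    microcalc_sparse = list(list(kind = "microcalc_cluster",
                                 center = c(round(0.40 * height),
                                            round(0.26 * width)),
                                 size_mm = 10, contrast = 0.40, n_dots = 12L))
  )
  out <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    sp <- phantom_spec(width = width, height = height,
                       lesions = specs[[k]], seed = seed + k - 1L)
    ph <- generate_phantom(sp)
    out[[k]] <- list(image = ph$image, truth = ph$truth,
                     descriptor = list(name = names(specs)[k], spec = sp))
  }
  names(out) <- names(specs)
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> breast area ", sum(x$breast), " px, ",
      length(x$rois), " ROI(s)",
      if (length(x$kinds)) paste0(" [", paste(x$kinds, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}
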