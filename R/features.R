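#' Per-tile intensity and texture features
#'
#' Computes a feature vector for every internal tile of the grid: the central
#' intensity moments (mean, population variance, skewness m3/sigma^3, kurtosis
#' m4/sigma^4) and the canonical gray-level co-occurrence (GLCM) texture
#' triplet: energy sum(p^2), entropy -sum(p log p) with 0 log 0 := 0, and
#' contrast sum((i-j)^2 p). The GLCM uses `n_levels` quantization bins over
#' the global intensity range of the image, displacement 1, and the four
#' orientations 0/45/90/135 degrees, each symmetrized and normalized, with the
#' statistics averaged over orientations.
#'
#' Tile positions (grid row/column) are stored separately from the feature
#' columns: spatial position is a contiguity check applied after clustering,
#' never a clustered feature. Tiles with zero intensity variance take
#' skewness = kurtosis = 0 (the moment ratios are undefined there and a flat
#' tile is symmetric by any reasonable convention), energy 1, entropy 0 and
#' contrast 0.
#'
#' @param image numeric matrix the grid was built on.
#' @param grid a `tile_grid` with roles assigned; only internal tiles enter.
#' @param n_levels GLCM quantization levels (default 64).
#' @return a `feature_matrix`: list with `features` (N x 7 matrix), `positions`
#'   (N x 2 matrix of tile row/col), `feature_names`, `stage = "raw"`.
#' @export
compute_tile_features <- function(image, grid, n_levels = 64L) {
  stopifnot(inherits(grid, "tile_grid"))
  pos <- internal_positions(grid)
  n <- nrow(pos)
  feats <- matrix(NA_real_, n, 7L)
  lo <- min(image); hi <- max(image)
  for (i in seq_len(n)) {
    px <- tile_pixels(image, grid, pos[i, 1L], pos[i, 2L])
    feats[i, ] <- c(intensity_moments(px),
                    glcm_stats(px, n_levels = n_levels, range_lo = lo,
                               range_hi = hi))
  }
  new_feature_matrix(feats, pos, stage = "raw", grid = grid)
}

new_feature_matrix <- function(features, positions, stage, grid = NULL) {
  colnames(features) <- c("mean", "variance", "skewness", "kurtosis",
                          "energy", "entropy", "contrast")[seq_len(ncol(features))]
  if (stage == "kl") colnames(features) <- paste0("kl", seq_len(ncol(features)))
  structure(
    list(features = features,
         positions = positions,
         feature_names = colnames(features),
         stage = stage,
         grid = grid),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$features), " tiles x ", ncol(x$features),
      " features (stage: ", x$stage, ")\n", sep = "")
  invisible(x)
}

#' @describeIn compute_tile_features tidy the feature matrix into a tibble
#'   with tile_row, tile_col and one column per feature.
#' @param x a `feature_matrix`.
#' @param ... unused.
#' @method tidy feature_matrix
#' @export
tidy.feature_matrix <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(tile_row = x$positions[, 1L], tile_col = x$positions[, 2L]),
    tibble::as_tibble(x$features)
  )
}

# population central moments; flat tiles get skewness = kurtosis = 0
intensity_moments <- function(px) {
  v <- as.vector(px)
  m <- mean(v)
  d <- v - m
  m2 <- mean(d^2)
  if (m2 <= 0) return(c(m, 0, 0, 0))
  c(m, m2, mean(d^3) / m2^1.5, mean(d^4) / m2^2)
}

# GLCM energy / entropy / contrast, averaged over the given offsets
# offsets in (d_row, d_col); default four orientations at displacement 1
glcm_stats <- function(px, n_levels = 64L, range_lo = min(px),
                       range_hi = max(px),
                       offsets = list(c(0L, 1L), c(-1L, 1L),
                                      c(-1L, 0L), c(-1L, -1L))) {
  g <- quantize_levels(px, n_levels, range_lo, range_hi)
  acc <- c(energy = 0, entropy = 0, contrast = 0)
  used <- 0L
  for (off in offsets) {
    p <- glcm_table(g, n_levels, off[1L], off[2L])
    if (is.null(p)) next
    lev_i <- p$i; lev_j <- p$j; pr <- p$p
    ent <- -sum(pr * log(pr))
    acc <- acc + c(sum(pr^2), ent, sum((lev_i - lev_j)^2 * pr))
    used <- used + 1L
  }
  if (used == 0L) return(c(energy = 1, entropy = 0, contrast = 0))
  acc / used
}

quantize_levels <- function(px, n_levels, lo, hi) {
  if (hi <= lo) return(matrix(1L, nrow(px), ncol(px)))
  g <- floor((px - lo) / (hi - lo) * n_levels) + 1L
  g[g > n_levels] <- n_levels
  g[g < 1L] <- 1L
  storage.mode(g) <- "integer"
  g
}

# symmetrized, normalized co-occurrence cells for one offset, sparse form
glcm_table <- function(g, n_levels, dr, dc) {
  nr <- nrow(g); nc <- ncol(g)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r1) < 1L || length(c1) < 1L) return(NULL)
  a <- g[r1, c1, drop = FALSE]
  b <- g[r1 + dr, c1 + dc, drop = FALSE]
  key <- c((a - 1L) * n_levels + b, (b - 1L) * n_levels + a)  # symmetrize
  tab <- table(key)
  k <- as.integer(names(tab))
  cnt <- as.numeric(tab)
  list(i = (k - 1L) %/% n_levels + 1L,
       j = (k - 1L) %% n_levels + 1L,
       p = cnt / sum(cnt))
}

#' Standardize features to zero mean and unit variance
#'
#' Per-column z-scores over the whole set of tiles, using the population
#' (biased) variance. Columns with zero variance map to all zeros rather than
#' NaN. Idempotent: standardizing an already standardized matrix changes
#' nothing (within numerical tolerance).
#'
#' @param fm a `feature_matrix` (any stage).
#' @return the feature matrix with `stage = "standardized"`.
#' @export
standardize_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$features
  if (nrow(x) < 2L) stop("Standardization needs at least 2 tiles.")
  mu <- colMeans(x)
  cen <- sweep(x, 2L, mu)
  sd_pop <- sqrt(colMeans(cen^2))
  z <- sweep(cen, 2L, ifelse(sd_pop > 0, sd_pop, 1), "/")
  z[, sd_pop == 0] <- 0
  out <- fm
  out$features <- z
  out$stage <- "standardized"
  out
}

#' Karhunen-Loeve (principal-axis) decorrelation of the features
#'
#' Projects standardized features onto the eigenvectors of their sample
#' (population) covariance, ordered by decreasing eigenvalue, retaining the
#' smallest leading set of components whose eigenvalue sum reaches
#' `variance_retained` of the total. The output columns are uncorrelated and,
#' at `variance_retained = 1`, total variance is preserved exactly.
#'
#' @param fm a `feature_matrix` with `stage = "standardized"`.
#' @param variance_retained fraction of total variance to keep, in (0, 1];
#'   default 0.95.
#' @return the feature matrix with `stage = "kl"`; attributes `eigenvalues`
#'   and `rotation` record the decomposition.
#' @export
kl_transform <- function(fm, variance_retained = 0.95) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$stage != "standardized") {
    stop("kl_transform() expects a standardized feature matrix; see standardize_features().")
  }
  if (!is.numeric(variance_retained) || length(variance_retained) != 1L ||
      variance_retained <= 0 || variance_retained > 1) {
    stop("`variance_retained` must lie in (0, 1].")
  }
  x <- fm$features
  cc <- crossprod(x) / nrow(x)          # population covariance (mean already 0)
  eg <- eigen(cc, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  total <- sum(ev)
  if (total <= 0) stop("Degenerate features: zero total variance.")
  k <- which(cumsum(ev) >= variance_retained * total - 1e-12)[1L]
  rot <- eg$vectors[, seq_len(k), drop = FALSE]
  out <- fm
  out$features <- x %*% rot
  out <- new_feature_matrix(out$features, fm$positions, stage = "kl",
                            grid = fm$grid)
  attr(out, "eigenvalues") <- ev
  attr(out, "rotation") <- rot
  out
}
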