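#' Partition an image into a grid of square tiles
#'
#' Divides a single-channel image into non-overlapping `tile_size` x
#' `tile_size` pixel squares. Residual margins where the image dimensions are
#' not multiples of `tile_size` are discarded so that every tile carries the
#' same number of pixels (features computed on tiles of different areas would
#' not be comparable).
#'
#' @param image numeric matrix; single-channel intensities.
#' @param tile_size side of the square tile in pixels (default 20).
#' @param pixel_pitch physical pixel size in mm/px (default 0.1), carried
#'   along so downstream distance gates can be expressed in mm.
#' @return a `tile_grid` object with fields `tile_size`, `n_rows`, `n_cols`,
#'   `role` (an `n_rows` x `n_cols` character matrix, all `"internal"` until
#'   [assign_tile_roles()] is applied) and `pixel_pitch`.
#' @seealso [assign_tile_roles()], [compute_tile_features()]
#' @export
tile_image <- function(image, tile_size = 20, pixel_pitch = 0.1) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a 2-D numeric matrix (single-channel).")
  }
  tile_size <- as.integer(tile_size)
  if (length(tile_size) != 1L || is.na(tile_size) || tile_size < 1L) {
    stop("`tile_size` must be a positive integer.")
  }
  if (tile_size > nrow(image) || tile_size > ncol(image)) {
    stop("`tile_size` (", tile_size, ") exceeds an image dimension (",
         nrow(image), "x", ncol(image), ").")
  }
  n_rows <- nrow(image) %/% tile_size
  n_cols <- ncol(image) %/% tile_size
  structure(
    list(
      tile_size = tile_size,
      n_rows = n_rows,
      n_cols = n_cols,
      role = matrix("internal", n_rows, n_cols),
      pixel_pitch = pixel_pitch
    ),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat("<tile_grid> ", x$n_rows, " x ", x$n_cols, " tiles of ",
      x$tile_size, " px (pitch ", x$pixel_pitch, " mm/px)\n", sep = "")
  tab <- table(factor(x$role, levels = c("background", "border", "internal")))
  cat("  roles: background ", tab[["background"]], ", border ",
      tab[["border"]], ", internal ", tab[["internal"]], "\n", sep = "")
  invisible(x)
}

# pixels of tile (r, c); grid coordinates are 1-based, row-major
tile_pixels <- function(image, grid, r, c) {
  ts <- grid$tile_size
  image[(r - 1L) * ts + seq_len(ts), (c - 1L) * ts + seq_len(ts)]
}

# n_rows x n_cols matrix of tile mean intensities
tile_means <- function(image, grid) {
  ts <- grid$tile_size
  cropped <- image[seq_len(grid$n_rows * ts), seq_len(grid$n_cols * ts), drop = FALSE]
  # fold rows: (ts, n_rows, width) -> column sums give n_rows x width
  a <- array(cropped, dim = c(ts, grid$n_rows, ncol(cropped)))
  rs <- colSums(a)                                   # n_rows x width
  b <- array(t(rs), dim = c(ts, grid$n_cols, grid$n_rows))
  t(colSums(b)) / ts^2                               # n_rows x n_cols
}

#' Classify tiles as background, border, or internal
#'
#' Dark tiles (mean intensity below a threshold placed at `background_quantile`
#' of the way up the tile-mean intensity range, or essentially zero) become
#' background. Non-background tiles within `border_width` 8-connected tile
#' steps of any background tile form the border strip: these are assigned to a
#' reserved border cluster downstream, which suppresses the spurious clusters
#' that the breast contour would otherwise generate, and renders the breast
#' contour in white on the segmented image.
#'
#' @param grid a `tile_grid` from [tile_image()] built on `image`.
#' @param image the same image the grid was derived from.
#' @param background_quantile position of the background threshold within the
#'   tile-mean range, in (0, 1); default 0.05.
#' @param border_width width of the border strip in tiles (default 1).
#' @return the grid with its `role` matrix filled in.
#' @export
assign_tile_roles <- function(grid, image, background_quantile = 0.05,
                              border_width = 1L) {
  stopifnot(inherits(grid, "tile_grid"))
  tm <- tile_means(image, grid)
  lo <- min(tm)
  hi <- max(tm)
  floor_eps <- 1e-6 * max(hi, 1e-12)
  thr <- lo + background_quantile * (hi - lo)
  bg <- (tm < thr) | (tm <= floor_eps)
  if (all(bg)) {
    stop("Degenerate image: every tile classified as background.")
  }
  role <- matrix("internal", grid$n_rows, grid$n_cols)
  role[bg] <- "background"
  # border: non-background tiles within border_width Chebyshev steps of background
  near <- bg
  for (step in seq_len(border_width)) near <- dilate8(near)
  role[near & !bg] <- "border"
  grid$role <- role
  grid
}

# one-step 8-neighbourhood dilation of a logical matrix
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    src_r <- seq_len(nr) - dr
    src_c <- seq_len(nc) - dc
    ok_r <- src_r >= 1 & src_r <= nr
    ok_c <- src_c >= 1 & src_c <= nc
    out[ok_r, ok_c] <- out[ok_r, ok_c] | m[src_r[ok_r], src_c[ok_c]]
  }
  out
}

# positions (row, col) of internal tiles in deterministic row-major order,
# i.e. ordered by (row, col); tile index = (row-1)*n_cols + col
internal_positions <- function(grid) {
  idx <- which(t(grid$role) == "internal")   # t() -> row-major ordering
  if (length(idx) == 0L) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  row <- (idx - 1L) %/% grid$n_cols + 1L
  col <- (idx - 1L) %% grid$n_cols + 1L
  cbind(row = row, col = col)
}
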