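#' Split feature-space clusters into spatially connected components
#'
#' A medically meaningful cluster must be a contiguous image region, so tile
#' position — deliberately kept out of the clustered features — is applied
#' here as a compulsory check: every feature-space cluster is split into its
#' spatially connected components on the tile grid (8-connectivity by
#' default). Labels are reassigned deterministically by smallest tile index
#' (row-major). Already-contiguous clusters pass through unchanged, so the
#' operation is idempotent.
#'
#' @param partition integer cluster labels, one per tile.
#' @param positions N x 2 matrix of tile (row, col) grid coordinates.
#' @param connectivity 8 (default) or 4.
#' @return integer vector of spatially contiguous cluster labels.
#' @export
split_spatial_components <- function(partition, positions, connectivity = 8L) {
  stopifnot(length(partition) == nrow(positions))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8.")
  n <- length(partition)
  out <- integer(n)
  next_label <- 1L
  # iterate source clusters in deterministic (smallest-member) order
  for (lab in unique(partition)) {
    members <- which(partition == lab)
    comp <- spatial_components(positions[members, , drop = FALSE], connectivity)
    for (k in unique(comp)) {
      out[members[comp == k]] <- next_label
      next_label <- next_label + 1L
    }
  }
  relabel_by_position(out, positions)
}

# connected components among a set of tiles; labels by first member
spatial_components <- function(pos, connectivity) {
  m <- nrow(pos)
  if (m == 1L) return(1L)
  dr <- abs(outer(pos[, 1L], pos[, 1L], "-"))
  dc <- abs(outer(pos[, 2L], pos[, 2L], "-"))
  adj <- if (connectivity == 8L) {
    pmax(dr, dc) == 1L | (dr + dc == 1L)      # Chebyshev <= 1, not self
  } else {
    dr + dc == 1L                              # Manhattan == 1
  }
  adjacency_components(adj)
}

# canonical labels 1..k ordered by each cluster's smallest row-major tile index
relabel_by_position <- function(labels, positions) {
  ord <- order(positions[, 1L], positions[, 2L])
  match(labels, unique(labels[ord]))
}

#' Install the reserved background, border and normal-tissue clusters
#'
#' Projects an internal-tile partition onto the full tile grid with the three
#' reserved labels: 0 = image background, 1 = breast border strip, 2 = normal
#' internal tissue. The largest internal cluster (ties broken by smallest
#' tile index) is designated normal tissue; all remaining clusters become
#' candidate findings with labels 3, 4, ... in smallest-tile-index order.
#'
#' @param partition integer labels over internal tiles (spatially contiguous;
#'   see [split_spatial_components()]).
#' @param positions N x 2 internal tile (row, col) coordinates.
#' @param grid the `tile_grid` with roles assigned.
#' @return a `segmentation_result`: list with `label_tiles` (n_rows x n_cols
#'   integer matrix), `candidates` (tibble: label, n_tiles, centroid_row,
#'   centroid_col, border_dist_tiles, border_dist_mm, isolated), `grid`,
#'   `positions`, `partition`.
#' @export
install_reserved_clusters <- function(partition, positions, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  if (length(partition) == 0L) stop("Degenerate grid: no internal tiles.")
  stopifnot(length(partition) == nrow(positions))
  label_tiles <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  label_tiles[grid$role == "background"] <- 0L
  label_tiles[grid$role == "border"] <- 1L

  sizes <- tabulate(partition)
  min_index <- vapply(seq_along(sizes), function(k) {
    i <- which(partition == k)
    min((positions[i, 1L] - 1L) * grid$n_cols + positions[i, 2L])
  }, numeric(1))
  normal <- order(-sizes, min_index)[1L]
  others <- setdiff(order(min_index), normal)

  final <- integer(length(partition))
  final[partition == normal] <- 2L
  for (k in seq_along(others)) final[partition == others[k]] <- k + 2L
  label_tiles[cbind(positions[, 1L], positions[, 2L])] <- final

  cand <- if (length(others) > 0L) {
    tibble::tibble(
      label = seq_along(others) + 2L,
      n_tiles = sizes[others],
      centroid_row = vapply(others, function(k)
        mean(positions[partition == k, 1L]), numeric(1)),
      centroid_col = vapply(others, function(k)
        mean(positions[partition == k, 2L]), numeric(1)),
      border_dist_tiles = NA_real_,
      border_dist_mm = NA_real_,
      isolated = NA
    )
  } else {
    tibble::tibble(
      label = integer(0), n_tiles = integer(0),
      centroid_row = numeric(0), centroid_col = numeric(0),
      border_dist_tiles = numeric(0), border_dist_mm = numeric(0),
      isolated = logical(0)
    )
  }
  structure(
    list(label_tiles = label_tiles, candidates = cand, grid = grid,
         positions = positions, partition = final),
    class = "segmentation_result"
  )
}

#' Merge spatially adjacent candidate clusters into single findings
#'
#' A lesion that straddles tile boundaries can fragment into several
#' feature-space clusters occupying adjacent tiles. What a reader calls one
#' finding is the maximal spatially connected group of suspicious (neither
#' reserved nor normal-tissue) tiles, and the isolation criterion is defined
#' on such groups — a finding is meaningful when it has no further
#' suspicious neighbors. This step coalesces 8-adjacent (or 4-adjacent)
#' candidate clusters into single candidates, relabeling deterministically;
#' it never touches the reserved or normal-tissue labels.
#'
#' @param sr a `segmentation_result` from [install_reserved_clusters()].
#' @param connectivity 8 (default) or 4.
#' @return the `segmentation_result` with merged candidate clusters.
#' @export
merge_adjacent_candidates <- function(sr, connectivity = 8L) {
  stopifnot(inherits(sr, "segmentation_result"))
  lt <- sr$label_tiles
  cand_tiles <- which(lt >= 3L, arr.ind = TRUE)
  if (nrow(cand_tiles) == 0L) return(sr)
  comp <- spatial_components(cand_tiles, as.integer(connectivity))
  # canonical group order by smallest row-major tile index
  key <- (cand_tiles[, 1L] - 1L) * sr$grid$n_cols + cand_tiles[, 2L]
  first <- vapply(unique(comp), function(k) min(key[comp == k]), numeric(1))
  new_of <- match(comp, unique(comp)[order(first)]) + 2L
  lt[cand_tiles] <- new_of
  sr$label_tiles <- lt
  pos <- sr$positions
  sr$partition <- lt[cbind(pos[, 1L], pos[, 2L])]
  k <- max(new_of) - 2L
  sr$candidates <- tibble::tibble(
    label = seq_len(k) + 2L,
    n_tiles = vapply(seq_len(k) + 2L, function(l) sum(lt == l), integer(1)),
    centroid_row = vapply(seq_len(k) + 2L, function(l)
      mean(which(lt == l, arr.ind = TRUE)[, 1L]), numeric(1)),
    centroid_col = vapply(seq_len(k) + 2L, function(l)
      mean(which(lt == l, arr.ind = TRUE)[, 2L]), numeric(1)),
    border_dist_tiles = NA_real_,
    border_dist_mm = NA_real_,
    isolated = NA
  )
  sr
}

#' Flag small isolated candidate clusters (mass-like findings)
#'
#' Small mass lesions show up as isolated point clusters in the segmented
#' image. A candidate is flagged isolated when it (a) spans at most
#' `max_tiles` tiles, (b) is immersed in uniform healthy tissue — every tile
#' 8-adjacent to the cluster but outside it carries the normal-tissue
#' label — and (c) lies at least `min_border_mm` from the breast border strip
#' (the criterion is unreliable near the border, where spurious squares
#' abound). The mm gate converts to tiles via the pixel pitch and tile size,
#' rounding up (conservative); tile distances are Euclidean between tile
#' centers.
#'
#' @param sr a `segmentation_result` with reserved clusters installed.
#' @param max_tiles maximum cluster size in tiles (default 4).
#' @param min_border_mm minimum distance from the border strip in mm
#'   (default 6).
#' @return the `segmentation_result` with the candidate table's
#'   `border_dist_tiles`, `border_dist_mm` and `isolated` columns filled.
#' @export
flag_isolated_small_clusters <- function(sr, max_tiles = 4L,
                                         min_border_mm = 6) {
  stopifnot(inherits(sr, "segmentation_result"))
  grid <- sr$grid
  mm_per_tile <- grid$pixel_pitch * grid$tile_size
  min_tiles <- ceiling(min_border_mm / mm_per_tile)
  border_pos <- which(grid$role == "border", arr.ind = TRUE)
  cand <- sr$candidates
  lt <- sr$label_tiles
  for (i in seq_len(nrow(cand))) {
    tiles <- which(lt == cand$label[i], arr.ind = TRUE)
    bd <- if (nrow(border_pos) == 0L) Inf else min(sqrt(
      outer(tiles[, 1L], border_pos[, 1L], "-")^2 +
      outer(tiles[, 2L], border_pos[, 2L], "-")^2))
    cand$border_dist_tiles[i] <- bd
    cand$border_dist_mm[i] <- bd * mm_per_tile
    cand$isolated[i] <- cand$n_tiles[i] <= max_tiles &&
      neighbors_all_normal(lt, tiles) &&
      bd >= min_tiles
  }
  sr$candidates <- cand
  sr
}

# TRUE iff every in-grid tile 8-adjacent to (but outside) the tile set is
# normal tissue (label 2)
neighbors_all_normal <- function(label_tiles, tiles) {
  nr <- nrow(label_tiles); nc <- ncol(label_tiles)
  inside <- matrix(FALSE, nr, nc)
  inside[tiles] <- TRUE
  for (i in seq_len(nrow(tiles))) {
    for (dr in -1:1) for (dc in -1:1) {
      r <- tiles[i, 1L] + dr; c <- tiles[i, 2L] + dc
      if (r < 1L || r > nr || c < 1L || c > nc) next
      if (inside[r, c]) next
      if (label_tiles[r, c] != 2L) return(FALSE)
    }
  }
  TRUE
}

#' Upsample tile labels to a pixel-resolution label image
#'
#' @param sr a `segmentation_result`.
#' @return integer matrix of size (n_rows x tile_size) x (n_cols x tile_size);
#'   every pixel inside the tiled area carries exactly one label.
#' @export
label_image <- function(sr) {
  stopifnot(inherits(sr, "segmentation_result"))
  ts <- sr$grid$tile_size
  kronecker(sr$label_tiles, matrix(1L, ts, ts))
}

#' Render the segmentation as a grayscale image
#'
#' Deterministic label-to-gray mapping: background black (0), border white
#' (1, so the breast contour is immediately visible), normal tissue mid-gray
#' (0.5), and candidate clusters on distinct 8-bit gray levels spread over
#' the remaining range. With more candidates than distinguishable levels the
#' mapping wraps around, with a warning.
#'
#' @param sr a `segmentation_result`.
#' @param at_pixel_resolution upsample tiles to pixels (default TRUE).
#' @return numeric matrix in `[0, 1]`.
#' @export
render_labels <- function(sr, at_pixel_resolution = TRUE) {
  stopifnot(inherits(sr, "segmentation_result"))
  labs <- sort(unique(as.vector(sr$label_tiles)))
  cand_labs <- labs[labs >= 3L]
  k <- length(cand_labs)
  pool <- setdiff(seq(60L, 235L, by = 1L), 128L)  # 8-bit grays, reserved-free
  if (k > 0L) {
    levels_8 <- pool[round(seq(1L, length(pool), length.out = min(k, length(pool))))]
    if (k > length(pool)) {
      warning("More candidate clusters (", k, ") than distinguishable gray ",
              "levels; gray assignment wraps.")
      levels_8 <- rep_len(levels_8, k)
    }
  } else levels_8 <- integer(0)
  gray_of <- c(`0` = 0, `1` = 1, `2` = 0.5)
  if (k > 0L) gray_of[as.character(cand_labs)] <- levels_8 / 255
  m <- matrix(gray_of[as.character(sr$label_tiles)],
              nrow(sr$label_tiles), ncol(sr$label_tiles))
  if (at_pixel_resolution) {
    ts <- sr$grid$tile_size
    m <- kronecker(m, matrix(1, ts, ts))
  }
  m
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result> ", x$grid$n_rows, " x ", x$grid$n_cols,
      " tiles; ", nrow(x$candidates), " candidate cluster(s)",
      if (nrow(x$candidates) > 0 && !all(is.na(x$candidates$isolated)))
        paste0(", ", sum(x$candidates$isolated), " isolated") else "",
      "\n", sep = "")
  invisible(x)
}

#' @describeIn install_reserved_clusters the candidate-cluster table.
#' @param x a `segmentation_result`.
#' @param ... unused.
#' @method tidy segmentation_result
#' @export
tidy.segmentation_result <- function(x, ...) x$candidates
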