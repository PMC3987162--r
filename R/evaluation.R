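#' ROI-referenced overlap fraction
#'
#' Fraction of the ground-truth ROI covered by a segmented cluster:
#' `|cluster intersect roi| / |roi|`. The denominator is the ROI area — the
#' convention in which a cluster fully covering the ROI scores 1 regardless
#' of how far it extends beyond it; intersection-over-union is available as
#' an alternative.
#'
#' @param cluster_mask logical matrix (or coercible) marking the cluster.
#' @param roi_mask logical matrix of the ROI, same dimensions, non-empty.
#' @param denominator `"roi"` (default) or `"union"` (IoU).
#' @return overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(cluster_mask, roi_mask, denominator = c("roi", "union")) {
  denominator <- match.arg(denominator)
  cluster_mask <- as.logical(cluster_mask)
  roi_mask <- as.logical(roi_mask)
  if (length(cluster_mask) != length(roi_mask)) {
    stop("`cluster_mask` and `roi_mask` must have the same dimensions.")
  }
  n_roi <- sum(roi_mask)
  if (n_roi == 0L) stop("Empty ROI mask.")
  inter <- sum(cluster_mask & roi_mask)
  if (denominator == "roi") inter / n_roi
  else inter / sum(cluster_mask | roi_mask)
}

#' Bin overlap fractions into the standard reporting histogram
#'
#' Ten bins with edges 0, 5, 15, 25, ..., 85, 95 percent: left-closed,
#' right-open, except that the last bin is closed above and additionally
#' absorbs fractions beyond 0.95 (a fraction of exactly 0.05 falls in the
#' "5-15%" bin).
#'
#' @param fractions numeric vector of overlap fractions in `[0, 1]`.
#' @return tibble with columns `bin` (labels "0-5%" ... "85-95%") and
#'   `count`; counts sum to `length(fractions)`.
#' @export
bin_overlaps <- function(fractions) {
  if (any(fractions < 0 | fractions > 1)) {
    stop("Overlap fractions must lie in [0, 1].")
  }
  edges <- c(0, 0.05, 0.15, 0.25, 0.35, 0.45, 0.55, 0.65, 0.75, 0.85, 1 + 1e-9)
  labels <- c("0-5%", "5-15%", "15-25%", "25-35%", "35-45%", "45-55%",
              "55-65%", "65-75%", "75-85%", "85-95%")
  idx <- findInterval(fractions, edges, rightmost.closed = TRUE)
  idx[idx > 10L] <- 10L
  tibble::tibble(bin = labels,
                 count = tabulate(idx, nbins = 10L))
}

#' Accuracy from confusion counts
#'
#' `acc = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy_from_counts <- function(tp, tn, fp, fn) {
  (tp + tn) / (tp + tn + fp + fn)
}

#' Image-denominator accuracy variant
#'
#' `acc = (N - FP - FN) / N`: errors counted against a fixed image total
#' `n`, the arithmetic used when per-class error counts are reported against
#' a whole-dataset denominator.
#'
#' @param n total number of images.
#' @param fp,fn error counts.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy_image_denominator <- function(n, fp, fn) (n - fp - fn) / n

#' Score one segmentation against its ground truth
#'
#' Computes, per ground-truth ROI, the best overlap fraction achieved by any
#' candidate cluster and by any isolated-flagged candidate, plus image-level
#' flags: whether any isolated candidate matches no ROI (a spurious
#' isolated finding) and whether a "big" candidate (more than `big_tiles`
#' tiles) exists that matches no ROI. All overlaps are evaluated at pixel
#' resolution, in the frame of the tiled image area.
#'
#' @param sr a `segmentation_result` (isolation flags filled).
#' @param truth a `ground_truth` (masks at full image resolution; they are
#'   cropped to the tiled area).
#' @param big_tiles size above which a candidate counts as a big cluster
#'   (default 4).
#' @return an `image_evaluation`: list with `roi` (tibble: kind, n_px,
#'   best_overlap, best_label, best_isolated_overlap), `n_isolated`,
#'   `spurious_isolated`, `spurious_big`, and `n_candidates`.
#' @export
evaluate_segmentation <- function(sr, truth, big_tiles = 4L) {
  stopifnot(inherits(sr, "segmentation_result"))
  stopifnot(inherits(truth, "ground_truth"))
  li <- label_image(sr)
  crop <- function(m) {
    if (nrow(m) < nrow(li) || ncol(m) < ncol(li)) {
      stop("Ground-truth mask smaller than the segmented image area.")
    }
    m[seq_len(nrow(li)), seq_len(ncol(li)), drop = FALSE]
  }
  cand <- sr$candidates
  iso_labels <- cand$label[which(cand$isolated)]
  n_roi <- length(truth$rois)
  roi_tb <- tibble::tibble(
    roi = seq_len(n_roi),
    kind = if (n_roi) truth$kinds else character(0),
    n_px = integer(n_roi), best_overlap = numeric(n_roi),
    best_label = NA_integer_, best_isolated_overlap = numeric(n_roi)
  )
  matched_any <- rep(FALSE, nrow(cand))
  for (r in seq_len(n_roi)) {
    roi <- crop(truth$rois[[r]])
    roi_tb$n_px[r] <- sum(roi)
    best <- 0; best_lab <- NA_integer_; best_iso <- 0
    for (i in seq_len(nrow(cand))) {
      ov <- overlap_fraction(li == cand$label[i], roi)
      if (ov > 0) matched_any[i] <- TRUE
      if (ov > best) { best <- ov; best_lab <- cand$label[i] }
      if (cand$label[i] %in% iso_labels && ov > best_iso) best_iso <- ov
    }
    roi_tb$best_overlap[r] <- best
    roi_tb$best_label[r] <- best_lab
    roi_tb$best_isolated_overlap[r] <- best_iso
  }
  structure(
    list(
      roi = roi_tb,
      n_candidates = nrow(cand),
      n_isolated = length(iso_labels),
      spurious_isolated = any(cand$isolated & !matched_any, na.rm = TRUE),
      spurious_big = any(cand$n_tiles > big_tiles & !matched_any)
    ),
    class = "image_evaluation"
  )
}

#' @export
print.image_evaluation <- function(x, ...) {
  cat("<image_evaluation> ", nrow(x$roi), " ROI(s), ", x$n_candidates,
      " candidate(s), ", x$n_isolated, " isolated\n", sep = "")
  invisible(x)
}

#' Confusion counts and accuracy over a set of evaluated images
#'
#' Aggregates per-image evaluations into class-specific confusion counts and
#' accuracy `(TP + TN) / (TP + TN + FP + FN)`, using the accounting unit
#' appropriate to each lesion class:
#'
#' * `small_mass` — unit: ROI for positives (TP iff some isolated-flagged
#'   candidate overlaps the ROI, FN otherwise); an image whose isolated
#'   candidates match no ROI contributes one FP; an ROI-free image with no
#'   spurious isolated finding contributes one TN.
#' * `large_mass` — unit: ROI for positives with a partial-match rule: TP iff
#'   the best candidate overlap reaches `match_threshold` (default 0.25,
#'   below which a match is not considered pathology-conclusive); FP/TN per
#'   ROI-free image by presence/absence of a spurious big cluster.
#' * `microcalc_cluster` — unit: image; a positive image is TP iff some
#'   candidate overlaps the micro-calcification region by at least
#'   `match_threshold`; a negative image is FP iff it shows a spurious big
#'   internal cluster.
#'
#' @param evaluations list of `image_evaluation` objects.
#' @param class one of `"small_mass"`, `"large_mass"`, `"microcalc_cluster"`.
#' @param match_threshold minimum overlap for a partial match (default 0.25).
#' @return an `evaluation_report`: tibble row with class, tp, tn, fp, fn,
#'   accuracy, accuracy_image_denominator and n_images.
#' @export
confusion_and_accuracy <- function(evaluations, class,
                                   match_threshold = 0.25) {
  class <- match.arg(class,
                     c("small_mass", "large_mass", "microcalc_cluster"))
  tp <- tn <- fp <- fn <- 0L
  for (ev in evaluations) {
    stopifnot(inherits(ev, "image_evaluation"))
    rois <- ev$roi[ev$roi$kind == class, , drop = FALSE]
    if (class == "small_mass") {
      tp <- tp + sum(rois$best_isolated_overlap > 0)
      fn <- fn + sum(rois$best_isolated_overlap == 0)
      if (ev$spurious_isolated) fp <- fp + 1L
      else if (nrow(rois) == 0L) tn <- tn + 1L
    } else if (class == "large_mass") {
      tp <- tp + sum(rois$best_overlap >= match_threshold)
      fn <- fn + sum(rois$best_overlap < match_threshold)
      if (nrow(rois) == 0L) {
        if (ev$spurious_big) fp <- fp + 1L else tn <- tn + 1L
      }
    } else {
      if (nrow(rois) > 0L) {
        if (any(rois$best_overlap >= match_threshold)) tp <- tp + 1L
        else fn <- fn + 1L
      } else {
        if (ev$spurious_big) fp <- fp + 1L else tn <- tn + 1L
      }
    }
  }
  n <- length(evaluations)
  structure(
    tibble::tibble(
      class = class, tp = tp, tn = tn, fp = fp, fn = fn,
      accuracy = accuracy_from_counts(tp, tn, fp, fn),
      accuracy_image_denominator = accuracy_image_denominator(n, fp, fn),
      n_images = n,
      match_threshold = match_threshold
    ),
    class = c("evaluation_report", "tbl_df", "tbl", "data.frame")
  )
}

#' @describeIn confusion_and_accuracy the report as a plain tibble.
#' @param x an `evaluation_report`.
#' @param ... unused.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @describeIn confusion_and_accuracy one-row accuracy summary.
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(class = x$class, accuracy = x$accuracy,
                 n_images = x$n_images)
}
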