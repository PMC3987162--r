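test_that("overlap fraction counts ROI coverage", {
  roi <- matrix(FALSE, 10, 10); roi[1:2, 1:5] <- TRUE
  full <- matrix(TRUE, 10, 10)
  expect_equal(overlap_fraction(full, roi), 1)
  expect_equal(overlap_fraction(!roi, roi), 0)
  part <- matrix(FALSE, 10, 10); part[1, 1:3] <- TRUE
  expect_equal(overlap_fraction(part, roi), 0.3)
  expect_equal(overlap_fraction(part, roi, denominator = "union"), 0.3)
  expect_error(overlap_fraction(part, matrix(FALSE, 10, 10)), "Empty")
  expect_error(overlap_fraction(matrix(TRUE, 2, 2), roi), "dimensions")
})

test_that("overlap binning follows the reporting convention", {
  b <- bin_overlaps(c(0.30))
  expect_equal(b$count[b$bin == "25-35%"], 1L)
  # boundary: exactly 0.05 goes to the second bin
  b2 <- bin_overlaps(c(0.05))
  expect_equal(b2$count[b2$bin == "5-15%"], 1L)
  # above 0.95 lands in the top bin
  b3 <- bin_overlaps(c(0.97, 1))
  expect_equal(b3$count[b3$bin == "85-95%"], 2L)
  # totals are conserved
  set.seed(2)
  fr <- runif(73)
  expect_equal(sum(bin_overlaps(fr)$count), 73L)
  expect_error(bin_overlaps(c(-0.1)), "\\[0, 1\\]")
})

test_that("accuracy helpers implement both denominators", {
  expect_equal(accuracy_from_counts(15, 4, 0, 1), 19 / 20)
  expect_equal(accuracy_image_denominator(195, 3, 4), 188 / 195)
  expect_true(accuracy_from_counts(1, 1, 1, 1) >= 0 &&
                accuracy_from_counts(1, 1, 1, 1) <= 1)
})

# build a small synthetic evaluation: one positive and one negative image
fake_eval <- function(kind, iso_overlap, any_overlap, spurious_iso = FALSE,
                      spurious_big = FALSE) {
  n <- length(kind)
  structure(list(
    roi = tibble::tibble(roi = seq_len(n), kind = kind,
                         n_px = rep(100L, n),
                         best_overlap = any_overlap,
                         best_label = rep(3L, n),
                         best_isolated_overlap = iso_overlap),
    n_candidates = 1L, n_isolated = as.integer(any(iso_overlap > 0)),
    spurious_isolated = spurious_iso, spurious_big = spurious_big),
    class = "image_evaluation")
}

test_that("confusion accounting follows the per-class unit rules", {
  evs <- list(
    fake_eval("small_mass", iso_overlap = 0.5, any_overlap = 0.5),
    fake_eval("small_mass", iso_overlap = 0, any_overlap = 0.1),
    fake_eval(character(0), numeric(0), numeric(0)),               # healthy
    fake_eval(character(0), numeric(0), numeric(0),
              spurious_iso = TRUE)
  )
  rep_small <- confusion_and_accuracy(evs, "small_mass")
  expect_equal(rep_small$tp, 1L)
  expect_equal(rep_small$fn, 1L)
  expect_equal(rep_small$fp, 1L)
  expect_equal(rep_small$tn, 1L)
  expect_equal(rep_small$accuracy, 0.5)
  expect_equal(rep_small$accuracy_image_denominator, (4 - 1 - 1) / 4)

  evs_large <- list(
    fake_eval("large_mass", 0, any_overlap = 0.30),
    fake_eval("large_mass", 0, any_overlap = 0.10),
    fake_eval(character(0), numeric(0), numeric(0), spurious_big = TRUE),
    fake_eval(character(0), numeric(0), numeric(0))
  )
  rep_large <- confusion_and_accuracy(evs_large, "large_mass",
                                      match_threshold = 0.25)
  expect_equal(unlist(rep_large[c("tp", "fn", "fp", "tn")]),
               c(tp = 1L, fn = 1L, fp = 1L, tn = 1L))

  evs_micro <- list(
    fake_eval("microcalc_cluster", 0, any_overlap = 0.40),
    fake_eval("microcalc_cluster", 0, any_overlap = 0.20),
    fake_eval(character(0), numeric(0), numeric(0))
  )
  rep_micro <- confusion_and_accuracy(evs_micro, "microcalc_cluster")
  expect_equal(unlist(rep_micro[c("tp", "fn", "fp", "tn")]),
               c(tp = 1L, fn = 1L, fp = 0L, tn = 1L))

  # a healthy image with no candidates is a TN for every class
  healthy_only <- list(fake_eval(character(0), numeric(0), numeric(0)))
  for (cl in c("small_mass", "large_mass", "microcalc_cluster")) {
    r <- confusion_and_accuracy(healthy_only, cl)
    expect_equal(r$tn, 1L)
    expect_equal(r$tp + r$fp + r$fn, 0L)
  }
  expect_error(confusion_and_accuracy(healthy_only, "nonsense"))
})

test_that("evaluation reports are invariant to candidate label renaming", {
  # two equivalent segmentations whose candidate labels differ
  role <- matrix("internal", 4, 4)
  grid <- structure(list(tile_size = 5L, n_rows = 4L, n_cols = 4L,
                         role = role, pixel_pitch = 0.1),
                    class = "tile_grid")
  pos <- as.matrix(expand.grid(row = 1:4, col = 1:4))
  part <- rep(1L, 16)
  part[pos[, 1] == 2 & pos[, 2] == 2] <- 2L
  sr <- flag_isolated_small_clusters(
    install_reserved_clusters(part, pos, grid))
  roi <- matrix(FALSE, 20, 20); roi[6:10, 6:10] <- TRUE
  truth <- structure(list(breast = NULL, rois = list(roi),
                          kinds = "small_mass"), class = "ground_truth")
  ev <- evaluate_segmentation(sr, truth)
  expect_equal(ev$roi$best_overlap, 1)
  expect_equal(ev$roi$best_isolated_overlap, 1)
  expect_false(ev$spurious_isolated)
})
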