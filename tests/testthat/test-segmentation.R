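# a grid with prescribed roles, for projecting partitions
role_grid <- function(role, tile_size = 10L, pixel_pitch = 0.1) {
  structure(list(tile_size = tile_size, n_rows = nrow(role),
                 n_cols = ncol(role), role = role,
                 pixel_pitch = pixel_pitch),
            class = "tile_grid")
}

all_internal <- function(nr, nc) matrix("internal", nr, nc)

test_that("feature clusters split into spatial components deterministically", {
  pos <- rbind(c(1, 1), c(6, 6))
  expect_equal(split_spatial_components(c(1L, 1L), pos), 1:2)

  # L-shaped diagonal chain: connected under 8-, split under 4-connectivity
  posL <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_equal(split_spatial_components(rep(1L, 3), posL, 8), rep(1L, 3))
  expect_equal(split_spatial_components(rep(1L, 3), posL, 4), 1:3)

  # already contiguous: idempotent
  posC <- rbind(c(1, 1), c(1, 2), c(2, 2))
  p1 <- split_spatial_components(rep(1L, 3), posC)
  expect_equal(p1, rep(1L, 3))
  expect_equal(split_spatial_components(p1, posC), p1)
})

test_that("reserved clusters install with the largest-cluster-normal rule", {
  role <- all_internal(3, 3)
  role[1, ] <- "background"
  role[2, ] <- "border"
  grid <- role_grid(role)
  pos <- cbind(rep(3, 3), 1:3)
  sr <- install_reserved_clusters(c(1L, 1L, 2L), pos, grid)
  expect_equal(sr$label_tiles[1, ], rep(0L, 3))
  expect_equal(sr$label_tiles[2, ], rep(1L, 3))
  expect_equal(sr$label_tiles[3, ], c(2L, 2L, 3L))   # largest -> normal
  expect_equal(sr$candidates$n_tiles, 1L)

  # tie for largest: the cluster containing the smaller tile index wins
  sr2 <- install_reserved_clusters(c(1L, 2L, 2L, 1L),
                                   cbind(rep(3, 4), c(1, 2, 3, 3)),
                                   role_grid(cbind(role, "internal")))
  expect_equal(sr2$label_tiles[3, 1], 2L)

  # single cluster: no candidates
  sr3 <- install_reserved_clusters(rep(1L, 3), pos, grid)
  expect_equal(nrow(sr3$candidates), 0L)

  expect_error(install_reserved_clusters(integer(0),
                                         matrix(0, 0, 2), grid),
               "internal")
})

test_that("adjacent candidate clusters merge into one finding", {
  grid <- role_grid(all_internal(5, 5))
  pos <- as.matrix(expand.grid(row = 1:5, col = 1:5))
  part <- rep(1L, 25)
  part[pos[, "row"] == 3 & pos[, "col"] == 3] <- 2L
  part[pos[, "row"] == 3 & pos[, "col"] == 4] <- 3L   # adjacent singleton
  part[pos[, "row"] == 1 & pos[, "col"] == 5] <- 4L   # far singleton
  sr <- install_reserved_clusters(part, pos, grid)
  expect_equal(nrow(sr$candidates), 3L)
  m <- merge_adjacent_candidates(sr)
  expect_equal(nrow(m$candidates), 2L)
  expect_equal(sort(m$candidates$n_tiles), c(1L, 2L))
})

test_that("the isolation criterion gates on size, neighbors and distance", {
  role <- all_internal(12, 12)
  role[, 12] <- "background"
  role[, 11] <- "border"
  grid <- role_grid(role, tile_size = 10L)     # 1 mm per tile -> gate 6 tiles
  pos <- as.matrix(expand.grid(row = 1:12, col = 1:10))
  internal_n <- nrow(pos)
  idx_of <- function(r, c) which(pos[, 1] == r & pos[, 2] == c)

  # single candidate tile deep inside (10 mm from border): flagged
  part <- rep(1L, internal_n)
  part[idx_of(6, 1)] <- 2L
  sr <- flag_isolated_small_clusters(
    install_reserved_clusters(part, pos, grid))
  expect_true(sr$candidates$isolated)
  expect_equal(sr$candidates$border_dist_mm, 10)

  # five-tile candidate: too large
  part2 <- rep(1L, internal_n)
  for (r in 4:8) part2[idx_of(r, 2)] <- 2L
  sr2 <- flag_isolated_small_clusters(
    install_reserved_clusters(part2, pos, grid))
  expect_false(sr2$candidates$isolated)

  # candidate adjacent to the border strip: distance gate fails
  part3 <- rep(1L, internal_n)
  part3[idx_of(6, 10)] <- 2L
  sr3 <- flag_isolated_small_clusters(
    install_reserved_clusters(part3, pos, grid))
  expect_false(sr3$candidates$isolated)

  # candidate touching another candidate: neighborhood not normal
  part4 <- rep(1L, internal_n)
  part4[idx_of(6, 2)] <- 2L
  part4[idx_of(6, 3)] <- 3L
  sr4 <- flag_isolated_small_clusters(
    install_reserved_clusters(part4, pos, grid))
  expect_equal(sr4$candidates$isolated, c(FALSE, FALSE))
})

test_that("label projection covers every pixel and renders deterministically", {
  role <- all_internal(3, 3)
  role[1, ] <- "background"
  grid <- role_grid(role, tile_size = 4L)
  pos <- as.matrix(expand.grid(row = 2:3, col = 1:3))
  part <- c(1L, 1L, 1L, 1L, 2L, 3L)
  sr <- install_reserved_clusters(part, pos, grid)
  li <- label_image(sr)
  expect_equal(dim(li), c(12L, 12L))
  expect_false(any(is.na(li)))
  expect_equal(sort(unique(as.vector(li))), c(0L, 2L, 3L, 4L))

  rend <- render_labels(sr)
  expect_equal(dim(rend), c(12L, 12L))
  expect_equal(length(unique(as.vector(rend))), 4L)   # k + 3 distinct grays
  expect_identical(rend, render_labels(sr))

  # reserved-only segmentation renders three values
  sr2 <- install_reserved_clusters(rep(1L, 6), pos, grid)
  sr2$label_tiles[1, ] <- 0L
  role2 <- role; role2[2, 1] <- "border"
  expect_lte(length(unique(as.vector(render_labels(sr2)))), 3L)
})
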