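#' Segment a grayscale image with chaotic-map clustering
#'
#' Runs the full pipeline on an in-memory image matrix: tiling, tile-role
#' assignment, feature extraction, standardization, Karhunen-Loeve
#' decorrelation, then either the chaotic-map route (KNN scale, Gaussian
#' coupling, map iteration, sign-bit mutual information) or the Euclidean
#' baseline, followed by the threshold hierarchy, stability selection,
#' spatial-contiguity splitting, reserved-cluster installation and the
#' isolation criterion. Degenerate states (no stability plateau, isolated
#' feature-space points) are propagated as flags, not errors.
#'
#' @param image numeric matrix, intensities in `[0, 1]` (any positive range
#'   is accepted; features are standardized).
#' @param config a [cmc_config()].
#' @return a `cmc_run`: list with `segmentation` (a `segmentation_result`),
#'   `hierarchy`, `selection`, `features` (KL stage), `grid`, `config`,
#'   `timings` (named seconds).
#' @export
segment_matrix <- function(image, config = cmc_config()) {
  stopifnot(inherits(config, "cmc_config"))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  t0 <- tic()

  grid <- tile_image(image, config$tile_size, config$pixel_pitch)
  grid <- assign_tile_roles(grid, image, config$background_quantile,
                            config$border_width)
  fm <- compute_tile_features(image, grid)
  fm <- standardize_features(fm)
  fm <- kl_transform(fm, config$variance_retained)
  timings["features"] <- tic() - t0

  t0 <- tic()
  if (config$mode == "cmc") {
    a <- knn_scale(fm, config$K)
    cs <- build_coupling(fm, a, config$sparsity_cutoff, on_isolated = "free")
    sr <- iterate_maps(cs, seed = config$seed,
                       t_transient = config$t_transient,
                       t_meas = config$t_meas)
    sr <- mutual_information(sr)
    thetas <- seq(config$theta_min, config$theta_max, by = config$theta_step)
    if (thetas[1L] == 0) thetas[1L] <- 0   # keep grid as given
    hierarchy <- build_hierarchy(sr$mi, thetas)
  } else {
    hierarchy <- euclidean_baseline(fm)
    sr <- NULL
  }
  timings["clustering"] <- tic() - t0

  t0 <- tic()
  selection <- select_stable_partition(hierarchy, config$min_plateau)
  part <- split_spatial_components(selection$partition, fm$positions,
                                   config$connectivity)
  seg <- install_reserved_clusters(part, fm$positions, grid)
  seg <- merge_adjacent_candidates(seg, config$connectivity)
  seg <- flag_isolated_small_clusters(seg, config$max_tiles,
                                      config$min_border_mm)
  timings["segmentation"] <- tic() - t0

  structure(
    list(segmentation = seg, hierarchy = hierarchy, selection = selection,
         features = fm, sync = sr, grid = grid, config = config,
         timings = timings),
    class = "cmc_run"
  )
}

#' @export
print.cmc_run <- function(x, ...) {
  cat("<cmc_run> mode: ", x$config$mode,
      ", selected theta = ", format(x$selection$selected_theta, digits = 3),
      if (x$selection$degenerate) " (degenerate plateau)" else "",
      "\n", sep = "")
  print(x$segmentation)
  invisible(x)
}

#' Segment an image file and write all pipeline outputs
#'
#' File-level front end of [segment_matrix()]: reads a grayscale PNG or TIFF,
#' runs the pipeline, and writes to `out_dir`: the label raster
#' (`labels.tiff`, 16-bit, plus `labels.csv` at tile resolution), the
#' grayscale rendering (`render.png`, border in white), the hierarchy summary
#' (`hierarchy.csv`), the candidate table (`candidates.csv`), the feature
#' matrix (`features.csv`), the effective configuration (`config.yaml`) and a
#' plain-text log (`run.log`) stamped with the config hash, seed and
#' per-phase timings. Identical input, config and seed produce bit-identical
#' outputs.
#'
#' @param image_path path to a grayscale PNG/TIFF image.
#' @param config a [cmc_config()].
#' @param out_dir output directory (created if missing).
#' @return the `cmc_run`, invisibly.
#' @export
run_segment <- function(image_path, config = cmc_config(), out_dir) {
  image <- read_gray_image(image_path)
  run <- segment_matrix(image, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seg <- run$segmentation

  li <- label_image(seg)
  tiff::writeTIFF(li / 65535, file.path(out_dir, "labels.tiff"),
                  bits.per.sample = 16L)
  utils::write.csv(label_tiles_table(seg),
                   file.path(out_dir, "labels.csv"), row.names = FALSE)
  png::writePNG(render_labels(seg), file.path(out_dir, "render.png"))
  utils::write.csv(run$hierarchy$summary,
                   file.path(out_dir, "hierarchy.csv"), row.names = FALSE)
  utils::write.csv(seg$candidates, file.path(out_dir, "candidates.csv"),
                   row.names = FALSE)
  utils::write.csv(feature_table(run$features),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  save_config(config, file.path(out_dir, "config.yaml"))

  log_lines <- c(
    paste0("cmcseg run | mode=", config$mode,
           " | seed=", config$seed,
           " | config_md5=", config_hash(config)),
    paste0("image: ", image_path, " (", nrow(image), "x", ncol(image), ")"),
    paste0("grid: ", seg$grid$n_rows, "x", seg$grid$n_cols, " tiles of ",
           seg$grid$tile_size, " px"),
    paste0("selected threshold: ",
           format(run$selection$selected_theta, digits = 6),
           if (run$selection$degenerate) " (degenerate plateau)" else ""),
    paste0("candidates: ", nrow(seg$candidates),
           " (isolated: ", sum(seg$candidates$isolated), ")"),
    paste0("timings [s]: ",
           paste(names(run$timings),
                 format(run$timings, digits = 3), sep = "=",
                 collapse = " "))
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(run)
}

label_tiles_table <- function(seg) {
  lt <- seg$label_tiles
  tibble::tibble(
    tile_row = rep(seq_len(nrow(lt)), times = ncol(lt)),
    tile_col = rep(seq_len(ncol(lt)), each = nrow(lt)),
    label = as.vector(lt)
  )
}

feature_table <- function(fm) {
  grid <- fm$grid
  role <- if (!is.null(grid)) {
    grid$role[cbind(fm$positions[, 1L], fm$positions[, 2L])]
  } else rep("internal", nrow(fm$positions))
  dplyr::bind_cols(
    tibble::tibble(tile_row = fm$positions[, 1L],
                   tile_col = fm$positions[, 2L],
                   role = role),
    tibble::as_tibble(fm$features)
  )
}

#' Write a phantom fixture set to disk
#'
#' Generates the canonical [fixture_suite()] and writes each fixture's image
#' (16-bit TIFF), per-ROI 8-bit mask PNGs, and a YAML descriptor recording
#' the lesion list and the seed.
#'
#' @param out_dir output directory.
#' @param seed base seed.
#' @param width,height fixture size in pixels.
#' @return invisibly, the fixture list.
#' @export
run_phantom <- function(out_dir, seed = 1L, width = 384L, height = 384L) {
  suite <- fixture_suite(seed = seed, width = width, height = height)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(suite)) {
    fx <- suite[[nm]]
    write_gray_image(fx$image, file.path(out_dir, paste0(nm, ".tiff")))
    for (r in seq_along(fx$truth$rois)) {
      png::writePNG(fx$truth$rois[[r]] * 1,
                    file.path(out_dir, paste0(nm, "_roi", r, ".png")))
    }
    png::writePNG(fx$truth$breast * 1,
                  file.path(out_dir, paste0(nm, "_breast.png")))
    desc <- fx$descriptor$spec
    yaml::write_yaml(
      list(name = nm, seed = desc$seed, width = desc$width,
           height = desc$height, pixel_pitch = desc$pixel_pitch,
           lesions = desc$lesions),
      file.path(out_dir, paste0(nm, ".yaml")))
  }
  invisible(suite)
}
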