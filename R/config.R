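#' Pipeline run configuration
#'
#' All tunable parameters of the segmentation pipeline in one validated
#' object. `K` (nearest neighbors for the coupling scale) is the method's
#' only free parameter; everything else is an implementation choice with a
#' documented default.
#'
#' @param tile_size tile side in pixels (default 20).
#' @param K nearest neighbors for the coupling scale (default 10).
#' @param theta_min,theta_max,theta_step threshold grid (default 0 to 0.69
#'   step 0.01).
#' @param t_transient,t_meas map iterations discarded / recorded
#'   (defaults 1000 / 2000).
#' @param seed RNG seed for the map initial state (default 1).
#' @param variance_retained KL variance fraction kept (default 0.95).
#' @param sparsity_cutoff coupling cutoff in units of `a` (default 5).
#' @param connectivity spatial connectivity, 4 or 8 (default 8).
#' @param max_tiles isolation criterion: maximum cluster size (default 4).
#' @param min_border_mm isolation criterion: minimum distance from the
#'   border strip in mm (default 6).
#' @param background_quantile background threshold position within the
#'   tile-mean intensity range (default 0.05).
#' @param border_width border strip width in tiles (default 1).
#' @param pixel_pitch mm per pixel (default 0.1).
#' @param min_plateau minimum stability-plateau width (default 0.05).
#' @param mode `"cmc"` (chaotic-map clustering) or `"euclidean"` (distance
#'   baseline).
#' @return a validated `cmc_config` list.
#' @export
cmc_config <- function(tile_size = 20L, K = 10L, theta_min = 0,
                       theta_max = 0.69, theta_step = 0.01,
                       t_transient = 1000L, t_meas = 2000L, seed = 1L,
                       variance_retained = 0.95, sparsity_cutoff = 5,
                       connectivity = 8L, max_tiles = 4L, min_border_mm = 6,
                       background_quantile = 0.05, border_width = 1L,
                       pixel_pitch = 0.1, min_plateau = 0.05,
                       mode = c("cmc", "euclidean")) {
  cfg <- list(
    tile_size = as.integer(tile_size), K = as.integer(K),
    theta_min = theta_min, theta_max = theta_max, theta_step = theta_step,
    t_transient = as.integer(t_transient), t_meas = as.integer(t_meas),
    seed = as.integer(seed), variance_retained = variance_retained,
    sparsity_cutoff = sparsity_cutoff,
    connectivity = as.integer(connectivity),
    max_tiles = as.integer(max_tiles), min_border_mm = min_border_mm,
    background_quantile = background_quantile,
    border_width = as.integer(border_width), pixel_pitch = pixel_pitch,
    min_plateau = min_plateau, mode = match.arg(mode)
  )
  validate_config(cfg)
  structure(cfg, class = "cmc_config")
}

config_field_names <- function() {
  setdiff(names(formals(cmc_config)), character(0))
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("Invalid config: ", msg)
  chk(cfg$tile_size >= 2L, "tile_size must be >= 2")
  chk(cfg$K >= 1L, "K must be >= 1")
  chk(cfg$theta_min >= 0 && cfg$theta_max <= log(2) + 1e-9 &&
        cfg$theta_min < cfg$theta_max, "theta range must lie in [0, ln 2]")
  chk(cfg$theta_step > 0, "theta_step must be > 0")
  chk(cfg$t_transient >= 0L, "t_transient must be >= 0")
  chk(cfg$t_meas >= 1L, "t_meas must be >= 1")
  chk(cfg$variance_retained > 0 && cfg$variance_retained <= 1,
      "variance_retained must lie in (0, 1]")
  chk(cfg$sparsity_cutoff > 0, "sparsity_cutoff must be > 0")
  chk(cfg$connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
  chk(cfg$max_tiles >= 1L, "max_tiles must be >= 1")
  chk(cfg$min_border_mm >= 0, "min_border_mm must be >= 0")
  chk(cfg$background_quantile > 0 && cfg$background_quantile < 1,
      "background_quantile must lie in (0, 1)")
  chk(cfg$border_width >= 0L, "border_width must be >= 0")
  chk(cfg$pixel_pitch > 0, "pixel_pitch must be > 0")
  chk(cfg$min_plateau >= 0, "min_plateau must be >= 0")
  chk(cfg$mode %in% c("cmc", "euclidean"), "mode must be cmc or euclidean")
  invisible(cfg)
}

#' Save / load a run configuration
#'
#' YAML round-trip: `load_config(save_config(cfg, path))` reproduces the
#' configuration exactly. Unknown keys in a loaded file are rejected.
#'
#' @param cfg a `cmc_config`.
#' @param path file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns a
#'   validated `cmc_config`.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cmc_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- config_field_names()
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("Unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(cmc_config, raw)
}

#' @export
print.cmc_config <- function(x, ...) {
  cat("<cmc_config> mode:", x$mode, "| tile_size:", x$tile_size,
      "| K:", x$K, "| seed:", x$seed, "\n")
  invisible(x)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}
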