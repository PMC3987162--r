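#' K-nearest-neighbor local scale
#'
#' Estimates the coupling bandwidth `a` as the average, over all points, of
#' the mean Euclidean distance from each point to its `K` nearest neighbors
#' (self excluded). `K` is the only free parameter of the clustering method.
#'
#' @param fm a `feature_matrix` (standardized or KL stage) or a plain numeric
#'   matrix of points (rows = points).
#' @param K number of nearest neighbors, `1 <= K < N`.
#' @return the scalar scale `a`.
#' @export
knn_scale <- function(fm, K = 10L) {
  x <- feature_points(fm)
  n <- nrow(x)
  K <- as.integer(K)
  if (K < 1L || K >= n) {
    stop("`K` must satisfy 1 <= K < N (N = ", n, ").")
  }
  d <- as.matrix(stats::dist(x))
  per_point <- vapply(seq_len(n), function(i) {
    mean(sort(d[i, -i], partial = K)[seq_len(K)])
  }, numeric(1))
  a <- mean(per_point)
  if (a <= 0) stop("Degenerate scale: all points coincide (a = 0).")
  a
}

feature_points <- function(fm) {
  if (inherits(fm, "feature_matrix")) fm$features else as.matrix(fm)
}

#' Gaussian coupling matrix between feature-space points
#'
#' Builds the pairwise coupling `J_ij = exp(-||r_i - r_j||^2 / (2 a^2))` and
#' the per-map normalizers `C_i = sum_{j != i} J_ij`. Pairs farther apart than
#' `sparsity_cutoff * a` are set to exactly zero; at the default cutoff of 5
#' scale lengths the truncated weights are below `exp(-12.5) < 4e-6`, so the
#' truncation is numerically negligible while keeping large systems sparse.
#' Use `sparsity_cutoff = Inf` for the exact dense coupling.
#'
#' A point with no nonzero coupling (isolated under the cutoff) has an
#' undefined update; by default this raises an error suggesting a larger
#' cutoff. With `on_isolated = "free"` such maps instead evolve under the
#' bare logistic map: an uncoupled chaotic map never synchronizes with
#' anything, so downstream it falls out as a singleton cluster — the natural
#' `C_i -> 0` limit, used by the full pipeline so outliers become findings
#' rather than crashes.
#'
#' @param fm feature matrix or plain point matrix.
#' @param a coupling scale, `a > 0` (see [knn_scale()]).
#' @param sparsity_cutoff distance cutoff in units of `a` (default 5).
#' @param on_isolated `"error"` (default) or `"free"`.
#' @return a `coupling_system`: list with `J` (N x N, zero diagonal), `C`,
#'   `a`, `sparsity_cutoff`, and `free` (logical vector of uncoupled maps,
#'   all FALSE unless `on_isolated = "free"` fired).
#' @export
build_coupling <- function(fm, a, sparsity_cutoff = 5,
                           on_isolated = c("error", "free")) {
  on_isolated <- match.arg(on_isolated)
  x <- feature_points(fm)
  if (!is.numeric(a) || length(a) != 1L || a <= 0) stop("`a` must be > 0.")
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- NULL
  J <- exp(-d^2 / (2 * a^2))
  if (is.finite(sparsity_cutoff)) J[d > sparsity_cutoff * a] <- 0
  diag(J) <- 0
  C <- rowSums(J)
  free <- C == 0
  if (any(free) && on_isolated == "error") {
    stop("Isolated point(s) ", paste(which(free), collapse = ", "),
         " have zero total coupling; raise `sparsity_cutoff` ",
         "or use on_isolated = \"free\".")
  }
  structure(
    list(J = J, C = C, a = a, sparsity_cutoff = sparsity_cutoff, free = free),
    class = "coupling_system"
  )
}

#' @export
print.coupling_system <- function(x, ...) {
  cat("<coupling_system> N = ", length(x$C), ", a = ",
      format(x$a, digits = 4), ", cutoff = ", x$sparsity_cutoff,
      " a, free maps: ", sum(x$free), "\n", sep = "")
  invisible(x)
}
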