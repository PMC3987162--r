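#' The logistic map driving the chaotic dynamics
#'
#' `f(x) = 1 - 2 x^2`, chaotic on `[-1, 1]`.
#'
#' @param x numeric vector in `[-1, 1]`.
#' @return `f(x)`, again in `[-1, 1]`.
#' @export
logistic_map <- function(x) 1 - 2 * x^2

#' Evolve the coupled chaotic map system and record sign bits
#'
#' Each map `x_i` starts uniformly at random in `[-1, 1]` (seeded) and is
#' updated synchronously by `x_i(t+1) = sum_{j != i} J_ij f(x_j(t)) / C_i`
#' with `f(x) = 1 - 2 x^2`. Because the update is a convex combination of
#' values of `f`, every trajectory stays in `[-1, 1]` forever. Maps marked
#' free (zero total coupling) evolve as `x <- f(x)`.
#'
#' The maps are chaotic, so there is no stationary state to converge to;
#' instead, after a transient of `t_transient` steps, the sign bits
#' `S_i(t) = 1` if `x_i(t) > 0` else `0` are recorded for `t_meas` further
#' steps. Synchronized maps produce identical bit sequences.
#'
#' @param cs a `coupling_system` from [build_coupling()].
#' @param seed integer RNG seed for the initial state (Mersenne-Twister,
#'   locally scoped: the caller's RNG state is untouched).
#' @param t_transient discarded burn-in iterations (default 1000).
#' @param t_meas recorded iterations (default 2000).
#' @param x0 optional explicit initial state (overrides the seeded draw).
#' @return a `sync_result`: list with `signs` (N x t_meas 0/1 matrix), `mi`
#'   (NULL until [mutual_information()] fills it), `t_transient`, `t_meas`,
#'   `seed`.
#' @export
iterate_maps <- function(cs, seed = 1L, t_transient = 1000L, t_meas = 2000L,
                         x0 = NULL) {
  stopifnot(inherits(cs, "coupling_system"))
  t_transient <- as.integer(t_transient)
  t_meas <- as.integer(t_meas)
  if (t_transient < 0L) stop("`t_transient` must be >= 0.")
  if (t_meas < 1L) stop("`t_meas` must be >= 1.")
  n <- length(cs$C)
  if (is.null(x0)) {
    x0 <- with_local_seed(seed, stats::runif(n, -1, 1))
  } else {
    stopifnot(length(x0) == n, all(abs(x0) <= 1))
  }
  # row-normalized update weights; free rows bypass the matrix product
  W <- cs$J / ifelse(cs$C > 0, cs$C, 1)
  free <- cs$free
  x <- x0
  signs <- matrix(0L, n, t_meas)
  total <- t_transient + t_meas
  for (t in seq_len(total)) {
    fx <- 1 - 2 * x^2
    x <- as.vector(W %*% fx)
    if (any(free)) x[free] <- fx[free]
    if (t > t_transient) signs[, t - t_transient] <- (x > 0)
  }
  structure(
    list(signs = signs, mi = NULL, t_transient = t_transient,
         t_meas = t_meas, seed = seed),
    class = "sync_result"
  )
}

# evaluate expr under a temporary Mersenne-Twister seed, restoring the
# caller's RNG state afterwards
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Pairwise mutual information of the sign-bit sequences
#'
#' Plug-in (empirical, natural-log) mutual information
#' `I_ij = H_i + H_j - H_ij` between the equal-time binary sign sequences of
#' every pair of maps, where `H_i` is the entropy of map i's bit distribution
#' and `H_ij` the joint entropy (0 log 0 := 0 throughout). `I_ij` is 0 for
#' independent maps and `ln 2` for exactly synchronized ones; tiny negative
#' values from finite-sample rounding are clipped to 0 and values are capped
#' at `ln 2`. The diagonal holds `I_ii = H_i`.
#'
#' @param sr a `sync_result` from [iterate_maps()].
#' @return the `sync_result` with its symmetric `mi` matrix filled.
#' @export
mutual_information <- function(sr) {
  stopifnot(inherits(sr, "sync_result"))
  s <- sr$signs
  n <- nrow(s)
  t_meas <- ncol(s)
  n1 <- rowSums(s)
  p1 <- n1 / t_meas
  h <- binary_entropy(p1)
  n11 <- tcrossprod(s)
  n10 <- matrix(n1, n, n) - n11          # i = 1, j = 0
  n01 <- t(n10)                          # i = 0, j = 1
  n00 <- t_meas - n11 - n10 - n01
  hij <- plogp(n11 / t_meas) + plogp(n10 / t_meas) +
         plogp(n01 / t_meas) + plogp(n00 / t_meas)
  mi <- outer(h, h, "+") - hij
  mi <- pmin(pmax(mi, 0), log(2))
  diag(mi) <- h
  sr$mi <- mi
  sr
}

plogp <- function(p) {
  out <- -p * log(p)
  out[p <= 0] <- 0
  out
}

binary_entropy <- function(p) plogp(p) + plogp(1 - p)

#' @export
print.sync_result <- function(x, ...) {
  cat("<sync_result> N = ", nrow(x$signs), ", t_meas = ", x$t_meas,
      " (transient ", x$t_transient, "), seed = ", x$seed,
      if (is.null(x$mi)) ", mi: not computed" else ", mi: filled",
      "\n", sep = "")
  invisible(x)
}
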