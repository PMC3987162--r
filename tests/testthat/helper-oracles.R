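# Independent brute-force oracles used to cross-check the production code.
# These deliberately avoid igraph and the package's own component machinery.

# union-find connected components of a logical adjacency matrix;
# labels canonicalized by smallest contained index
oracle_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (isTRUE(adj[i, j])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# plug-in mutual information of two bit vectors, written out longhand
oracle_mi <- function(si, sj) {
  t_meas <- length(si)
  ent <- function(p) sum(ifelse(p > 0, -p * log(p), 0))
  hi <- ent(table(factor(si, levels = 0:1)) / t_meas)
  hj <- ent(table(factor(sj, levels = 0:1)) / t_meas)
  hij <- ent(table(factor(si, levels = 0:1),
                   factor(sj, levels = 0:1)) / t_meas)
  hi + hj - hij
}

# two tight, well-separated point groups (between/within spread ratio >= 10)
two_group_features <- function(n_per = 30L, dims = 3L, ratio = 20,
                               seed = 1L) {
  set.seed(seed)
  offset <- ratio / sqrt(dims)
  x <- rbind(matrix(stats::rnorm(n_per * dims), n_per),
             matrix(stats::rnorm(n_per * dims), n_per) + offset)
  list(x = x, labels = rep(1:2, each = n_per))
}

# small synthetic mi matrix with prescribed block structure
block_mi <- function(sizes, within = log(2), between = 0) {
  n <- sum(sizes)
  grp <- rep(seq_along(sizes), sizes)
  mi <- matrix(between, n, n)
  for (g in seq_along(sizes)) mi[grp == g, grp == g] <- within
  diag(mi) <- log(2)
  mi
}

# same partition up to label renaming?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(as.integer(factor(a, levels = unique(a))) ==
          as.integer(factor(b, levels = unique(b))))
}
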