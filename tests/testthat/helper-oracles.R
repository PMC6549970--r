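# Independent oracles used across tests.

# exact optimal 1-D k-means by enumerating contiguous splits of the sorted
# values (an optimal 1-D k-partition is contiguous in sorted order)
oracle_kmeans_1d <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  if (k >= n) return(0)
  wss <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
  if (k == 1) return(wss(x))
  splits <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (c in seq_len(ncol(splits))) {
    bounds <- c(0, splits[, c], n)
    tot <- 0
    for (g in seq_len(k)) tot <- tot + wss(x[(bounds[g] + 1):bounds[g + 1]])
    if (tot < best) best <- tot
  }
  best
}

# exhaustive trimmed k-means on 1-D data: all discard sets of size m,
# exact k-means on the remainder
oracle_trimmed_kmeans_1d <- function(x, k, m) {
  n <- length(x)
  if (m == 0) return(list(objective = oracle_kmeans_1d(x, k)))
  sets <- utils::combn(n, m)
  best <- Inf; best_set <- NULL
  for (c in seq_len(ncol(sets))) {
    obj <- oracle_kmeans_1d(x[-sets[, c]], k)
    if (obj < best) { best <- obj; best_set <- sets[, c] }
  }
  list(objective = best, discard = best_set)
}

# direct 2-D binning on given edges (no smoothing/floor); counts matrix
oracle_hist2d <- function(x, y, x_edges, y_edges) {
  nx <- length(x_edges) - 1; ny <- length(y_edges) - 1
  h <- matrix(0, nx, ny)
  for (i in seq_along(x)) {
    ix <- min(max(findInterval(x[i], x_edges, all.inside = TRUE), 1), nx)
    iy <- min(max(findInterval(y[i], y_edges, all.inside = TRUE), 1), ny)
    h[ix, iy] <- h[ix, iy] + 1
  }
  h
}

# closed-form KL between two (product-form) 2-D Gaussians:
# sum of the per-axis 1-D Gaussian divergences
oracle_gauss_kl_1d <- function(mu1, s1, mu2, s2) {
  0.5 * ((s1^2 + (mu1 - mu2)^2) / s2^2 - 1 + log(s2^2 / s1^2))
}

# density_grid holding a discretized product Gaussian on given edges
# (floored like the estimator's contract requires, so far tails stay finite)
gaussian_grid <- function(x_edges, y_edges, mux, sx, muy, sy,
                          floor = 1e-300) {
  px <- diff(stats::pnorm(x_edges, mux, sx))
  py <- diff(stats::pnorm(y_edges, muy, sy))
  m <- outer(px, py) + floor
  m <- m / sum(m)
  structure(list(x_edges = x_edges, y_edges = y_edges, mass = m),
            class = "density_grid")
}

# arbitrary valid density grid from nonnegative weights
grid_from_mass <- function(m, x_edges = seq(0, 1, length.out = nrow(m) + 1),
                           y_edges = seq(0, 1, length.out = ncol(m) + 1)) {
  structure(list(x_edges = x_edges, y_edges = y_edges, mass = m / sum(m)),
            class = "density_grid")
}
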