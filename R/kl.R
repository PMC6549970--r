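#' Density-grid configuration
#'
#' Controls the 2-D histogram density estimator used for K-L comparison:
#' grid resolution, Gaussian smoothing (in bins), the regularization floor
#' added before renormalization (so the support is common and the
#' divergence finite), and the fractional padding of the pooled axis range.
#'
#' @param bins Integer vector `c(nx, ny)` (duration x parameter).
#' @param smooth_sigma Gaussian kernel s.d. in bins (0 = no smoothing).
#' @param floor Regularization mass added per cell before renormalizing.
#' @param pad Fractional padding of each axis range.
#' @return A list of class `density_grid_config`.
#' @export
density_grid_config <- function(bins = c(32, 32), smooth_sigma = 1,
                                floor = 1e-6, pad = 0.05) {
  stopifnot(length(bins) == 2, all(bins >= 1), smooth_sigma >= 0, floor > 0)
  structure(list(bins = as.integer(bins), smooth_sigma = smooth_sigma,
                 floor = floor, pad = pad),
            class = "density_grid_config")
}

# axis edges over the pooled range of the values, padded; zero range
# collapses to a single bin with a warning
.axis_edges <- function(values, nbins, pad) {
  rng <- range(values)
  if (diff(rng) <= 0) {
    warning("degenerate axis (zero range): using a single bin")
    return(c(rng[1] - 0.5, rng[1] + 0.5))
  }
  span <- diff(rng) * pad
  seq(rng[1] - span, rng[2] + span, length.out = nbins + 1)
}

#' Pooled grid edges for a comparison pair
#'
#' Edges span the occupied range of both repertoires for (duration,
#' parameter), so a template/target pair is always binned on a common grid.
#'
#' @param a,b [repertoire()] objects.
#' @param parameter One of [sap_parameters()].
#' @param cfg A [density_grid_config()].
#' @return List with `x_edges` (duration, ms) and `y_edges` (parameter).
#' @export
pooled_grid <- function(a, b, parameter, cfg = density_grid_config()) {
  stopifnot(parameter %in% sap_parameters())
  dur <- c(a$syllables$duration_ms, b$syllables$duration_ms)
  par <- c(a$syllables[[parameter]], b$syllables[[parameter]])
  list(x_edges = .axis_edges(dur, cfg$bins[1], cfg$pad),
       y_edges = .axis_edges(par, cfg$bins[2], cfg$pad))
}

# separable Gaussian smoothing of a matrix, truncated at 3 sigma, applied
# as banded convolution matrices (kernel renormalized; mass preserved up to
# edge truncation)
.smooth_mat <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  K <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- kern[o + r + 1]
  }
  K
}

.smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  Kx <- .smooth_mat(nrow(m), sigma)
  Ky <- .smooth_mat(ncol(m), sigma)
  Kx %*% m %*% t(Ky)
}

#' Estimate the 2-D (duration, parameter) density of a repertoire
#'
#' Histogram of syllable (duration, parameter) values on the supplied grid,
#' smoothed with a small Gaussian kernel, floored and renormalized to sum 1.
#'
#' @param r A [repertoire()] with >= 2 syllables.
#' @param parameter One of [sap_parameters()].
#' @param grid Edges from [pooled_grid()]; defaults to the repertoire's own
#'   range (comparisons must pass a common pooled grid).
#' @param cfg A [density_grid_config()].
#' @return An object of class `density_grid`: list with `x_edges`,
#'   `y_edges`, `mass` (matrix summing to 1, every cell > 0).
#' @export
estimate_density <- function(r, parameter, grid = NULL,
                             cfg = density_grid_config()) {
  stopifnot(inherits(r, "repertoire"), parameter %in% sap_parameters())
  if (nrow(r$syllables) < 2)
    stop("repertoire of ", r$bird_id, " has fewer than 2 syllables")
  if (is.null(grid)) grid <- pooled_grid(r, r, parameter, cfg)
  x <- r$syllables$duration_ms
  y <- r$syllables[[parameter]]
  nx <- length(grid$x_edges) - 1L
  ny <- length(grid$y_edges) - 1L
  ix <- pmin(pmax(findInterval(x, grid$x_edges, all.inside = TRUE), 1L), nx)
  iy <- pmin(pmax(findInterval(y, grid$y_edges, all.inside = TRUE), 1L), ny)
  h <- matrix(tabulate((iy - 1L) * nx + ix, nbins = nx * ny), nx, ny)
  h <- h / sum(h)
  h <- .smooth2d(h, cfg$smooth_sigma)
  h <- h + cfg$floor
  h <- h / sum(h)
  structure(list(x_edges = grid$x_edges, y_edges = grid$y_edges, mass = h),
            class = "density_grid")
}

#' Kullback-Leibler divergence between two density grids
#'
#' `sum(p * log(p / q))` in nats over the cells of a common grid. Zero for
#' identical grids, nonnegative always, asymmetric in general.
#'
#' @param template,target `density_grid` objects on identical grids
#'   (template plays p, target plays q).
#' @return Nonnegative scalar (nats).
#' @export
kl <- function(template, target) {
  stopifnot(inherits(template, "density_grid"), inherits(target, "density_grid"))
  if (!identical(dim(template$mass), dim(target$mass)) ||
      !isTRUE(all.equal(template$x_edges, target$x_edges)) ||
      !isTRUE(all.equal(template$y_edges, target$y_edges)))
    stop("density grids do not match; build both on a common pooled grid")
  p <- template$mass; q <- target$mass
  max(0, sum(p * log(p / q)))
}

#' All pairwise K-L divergences among a set of repertoires
#'
#' For each of the 13 summary parameters, computes the divergence for every
#' ordered (template, target) pair of distinct birds. For each unordered
#' pair the two repertoires are binned on a grid pooled over both, then both
#' directions evaluated. Birds with fewer than 2 syllables are excluded
#' with a warning.
#'
#' @param repertoires List of [repertoire()] objects (>= 2 usable).
#' @param parameters Parameters to compare (default all 13).
#' @param cfg A [density_grid_config()].
#' @return An object of class `kl_matrix_set`: list with `bird_ids`,
#'   `population_ids`, and `matrices` (named list of n x n matrices, rows =
#'   template, columns = target, diagonal `NA`).
#' @export
pairwise_kl_matrices <- function(repertoires, parameters = sap_parameters(),
                                 cfg = density_grid_config()) {
  usable <- vapply(repertoires, function(r) nrow(r$syllables) >= 2, logical(1))
  if (any(!usable)) {
    warning("excluding ", sum(!usable),
            " bird(s) with fewer than 2 syllables: ",
            paste(vapply(repertoires[!usable], `[[`, "", "bird_id"),
                  collapse = ", "))
    repertoires <- repertoires[usable]
  }
  n <- length(repertoires)
  if (n < 2) stop("need at least 2 repertoires with >= 2 syllables")
  ids <- vapply(repertoires, `[[`, "", "bird_id")
  if (anyDuplicated(ids)) stop("bird_ids must be unique")
  pops <- vapply(repertoires, `[[`, "", "population_id")
  mats <- lapply(parameters, function(p) {
    m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    m
  })
  names(mats) <- parameters
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      for (p in parameters) {
        grid <- pooled_grid(repertoires[[i]], repertoires[[j]], p, cfg)
        di <- estimate_density(repertoires[[i]], p, grid, cfg)
        dj <- estimate_density(repertoires[[j]], p, grid, cfg)
        mats[[p]][i, j] <- kl(di, dj)
        mats[[p]][j, i] <- kl(dj, di)
      }
    }
  }
  structure(list(bird_ids = ids, population_ids = pops, matrices = mats),
            class = "kl_matrix_set")
}

#' @export
print.kl_matrix_set <- function(x, ...) {
  n <- length(x$bird_ids)
  cat(sprintf("<kl_matrix_set: %d birds, %d parameters, %d ordered pairs each>\n",
              n, length(x$matrices), n * (n - 1)))
  invisible(x)
}

#' Long-format view of a K-L matrix set
#'
#' @param m A `kl_matrix_set`.
#' @return Data frame with `template_id`, `target_id`, `parameter`,
#'   `kl_nats` (one row per ordered pair per parameter).
#' @export
kl_long <- function(m) {
  stopifnot(inherits(m, "kl_matrix_set"))
  n <- length(m$bird_ids)
  pairs <- which(row(diag(n)) != col(diag(n)), arr.ind = TRUE)
  do.call(rbind, lapply(names(m$matrices), function(p) {
    data.frame(template_id = m$bird_ids[pairs[, 1]],
               target_id = m$bird_ids[pairs[, 2]],
               parameter = p,
               kl_nats = m$matrices[[p]][pairs],
               stringsAsFactors = FALSE)
  }))
}

#' Symmetrize a full K-L matrix set into half-matrix pair summaries
#'
#' For each unordered pair of birds, the per-parameter value is the
#' arithmetic mean of the two directed divergences.
#'
#' @param m A `kl_matrix_set`.
#' @return Data frame with `bird_a`, `bird_b` and one column per parameter;
#'   `n(n-1)/2` rows.
#' @export
symmetrize <- function(m) {
  stopifnot(inherits(m, "kl_matrix_set"))
  n <- length(m$bird_ids)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  out <- data.frame(bird_a = m$bird_ids[idx[, 1]],
                    bird_b = m$bird_ids[idx[, 2]],
                    stringsAsFactors = FALSE)
  for (p in names(m$matrices)) {
    mm <- m$matrices[[p]]
    out[[p]] <- (mm[idx] + mm[idx[, c(2, 1), drop = FALSE]]) / 2
  }
  out
}

#' Tutor-tutee repertoire divergences
#'
#' One averaged bidirectional K-L per (tutee, tutor) pair per parameter.
#' Tutees whose tutor is missing from `tutors` are skipped with a warning.
#'
#' @param tutees List of [repertoire()] objects.
#' @param tutors Named list of tutor [repertoire()] objects; `tutor_map`
#'   gives the tutor name for each tutee.
#' @param tutor_map Character vector, one tutor id per tutee (defaults to a
#'   single shared tutor when `tutors` has length 1).
#' @param parameters,cfg As in [pairwise_kl_matrices()].
#' @return Data frame with `tutee_id`, `tutor_id`, `population_id` and one
#'   averaged-K-L column per parameter.
#' @export
tutor_tutee_kl <- function(tutees, tutors, tutor_map = NULL,
                           parameters = sap_parameters(),
                           cfg = density_grid_config()) {
  if (inherits(tutors, "repertoire")) tutors <- list(tutors)
  if (is.null(names(tutors)))
    names(tutors) <- vapply(tutors, `[[`, "", "bird_id")
  if (is.null(tutor_map)) {
    if (length(tutors) != 1)
      stop("tutor_map required when there are multiple tutors")
    tutor_map <- rep(names(tutors), length(tutees))
  }
  stopifnot(length(tutor_map) == length(tutees))
  rows <- list()
  for (i in seq_along(tutees)) {
    tutor <- tutors[[tutor_map[i]]]
    if (is.null(tutor)) {
      warning("no tutor recording for tutee ",
              tutees[[i]]$bird_id, "; pair skipped")
      next
    }
    rec <- data.frame(tutee_id = tutees[[i]]$bird_id,
                      tutor_id = tutor$bird_id,
                      population_id = tutees[[i]]$population_id,
                      stringsAsFactors = FALSE)
    for (p in parameters) {
      grid <- pooled_grid(tutees[[i]], tutor, p, cfg)
      da <- estimate_density(tutees[[i]], p, grid, cfg)
      db <- estimate_density(tutor, p, grid, cfg)
      rec[[p]] <- (kl(da, db) + kl(db, da)) / 2
    }
    rows[[length(rows) + 1L]] <- rec
  }
  do.call(rbind, rows)
}
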