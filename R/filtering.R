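#' Repertoire container
#'
#' The retained syllables of one bird, tagged with its population. At least
#' 2 syllables are required downstream for density estimation; construction
#' permits fewer so that filtering can be applied first.
#'
#' @param syllables Data frame of syllable records (must contain
#'   `duration_ms` and the [sap_parameters()] columns).
#' @param bird_id,population_id Identifiers.
#' @return An object of class `repertoire`.
#' @export
repertoire <- function(syllables, bird_id, population_id = NA_character_) {
  need <- c("duration_ms", sap_parameters())
  missing_cols <- setdiff(need, names(syllables))
  if (length(missing_cols) > 0)
    stop("syllable table lacks columns: ", paste(missing_cols, collapse = ", "))
  structure(list(bird_id = as.character(bird_id),
                 population_id = as.character(population_id),
                 syllables = syllables),
            class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire: bird %s, population %s, %d syllables>\n",
              x$bird_id, x$population_id, nrow(x$syllables)))
  invisible(x)
}

#' Drop syllables shorter than a duration floor
#'
#' Removes cage-noise clicks: syllables strictly shorter than `min_ms`
#' (default 20 ms) are discarded; a syllable of exactly `min_ms` is kept.
#' Order is preserved.
#'
#' @param syllables Data frame with a `duration_ms` column, or a
#'   [repertoire()].
#' @param min_ms Duration floor in ms (> 0).
#' @return Object of the same type with only the retained records.
#' @export
drop_short_syllables <- function(syllables, min_ms = 20) {
  stopifnot(min_ms > 0)
  if (inherits(syllables, "repertoire")) {
    syllables$syllables <-
      drop_short_syllables(syllables$syllables, min_ms)
    return(syllables)
  }
  syllables[syllables$duration_ms >= min_ms, , drop = FALSE]
}

#' Trimmed-clustering configuration
#'
#' @param alpha Trimming fraction in \[0, 0.5): exactly `floor(alpha * n)`
#'   records are discarded as outliers.
#' @param k Number of clusters (>= 1; default 2, separating the main
#'   duration mode from residual noise).
#' @param features Character vector of columns to cluster on (standardized);
#'   default duration only.
#' @param restr_factor Upper bound (>= 1) on the ratio of cluster variances,
#'   applied only when `scale_clusters = TRUE`.
#' @param scale_clusters Use cluster-specific variances (scaled distances)
#'   instead of the plain squared-distance objective.
#' @param n_starts Number of seeded multistart initializations.
#' @return A list of class `trim_config`.
#' @export
trim_config <- function(alpha = 0.03, k = 2, features = "duration_ms",
                        restr_factor = 50, scale_clusters = FALSE,
                        n_starts = 20) {
  stopifnot(alpha >= 0, alpha < 0.5, k >= 1, restr_factor >= 1, n_starts >= 1)
  structure(list(alpha = alpha, k = as.integer(k), features = features,
                 restr_factor = restr_factor, scale_clusters = scale_clusters,
                 n_starts = as.integer(n_starts)),
            class = "trim_config")
}

# One run of concentration steps from given initial centers.
# X: n x d matrix; m: number of points to trim.
.concentrate <- function(X, centers, k, m, restr_factor, scale_clusters,
                         max_iter = 50) {
  n <- nrow(X)
  sig <- rep(1, k)
  for (it in seq_len(max_iter)) {
    d2 <- vapply(seq_len(k), function(j) {
      rowSums(sweep(X, 2, centers[j, ], `-`)^2) / sig[j] +
        if (scale_clusters) ncol(X) * log(sig[j]) else 0
    }, numeric(n))
    d2 <- matrix(d2, nrow = n)
    assign <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_len(n), assign)]
    keep <- rep(TRUE, n)
    if (m > 0) keep[order(dmin, decreasing = TRUE)[seq_len(m)]] <- FALSE
    new_centers <- centers
    for (j in seq_len(k)) {
      sel <- keep & assign == j
      if (any(sel)) new_centers[j, ] <- colMeans(X[sel, , drop = FALSE])
    }
    if (scale_clusters) {
      v <- vapply(seq_len(k), function(j) {
        sel <- keep & assign == j
        if (sum(sel) > 1)
          mean(rowSums(sweep(X[sel, , drop = FALSE], 2,
                             new_centers[j, ], `-`)^2))
        else 1e-8
      }, numeric(1))
      v <- pmax(v, 1e-8)
      # clamp the variance ratio to the restriction factor
      vmin <- max(v) / restr_factor
      sig <- pmax(v, vmin)
    }
    if (max(abs(new_centers - centers)) < 1e-10) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  d2p <- vapply(seq_len(k), function(j)
    rowSums(sweep(X, 2, centers[j, ], `-`)^2), numeric(n))
  d2p <- matrix(d2p, nrow = n)
  assign <- max.col(-d2p, ties.method = "first")
  dmin <- d2p[cbind(seq_len(n), assign)]
  keep <- rep(TRUE, n)
  if (m > 0) keep[order(dmin, decreasing = TRUE)[seq_len(m)]] <- FALSE
  list(centers = centers, assign = assign, keep = keep,
       objective = sum(dmin[keep]))
}

#' Trimmed k-means
#'
#' Jointly chooses `floor(alpha * n)` points to discard and a k-partition of
#' the rest minimizing the total within-cluster squared distance
#' (concentration steps with seeded multistart). Deterministic given `seed`.
#'
#' @param x Numeric vector or matrix (rows = observations).
#' @param k Number of clusters.
#' @param alpha Trimming fraction in \[0, 0.5).
#' @param n_starts Multistart count.
#' @param seed Integer seed for the initializations.
#' @param restr_factor,scale_clusters See [trim_config()].
#' @return List with `cluster` (labels, `NA` for trimmed points), `keep`
#'   (logical), `centers`, `objective`.
#' @export
trimmed_kmeans <- function(x, k = 2, alpha = 0.03, n_starts = 20, seed = 1,
                           restr_factor = 50, scale_clusters = FALSE) {
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  n <- nrow(X)
  m <- floor(alpha * n)
  if (n < k + m + 1)
    stop("too few observations (", n, ") for k = ", k, ", alpha = ", alpha)
  best <- NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  # deterministic quantile-based start plus random restarts
  inits <- c(list(matrix(apply(X, 2, stats::quantile,
                               probs = seq(0.1, 0.9, length.out = k)),
                         nrow = k)),
             lapply(seq_len(n_starts), function(i)
               X[sample.int(n, k), , drop = FALSE]))
  for (centers in inits) {
    fit <- .concentrate(X, matrix(centers, nrow = k), k, m,
                        restr_factor, scale_clusters)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  cluster <- ifelse(best$keep, best$assign, NA_integer_)
  list(cluster = cluster, keep = best$keep, centers = best$centers,
       objective = best$objective)
}

#' Robust noise trimming of a syllable table
#'
#' Standardizes the configured feature columns (duration by default) and
#' runs [trimmed_kmeans()], discarding exactly `floor(alpha * n)` syllables
#' as residual noise. If the table is too small for the configuration the
#' filter is skipped with a warning and everything is kept.
#'
#' @param syllables Data frame of syllable records or a [repertoire()].
#' @param cfg A [trim_config()].
#' @param seed Integer seed.
#' @return List with `kept`, `discarded` (data frames partitioning the
#'   input) and `cluster` (labels aligned to the input rows, `NA` =
#'   trimmed). For a `repertoire` input, `kept` is a `repertoire`.
#' @export
trimmed_cluster_filter <- function(syllables, cfg = trim_config(), seed = 1) {
  if (inherits(syllables, "repertoire")) {
    res <- trimmed_cluster_filter(syllables$syllables, cfg, seed)
    res$kept <- repertoire(res$kept, syllables$bird_id,
                           syllables$population_id)
    return(res)
  }
  stopifnot(inherits(cfg, "trim_config"))
  n <- nrow(syllables)
  m <- floor(cfg$alpha * n)
  if (n < cfg$k + m + 1) {
    warning("too few syllables (", n, ") for trimmed clustering; all kept")
    return(list(kept = syllables,
                discarded = syllables[0, , drop = FALSE],
                cluster = rep(1L, n)))
  }
  X <- as.matrix(syllables[, cfg$features, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  Xs <- scale(X, center = TRUE, scale = sds)
  fit <- trimmed_kmeans(Xs, k = cfg$k, alpha = cfg$alpha,
                        n_starts = cfg$n_starts, seed = seed,
                        restr_factor = cfg$restr_factor,
                        scale_clusters = cfg$scale_clusters)
  list(kept = syllables[fit$keep, , drop = FALSE],
       discarded = syllables[!fit$keep, , drop = FALSE],
       cluster = fit$cluster)
}
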