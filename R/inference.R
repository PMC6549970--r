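#' Build the log-transformed analysis table from K-L matrices
#'
#' Stacks per-population full (ordered-pair) K-L matrices into one table,
#' taking the natural log of `max(value, floor)` for each parameter. Only
#' pairs whose template and target share a population are included, so the
#' row count is the sum of `n_i * (n_i - 1)` over populations.
#'
#' @param matrices A `kl_matrix_set` or list of them (one per population).
#' @param floor Values below this are floored before the log (> 0).
#' @return An `analysis_table` data frame: `template_id`, `target_id`,
#'   `population_id`, one log-K-L column per parameter. The number of
#'   floored cells is recorded in attribute `n_floored` (and messaged when
#'   positive).
#' @export
build_analysis_table <- function(matrices, floor = 1e-8) {
  stopifnot(floor > 0)
  if (inherits(matrices, "kl_matrix_set")) matrices <- list(matrices)
  n_floored <- 0L
  rows <- lapply(matrices, function(m) {
    stopifnot(inherits(m, "kl_matrix_set"))
    n <- length(m$bird_ids)
    idx <- which(row(diag(n)) != col(diag(n)), arr.ind = TRUE)
    same_pop <- m$population_ids[idx[, 1]] == m$population_ids[idx[, 2]]
    idx <- idx[same_pop, , drop = FALSE]
    out <- data.frame(template_id = m$bird_ids[idx[, 1]],
                      target_id = m$bird_ids[idx[, 2]],
                      population_id = m$population_ids[idx[, 1]],
                      stringsAsFactors = FALSE)
    for (p in names(m$matrices)) {
      v <- m$matrices[[p]][idx]
      n_floored <<- n_floored + sum(v < floor)
      out[[p]] <- log(pmax(v, floor))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (n_floored > 0)
    message(n_floored, " K-L cells below the floor of ", floor,
            " were floored before the log transform")
  structure(out, n_floored = n_floored,
            class = c("analysis_table", "data.frame"))
}

#' Principal components of the log K-L parameters
#'
#' Eigendecomposition (via [stats::prcomp()]) of the centred log-K-L
#' columns. The first component, conventionally a shared "overall
#' divergence" axis on which all parameters load with the same sign, is
#' appended to the table as `PC1`. The sign is fixed so PC1 loadings sum
#' positive (larger PC1 = larger overall divergence). Constant columns are
#' excluded with a warning.
#'
#' @param table An `analysis_table` (or data frame with the parameter
#'   columns).
#' @param scale. Scale columns to unit variance before the decomposition.
#' @return An object of class `kl_pca`: list with `loadings` (columns =
#'   components, unit norm), `proportions` (variance shares, sum 1),
#'   `scores`, `table` (input with `PC1` appended), `dropped` (constant
#'   columns removed).
#' @export
pca_pc1 <- function(table, scale. = FALSE) {
  params <- intersect(sap_parameters(), names(table))
  if (length(params) < 2) stop("need at least 2 parameter columns")
  X <- as.matrix(table[, params, drop = FALSE])
  if (nrow(X) < 2) stop("need at least 2 rows")
  sds <- apply(X, 2, stats::sd)
  dropped <- params[sds == 0]
  if (length(dropped) > 0) {
    warning("excluding constant column(s): ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  if (sum(pc$rotation[, 1]) < 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  proportions <- pc$sdev^2 / sum(pc$sdev^2)
  table$PC1 <- pc$x[, 1]
  structure(list(loadings = pc$rotation, proportions = proportions,
                 scores = pc$x, table = table, dropped = dropped),
            class = "kl_pca")
}

#' @export
print.kl_pca <- function(x, ...) {
  cat(sprintf("<kl_pca: %d components; PC1 explains %.1f%% of the variance>\n",
              length(x$proportions), 100 * x$proportions[1]))
  invisible(x)
}

#' Fit the population song-variability mixed model
#'
#' Fits `PC1 ~ <fixed> + (1 | template_id) + (1 | target_id)` by penalized
#' restricted maximum likelihood: a weak log-barrier on the random-effect
#' scale parameters keeps the template, target and residual variances
#' strictly positive (no singular fits), mirroring a weak prior over the
#' random effects. Bird identifiers realize the nesting within population
#' (each bird belongs to exactly one population). A parallel penalized ML
#' fit is stored for likelihood-ratio comparisons. Population means and
#' Wald confidence intervals come from the fixed-effect estimates and their
#' covariance (cell-means parameterization).
#'
#' @param table Data frame with `PC1`, `template_id`, `target_id`,
#'   `population_id` (e.g. the `table` element of [pca_pc1()]).
#' @param fixed Right-hand side of the fixed-effects formula (default
#'   `~ population_id`). Use `~ 1` for the null model.
#' @param response Response column name (default `"PC1"`).
#' @param conf_level Confidence level for the population means.
#' @param barrier_weight Weight of the log-barrier penalty (0 disables it,
#'   allowing variances to hit zero).
#' @param ci Compute population means and confidence intervals (requires
#'   the REML and cell-means fits). Set `FALSE` when only the ML
#'   log-likelihood is needed, e.g. inside likelihood-ratio simulations;
#'   variance components are then taken from the ML fit.
#' @return An object of class `variability_fit`; see
#'   [print.variability_fit()], [coef.variability_fit()],
#'   [predict.variability_fit()], [likelihood_ratio_test()].
#' @export
fit_variability <- function(table, fixed = ~ population_id,
                            response = "PC1", conf_level = 0.95,
                            barrier_weight = 1e-2, ci = TRUE) {
  need <- c(response, "template_id", "target_id", "population_id")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0)
    stop("table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (length(unique(table$population_id)) < 2 &&
      "population_id" %in% all.vars(fixed))
    stop("need at least 2 populations for a population fixed effect")
  dat <- as.data.frame(table)
  dat$population_id <- factor(dat$population_id)
  rhs <- paste(deparse(fixed[[length(fixed)]]), collapse = " ")
  full <- stats::as.formula(paste(
    response, "~", rhs, "+ (1 | template_id) + (1 | target_id)"))
  ml <- fit_penalized_lmm(full, dat, REML = FALSE,
                          barrier_weight = barrier_weight)
  reml <- if (ci) fit_penalized_lmm(full, dat, REML = TRUE,
                                    barrier_weight = barrier_weight) else ml
  vc <- as.data.frame(lme4::VarCorr(reml$mod))
  variances <- stats::setNames(vc$vcov, vc$grp)

  means <- NULL
  if (ci && "population_id" %in% all.vars(fixed)) {
    cm_formula <- stats::as.formula(paste(
      response, "~ 0 + population_id + (1 | template_id) + (1 | target_id)"))
    cm <- fit_penalized_lmm(cm_formula, dat, REML = TRUE,
                            barrier_weight = barrier_weight)
    est <- lme4::fixef(cm$mod)
    se <- sqrt(diag(as.matrix(stats::vcov(cm$mod))))
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    means <- data.frame(
      population = sub("^population_id", "", names(est)),
      mean = as.numeric(est),
      ci_low = as.numeric(est - zq * se),
      ci_high = as.numeric(est + zq * se),
      stringsAsFactors = FALSE)
    rownames(means) <- NULL
  }
  structure(list(means = means, variances = variances,
                 model = reml$mod, model_ml = ml$mod,
                 logLik_ml = ml$logLik, n_par = ml$n_par,
                 fixed = fixed, response = response,
                 conf_level = conf_level, table = dat,
                 call = match.call()),
            class = "variability_fit")
}

#' @describeIn fit_variability Print fitted population means and variance
#'   components.
#' @param x,object A `variability_fit`.
#' @param ... Unused.
#' @export
print.variability_fit <- function(x, ...) {
  cat("Population song-variability mixed model\n")
  cat("  fixed:", deparse(x$fixed), "  response:", x$response, "\n")
  if (!is.null(x$means)) {
    cat(sprintf("  population means (%d%% CI):\n", round(100 * x$conf_level)))
    for (i in seq_len(nrow(x$means)))
      cat(sprintf("    %-12s %8.4f  [%8.4f, %8.4f]\n",
                  x$means$population[i], x$means$mean[i],
                  x$means$ci_low[i], x$means$ci_high[i]))
  }
  cat("  variance components:\n")
  for (nm in names(x$variances))
    cat(sprintf("    %-12s %g\n", nm, x$variances[[nm]]))
  invisible(x)
}

#' @describeIn fit_variability Summary: means, variances, sample structure,
#'   ML log-likelihood.
#' @export
summary.variability_fit <- function(object, ...) {
  structure(list(fit = object,
                 n_rows = nrow(object$table),
                 n_templates = length(unique(object$table$template_id)),
                 n_populations = length(unique(object$table$population_id)),
                 logLik_ml = object$logLik_ml),
            class = "summary.variability_fit")
}

#' @export
print.summary.variability_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d pairwise rows, %d birds, %d populations; ML logLik %.3f\n",
              x$n_rows, x$n_templates, x$n_populations, x$logLik_ml))
  invisible(x)
}

#' @describeIn fit_variability Named vector of fitted population means.
#' @export
coef.variability_fit <- function(object, ...) {
  if (is.null(object$means)) return(lme4::fixef(object$model))
  stats::setNames(object$means$mean, object$means$population)
}

#' @describeIn fit_variability Predict population-level means for new data
#'   (`newdata` needs a `population_id` column; random effects set to 0).
#' @param newdata Data frame with `population_id`.
#' @export
predict.variability_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$means))
    stop("model has no population fixed effect")
  if (is.null(newdata))
    newdata <- data.frame(population_id = object$means$population)
  idx <- match(as.character(newdata$population_id), object$means$population)
  if (anyNA(idx)) stop("unknown population(s): ",
                       paste(unique(newdata$population_id[is.na(idx)]),
                             collapse = ", "))
  stats::setNames(object$means$mean[idx], newdata$population_id)
}

#' @describeIn fit_variability Residuals of the REML fit.
#' @export
residuals.variability_fit <- function(object, ...) {
  stats::residuals(object$model)
}

#' @describeIn fit_variability Plot fitted population means with CI bars.
#' @export
plot.variability_fit <- function(x, ...) {
  if (is.null(x$means)) stop("model has no population fixed effect")
  m <- x$means
  xs <- seq_len(nrow(m))
  graphics::plot(xs, m$mean, xaxt = "n", xlab = "population",
                 ylab = paste("fitted mean", x$response),
                 ylim = range(c(m$ci_low, m$ci_high)), pch = 19,
                 xlim = c(0.5, nrow(m) + 0.5), ...)
  graphics::axis(1, at = xs, labels = m$population)
  graphics::segments(xs, m$ci_low, xs, m$ci_high)
  invisible(x)
}

#' Likelihood-ratio test between two nested variability fits
#'
#' `chi^2 = 2 (logLik_full - logLik_reduced)` (floored at 0) with degrees of
#' freedom the difference in parameter counts, compared against the
#' upper-tail chi-square. Both log-likelihoods are the ML criteria stored by
#' [fit_variability()] (never REML).
#'
#' @param full,reduced `variability_fit` objects; `reduced` must be nested
#'   in `full` (fewer or equal parameters, same response and data size).
#' @return A `model_comparison`: list with `chi_square`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "variability_fit"),
            inherits(reduced, "variability_fit"))
  if (!identical(full$response, reduced$response) ||
      nrow(full$table) != nrow(reduced$table))
    stop("models were not fit to the same response/data")
  df <- full$n_par - reduced$n_par
  if (df < 0) stop("'reduced' has more parameters than 'full'; not nested")
  chisq <- max(0, 2 * (full$logLik_ml - reduced$logLik_ml))
  p <- if (chisq <= 0) 1 else stats::pchisq(chisq, max(df, 1),
                                            lower.tail = FALSE)
  structure(list(chi_square = chisq, df = df, p_value = p),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("LRT: chi-square = %.3f, d.f. = %d, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Population effect test (full vs. intercept-only model)
#'
#' Convenience wrapper: fits the variability model with and without the
#' population fixed effect and returns their likelihood-ratio comparison.
#'
#' @inheritParams fit_variability
#' @return A `model_comparison`.
#' @export
compare_populations <- function(table, response = "PC1",
                                barrier_weight = 1e-2) {
  full <- fit_variability(table, fixed = ~ population_id,
                          response = response,
                          barrier_weight = barrier_weight, ci = FALSE)
  null <- fit_variability(table, fixed = ~ 1, response = response,
                          barrier_weight = barrier_weight, ci = FALSE)
  likelihood_ratio_test(full, null)
}

#' One-way ANOVA on per-bird maximum syllable duration
#'
#' @param max_duration_ms Numeric vector, one value per bird (the bird's
#'   longest retained syllable, ms).
#' @param group Factor/character of group labels (>= 2 groups, >= 2 birds
#'   each).
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
anova_max_duration <- function(max_duration_ms, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("every group needs at least 2 birds")
  fit <- stats::aov(max_duration_ms ~ group)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], df_between = s[["Df"]][1],
       df_within = s[["Df"]][2], p = s[["Pr(>F)"]][1])
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum test with midrank ties. `U` counts pairs where a value of `a`
#' exceeds one of `b` (ties count one half). The normal approximation uses
#' the tie-corrected variance; for small samples (both sizes <= 8 by
#' default) the exact permutation p-value is obtained by enumerating all
#' group labelings.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact Force exact enumeration (`TRUE`/`FALSE`); default chooses
#'   exact when both samples have at most 8 values.
#' @return List with `U`, `z`, `p` (two-tailed, by the chosen method),
#'   `method`.
#' @export
mann_whitney_directed <- function(a, b, exact = NULL) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  if (is.null(exact)) exact <- n1 <= 8 && n2 <= 8
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  p_norm <- min(1, 2 * stats::pnorm(-abs(z)))
  if (exact) {
    combos <- utils::combn(N, n1)
    us <- apply(combos, 2, function(idx)
      sum(rk[idx]) - n1 * (n1 + 1) / 2)
    p_exact <- min(1, 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9)))
    list(U = U, z = z, p = p_exact, method = "exact enumeration")
  } else {
    list(U = U, z = z, p = p_norm, method = "normal approximation")
  }
}
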