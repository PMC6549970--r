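#' Read a pipeline manifest
#'
#' The manifest is a YAML file describing populations, birds and their
#' recordings, plus per-bird segmentation overrides, per-population trimming
#' settings and analysis options. Schema (all analysis/threshold keys
#' optional):
#'
#' ```yaml
#' seed: 1
#' simulate:                    # optional synthetic front end
#'   populations:
#'     - {id: A, n_birds: 3, syllables_per_bird: 12, dispersion: 1, seed: 11}
#'   render: {sample_rate: 22050, gap_ms: 50}
#'   noise: {click_rate: 0.3}
#' populations:                 # recordings (filled in by the simulate stage)
#'   - id: A
#'     alpha: 0.03
#'     k: 2
#'     birds:
#'       - id: A_b01
#'         wav: [recordings/A_b01.wav]
#'         thresholds: {amplitude_floor: -20, min_gap_ms: 5}
#' defaults:
#'   thresholds: {continuity_min: 0.9, min_gap_ms: 5}
#' analysis:
#'   grid_bins: [32, 32]
#'   kl_floor: 1.0e-8
#'   min_duration_ms: 20
#' ```
#'
#' @param path Path to the YAML manifest (or a list already in that shape).
#' @return The manifest list (validated: unique bird ids).
#' @export
read_manifest <- function(path) {
  m <- if (is.list(path)) path else yaml::read_yaml(path)
  ids <- unlist(lapply(m$populations, function(p)
    vapply(p$birds, `[[`, "", "id")))
  if (anyDuplicated(ids))
    stop("bird ids must be unique across the manifest: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m
}

.stage_dir <- function(out_dir, stage) {
  d <- file.path(out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

.need_stage <- function(out_dir, stage, file) {
  p <- file.path(out_dir, stage, file)
  if (!file.exists(p))
    stop("missing output of upstream stage '", stage, "' (", p,
         "); run it first")
  p
}

.log_line <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the song-variability pipeline
#'
#' Orchestrates the stages `simulate` (synthesize recordings from the
#' manifest's `simulate` block), `extract` (WAV to feature tracks to
#' syllable tables), `filter` (20 ms duration rule + trimmed clustering),
#' `kl` (within-population pairwise divergence matrices) and `analyze`
#' (log transform, PCA, mixed model, LRT). Each stage reads its
#' predecessor's CSV outputs from `out_dir`; rerunning with the same inputs
#' and seed reproduces identical outputs. A `run_metadata.json` records
#' configuration, seed and per-stage record counts.
#'
#' @param manifest Path to a manifest YAML or the list from
#'   [read_manifest()].
#' @param stages Character subset of
#'   `c("simulate", "extract", "filter", "kl", "analyze")`, executed in
#'   dependency order.
#' @param out_dir Output/run directory.
#' @param seed Integer; overrides the manifest seed.
#' @return Invisibly, a list with the run metadata and (if the analyze
#'   stage ran) the [fit_variability()] object.
#' @export
run_pipeline <- function(manifest,
                         stages = c("simulate", "extract", "filter", "kl",
                                    "analyze"),
                         out_dir = "songvar_run", seed = NULL) {
  all_stages <- c("simulate", "extract", "filter", "kl", "analyze")
  stages <- all_stages[all_stages %in% stages]
  if (length(stages) == 0) stop("no recognized stages requested")
  m <- read_manifest(manifest)
  if (!is.null(seed)) m$seed <- seed
  if (is.null(m$seed)) m$seed <- 1
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = m$seed, stages = stages, counts = list(),
               package_version = as.character(utils::packageVersion("songvar")))
  ana <- m$analysis
  grid_cfg <- density_grid_config(
    bins = if (!is.null(ana$grid_bins)) unlist(ana$grid_bins) else c(32, 32))
  min_dur <- if (!is.null(ana$min_duration_ms)) ana$min_duration_ms else 20
  kl_floor <- if (!is.null(ana$kl_floor)) ana$kl_floor else 1e-8
  fit <- NULL

  if ("simulate" %in% stages) {
    if (is.null(m$simulate)) stop("manifest has no 'simulate' block")
    d <- .stage_dir(out_dir, "simulate")
    rcfg <- do.call(render_config, as.list(m$simulate$render %||% list()))
    nspec <- if (!is.null(m$simulate$noise))
      do.call(noise_spec, as.list(m$simulate$noise)) else NULL
    pops <- list()
    truth <- list()
    for (ps in m$simulate$populations) {
      ps$seed <- (ps$seed %||% 0) + m$seed
      ps$population_id <- ps$population_id %||% ps$id
      spec <- do.call(population_spec, ps[names(ps) %in%
        names(formals(population_spec))])
      reps <- generate_population(spec)
      birds <- list()
      for (r in reps) {
        rend <- render_waveform(r, rcfg)
        if (!is.null(nspec))
          rend <- inject_noise(rend, nspec,
                               seed = m$seed + length(truth) + 1L)
        wav_path <- file.path(d, paste0(r$bird_id, ".wav"))
        write_wav(rend$waveform, wav_path)
        truth[[r$bird_id]] <- list(bird = r$bird_id,
                                   annotations = rend$annotations)
        birds[[length(birds) + 1L]] <-
          list(id = r$bird_id, wav = list(wav_path))
      }
      pops[[length(pops) + 1L]] <-
        list(id = spec$population_id, birds = birds,
             alpha = ps$alpha %||% 0.03, k = ps$k %||% 2)
      .log_line("simulate", spec$population_id, ": ", length(birds),
                " birds rendered")
    }
    m$populations <- pops
    jsonlite::write_json(lapply(truth, function(t)
      list(bird = t$bird, annotations = t$annotations)),
      file.path(d, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    meta$counts$simulate <- length(truth)
  }

  if ("extract" %in% stages) {
    if (is.null(m$populations)) stop("manifest has no 'populations' block")
    d <- .stage_dir(out_dir, "extract")
    rows <- list()
    for (p in m$populations) {
      for (b in p$birds) {
        tracks <- lapply(unlist(b$wav), function(f)
          compute_features(read_wav(f)))
        syl <- list()
        for (ti in seq_along(tracks)) {
          tr <- tracks[[ti]]
          thr_args <- c(b$thresholds,
                        m$defaults$thresholds[setdiff(
                          names(m$defaults$thresholds), names(b$thresholds))])
          thr <- if (!is.null(thr_args$amplitude_floor))
            do.call(segmentation_thresholds, thr_args)
          else do.call(suggest_thresholds, c(list(track = tr), thr_args))
          segs <- segment_syllables(tr, thr)
          syl[[ti]] <- syllable_table(tr, segs, b$id)
          utils::write.csv(as.data.frame(tr),
                           file.path(d, sprintf("%s_track%02d.csv",
                                                b$id, ti)),
                           row.names = FALSE)
        }
        tab <- do.call(rbind, syl)
        tab$population_id <- p$id
        rows[[length(rows) + 1L]] <- tab
        .log_line("extract", b$id, ": ", nrow(tab), " syllables")
      }
    }
    all_syl <- do.call(rbind, rows)
    utils::write.csv(all_syl, file.path(d, "syllables.csv"),
                     row.names = FALSE)
    meta$counts$extract <- nrow(all_syl)
  }

  if ("filter" %in% stages) {
    src <- .need_stage(out_dir, "extract", "syllables.csv")
    d <- .stage_dir(out_dir, "filter")
    syl <- utils::read.csv(src, stringsAsFactors = FALSE)
    pop_cfg <- stats::setNames(
      lapply(m$populations, function(p)
        trim_config(alpha = p$alpha %||% 0.03, k = p$k %||% 2)),
      vapply(m$populations, `[[`, "", "id"))
    kept_all <- list(); log_all <- list()
    for (bid in unique(syl$bird_id)) {
      tab <- syl[syl$bird_id == bid, , drop = FALSE]
      short <- tab$duration_ms < min_dur
      log_short <- data.frame(bird_id = rep(bid, sum(short)),
                              syllable = which(short),
                              reason = rep("short", sum(short)))
      tab2 <- tab[!short, , drop = FALSE]
      cfg <- pop_cfg[[tab$population_id[1]]] %||% trim_config()
      res <- withCallingHandlers(
        trimmed_cluster_filter(tab2, cfg, seed = m$seed),
        warning = function(w) {
          .log_line("filter", bid, ": ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      trm <- which(!short)[is.na(res$cluster)]
      log_trim <- data.frame(bird_id = rep(bid, length(trm)),
                             syllable = trm,
                             reason = rep("trimmed", length(trm)))
      kept_all[[bid]] <- res$kept
      log_all[[bid]] <- rbind(log_short, log_trim)
      .log_line("filter", bid, ": ", sum(short), " short + ",
                nrow(res$discarded), " trimmed discarded, ",
                nrow(res$kept), " kept")
    }
    kept <- do.call(rbind, kept_all)
    utils::write.csv(kept, file.path(d, "syllables_filtered.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, log_all),
                     file.path(d, "discard_log.csv"), row.names = FALSE)
    meta$counts$filter <- nrow(kept)
  }

  if ("kl" %in% stages) {
    src <- .need_stage(out_dir, "filter", "syllables_filtered.csv")
    d <- .stage_dir(out_dir, "kl")
    syl <- utils::read.csv(src, stringsAsFactors = FALSE)
    msets <- list(); sym <- list()
    for (pid in unique(syl$population_id)) {
      sub <- syl[syl$population_id == pid, , drop = FALSE]
      bird_ids <- unique(sub$bird_id)
      if (length(bird_ids) < 2)
        stop("population '", pid, "' has fewer than 2 birds; ",
             "pairwise K-L needs at least 2")
      reps <- lapply(bird_ids, function(bid)
        repertoire(sub[sub$bird_id == bid, , drop = FALSE], bid, pid))
      msets[[pid]] <- pairwise_kl_matrices(reps, cfg = grid_cfg)
      sym[[pid]] <- symmetrize(msets[[pid]])
      sym[[pid]]$population_id <- pid
      .log_line("kl", pid, ": ", length(bird_ids), " birds, ",
                length(bird_ids) * (length(bird_ids) - 1),
                " ordered pairs per parameter")
    }
    long <- do.call(rbind, lapply(names(msets), function(pid) {
      x <- kl_long(msets[[pid]]); x$population_id <- pid; x
    }))
    utils::write.csv(long, file.path(d, "kl_full_matrix.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, sym),
                     file.path(d, "kl_symmetrized.csv"), row.names = FALSE)
    meta$counts$kl <- nrow(long)
  }

  if ("analyze" %in% stages) {
    src <- .need_stage(out_dir, "kl", "kl_full_matrix.csv")
    d <- .stage_dir(out_dir, "analyze")
    long <- utils::read.csv(src, stringsAsFactors = FALSE)
    tab <- .table_from_long(long, kl_floor)
    pca <- pca_pc1(tab)
    fit <- fit_variability(pca$table)
    cmp <- compare_populations(pca$table)
    utils::write.csv(fit$means, file.path(d, "fitted_means.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(test = "population_vs_null",
                                chi_square = cmp$chi_square, df = cmp$df,
                                p_value = cmp$p_value),
                     file.path(d, "model_comparison.csv"), row.names = FALSE)
    utils::write.csv(data.frame(component = seq_along(pca$proportions),
                                proportion = pca$proportions),
                     file.path(d, "pca_proportions.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(pca$loadings),
                     file.path(d, "pca_loadings.csv"), row.names = TRUE)
    .log_line("analyze", "PC1 ", sprintf("%.1f%%", 100 * pca$proportions[1]),
              "; population LRT chi-square ",
              sprintf("%.2f (df %d, p %.3g)", cmp$chi_square, cmp$df,
                      cmp$p_value))
    meta$counts$analyze <- nrow(pca$table)
  }

  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(metadata = meta, fit = fit))
}

# rebuild an analysis table from the long-format K-L CSV
.table_from_long <- function(long, floor) {
  key <- paste(long$population_id, long$template_id, long$target_id,
               sep = "\r")
  wide <- unique(data.frame(template_id = long$template_id,
                            target_id = long$target_id,
                            population_id = long$population_id,
                            key = key, stringsAsFactors = FALSE))
  for (p in unique(long$parameter)) {
    sub <- long[long$parameter == p, ]
    wide[[p]] <- log(pmax(sub$kl_nats[match(wide$key, key[long$parameter == p])],
                          floor))
  }
  wide$key <- NULL
  structure(wide, class = c("analysis_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
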