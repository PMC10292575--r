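# End-to-end orchestration: synthetic generation (or supplied matrices) ->
# cleaning -> connectivity -> hemisphere flipping -> density sweep ->
# connectedness screen -> pre-attack metrics -> attacks -> statistics.

#' Configure a pipeline run
#'
#' @param mode \code{"synthetic"} (generate a cohort from \code{cohort}),
#'   \code{"timeseries"} (supply \code{series} + \code{cohort_table}) or
#'   \code{"matrices"} (supply \code{matrices} + \code{cohort_table}).
#' @param cohort a \code{\link{cohort_spec}} for synthetic mode; defaults to
#'   \code{cohort_spec(seed = seed)}.
#' @param series named list of \code{\link{regional_ts}}
#'   (\code{"<subject>_<timepoint>"}) for timeseries mode.
#' @param matrices named list of \code{\link{connectivity_matrix}} for
#'   matrices mode.
#' @param cohort_table data.frame (subject_id, group, timepoint, lesion_side,
#'   lesion_volume_cm3) describing supplied series/matrices.
#' @param densities density grid (default \code{seq(0.1, 1, 0.1)}).
#' @param range analysis range for AUCs, default \code{c(0.3, 1)}.
#' @param processing list: \code{n_discard}, \code{winsorize} (NULL or
#'   c(lower, upper) percentiles), \code{wavelet_scale} (NULL to skip),
#'   \code{scale_by_region_mean}. Synthetic series are generated directly at
#'   the cleaned length with planted second-order structure, so the synthetic
#'   default discards nothing and skips the wavelet stage.
#' @param attacks list: \code{strategies} (subset of
#'   \code{c("random", "targeted", "mask")}), \code{n_replicates} for random
#'   attacks, \code{adaptive} for targeted, \code{lesion_sets} (named list of
#'   \code{\link{lesion_node_set}}) or \code{lesion_specs} (list of
#'   \code{\link{lesion_spec}}; default the three clinically representative
#'   sizes scaled to the atlas).
#' @param alpha significance level for reporting (default 0.05).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param output_dir optional directory for CSV/JSON artifacts.
#' @param keep_graphs keep the per-subject density stacks on the returned
#'   object (memory-heavy; default FALSE).
#' @return a \code{run_config} list.
#' @export
run_config <- function(mode = c("synthetic", "timeseries", "matrices"),
                       cohort = NULL, series = NULL, matrices = NULL,
                       cohort_table = NULL,
                       densities = seq(0.1, 1, by = 0.1),
                       range = c(0.3, 1),
                       processing = list(),
                       attacks = list(),
                       alpha = 0.05, seed = 1L,
                       output_dir = NULL, keep_graphs = FALSE) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1)
  proc <- utils::modifyList(
    list(n_discard = if (mode == "synthetic") 0L else 5L,
         winsorize = c(5, 95),
         wavelet_scale = NULL,
         scale_by_region_mean = FALSE),
    processing)
  atk <- utils::modifyList(
    list(strategies = c("random", "targeted", "mask"),
         n_replicates = 20L, adaptive = FALSE,
         lesion_sets = NULL, lesion_specs = NULL),
    attacks)
  if (range[1L] < min(densities) - 1e-9 || range[2L] > max(densities) + 1e-9)
    stop("analysis range must lie inside the density grid span")
  structure(list(mode = mode, cohort = cohort, series = series,
                 matrices = matrices, cohort_table = cohort_table,
                 densities = densities, range = range,
                 processing = proc, attacks = atk, alpha = alpha,
                 seed = as.integer(seed), output_dir = output_dir,
                 keep_graphs = keep_graphs),
            class = "run_config")
}

# small deterministic string hash (31-multiplier rolling hash) for provenance
fnv1a <- function(s) {
  h <- 5381
  for (b in as.integer(charToRaw(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full lesion-simulation pipeline
#'
#' Executes every stage of the analysis on a synthetic or user-supplied
#' cohort: signal cleaning, Pearson connectivity, hemisphere flipping for
#' right-lesion patients, strength normalization, positive-weight masking,
#' the proportional density sweep with binarization, the connectedness
#' screen, pre-attack global-efficiency and mean-degree profiles with AUC
#' summaries, the requested attack simulations, and the statistical battery
#' (mixed models, pairwise t tests with Benjamini-Hochberg correction per
#' family, and the cost-resilience Spearman correlation). Re-running with the
#' same config is bit-identical.
#'
#' @param config a \code{\link{run_config}}.
#' @return object of class \code{lesionsim_run}: \code{cohort} (table),
#'   \code{outcomes} (wide per-session AUC table), \code{results} (tidy test
#'   table), \code{models} (mixed-model rows), \code{correlation},
#'   \code{connected_min_density}, \code{lesions}, \code{curves} (group mean
#'   and SD per density), \code{config}, \code{provenance}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  # --- inputs -------------------------------------------------------------
  communities <- NULL
  pairing <- NULL
  if (config$mode == "synthetic") {
    spec <- config$cohort
    if (is.null(spec)) spec <- cohort_spec(seed = seed)
    gen <- generate_cohort(spec)
    series <- gen$series
    cohort <- gen$cohort
    communities <- gen$communities
    pairing <- gen$pairing
  } else {
    cohort <- config$cohort_table
    if (is.null(cohort)) stop("supply cohort_table for non-synthetic modes")
    series <- config$series
  }

  # --- connectivity -------------------------------------------------------
  mats <- if (config$mode == "matrices") {
    config$matrices
  } else {
    proc <- config$processing
    lapply(series, function(ts) {
      ts <- clean_series(ts, n_discard = proc$n_discard,
                         scale_by_region_mean = proc$scale_by_region_mean)
      if (!is.null(proc$winsorize))
        ts <- winsorize_series(ts, proc$winsorize[1L], proc$winsorize[2L])
      if (!is.null(proc$wavelet_scale))
        ts <- wavelet_band(ts, proc$wavelet_scale)
      pearson_connectivity(ts)
    })
  }
  n_regions <- nrow(mats[[1L]]$weights)
  if (is.null(pairing)) pairing <- homotopic_pairing(n_regions)

  # --- hemisphere flipping for right-lesion patients ----------------------
  right <- unique(cohort$subject_id[cohort$group == "patient" &
                                      cohort$lesion_side == "right"])
  key_subject <- sub("_[^_]+$", "", names(mats))
  for (i in seq_along(mats))
    if (key_subject[i] %in% right)
      mats[[i]] <- flip_hemispheres(mats[[i]], pairing)

  # --- lesion node sets ---------------------------------------------------
  lesions <- config$attacks$lesion_sets
  if (is.null(lesions) && "mask" %in% config$attacks$strategies) {
    specs <- config$attacks$lesion_specs
    if (is.null(specs)) specs <- default_lesion_specs(n_regions)
    if (is.null(communities)) {
      k <- if (n_regions %% 12L == 0L) 6L else
        max(which((n_regions / 2L) %% seq_len(6L) == 0L))
      communities <- community_labels(n_regions, k)
    }
    sets <- generate_lesion_node_sets(specs, n_regions,
                                      seed = (seed + 101L) %% .Machine$integer.max,
                                      communities = communities)
    lesions <- lapply(names(sets), function(nm)
      lesion_node_set(nm, sets[[nm]], "list"))
    names(lesions) <- names(sets)
  }

  # --- graphs, metrics, attacks per session -------------------------------
  rlo <- config$range[1L]; rhi <- config$range[2L]
  strategies <- config$attacks$strategies
  conn_min <- numeric(length(mats))
  strength <- numeric(length(mats))
  rows <- vector("list", length(mats))
  curve_rows <- list()
  stacks <- if (config$keep_graphs) vector("list", length(mats)) else NULL
  for (i in seq_along(mats)) {
    nrm <- normalize_strength(mats[[i]])
    strength[i] <- nrm$total_strength
    stack <- density_sweep(mask_positive(nrm$matrix), config$densities)
    if (config$keep_graphs) stacks[[i]] <- stack
    conn_min[i] <- connected_density_range(stack)
    pe <- density_profile(stack, "global_efficiency", rlo, rhi)
    pd <- density_profile(stack, "mean_degree", rlo, rhi)
    row <- list(pre_eglob_auc = attr(pe, "auc"),
                pre_degree_auc = attr(pd, "auc"))
    curve_rows[[length(curve_rows) + 1L]] <-
      data.frame(key = names(mats)[i], metric = "pre_eglob",
                 density = pe$density, value = pe$value)
    if ("random" %in% strategies) {
      ar <- serial_random_attack(stack, config$attacks$n_replicates,
                                 seed = (seed + 7L * i) %% .Machine$integer.max,
                                 range_lo = rlo, range_hi = rhi)
      row$random_auc <- ar$summary_auc
      curve_rows[[length(curve_rows) + 1L]] <-
        data.frame(key = names(mats)[i], metric = "random_attack",
                   density = ar$densities, value = ar$per_density_summary)
    }
    if ("targeted" %in% strategies) {
      at <- serial_targeted_attack(stack, recompute = config$attacks$adaptive,
                                   range_lo = rlo, range_hi = rhi)
      row$targeted_auc <- at$summary_auc
      curve_rows[[length(curve_rows) + 1L]] <-
        data.frame(key = names(mats)[i], metric = "targeted_attack",
                   density = at$densities, value = at$per_density_summary)
    }
    if ("mask" %in% strategies) {
      for (nm in names(lesions)) {
        am <- mask_attack(stack, lesions[[nm]], range_lo = rlo,
                          range_hi = rhi)
        row[[paste0("mask_", gsub("[^a-z0-9]+", "_", nm), "_auc")]] <-
          am$summary_auc
        curve_rows[[length(curve_rows) + 1L]] <-
          data.frame(key = names(mats)[i], metric = paste0("mask:", nm),
                     density = am$densities, value = am$per_density_summary)
      }
    }
    rows[[i]] <- as.data.frame(row)
  }
  keys <- names(mats)
  meta <- cohort[match(keys, paste(cohort$subject_id, cohort$timepoint,
                                   sep = "_")), , drop = FALSE]
  outcomes <- cbind(meta, do.call(rbind, rows),
                    connected_min_density = conn_min,
                    total_strength = strength)
  rownames(outcomes) <- NULL

  # group mean +/- SD per density, mirroring the figure logic
  curves_long <- do.call(rbind, curve_rows)
  curves_long <- merge(curves_long,
                       data.frame(key = keys, group = meta$group,
                                  timepoint = meta$timepoint),
                       by = "key")
  curves <- stats::aggregate(value ~ metric + group + timepoint + density,
                             curves_long, function(v) c(mean = mean(v),
                                                        sd = stats::sd(v)))
  curves <- cbind(curves[, c("metric", "group", "timepoint", "density")],
                  mean = curves$value[, "mean"], sd = curves$value[, "sd"])

  # --- statistics ---------------------------------------------------------
  outcome_cols <- setdiff(names(outcomes),
                          c(names(meta), "connected_min_density",
                            "total_strength"))
  long_table <- function(col) {
    tb <- outcomes[, c("subject_id", "group", "timepoint", "lesion_side",
                       "lesion_volume_cm3")]
    tb$outcome <- outcomes[[col]]
    tb
  }
  families <- c(pre_eglob_auc = "spontaneous E_glob",
                pre_degree_auc = "mean degree",
                random_auc = "random attack",
                targeted_auc = "targeted attack")
  models <- list(); tests <- list()
  has_patients <- sum(outcomes$group == "patient" &
                        outcomes$timepoint == "TP1") >= 3L
  for (col in outcome_cols) {
    fam <- if (col %in% names(families)) families[[col]] else
      paste("mask attack:", sub("^mask_(.*)_auc$", "\\1", col))
    tb <- long_table(col)
    if (has_patients) {
      mm <- fit_longitudinal_model(tb)
      mm$family <- fam
      mm$name <- paste0(fam, ": timepoint omnibus")
      models[[col]] <- mm
      pc <- pairwise_comparisons(tb, family = fam)
      tests[[col]] <- pc
    }
  }
  # combined mask-attack model with timepoint x attack-type interaction
  mask_cols <- grep("^mask_.*_auc$", outcome_cols, value = TRUE)
  if (has_patients && length(mask_cols) >= 2L) {
    combined <- do.call(rbind, lapply(mask_cols, function(col) {
      tb <- long_table(col)
      tb$attack_type <- sub("^mask_(.*)_auc$", "\\1", col)
      tb
    }))
    mm <- fit_longitudinal_model(combined, include_attack_interaction = TRUE)
    mm$family <- "mask attacks combined"
    mm$name <- "mask attacks: timepoint omnibus (with attack interaction)"
    models[["mask_combined"]] <- mm
  }
  models <- if (length(models)) do.call(rbind, models) else NULL
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  results <- rbind(models, tests)
  if (!is.null(results)) rownames(results) <- NULL

  # cost-resilience correlation: TP3 - TP2 change in post-attack AUC(E_glob)
  # against the change in pre-attack AUC(mean degree)
  correlation <- NULL
  res_col <- intersect(c("random_auc", "targeted_auc", mask_cols),
                       outcome_cols)[1L]
  if (has_patients && !is.na(res_col)) {
    p2 <- outcomes[outcomes$group == "patient" & outcomes$timepoint == "TP2", ]
    p3 <- outcomes[outcomes$group == "patient" & outcomes$timepoint == "TP3", ]
    p3 <- p3[match(p2$subject_id, p3$subject_id), ]
    if (nrow(p2) >= 4L) {
      correlation <- cost_resilience_correlation(
        p3[[res_col]] - p2[[res_col]],
        p3$pre_degree_auc - p2$pre_degree_auc)
      correlation$resilience_outcome <- res_col
    }
  }

  cfg_json <- jsonlite::toJSON(list(mode = config$mode,
                                    densities = config$densities,
                                    range = config$range,
                                    processing = config$processing,
                                    strategies = config$attacks$strategies,
                                    n_replicates = config$attacks$n_replicates,
                                    alpha = config$alpha, seed = seed),
                               auto_unbox = TRUE, digits = NA)
  run <- structure(list(cohort = cohort, outcomes = outcomes,
                        n_regions = n_regions,
                        results = results, models = models,
                        correlation = correlation,
                        curves = curves,
                        connected_min_density =
                          stats::setNames(conn_min, keys),
                        lesions = lesions, stacks = stacks,
                        config = config,
                        provenance = list(config_hash = fnv1a(cfg_json),
                                          config_json = as.character(cfg_json),
                                          seed = seed,
                                          version = as.character(
                                            utils::packageVersion("lesionsim")))),
                   class = "lesionsim_run")
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

#' @export
print.lesionsim_run <- function(x, ...) {
  cat("Lesion-simulation pipeline run\n")
  cat(sprintf("  %d sessions (%d patients, %d controls), %d regions\n",
              nrow(x$outcomes),
              length(unique(x$cohort$subject_id[x$cohort$group == "patient"])),
              length(unique(x$cohort$subject_id[x$cohort$group == "control"])),
              x$n_regions))
  cat(sprintf("  analysis range [%g, %g]; config %s; seed %d\n",
              x$config$range[1L], x$config$range[2L],
              x$provenance$config_hash, x$provenance$seed))
  if (!is.null(x$models)) {
    cat("  mixed-model omnibus tests:\n")
    for (i in seq_len(nrow(x$models)))
      cat(sprintf("    %-55s F=%8.4g  p=%.4g\n", x$models$name[i],
                  x$models$statistic[i], x$models$p_raw[i]))
  }
  if (!is.null(x$correlation))
    cat(sprintf("  cost-resilience Spearman rho=%.3f (p=%.4g, n=%d, %s)\n",
                x$correlation$rho, x$correlation$p, x$correlation$n,
                x$correlation$resilience_outcome))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write run artifacts to a directory
#'
#' Cohort table, per-session outcome AUCs, group curves, tidy test results
#' with a text report, lesion node sets and a provenance JSON.
#'
#' @param run a \code{lesionsim_run}.
#' @param dir output directory (created if missing).
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(run$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(run$curves, file.path(dir, "group_curves.csv"),
                   row.names = FALSE)
  if (!is.null(run$results))
    write_test_results(run$results, file.path(dir, "test_results.csv"))
  for (nm in names(run$lesions))
    writeLines(as.character(run$lesions[[nm]]$node_ids),
               file.path(dir, sprintf("lesion_%s.txt",
                                      gsub("[^a-z0-9]+", "_", nm))))
  prov <- run$provenance
  if (!is.null(run$correlation)) prov$cost_resilience <- run$correlation
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
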