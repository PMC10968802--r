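#' Study-level configuration
#'
#' One object holding every knob of the synthetic selection study: the
#' master seed, the per-cell-line marker signatures and their baseline CSC
#' fractions, the [selection_params()] shared by all series, the
#' [cytosim_config()] defaults for the event-level path, and the
#' [gp_config()] used for fitting. Built from a YAML file (the packaged
#' `extdata/default_study.yaml` by default), with `...` overriding
#' top-level entries.
#'
#' @param path Path to a YAML study configuration; `NULL` loads the
#'   packaged default.
#' @param ... Named top-level overrides (e.g. `master_seed = 7`).
#' @return An object of class `study_config`.
#' @export
study_config <- function(path = NULL, ...) {
  if (is.null(path))
    path <- system.file("extdata", "default_study.yaml", package = "cscgp")
  raw <- yaml::read_yaml(path)
  raw <- utils::modifyList(raw, list(...))
  sel <- utils::modifyList(.cscgp_defaults$selection, raw$selection %||% list())
  gp <- utils::modifyList(.cscgp_defaults$gp, raw$gp %||% list())
  fc <- utils::modifyList(.cscgp_defaults$forecast, raw$forecast %||% list())
  st <- utils::modifyList(.cscgp_defaults$stats, raw$stats %||% list())
  cy <- utils::modifyList(.cscgp_defaults$cytosim, raw$cytosim %||% list())
  design <- raw$study_design %||% .cscgp_defaults$study_design
  structure(list(
    master_seed = as.integer(raw$master_seed %||% 42L),
    selection = sel,
    study_design = design,
    cytosim = cy,
    gp = gp,
    forecast = fc,
    stats = st
  ), class = "study_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.design_table <- function(config) {
  rows <- list()
  k <- 0L
  for (cl in names(config$study_design)) {
    for (sig in names(config$study_design[[cl]])) {
      k <- k + 1L
      rows[[k]] <- data.frame(cell_line = cl, signature = sig,
                              f0 = config$study_design[[cl]][[sig]],
                              pair_index = k, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.series_params <- function(config, f0) {
  sel <- config$selection
  selection_params(f0 = f0, d_r = sel$d_r, d_s = sel$d_s, d0 = sel$d0,
                   noise_sd = sel$noise_sd, times = sel$times,
                   n_replicates = sel$n_replicates)
}

#' Simulate the full synthetic marker-series study
#'
#' Generates one treated/control series pair per (cell line, signature) of
#' the study design — 12 series under the default 2 x 3 x 2 design — each
#' pair drawn with a sub-seed derived from the master seed and the pair's
#' design index, so adding a signature never perturbs existing series.
#' When `out_dir` is given, each series is written to CSV and a
#' `manifest.csv` records every file with its sub-seed and MD5 checksum.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return Invisibly, a list with `series` (one combined `marker_series`
#'   data frame) and `manifest` (`NULL` unless `out_dir` was given).
#' @export
simulate_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  design <- .design_table(config)
  all_series <- list()
  manifest <- NULL
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (i in seq_len(nrow(design))) {
    params <- .series_params(config, design$f0[i])
    sub_seed <- .sub_seed(config$master_seed, design$pair_index[i])
    pair <- generate_series(params, design$cell_line[i],
                            design$signature[i], seed = sub_seed)
    all_series[[2 * i - 1]] <- pair$treated
    all_series[[2 * i]] <- pair$control
    if (!is.null(out_dir)) {
      slug <- tolower(gsub("[^A-Za-z0-9]+", "_", paste(
        design$cell_line[i], design$signature[i])))
      for (arm in c("treated", "control")) {
        f <- file.path(out_dir, paste0(slug, "_", arm, ".csv"))
        write_marker_series(pair[[arm]], f)
        manifest <- rbind(manifest, data.frame(
          file = basename(f), sub_seed = sub_seed,
          md5 = unname(tools::md5sum(f)), stringsAsFactors = FALSE))
      }
    }
  }
  series <- .new_marker_series(do.call(rbind, all_series))
  if (!is.null(out_dir)) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    write_marker_series(series, file.path(out_dir, "series.csv"))
  }
  invisible(list(series = series, manifest = manifest))
}

# regenerate the percent observations of one study through the event-level
# path: simulate a gated cytometry experiment per (series, time, replicate)
.series_via_events <- function(config) {
  design <- .design_table(config)
  sel <- config$selection
  out <- list()
  n <- 0L
  for (i in seq_len(nrow(design))) {
    params <- .series_params(config, design$f0[i])
    query <- signature_query(design$signature[i])
    for (arm in c("treated", "control")) {
      tables <- list()
      k <- 0L
      for (tt in sel$times) {
        p_sig <- csc_fraction(params, tt, treated = (arm == "treated"))
        live_frac <- 1 - dead_fraction(params, tt, treated = (arm == "treated"))
        for (rep_id in seq_len(sel$n_replicates)) {
          k <- k + 1L
          ev_seed <- .sub_seed(config$master_seed,
                               1000L * i + 100L * (arm == "treated") + k)
          cyto <- cytosim_config(
            n_events = config$cytosim$n_events,
            live_fraction = live_frac,
            joint_probs = signature_joint(query, p_sig),
            seed = ev_seed)
          events <- simulate_events(cyto, with_truth = FALSE)
          tables[[k]] <- list(time_h = tt, replicate = rep_id, events = events)
        }
      }
      n <- n + 1L
      out[[n]] <- series_from_events(
        tables, query, default_gate(cytosim_config(seed = 0L)),
        cell_line = design$cell_line[i], signature = design$signature[i],
        treatment = arm)
    }
  }
  .new_marker_series(do.call(rbind, out))
}

#' Run the complete pipeline: simulate, fit, compare, summarise
#'
#' Chains the synthetic-data generator, (optionally) the event-level
#' cytometry simulation plus gating, the GP forecasting of every series,
#' and the per-time-point treated-vs-control statistics. With
#' `skip_events = TRUE` (the default fast path) percent series come
#' directly from the survival model; with `FALSE` they are re-derived by
#' gating simulated event tables.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory for `series.csv`, `results.csv`,
#'   `stats.csv`, `manifest.csv` and `summary.txt`.
#' @param skip_events Use the fast percentage-level path (default) instead
#'   of the event-level path.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `series`, `results` (a `study_results`),
#'   `stats` (per-time-point comparisons) and `summary` (named vector of
#'   mean/min/max r2_all).
#' @export
end_to_end <- function(config = study_config(), out_dir = NULL,
                       skip_events = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  say("simulate: master_seed=%d, %d cell lines, noise_sd=%.2f",
      config$master_seed, length(config$study_design),
      config$selection$noise_sd)
  sim <- simulate_study(config, out_dir = out_dir)
  series <- if (skip_events) sim$series else {
    say("gate: event-level path, n_events=%d", config$cytosim$n_events)
    .series_via_events(config)
  }

  gp_cfg <- do.call(gp_config, config$gp[setdiff(names(config$gp), "seed")])
  gp_cfg$seed <- config$master_seed
  say("fit: population=%d, generations=%d, master_seed=%d",
      gp_cfg$population_size, gp_cfg$max_generations, config$master_seed)
  results <- run_study(series, gp_cfg,
                       train_times = config$forecast$train_times,
                       validation_time = config$forecast$validation_time,
                       followup_time = config$forecast$followup_time)

  say("compare: treated vs control per time point")
  stats_rows <- list()
  design <- .design_table(config)
  for (i in seq_len(nrow(design))) {
    tr <- series[series$cell_line == design$cell_line[i] &
                   series$signature == design$signature[i] &
                   series$treatment == "treated", ]
    ct <- series[series$cell_line == design$cell_line[i] &
                   series$signature == design$signature[i] &
                   series$treatment == "control", ]
    cmp <- compare_series(tr, ct, alpha_normality = config$stats$alpha_normality)
    cmp <- cbind(cell_line = design$cell_line[i],
                 signature = design$signature[i], cmp)
    stats_rows[[i]] <- cmp
  }
  stats_df <- do.call(rbind, stats_rows)
  smry <- attr(results, "summary")

  if (!is.null(out_dir)) {
    write_study_results(results, file.path(out_dir, "results.csv"))
    write.csv(stats_df, file.path(out_dir, "stats.csv"), row.names = FALSE)
    txt <- c(sprintf("series fitted: %d", nrow(results)),
             sprintf("r2_all mean: %.4f", smry["mean_r2"]),
             sprintf("r2_all min:  %.4f", smry["min_r2"]),
             sprintf("r2_all max:  %.4f", smry["max_r2"]))
    writeLines(txt, file.path(out_dir, "summary.txt"))
  }
  say("done: r2_all mean %.3f (min %.3f, max %.3f)",
      smry["mean_r2"], smry["min_r2"], smry["max_r2"])
  invisible(list(series = series, results = results, stats = stats_df,
                 summary = smry))
}
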