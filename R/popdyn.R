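#' Parameters of the two-compartment drug-selection model
#'
#' The live tumour population is split into a resistant CSC compartment
#' (initial fraction `f0`) and a sensitive bulk compartment. Under 5-FU both
#' die exponentially but at different rates (`d_r` for CSC, `d_s >= d_r` for
#' bulk), so the surviving population is progressively enriched for CSC.
#' Without drug both compartments share the baseline rate `d0` and the CSC
#' fraction stays at `f0`.
#'
#' @param f0 Initial CSC fraction, strictly inside (0, 1).
#' @param d_r CSC death rate under 5-FU, per hour, `>= 0`.
#' @param d_s Sensitive-cell death rate under 5-FU, per hour, `>= d_r`.
#' @param d0 Baseline death rate untreated, per hour, `>= 0`.
#' @param noise_sd Replicate noise on the percent scale (percentage points).
#' @param times Assay times in hours, strictly increasing and positive.
#' @param n_replicates Number of replicates per time point.
#' @return An object of class `selection_params`.
#' @examples
#' p <- selection_params()
#' fold_enrichment(p, 52)
#' @export
selection_params <- function(f0 = .cscgp_defaults$selection$f0,
                             d_r = .cscgp_defaults$selection$d_r,
                             d_s = .cscgp_defaults$selection$d_s,
                             d0 = .cscgp_defaults$selection$d0,
                             noise_sd = .cscgp_defaults$selection$noise_sd,
                             times = .cscgp_defaults$selection$times,
                             n_replicates = .cscgp_defaults$selection$n_replicates) {
  if (!is.numeric(f0) || length(f0) != 1L || f0 <= 0 || f0 >= 1)
    stop("`f0` must be a single number strictly between 0 and 1")
  if (d_r < 0) stop("`d_r` must be >= 0")
  if (d_s < d_r) stop("`d_s` must be >= `d_r`")
  if (d0 < 0) stop("`d0` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (length(times) < 1L || any(times <= 0) || is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing and positive")
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1")
  structure(list(f0 = f0, d_r = d_r, d_s = d_s, d0 = d0,
                 noise_sd = noise_sd, times = as.numeric(times),
                 n_replicates = as.integer(n_replicates)),
            class = "selection_params")
}

.check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("time `t` must be finite and non-negative")
  as.numeric(t)
}

#' CSC fraction among surviving cells
#'
#' Closed form of the two-compartment exponential-kill model. In the treated
#' arm the fraction is
#' `f0 exp(-d_r t) / (f0 exp(-d_r t) + (1 - f0) exp(-d_s t))`,
#' non-decreasing in `t` whenever `d_s > d_r`. In the control arm both
#' compartments die at the shared baseline rate, so the fraction is the
#' time-invariant `f0`.
#'
#' @param params A [selection_params()] object.
#' @param t Time in hours (vectorised), `>= 0`.
#' @param treated Logical; `TRUE` for the 5-FU arm.
#' @return CSC fraction(s) in (0, 1).
#' @export
csc_fraction <- function(params, t, treated = TRUE) {
  stopifnot(inherits(params, "selection_params"))
  t <- .check_time(t)
  if (!treated) return(rep(params$f0, length(t)))
  # work on the log-odds scale for numerical stability at large t
  num_log <- log(params$f0) - params$d_r * t
  den_log <- log1p(-params$f0) - params$d_s * t
  1 / (1 + exp(den_log - num_log))
}

#' Fold enrichment of the CSC fraction, treated relative to control
#'
#' @inheritParams csc_fraction
#' @return Ratio `csc_fraction(treated) / csc_fraction(control)`, `>= 0`.
#' @export
fold_enrichment <- function(params, t) {
  csc_fraction(params, t, treated = TRUE) /
    csc_fraction(params, t, treated = FALSE)
}

#' Dead-cell fraction over time
#'
#' Treated: `1 - (f0 exp(-d_r t) + (1 - f0) exp(-d_s t))`; control:
#' `1 - exp(-d0 t)`. Both are non-decreasing in `t`, and the treated arm
#' dominates the control whenever `d_s >= d_r >= d0`.
#'
#' @inheritParams csc_fraction
#' @return Dead fraction(s) in `[0, 1)`.
#' @export
dead_fraction <- function(params, t, treated = TRUE) {
  stopifnot(inherits(params, "selection_params"))
  t <- .check_time(t)
  if (!treated) return(1 - exp(-params$d0 * t))
  1 - (params$f0 * exp(-params$d_r * t) +
         (1 - params$f0) * exp(-params$d_s * t))
}

.new_marker_series <- function(df) {
  df <- df[order(df$cell_line, df$signature, df$treatment,
                 df$time_h, df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("marker_series", "data.frame")
  df
}

#' Generate a treated/control pair of marker-percentage time series
#'
#' Each observation is `100 * csc_fraction(...)` plus additive Gaussian
#' noise of SD `noise_sd` percentage points, clipped to `[0, 100]` —
#' emulating percent-positive flow-cytometry readouts with replicate
#' measurement error. The RNG is seeded inside the function (treated arm
#' drawn first, then control), so one seed fully determines the pair.
#'
#' @param params A [selection_params()] object.
#' @param cell_line Cell-line label, e.g. `"HCT-116"`.
#' @param signature Marker-signature label, e.g. `"CD44+ABCG2+ALDH1+"`.
#' @param seed Integer seed for the replicate noise.
#' @return A list with elements `treated` and `control`, each a
#'   `marker_series` data frame with columns
#'   `cell_line, signature, treatment, time_h, replicate, percent`.
#' @export
generate_series <- function(params, cell_line, signature, seed) {
  stopifnot(inherits(params, "selection_params"))
  if (length(seed) != 1L || !is.finite(seed)) stop("`seed` must be an integer")
  set.seed(as.integer(seed))
  arm <- function(treated) {
    grid <- expand.grid(replicate = seq_len(params$n_replicates),
                        time_h = params$times)
    truth <- 100 * csc_fraction(params, grid$time_h, treated = treated)
    pct <- truth + rnorm(nrow(grid), mean = 0, sd = params$noise_sd)
    pct <- pmin(pmax(pct, 0), 100)
    .new_marker_series(data.frame(
      cell_line = cell_line, signature = signature,
      treatment = if (treated) "treated" else "control",
      time_h = grid$time_h, replicate = grid$replicate, percent = pct,
      stringsAsFactors = FALSE))
  }
  treated <- arm(TRUE)
  control <- arm(FALSE)
  list(treated = treated, control = control)
}

.series_cols <- c("cell_line", "signature", "treatment",
                  "time_h", "replicate", "percent")

.validate_marker_series <- function(df) {
  missing <- setdiff(.series_cols, names(df))
  if (length(missing))
    stop("marker series is missing columns: ", paste(missing, collapse = ", "))
  if (any(df$percent < 0 | df$percent > 100))
    stop("marker series percents must lie in [0, 100]")
  key <- interaction(df$cell_line, df$signature, df$treatment,
                     df$time_h, df$replicate, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (time_h, replicate) observations in marker series")
  invisible(df)
}

#' Write / read marker series CSV
#'
#' Normative on-disk format: UTF-8 CSV with header
#' `cell_line,signature,treatment,time_h,replicate,percent`, '.' decimal
#' separator, one observation per row. Several series may share one file.
#'
#' @param series A `marker_series` data frame (or plain data frame with the
#'   same columns).
#' @param path File path.
#' @return `read_marker_series` returns a `marker_series` data frame;
#'   `write_marker_series` returns `path` invisibly.
#' @export
write_marker_series <- function(series, path) {
  .validate_marker_series(series)
  write.csv(series[, .series_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_marker_series
#' @export
read_marker_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .validate_marker_series(df)
  .new_marker_series(df)
}
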