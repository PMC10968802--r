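#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. A zero total sum of
#' squares (all `y_true` identical) is an explicit classed error
#' (`cscgp_degenerate_error`), never a silent `NaN`.
#'
#' @param y_true,y_pred Equal-length numeric vectors, length `>= 2`.
#' @return A real number `<= 1`.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    stop("`y_true` and `y_pred` must have equal length >= 2")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0)
    stop(structure(class = c("cscgp_degenerate_error", "error", "condition"),
                   list(message = "R-squared undefined: y_true has zero variance",
                        call = sys.call(-1))))
  1 - sum((y_true - y_pred)^2) / ss_tot
}

.series_identity <- function(series) {
  id <- unique(series[, c("cell_line", "signature", "treatment")])
  if (nrow(id) != 1L)
    stop("`series` must contain exactly one (cell_line, signature, treatment) series")
  id
}

#' Fit one marker series with GP and score the held-out validation point
#'
#' Replicates are averaged to one mean per time point. The GP is trained on
#' the `train_times` means only; the coefficient of determination `r2_all`
#' is computed over the training *and* validation means with the trained
#' expression, the absolute error at `validation_time` is reported
#' separately, and the expression is extrapolated to `followup_time`
#' (reported raw and clipped to `[0, 100]`, since the quantity is a
#' percentage).
#'
#' @param series A `marker_series` containing one series with observations
#'   at every train and validation time.
#' @param config A [gp_config()].
#' @param train_times Times used for fitting (default 24/33/43 h).
#' @param validation_time Held-out time (default 52 h).
#' @param followup_time Extrapolation target (default 67 h).
#' @return A `fit_result` list: identity labels, `expression` (canonical
#'   string), `means` (per-time observed means and predictions), `r2_train`,
#'   `r2_all`, `validation_abs_error`, `pred_followup_raw`,
#'   `pred_followup_clipped`, and the underlying `gp_fit`.
#' @export
fit_series <- function(series, config = gp_config(),
                       train_times = .cscgp_defaults$forecast$train_times,
                       validation_time = .cscgp_defaults$forecast$validation_time,
                       followup_time = .cscgp_defaults$forecast$followup_time) {
  .validate_marker_series(series)
  id <- .series_identity(series)
  needed <- c(train_times, validation_time)
  have <- unique(series$time_h)
  missing <- setdiff(needed, have)
  if (length(missing))
    stop("series is missing required time points: ",
         paste(missing, collapse = ", "))
  means <- aggregate(percent ~ time_h, data = series, FUN = mean)
  means <- means[means$time_h %in% needed, ]
  means <- means[order(means$time_h), ]

  y_all <- means$percent
  if (length(unique(y_all)) == 1L)
    stop(structure(class = c("cscgp_degenerate_error", "error", "condition"),
                   list(message = "constant series: R-squared undefined",
                        call = sys.call(-1))))

  train <- means[means$time_h %in% train_times, ]
  fit <- evolve(train$time_h, train$percent, config,
                eval_range = c(min(train_times), followup_time))

  pred_all <- gp_predict(fit, means$time_h)
  pred_train <- pred_all[means$time_h %in% train_times]
  pred_val <- pred_all[means$time_h == validation_time]
  obs_val <- y_all[means$time_h == validation_time]

  r2_train <- if (length(unique(train$percent)) == 1L) NA_real_ else
    r_squared(train$percent, pred_train)
  r2_all <- r_squared(y_all, pred_all)
  pred_fu <- gp_predict(fit, followup_time)

  structure(list(
    cell_line = id$cell_line, signature = id$signature,
    treatment = id$treatment,
    expression = serialize_tree(fit$best$tree),
    means = data.frame(time_h = means$time_h, observed = y_all,
                       predicted = pred_all,
                       role = ifelse(means$time_h %in% train_times,
                                     "train", "validation")),
    r2_train = r2_train, r2_all = r2_all,
    validation_abs_error = abs(pred_val - obs_val),
    pred_followup_raw = pred_fu,
    pred_followup_clipped = min(max(pred_fu, 0), 100),
    followup_time = followup_time,
    gp_fit = fit
  ), class = "fit_result")
}

#' Fit every series of a study and tabulate per-model R-squared
#'
#' Splits a multi-series collection by (cell line, signature, treatment),
#' fits each series independently with a sub-seeded copy of `config`
#' (sub-seeds are keyed to the alphabetical rank of the series identity, so
#' results are invariant to input order), and tabulates one row per model.
#' Per-series failures (e.g. degenerate constant series) are isolated: the
#' row is kept with `NA` scores and the error message in `error`.
#'
#' @param series_collection A `marker_series` data frame holding several
#'   series, or a list of single-series data frames.
#' @param config A [gp_config()]; `config$seed` acts as the master seed.
#' @param ... Passed on to [fit_series()].
#' @return A `study_results` data frame with columns
#'   `cell_line, signature, treatment, expression, r2_train, r2_all,
#'   abs_err_52h, pred_67h_raw, pred_67h_clipped, error`, with a `summary`
#'   attribute holding mean/min/max `r2_all` and the `fit_result`s in the
#'   `fits` attribute.
#' @export
run_study <- function(series_collection, config = gp_config(), ...) {
  if (is.data.frame(series_collection)) {
    .validate_marker_series(series_collection)
    key <- interaction(series_collection$cell_line,
                       series_collection$signature,
                       series_collection$treatment, drop = TRUE)
    series_list <- split(series_collection, key)
  } else {
    series_list <- series_collection
  }
  if (!length(series_list)) {
    warning("empty series collection: nothing to fit")
    out <- data.frame(cell_line = character(0), signature = character(0),
                      treatment = character(0), expression = character(0),
                      r2_train = numeric(0), r2_all = numeric(0),
                      abs_err_52h = numeric(0), pred_67h_raw = numeric(0),
                      pred_67h_clipped = numeric(0), error = character(0))
    attr(out, "summary") <- c(mean_r2 = NA_real_, min_r2 = NA_real_,
                              max_r2 = NA_real_)
    class(out) <- c("study_results", "data.frame")
    return(out)
  }
  ids <- vapply(series_list, function(s) {
    id <- .series_identity(s)
    paste(id$cell_line, id$signature, id$treatment, sep = "|")
  }, character(1))
  rank <- match(ids, sort(ids))

  rows <- vector("list", length(series_list))
  fits <- vector("list", length(series_list))
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    id <- .series_identity(s)
    cfg <- config
    cfg$seed <- .sub_seed(config$seed, rank[i])
    res <- tryCatch(fit_series(s, cfg, ...), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(
        cell_line = id$cell_line, signature = id$signature,
        treatment = id$treatment, expression = NA_character_,
        r2_train = NA_real_, r2_all = NA_real_, abs_err_52h = NA_real_,
        pred_67h_raw = NA_real_, pred_67h_clipped = NA_real_,
        error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      fits[[i]] <- res
      rows[[i]] <- data.frame(
        cell_line = res$cell_line, signature = res$signature,
        treatment = res$treatment, expression = res$expression,
        r2_train = res$r2_train, r2_all = res$r2_all,
        abs_err_52h = res$validation_abs_error,
        pred_67h_raw = res$pred_followup_raw,
        pred_67h_clipped = res$pred_followup_clipped,
        error = NA_character_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_line, out$signature, out$treatment), ]
  rownames(out) <- NULL
  attr(out, "summary") <- c(mean_r2 = mean(out$r2_all, na.rm = TRUE),
                            min_r2 = suppressWarnings(min(out$r2_all, na.rm = TRUE)),
                            max_r2 = suppressWarnings(max(out$r2_all, na.rm = TRUE)))
  attr(out, "fits") <- fits
  class(out) <- c("study_results", "data.frame")
  out
}

#' @export
print.study_results <- function(x, ...) {
  df <- as.data.frame(x)
  df$expression <- ifelse(is.na(df$expression), NA,
                          substr(df$expression, 1, 40))
  print(df[, setdiff(names(df), "error")], ...)
  s <- attr(x, "summary")
  cat(sprintf("r2_all: mean %.3f, min %.3f, max %.3f\n",
              s["mean_r2"], s["min_r2"], s["max_r2"]))
  invisible(x)
}

#' Write study results to CSV
#'
#' Columns: `cell_line,signature,treatment,expression,r2_train,r2_all,`
#' `abs_err_52h,pred_67h_raw,pred_67h_clipped`.
#'
#' @param results A `study_results` data frame.
#' @param path File path.
#' @export
write_study_results <- function(results, path) {
  cols <- c("cell_line", "signature", "treatment", "expression",
            "r2_train", "r2_all", "abs_err_52h", "pred_67h_raw",
            "pred_67h_clipped")
  write.csv(as.data.frame(results)[, cols], path, row.names = FALSE)
  invisible(path)
}
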