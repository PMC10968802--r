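#' Compare treated and control replicate percentages at one time point
#'
#' Dispatch rule: both groups are screened for normality with the
#' Shapiro-Wilk test at `alpha_normality`; if both pass, an independent
#' two-sample t-test (pooled variance) compares the means, otherwise the
#' Mann-Whitney rank-sum test is used. Tests are two-sided. Groups with
#' zero variance (Shapiro-Wilk undefined) are routed to the rank-sum test.
#'
#' @param treated,control Numeric vectors of replicate percents, each with
#'   at least 3 values.
#' @param alpha_normality Significance level of the normality screen.
#' @param time_h Optional time label carried through to the result.
#' @return A `comparison_result` data frame row: `time_h`, `test_name`
#'   (`"t"` or `"rank-sum"`), `statistic`, `p_value`, `fold_change`
#'   (treated mean / control mean) and `stars` (`*`, `**`, `***` at
#'   0.05/0.01/0.001).
#' @export
compare_groups <- function(treated, control,
                           alpha_normality = .cscgp_defaults$stats$alpha_normality,
                           time_h = NA_real_) {
  if (length(treated) < 3L || length(control) < 3L)
    stop("insufficient replicates: both groups need n >= 3")
  sw_p <- function(x) {
    if (length(unique(x)) == 1L) return(0)   # zero variance: treat as non-normal
    tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  }
  normal <- sw_p(treated) > alpha_normality && sw_p(control) > alpha_normality
  if (normal) {
    ht <- t.test(treated, control, var.equal = TRUE)
    test_name <- "t"
  } else {
    ht <- suppressWarnings(wilcox.test(treated, control, exact = FALSE))
    test_name <- "rank-sum"
  }
  p <- ht$p.value
  fold <- mean(treated) / mean(control)
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  structure(data.frame(time_h = time_h, test_name = test_name,
                       statistic = unname(ht$statistic), p_value = p,
                       fold_change = fold, stars = stars,
                       stringsAsFactors = FALSE),
            class = c("comparison_result", "data.frame"))
}

#' Per-time-point comparison of a treated/control series pair
#'
#' Applies [compare_groups()] at every shared time point.
#'
#' @param treated_series,control_series `marker_series` data frames for the
#'   two arms of one (cell line, signature).
#' @param alpha_normality Passed to [compare_groups()].
#' @return A data frame with one `comparison_result` row per time point.
#' @export
compare_series <- function(treated_series, control_series,
                           alpha_normality = .cscgp_defaults$stats$alpha_normality) {
  .validate_marker_series(treated_series)
  .validate_marker_series(control_series)
  times <- intersect(unique(treated_series$time_h),
                     unique(control_series$time_h))
  if (!length(times)) stop("series share no time points")
  rows <- lapply(sort(times), function(tt) {
    compare_groups(treated_series$percent[treated_series$time_h == tt],
                   control_series$percent[control_series$time_h == tt],
                   alpha_normality = alpha_normality, time_h = tt)
  })
  do.call(rbind, rows)
}
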