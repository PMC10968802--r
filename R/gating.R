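#' Gate specification: scatter gate plus per-channel positivity thresholds
#'
#' First-level gating retains events with `fsc >= fsc_min` (debris and dead
#' cells have lower forward scatter) and, when `ssc_max` is set,
#' `ssc <= ssc_max`. Second-level (quadrant/threshold) gating classifies a
#' channel as positive when its intensity is `>=` the channel threshold;
#' events exactly at a threshold count as positive.
#'
#' @param fsc_min Forward-scatter cut-off, `> 0` (0 disables the gate).
#' @param ssc_max Optional side-scatter upper cut-off (`NA` disables).
#' @param thresholds Named numeric vector of per-channel positivity
#'   thresholds (names among `cd24, cd44, aldh1, abcg2`), strictly positive.
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(fsc_min, ssc_max = NA_real_, thresholds = numeric()) {
  if (!is.numeric(fsc_min) || length(fsc_min) != 1L || fsc_min < 0)
    stop("`fsc_min` must be a single non-negative number")
  if (!is.na(ssc_max) && ssc_max <= 0)
    stop("`ssc_max` must be strictly positive when set")
  if (length(thresholds)) {
    if (is.null(names(thresholds)) ||
        !all(names(thresholds) %in% .marker_channels))
      stop("threshold names must be marker channels: ",
           paste(.marker_channels, collapse = ", "))
    if (any(thresholds <= 0)) stop("thresholds must be strictly positive")
  }
  structure(list(fsc_min = fsc_min, ssc_max = ssc_max,
                 thresholds = thresholds),
            class = "gate_spec")
}

#' Default gate for simulator-generated events
#'
#' Places the live gate and each channel threshold at the midpoint between
#' the simulated negative and positive cluster means on the log scale.
#'
#' @param config A [cytosim_config()] object.
#' @return A [gate_spec()].
#' @export
default_gate <- function(config) {
  stopifnot(inherits(config, "cytosim_config"))
  fsc_min <- exp((config$fsc_live_meanlog + config$fsc_dead_meanlog) / 2)
  thr <- exp((config$neg_meanlog + config$pos_meanlog) / 2)
  gate_spec(fsc_min = fsc_min,
            thresholds = setNames(rep(thr, length(.marker_channels)),
                                  .marker_channels))
}

#' Marker-signature query
#'
#' Parses the signature mini-language: comma-separated `NAME+` / `NAME-`
#' tokens, e.g. `"CD24-,CD44+"`. Unmentioned markers are ignored. At least
#' one marker must not be ignored.
#'
#' @param x Either a signature string (also accepted in the compact label
#'   form `"CD24-CD44+"`) or a named character vector/list mapping channel
#'   to `"positive"`, `"negative"` or `"ignored"`.
#' @return Named list over all channels with states
#'   `positive|negative|ignored`, of class `signature_query`.
#' @examples
#' signature_query("CD24-,CD44+")
#' signature_query("CD44+ABCG2+ALDH1+")
#' @export
signature_query <- function(x) {
  query <- setNames(as.list(rep("ignored", length(.marker_channels))),
                    .marker_channels)
  if (is.character(x) && is.null(names(x)) && length(x) == 1L) {
    tokens <- regmatches(x, gregexpr("[A-Za-z0-9]+[+-]", x))[[1]]
    if (!length(tokens) || nchar(gsub("[ ,]", "", x)) != sum(nchar(tokens)))
      stop("cannot parse signature string: ", x)
    for (tok in tokens) {
      ch <- tolower(sub("[+-]$", "", tok))
      ch <- sub("^aldh1a1$", "aldh1", ch)
      if (!ch %in% .marker_channels) stop("unknown marker in signature: ", tok)
      query[[ch]] <- if (grepl("\\+$", tok)) "positive" else "negative"
    }
  } else {
    x <- as.list(x)
    if (is.null(names(x)) || !all(tolower(names(x)) %in% .marker_channels))
      stop("named signature states must use marker channel names")
    for (ch in names(x)) {
      if (!x[[ch]] %in% c("positive", "negative", "ignored"))
        stop("signature states must be positive/negative/ignored")
      query[[tolower(ch)]] <- x[[ch]]
    }
  }
  if (all(unlist(query) == "ignored"))
    stop("signature query must constrain at least one marker")
  structure(query, class = "signature_query")
}

#' First-level live gate on scatter
#'
#' Retains exactly the events with `fsc >= fsc_min` and (when `ssc_max` is
#' set) `ssc <= ssc_max`; input order is preserved. Idempotent.
#'
#' @param events Event table with `fsc` and `ssc` columns.
#' @param gate A [gate_spec()].
#' @return The retained subset of `events`. An empty result is allowed but
#'   raised as a warning.
#' @export
live_gate <- function(events, gate) {
  stopifnot(inherits(gate, "gate_spec"))
  if (!all(c("fsc", "ssc") %in% names(events)))
    stop("event table must contain `fsc` and `ssc` columns")
  keep <- events$fsc >= gate$fsc_min
  if (!is.na(gate$ssc_max)) keep <- keep & events$ssc <= gate$ssc_max
  out <- events[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("live gate retained zero events")
  out
}

.positivity <- function(events, gate, channel) {
  thr <- gate$thresholds[[channel]]
  if (is.null(thr))
    stop("gate has no threshold for channel: ", channel)
  events[[channel]] >= thr
}

#' Percent of live-gated events matching a marker signature
#'
#' Quadrant statistic computed on the live gate only:
#' `100 * matching / live-gated`, with positivity defined as intensity
#' `>=` the channel threshold.
#'
#' @param events Event table.
#' @param query A [signature_query()] (or signature string).
#' @param gate A [gate_spec()] carrying thresholds for every queried channel.
#' @return Percent in `[0, 100]`.
#' @export
percent_positive <- function(events, query, gate) {
  if (is.character(query)) query <- signature_query(query)
  stopifnot(inherits(query, "signature_query"))
  live <- suppressWarnings(live_gate(events, gate))
  if (nrow(live) == 0L)
    stop("empty live gate: cannot compute percent positive",
         call. = FALSE)
  match <- rep(TRUE, nrow(live))
  for (ch in .marker_channels) {
    if (query[[ch]] == "ignored") next
    pos <- .positivity(live, gate, ch)
    match <- match & (if (query[[ch]] == "positive") pos else !pos)
  }
  100 * sum(match) / nrow(live)
}

#' Assemble a marker series from per-time-point event tables
#'
#' @param tables A list; each element is a list with fields `time_h`,
#'   `replicate` and `events` (an event table).
#' @param query A [signature_query()] (or signature string).
#' @param gate A [gate_spec()].
#' @param cell_line,signature Labels for the output series.
#' @param treatment `"treated"` or `"control"`.
#' @return A `marker_series` data frame, sorted by time then replicate;
#'   input order does not matter. Duplicate (time, replicate) keys error.
#' @export
series_from_events <- function(tables, query, gate,
                               cell_line = "unknown", signature = "unknown",
                               treatment = "treated") {
  if (is.character(query)) query <- signature_query(query)
  if (!length(tables)) stop("`tables` must be a non-empty list")
  key <- vapply(tables, function(tb) paste(tb$time_h, tb$replicate), character(1))
  if (anyDuplicated(key))
    stop("duplicate (time_h, replicate) keys in event tables")
  rows <- lapply(tables, function(tb) {
    data.frame(cell_line = cell_line, signature = signature,
               treatment = treatment, time_h = tb$time_h,
               replicate = tb$replicate,
               percent = percent_positive(tb$events, query, gate),
               stringsAsFactors = FALSE)
  })
  .new_marker_series(do.call(rbind, rows))
}
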