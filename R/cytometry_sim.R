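.marker_channels <- c("cd24", "cd44", "aldh1", "abcg2")

#' Configuration for the event-level flow-cytometry simulator
#'
#' Events are drawn from log-normal mixtures: live cells form a high-FSC
#' scatter cluster, dead cells/debris a low-FSC cluster with a wider SSC
#' spread (apoptotic granularity is modelled as increased spread, not a
#' separate cluster). Each live event is assigned one marker-state
#' combination according to `joint_probs`; channels in the positive state
#' draw fluorescence from the positive log-normal component, others from
#' the negative component.
#'
#' @param n_events Number of events to simulate, `>= 1`.
#' @param live_fraction Expected fraction of live events, in `[0, 1]`.
#' @param joint_probs Named numeric vector of probabilities over marker-state
#'   combinations; names are 4-character strings of `+`/`-` in channel order
#'   `cd24, cd44, aldh1, abcg2` (e.g. `"-+--"`). Must sum to 1.
#' @param seed Integer seed.
#' @param ... Overrides for the log-scale cluster locations/spreads (see
#'   names in the returned object).
#' @return An object of class `cytosim_config`.
#' @export
cytosim_config <- function(n_events = .cscgp_defaults$cytosim$n_events,
                           live_fraction = .cscgp_defaults$cytosim$live_fraction,
                           joint_probs = NULL,
                           seed = 1L, ...) {
  defaults <- .cscgp_defaults$cytosim
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    stop("unknown cytosim parameters: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, dots)
  cfg$n_events <- as.integer(n_events)
  cfg$live_fraction <- live_fraction
  cfg$seed <- as.integer(seed)
  if (cfg$n_events < 1L) stop("`n_events` must be >= 1")
  if (live_fraction < 0 || live_fraction > 1)
    stop("`live_fraction` must lie in [0, 1]")
  if (is.null(joint_probs))
    joint_probs <- independent_joint(cfg$background)
  .validate_joint(joint_probs)
  cfg$joint_probs <- joint_probs
  structure(cfg, class = "cytosim_config")
}

.all_combos <- function() {
  grid <- expand.grid(rep(list(c("-", "+")), length(.marker_channels)),
                      stringsAsFactors = FALSE)
  apply(grid, 1, paste0, collapse = "")
}

.validate_joint <- function(p) {
  if (is.null(names(p)) || !all(nchar(names(p)) == 4L) ||
      !all(grepl("^[+-]{4}$", names(p))))
    stop("joint_probs names must be 4-character +/- strings over (cd24, cd44, aldh1, abcg2)")
  if (anyDuplicated(names(p))) stop("duplicate combination names in joint_probs")
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
    stop("joint_probs must be probabilities summing to 1")
  invisible(p)
}

#' Joint marker-state distribution from independent per-marker positivity
#'
#' @param background Named vector of per-marker positivity probabilities
#'   (names `cd24, cd44, aldh1, abcg2`).
#' @return Named probability vector over all 16 `+`/`-` combinations.
#' @export
independent_joint <- function(background = .cscgp_defaults$cytosim$background) {
  stopifnot(all(.marker_channels %in% names(background)))
  combos <- .all_combos()
  p <- vapply(combos, function(cmb) {
    states <- strsplit(cmb, "")[[1]]
    prod(ifelse(states == "+", background[.marker_channels],
                1 - background[.marker_channels]))
  }, numeric(1))
  p / sum(p)
}

#' Joint distribution with a prescribed signature-positive fraction
#'
#' Rescales an independent background joint so that the total probability of
#' combinations satisfying `query` equals `p_signature` — used to simulate
#' event tables whose gated signature percentage has a known ground truth.
#'
#' @param query A [signature_query()] object.
#' @param p_signature Target probability of satisfying the signature, (0, 1).
#' @param background Per-marker background positivity.
#' @return Named probability vector over all 16 combinations.
#' @export
signature_joint <- function(query, p_signature,
                            background = .cscgp_defaults$cytosim$background) {
  stopifnot(p_signature > 0, p_signature < 1)
  p <- independent_joint(background)
  sat <- vapply(names(p), function(cmb) .combo_satisfies(cmb, query), logical(1))
  q <- sum(p[sat])
  if (q <= 0 || q >= 1) stop("signature must be satisfiable but not certain under background")
  p[sat] <- p[sat] * p_signature / q
  p[!sat] <- p[!sat] * (1 - p_signature) / (1 - q)
  p
}

.combo_satisfies <- function(combo, query) {
  states <- strsplit(combo, "")[[1]]
  names(states) <- .marker_channels
  for (ch in names(query)) {
    if (query[[ch]] == "ignored") next
    want <- if (query[[ch]] == "positive") "+" else "-"
    if (states[[ch]] != want) return(FALSE)
  }
  TRUE
}

#' Simulate a flow-cytometry event table
#'
#' @param config A [cytosim_config()] object.
#' @param with_truth Keep the hidden ground-truth label columns
#'   (`truth_live`, `truth_cd24`, ...) used for testing the gating module.
#' @return A data frame with columns `fsc, ssc, cd24, cd44, aldh1, abcg2`
#'   (all strictly positive intensities) and, if `with_truth`, the logical
#'   truth columns. Identical seeds give identical tables.
#' @export
simulate_events <- function(config, with_truth = TRUE) {
  stopifnot(inherits(config, "cytosim_config"))
  set.seed(config$seed)
  n <- config$n_events
  live <- runif(n) < config$live_fraction
  n_live <- sum(live)

  fsc <- numeric(n); ssc <- numeric(n)
  fsc[live] <- rlnorm(n_live, config$fsc_live_meanlog, config$fsc_live_sdlog)
  fsc[!live] <- rlnorm(n - n_live, config$fsc_dead_meanlog, config$fsc_dead_sdlog)
  ssc[live] <- rlnorm(n_live, config$ssc_live_meanlog, config$ssc_live_sdlog)
  ssc[!live] <- rlnorm(n - n_live, config$ssc_dead_meanlog, config$ssc_dead_sdlog)

  combos <- names(config$joint_probs)
  combo_idx <- integer(n)
  combo_idx[live] <- sample.int(length(combos), n_live, replace = TRUE,
                                prob = config$joint_probs)
  # dead events still emit fluorescence, drawn from background states
  bg_joint <- independent_joint(config$background)
  combo_idx[!live] <- sample.int(length(combos), n - n_live, replace = TRUE,
                                 prob = bg_joint[combos])

  state <- do.call(rbind, strsplit(combos[combo_idx], ""))
  colnames(state) <- .marker_channels
  events <- data.frame(fsc = fsc, ssc = ssc)
  for (ch in .marker_channels) {
    pos <- state[, ch] == "+"
    x <- numeric(n)
    x[pos] <- rlnorm(sum(pos), config$pos_meanlog, config$pos_sdlog)
    x[!pos] <- rlnorm(sum(!pos), config$neg_meanlog, config$neg_sdlog)
    events[[ch]] <- x
  }
  if (with_truth) {
    events$truth_live <- live
    for (ch in .marker_channels)
      events[[paste0("truth_", ch)]] <- state[, ch] == "+"
  }
  events
}

#' Write / read event-table CSV
#'
#' Normative format: header `fsc,ssc,cd24,cd44,aldh1,abcg2` plus optional
#' `truth_*` columns (emitted only when `with_truth = TRUE`).
#'
#' @param events An event table data frame.
#' @param path File path.
#' @param with_truth Include the ground-truth label columns if present.
#' @return `read_events` returns the data frame; `write_events` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path, with_truth = FALSE) {
  base <- c("fsc", "ssc", .marker_channels)
  missing <- setdiff(base, names(events))
  if (length(missing))
    stop("event table is missing columns: ", paste(missing, collapse = ", "))
  cols <- base
  if (with_truth) cols <- c(cols, grep("^truth_", names(events), value = TRUE))
  write.csv(events[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("fsc", "ssc", .marker_channels), names(df))
  if (length(missing))
    stop("event table is missing columns: ", paste(missing, collapse = ", "))
  df
}
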