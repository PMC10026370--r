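#' Replay evidence for one ordered state pair
#'
#' The replay-probability time course for transition i -> j at lag tau is
#' the element-wise product of state i's reactivation series with state
#' j's series shifted tau forward: `R_t = probs[t, i] * probs[t + tau, j]`.
#' The trailing tau samples are dropped, so the result has length T - tau.
#'
#' @param react A `reactivation` object from [decode_rest()].
#' @param pair Length-2 integer vector (i, j) of state indices; i may equal
#'   j (self-pairs are part of the 64-pair enumeration).
#' @param lag_ms Replay lag tau in ms; must be a multiple of the sample
#'   period.
#' @return Numeric evidence vector of length T - tau, entries in (0, 1).
#' @export
replay_evidence <- function(react, pair, lag_ms = 40) {
  stopifnot(inherits(react, "reactivation"), length(pair) == 2L)
  lag <- ms_to_samples(lag_ms, react$rate_hz, "replay lag")
  t_all <- nrow(react$probs)
  if (lag >= t_all) stop("lag exceeds session length")
  idx <- seq_len(t_all - lag)
  react$probs[idx, pair[1]] * react$probs[idx + lag, pair[2]]
}

#' Detect replay onsets by percentile thresholding
#'
#' The threshold is the transition- and session-specific 99th percentile
#' of the evidence series (linear interpolation between order statistics,
#' computed on the full series). Onsets are the samples whose evidence
#' strictly exceeds the threshold; every suprathreshold sample counts as
#' an onset unless `collapse_runs = TRUE`, in which case only the evidence
#' peak of each suprathreshold run is kept. Onsets too close to either
#' session edge to be epoched at `epoch_halfwidth_ms` are excluded.
#'
#' @param evidence Evidence vector from [replay_evidence()].
#' @param percentile Threshold percentile (default 99).
#' @param rate_hz Sampling rate.
#' @param epoch_halfwidth_ms Peri-event half-width used downstream; onsets
#'   whose window would overrun the session are dropped.
#' @param session_length Total session length in samples (defaults to
#'   `length(evidence)`; pass the un-truncated session length so the edge
#'   rule matches the epoching stage).
#' @param collapse_runs Keep only the per-run evidence peak.
#' @return List: `onsets` (1-based sample indices, strictly increasing),
#'   `threshold`, `n_raw` (suprathreshold count before edge exclusion).
#' @export
detect_onsets <- function(evidence, percentile = 99, rate_hz = 100,
                          epoch_halfwidth_ms = 500,
                          session_length = length(evidence),
                          collapse_runs = FALSE) {
  hw <- ms_to_samples(epoch_halfwidth_ms, rate_hz, "epoch half-width")
  if (length(evidence) <= 2L * hw)
    stop("length error: evidence series shorter than one epoch window")
  thr <- unname(stats::quantile(evidence, percentile / 100, type = 7))
  above <- which(evidence > thr)
  n_raw <- length(above)
  if (collapse_runs && n_raw) {
    runs <- cumsum(c(1L, diff(above) > 1L))
    above <- vapply(split(above, runs),
                    function(ix) ix[which.max(evidence[ix])], integer(1))
    above <- sort(unname(above))
  }
  keep <- above > hw & above + hw <= session_length
  list(onsets = above[keep], threshold = thr, n_raw = n_raw)
}

#' Build the full replay event set over all 64 ordered pairs
#'
#' @param react A `reactivation` object (8 state columns).
#' @param task A [task_structure()].
#' @param lag_ms Replay lag (ms).
#' @param percentile,epoch_halfwidth_ms,collapse_runs See [detect_onsets()].
#' @return Object of class `replay_events`: `pairs` (canonical 64-row pair
#'   table with per-pair `threshold` and `n_onsets`), `onsets` (list of
#'   onset vectors, one per pair, 1-based), `lag_ms`, `rate_hz`,
#'   `session_id`, `session_length`.
#' @export
detect_replay_events <- function(react, task = task_structure(),
                                 lag_ms = 40, percentile = 99,
                                 epoch_halfwidth_ms = 500,
                                 collapse_runs = FALSE) {
  pairs <- canonical_pairs(task)
  t_all <- nrow(react$probs)
  res <- lapply(seq_len(nrow(pairs)), function(r) {
    ev <- replay_evidence(react, c(pairs$from_idx[r], pairs$to_idx[r]),
                          lag_ms)
    detect_onsets(ev, percentile, react$rate_hz, epoch_halfwidth_ms,
                  session_length = t_all, collapse_runs = collapse_runs)
  })
  pairs$threshold <- vapply(res, `[[`, numeric(1), "threshold")
  pairs$n_onsets <- vapply(res, function(x) length(x$onsets), integer(1))
  structure(list(pairs = pairs, onsets = lapply(res, `[[`, "onsets"),
                 lag_ms = lag_ms, rate_hz = react$rate_hz,
                 session_id = react$session_id, session_length = t_all),
            class = "replay_events")
}

#' @export
print.replay_events <- function(x, ...) {
  cat(sprintf("<replay_events '%s': %d pairs, %d onsets, lag %g ms>\n",
              x$session_id, nrow(x$pairs), sum(x$pairs$n_onsets), x$lag_ms))
  invisible(x)
}

# forward / backward transition templates (8 x 8 0/1 matrices)
transition_templates <- function(task) {
  n <- task$n_states
  tf <- matrix(0, n, n)
  pairs <- canonical_pairs(task)
  inf <- pairs[pairs$inferred, ]
  tf[cbind(inf$from_idx, inf$to_idx)] <- 1
  list(forward = tf, backward = t(tf))
}

#' TDLM sequenceness across a grid of lags
#'
#' Temporally delayed linear modelling in two levels. First level: for
#' each lag, every state's reactivation series is regressed jointly onto
#' all states' lag-shifted series (plus an intercept), giving an empirical
#' 8 x 8 lagged-influence matrix. Second level: that matrix, vectorised,
#' is regressed onto the forward-transition template, the backward
#' template, the identity (self-transition control) and a constant;
#' the template coefficients are the forward and backward sequenceness at
#' that lag.
#'
#' @param react A `reactivation` object.
#' @param task A [task_structure()].
#' @param lags_ms Lag grid in ms (positive multiples of the sample period).
#' @return Object of class `sequenceness`: `lags_ms`, `forward`,
#'   `backward`, `contrast` (forward - backward).
#' @export
sequenceness <- function(react, task = task_structure(),
                         lags_ms = seq(10, 100, by = 10)) {
  stopifnot(inherits(react, "reactivation"))
  if (any(lags_ms <= 0)) stop("lags must be positive")
  tmpl <- transition_templates(task)
  n <- ncol(react$probs)
  d2 <- cbind(forward = as.vector(tmpl$forward),
              backward = as.vector(tmpl$backward),
              identity = as.vector(diag(n)),
              const = 1)
  fb <- vapply(lags_ms, function(lg) {
    lag <- ms_to_samples(lg, react$rate_hz, "sequenceness lag")
    t_all <- nrow(react$probs)
    x <- cbind(react$probs[seq_len(t_all - lag), , drop = FALSE], 1)
    y <- react$probs[(lag + 1L):t_all, , drop = FALSE]
    qx <- qr(x)
    if (qx$rank < ncol(x))
      stop("conditioning error: singular first-level design")
    beta <- qr.coef(qx, y)[seq_len(n), , drop = FALSE]  # 8 x 8, [i, j]: i -> j
    stats::lm.fit(d2, as.vector(beta))$coefficients[c("forward", "backward")]
  }, numeric(2))
  structure(list(lags_ms = lags_ms, forward = unname(fb[1, ]),
                 backward = unname(fb[2, ]),
                 contrast = unname(fb[1, ] - fb[2, ])),
            class = "sequenceness")
}

#' Replay strength: post- minus pre-learning forward sequenceness
#'
#' The covariate used to check that group differences in replay-network
#' coupling are not explained by replay per se: the change in forward
#' sequenceness at the replay lag from the pre- to the post-learning rest
#' session.
#'
#' @param post,pre `sequenceness` objects for the two rest sessions.
#' @param at_lag_ms Lag at which to read the forward coefficient
#'   (default 40 ms).
#' @return Scalar replay strength.
#' @export
replay_strength <- function(post, pre, at_lag_ms = 40) {
  stopifnot(inherits(post, "sequenceness"), inherits(pre, "sequenceness"))
  ip <- match(at_lag_ms, post$lags_ms)
  iq <- match(at_lag_ms, pre$lags_ms)
  if (is.na(ip) || is.na(iq)) stop("lag grid does not contain at_lag_ms")
  post$forward[ip] - pre$forward[iq]
}

#' Write replay events to TSV + JSON
#'
#' TSV rows are (from, to, onset_sample) with 0-based onsets; thresholds
#' and the lag go to a JSON side-car.
#'
#' @param events A `replay_events` object.
#' @param path Output TSV path.
#' @export
write_replay_events <- function(events, path) {
  rows <- do.call(rbind, lapply(seq_along(events$onsets), function(r) {
    if (!length(events$onsets[[r]])) return(NULL)
    data.frame(from = events$pairs$from[r], to = events$pairs$to[r],
               onset_sample = events$onsets[[r]] - 1L)
  }))
  if (is.null(rows))
    rows <- data.frame(from = character(), to = character(),
                       onset_sample = integer())
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(lag_ms = events$lag_ms, rate_hz = events$rate_hz,
         session_id = events$session_id,
         thresholds = stats::setNames(
           as.list(events$pairs$threshold),
           paste0(events$pairs$from, ">", events$pairs$to))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a sequenceness result to TSV
#' @param sq A `sequenceness` object.
#' @param path Output TSV path.
#' @export
write_sequenceness <- function(sq, path) {
  utils::write.table(
    data.frame(lag_ms = sq$lags_ms, forward = sq$forward,
               backward = sq$backward, contrast = sq$contrast),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
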