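#' Train one-vs-rest sparse logistic state classifiers
#'
#' For each task state, fits an L1-penalised logistic regression on the
#' sensor vector observed a fixed latency after each localizer trial onset
#' (a single time slice per trial). Negative examples are the other
#' states' trials plus, by default, an equal number of "null" samples
#' drawn from inter-trial intervals; null negatives shrink spatially
#' correlated false reactivations when the decoders are later applied to
#' rest data. Channels are z-scored with localizer statistics, and the
#' same transform is stored for application to rest sessions.
#'
#' @param localizer A [sensor_ts()] localizer recording.
#' @param trials Trial table (`onset` 0-based sample, `state_idx`).
#' @param time_ms Training latency after trial onset (ms). Default 180 ms,
#'   the group-level peak-decodability latency.
#' @param penalty L1 regularisation strength (glmnet lambda).
#' @param null_negatives Include inter-trial null samples as negatives.
#' @return Object of class `state_classifiers`: `weights`
#'   ((channels + 1) x n_states, intercept last), `time_ms`, `penalty`,
#'   `center`/`scale` (per-channel z-scoring), `n_states`.
#' @export
train_classifiers <- function(localizer, trials, time_ms = 180,
                              penalty = 0.01, null_negatives = TRUE) {
  stopifnot(inherits(localizer, "sensor_ts"))
  n_states <- max(trials$state_idx)
  counts <- tabulate(trials$state_idx, n_states)
  if (any(counts < 2L))
    stop("insufficient data: every state needs at least 2 trials")
  off <- ms_to_samples(time_ms, localizer$rate_hz, "training latency")
  cols <- trials$onset + off + 1L  # 0-based onset -> 1-based column
  if (any(cols < 1L) || any(cols > n_samples(localizer)))
    stop("training latency falls outside the session for some trials")
  feats <- t(localizer$data[, cols, drop = FALSE])  # trials x channels
  ctr <- colMeans(feats)
  scl <- apply(feats, 2, stats::sd)
  if (any(scl < 1e-12)) stop("conditioning error: constant channel features")
  feats <- scale(feats, ctr, scl)
  labels <- trials$state_idx

  if (null_negatives) {
    nulls <- null_sample_columns(localizer, trials, n = nrow(trials))
    null_feats <- scale(t(localizer$data[, nulls, drop = FALSE]), ctr, scl)
    feats <- rbind(feats, null_feats)
    labels <- c(labels, rep(0L, length(nulls)))
  }

  # fit along a short decreasing path ending at the target penalty
  # (glmnet converges more reliably warm-started than at a lone lambda)
  lam <- penalty * c(64, 16, 4, 1)
  w <- vapply(seq_len(n_states), function(s) {
    y <- as.integer(labels == s)
    fit <- glmnet::glmnet(feats, y, family = "binomial", alpha = 1,
                          lambda = lam, standardize = FALSE)
    cf <- as.numeric(glmnet::coef.glmnet(fit, s = penalty))
    c(cf[-1], cf[1])
  }, numeric(ncol(feats) + 1L))

  structure(list(weights = w, time_ms = time_ms, penalty = penalty,
                 center = ctr, scale = scl, n_states = n_states,
                 null_negatives = null_negatives),
            class = "state_classifiers")
}

# inter-trial samples at least one evoked window away from any onset
null_sample_columns <- function(localizer, trials, n) {
  total <- n_samples(localizer)
  guard <- as.integer(round(0.6 * localizer$rate_hz))  # 600 ms post-onset
  bad <- unique(unlist(lapply(trials$onset + 1L,
                              function(o) max(1L, o - 2L):min(total, o + guard))))
  free <- setdiff(seq_len(total), bad)
  if (length(free) < n)
    stop("not enough inter-trial samples for null negatives")
  sort(sample(free, n))
}

#' Select the training latency by cross-validated decodability
#'
#' Trains a family of classifiers at each candidate latency and evaluates
#' multi-class (argmax over one-vs-rest probabilities) accuracy with
#' stratified k-fold cross-validation, optionally pooled over several
#' localizer sessions. Returns the latency with the highest mean accuracy,
#' breaking ties towards the earlier latency.
#'
#' @param localizers A [sensor_ts()] or list of them.
#' @param trials Trial table or list matching `localizers`.
#' @param candidates_ms Candidate latencies (ms).
#' @param n_folds Cross-validation folds (>= 2).
#' @param penalty,null_negatives Passed to [train_classifiers()].
#' @return List: `time_ms` (selected latency), `accuracy` (mean CV accuracy
#'   per candidate), `candidates_ms`.
#' @export
select_training_time <- function(localizers, trials,
                                 candidates_ms = seq(100, 300, by = 40),
                                 n_folds = 5L, penalty = 0.01,
                                 null_negatives = FALSE) {
  if (length(candidates_ms) == 0L) stop("empty candidate latency set")
  if (n_folds < 2L) stop("need at least 2 folds")
  if (inherits(localizers, "sensor_ts")) {
    localizers <- list(localizers)
    trials <- list(trials)
  }
  acc <- vapply(candidates_ms, function(tm) {
    mean(mapply(function(loc, tr)
      cv_accuracy(loc, tr, tm, n_folds, penalty, null_negatives),
      localizers, trials))
  }, numeric(1))
  best <- which(acc == max(acc))[1L]  # ties -> earliest candidate
  list(time_ms = candidates_ms[best], accuracy = acc,
       candidates_ms = candidates_ms)
}

cv_accuracy <- function(localizer, trials, time_ms, n_folds, penalty,
                        null_negatives) {
  n <- nrow(trials)
  folds <- integer(n)
  for (s in unique(trials$state_idx)) {   # stratified fold assignment
    idx <- which(trials$state_idx == s)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  correct <- logical(n)
  for (f in seq_len(n_folds)) {
    hold <- folds == f
    clf <- train_classifiers(localizer, trials[!hold, , drop = FALSE],
                             time_ms = time_ms, penalty = penalty,
                             null_negatives = null_negatives)
    off <- ms_to_samples(time_ms, localizer$rate_hz)
    feats <- t(localizer$data[, trials$onset[hold] + off + 1L, drop = FALSE])
    p <- predict_probs(clf, feats)
    correct[hold] <- max.col(p, ties.method = "first") ==
      trials$state_idx[hold]
  }
  mean(correct)
}

predict_probs <- function(clf, feats) {
  z <- scale(feats, clf$center, clf$scale)
  nch <- length(clf$center)
  stats::plogis(z %*% clf$weights[seq_len(nch), , drop = FALSE] +
                  rep(1, nrow(z)) %o% clf$weights[nch + 1L, ])
}

#' Decode state-reactivation probabilities in rest data
#'
#' Applies the trained one-vs-rest classifiers sample-by-sample:
#' `probs[t, s] = sigmoid(beta_s . [x_t; 1])` after z-scoring each channel
#' with the localizer statistics stored in the classifier object. No
#' temporal smoothing is applied.
#'
#' @param rest A [sensor_ts()] rest recording (same channel count as
#'   training).
#' @param classifiers A `state_classifiers` object.
#' @return Object of class `reactivation`: `probs` (time x n_states, each
#'   entry strictly in (0, 1)), `rate_hz`, `session_id`.
#' @export
decode_rest <- function(rest, classifiers) {
  stopifnot(inherits(rest, "sensor_ts"),
            inherits(classifiers, "state_classifiers"))
  if (n_channels(rest) != length(classifiers$center))
    stop("shape error: rest channel count does not match training")
  probs <- predict_probs(classifiers, t(rest$data))
  structure(list(probs = unname(probs), rate_hz = rest$rate_hz,
                 session_id = rest$session_id),
            class = "reactivation")
}

#' @export
print.reactivation <- function(x, ...) {
  cat(sprintf("<reactivation '%s': %d samples x %d states @ %g Hz>\n",
              x$session_id, nrow(x$probs), ncol(x$probs), x$rate_hz))
  invisible(x)
}

#' Serialize classifiers to JSON
#'
#' @param clf A `state_classifiers` object.
#' @param path Output path.
#' @return `path`, invisibly; `read_classifiers_json` returns the object.
#' @export
write_classifiers_json <- function(clf, path) {
  jsonlite::write_json(
    list(weights = clf$weights, time_ms = clf$time_ms,
         penalty = clf$penalty, center = clf$center, scale = clf$scale,
         n_states = clf$n_states, null_negatives = clf$null_negatives),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_classifiers_json
#' @export
read_classifiers_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = matrix(x$weights, ncol = x$n_states),
                 time_ms = x$time_ms, penalty = x$penalty,
                 center = x$center, scale = x$scale,
                 n_states = x$n_states,
                 null_negatives = x$null_negatives),
            class = "state_classifiers")
}
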