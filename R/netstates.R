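#' Network-state activation time courses
#'
#' Container for per-sample posterior (or ground-truth) probabilities over
#' K latent network states.
#'
#' @param probs time x K matrix. If not centred, rows sum to 1 and entries
#'   lie in \[0, 1\]; after [centre_columns()] every column has mean 0.
#' @param rate_hz Sampling rate.
#' @param session_id Session label.
#' @param centred Whether columns have been mean-centred.
#' @return Object of class `state_activation`.
#' @export
state_activation <- function(probs, rate_hz, session_id = "session",
                             centred = FALSE) {
  probs <- as.matrix(probs)
  if (!centred) {
    if (any(probs < -1e-8) || any(probs > 1 + 1e-8))
      stop("uncentred activation probabilities must lie in [0, 1]")
    if (max(abs(rowSums(probs) - 1)) > 1e-6)
      stop("uncentred activation rows must sum to 1")
  }
  structure(list(probs = unname(probs), rate_hz = rate_hz,
                 session_id = as.character(session_id), centred = centred),
            class = "state_activation")
}

#' @export
print.state_activation <- function(x, ...) {
  cat(sprintf("<state_activation '%s': %d samples x %d states%s>\n",
              x$session_id, nrow(x$probs), ncol(x$probs),
              if (x$centred) ", centred" else ""))
  invisible(x)
}

#' Mean-centre the columns of a state-activation matrix
#'
#' Per-session column centring applied before any evoked analysis, so that
#' epoched responses measure activation relative to the session mean.
#'
#' @param sa A `state_activation` object (not already centred).
#' @return The centred `state_activation`.
#' @export
centre_columns <- function(sa) {
  stopifnot(inherits(sa, "state_activation"))
  if (sa$centred) stop("state error: activation is already centred")
  sa$probs <- sweep(sa$probs, 2, colMeans(sa$probs))
  sa$centred <- TRUE
  sa
}

#' Time-delay embedding of a sensor recording
#'
#' Augments each sample with lagged copies of every channel: column
#' (c, l) at output row t holds channel c at input time t + l. Edge rows
#' that would index outside the recording are trimmed, so the output has
#' `T - (max(lags) - min(lags))` rows. Columns are ordered lag-major
#' within channel: (c1,l1), (c1,l2), ..., (c2,l1), ...
#'
#' @param ts A [sensor_ts()] or a channels x time matrix.
#' @param lags Integer lag set in samples (e.g. `-7:7`).
#' @return time x (channels * length(lags)) embedded matrix, with
#'   attribute `lead` (number of leading input samples trimmed).
#' @export
tde_embed <- function(ts, lags) {
  x <- if (inherits(ts, "sensor_ts")) ts$data else as.matrix(ts)
  lags <- as.integer(sort(lags))
  if (!length(lags)) stop("need at least one lag")
  t_all <- ncol(x)
  lead <- max(0L, -min(lags))
  tail <- max(0L, max(lags))
  n <- t_all - lead - tail
  if (n < 1L) stop("length error: lag span is not shorter than the session")
  out <- matrix(0, n, nrow(x) * length(lags))
  col <- 0L
  for (c in seq_len(nrow(x))) {
    for (l in lags) {
      col <- col + 1L
      out[, col] <- x[c, (lead + 1L + l):(lead + n + l)]
    }
  }
  attr(out, "lead") <- lead
  attr(out, "lags") <- lags
  out
}

# per-sample log-density under each state's zero-mean Gaussian
gauss_logliks <- function(x, covs) {
  d <- ncol(x)
  vapply(covs, function(C) {
    R <- chol(C)
    y <- x %*% backsolve(R, diag(d))
    -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) + rowSums(y^2))
  }, numeric(nrow(x)))
}

# scaled forward-backward (compiled); logB: T x K log observation densities
forward_backward <- function(logB, P, pi0) {
  .fb_core(logB, as.matrix(P), as.numeric(pi0))
}

prepare_embedded <- function(ts, model) {
  emb <- tde_embed(ts, model$lags)
  x <- sweep(emb, 2, model$mu)
  if (!is.null(model$basis)) x <- x %*% model$basis
  if (!is.null(model$sds)) x <- sweep(x, 2, model$sds, "/")
  attr(x, "lead") <- attr(emb, "lead")
  x
}

#' Fit a time-delay-embedded hidden Markov model
#'
#' The TDE-HMM observation model: each latent network state is a zero-mean
#' multivariate Gaussian over the time-delay-embedded (optionally
#' PCA-reduced and standardised) signal, so a state's covariance captures
#' both the spatial and the spectral signature of a network. Fitting is
#' EM (scaled forward-backward E-step; closed-form covariance and
#' transition updates), restarted `n_restarts` times from seeded random
#' responsibilities; the restart with the highest final log-likelihood is
#' returned.
#'
#' @param sessions A [sensor_ts()] or list of them (the reference data
#'   set, in the two-step scheme).
#' @param K Number of latent states (default 12).
#' @param lags Embedding lags in samples (default `-7:7`).
#' @param n_pcs Reduced dimensionality after PCA of the embedded signal.
#'   `NULL` (default) uses `min(2 * channels, 48)`; `0` disables the PCA
#'   rotation entirely.
#' @param n_restarts EM restarts.
#' @param seed Integer seed.
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @param standardize Standardise reduced columns to unit variance.
#' @return Object of class `hmm_model`: `K`, `lags`, `mu`, `basis`,
#'   `sds`, `covs` (list of K covariance matrices), `P` (transition
#'   matrix), `pi0`, `loglik` (per-iteration trace of the best restart),
#'   `converged`.
#' @export
fit_hmm <- function(sessions, K = 12L, lags = -7:7, n_pcs = NULL,
                    n_restarts = 2L, seed = 1L, max_iter = 50L,
                    tol = 1e-5, standardize = TRUE) {
  if (K < 1L) stop("K must be at least 1")
  if (inherits(sessions, "sensor_ts")) sessions <- list(sessions)
  nch <- n_channels(sessions[[1]])
  emb <- lapply(sessions, tde_embed, lags = lags)
  mu <- colMeans(do.call(rbind, emb))
  xs <- lapply(emb, function(e) sweep(e, 2, mu))
  basis <- NULL
  if (is.null(n_pcs)) n_pcs <- min(2L * nch, 48L)
  if (n_pcs > 0L && n_pcs < ncol(xs[[1]])) {
    cc <- crossprod(do.call(rbind, xs)) / (sum(vapply(xs, nrow, 1L)) - 1)
    basis <- eigen(cc, symmetric = TRUE)$vectors[, seq_len(n_pcs),
                                                 drop = FALSE]
    xs <- lapply(xs, function(x) x %*% basis)
  }
  sds <- NULL
  if (standardize) {
    sds <- apply(do.call(rbind, xs), 2, stats::sd)
    xs <- lapply(xs, function(x) sweep(x, 2, sds, "/"))
  }
  d <- ncol(xs[[1]])
  total <- sum(vapply(xs, nrow, 1L))
  if (total < 10L * K * d)
    stop(sprintf("reference data too short: need >= %d samples", 10 * K * d))

  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- em_run(xs, K, d, max_iter, tol)
    if (is.null(best) || utils::tail(fit$loglik, 1) >
        utils::tail(best$loglik, 1)) best <- fit
  }
  if (!best$converged)
    warning("EM did not converge within max_iter; returning best fit so far")
  structure(list(K = K, lags = as.integer(sort(lags)), mu = mu,
                 basis = basis, sds = sds, covs = best$covs, P = best$P,
                 pi0 = best$pi0, loglik = best$loglik,
                 converged = best$converged, n_channels = nch),
            class = "hmm_model")
}

em_run <- function(xs, K, d, max_iter, tol) {
  # init: randomly weighted covariances with a random scale perturbation,
  # sticky transitions, uniform initial distribution
  x_all <- do.call(rbind, xs)
  covs <- lapply(seq_len(K), function(k) {
    g <- stats::rexp(nrow(x_all))
    (crossprod(x_all * sqrt(g / sum(g))) + diag(1e-6, d)) *
      stats::runif(1, 0.7, 1.4)
  })
  P <- matrix(if (K > 1) 0.1 / (K - 1) else 0, K, K)
  diag(P) <- if (K > 1) 0.9 else 1
  pi0 <- rep(1 / K, K)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e <- lapply(xs, function(x) forward_backward(gauss_logliks(x, covs),
                                                 P, pi0))
    ll <- sum(vapply(e, `[[`, numeric(1), "loglik"))
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) <
        tol * (abs(ll_trace[it - 1]) + 1)) {
      converged <- TRUE
      break
    }
    gam_all <- do.call(rbind, lapply(e, `[[`, "gamma"))
    covs <- lapply(seq_len(K), function(k) {
      g <- gam_all[, k]
      crossprod(x_all * sqrt(g)) / sum(g) + diag(1e-6, d)
    })
    xi <- Reduce(`+`, lapply(e, `[[`, "xi_sum"))
    P <- xi / rowSums(xi)
    pi0 <- rowMeans(matrix(vapply(e, function(z) z$gamma[1, ],
                                  numeric(K)), nrow = K))
  }
  list(covs = covs, P = P, pi0 = pi0, loglik = ll_trace,
       converged = converged)
}

#' Infer state activation with frozen observation models
#'
#' The second step of the two-step scheme: embeds and projects a study
#' session with the model's stored basis and runs forward-backward with
#' the observation models (and, by default, the transition matrix) frozen
#' at their reference-fitted values. Posteriors at the edge samples
#' trimmed by the embedding are padded by repeating the nearest inferred
#' row, so the output aligns sample-for-sample with the input.
#'
#' @param model A fitted [fit_hmm()] model.
#' @param ts A [sensor_ts()] study session (same channel count).
#' @param reestimate_transitions Re-estimate the transition matrix on this
#'   session (EM over P only) before the final posterior pass.
#' @return A `state_activation` with time x K posterior probabilities.
#' @export
infer_states <- function(model, ts, reestimate_transitions = FALSE) {
  stopifnot(inherits(model, "hmm_model"), inherits(ts, "sensor_ts"))
  if (n_channels(ts) != model$n_channels)
    stop("shape error: channel count does not match the fitted model")
  x <- prepare_embedded(ts, model)
  logB <- gauss_logliks(x, model$covs)
  P <- model$P
  if (reestimate_transitions && model$K > 1L) {
    for (it in 1:20) {
      e <- forward_backward(logB, P, model$pi0)
      newP <- e$xi_sum / rowSums(e$xi_sum)
      if (max(abs(newP - P)) < 1e-8) break
      P <- newP
    }
  }
  e <- forward_backward(logB, P, model$pi0)
  lead <- attr(x, "lead")
  t_all <- n_samples(ts)
  pad_head <- lead
  pad_tail <- t_all - lead - nrow(e$gamma)
  probs <- rbind(
    e$gamma[rep(1L, pad_head), , drop = FALSE],
    e$gamma,
    e$gamma[rep(nrow(e$gamma), pad_tail), , drop = FALSE])
  state_activation(probs, ts$rate_hz, ts$session_id)
}

#' Identify the DMN-like state of a fitted model
#'
#' @param sa Inferred `state_activation` for a session (used by
#'   `by_ground_truth`).
#' @param mode One of `"by_ground_truth"` (synthetic data: the state whose
#'   inferred activation correlates maximally with the generator's DMN
#'   occupancy), `"by_index"` (pass-through), `"by_power_profile"`
#'   (per-state sensor power aggregated over a channel-to-region map;
#'   for real recordings).
#' @param reference For `by_ground_truth`: the ground-truth DMN occupancy
#'   vector (or a `state_activation` plus `true_dmn`). For `by_index`:
#'   the index itself.
#' @param true_dmn Column of `reference` holding the DMN occupancy, when
#'   `reference` is a matrix or `state_activation`.
#' @param model,channel_regions,target_regions For `by_power_profile`: a
#'   fitted `hmm_model`, a character region label per channel, and the
#'   region labels defining the DMN.
#' @return The 1-based index of the DMN-like state, with attribute
#'   `correlation` where applicable.
#' @export
identify_dmn <- function(sa = NULL,
                         mode = c("by_ground_truth", "by_index",
                                  "by_power_profile"),
                         reference = NULL, true_dmn = NULL,
                         model = NULL, channel_regions = NULL,
                         target_regions = NULL) {
  mode <- match.arg(mode)
  if (mode == "by_index") return(as.integer(reference))
  if (mode == "by_ground_truth") {
    stopifnot(inherits(sa, "state_activation"))
    ref <- reference
    if (inherits(ref, "state_activation")) ref <- ref$probs
    if (is.matrix(ref)) {
      stopifnot(!is.null(true_dmn))
      ref <- ref[, true_dmn]
    }
    stopifnot(length(ref) == nrow(sa$probs))
    cors <- suppressWarnings(as.numeric(stats::cor(sa$probs, ref)))
    cors[is.na(cors)] <- -Inf
    ord <- order(cors, decreasing = TRUE)
    if (length(cors) > 1 && cors[ord[1]] - cors[ord[2]] < 1e-6)
      stop("tie error: two states match the reference equally well")
    return(structure(ord[1], correlation = cors[ord[1]]))
  }
  # by_power_profile: relative embedded-signal power of the target region
  stopifnot(inherits(model, "hmm_model"),
            length(channel_regions) == model$n_channels)
  nl <- length(model$lags)
  target <- channel_regions %in% target_regions
  if (!any(target)) stop("no channels map onto the target regions")
  score <- vapply(model$covs, function(C) {
    if (!is.null(model$sds)) C <- C * tcrossprod(model$sds)
    if (!is.null(model$basis)) {
      pw <- rowSums((model$basis %*% C) * model$basis)
    } else pw <- diag(C)
    ch_pow <- rowSums(matrix(pw, nrow = model$n_channels, byrow = TRUE))
    mean(ch_pow[target]) / mean(ch_pow)
  }, numeric(1))
  which.max(score)
}

#' Summarise the dynamics of a state-activation time course
#'
#' Computed from the per-sample argmax path of the (uncentred) posterior:
#' fractional occupancy, mean state lifetime, mean inter-visit interval
#' and the overall switch rate.
#'
#' @param sa An uncentred `state_activation`.
#' @return Object of class `dynamics_summary`: `fractional_occupancy`,
#'   `mean_lifetime_ms`, `mean_interval_ms` (NA for unvisited or
#'   single-visit states), `switch_rate_hz`.
#' @export
summarize_dynamics <- function(sa) {
  stopifnot(inherits(sa, "state_activation"))
  if (sa$centred) stop("state error: dynamics need uncentred probabilities")
  path <- max.col(sa$probs, ties.method = "first")
  K <- ncol(sa$probs)
  ms_per <- 1000 / sa$rate_hz
  r <- rle(path)
  fo <- tabulate(path, K) / length(path)
  life <- rep(NA_real_, K)
  intv <- rep(NA_real_, K)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_len(K)) {
    runs <- which(r$values == k)
    if (length(runs)) life[k] <- mean(r$lengths[runs]) * ms_per
    if (length(runs) > 1L)
      intv[k] <- mean(starts[runs][-1] - ends[runs][-length(runs)] - 1L) *
        ms_per
  }
  structure(list(fractional_occupancy = fo, mean_lifetime_ms = life,
                 mean_interval_ms = intv,
                 switch_rate_hz = sum(diff(path) != 0) /
                   (length(path) / sa$rate_hz)),
            class = "dynamics_summary")
}

#' State-masked Welch power spectra
#'
#' Averages single-channel periodograms over fixed-length segments that
#' fall entirely within contiguous runs of each state's argmax path.
#' Reported as a diagnostic; not consumed downstream.
#'
#' @param ts The [sensor_ts()] the activation was inferred from.
#' @param sa The matching uncentred `state_activation`.
#' @param seg_s Segment length in seconds.
#' @return List with `freq_hz` and `power` (states x frequency matrix of
#'   channel-mean power; NA rows for states with no long-enough run).
#' @export
state_spectra <- function(ts, sa, seg_s = 1) {
  stopifnot(inherits(ts, "sensor_ts"), inherits(sa, "state_activation"))
  path <- max.col(sa$probs, ties.method = "first")
  nseg <- as.integer(round(seg_s * ts$rate_hz))
  freqs <- seq_len(nseg %/% 2) * ts$rate_hz / nseg
  K <- ncol(sa$probs)
  pw <- matrix(NA_real_, K, length(freqs))
  r <- rle(path)
  ends <- cumsum(r$lengths)
  for (k in seq_len(K)) {
    segs <- list()
    for (j in which(r$values == k & r$lengths >= nseg)) {
      s0 <- ends[j] - r$lengths[j] + 1L
      n_fit <- r$lengths[j] %/% nseg
      for (i in seq_len(n_fit))
        segs[[length(segs) + 1L]] <- s0 + (i - 1L) * nseg + 0:(nseg - 1L)
    }
    if (!length(segs)) next
    acc <- numeric(length(freqs))
    for (idx in segs) {
      seg <- ts$data[, idx, drop = FALSE]
      f <- Mod(stats::mvfft(t(seg)))^2 / nseg
      acc <- acc + rowMeans(f[2:(length(freqs) + 1L), , drop = FALSE])
    }
    pw[k, ] <- acc / length(segs)
  }
  list(freq_hz = freqs, power = pw)
}

#' Serialize a fitted HMM to JSON
#' @param model An `hmm_model`.
#' @param path Output path.
#' @export
write_hmm_json <- function(model, path) {
  jsonlite::write_json(
    list(K = model$K, lags = model$lags, mu = model$mu,
         basis = model$basis, sds = model$sds, covs = model$covs,
         P = model$P, pi0 = model$pi0, n_channels = model$n_channels),
    path, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) if (is.null(m)) NULL else as.matrix(m)
  covs <- if (is.array(x$covs) && length(dim(x$covs)) == 3L) {
    lapply(seq_len(x$K), function(k) x$covs[k, , ])
  } else {
    lapply(seq_len(x$K), function(k) as.matrix(x$covs[[k]]))
  }
  structure(list(K = x$K, lags = x$lags, mu = x$mu,
                 basis = as_mat(x$basis), sds = x$sds,
                 covs = covs,
                 P = as.matrix(x$P), pi0 = x$pi0,
                 loglik = NULL, converged = NA,
                 n_channels = x$n_channels),
            class = "hmm_model")
}

#' Write a state-activation matrix / dynamics summary to TSV
#' @param sa A `state_activation`.
#' @param path Output path.
#' @export
write_state_activation <- function(sa, path) {
  utils::write.table(sa$probs, path, sep = "\t", row.names = FALSE,
                     col.names = paste0("state", seq_len(ncol(sa$probs))))
  invisible(path)
}

#' @rdname write_state_activation
#' @param dyn A `dynamics_summary`.
#' @export
write_dynamics <- function(dyn, path) {
  utils::write.table(
    data.frame(state = seq_along(dyn$fractional_occupancy),
               fractional_occupancy = dyn$fractional_occupancy,
               mean_lifetime_ms = dyn$mean_lifetime_ms,
               mean_interval_ms = dyn$mean_interval_ms),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
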