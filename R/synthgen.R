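#' Configuration for the synthetic MEG cohort generator
#'
#' Bundles every knob of the generative model: sensor geometry, sampling
#' rate, replay-event schedule, network-state Markov chain, and the planted
#' coupling between task-relevant replay onsets and the DMN-like network
#' state. Identical configurations (including `seed`) produce bit-identical
#' sessions.
#'
#' Defaults encode the study conditions emulated throughout the package:
#' an analysis-rate recording at 100 Hz so the 40 ms replay lag is exactly
#' 4 samples; 8 task states; 12 network states with one DMN-like state;
#' replay events scheduled on all 64 ordered state pairs; and a
#' raised-cosine coupling profile that peaks at replay onset (the evoked
#' coupling reported in this literature is a transient locked to onset, not
#' a plateau).
#'
#' @param n_channels Number of sensor channels.
#' @param rate_hz Sampling rate (samples/s).
#' @param session_length_s Rest-session duration in seconds.
#' @param n_states Number of task states (8).
#' @param replay_lag_ms Replay lag tau in ms; must be a multiple of the
#'   sample period. Default 40 ms.
#' @param n_replay_events_per_pair Planted replay events per ordered pair.
#' @param pattern_snr Peak amplitude of each state pattern relative to
#'   unit-variance channel noise.
#' @param n_network_states Number of latent network states K.
#' @param dmn_index Index (1-based) of the DMN-like network state.
#' @param coupling_amplitude Peak increase in DMN occupancy probability
#'   around task-relevant replay onsets (POST sessions only).
#' @param coupling_window_ms Half-width of the coupling window.
#' @param coupling_shape `"hann"` (raised cosine peaking at onset; default)
#'   or `"boxcar"` (constant boost across the window).
#' @param baseline_coupling Non-specific coupling amplitude applied to all
#'   64 pairs equally, in both sessions. Default 0.
#' @param session `"PRE"` or `"POST"`. PRE forces the task-relevant
#'   coupling amplitude to zero.
#' @param group_effect Multiplier on `coupling_amplitude` (e.g. 1 for a
#'   control-like participant, 0 for a patient-like participant).
#' @param event_pairs Which ordered pairs receive planted events: `"all"`
#'   (64 pairs), `"forward"` (the 6 structural adjacencies), `"backward"`
#'   (their 6 reversals), `"both"` (12), or a data frame with columns
#'   `from_idx`, `to_idx`.
#' @param trials_per_state Localizer trials per state.
#' @param iti_ms Localizer inter-trial interval.
#' @param evoked_peak_ms Latency of the peak of the simulated
#'   stimulus-evoked response. Default 180 ms.
#' @param evoked_dur_ms Duration of the evoked response (half-sine from 0
#'   to `evoked_dur_ms`, peaking at `evoked_dur_ms / 2`).
#' @param stimulus_dmn_deactivation Peak reduction of DMN occupancy in the
#'   0-500 ms post-stimulus window of localizer trials.
#' @param state_var Variance of the network-state-specific sensor signal
#'   (per factor, on top of unit channel noise).
#' @param net_rank Rank of each network state's spatial signature.
#' @param factor_ar AR(1) coefficient of the state factors; gives each
#'   network state a temporally structured (band-limited) signature.
#' @param dwell_ms Mean dwell time of the network-state Markov chain.
#' @param soft_eps Softness of the ground-truth state-activation law:
#'   occupancy probability is `(1 - soft_eps)` for the current chain state
#'   and `soft_eps / K` elsewhere, leaving headroom for the planted boost.
#' @param dmn_visit_ms Mean duration of the DMN visits inserted to realize
#'   the planted coupling in the sampled state path.
#' @param ar_coef Optional AR(1) coefficient applied to the channel noise.
#' @param network_seed Seed for the network states' spatial signatures.
#'   Kept fixed across a cohort so every participant expresses the same
#'   networks (as real resting-state networks are shared across brains)
#'   and one reference-fitted model transfers to all sessions.
#' @param seed Integer seed for everything session-specific.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 64L,
                         rate_hz = 100,
                         session_length_s = 120,
                         n_states = 8L,
                         replay_lag_ms = 40,
                         n_replay_events_per_pair = 5L,
                         pattern_snr = 5,
                         n_network_states = 12L,
                         dmn_index = 2L,
                         coupling_amplitude = 0.1,
                         coupling_window_ms = 100,
                         coupling_shape = c("hann", "boxcar"),
                         baseline_coupling = 0,
                         session = c("POST", "PRE"),
                         group_effect = 1,
                         event_pairs = "all",
                         trials_per_state = 20L,
                         iti_ms = 1000,
                         evoked_peak_ms = 180,
                         evoked_dur_ms = 360,
                         stimulus_dmn_deactivation = 0.05,
                         state_var = 6,
                         net_rank = 2L,
                         factor_ar = 0.7,
                         dwell_ms = 200,
                         soft_eps = 0.15,
                         dmn_visit_ms = 30,
                         ar_coef = 0,
                         network_seed = 1000L,
                         seed = 1L) {
  cfg <- list(n_channels = as.integer(n_channels), rate_hz = rate_hz,
              session_length_s = session_length_s,
              n_states = as.integer(n_states),
              replay_lag_ms = replay_lag_ms,
              n_replay_events_per_pair = as.integer(n_replay_events_per_pair),
              pattern_snr = pattern_snr,
              n_network_states = as.integer(n_network_states),
              dmn_index = as.integer(dmn_index),
              coupling_amplitude = coupling_amplitude,
              coupling_window_ms = coupling_window_ms,
              coupling_shape = match.arg(coupling_shape),
              baseline_coupling = baseline_coupling,
              session = match.arg(session),
              group_effect = group_effect,
              event_pairs = event_pairs,
              trials_per_state = as.integer(trials_per_state),
              iti_ms = iti_ms,
              evoked_peak_ms = evoked_peak_ms,
              evoked_dur_ms = evoked_dur_ms,
              stimulus_dmn_deactivation = stimulus_dmn_deactivation,
              state_var = state_var, net_rank = as.integer(net_rank),
              factor_ar = factor_ar,
              dwell_ms = dwell_ms, soft_eps = soft_eps,
              dmn_visit_ms = dmn_visit_ms, ar_coef = ar_coef,
              network_seed = as.integer(network_seed),
              seed = as.integer(seed))
  if (cfg$rate_hz <= 0) stop("rate_hz must be positive")
  ms_to_samples(cfg$replay_lag_ms, cfg$rate_hz, "replay lag")
  if (cfg$coupling_amplitude < 0) stop("coupling_amplitude must be >= 0")
  if (cfg$dmn_index > cfg$n_network_states)
    stop("dmn_index must not exceed n_network_states")
  class(cfg) <- "synth_config"
  cfg
}

#' Random unit-norm sensor patterns for the task states
#'
#' Draws isotropic Gaussian channel patterns, optionally pushed towards an
#' orthonormal set, and scales every row to unit norm. These stand in for
#' the visually evoked sensor topographies a localizer elicits.
#'
#' @param n_states Number of task states.
#' @param n_channels Number of channels; must be >= `n_states` for the
#'   states to be linearly separable.
#' @param seed Integer seed.
#' @param orthonormal_frac In \[0, 1\]: 0 keeps the raw isotropic draws,
#'   1 returns exactly orthogonal rows; intermediate values interpolate
#'   before renormalising.
#' @return `n_states` x `n_channels` matrix with unit-norm rows.
#' @export
make_patterns <- function(n_states, n_channels, seed = 1L,
                          orthonormal_frac = 0) {
  if (n_channels < n_states)
    stop("infeasible separability: n_channels must be >= n_states")
  stopifnot(orthonormal_frac >= 0, orthonormal_frac <= 1)
  set.seed(seed)
  raw <- matrix(stats::rnorm(n_states * n_channels), n_states, n_channels)
  unit <- raw / sqrt(rowSums(raw^2))
  if (orthonormal_frac > 0) {
    q <- t(qr.Q(qr(t(raw)))[, seq_len(n_states), drop = FALSE])
    # qr.Q can flip signs relative to the raw rows; align before blending
    sgn <- sign(rowSums(q * unit))
    sgn[sgn == 0] <- 1
    q <- q * sgn
    blend <- (1 - orthonormal_frac) * unit + orthonormal_frac * q
    blend / sqrt(rowSums(blend^2))
  } else {
    unit
  }
}

# half-sine pulse kernel of ~20 ms support, unit peak
pulse_kernel <- function(rate_hz, width_ms = 20) {
  len <- max(1L, as.integer(round(width_ms * rate_hz / 1000)) + 1L)
  k <- sin(pi * seq_len(len) / (len + 1))
  k / max(k)
}

# coupling boost profile over offsets -w..w (samples), unit peak at 0
coupling_profile <- function(w, shape) {
  off <- -w:w
  if (shape == "hann") 0.5 * (1 + cos(pi * off / (w + 1))) else rep(1, 2 * w + 1)
}

# first-order Markov chain with uniform stationary distribution and mean
# dwell time `dwell` samples
simulate_chain <- function(n, K, dwell) {
  p_stay <- max(0, 1 - 1 / dwell)
  path <- integer(n)
  path[1] <- sample.int(K, 1L)
  u <- stats::runif(n)
  switches <- u > p_stay
  for (t in 2:n) {
    if (switches[t]) {
      s <- sample.int(K - 1L, 1L)
      path[t] <- if (s >= path[t - 1]) s + 1L else s
    } else path[t] <- path[t - 1]
  }
  path
}

# one-hot softened occupancy law: (1 - eps) on the chain state, eps/K off
soft_activation <- function(path, K, eps) {
  n <- length(path)
  probs <- matrix(eps / K, n, K)
  probs[cbind(seq_len(n), path)] <- probs[cbind(seq_len(n), path)] + (1 - eps)
  probs
}

# add `boost` to column dmn at row t, rescaling the other columns so the
# row still sums to one; the DMN increment is exact (boost pre-capped)
apply_dmn_boost <- function(probs, rows, boost, dmn) {
  p_dmn <- probs[rows, dmn]
  new_dmn <- pmin(p_dmn + boost, 1 - 1e-9)
  scale <- (1 - new_dmn) / (1 - p_dmn)
  probs[rows, ] <- probs[rows, , drop = FALSE] * scale
  probs[rows, dmn] <- new_dmn
  probs
}

# random orthonormal spatial signatures, `rank` directions per network state
network_loadings <- function(n_channels, K, rank) {
  need <- K * rank
  stopifnot(need <= n_channels)
  q <- qr.Q(qr(matrix(stats::rnorm(n_channels * need), n_channels, need)))
  lapply(seq_len(K), function(k)
    q[, ((k - 1) * rank + 1):(k * rank), drop = FALSE])
}

# background sensor noise: iid N(0,1) per channel, optional AR(1) colouring,
# plus the state-dependent low-rank covariance signature. The state factors
# are AR(1) (unit marginal variance), giving each network state an
# oscillatory-band-like temporal signature that the time-delay embedding
# can pick up, not just an instantaneous spatial one.
network_noise <- function(cfg, path, loadings) {
  n <- length(path)
  x <- matrix(stats::rnorm(cfg$n_channels * n), cfg$n_channels, n)
  if (cfg$ar_coef != 0) {
    a <- cfg$ar_coef
    for (t in 2:n) x[, t] <- a * x[, t - 1] + sqrt(1 - a^2) * x[, t]
  }
  amp <- sqrt(cfg$state_var)
  a_f <- cfg$factor_ar
  for (k in seq_len(cfg$n_network_states)) {
    idx <- which(path == k)
    if (!length(idx)) next
    f <- matrix(stats::rnorm(cfg$net_rank * n), cfg$net_rank, n)
    if (a_f != 0) {
      f <- f * sqrt(1 - a_f^2)
      for (t in 2:n) f[, t] <- a_f * f[, t - 1] + f[, t]
      f[, 1] <- f[, 1] / sqrt(1 - a_f^2)
    }
    x[, idx] <- x[, idx] + amp * (loadings[[k]] %*% f[, idx, drop = FALSE])
  }
  x
}

# stamp amplitude * kernel (x) pattern into data centred at sample t
add_pulse <- function(data, pattern, t, kernel, amplitude) {
  half <- (length(kernel) - 1L) %/% 2L
  cols <- (t - half):(t - half + length(kernel) - 1L)
  ok <- cols >= 1L & cols <= ncol(data)
  data[, cols[ok]] <- data[, cols[ok]] +
    amplitude * outer(pattern, kernel[ok])
  data
}

resolve_event_pairs <- function(cfg, task) {
  pairs <- canonical_pairs(task)
  if (is.data.frame(cfg$event_pairs)) {
    key <- paste(cfg$event_pairs$from_idx, cfg$event_pairs$to_idx)
    pairs[paste(pairs$from_idx, pairs$to_idx) %in% key, , drop = FALSE]
  } else {
    switch(cfg$event_pairs,
      all = pairs,
      forward = pairs[pairs$inferred, , drop = FALSE],
      backward = {
        rev_key <- paste(task$inferred_pairs$to, task$inferred_pairs$from)
        pairs[paste(pairs$from, pairs$to) %in% rev_key, , drop = FALSE]
      },
      both = {
        rev_key <- paste(task$inferred_pairs$to, task$inferred_pairs$from)
        pairs[pairs$inferred | paste(pairs$from, pairs$to) %in% rev_key, ,
              drop = FALSE]
      },
      stop("unknown event_pairs specification"))
  }
}

#' Simulate a stimulus-localizer session
#'
#' Trials present each task state `trials_per_state` times in randomised
#' order at a fixed inter-trial interval. Each trial adds its state's
#' sensor pattern modulated by a half-sine evoked envelope (peak
#' `evoked_dur_ms / 2` after onset, amplitude `pattern_snr` against
#' unit-variance noise); inter-trial samples contain noise only. A
#' network-state Markov chain runs throughout, with a transient reduction
#' of DMN occupancy after each stimulus (task-induced deactivation).
#'
#' @param config A [synth_config()].
#' @param patterns `n_states` x `n_channels` pattern matrix from
#'   [make_patterns()].
#' @param length_s Optional explicit session length; an error is raised if
#'   it cannot hold the requested trials.
#' @return List with `ts` ([sensor_ts()]), `trials` (data frame: `onset`
#'   0-based sample, `state_idx`, `state`), `activation` (ground-truth
#'   time x K occupancy law) and `ground_truth` (chain path, loadings).
#' @export
simulate_localizer <- function(config, patterns, length_s = NULL) {
  cfg <- config
  stopifnot(inherits(cfg, "synth_config"),
            nrow(patterns) == cfg$n_states,
            ncol(patterns) == cfg$n_channels)
  set.seed(cfg$network_seed)
  loadings <- network_loadings(cfg$n_channels, cfg$n_network_states,
                               cfg$net_rank)
  set.seed(cfg$seed)
  rate <- cfg$rate_hz
  iti <- ms_to_samples(cfg$iti_ms, rate, "inter-trial interval")
  dur <- ms_to_samples(cfg$evoked_dur_ms, rate, "evoked duration")
  margin <- as.integer(rate)  # 1 s at each edge
  n_trials <- cfg$trials_per_state * cfg$n_states
  if (cfg$trials_per_state < 10L)
    stop("need at least 10 trials per state")
  need <- 2L * margin + n_trials * iti
  n <- if (is.null(length_s)) need else as.integer(round(length_s * rate))
  if (n < need)
    stop(sprintf("capacity error: localizer needs %.1f s for %d trials",
                 need / rate, n_trials))
  labels <- sample(rep(seq_len(cfg$n_states), cfg$trials_per_state))
  onsets <- margin + (seq_len(n_trials) - 1L) * iti  # 0-based samples

  K <- cfg$n_network_states
  path <- simulate_chain(n, K, cfg$dwell_ms * rate / 1000)
  x <- network_noise(cfg, path, loadings)

  env <- sin(pi * seq_len(dur) / dur)  # evoked envelope, peak at dur/2
  for (i in seq_len(n_trials)) {
    cols <- onsets[i] + seq_len(dur)  # 1-based columns after the onset
    x[, cols] <- x[, cols] +
      cfg$pattern_snr * outer(patterns[labels[i], ], env)
  }

  probs <- soft_activation(path, K, cfg$soft_eps)
  if (cfg$stimulus_dmn_deactivation > 0) {
    w <- as.integer(round(0.5 * rate))  # 500 ms post-stimulus
    deact <- cfg$stimulus_dmn_deactivation * sin(pi * seq_len(w) / w)
    for (i in seq_len(n_trials)) {
      rows <- onsets[i] + seq_len(w)
      probs <- apply_dmn_boost(probs, rows,
                               -pmin(deact, probs[rows, cfg$dmn_index] - 1e-6),
                               cfg$dmn_index)
    }
  }

  list(ts = sensor_ts(x, rate, sprintf("localizer_seed%d", cfg$seed)),
       trials = data.frame(onset = onsets, state_idx = labels,
                           state = LETTERS[labels]),
       activation = state_activation(probs, rate,
                                     sprintf("localizer_seed%d", cfg$seed)),
       ground_truth = list(network_path = path, loadings = loadings))
}

#' Simulate a rest session with planted replay and network dynamics
#'
#' Schedules replay events on the configured ordered state pairs with
#' non-overlapping coupling windows, inserting `pattern_i` at the onset and
#' `pattern_j` one replay lag later (each as a 20 ms half-sine pulse of
#' amplitude `pattern_snr`). A K-state Markov chain of network states runs
#' in parallel, each state contributing a distinct low-rank spatial
#' covariance signature. Around onsets of task-relevant (structurally
#' adjacent) pairs the probability of occupying the DMN-like state is
#' raised by `coupling_amplitude` at onset (profile per `coupling_shape`)
#' — in POST sessions only; PRE sessions force the task-relevant amplitude
#' to zero. A `baseline_coupling` amplitude, applied to all pairs equally
#' in both sessions, models non-specific replay-network association.
#'
#' @param config A [synth_config()].
#' @param patterns Pattern matrix from [make_patterns()].
#' @param task A [task_structure()].
#' @return List with `ts` ([sensor_ts()]), `activation` (ground-truth soft
#'   occupancy, class `state_activation`), and `ground_truth`: `patterns`,
#'   `replay_onsets` (data frame `from_idx`, `to_idx`, `onset` 0-based,
#'   `inferred`), `network_path`, `coupled_pairs`, `loadings`.
#' @export
simulate_rest <- function(config, patterns, task = task_structure()) {
  cfg <- config
  stopifnot(inherits(cfg, "synth_config"),
            nrow(patterns) == cfg$n_states,
            ncol(patterns) == cfg$n_channels)
  set.seed(cfg$network_seed)
  loadings <- network_loadings(cfg$n_channels, cfg$n_network_states,
                               cfg$net_rank)
  set.seed(cfg$seed + 1L)
  rate <- cfg$rate_hz
  n <- as.integer(round(cfg$session_length_s * rate))
  lag <- ms_to_samples(cfg$replay_lag_ms, rate, "replay lag")
  w <- ms_to_samples(cfg$coupling_window_ms, rate, "coupling window")
  kernel <- pulse_kernel(rate)

  sched_pairs <- resolve_event_pairs(cfg, task)
  n_ev <- nrow(sched_pairs) * cfg$n_replay_events_per_pair
  margin <- as.integer(round(0.5 * rate)) + w + lag + length(kernel)
  min_gap <- 2L * w + lag + length(kernel)  # non-overlapping +-window
  slack <- n - 2L * margin - n_ev * min_gap
  if (slack < n_ev)
    stop(sprintf(
      "capacity error: %d events at >= %d-sample spacing exceed %.1f s",
      n_ev, min_gap, cfg$session_length_s))
  offs <- sort(sample.int(slack, n_ev))
  onsets <- margin + offs + (seq_len(n_ev) - 1L) * min_gap  # 1-based
  pair_rows <- sample(rep(seq_len(nrow(sched_pairs)),
                          cfg$n_replay_events_per_pair))
  events <- data.frame(
    from_idx = sched_pairs$from_idx[pair_rows],
    to_idx = sched_pairs$to_idx[pair_rows],
    onset = onsets - 1L,  # 0-based in outputs
    inferred = sched_pairs$inferred[pair_rows])

  K <- cfg$n_network_states
  path <- simulate_chain(n, K, cfg$dwell_ms * rate / 1000)
  probs <- soft_activation(path, K, cfg$soft_eps)

  amp_task <- if (cfg$session == "PRE") 0 else
    cfg$coupling_amplitude * cfg$group_effect
  prof <- coupling_profile(w, cfg$coupling_shape)
  visit_dwell <- max(1, cfg$dmn_visit_ms * rate / 1000)
  for (i in seq_len(n_ev)) {
    boost_amp <- cfg$baseline_coupling + if (events$inferred[i]) amp_task else 0
    if (boost_amp <= 0) next
    rows <- onsets[i] + (-w:w)
    probs <- apply_dmn_boost(probs, rows, boost_amp * prof, cfg$dmn_index)
    # realize the boost in the sampled path as short DMN visits, centred
    # on their trigger sample so the occupancy increment keeps the
    # profile's peak at the onset; the hazard integrates to the planted
    # increment
    hazard <- boost_amp * prof / ((1 - 1 / K) * visit_dwell)
    t0 <- 1L
    while (t0 <= length(rows)) {
      if (path[rows[t0]] != cfg$dmn_index &&
          stats::runif(1) < hazard[t0]) {
        len <- 1L + stats::rgeom(1, 1 / visit_dwell)
        lo <- max(1L, t0 - len %/% 2L)
        idx <- rows[lo:min(length(rows), lo + len - 1L)]
        path[idx] <- cfg$dmn_index
        t0 <- t0 + len
      } else t0 <- t0 + 1L
    }
  }

  x <- network_noise(cfg, path, loadings)
  for (i in seq_len(n_ev)) {
    x <- add_pulse(x, patterns[events$from_idx[i], ], onsets[i],
                   kernel, cfg$pattern_snr)
    x <- add_pulse(x, patterns[events$to_idx[i], ], onsets[i] + lag,
                   kernel, cfg$pattern_snr)
  }

  sid <- sprintf("rest_%s_seed%d", cfg$session, cfg$seed)
  coupled <- unique(events[events$inferred, c("from_idx", "to_idx")])
  list(ts = sensor_ts(x, rate, sid),
       activation = state_activation(probs, rate, sid),
       ground_truth = list(patterns = patterns, replay_onsets = events,
                           network_path = path, coupled_pairs = coupled,
                           loadings = loadings, config = cfg))
}

#' Ground-truth onsets in canonical pair order
#'
#' Re-organises a rest session's planted replay onsets into the canonical
#' 64-pair list layout used by the epoching stage (1-based sample
#' indices), so planted events can be fed to [epoch_evoked()] directly or
#' compared against detected onsets.
#'
#' @param ground_truth The `ground_truth` element of [simulate_rest()].
#' @param task A [task_structure()].
#' @return List of 64 integer vectors of 1-based onset samples.
#' @export
ground_truth_onsets <- function(ground_truth, task = task_structure()) {
  pairs <- canonical_pairs(task)
  ev <- ground_truth$replay_onsets
  key <- paste(ev$from_idx, ev$to_idx)
  lapply(paste(pairs$from_idx, pairs$to_idx), function(k)
    sort(ev$onset[key == k]) + 1L)
}

#' Write the ground truth of a simulated rest session to disk
#'
#' Replay onsets go to TSV (0-based samples); the remaining ground truth
#' (network path, coupled pairs, configuration) to JSON.
#'
#' @param ground_truth The `ground_truth` element of [simulate_rest()].
#' @param path Output TSV path (JSON side-car at `<path>.json`).
#' @export
write_ground_truth <- function(ground_truth, path) {
  utils::write.table(ground_truth$replay_onsets, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- ground_truth$config
  jsonlite::write_json(
    list(network_path = ground_truth$network_path,
         coupled_pairs = ground_truth$coupled_pairs,
         config = cfg[setdiff(names(cfg), "event_pairs")]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
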