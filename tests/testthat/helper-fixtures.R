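# Shared fixtures: everything is generated in code at test time.

# reactivation container from a raw probability matrix
as_react <- function(probs, rate_hz = 100, session_id = "fixture") {
  structure(list(probs = as.matrix(probs), rate_hz = rate_hz,
                 session_id = session_id), class = "reactivation")
}

# classifier object with hand-specified weights, identity feature scaling
as_classifiers <- function(weights) {
  nch <- nrow(weights) - 1L
  structure(list(weights = weights, time_ms = 0, penalty = 0,
                 center = rep(0, nch), scale = rep(1, nch),
                 n_states = ncol(weights), null_negatives = FALSE),
            class = "state_classifiers")
}

# brute-force HMM posterior by enumeration of all K^T latent paths;
# independent oracle for the scaled forward-backward recursion
fb_bruteforce <- function(logB, P, pi0) {
  t_all <- nrow(logB)
  K <- ncol(logB)
  B <- exp(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), t_all)))
  w <- apply(paths, 1, function(s) {
    p <- pi0[s[1]] * B[1, s[1]]
    if (t_all > 1)
      for (t in 2:t_all) p <- p * P[s[t - 1], s[t]] * B[t, s[t]]
    p
  })
  total <- sum(w)
  gamma <- matrix(0, t_all, K)
  for (t in seq_len(t_all))
    for (k in seq_len(K))
      gamma[t, k] <- sum(w[paths[, t] == k]) / total
  list(gamma = gamma, loglik = log(total))
}

# small synthetic configuration for fast unit tests
quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_channels = 32L, session_length_s = 70,
         n_replay_events_per_pair = 3L, trials_per_state = 10L,
         iti_ms = 800),
    list(...))
  do.call(synth_config, args)
}

# simulate a 3-state zero-mean Gaussian HMM directly in observation space
simulate_gauss_hmm <- function(t_all, covs, P, seed) {
  set.seed(seed)
  K <- length(covs)
  d <- nrow(covs[[1]])
  path <- integer(t_all)
  path[1] <- sample.int(K, 1)
  for (t in 2:t_all)
    path[t] <- sample.int(K, 1, prob = P[path[t - 1], ])
  chols <- lapply(covs, chol)
  x <- matrix(0, t_all, d)
  for (k in seq_len(K)) {
    idx <- which(path == k)
    if (length(idx))
      x[idx, ] <- matrix(stats::rnorm(length(idx) * d),
                         length(idx), d) %*% chols[[k]]
  }
  list(x = x, path = path)
}
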