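toy_model <- function(covs, P, pi0, lags = 0L, nch = nrow(covs[[1]])) {
  structure(list(K = length(covs), lags = as.integer(lags),
                 mu = rep(0, nch * length(lags)), basis = NULL, sds = NULL,
                 covs = covs, P = P, pi0 = pi0, n_channels = nch),
            class = "hmm_model")
}

test_that("time-delay embedding reproduces direct indexing", {
  x <- matrix(seq_len(30), 3, 10)  # 3 channels, 10 samples
  # identity embedding
  e0 <- tde_embed(x, 0)
  expect_equal(unname(e0[, ]), unname(t(x)))
  # lags {-1, 0, +1}: 9 columns; row t holds samples t-1, t, t+1
  e <- tde_embed(x, -1:1)
  expect_equal(dim(e), c(8L, 9L))
  for (t in seq_len(nrow(e)))
    for (c in 1:3)
      expect_equal(unname(e[t, (c - 1) * 3 + 1:3]), x[c, t + 0:2])
  expect_equal(nrow(tde_embed(x, c(-2, 3))), 10L - 5L)
  expect_error(tde_embed(x, -6:6), "length")
})

test_that("forward-backward matches brute-force path enumeration", {
  set.seed(11)
  for (rep in 1:6) {
    K <- sample(2:3, 1)
    t_all <- sample(3:8, 1)
    logB <- matrix(rnorm(t_all * K), t_all, K)
    P <- matrix(rexp(K * K), K, K)
    P <- P / rowSums(P)
    pi0 <- rexp(K)
    pi0 <- pi0 / sum(pi0)
    got <- replaydmn:::forward_backward(logB, P, pi0)
    want <- fb_bruteforce(logB, P, pi0)
    expect_equal(got$gamma, want$gamma, tolerance = 1e-10)
    expect_equal(got$loglik, want$loglik, tolerance = 1e-10)
  }
})

test_that("posterior inference on a hand-specified 2-state toy is exact", {
  covs <- list(diag(c(1, 1)), diag(c(4, 0.25)))
  P <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  pi0 <- c(0.6, 0.4)
  model <- toy_model(covs, P, pi0)
  x <- matrix(c(0.1, -0.2, 2.5, 0.1, -0.1, 3.0), nrow = 2)
  sa <- infer_states(model, sensor_ts(x, 100))
  logB <- replaydmn:::gauss_logliks(t(x), covs)
  want <- fb_bruteforce(logB, P, pi0)
  expect_equal(sa$probs, want$gamma, tolerance = 1e-10)
  expect_equal(rowSums(sa$probs), rep(1, 3), tolerance = 1e-8)
})

test_that("a single-state model yields unit posteriors and the sample covariance", {
  set.seed(12)
  ts <- sensor_ts(matrix(rnorm(3 * 400), 3, 400), 100)
  fit <- suppressWarnings(fit_hmm(ts, K = 1, lags = 0L, n_pcs = 0,
                                  standardize = FALSE, n_restarts = 1,
                                  max_iter = 5))
  sa <- infer_states(fit, ts)
  expect_true(all(sa$probs == 1))
  xc <- scale(t(ts$data), scale = FALSE)
  expect_equal(fit$covs[[1]], crossprod(xc) / 400 + diag(1e-6, 3),
               tolerance = 1e-8)
  expect_equal(rowSums(fit$P), 1)
})

test_that("EM increases the log-likelihood and recovers planted covariances", {
  set.seed(13)
  make_spd <- function(d, scale) {
    a <- matrix(rnorm(d * d), d)
    crossprod(a) / d * scale + diag(0.2, d)
  }
  covs <- list(make_spd(4, 0.3), make_spd(4, 1), make_spd(4, 3))
  P <- matrix(0.04, 3, 3)
  diag(P) <- 0.92
  sim <- simulate_gauss_hmm(3000, covs, P, seed = 77)
  fit <- fit_hmm(sensor_ts(t(sim$x), 100), K = 3, lags = 0L, n_pcs = 0,
                 standardize = FALSE, n_restarts = 2, seed = 5,
                 max_iter = 60)
  # monotone log-likelihood (numerical jitter tolerance)
  expect_true(all(diff(fit$loglik) > -1e-8 * abs(fit$loglik[-1])))
  # covariances recovered up to state permutation
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  match_cor <- vapply(perms, function(pm)
    mean(vapply(1:3, function(k)
      cor(as.vector(fit$covs[[pm[k]]]), as.vector(covs[[k]])),
      numeric(1))), numeric(1))
  expect_gt(max(match_cor), 0.9)
  # transition rows are normalised
  expect_equal(rowSums(fit$P), rep(1, 3), tolerance = 1e-10)
  expect_error(fit_hmm(sensor_ts(t(sim$x), 100), K = 0), "at least 1")
})

test_that("two-step application reproduces the fit-time posteriors", {
  set.seed(14)
  covs <- list(diag(c(1, 1, 1)), 3 * diag(c(1, 2, 0.5)))
  P <- matrix(c(0.9, 0.1, 0.15, 0.85), 2, 2, byrow = TRUE)
  sim <- simulate_gauss_hmm(1500, covs, P, seed = 21)
  ts <- sensor_ts(t(sim$x), 100)
  fit <- fit_hmm(ts, K = 2, lags = -1:1, n_pcs = 4, n_restarts = 1,
                 seed = 3, max_iter = 40)
  sa <- infer_states(fit, ts)
  # recompute the E-step with the stored preprocessing
  x <- replaydmn:::prepare_embedded(ts, fit)
  e <- replaydmn:::forward_backward(
    replaydmn:::gauss_logliks(x, fit$covs), fit$P, fit$pi0)
  lead <- attr(x, "lead")
  expect_lt(max(abs(sa$probs[(lead + 1):(lead + nrow(e$gamma)), ] -
                      e$gamma)), 1e-6)
  # padded edges align the posterior with the input sample-for-sample
  expect_equal(nrow(sa$probs), ncol(ts$data))
  expect_equal(sa$probs[1, ], sa$probs[lead + 1, ])
})

test_that("permuting model state labels permutes the posteriors", {
  covs <- list(diag(2), 2 * diag(2), 0.5 * diag(2))
  P <- matrix(c(0.8, 0.1, 0.1, 0.2, 0.7, 0.1, 0.3, 0.2, 0.5), 3, 3,
              byrow = TRUE)
  pi0 <- c(0.5, 0.3, 0.2)
  set.seed(15)
  ts <- sensor_ts(matrix(rnorm(2 * 50), 2, 50), 100)
  pm <- c(3, 1, 2)
  m1 <- toy_model(covs, P, pi0)
  m2 <- toy_model(covs[pm], P[pm, pm], pi0[pm])
  sa1 <- infer_states(m1, ts)
  sa2 <- infer_states(m2, ts)
  expect_equal(sa2$probs, sa1$probs[, pm], tolerance = 1e-12)
})

test_that("column centring is exact and guarded against repetition", {
  sa <- state_activation(cbind(c(0.2, 0.4), c(0.8, 0.6)), 100)
  cc <- centre_columns(sa)
  expect_equal(cc$probs[, 1], c(-0.1, 0.1), tolerance = 1e-12)
  expect_true(all(abs(colMeans(cc$probs)) < 1e-12))
  expect_error(centre_columns(cc), "already centred")
  const <- centre_columns(state_activation(matrix(c(0.3, 0.7), 2, 2,
                                                  byrow = TRUE), 100))
  expect_true(all(const$probs == 0))
})

test_that("DMN identification works by index, ground truth and power profile", {
  expect_equal(identify_dmn(mode = "by_index", reference = 1), 1L)
  set.seed(16)
  truth <- matrix(runif(500 * 3), 500, 3)
  truth <- truth / rowSums(truth)
  noisy <- truth[, c(2, 3, 1)] + matrix(rnorm(1500, 0, 0.05), 500, 3)
  sa <- structure(list(probs = noisy, rate_hz = 100, session_id = "x",
                       centred = FALSE), class = "state_activation")
  got <- identify_dmn(sa, "by_ground_truth", reference = truth,
                      true_dmn = 3)
  expect_equal(as.integer(got), 2L)
  expect_gt(attr(got, "correlation"), 0.8)
  # identical columns tie
  sa2 <- structure(list(probs = truth[, c(1, 1, 2)], rate_hz = 100,
                        session_id = "x", centred = FALSE),
                   class = "state_activation")
  expect_error(identify_dmn(sa2, "by_ground_truth", reference = truth,
                            true_dmn = 1), "tie")
  # power profile: state 2 loads on the "dmn" channels
  covs <- list(diag(c(1, 1, 1, 1)), diag(c(5, 5, 1, 1)))
  model <- toy_model(covs, diag(2), c(0.5, 0.5), nch = 4)
  expect_equal(identify_dmn(model = model, mode = "by_power_profile",
                            channel_regions = c("mpfc", "mpfc", "occ",
                                                "occ"),
                            target_regions = "mpfc"), 2L)
})

test_that("dynamics summaries match hand-computed paths", {
  # constant single-state path
  p1 <- matrix(c(1, 0, 0), 100, 3, byrow = TRUE)
  d1 <- summarize_dynamics(state_activation(p1, 100))
  expect_equal(d1$fractional_occupancy, c(1, 0, 0))
  expect_equal(d1$switch_rate_hz, 0)
  # strict alternation at 100 Hz: every lifetime is one sample = 10 ms
  p2 <- matrix(0.1, 200, 2)
  p2[seq(1, 199, 2), 1] <- 0.9
  p2[seq(2, 200, 2), 2] <- 0.9
  p2 <- p2 / rowSums(p2)
  d2 <- summarize_dynamics(state_activation(p2, 100))
  expect_equal(d2$mean_lifetime_ms, c(10, 10))
  expect_equal(sum(d2$fractional_occupancy), 1, tolerance = 1e-8)
  expect_equal(d2$switch_rate_hz, 199 / 2)
  expect_error(
    summarize_dynamics(centre_columns(state_activation(p2, 100))),
    "uncentred")
})

test_that("state-masked spectra are finite where states have long runs", {
  set.seed(17)
  ts <- sensor_ts(matrix(rnorm(2 * 2000), 2, 2000), 100)
  probs <- matrix(0.05, 2000, 2)
  probs[1:1000, 1] <- 0.95
  probs[1001:2000, 2] <- 0.95
  probs <- probs / rowSums(probs)
  sp <- state_spectra(ts, state_activation(probs, 100), seg_s = 0.5)
  expect_true(all(is.finite(sp$power)))
  expect_equal(length(sp$freq_hz), 25L)
})

test_that("fitted models survive a JSON round-trip", {
  set.seed(18)
  covs <- list(diag(c(1, 2)), diag(c(3, 0.5)))
  sim <- simulate_gauss_hmm(800, covs,
                            matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                            seed = 9)
  ts <- sensor_ts(t(sim$x), 100)
  fit <- fit_hmm(ts, K = 2, lags = -1:1, n_pcs = 3, n_restarts = 1,
                 seed = 2, max_iter = 20)
  path <- tempfile(fileext = ".json")
  write_hmm_json(fit, path)
  fit2 <- read_hmm_json(path)
  expect_equal(infer_states(fit2, ts)$probs, infer_states(fit, ts)$probs,
               tolerance = 1e-8)
  unlink(path)
})
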