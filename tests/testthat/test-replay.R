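test_that("replay evidence is the lagged element-wise product", {
  probs <- matrix(0.5, 4, 8)
  probs[, 1] <- c(0.5, 0.2, 0.9, 0.5)
  probs[, 2] <- c(0.1, 0.4, 0.8, 0.3)
  react <- as_react(probs)
  # tau = 1 sample (10 ms at 100 Hz), hand-computed products
  expect_equal(replay_evidence(react, c(1, 2), lag_ms = 10),
               c(0.5 * 0.4, 0.2 * 0.8, 0.9 * 0.3), tolerance = 1e-12)
  # zero reactivation of the first state nulls the evidence
  probs[2, 1] <- 0
  expect_equal(replay_evidence(as_react(probs), c(1, 2), 10)[2], 0)
  # lag must be integral in samples
  expect_error(replay_evidence(react, c(1, 2), lag_ms = 15), "multiple")
})

test_that("all 64 ordered pairs get an evidence series and threshold", {
  set.seed(1)
  react <- as_react(matrix(runif(3000 * 8), 3000, 8))
  events <- detect_replay_events(react, epoch_halfwidth_ms = 100)
  expect_equal(nrow(events$pairs), 64L)
  expect_length(events$onsets, 64L)
  expect_true(all(is.finite(events$pairs$threshold)))
  # self-pairs are enumerated too
  expect_equal(sum(events$pairs$from_idx == events$pairs$to_idx), 8L)
})

test_that("the 99th-percentile rule passes about 1% of iid evidence", {
  set.seed(2)
  ev <- runif(10000)
  det <- detect_onsets(ev, percentile = 99, rate_hz = 100,
                       epoch_halfwidth_ms = 500)
  sd3 <- 3 * sqrt(10000 * 0.01 * 0.99)
  expect_lt(abs(det$n_raw - 100), sd3)
  # every retained onset strictly exceeds the threshold and is epochable
  expect_true(all(ev[det$onsets] > det$threshold))
  expect_true(all(det$onsets > 50 & det$onsets <= 10000 - 50))

  # property: suprathreshold fraction lies in [0.005, 0.015] across seeds
  fr <- vapply(1:20, function(s) {
    set.seed(100 + s)
    detect_onsets(runif(8000), 99, 100, 100)$n_raw / 8000
  }, numeric(1))
  expect_true(all(fr >= 0.005 & fr <= 0.015))
})

test_that("degenerate evidence series yield no onsets", {
  expect_equal(detect_onsets(rep(0.3, 5000), 99, 100, 100)$onsets,
               integer(0))
  expect_error(detect_onsets(runif(50), 99, 100, 500), "length")
})

test_that("onsets shift exactly with a common delay of both series", {
  set.seed(3)
  probs <- matrix(0.4 + 0.1 * runif(2000 * 8), 2000, 8)
  spikes <- c(300, 700, 1200, 1700)
  probs[spikes, 1] <- 0.99
  probs[spikes + 4, 2] <- 0.99
  d <- 7L
  delayed <- rbind(matrix(0.45, d, 8), probs[1:(2000 - d), ])
  ev1 <- replay_evidence(as_react(probs), c(1, 2), 40)
  ev2 <- replay_evidence(as_react(delayed), c(1, 2), 40)
  on1 <- detect_onsets(ev1, 99, 100, 100)$onsets
  on2 <- detect_onsets(ev2, 99, 100, 100)$onsets
  expect_equal(on2, on1 + d)
})

test_that("run collapsing keeps one onset per suprathreshold run", {
  ev <- rep(0.1, 2000)
  ev[500:503] <- c(0.5, 0.8, 0.9, 0.6)   # one 4-sample excursion
  ev[900] <- 0.7
  det <- detect_onsets(ev, 99, 100, 100, collapse_runs = TRUE)
  expect_equal(det$onsets, c(502L, 900L))
})

test_that("planted replay onsets are recovered through decoding", {
  cfg <- quick_config(pattern_snr = 5, n_replay_events_per_pair = 5L,
                      session_length_s = 120, seed = 12)
  pat <- make_patterns(8, cfg$n_channels, seed = 12)
  loc <- simulate_localizer(cfg, pat)
  clf <- train_classifiers(loc$ts, loc$trials)
  sim <- simulate_rest(cfg, pat)
  react <- decode_rest(sim$ts, clf)
  events <- detect_replay_events(react, lag_ms = cfg$replay_lag_ms)
  truth <- ground_truth_onsets(sim$ground_truth)
  hits <- 0L
  total <- 0L
  for (p in seq_len(64)) {
    for (o in truth[[p]]) {
      total <- total + 1L
      if (any(abs(events$onsets[[p]] - o) <= 1L)) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.8)
})

test_that("sequenceness recovers planted forward transitions at 40 ms", {
  task <- task_structure()
  set.seed(4)
  base <- matrix(plogis(rnorm(6000 * 8, -2, 0.3)), 6000, 8)
  fwd <- canonical_pairs(task)
  fwd <- fwd[fwd$inferred, ]
  for (r in seq_len(nrow(fwd))) {
    at <- sample(100:5900, 40)
    base[at, fwd$from_idx[r]] <- 0.95
    base[at + 4, fwd$to_idx[r]] <- 0.95
  }
  sq <- sequenceness(as_react(base), task, lags_ms = seq(10, 100, 10))
  expect_equal(sq$lags_ms[which.max(sq$forward)], 40)
  expect_gt(sq$contrast[sq$lags_ms == 40], 0)

  # symmetric planting nulls the forward-backward contrast
  set.seed(5)
  sym <- matrix(plogis(rnorm(6000 * 8, -2, 0.3)), 6000, 8)
  for (r in seq_len(nrow(fwd))) {
    at <- sample(100:5900, 20)
    sym[at, fwd$from_idx[r]] <- 0.95
    sym[at + 4, fwd$to_idx[r]] <- 0.95
    at2 <- sample(100:5900, 20)
    sym[at2, fwd$to_idx[r]] <- 0.95
    sym[at2 + 4, fwd$from_idx[r]] <- 0.95
  }
  sq_sym <- sequenceness(as_react(sym), task, lags_ms = seq(10, 100, 10))
  fwd40 <- sq$forward[sq$lags_ms == 40]
  expect_lt(abs(sq_sym$contrast[sq_sym$lags_ms == 40]), 0.2 * fwd40)

  # replay strength is the POST - PRE forward coefficient at the lag
  expect_equal(replay_strength(sq, sq_sym, 40),
               fwd40 - sq_sym$forward[sq_sym$lags_ms == 40])
})

test_that("null reactivations give near-zero forward sequenceness", {
  f40 <- vapply(1:30, function(s) {
    set.seed(200 + s)
    react <- as_react(matrix(runif(3000 * 8), 3000, 8))
    sq <- sequenceness(react, lags_ms = c(40))
    sq$forward[1]
  }, numeric(1))
  z <- mean(f40) / (sd(f40) / sqrt(length(f40)))
  expect_lt(abs(z), 3)
})

test_that("replay events and sequenceness round-trip to disk", {
  set.seed(6)
  react <- as_react(matrix(runif(2500 * 8), 2500, 8))
  events <- detect_replay_events(react, epoch_halfwidth_ms = 100)
  path <- tempfile(fileext = ".tsv")
  write_replay_events(events, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), sum(events$pairs$n_onsets))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$lag_ms, 40)
  sq <- sequenceness(react, lags_ms = c(20, 40))
  write_sequenceness(sq, path)
  tab2 <- read.delim(path)
  expect_equal(tab2$forward, sq$forward, tolerance = 1e-8)
  unlink(c(path, paste0(path, ".json")))
})
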