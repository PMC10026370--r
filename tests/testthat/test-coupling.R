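# centred single-state activation fixture
centred_sa <- function(values, K = 1, rate = 100) {
  m <- if (is.matrix(values)) values else
    matrix(rep(values, K), ncol = K)
  state_activation(m, rate, centred = TRUE)
}

test_that("epoching averages the peri-onset windows per transition", {
  v <- c(0, 1, 2, 3, 4, 5, 0, 0)
  sa <- centred_sa(v)
  # one event: the evoked row is that window exactly (halfwidth 1 sample)
  ev1 <- epoch_evoked(sa, list(3L), halfwidth_ms = 10)
  expect_equal(as.numeric(ev1$values[1, , 1]), c(1, 2, 3))
  # two events with windows [1,2,3] and [3,4,5] average to [2,3,4]
  ev2 <- epoch_evoked(sa, list(c(3L, 5L)), halfwidth_ms = 10)
  expect_equal(as.numeric(ev2$values[1, , 1]), c(2, 3, 4))
  expect_equal(ev2$n_events, 2L)
  # transitions without events are flagged and left missing
  ev3 <- epoch_evoked(sa, list(integer(0), 3L), halfwidth_ms = 10)
  expect_equal(ev3$n_events, c(0L, 1L))
  expect_true(all(is.na(ev3$values[1, , ])))
  # uncentred input is rejected
  raw <- state_activation(matrix(1, 8, 1), 100)
  expect_error(epoch_evoked(raw, list(3L), 10), "centred")
})

test_that("the task-relevance design marks exactly the six forward adjacencies", {
  d <- make_design()
  expect_equal(dim(d), c(64L, 2L))
  expect_equal(sum(d[, "inferred"]), 6)
  expect_equal(sum(d[, "const"]), 64)
  pairs <- canonical_pairs(task_structure())
  expect_true(all(d[pairs$from_idx == pairs$to_idx, "inferred"] == 0))
  expect_equal(sum(make_design(include_backward = TRUE)[, "inferred"]), 12)
})

test_that("coupling regression equals the group-means closed form", {
  d <- make_design()
  # constant blocks: beta_inferred = 0.3 - 0.1, beta_nonspecific = 0.1
  vals <- array(0.1, c(64, 5, 2))
  vals[d[, 1] == 1, , ] <- 0.3
  ev <- structure(list(values = vals, n_events = rep(1L, 64),
                       time_ms = seq(-20, 20, 10), session_id = "s"),
                  class = "evoked_tensor")
  b <- fit_coupling(ev, d)
  expect_equal(b$beta_inferred, matrix(0.2, 5, 2), tolerance = 1e-12)
  expect_equal(b$beta_nonspecific, matrix(0.1, 5, 2), tolerance = 1e-12)

  # all-equal responses carry no contrast
  ev$values[] <- 0.42
  b0 <- fit_coupling(ev, d)
  expect_equal(b0$beta_inferred, matrix(0, 5, 2), tolerance = 1e-12)

  # OLS oracle on random fixtures, including dropped transitions
  set.seed(21)
  for (rep in 1:5) {
    vals <- array(rnorm(64 * 3 * 4), c(64, 3, 4))
    n_ev <- rep(1L, 64)
    n_ev[sample(which(d[, 1] == 0), 5)] <- 0L
    evr <- structure(list(values = vals, n_events = n_ev,
                          time_ms = c(-10, 0, 10), session_id = "s"),
                     class = "evoked_tensor")
    br <- fit_coupling(evr, d)
    keep <- n_ev > 0
    inf <- keep & d[, 1] == 1
    non <- keep & d[, 1] == 0
    for (tt in 1:3)
      for (k in 1:4) {
        expect_equal(br$beta_inferred[tt, k],
                     mean(vals[inf, tt, k]) - mean(vals[non, tt, k]),
                     tolerance = 1e-10)
        expect_equal(br$beta_nonspecific[tt, k], mean(vals[non, tt, k]),
                     tolerance = 1e-10)
      }
  }
  # a session with only one design level present cannot be fitted
  ev_bad <- structure(list(values = vals, n_events = as.integer(d[, 1]),
                           time_ms = c(-10, 0, 10), session_id = "s"),
                      class = "evoked_tensor")
  expect_error(fit_coupling(ev_bad, d), "rank")
})

test_that("the session contrast is an element-wise difference", {
  d <- make_design()
  mk <- function(x) {
    vals <- array(x, c(64, 3, 2))
    ev <- structure(list(values = vals, n_events = rep(1L, 64),
                         time_ms = c(-10, 0, 10), session_id = "s"),
                    class = "evoked_tensor")
    fit_coupling(ev, d)
  }
  pre <- mk(0.2)
  post <- mk(0.2)
  expect_equal(delta_contrast(post, pre)$delta_inferred,
               matrix(0, 3, 2), tolerance = 1e-12)
  post2 <- post
  post2$beta_inferred[2, 1] <- post2$beta_inferred[2, 1] + 0.05
  dd <- delta_contrast(post2, pre)
  expect_equal(dd$delta_inferred[2, 1], 0.05, tolerance = 1e-12)
  expect_equal(sum(abs(dd$delta_inferred)), 0.05, tolerance = 1e-12)
  bad <- mk(0.1)
  bad$beta_inferred <- bad$beta_inferred[1:2, ]
  expect_error(delta_contrast(bad, pre), "shape")
})

test_that("uniform coupling on all pairs loads on the non-specific term only", {
  d <- make_design()
  t_inf <- vapply(1:50, function(s) {
    set.seed(300 + s)
    vals <- array(rnorm(64 * 1 * 1, sd = 0.05), c(64, 1, 1)) + 0.2
    ev <- structure(list(values = vals, n_events = rep(1L, 64),
                         time_ms = 0, session_id = "s"),
                    class = "evoked_tensor")
    fit_coupling(ev, d)$beta_inferred[1, 1]
  }, numeric(1))
  z <- mean(t_inf) / (sd(t_inf) / sqrt(50))
  expect_lt(abs(z), 3)
})

test_that("evoked PCA recovers a planted rank-1 structure", {
  d <- make_design()
  tm <- seq(-50, 50, 10)
  K <- 3
  pattern <- outer(cos(pi * tm / 100), c(0.2, 1, -0.5))  # peak on state 2
  mk_tensor <- function(scores) {
    vals <- array(0, c(64, length(tm), K))
    for (p in 1:64) vals[p, , ] <- scores[p] * pattern
    structure(list(values = vals, n_events = rep(1L, 64), time_ms = tm,
                   session_id = "s"), class = "evoked_tensor")
  }
  set.seed(22)
  tensors <- list()
  for (pid in c("a", "b")) {
    for (ses in c("PRE", "POST")) {
      sc <- rnorm(64)
      tensors[[paste(pid, ses)]] <- list(evoked = mk_tensor(sc),
                                         participant = pid, session = ses)
    }
  }
  pca <- evoked_pca(tensors, d, dmn = 2)
  expect_gt(pca$explained_variance[1], 0.999)
  cosine <- sum(pca$coefficients[, 1] * as.vector(pattern)) /
    sqrt(sum(pattern^2))
  expect_gt(abs(cosine), 0.999)
  # sign convention: positive DMN loading at onset
  expect_gt(pca$loading_arrays[[1]][tm == 0, 2], 0)
  # scores of centred data are centred per PC
  expect_lt(abs(sum(pca$scores$pc1)), 1e-8)
  # POST - PRE contrast exists for both participants
  expect_equal(sort(pca$delta_pc$participant), c("a", "b"))

  # reconstruction from all PCs reproduces the centred data
  st <- replaydmn:::stack_evoked(tensors)
  xc <- sweep(st$x, 2, colMeans(st$x))
  sv <- svd(xc)
  rec <- sv$u %*% diag(sv$d) %*% t(sv$v)
  expect_lt(max(abs(rec - xc)), 1e-8)
})

test_that("group-wise PC contrasts keep their planted signs", {
  # control-like participants gain task-relevant PC expression after
  # learning; patient-like participants lose a little
  d <- make_design()
  tm <- seq(-50, 50, 10)
  pattern <- outer(cos(pi * tm / 100), c(0, 1, 0))
  mk_tensor <- function(gain, seed) {
    set.seed(seed)
    vals <- array(rnorm(64 * length(tm) * 3, sd = 0.05),
                  c(64, length(tm), 3))
    for (p in 1:64)
      vals[p, , ] <- vals[p, , ] + (0.2 + gain * d[p, 1]) * pattern
    structure(list(values = vals, n_events = rep(1L, 64), time_ms = tm,
                   session_id = "s"), class = "evoked_tensor")
  }
  tensors <- list()
  gains <- c(c1 = 0.5, c2 = 0.6, p1 = -0.2, p2 = -0.25)
  i <- 0
  for (pid in names(gains)) {
    i <- i + 1
    tensors[[2 * i - 1]] <- list(evoked = mk_tensor(0, 400 + i),
                                 participant = pid, session = "PRE")
    tensors[[2 * i]] <- list(evoked = mk_tensor(gains[[pid]], 500 + i),
                             participant = pid, session = "POST")
  }
  pca <- evoked_pca(tensors, d, dmn = 2)
  dp <- pca$delta_pc
  expect_true(all(dp$delta_inferred_pc[dp$participant %in%
                                         c("c1", "c2")] > 0))
  expect_true(all(dp$delta_inferred_pc[dp$participant %in%
                                         c("p1", "p2")] < 0))
})

test_that("stimulus-evoked deactivation scores match their definition", {
  # flat trace scores zero
  expect_equal(deactivation_score(matrix(0.3, 11, 2), dmn = 2), 0)
  # 0.1 pre-stimulus, -0.1 post-stimulus scores 0.2
  ep <- matrix(0, 11, 2)
  ep[1:5, 2] <- 0.1
  ep[7:11, 2] <- -0.1
  expect_equal(deactivation_score(ep, dmn = 2), 0.2)

  # full pipeline: per-participant deactivation and rest-aligned PC sign
  set.seed(23)
  mk_session <- function(pid, deact) {
    probs <- matrix(rnorm(3000 * 2, sd = 0.02), 3000, 2)
    onsets <- seq(200, 2800, by = 200)
    for (o in onsets) {
      probs[(o - 50):o, 2] <- probs[(o - 50):o, 2] + deact / 2
      probs[(o + 1):(o + 50), 2] <- probs[(o + 1):(o + 50), 2] - deact / 2
    }
    list(sa = state_activation(probs, 100, centred = TRUE),
         onsets = onsets, participant = pid)
  }
  sessions <- list(mk_session("a", 0.2), mk_session("b", 0.05))
  se <- stimulus_evoked(sessions, halfwidth_ms = 500, dmn = 2)
  tab <- se$participant_table
  expect_gt(tab$deactivation[tab$participant == "a"], 0.15)
  expect_gt(tab$deactivation[tab$participant == "a"],
            tab$deactivation[tab$participant == "b"])
  # aligning to a reference PC fixes the sign
  se2 <- stimulus_evoked(sessions, dmn = 2, rest_pc = -se$loadings)
  expect_equal(se2$loadings, -se$loadings, tolerance = 1e-10)
})
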