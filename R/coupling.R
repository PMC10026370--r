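#' Epoch centred state activation around replay onsets, per transition
#'
#' For each of the 64 ordered state pairs, averages the centred
#' \[time, state\] activation over windows of `-halfwidth..+halfwidth`
#' around that transition's replay onsets. Transitions with no detected
#' onsets yield missing (NA) rows, flagged by `n_events`.
#'
#' @param sa A centred `state_activation`.
#' @param events A `replay_events` object from [detect_replay_events()]
#'   (onsets guaranteed epochable), or a list of onset vectors in
#'   canonical pair order.
#' @param halfwidth_ms Peri-event half-width (default 500 ms: 101 time
#'   points at 100 Hz, symmetric around onset).
#' @return Object of class `evoked_tensor`: `values` (transitions x time
#'   x K array), `n_events` (per transition), `time_ms` (peri-event axis),
#'   `session_id`.
#' @export
epoch_evoked <- function(sa, events, halfwidth_ms = 500) {
  stopifnot(inherits(sa, "state_activation"))
  if (!sa$centred) stop("state error: activation must be centred first")
  onsets <- if (inherits(events, "replay_events")) events$onsets else events
  hw <- ms_to_samples(halfwidth_ms, sa$rate_hz, "epoch half-width")
  n_pairs <- length(onsets)
  K <- ncol(sa$probs)
  vals <- array(NA_real_, c(n_pairs, 2L * hw + 1L, K))
  n_ev <- integer(n_pairs)
  for (p in seq_len(n_pairs)) {
    ons <- onsets[[p]]
    ons <- ons[ons > hw & ons + hw <= nrow(sa$probs)]
    n_ev[p] <- length(ons)
    if (!n_ev[p]) next
    acc <- matrix(0, 2L * hw + 1L, K)
    for (o in ons) acc <- acc + sa$probs[(o - hw):(o + hw), , drop = FALSE]
    vals[p, , ] <- acc / n_ev[p]
  }
  structure(list(values = vals, n_events = n_ev,
                 time_ms = seq(-hw, hw) * 1000 / sa$rate_hz,
                 session_id = sa$session_id),
            class = "evoked_tensor")
}

#' Design matrix for the transition-specific coupling regression
#'
#' 64 rows in canonical pair order; column `inferred` is the indicator of
#' the 6 forward structural adjacencies (optionally also their reversals),
#' column `const` is all ones. Self-pairs never carry the indicator.
#'
#' @param task A [task_structure()].
#' @param include_backward Also mark the 6 reversed adjacencies as
#'   task-relevant.
#' @return 64 x 2 numeric matrix with columns `inferred`, `const`.
#' @export
make_design <- function(task = task_structure(), include_backward = FALSE) {
  pairs <- canonical_pairs(task)
  ind <- as.numeric(pairs$inferred)
  if (include_backward) {
    rev_key <- paste(task$inferred_pairs$to, task$inferred_pairs$from)
    ind <- pmax(ind, as.numeric(paste(pairs$from, pairs$to) %in% rev_key))
  }
  cbind(inferred = ind, const = 1)
}

#' Transition-specific coupling regression for one session
#'
#' At every (peri-event time, state) cell, regresses the 64 evoked
#' activation values onto the task-relevance design by ordinary least
#' squares. With the \{indicator, intercept\} design this is equivalent to
#' `beta_inferred = mean(inferred rows) - mean(non-inferred rows)` and
#' `beta_nonspecific = mean(non-inferred rows)`. Transitions with no
#' events are dropped listwise.
#'
#' @param evoked An `evoked_tensor`.
#' @param design Matrix from [make_design()].
#' @return Object of class `coupling_betas`: `beta_inferred` and
#'   `beta_nonspecific` (time x K matrices), `time_ms`, `session_id`,
#'   `n_dropped` (transitions without events).
#' @export
fit_coupling <- function(evoked, design = make_design()) {
  stopifnot(inherits(evoked, "evoked_tensor"),
            nrow(design) == dim(evoked$values)[1])
  keep <- evoked$n_events > 0L
  d <- design[keep, , drop = FALSE]
  if (length(unique(d[, 1])) < 2L)
    stop("rank error: need both inferred and non-inferred transitions")
  nt <- dim(evoked$values)[2]
  K <- dim(evoked$values)[3]
  y <- matrix(evoked$values[keep, , ], nrow = sum(keep))  # 64' x (time*K)
  beta <- solve(crossprod(d), crossprod(d, y))            # 2 x (time*K)
  structure(list(beta_inferred = matrix(beta[1, ], nt, K),
                 beta_nonspecific = matrix(beta[2, ], nt, K),
                 time_ms = evoked$time_ms, session_id = evoked$session_id,
                 n_dropped = sum(!keep)),
            class = "coupling_betas")
}

#' Post-learning minus pre-learning coupling contrast
#'
#' `delta_beta_inferred = beta_inferred[POST] - beta_inferred[PRE]`,
#' element-wise over (peri-event time, state).
#'
#' @param post,pre `coupling_betas` for the two rest sessions (matching
#'   shapes).
#' @return Object of class `coupling_delta` with `delta_inferred`
#'   (time x K) and `time_ms`.
#' @export
delta_contrast <- function(post, pre) {
  stopifnot(inherits(post, "coupling_betas"),
            inherits(pre, "coupling_betas"))
  if (!identical(dim(post$beta_inferred), dim(pre$beta_inferred)))
    stop("shape error: sessions have different evoked dimensions")
  structure(list(delta_inferred = post$beta_inferred - pre$beta_inferred,
                 time_ms = post$time_ms),
            class = "coupling_delta")
}

# stack evoked tensors into an (entries x time*K) matrix with row metadata
stack_evoked <- function(tensors) {
  rows <- list()
  meta <- list()
  for (tn in tensors) {
    keep <- which(tn$evoked$n_events > 0L)
    v <- tn$evoked$values
    m <- matrix(v[keep, , ], nrow = length(keep))
    rows[[length(rows) + 1L]] <- m
    meta[[length(meta) + 1L]] <- data.frame(
      participant = tn$participant, session = tn$session,
      transition = keep)
  }
  list(x = do.call(rbind, rows), meta = do.call(rbind, meta))
}

#' PCA of replay-evoked responses across the cohort
#'
#' Concatenates every (participant, session, transition) vectorised
#' \[time x K\] evoked response over the whole cohort, column-centres, and
#' eigendecomposes. The first PC captures the dominant evoked
#' activation profile; its sign is fixed so the DMN loading at onset
#' (0 ms) is positive. Per participant and session, the 64 PC-1 scores
#' are regressed on the task-relevance design, giving `beta_inferred[PC]`
#' and the POST - PRE contrast `delta_inferred[PC]`.
#'
#' @param tensors List of entries, each `list(evoked = <evoked_tensor>,
#'   participant = <id>, session = "PRE"|"POST")`.
#' @param design Matrix from [make_design()].
#' @param dmn Index of the DMN-like state (for the sign convention).
#' @param n_pcs Number of PCs to retain.
#' @return Object of class `evoked_pca`: `coefficients` (time*K x n_pcs
#'   loadings, unit norm), `loading_arrays` (list of time x K matrices),
#'   `explained_variance`, `scores` (data frame: participant, session,
#'   transition, pc1), `beta_pc` (participant x session table of
#'   beta_inferred\[PC\]), `delta_pc` (per-participant POST - PRE),
#'   `time_ms`, `center`.
#' @export
evoked_pca <- function(tensors, design = make_design(), dmn = 2L,
                       n_pcs = 3L) {
  participants <- unique(vapply(tensors, function(t)
    as.character(t$participant), character(1)))
  if (length(participants) < 2L)
    stop("need evoked data from at least 2 participants")
  st <- stack_evoked(tensors)
  if (all(abs(st$x) < 1e-300)) stop("degenerate spectrum: all-zero data")
  ctr <- colMeans(st$x)
  xc <- sweep(st$x, 2, ctr)
  sv <- svd(xc, nu = 0, nv = n_pcs)
  load <- sv$v
  ev <- sv$d^2 / sum(sv$d^2)
  tm <- tensors[[1]]$evoked$time_ms
  nt <- length(tm)
  K <- length(ctr) / nt
  lag0 <- which(tm == 0)
  for (j in seq_len(ncol(load))) {      # orient: positive DMN loading at 0 ms
    lmat <- matrix(load[, j], nt, K)
    if (lmat[lag0, dmn] < 0) load[, j] <- -load[, j]
  }
  scores <- xc %*% load
  sc <- cbind(st$meta, pc1 = scores[, 1])

  beta_rows <- list()
  for (key in unique(paste(sc$participant, sc$session))) {
    idx <- which(paste(sc$participant, sc$session) == key)
    d <- design[sc$transition[idx], , drop = FALSE]
    b <- tryCatch(solve(crossprod(d), crossprod(d, sc$pc1[idx])),
                  error = function(e) matrix(NA_real_, 2, 1))
    beta_rows[[key]] <- data.frame(
      participant = sc$participant[idx[1]], session = sc$session[idx[1]],
      beta_inferred_pc = b[1, 1])
  }
  beta_pc <- do.call(rbind, c(beta_rows, make.row.names = FALSE))
  wide <- stats::reshape(beta_pc, idvar = "participant",
                         timevar = "session", direction = "wide")
  delta <- NULL
  if (all(c("beta_inferred_pc.POST", "beta_inferred_pc.PRE") %in%
          names(wide)))
    delta <- data.frame(participant = wide$participant,
                        delta_inferred_pc = wide$beta_inferred_pc.POST -
                          wide$beta_inferred_pc.PRE)
  structure(list(coefficients = load,
                 loading_arrays = lapply(seq_len(ncol(load)), function(j)
                   matrix(load[, j], nt, K)),
                 explained_variance = ev[seq_len(ncol(load))],
                 scores = sc, beta_pc = beta_pc, delta_pc = delta,
                 time_ms = tm, center = ctr),
            class = "evoked_pca")
}

#' Stimulus-evoked network modulation from localizer sessions
#'
#' Epochs the centred state activation around stimulus onsets, runs a PCA
#' over the vectorised per-trial epochs concatenated across participants
#' (sign-aligned to a rest-derived PC when given, by the sign of the
#' loading correlation), and computes per participant both the mean PC-1
#' score and a simple DMN deactivation score: mean DMN activation in
#' (-halfwidth, 0\] ms minus mean in (0, +halfwidth\] ms.
#'
#' @param sessions List of entries `list(sa = <centred state_activation>,
#'   onsets = <1-based trial onset samples>, participant = <id>)`.
#' @param halfwidth_ms Peri-stimulus half-width (default 500 ms).
#' @param dmn DMN state index.
#' @param rest_pc Optional loading vector (time*K) from the rest-replay
#'   [evoked_pca()] to align the stimulus PC sign to.
#' @return List of class `stimulus_evoked`: `loadings` (PC-1, unit norm),
#'   `loading_array` (time x K), `explained_variance`, `participant_table`
#'   (participant, mean_pc1, deactivation), `time_ms`.
#' @export
stimulus_evoked <- function(sessions, halfwidth_ms = 500, dmn = 2L,
                            rest_pc = NULL) {
  if (!length(sessions)) stop("no localizer sessions supplied")
  rows <- list()
  who <- character(0)
  deact <- numeric(0)
  tm <- NULL
  for (s in sessions) {
    sa <- s$sa
    stopifnot(inherits(sa, "state_activation"))
    if (!sa$centred) stop("state error: activation must be centred")
    hw <- ms_to_samples(halfwidth_ms, sa$rate_hz, "epoch half-width")
    ons <- s$onsets[s$onsets > hw & s$onsets + hw <= nrow(sa$probs)]
    if (!length(ons)) stop("no epochable trials for a participant")
    tm <- seq(-hw, hw) * 1000 / sa$rate_hz
    d_i <- numeric(length(ons))
    for (i in seq_along(ons)) {
      ep <- sa$probs[(ons[i] - hw):(ons[i] + hw), , drop = FALSE]
      rows[[length(rows) + 1L]] <- as.vector(ep)
      d_i[i] <- mean(ep[1:hw, dmn]) - mean(ep[(hw + 2L):(2L * hw + 1L), dmn])
    }
    who <- c(who, rep(s$participant, length(ons)))
    deact <- c(deact, d_i)
  }
  x <- do.call(rbind, rows)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0, nv = 1)
  load <- sv$v[, 1]
  nt <- length(tm)
  K <- length(ctr) / nt
  if (!is.null(rest_pc)) {
    if (stats::cor(load, rest_pc) < 0) load <- -load
  } else if (matrix(load, nt, K)[which(tm == 0), dmn] < 0) {
    load <- -load
  }
  pc1 <- as.numeric(xc %*% load)
  tab <- data.frame(
    participant = unique(who),
    mean_pc1 = vapply(unique(who), function(p) mean(pc1[who == p]),
                      numeric(1)),
    deactivation = vapply(unique(who), function(p) mean(deact[who == p]),
                          numeric(1)))
  rownames(tab) <- NULL
  structure(list(loadings = load,
                 loading_array = matrix(load, nt, K),
                 explained_variance = sv$d[1]^2 / sum(sv$d^2),
                 participant_table = tab, time_ms = tm),
            class = "stimulus_evoked")
}

#' Simple DMN deactivation score for one peri-stimulus epoch
#'
#' Mean DMN activation in the pre-stimulus half (-halfwidth, 0\] minus the
#' post-stimulus half (0, +halfwidth\] of a centred epoch.
#'
#' @param epoch time x K centred epoch matrix (odd row count, onset in the
#'   middle row).
#' @param dmn DMN column index.
#' @return Scalar deactivation score.
#' @export
deactivation_score <- function(epoch, dmn = 2L) {
  nt <- nrow(epoch)
  hw <- (nt - 1L) %/% 2L
  mean(epoch[1:hw, dmn]) - mean(epoch[(hw + 2L):nt, dmn])
}
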