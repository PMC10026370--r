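#' Configuration for an end-to-end synthetic cohort run
#'
#' Collects the generator settings, the analysis parameters and the
#' cohort layout for [run_cohort()]. Group-level coupling is expressed
#' through `group_effect` multipliers on the planted coupling amplitude
#' (1 = full coupling, control-like; 0 = no task-relevant coupling,
#' patient-like).
#'
#' Cohort-scale defaults are desk-scale: 32 channels, 90 s rest sessions,
#' 5 events per ordered pair and a planted coupling amplitude of 0.25,
#' sized by an a-priori power calculation so a 15 + 15 cohort detects the
#' group contrast reliably through the full decoding + HMM chain (see the
#' package vignette for the calculation).
#'
#' @param n_per_group Participants per group.
#' @param group_effects Named numeric vector of coupling multipliers, one
#'   per group.
#' @param synth Named list of [synth_config()] overrides shared by the
#'   cohort.
#' @param n_reference_sessions Rest sessions in the reference set used to
#'   fit the HMM observation models (two-step scheme).
#' @param hmm Optional pre-fitted `hmm_model`; skips the reference fit.
#' @param hmm_lags,hmm_n_pcs,hmm_restarts,hmm_max_iter TDE-HMM settings.
#' @param lag_ms Replay lag (ms). Default 40.
#' @param percentile Replay-onset threshold percentile. Default 99.
#' @param halfwidth_ms Peri-event epoch half-width. Default 500.
#' @param train_time_ms Classifier training latency. Default 180.
#' @param n_perm Permutations for the group statistics. Default 500.
#' @param seq_lags_ms Lag grid for the sequenceness covariate.
#' @param compute_sequenceness,stimulus_analysis,run_pca Toggles for the
#'   optional stages.
#' @param seed Master seed; every session and permutation seed is derived
#'   from it deterministically.
#' @return List of class `run_config`.
#' @export
run_config <- function(n_per_group = 15L,
                       group_effects = c(control = 1, patient = 0),
                       synth = list(),
                       n_reference_sessions = 3L,
                       hmm = NULL,
                       hmm_lags = -3:3,
                       hmm_n_pcs = 24L,
                       hmm_restarts = 2L,
                       hmm_max_iter = 30L,
                       lag_ms = 40,
                       percentile = 99,
                       halfwidth_ms = 500,
                       train_time_ms = 180,
                       n_perm = 500L,
                       seq_lags_ms = c(20, 40, 60, 80),
                       compute_sequenceness = TRUE,
                       stimulus_analysis = TRUE,
                       run_pca = TRUE,
                       seed = 1L) {
  base <- list(n_channels = 32L, session_length_s = 100,
               n_replay_events_per_pair = 8L, coupling_amplitude = 0.4,
               coupling_window_ms = 50, dmn_visit_ms = 40,
               trials_per_state = 12L, iti_ms = 800)
  base[names(synth)] <- synth
  cfg <- list(n_per_group = as.integer(n_per_group),
              group_effects = group_effects, synth = base,
              n_reference_sessions = as.integer(n_reference_sessions),
              hmm = hmm, hmm_lags = hmm_lags,
              hmm_n_pcs = as.integer(hmm_n_pcs),
              hmm_restarts = as.integer(hmm_restarts),
              hmm_max_iter = as.integer(hmm_max_iter),
              lag_ms = lag_ms, percentile = percentile,
              halfwidth_ms = halfwidth_ms, train_time_ms = train_time_ms,
              n_perm = as.integer(n_perm), seq_lags_ms = seq_lags_ms,
              compute_sequenceness = compute_sequenceness,
              stimulus_analysis = stimulus_analysis, run_pca = run_pca,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

make_synth <- function(config, ...) {
  do.call(synth_config, utils::modifyList(config$synth, list(...)))
}

#' Fit the reference HMM for a cohort run
#'
#' Simulates `n_reference_sessions` coupling-free rest sessions with the
#' cohort's network signatures and fits the TDE-HMM observation models on
#' them — the reference half of the two-step scheme.
#'
#' @param config A [run_config()].
#' @param seed Seed for the reference sessions and the EM restarts.
#' @return A fitted `hmm_model`.
#' @export
fit_reference_hmm <- function(config, seed = config$seed) {
  sessions <- lapply(seq_len(config$n_reference_sessions), function(i) {
    scfg <- make_synth(config, seed = seed * 131L + i,
                       group_effect = 0, session = "PRE")
    pat <- make_patterns(scfg$n_states, scfg$n_channels,
                         seed = seed * 131L + i)
    simulate_rest(scfg, pat)$ts
  })
  fit_hmm(sessions, K = config$synth$n_network_states %||% 12L,
          lags = config$hmm_lags, n_pcs = config$hmm_n_pcs,
          n_restarts = config$hmm_restarts, seed = seed,
          max_iter = config$hmm_max_iter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full single-participant pass: localizer -> decoders -> rest sessions ->
# replay events -> state inference -> coupling betas (+ optional extras)
analyse_participant <- function(config, model, task, design, pid, group,
                                ge, seed) {
  scfg0 <- make_synth(config, seed = seed, group_effect = ge)
  patterns <- make_patterns(scfg0$n_states, scfg0$n_channels, seed = seed)
  loc <- simulate_localizer(make_synth(config, seed = seed + 1L,
                                       group_effect = ge), patterns)
  clf <- train_classifiers(loc$ts, loc$trials,
                           time_ms = config$train_time_ms)
  out <- list(participant = pid, group = group)
  evoked <- list()
  seqs <- list()
  dmn_votes <- integer(0)
  for (ses in c("PRE", "POST")) {
    scfg <- make_synth(config, seed = seed + if (ses == "PRE") 2L else 3L,
                       group_effect = ge, session = ses)
    sim <- simulate_rest(scfg, patterns, task)
    react <- decode_rest(sim$ts, clf)
    events <- detect_replay_events(react, task, lag_ms = config$lag_ms,
                                   percentile = config$percentile,
                                   epoch_halfwidth_ms = config$halfwidth_ms)
    sa <- infer_states(model, sim$ts)
    dmn_hat <- identify_dmn(sa, "by_ground_truth",
                            reference = sim$activation,
                            true_dmn = scfg$dmn_index)
    dmn_votes <- c(dmn_votes, as.integer(dmn_hat))
    sac <- centre_columns(sa)
    ev <- epoch_evoked(sac, events, halfwidth_ms = config$halfwidth_ms)
    out[[paste0("betas_", ses)]] <- fit_coupling(ev, design)
    evoked[[ses]] <- list(evoked = ev, participant = pid, session = ses)
    if (config$compute_sequenceness)
      seqs[[ses]] <- sequenceness(react, task, config$seq_lags_ms)
  }
  out$delta <- delta_contrast(out$betas_POST, out$betas_PRE)
  out$dmn_hat <- dmn_votes
  out$evoked <- evoked
  if (config$compute_sequenceness)
    out$replay_strength <- replay_strength(seqs$POST, seqs$PRE,
                                           at_lag_ms = config$lag_ms)
  if (config$stimulus_analysis) {
    sa_loc <- centre_columns(infer_states(model, loc$ts))
    out$stimulus <- list(sa = sa_loc, onsets = loc$trials$onset + 1L,
                         participant = pid)
  }
  out
}

#' Run the full synthetic-cohort analysis
#'
#' Generates two groups of participants (localizer + PRE/POST rest each),
#' trains per-participant decoders, detects replay events, infers network
#' states with a reference-fitted TDE-HMM (two-step), fits the
#' transition-specific coupling regression per session, forms the
#' POST - PRE contrast, and runs the group statistics: per-group
#' sign-flip tests and the between-group permutation test on
#' `delta_beta_inferred[DMN]`, the cohort-level evoked PCA with its group
#' contrast, and (optionally) the stimulus-evoked analysis.
#'
#' @param config A [run_config()].
#' @return Object of class `results_bundle`: `summary` (one row per
#'   participant), `tests` (named list of `perm_test`), `pca`
#'   (`evoked_pca` or NULL), `stimulus` (`stimulus_evoked` or NULL),
#'   `dmn_index` (consensus inferred DMN state), `model`, `config`,
#'   `effects` (participants x time matrix of delta contrasts in the DMN
#'   column), `time_ms`.
#' @export
run_cohort <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  task <- task_structure()
  design <- make_design(task)
  set.seed(config$seed)
  subj_seeds <- sample.int(.Machine$integer.max %/% 2L,
                           2L * config$n_per_group) %/% 8L * 8L
  model <- config$hmm %||% fit_reference_hmm(config)

  groups <- rep(names(config$group_effects), each = config$n_per_group)
  res <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    res[[i]] <- analyse_participant(
      config, model, task, design,
      pid = sprintf("%s%02d", substr(groups[i], 1, 1),
                    (i - 1L) %% config$n_per_group + 1L),
      group = groups[i], ge = config$group_effects[[groups[i]]],
      seed = subj_seeds[i])
  }

  votes <- unlist(lapply(res, `[[`, "dmn_hat"))
  dmn <- as.integer(names(which.max(table(votes))))
  time_ms <- res[[1]]$delta$time_ms
  effects <- t(vapply(res, function(r) r$delta$delta_inferred[, dmn],
                      numeric(length(time_ms))))
  rownames(effects) <- vapply(res, `[[`, character(1), "participant")
  lag0 <- which(time_ms == 0)

  tests <- list()
  for (g in unique(groups)) {
    tests[[paste0("signflip_", g)]] <- signflip_test(
      effects[groups == g, , drop = FALSE], n_perm = config$n_perm,
      tail = "right", seed = config$seed + 17L, time_ms = time_ms)
  }
  tests$group <- group_perm_test(effects, groups, n_perm = config$n_perm,
                                 tail = "two", seed = config$seed + 29L,
                                 time_ms = time_ms)
  strength <- if (config$compute_sequenceness)
    vapply(res, `[[`, numeric(1), "replay_strength") else NULL
  if (!is.null(strength)) {
    tests$group_controlling_strength <- group_perm_test(
      residualize(effects, strength), groups, n_perm = config$n_perm,
      tail = "two", seed = config$seed + 43L, time_ms = time_ms)
  }

  pca <- NULL
  delta_pc <- rep(NA_real_, length(res))
  if (config$run_pca) {
    tensors <- unlist(lapply(res, function(r) unname(r$evoked)),
                      recursive = FALSE)
    pca <- evoked_pca(tensors, design, dmn = dmn)
    ord <- match(vapply(res, `[[`, character(1), "participant"),
                 pca$delta_pc$participant)
    delta_pc <- pca$delta_pc$delta_inferred_pc[ord]
  }
  stim <- NULL
  if (config$stimulus_analysis) {
    stim <- stimulus_evoked(lapply(res, `[[`, "stimulus"), dmn = dmn,
                            rest_pc = if (!is.null(pca))
                              pca$coefficients[, 1] else NULL)
  }

  summary_tab <- data.frame(
    participant = vapply(res, `[[`, character(1), "participant"),
    group = groups,
    beta_inferred_dmn_post_0ms = vapply(res, function(r)
      r$betas_POST$beta_inferred[lag0, dmn], numeric(1)),
    delta_beta_inferred_dmn_0ms = effects[, lag0],
    replay_strength = if (is.null(strength)) NA_real_ else strength,
    delta_beta_inferred_pc = delta_pc,
    stimulus_pc1 = NA_real_, deactivation = NA_real_)
  if (!is.null(stim)) {
    m <- match(summary_tab$participant, stim$participant_table$participant)
    summary_tab$stimulus_pc1 <- stim$participant_table$mean_pc1[m]
    summary_tab$deactivation <- stim$participant_table$deactivation[m]
  }

  structure(list(summary = summary_tab, tests = tests, pca = pca,
                 stimulus = stim, dmn_index = dmn, model = model,
                 config = config, effects = effects, time_ms = time_ms),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("<results_bundle: %d participants, DMN state %d>\n",
              nrow(x$summary), x$dmn_index))
  for (nm in names(x$tests)) {
    tt <- x$tests[[nm]]
    cat(sprintf("  %-28s peak t(%d) = %6.2f at %+5.0f ms, P_FWE = %.4g\n",
                nm, tt$df, tt$peak_stat, tt$peak_time_ms, tt$p_fwe))
  }
  invisible(x)
}

#' Write a results bundle to a directory
#'
#' `summary.tsv` (one row per participant), `perm_tests.tsv`, the PC-1
#' loading matrix, and a JSON provenance block (configuration, seed,
#' package version, consensus DMN state).
#'
#' @param bundle A `results_bundle` from [run_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(bundle$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_perm_tests(bundle$tests, file.path(out_dir, "perm_tests.tsv"),
                   seed = bundle$config$seed)
  if (!is.null(bundle$pca))
    utils::write.table(bundle$pca$loading_arrays[[1]],
                       file.path(out_dir, "rest_pc1_loading.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  cfg <- bundle$config
  cfg$hmm <- NULL
  jsonlite::write_json(
    list(config = cfg, dmn_index = bundle$dmn_index,
         package_version = as.character(utils::packageVersion("replaydmn"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(out_dir)
}
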