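one_sample_t <- function(effects) {
  n <- nrow(effects)
  m <- colMeans(effects)
  s <- sqrt((colSums(effects^2) - n * m^2) / (n - 1))
  m / (s / sqrt(n))
}

pooled_two_sample_t <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- (colSums(xa^2) - na * ma^2) / (na - 1)
  vb <- (colSums(xb^2) - nb * mb^2) / (nb - 1)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  (ma - mb) / (sp * sqrt(1 / na + 1 / nb))
}

perm_result <- function(obs, null_max, time_ms, tail, n_perm, df) {
  peak_val <- if (tail == "right") max(obs) else max(abs(obs))
  peak_idx <- if (tail == "right") which.max(obs) else which.max(abs(obs))
  structure(list(
    observed_stat = obs,
    time_ms = time_ms,
    peak_time_ms = if (is.null(time_ms)) peak_idx else time_ms[peak_idx],
    peak_stat = obs[peak_idx],
    p_fwe = (1 + sum(null_max >= peak_val)) / (n_perm + 1),
    n_perm = n_perm, tail = tail, df = df,
    null_max_distribution = null_max), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test: peak t(%d) = %.3f at %s ms, P_FWE = %.4g (%s-tailed, %d perms)>\n",
    x$df, x$peak_stat, format(x$peak_time_ms), x$p_fwe, x$tail, x$n_perm))
  invisible(x)
}

#' One-sample sign-flip permutation test with max-statistic FWE
#'
#' The observed statistic is the one-sample t at each peri-event time
#' point. The null is built by randomly flipping the sign of each
#' participant's entire effect time course (whole-row flips preserve
#' within-subject autocorrelation, which the max-statistic correction over
#' time requires) and recording the maximum t (right tail) or maximum |t|
#' (two-tailed) across time. The family-wise peak-level p-value uses the
#' add-one convention `(1 + #{null >= observed peak}) / (n_perm + 1)` and
#' so is never zero.
#'
#' @param effects participants x time matrix of effect time courses.
#' @param n_perm Number of permutations (default 500).
#' @param tail `"right"` or `"two"`.
#' @param seed Integer seed.
#' @param time_ms Optional peri-event time axis for reporting.
#' @return A `perm_test` object: `observed_stat`, `peak_time_ms`,
#'   `peak_stat`, `p_fwe`, `n_perm`, `tail`, `null_max_distribution`.
#' @export
signflip_test <- function(effects, n_perm = 500L,
                          tail = c("right", "two"), seed = 1L,
                          time_ms = NULL) {
  tail <- match.arg(tail)
  effects <- as.matrix(effects)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  n <- nrow(effects)
  if (n < 2L) stop("need at least 2 participants")
  if (!all(is.finite(effects))) stop("effects must be finite")
  obs <- one_sample_t(effects)
  obs[is.na(obs)] <- 0  # zero-variance columns: no evidence either way
  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  sumsq <- colSums(effects^2)
  m <- (flips %*% effects) / n                         # n_perm x time
  v <- sweep(-(m^2) * n, 2, sumsq, "+") / (n - 1)
  tt <- m / sqrt(v / n)
  tt[!is.finite(tt)] <- 0
  null_max <- if (tail == "right") apply(tt, 1, max) else
    apply(abs(tt), 1, max)
  perm_result(obs, null_max, time_ms, tail, n_perm, df = n - 1L)
}

#' Two-sample group-membership permutation test with max-statistic FWE
#'
#' Observed statistic: pooled-variance two-sample t (group A minus group
#' B) at each time point; null: random reassignments of group labels
#' preserving group sizes, recording the max (or max |t|) over time.
#'
#' @param effects participants x time matrix.
#' @param groups Factor/vector with exactly two levels, length
#'   `nrow(effects)`. The first level (or `"control"` if present) is the
#'   positive side of the contrast.
#' @param n_perm,tail,seed,time_ms As in [signflip_test()].
#' @return A `perm_test` object.
#' @export
group_perm_test <- function(effects, groups, n_perm = 500L,
                            tail = c("two", "right"), seed = 1L,
                            time_ms = NULL) {
  tail <- match.arg(tail)
  effects <- as.matrix(effects)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  lv <- levels(groups)
  if ("control" %in% lv) lv <- c("control", setdiff(lv, "control"))
  ia <- which(groups == lv[1]); ib <- which(groups == lv[2])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both groups need at least 2 participants")
  obs <- pooled_two_sample_t(effects[ia, , drop = FALSE],
                             effects[ib, , drop = FALSE])
  obs[is.na(obs)] <- 0
  set.seed(seed)
  n <- nrow(effects)
  null_max <- vapply(seq_len(n_perm), function(p) {
    pa <- sample.int(n, length(ia))
    tt <- pooled_two_sample_t(effects[pa, , drop = FALSE],
                              effects[-pa, , drop = FALSE])
    tt[!is.finite(tt)] <- 0
    if (tail == "right") max(tt) else max(abs(tt))
  }, numeric(1))
  perm_result(obs, null_max, time_ms, tail, n_perm,
              df = length(ia) + length(ib) - 2L)
}

#' Residualize effect time courses on a covariate
#'
#' OLS residuals of each time point's effects on \{covariate, intercept\}
#' — used to ask whether a group difference in coupling survives removal
#' of variance attributable to replay strength per se.
#'
#' @param effects participants x time matrix (or a vector).
#' @param covariate Per-participant covariate values.
#' @return Residual matrix (or vector) of the same shape.
#' @export
residualize <- function(effects, covariate) {
  vec <- is.null(dim(effects))
  e <- as.matrix(effects)
  if (length(covariate) != nrow(e)) stop("covariate length mismatch")
  if (nrow(e) < 3L) stop("need at least 3 participants")
  if (stats::sd(covariate) < 1e-12)
    stop("conditioning error: covariate is constant")
  x <- cbind(1, covariate)
  res <- e - x %*% solve(crossprod(x), crossprod(x, e))
  if (vec) drop(res) else res
}

#' Multiple regression of a per-participant outcome on covariates
#'
#' OLS with intercept and two-tailed t-based p-values; e.g. regressing the
#' coupling contrast on diagnosis and antipsychotic (chlorpromazine-
#' equivalent) dose.
#'
#' @param outcome Numeric per-participant outcome.
#' @param predictors Data frame of predictors (e.g. `diagnosis`, `dose`).
#' @return Data frame: `term`, `estimate`, `se`, `t`, `p`.
#' @export
covariate_regression <- function(outcome, predictors) {
  predictors <- as.data.frame(predictors)
  if (length(outcome) <= ncol(predictors) + 1L)
    stop("need more participants than predictors")
  fit <- stats::lm(outcome ~ ., data = cbind(outcome = outcome, predictors))
  if (any(is.na(stats::coef(fit))))
    stop("conditioning error: rank-deficient predictor set")
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
             t = s[, 3], p = s[, 4], row.names = NULL)
}

#' Normality-gated association test
#'
#' `method = "auto"` runs Shapiro-Wilk on both variables at alpha = 0.05:
#' if both pass, Pearson's correlation; otherwise Spearman's rank
#' correlation. Two-tailed p-value.
#'
#' @param x,y Numeric vectors of equal length (n >= 5).
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return List: `statistic` (correlation coefficient), `p`, `method`.
#' @export
assoc <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 5L) stop("need at least 5 observations")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("undefined correlation: constant input")
  if (method == "auto") {
    normal <- stats::shapiro.test(x)$p.value > 0.05 &&
      stats::shapiro.test(y)$p.value > 0.05
    method <- if (normal) "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided"))
  list(statistic = unname(ct$estimate), p = ct$p.value, method = method)
}

#' Write a set of permutation-test results to TSV
#'
#' @param tests Named list of `perm_test` objects.
#' @param path Output path.
#' @param seed Seed used for the permutations (recorded for audit).
#' @export
write_perm_tests <- function(tests, path, seed = NA_integer_) {
  utils::write.table(
    data.frame(test = names(tests),
               peak_time_ms = vapply(tests, `[[`, numeric(1), "peak_time_ms"),
               peak_stat = vapply(tests, `[[`, numeric(1), "peak_stat"),
               df = vapply(tests, `[[`, numeric(1), "df"),
               p_fwe = vapply(tests, `[[`, numeric(1), "p_fwe"),
               tail = vapply(tests, `[[`, character(1), "tail"),
               n_perm = vapply(tests, `[[`, numeric(1), "n_perm"),
               seed = seed),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
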