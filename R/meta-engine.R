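#' Standardized mean difference for one study
#'
#' Computes the standardized mean difference (SMD) of a two-arm study from
#' its summary statistics, with the pooling sd formed from the two arms'
#' n - 1 weighted variances. Two conventions are available:
#'
#' * `correction = "hedges"`: Hedges' g with the small-sample factor
#'   `J = 1 - 3/(4N - 9)` (N = n1 + n2) and sampling variance
#'   `N/(n1 n2) + g^2 / (2 (N - 3.94))`.
#' * `correction = "none"`: the uncorrected SMD (Cohen's d) with variance
#'   `N/(n1 n2) + d^2 / (2 (N - 2))`. This is the convention that
#'   reproduces the packaged hepatocellular-carcinoma panel's published
#'   forest-plot numbers to printed precision, and is the default used by
#'   the fixture-backed pipeline.
#'
#' @param n1,mean1,sd1 Case-arm size, mean, sd.
#' @param n2,mean2,sd2 Control-arm size, mean, sd.
#' @param correction `"hedges"` or `"none"`.
#' @return List with `g` (the SMD), `variance` and `se`.
#' @examples
#' smd_effect(354, 8.0304, 1.6810, 50, 8.9665, 0.8451, correction = "hedges")
#' @export
smd_effect <- function(n1, mean1, sd1, n2, mean2, sd2,
                       correction = c("none", "hedges")) {
  correction <- match.arg(correction)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  N <- n1 + n2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (N - 2)
  if (sp2 <= 0) stop("pooled sd is zero: SMD undefined", call. = FALSE)
  d <- (mean1 - mean2) / sqrt(sp2)
  if (correction == "hedges") {
    J <- 1 - 3 / (4 * N - 9)
    g <- J * d
    v <- N / (n1 * n2) + g^2 / (2 * (N - 3.94))
  } else {
    g <- d
    v <- N / (n1 * n2) + d^2 / (2 * (N - 2))
  }
  list(g = g, variance = v, se = sqrt(v))
}

#' Hedges' g for a study summary row
#'
#' Small-sample corrected SMD (see [smd_effect()], `correction = "hedges"`).
#'
#' @param study A one-row data frame (or list) with fields `study_id`,
#'   `n_case`, `mean_case`, `sd_case`, `n_control`, `mean_control`,
#'   `sd_control`.
#' @return One-row data frame: `study_id`, `g`, `variance`, `se`.
#' @export
hedges_g <- function(study) {
  e <- smd_effect(study$n_case, study$mean_case, study$sd_case,
                  study$n_control, study$mean_control, study$sd_control,
                  correction = "hedges")
  data.frame(study_id = study$study_id, g = e$g, variance = e$variance, se = e$se)
}

#' Per-study effect sizes for a panel
#'
#' @param studies Study table as from [read_studies_tsv()].
#' @param correction Passed to [smd_effect()].
#' @return Data frame: `study_id`, `g`, `variance`, `se`.
#' @export
effect_sizes <- function(studies, correction = c("none", "hedges")) {
  correction <- match.arg(correction)
  res <- lapply(seq_len(nrow(studies)), function(i) {
    s <- studies[i, ]
    e <- smd_effect(s$n_case, s$mean_case, s$sd_case,
                    s$n_control, s$mean_control, s$sd_control, correction)
    data.frame(study_id = s$study_id, g = e$g, variance = e$variance, se = e$se)
  })
  do.call(rbind, res)
}

check_effects <- function(effects, min_k = 1L) {
  if (!is.data.frame(effects) || !all(c("g", "variance") %in% names(effects)))
    stop("'effects' must be a data frame with columns g and variance", call. = FALSE)
  if (nrow(effects) < min_k)
    stop(sprintf("need at least %d effect size(s)", min_k), call. = FALSE)
  if (any(effects$variance <= 0))
    stop("all sampling variances must be positive", call. = FALSE)
  invisible(effects)
}

new_meta_result <- function(pooled, se, z, p, Q, df_Q, p_Q, I2, tau2, model, k,
                            weights) {
  structure(list(
    pooled = pooled, se = se,
    ci_low = pooled - 1.96 * se, ci_high = pooled + 1.96 * se,
    z = z, p = p, Q = Q, df_Q = df_Q, p_Q = p_Q, I2 = I2, tau2 = tau2,
    model = model, k = k, weights = weights
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "%s-effects meta-analysis of %d studies\n  pooled SMD %.3f (95%% CI %.3f to %.3f), z = %.3f, p = %.4g\n  heterogeneity: Q = %.2f (df %d, p = %.4g), I2 = %.1f%%, tau2 = %.4f\n",
    x$model, x$k, x$pooled, x$ci_low, x$ci_high, x$z, x$p,
    x$Q, x$df_Q, x$p_Q, x$I2, x$tau2))
  invisible(x)
}

heterogeneity <- function(g, v) {
  w <- 1 / v
  mu <- sum(w * g) / sum(w)
  Q <- sum(w * (g - mu)^2)
  df <- length(g) - 1L
  p_Q <- if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  I2 <- if (Q > 0 && df > 0) max(0, (Q - df) / Q) * 100 else 0
  list(w = w, mu = mu, Q = Q, df = df, p_Q = p_Q, I2 = I2)
}

#' Fixed-effect (inverse-variance) pooling
#'
#' @param effects Data frame with columns `g` and `variance` (one row per
#'   study), as from [effect_sizes()].
#' @return A `meta_result` with the pooled SMD, 1.96-based 95% CI, z and
#'   two-sided p, Cochrane's Q with its df and p, I2 (percent) and
#'   `tau2 = 0`.
#' @export
pool_fixed <- function(effects) {
  check_effects(effects, 1L)
  h <- heterogeneity(effects$g, effects$variance)
  se <- sqrt(1 / sum(h$w))
  z <- h$mu / se
  new_meta_result(h$mu, se, z, 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                  h$Q, h$df, h$p_Q, h$I2, 0, "fixed", nrow(effects),
                  h$w / sum(h$w))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Between-study variance by the moment estimator
#' `tau2 = max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)` over
#' fixed-effect weights, then inverse-variance pooling with weights
#' `1 / (variance + tau2)`. With a single study the result reduces to the
#' fixed-effect pooling of that study. Q, I2 and their p-value are reported
#' from the fixed-effect weights, as is conventional.
#'
#' @inheritParams pool_fixed
#' @return A `meta_result` with `model = "random"`.
#' @export
pool_random <- function(effects) {
  check_effects(effects, 1L)
  h <- heterogeneity(effects$g, effects$variance)
  C <- sum(h$w) - sum(h$w^2) / sum(h$w)
  tau2 <- if (h$df > 0 && C > 0) max(0, (h$Q - h$df) / C) else 0
  wr <- 1 / (effects$variance + tau2)
  mu <- sum(wr * effects$g) / sum(wr)
  se <- sqrt(1 / sum(wr))
  z <- mu / se
  new_meta_result(mu, se, z, 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                  h$Q, h$df, h$p_Q, h$I2, tau2, "random", nrow(effects),
                  wr / sum(wr))
}

#' Pool with the heterogeneity-driven model choice
#'
#' Applies the rule: random effects when the heterogeneity test has
#' `p < 0.05` or `I2 > 50` percent, otherwise fixed effects. The chosen
#' model is recorded in the result's `model` field.
#'
#' @inheritParams pool_fixed
#' @param p_cut,i2_cut Rule constants (defaults 0.05 and 50).
#' @return A `meta_result` from [pool_random()] or [pool_fixed()].
#' @export
select_model <- function(effects, p_cut = 0.05, i2_cut = 50) {
  check_effects(effects, 2L)
  h <- heterogeneity(effects$g, effects$variance)
  if ((!is.na(h$p_Q) && h$p_Q < p_cut) || h$I2 > i2_cut)
    pool_random(effects)
  else
    pool_fixed(effects)
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Classic form: ordinary least squares of the standardized effect
#' `g / se` on the precision `1 / se`; the intercept estimates asymmetry
#' and is tested against zero with a two-sided t test on K - 2 df.
#'
#' @inheritParams pool_fixed
#' @return List with `method = "egger"`, `statistic` (the intercept), `se`,
#'   `t` and `p`.
#' @export
egger_test <- function(effects) {
  check_effects(effects, 3L)
  se <- sqrt(effects$variance)
  y <- effects$g / se
  x <- 1 / se
  if (stats::sd(x) == 0)
    stop("all standard errors equal: precision regressor is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  structure(list(method = "egger", statistic = sm[1, 1], se = sm[1, 2],
                 t = sm[1, 3], p = sm[1, 4],
                 note = "OLS of g/se on 1/se; intercept tested, t with K-2 df"),
            class = "bias_test_result")
}

#' Begg-Mazumdar rank correlation test for publication bias
#'
#' Kendall's tau between the variance-standardized deviations from the
#' fixed-effect pooled estimate and the sampling variances, with the
#' continuity-corrected normal approximation for the test.
#'
#' @inheritParams pool_fixed
#' @return List with `method = "begg"`, `statistic` (Kendall tau) and `p`.
#' @export
begg_test <- function(effects) {
  check_effects(effects, 3L)
  k <- nrow(effects)
  w <- 1 / effects$variance
  mu <- sum(w * effects$g) / sum(w)
  vstar <- effects$variance - 1 / sum(w)
  vstar[vstar <= 0] <- .Machine$double.eps
  u <- (effects$g - mu) / sqrt(vstar)
  tau <- stats::cor(u, effects$variance, method = "kendall")
  S <- tau * k * (k - 1) / 2
  sd_s <- sqrt(k * (k - 1) * (2 * k + 5) / 18)
  z <- max(0, abs(S) - 1) / sd_s
  structure(list(method = "begg", statistic = tau,
                 p = 2 * stats::pnorm(z, lower.tail = FALSE),
                 note = "Kendall tau, continuity-corrected normal approximation"),
            class = "bias_test_result")
}

#' @export
print.bias_test_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, p = %.4g\n", x$method, x$statistic, x$p))
  invisible(x)
}

#' Funnel-plot coordinates
#'
#' @inheritParams pool_fixed
#' @return Data frame `study_id`, `g`, `se` sorted by `se` ascending, with
#'   the fixed-effect pooled estimate attached as attribute `"pooled"`
#'   (the funnel's reference line).
#' @export
funnel_points <- function(effects) {
  check_effects(effects, 1L)
  d <- data.frame(study_id = effects$study_id, g = effects$g,
                  se = sqrt(effects$variance))
  d <- d[order(d$se), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "pooled") <- pool_fixed(effects)$pooled
  d
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the panel omitting each study in turn, under the given model.
#'
#' @inheritParams pool_fixed
#' @param model `"random"` (default), `"fixed"`, or `"select"` to re-apply
#'   the heterogeneity rule each time.
#' @return Data frame: `omitted`, `pooled`, `ci_low`, `ci_high`, `I2`,
#'   `model`.
#' @export
leave_one_out <- function(effects, model = c("random", "fixed", "select")) {
  model <- match.arg(model)
  check_effects(effects, 3L)
  fun <- switch(model, random = pool_random, fixed = pool_fixed,
                select = select_model)
  res <- lapply(seq_len(nrow(effects)), function(i) {
    m <- fun(effects[-i, , drop = FALSE])
    data.frame(omitted = effects$study_id[i], pooled = m$pooled,
               ci_low = m$ci_low, ci_high = m$ci_high, I2 = m$I2,
               model = m$model)
  })
  do.call(rbind, res)
}

#' Forest-table export for a pooled panel
#'
#' @inheritParams pool_fixed
#' @param result A `meta_result` for the same panel (its weights are used).
#' @return Data frame: per-study `study_id`, `g`, `se`, `ci_low`, `ci_high`,
#'   `weight` (percent).
#' @export
forest_table <- function(effects, result) {
  check_effects(effects, 1L)
  stopifnot(inherits(result, "meta_result"), result$k == nrow(effects))
  data.frame(study_id = effects$study_id, g = effects$g,
             se = sqrt(effects$variance),
             ci_low = effects$g - 1.96 * sqrt(effects$variance),
             ci_high = effects$g + 1.96 * sqrt(effects$variance),
             weight = 100 * result$weights)
}
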