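#' Two-group summary of an expression cohort arm
#'
#' A `group_summary` holds the sufficient statistics of one study arm:
#' sample size, mean expression and standard deviation (n - 1 denominator).
#' All two-group operations in the package consume pairs of these objects,
#' so cohorts reported only as summary rows are first-class inputs.
#'
#' @param n Integer sample count, at least 2.
#' @param mean Arithmetic mean expression (platform-specific units).
#' @param sd Standard deviation on the same scale, non-negative.
#' @return An object of class `group_summary`.
#' @examples
#' group_summary(50, 8.97, 0.85)
#' @export
group_summary <- function(n, mean, sd) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("'n' must be a single integer >= 2", call. = FALSE)
  if (!is.finite(mean)) stop("'mean' must be finite", call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("'sd' must be finite and >= 0", call. = FALSE)
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("group summary: n = %d, mean = %.4g, sd = %.4g\n", x$n, x$mean, x$sd))
  invisible(x)
}

#' Summarize sample-level expression values into a group summary
#'
#' @param values Numeric vector of at least 2 finite expression measurements.
#' @return A [group_summary()] with the arithmetic mean and the n - 1 sd.
#' @examples
#' summarize_samples(c(1, 2, 3)) # n = 3, mean = 2, sd = 1
#' @export
summarize_samples <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || !all(is.finite(values)))
    stop("need at least 2 finite values to summarize a group", call. = FALSE)
  group_summary(length(values), mean(values), stats::sd(values))
}

new_ttest_result <- function(t, df, p, method) {
  structure(list(t = t, df = df, p = p, method = method), class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("%s two-sample t: t = %.4f, df = %.2f, p = %.4g\n",
              x$method, x$t, x$df, x$p))
  invisible(x)
}

check_t_input <- function(case, control) {
  stopifnot(inherits(case, "group_summary"), inherits(control, "group_summary"))
  if (case$sd == 0 && control$sd == 0)
    stop("both group sds are zero: the t statistic is undefined", call. = FALSE)
}

#' Welch's unequal-variance t test from group summaries
#'
#' Computes `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. The sign
#' of `t` follows `case$mean - control$mean`.
#'
#' @param case,control [group_summary()] objects; not both sds may be zero.
#' @return A `ttest_result` with fields `t`, `df`, `p`, `method`.
#' @examples
#' welch_t(group_summary(354, 8.0304, 1.6810), group_summary(50, 8.9665, 0.8451))
#' @seealso [pooled_t()] for the equal-variance variant.
#' @export
welch_t <- function(case, control) {
  check_t_input(case, control)
  v1 <- case$sd^2 / case$n
  v2 <- control$sd^2 / control$n
  t <- (case$mean - control$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (case$n - 1) + v2^2 / (control$n - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  new_ttest_result(t, df, p, "welch")
}

#' Pooled-variance (Student) t test from group summaries
#'
#' Equal-variance two-sample t statistic with `df = n1 + n2 - 2`. For equal
#' group sizes the statistic coincides with [welch_t()].
#'
#' @inheritParams welch_t
#' @return A `ttest_result`.
#' @export
pooled_t <- function(case, control) {
  check_t_input(case, control)
  n1 <- case$n; n2 <- control$n
  sp <- sqrt(((n1 - 1) * case$sd^2 + (n2 - 1) * control$sd^2) / (n1 + n2 - 2))
  t <- (case$mean - control$mean) / (sp * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  new_ttest_result(t, df, p, "pooled")
}

#' Fold change between case and control means with the screening rule
#'
#' Linear-scale fold change is `case mean / control mean`; for log2-scale
#' input it is `2^(case mean - control mean)`. A marker passes the screen
#' when the fold change is strictly below 0.5 or strictly above 2 and the
#' accompanying two-group p-value is below 0.05 (both bounds non-inclusive).
#'
#' @inheritParams welch_t
#' @param scale `"linear"` (means are expression levels, must be positive)
#'   or `"log2"` (means are log2 expression).
#' @param p Two-sided p-value from the accompanying group comparison.
#' @return List with `fc` (linear-scale ratio) and `passes` (logical).
#' @examples
#' fold_change(group_summary(10, 4, 1), group_summary(10, 1, 1), "linear", 0.01)
#' @export
fold_change <- function(case, control, scale = c("linear", "log2"), p) {
  scale <- match.arg(scale)
  stopifnot(inherits(case, "group_summary"), inherits(control, "group_summary"))
  if (!is.finite(p) || p < 0 || p > 1) stop("'p' must be a probability", call. = FALSE)
  if (scale == "linear") {
    if (control$mean <= 0 || case$mean <= 0)
      stop("linear-scale fold change needs strictly positive means", call. = FALSE)
    fc <- case$mean / control$mean
  } else {
    fc <- 2^(case$mean - control$mean)
  }
  structure(list(fc = fc, passes = (fc < 0.5 || fc > 2) && p < 0.05),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("fold change = %.4g; passes FC<0.5|FC>2 & p<0.05 screen: %s\n",
              x$fc, x$passes))
  invisible(x)
}

#' Diagnostic ROC area from sample-level values
#'
#' The AUC equals the Mann-Whitney concordance probability with midrank
#' handling of ties. Orientation is automatic: the curve is oriented so that
#' AUC >= 0.5 and the chosen direction is reported as `orientation`
#' (`"case_low"` when lower marker values indicate cases, as for a
#' down-regulated microRNA). The standard error and 95% CI use DeLong's
#' covariance-based nonparametric method.
#'
#' @param case_values,control_values Numeric vectors of marker values, at
#'   least one per group (>= 10 recommended for CI validity).
#' @return List with `auc`, `se`, `ci_low`, `ci_high`, `orientation`.
#' @examples
#' r <- roc_auc(c(1, 2), c(3, 4)) # perfect separation, case_low
#' r$auc
#' @export
roc_auc <- function(case_values, control_values) {
  case_values <- as.numeric(case_values)
  control_values <- as.numeric(control_values)
  if (length(case_values) < 1L || length(control_values) < 1L)
    stop("both groups must contain at least one value", call. = FALSE)
  resp <- c(rep("control", length(control_values)), rep("case", length(case_values)))
  pred <- c(control_values, case_values)
  r <- pROC::roc(response = resp, predictor = pred,
                 levels = c("control", "case"), direction = "<",
                 quiet = TRUE)
  if (as.numeric(pROC::auc(r)) < 0.5)
    r <- pROC::roc(response = resp, predictor = pred,
                   levels = c("control", "case"), direction = ">",
                   quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  structure(list(
    auc = auc,
    se = sqrt(v),
    ci_low = max(0, ci[1]),
    ci_high = min(1, ci[3]),
    orientation = if (r$direction == ">") "case_low" else "case_high"
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (95%% CI %.4f-%.4f, se %.4f), orientation: %s\n",
              x$auc, x$ci_low, x$ci_high, x$se, x$orientation))
  invisible(x)
}

#' Export ROC curve coordinates
#'
#' @param case_values,control_values As in [roc_auc()].
#' @return Data frame of thresholds with sensitivity and specificity,
#'   suitable for external plotting.
#' @export
roc_coordinates <- function(case_values, control_values) {
  resp <- c(rep("control", length(control_values)), rep("case", length(case_values)))
  pred <- c(control_values, case_values)
  r <- pROC::roc(response = resp, predictor = pred,
                 levels = c("control", "case"), direction = "auto", quiet = TRUE)
  co <- pROC::coords(r, x = "all", ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  as.data.frame(co)
}

#' Read a sample-level expression table
#'
#' Expects a TSV with columns `sample_id`, `group` (`case`/`control`) and
#' `value`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with those three columns.
#' @export
read_samples_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "value")
  if (!all(need %in% names(d)))
    stop("sample table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!all(d$group %in% c("case", "control")))
    stop("'group' must be 'case' or 'control'", call. = FALSE)
  d[need]
}

#' Read a panel of study summary rows
#'
#' Expects a TSV with columns `study_id`, `n_case`, `mean_case`, `sd_case`,
#' `n_control`, `mean_control`, `sd_control` and `source` (e.g. GEO, TCGA,
#' qPCR, synthetic). The packaged fixture
#' `system.file("extdata", "hcc_mir146a_studies.tsv", package = "mirnetmeta")`
#' holds the 11 hepatocellular-carcinoma cohorts used throughout the
#' documentation.
#'
#' @param path Path to the TSV file.
#' @return Data frame of study summaries with unique `study_id`s.
#' @export
read_studies_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("study_id", "n_case", "mean_case", "sd_case",
            "n_control", "mean_control", "sd_control")
  if (!all(need %in% names(d)))
    stop("study table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(d$study_id))
    stop("study_id values must be unique within a panel", call. = FALSE)
  if (!"source" %in% names(d)) d$source <- "unknown"
  d
}

study_arms <- function(row) {
  list(case = group_summary(row$n_case, row$mean_case, row$sd_case),
       control = group_summary(row$n_control, row$mean_control, row$sd_control))
}

#' Per-study two-group t tests for a panel of summaries
#'
#' Convenience wrapper applying [welch_t()] (default) or [pooled_t()] to
#' every row of a study table.
#'
#' @param studies Data frame as returned by [read_studies_tsv()].
#' @param method `"welch"` or `"pooled"`.
#' @return Data frame: `study_id`, `t`, `df`, `p`.
#' @export
panel_t_tests <- function(studies, method = c("welch", "pooled")) {
  method <- match.arg(method)
  fun <- if (method == "welch") welch_t else pooled_t
  res <- lapply(seq_len(nrow(studies)), function(i) {
    arms <- study_arms(studies[i, ])
    r <- fun(arms$case, arms$control)
    data.frame(study_id = studies$study_id[i], t = r$t, df = r$df, p = r$p)
  })
  do.call(rbind, res)
}
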