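#' Lin's concordance correlation coefficient
#'
#' Agreement between two continuous measurements of the same quantity,
#' combining precision (Pearson correlation) with accuracy (departure of the
#' best-fit line from the 45-degree identity line). For paired vectors
#' \eqn{x, y},
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with all moments in the 1/n (biased) convention of Lin's original
#' estimator. Unlike an intraclass correlation it makes no normality or
#' equal-variance assumption about the two raters, which is why it is the
#' usual choice for skewed agreement data.
#'
#' The default confidence interval applies the Fisher z-transform to the
#' estimate with Lin's asymptotic variance and back-transforms the bounds;
#' `ci = "bootstrap"` gives a nonparametric percentile interval over
#' resampled pairs instead.
#'
#' Pairs with a missing value in either vector are deleted; at least 3
#' complete pairs and non-degenerate variance are required.
#'
#' @param x,y Numeric vectors of equal length.
#' @param conf_level Confidence level, default 0.95.
#' @param ci Interval method: `"asymptotic"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap replicates when `ci = "bootstrap"`.
#' @param label Optional name for the quantity being compared.
#' @return An object of class `cps_ccc` with fields `estimate`, `ci_lower`,
#'   `ci_upper`, `n_pairs`, `pearson_r`, `conf_level`, `label`. Use
#'   [generics::tidy()] for a one-row tibble.
#' @references Lin, L. I-K. (1989) A concordance correlation coefficient to
#'   evaluate reproducibility. Biometrics 45, 255-268.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- x + rnorm(50, sd = 0.5)
#' ccc(x, y)
ccc <- function(x, y, conf_level = 0.95, ci = c("asymptotic", "bootstrap"),
                boot_reps = 2000, label = NULL) {
  ci <- match.arg(ci)
  if (length(x) != length(y)) {
    rlang::abort("x and y must have equal length", class = "playscale_value_error")
  }
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) {
    rlang::abort("Fewer than 3 complete pairs", class = "playscale_too_few_pairs")
  }
  est <- ccc_estimate(x, y)
  if (is.na(est$ccc)) {
    rlang::abort("CCC undefined: both vectors have zero variance",
                 class = "playscale_degenerate")
  }
  bounds <- if (ci == "asymptotic") {
    ccc_asymptotic_ci(est, n, conf_level)
  } else {
    ccc_bootstrap_ci(x, y, conf_level, boot_reps)
  }
  structure(
    list(estimate = est$ccc, ci_lower = bounds[1], ci_upper = bounds[2],
         n_pairs = n, pearson_r = est$r, conf_level = conf_level,
         ci_method = ci, label = label),
    class = "cps_ccc"
  )
}

# Point estimate with 1/n moments; returns ccc = NA when both variances are 0.
ccc_estimate <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  ccc <- if (sx2 == 0 && sy2 == 0) NA_real_ else 2 * sxy / denom
  r <- if (sx2 == 0 || sy2 == 0) NA_real_ else sxy / sqrt(sx2 * sy2)
  list(ccc = ccc, r = r, mx = mx, my = my, sx2 = sx2, sy2 = sy2)
}

# Fisher-z CI with Lin's asymptotic variance of the transformed estimate.
ccc_asymptotic_ci <- function(est, n, conf_level) {
  p <- est$ccc
  r <- est$r
  if (!is.finite(r) || abs(r) < .Machine$double.eps || 1 - p^2 < 1e-12) {
    # perfect agreement (or degenerate correlation): no sampling spread
    # representable on the z scale
    return(c(p, p))
  }
  u <- (est$mx - est$my) / sqrt(sqrt(est$sx2 * est$sy2))  # u^2 = d^2/(sx*sy)
  v2 <- 1 / (n - 2) * (
    (1 - r^2) * p^2 / ((1 - p^2) * r^2) +
      2 * p^3 * (1 - p) * u^2 / (r * (1 - p^2)^2) -
      p^4 * u^4 / (2 * r^2 * (1 - p^2)^2)
  )
  v2 <- max(v2, 0)
  z <- atanh(p)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tanh(z + c(-1, 1) * q * sqrt(v2))
}

ccc_bootstrap_ci <- function(x, y, conf_level, boot_reps) {
  n <- length(x)
  reps <- vapply(seq_len(boot_reps), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    ccc_estimate(x[idx], y[idx])$ccc
  }, numeric(1))
  reps <- reps[is.finite(reps)]
  a <- (1 - conf_level) / 2
  unname(stats::quantile(reps, c(a, 1 - a), type = 7))
}

#' Qualitative agreement band for a concordance estimate
#'
#' Labels a CCC as `"poor"` (< 0.5), `"moderate"` (0.5--0.65) or `"good"`
#' (> 0.65). These cut-offs are reporting conventions, not part of the
#' statistic.
#'
#' @param estimate Numeric vector of CCC estimates.
#' @return A character vector.
#' @export
agreement_band <- function(estimate) {
  dplyr::case_when(
    is.na(estimate) ~ NA_character_,
    estimate < 0.5 ~ "poor",
    estimate <= 0.65 ~ "moderate",
    TRUE ~ "good"
  )
}

#' @export
print.cps_ccc <- function(x, digits = 2, ...) {
  lbl <- if (is.null(x$label)) "" else paste0(" (", x$label, ")")
  cat(sprintf("Concordance correlation%s: %.*f [%.*f-%.*f], n = %d (%s, %g%% CI)\n",
              lbl, digits, x$estimate, digits, x$ci_lower, digits, x$ci_upper,
              x$n_pairs, x$ci_method, 100 * x$conf_level))
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal consistency of a set of items:
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)}
#' where \eqn{s_i^2} are the sample (n-1) variances of the k items and
#' \eqn{s_T^2} the variance of the row totals. Cases with any missing item
#' are dropped listwise.
#'
#' @param items A numeric matrix or data frame, cases in rows, items in
#'   columns (at least 2 items and 3 complete cases).
#' @return An object of class `cps_alpha` with fields `alpha`, `k_items`,
#'   `n_cases`.
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(2, 2, 4, 4))
#' cronbach_alpha(m)
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  storage.mode(m) <- "double"
  if (ncol(m) < 2) {
    rlang::abort("Cronbach's alpha needs at least 2 items",
                 class = "playscale_value_error")
  }
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3) {
    rlang::abort("Fewer than 3 complete cases", class = "playscale_too_few_pairs")
  }
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) {
    rlang::abort("Total-score variance is zero; alpha undefined",
                 class = "playscale_degenerate")
  }
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
  structure(list(alpha = alpha, k_items = k, n_cases = n),
            class = "cps_alpha")
}

#' @export
print.cps_alpha <- function(x, digits = 2, ...) {
  cat(sprintf("Cronbach's alpha = %.*f (%d items, %d cases)\n",
              digits, x$alpha, x$k_items, x$n_cases))
  invisible(x)
}

#' Paired stability test between two timepoints
#'
#' Two-sided paired t-test on the differences between matched measurements
#' (the same informant's metric at time 1 and time 2), reporting the means
#' and standard deviations at each timepoint alongside the test.
#'
#' A constant difference with zero variance leaves the t statistic
#' undefined; this degenerate case is an error rather than an infinite
#' statistic.
#'
#' @param t1,t2 Numeric vectors of matched measurements (same informant
#'   order). Pairs with a missing value are dropped.
#' @return An object of class `cps_paired` with the timepoint means and
#'   SDs, `t_statistic`, `df`, `p_value`, `mean_diff` and `n_pairs`.
#' @export
paired_stability <- function(t1, t2) {
  if (length(t1) != length(t2)) {
    rlang::abort("t1 and t2 must have equal length", class = "playscale_value_error")
  }
  ok <- stats::complete.cases(t1, t2)
  t1 <- as.numeric(t1[ok]); t2 <- as.numeric(t2[ok])
  n <- length(t1)
  if (n < 3) {
    rlang::abort("Fewer than 3 complete pairs", class = "playscale_too_few_pairs")
  }
  d <- t2 - t1
  if (stats::var(d) == 0 && any(d != 0)) {
    rlang::abort("Constant nonzero difference: zero difference-variance, t undefined",
                 class = "playscale_degenerate")
  }
  if (all(d == 0)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = n - 1), p.value = 1)
  } else {
    tt <- stats::t.test(t2, t1, paired = TRUE)
  }
  structure(
    list(mean_t1 = mean(t1), sd_t1 = stats::sd(t1),
         mean_t2 = mean(t2), sd_t2 = stats::sd(t2),
         mean_diff = mean(d),
         t_statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, n_pairs = n),
    class = "cps_paired"
  )
}

#' @export
print.cps_paired <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Paired stability: t1 %.*f (%.*f), t2 %.*f (%.*f); t(%d) = %.2f, p = %.3g, n = %d\n",
    digits, x$mean_t1, digits, x$sd_t1, digits, x$mean_t2, digits, x$sd_t2,
    x$df, x$t_statistic, x$p_value, x$n_pairs))
  invisible(x)
}

# Run ccc() per metric over a paired wide table; <3 pairs or degenerate
# input yields a not-estimable row instead of an error.
agreement_by_metric <- function(paired, metrics, analysis, conf_level, ci) {
  rows <- purrr::map(metrics, function(m) {
    x <- paired[[paste0(m, "_a")]]
    y <- paired[[paste0(m, "_b")]]
    res <- tryCatch(
      ccc(x, y, conf_level = conf_level, ci = ci, label = m),
      playscale_too_few_pairs = function(e) NULL,
      playscale_degenerate = function(e) NULL
    )
    if (is.null(res)) {
      tibble::tibble(metric = m, ccc = NA_real_, ci_lower = NA_real_,
                     ci_upper = NA_real_,
                     n_pairs = sum(stats::complete.cases(x, y)),
                     estimable = FALSE)
    } else {
      tibble::tibble(metric = m, ccc = res$estimate, ci_lower = res$ci_lower,
                     ci_upper = res$ci_upper, n_pairs = res$n_pairs,
                     estimable = TRUE)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$band <- agreement_band(out$ccc)
  out$analysis <- analysis
  class(out) <- c("cps_agreement", class(out))
  out
}

#' Cross-informant agreement per metric
#'
#' Pairs the mother's and father's scored metrics for each child at one
#' timepoint and computes a concordance correlation coefficient per metric.
#' Children with a single informant are excluded pairwise (within each
#' metric); a metric with fewer than 3 complete pairs is reported as
#' not-estimable rather than raising.
#'
#' @param metrics A scored metrics table from [score_cps()].
#' @param timepoint Timepoint at which to pair informants (default `"t1"`).
#' @param metric_cols Metric columns to analyse.
#' @param conf_level,ci Passed to [ccc()].
#' @return A `cps_agreement` tibble: one row per metric with `ccc`,
#'   `ci_lower`, `ci_upper`, `n_pairs`, `estimable`, `band`, `analysis`.
#' @export
#' @examples
#' sim <- simulate_cps(cps_sim_config(n_children = 40, seed = 7))
#' cross_informant(score_cps(sim))
cross_informant <- function(metrics, timepoint = "t1",
                            metric_cols = cps_metric_names(),
                            conf_level = 0.95, ci = "asymptotic") {
  tp <- metrics[metrics$timepoint == timepoint, , drop = FALSE]
  mo <- tp[tp$role == "mother", c("child_id", metric_cols)]
  fa <- tp[tp$role == "father", c("child_id", metric_cols)]
  paired <- dplyr::inner_join(mo, fa, by = "child_id",
                              suffix = c("_a", "_b"))
  agreement_by_metric(paired, metric_cols,
                      paste0("cross_informant_", timepoint),
                      conf_level, ci)
}

#' Test-retest reliability per metric, for one informant role
#'
#' Pairs each informant's metric value at time 1 with their value at time 2
#' (mothers and fathers analysed separately, since both parents report on
#' the same child) and computes a concordance correlation coefficient per
#' metric. Informants present at only one timepoint are excluded pairwise.
#'
#' @param metrics A scored metrics table from [score_cps()].
#' @param role `"mother"` or `"father"`.
#' @inheritParams cross_informant
#' @return A `cps_agreement` tibble as for [cross_informant()].
#' @export
test_retest <- function(metrics, role, metric_cols = cps_metric_names(),
                        conf_level = 0.95, ci = "asymptotic") {
  stopifnot(role %in% c("mother", "father"))
  rr <- metrics[metrics$role == role, , drop = FALSE]
  t1 <- rr[rr$timepoint == "t1", c("child_id", "informant_id", metric_cols)]
  t2 <- rr[rr$timepoint == "t2", c("child_id", "informant_id", metric_cols)]
  paired <- dplyr::inner_join(t1, t2, by = c("child_id", "informant_id"),
                              suffix = c("_a", "_b"))
  agreement_by_metric(paired, metric_cols, paste0("test_retest_", role),
                      conf_level, ci)
}

#' Timepoint stability of every metric, by informant role
#'
#' For each role and metric, runs [paired_stability()] across the two
#' timepoints on informants present at both, producing the familiar
#' means-and-SDs-by-timepoint table with the paired t-test alongside. A
#' metric whose differences are degenerate (zero variance) is reported with
#' `NA` test columns and a warning.
#'
#' @param metrics A scored metrics table from [score_cps()].
#' @param roles Roles to analyse.
#' @param metric_cols Metric columns to analyse.
#' @return A tibble: one row per role x metric with timepoint means/SDs,
#'   `t_statistic`, `df`, `p_value`, `n_pairs`.
#' @export
stability_table <- function(metrics, roles = c("mother", "father"),
                            metric_cols = cps_metric_names()) {
  combos <- tidyr::expand_grid(role = roles, metric = metric_cols)
  rows <- purrr::pmap(combos, function(role, metric) {
    rr <- metrics[metrics$role == role, , drop = FALSE]
    t1 <- rr[rr$timepoint == "t1", c("child_id", "informant_id", metric)]
    t2 <- rr[rr$timepoint == "t2", c("child_id", "informant_id", metric)]
    paired <- dplyr::inner_join(t1, t2, by = c("child_id", "informant_id"),
                                suffix = c("_a", "_b"))
    res <- tryCatch(
      paired_stability(paired[[paste0(metric, "_a")]],
                       paired[[paste0(metric, "_b")]]),
      playscale_too_few_pairs = function(e) NULL,
      playscale_degenerate = function(e) {
        rlang::warn(paste0("Degenerate differences for ", role, "/", metric,
                           "; t-test not reported"))
        NULL
      }
    )
    if (is.null(res)) {
      tibble::tibble(role = role, metric = metric,
                     mean_t1 = NA_real_, sd_t1 = NA_real_,
                     mean_t2 = NA_real_, sd_t2 = NA_real_,
                     t_statistic = NA_real_, df = NA_integer_,
                     p_value = NA_real_, n_pairs = nrow(paired))
    } else {
      tibble::tibble(role = role, metric = metric,
                     mean_t1 = res$mean_t1, sd_t1 = res$sd_t1,
                     mean_t2 = res$mean_t2, sd_t2 = res$sd_t2,
                     t_statistic = res$t_statistic, df = res$df,
                     p_value = res$p_value, n_pairs = res$n_pairs)
    }
  })
  dplyr::bind_rows(rows)
}
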