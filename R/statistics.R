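# Cohort statistics: group comparisons, regional contrasts, three-plane
# correlations, inter-observer reliability and sample size. Parametric tests
# throughout; normality is screened and reported but never switches the test.

test_result <- function(test, statistic, df, p_value, means = NULL, sds = NULL,
                        ns = NULL, ci = NULL, adjustment = "none", extra = NULL) {
  structure(
    c(list(test = test, statistic = unname(statistic), df = unname(df),
           p_value = unname(p_value), means = means, sds = sds, ns = ns,
           ci = ci, adjustment = adjustment), extra),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, df %s, p %.4g (%s)\n", x$test, x$statistic,
              paste(signif(x$df, 5), collapse = "/"), x$p_value, x$adjustment))
  if (!is.null(x$means)) {
    cat("  group means:", paste(sprintf("%.3f +/- %.3f", x$means, x$sds),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Two-sample t-test (Welch by default)
#'
#' @param a,b numeric vectors, n >= 2 each.
#' @param var_equal use the pooled-variance (Student) form instead of Welch.
#' @return a `test_result` with group means and SDs.
#' @export
two_sample_t <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("degenerate input: zero variance in both groups", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  test_result(if (var_equal) "two-sample t (pooled)" else "two-sample t (Welch)",
              ht$statistic, ht$parameter, ht$p.value,
              means = c(mean(a), mean(b)), sds = c(stats::sd(a), stats::sd(b)),
              ns = c(length(a), length(b)), ci = unname(ht$conf.int))
}

#' One-way ANOVA with Bonferroni-adjusted pairwise post hoc tests
#'
#' The omnibus F-test uses the classical pooled-variance one-way ANOVA; post
#' hoc pairwise pooled t-tests are Bonferroni-adjusted with the full family
#' size m = k(k-1)/2.
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) with k >= 3 levels, n >= 2 per group.
#' @return a `test_result`; element `pairwise` is a data.frame of pairwise
#'   comparisons with raw and adjusted p-values.
#' @export
anova_bonferroni <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 3) stop("need k >= 3 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("every group needs n >= 2", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  m <- k * (k - 1) / 2
  lev <- levels(groups)
  prs <- utils::combn(lev, 2)
  s2 <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  pw <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
    g1 <- values[groups == prs[1, j]]; g2 <- values[groups == prs[2, j]]
    se <- sqrt(s2 * (1 / length(g1) + 1 / length(g2)))
    tt <- (mean(g1) - mean(g2)) / se
    p <- 2 * stats::pt(-abs(tt), dfe)
    data.frame(group1 = prs[1, j], group2 = prs[2, j], statistic = tt,
               p_raw = p, p_adjusted = min(1, p * m), stringsAsFactors = FALSE)
  }))
  test_result("one-way ANOVA", an["groups", "F value"],
              c(an["groups", "Df"], dfe), an["groups", "Pr(>F)"],
              means = tapply(values, groups, mean),
              sds = tapply(values, groups, stats::sd),
              ns = as.integer(table(groups)),
              adjustment = "bonferroni",
              extra = list(pairwise = pw, family_size = m))
}

#' Paired t-test
#'
#' @param x,y paired numeric vectors of equal length, n >= 2.
#' @return a `test_result`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need n >= 2 pairs", call. = FALSE)
  if (stats::sd(x - y) == 0 && all(x == y)) {
    # identical pairs: define p = 1 rather than erroring on sd = 0
    return(test_result("paired t", 0, length(x) - 1, 1,
                       means = c(mean(x), mean(y)),
                       sds = c(stats::sd(x), stats::sd(y)), ns = length(x)))
  }
  if (stats::sd(x - y) == 0) {
    stop("degenerate input: all pairwise differences equal", call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  test_result("paired t", ht$statistic, ht$parameter, ht$p.value,
              means = c(mean(x), mean(y)), sds = c(stats::sd(x), stats::sd(y)),
              ns = length(x), ci = unname(ht$conf.int))
}

#' Pearson correlation with least-squares regression line
#'
#' @param x,y numeric vectors, n >= 3; `x` must vary.
#' @return object of class `association_result`: `pearson_r`, `p`, `slope`,
#'   `intercept`, `slope_ci` (95 percent), `n`.
#' @export
pearson_with_regression <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need n >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate input: x has zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit)["x", ]
  structure(list(pearson_r = unname(ct$estimate), p = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_ci = unname(ci), n = length(x)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("r = %.3f (p = %.3g), y = %.3f + %.3f x  [slope 95%% CI %.3f..%.3f], n = %d\n",
              x$pearson_r, x$p, x$intercept, x$slope, x$slope_ci[1],
              x$slope_ci[2], x$n))
  invisible(x)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measures
#'
#' Mean squares come from the subjects x raters two-way decomposition; the
#' confidence interval follows McGraw & Wong's F-based approximation.
#'
#' @param m numeric matrix, subjects in rows (>= 5), raters in columns (>= 2).
#' @param conf_level confidence level for the interval.
#' @return object of class `reliability_result`: `icc`, `ci`, `model`.
#' @export
icc_2_1 <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 5 || k < 2) stop("need >= 5 subjects and >= 2 raters", call. = FALSE)
  if (stats::sd(as.numeric(m)) == 0) {
    stop("degenerate input: constant rating matrix", call. = FALSE)
  }
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, col_m, "+") + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, ci = c(lower, upper), model = "ICC(2,1) absolute agreement",
                 n_subjects = n, n_raters = k),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("%s: %.3f (95%% CI %.3f-%.3f), %d subjects x %d raters\n",
              x$model, x$icc, x$ci[1], x$ci[2], x$n_subjects, x$n_raters))
  invisible(x)
}

#' Sample size for a two-group comparison of means
#'
#' Normal-approximation formula `n = 2 sigma^2 (z_{1-alpha/2} + z_power)^2 /
#' (mu1 - mu2)^2` per group, rounded up.
#'
#' @param mu1,mu2 group means (must differ).
#' @param sigma common standard deviation (> 0).
#' @param power target power in (0, 1).
#' @param alpha two-sided significance level in (0, 1).
#' @return integer sample size per group.
#' @export
sample_size_two_means <- function(mu1, mu2, sigma, power = 0.80, alpha = 0.05) {
  if (mu1 == mu2) stop("means must differ", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1) {
    stop("power and alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling(2 * sigma^2 * z^2 / (mu1 - mu2)^2))
}

#' Kolmogorov-Smirnov normality screen
#'
#' Tests the values against a normal distribution with moments estimated from
#' the sample. Reported for transparency only: the analysis battery stays
#' parametric regardless of the outcome.
#'
#' @param x numeric vector, n >= 5.
#' @return a `test_result`.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("need n >= 5", call. = FALSE)
  ht <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  test_result("Kolmogorov-Smirnov normality", ht$statistic, NA_real_, ht$p.value)
}

#' Run the full statistical battery on a cohort table
#'
#' Reproduces the study-style comparisons on any measured cohort: scoliotic
#' versus control delta(A-P) and rotation over matching segments, curve-type
#' ANOVA, apical versus junctional paired contrasts, and the coronal - axial -
#' sagittal coupling regressions against the simulated standing Cobb angle
#' (slopes also expressed per 10 degrees).
#'
#' @param tbl cohort table from [measure_cohort()] (scoliotic subjects in
#'   group `"ais"`, controls in group `"control"`).
#' @return list of class `paper_battery` with sections `group_comparisons`,
#'   `curve_type_anova`, `apical_vs_junctional`, `couplings`, `normality`.
#' @export
run_paper_battery <- function(tbl) {
  grab <- function(region, group, col = "delta_ap_percent") {
    tbl[[col]][tbl$region == region & tbl$group %in% group]
  }
  out <- list(group_comparisons = list(), curve_type_anova = list(),
              apical_vs_junctional = list(), couplings = list(),
              normality = list())
  pairs <- list(
    thoracic = c("main_thoracic", "thoracic_T4T12"),
    lumbar = c("thoracolumbar", "lumbar_L1L5")
  )
  for (nm in names(pairs)) {
    ais <- grab(pairs[[nm]][1], "ais")
    ctl <- grab(pairs[[nm]][2], "control")
    if (length(ais) >= 2 && length(ctl) >= 2) {
      out$group_comparisons[[paste0(nm, "_delta_ap")]] <- two_sample_t(ais, ctl)
      out$group_comparisons[[paste0(nm, "_rotation")]] <-
        two_sample_t(grab(pairs[[nm]][1], "ais", "axial_rotation_deg"),
                     grab(pairs[[nm]][2], "control", "axial_rotation_deg"))
    } else if (length(ais) >= 2) {
      warning("no control group: skipping ", nm, " group comparison")
    }
  }
  mt <- tbl[tbl$region == "main_thoracic" & tbl$group %in% "ais", ]
  if (nrow(mt) && length(unique(mt$pattern)) >= 3 &&
      min(table(mt$pattern)) >= 2) {
    out$curve_type_anova$thoracic_delta_ap <-
      anova_bonferroni(mt$delta_ap_percent, mt$pattern)
    tlr <- tbl[tbl$region == "thoracolumbar" & tbl$group %in% "ais", ]
    out$curve_type_anova$lumbar_delta_ap <-
      anova_bonferroni(tlr$delta_ap_percent, tlr$pattern)
  }
  for (jn in c("proximal_junctional", "distal_junctional")) {
    ap <- tbl[tbl$region == "apical_thoracic", c("subject_id", "delta_ap_percent")]
    ju <- tbl[tbl$region == jn, c("subject_id", "delta_ap_percent")]
    mg <- merge(ap, ju, by = "subject_id")
    if (nrow(mg) >= 2) {
      out$apical_vs_junctional[[paste0("apical_thoracic_vs_", jn)]] <-
        paired_t(mg$delta_ap_percent.x, mg$delta_ap_percent.y)
    }
  }
  if (nrow(mt) >= 3 && any(is.finite(mt$standing_cobb_deg))) {
    out$couplings$standing_vs_ct_cobb <-
      pearson_with_regression(mt$standing_cobb_deg, mt$cobb_deg)
    out$couplings$standing_vs_rotation <-
      pearson_with_regression(mt$standing_cobb_deg, mt$axial_rotation_deg)
    out$couplings$standing_vs_delta_ap <-
      pearson_with_regression(mt$standing_cobb_deg, mt$delta_ap_percent)
    out$couplings$rotation_vs_delta_ap <-
      pearson_with_regression(mt$axial_rotation_deg, mt$delta_ap_percent)
    out$couplings$per_10deg <- c(
      rotation = out$couplings$standing_vs_rotation$slope * 10,
      delta_ap = out$couplings$standing_vs_delta_ap$slope * 10
    )
  }
  for (rg in unique(tbl$region)) {
    v <- tbl$delta_ap_percent[tbl$region == rg]
    if (length(v) >= 5) out$normality[[rg]] <- ks_normality(v)
  }
  class(out) <- "paper_battery"
  out
}

#' @export
print.paper_battery <- function(x, ...) {
  for (sec in c("group_comparisons", "curve_type_anova", "apical_vs_junctional")) {
    if (length(x[[sec]])) {
      cat("##", sec, "\n")
      for (nm in names(x[[sec]])) { cat(nm, ": "); print(x[[sec]][[nm]]) }
    }
  }
  if (length(x$couplings)) {
    cat("## couplings\n")
    for (nm in setdiff(names(x$couplings), "per_10deg")) {
      cat(nm, ": "); print(x$couplings[[nm]])
    }
    if (!is.null(x$couplings$per_10deg)) {
      cat(sprintf("per 10 deg standing Cobb: rotation %+.2f deg, delta(A-P) %+.2f points\n",
                  x$couplings$per_10deg["rotation"], x$couplings$per_10deg["delta_ap"]))
    }
  }
  invisible(x)
}
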