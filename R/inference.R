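#' Per-clock paired differences between two timepoints
#'
#' For one subject, returns the vector of per-clock differences
#' `value(t2) - value(t1)` over the year-scale clocks present at both
#' timepoints; clocks missing (NA) at either timepoint are excluded and
#' reported via attribute `"excluded"`.
#'
#' @param metric an `age_metric_table`.
#' @param meta sample metadata.
#' @param subject subject ID.
#' @param t1,t2 timepoint labels.
#' @return Named numeric vector of per-clock differences (years).
#' @export
paired_differences <- function(metric, meta, subject, t1, t2) {
  stopifnot(inherits(metric, "age_metric_table"))
  meta <- align_meta(metric$values, meta)
  r1 <- meta$sample[meta$subject == subject & meta$timepoint == t1]
  r2 <- meta$sample[meta$subject == subject & meta$timepoint == t2]
  if (length(r1) != 1 || length(r2) != 1) {
    stop("subject ", subject, " lacks a unique sample at ", t1, " or ", t2)
  }
  d <- metric$values[r2, ] - metric$values[r1, ]
  excl <- names(d)[is.na(d)]
  d <- d[!is.na(d)]
  attr(d, "excluded") <- excl
  attr(d, "subject") <- subject
  attr(d, "pair") <- c(t1, t2)
  d
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (classical convention; the count is reported),
#' absolute values are mid-ranked under ties, and the two-sided p-value comes
#' from the exact signed-rank distribution when n <= 25 and there are no ties,
#' otherwise from the normal approximation with tie correction and continuity
#' correction. With no nonzero difference the p-value is defined as 1.
#'
#' @param diffs numeric vector of paired differences.
#' @return List with `p.value`, `statistic` (W+, sum of positive ranks),
#'   `n_used`, `n_zero`, `exact`.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  diffs <- diffs[!is.na(diffs)]
  n_zero <- sum(diffs == 0)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) {
    return(list(p.value = 1, statistic = NA_real_, n_used = 0L,
                n_zero = n_zero, exact = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= 25) {
    if (W > n * (n + 1) / 4) {
      p <- 2 * stats::psignrank(W - 1, n, lower.tail = FALSE)
    } else {
      p <- 2 * stats::psignrank(W, n)
    }
    p <- min(1, p)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- W - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(p.value = p, statistic = W, n_used = n, n_zero = n_zero, exact = exact)
}

#' Sign-flip permutation test on the mean paired difference
#'
#' Builds a null distribution by randomly assigning a positive or negative
#' sign to each per-clock difference and recomputing the mean, and reports the
#' two-sided p-value as the plain proportion of permuted means whose absolute
#' value is at least the absolute observed mean (no +1 smoothing, so zero
#' exceedances is reportable as "< 1/n_permutations"). Fully seeded.
#'
#' @param diffs numeric vector of paired differences (non-empty).
#' @param n_permutations number of sign assignments to draw (>= 1); default
#'   10000.
#' @param seed integer seed.
#' @return List with `mean` (observed mean difference), `p` (exceedance /
#'   n_permutations), `exceedance`, `n_permutations`, and `p_label` (the
#'   reporting string, `"< 1/n"` when the exceedance count is 0).
#' @export
signflip_permutation_test <- function(diffs, n_permutations = 10000, seed = 1) {
  diffs <- diffs[!is.na(diffs)]
  if (!length(diffs)) stop("empty difference vector")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  obs <- mean(diffs)
  set.seed(stage_seed(seed, "signflip"))
  n <- length(diffs)
  signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                  n_permutations, n)
  perm_means <- drop(signs %*% diffs) / n
  # ">= observed" with a one-ulp-scale tolerance: the identity and negation
  # assignments must count as exceedances even though the permuted mean is
  # accumulated in a different floating-point order than mean(diffs)
  exceed <- sum(abs(perm_means) >= abs(obs) * (1 - 1e-8))
  p <- exceed / n_permutations
  label <- if (exceed == 0) sprintf("< %.2e", 1 / n_permutations)
           else sprintf("%.4g", p)
  list(mean = obs, p = p, exceedance = exceed,
       n_permutations = as.integer(n_permutations), p_label = label)
}

#' Per-subject timepoint comparisons across the clock panel
#'
#' For each subject, treats the year-scale clocks as repeated measures and
#' compares two timepoints: mean paired difference, its standard error and
#' t-based 95% confidence interval, the paired Wilcoxon signed-rank p, and the
#' sign-flip permutation p. Permutation seeds are derived per (subject, pair,
#' metric) so results do not depend on evaluation order.
#'
#' @param metric an `age_metric_table`.
#' @param meta sample metadata.
#' @param t1,t2 timepoint labels.
#' @param subjects subjects to compare; default all in metadata.
#' @param n_permutations sign-flip draws per subject.
#' @param seed integer master seed.
#' @return data.frame, one row per subject: subject, metric, t1, t2, n_clocks,
#'   mean_diff, se, ci_low, ci_high, wilcoxon_p, perm_p, perm_p_label,
#'   exceedance, n_permutations.
#' @export
compare_timepoints <- function(metric, meta, t1, t2, subjects = NULL,
                               n_permutations = 10000, seed = 1) {
  subjects <- subjects %||% unique(meta$subject)
  rows <- lapply(subjects, function(s) {
    d <- paired_differences(metric, meta, s, t1, t2)
    n <- length(d)
    se <- stats::sd(d) / sqrt(n)
    ci <- mean(d) + c(-1, 1) * stats::qt(0.975, n - 1) * se
    w <- wilcoxon_signed_rank(d)
    pt <- signflip_permutation_test(
      d, n_permutations,
      seed = stage_seed(seed, paste(s, t1, t2, metric$metric)))
    data.frame(subject = s, metric = metric$metric, t1 = t1, t2 = t2,
               n_clocks = n, mean_diff = mean(d), se = se,
               ci_low = ci[1], ci_high = ci[2],
               wilcoxon_p = w$p.value, perm_p = pt$p,
               perm_p_label = pt$p_label, exceedance = pt$exceedance,
               n_permutations = pt$n_permutations,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Crossed random-intercept mixed model for a timepoint contrast
#'
#' Fits, by REML, `value ~ timepoint + (1 | subject) + (1 | clock)` on the
#' long-format metric values, using only the two contrasted timepoints (the
#' default) or the whole trajectory. The fixed effect for `t2` is the average
#' within-subject, within-clock change from `t1`. P-values use the
#' Satterthwaite degrees-of-freedom approximation (the method used is recorded
#' in the result); a boundary (zero) variance component produces a warning,
#' not an error.
#'
#' @param metric an `age_metric_table`.
#' @param meta sample metadata.
#' @param t1 reference timepoint.
#' @param t2 contrasted timepoint.
#' @param all_timepoints if `TRUE`, fit one model on all timepoints (with `t1`
#'   as reference level) instead of the two-timepoint subset.
#' @return Object of class `lmm_fit`: list with `estimates` (data.frame of
#'   fixed-effect contrasts: term, estimate, se, df, p), `varcomp` (subject,
#'   clock, residual SDs), `method`, `n_obs`, `singular`, and the underlying
#'   `fit`.
#' @export
fit_lmm <- function(metric, meta, t1, t2, all_timepoints = FALSE) {
  long <- metric_long(metric, meta)
  tps <- unique(meta$timepoint)
  keep_tps <- if (all_timepoints) tps else c(t1, t2)
  long <- long[long$timepoint %in% keep_tps, , drop = FALSE]
  if (length(unique(long$subject)) < 2) stop("need >= 2 subjects")
  if (length(unique(long$clock)) < 2) stop("need >= 2 clocks")
  if (!all(c(t1, t2) %in% long$timepoint)) {
    stop("both contrasted timepoints must be present")
  }
  long$timepoint <- factor(long$timepoint,
                           levels = c(t1, setdiff(keep_tps, t1)))
  fit <- suppressMessages(
    lmerTest::lmer(value ~ timepoint + (1 | subject) + (1 | clock),
                   data = long, REML = TRUE))
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    stop("LMM did not converge (optimizer code ", conv, "): ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  }
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("boundary fit: at least one variance component estimated as 0")
  }
  co <- stats::coef(summary(fit))
  terms <- rownames(co)[-1]
  est <- data.frame(term = sub("^timepoint", "", terms),
                    estimate = co[-1, "Estimate"],
                    se = co[-1, "Std. Error"],
                    df = co[-1, "df"],
                    p = co[-1, "Pr(>|t|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$sdcor, ifelse(is.na(vc$grp), "residual", vc$grp))
  names(varcomp)[names(varcomp) == "Residual"] <- "residual"
  structure(list(estimates = est, varcomp = varcomp,
                 method = "REML + Satterthwaite df", n_obs = nrow(long),
                 singular = singular, contrast = c(t1 = t1, t2 = t2),
                 fit = fit),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %d obs, contrast %s -> %s (%s)\n", x$n_obs,
              x$contrast[["t1"]], x$contrast[["t2"]], x$method))
  print(x$estimates, row.names = FALSE)
  cat("variance components (SD): ",
      paste(names(x$varcomp), sprintf("%.3f", x$varcomp), sep = "=",
            collapse = "  "), "\n")
  invisible(x)
}

#' Leave-one-clock-out sensitivity analysis
#'
#' Repeats the mean paired difference, Wilcoxon signed-rank and sign-flip
#' permutation calculations with each clock excluded in turn, and flags rows
#' where either p-value crosses the 0.05 threshold relative to the all-clock
#' analysis.
#'
#' @inheritParams compare_timepoints
#' @param subject subject ID.
#' @param alpha significance threshold used for crossing flags.
#' @return data.frame with one row per excluded clock: excluded_clock,
#'   mean_diff, wilcoxon_p, perm_p, crosses_alpha. The all-clock result is
#'   attached as attribute `"baseline"`.
#' @export
leave_one_out_sensitivity <- function(metric, meta, subject, t1, t2,
                                      n_permutations = 10000, seed = 1,
                                      alpha = 0.05) {
  d <- paired_differences(metric, meta, subject, t1, t2)
  if (length(d) < 3) stop("need >= 3 clocks for leave-one-out sensitivity")
  base_w <- wilcoxon_signed_rank(d)
  base_p <- signflip_permutation_test(
    d, n_permutations, seed = stage_seed(seed, paste("loo-base", subject)))
  rows <- lapply(seq_along(d), function(i) {
    di <- d[-i]
    w <- wilcoxon_signed_rank(di)
    p <- signflip_permutation_test(
      di, n_permutations,
      seed = stage_seed(seed, paste("loo", subject, names(d)[i])))
    data.frame(excluded_clock = names(d)[i], mean_diff = mean(di),
               wilcoxon_p = w$p.value, perm_p = p$p,
               crosses_alpha = xor(w$p.value < alpha, base_w$p.value < alpha) ||
                 xor(p$p < alpha, base_p$p < alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- data.frame(mean_diff = mean(d),
                                      wilcoxon_p = base_w$p.value,
                                      perm_p = base_p$p)
  out
}
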