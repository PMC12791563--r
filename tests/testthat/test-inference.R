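test_that("paired differences align clocks and report exclusions", {
  fx <- exact_cohort(n_clocks = 4)
  ead <- compute_ead(fx$clock_table, fx$metadata, fx$registry)
  d <- paired_differences(ead, fx$metadata, "A1", "L-45", "FD+4")
  expect_length(d, 4)
  # affine clocks: the change is slope * age increment, identical per clock set
  expect_equal(mean(d),
               mean(ead$values["A1_FD+4", ] - ead$values["A1_L-45", ]))

  withNA <- ead
  withNA$values["A1_FD+4", "clk2"] <- NA
  d2 <- paired_differences(withNA, fx$metadata, "A1", "L-45", "FD+4")
  expect_length(d2, 3)
  expect_equal(attr(d2, "excluded"), "clk2")

  expect_error(paired_differences(ead, fx$metadata, "A9", "L-45", "FD+4"),
               "A9")
})

test_that("signed-rank p-values match exact enumeration", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3))$p.value, 0.25)
  expect_equal(wilcoxon_signed_rank(c(1, -1))$p.value, 1)
  expect_equal(wilcoxon_signed_rank(numeric(0))$p.value, 1)
  expect_equal(wilcoxon_signed_rank(c(0, 0))$p.value, 1)

  set.seed(40)
  for (n in c(7, 12, 15)) {
    d <- round(rnorm(n), 3) + seq_len(n) * 1e-4   # distinct magnitudes
    got <- wilcoxon_signed_rank(d)
    expect_true(got$exact)
    expect_equal(got$p.value, enum_wilcoxon_p(d), tolerance = 1e-12)
  }

  # all one sign, n = 15: the extreme two-sided tail
  d <- (1:15) / 7
  expect_equal(wilcoxon_signed_rank(d)$p.value, 2 / 2^15, tolerance = 1e-12)
})

test_that("signed-rank approximation agrees with wilcox.test under ties", {
  d <- c(1, 1, -2, 2, 3, -3, 4, 5, 5, -6, 7, 8, 8, 9, -10, 11, 12, 12,
         13, -14, 15, 16, 17, 18, 19, 20)
  got <- wilcoxon_signed_rank(d)
  ref <- suppressWarnings(stats::wilcox.test(d, correct = TRUE))
  expect_false(got$exact)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("sign-flip permutation test matches enumeration and conventions", {
  # observed mean zero: every permuted mean qualifies
  r0 <- signflip_permutation_test(c(1, -1), 500, seed = 1)
  expect_equal(r0$p, 1)

  # exhaustive oracle at small n, Monte-Carlo within 3 binomial SDs
  set.seed(41)
  for (rep in 1:4) {
    d <- rnorm(9, 0.4, 1)
    p_true <- enum_signflip_p(d)
    est <- signflip_permutation_test(d, 4000, seed = rep)
    tol <- 3 * sqrt(p_true * (1 - p_true) / 4000)
    expect_lt(abs(est$p - p_true), max(tol, 1e-3))
  }

  # zero exceedances reported as "< 1/n_permutations"
  ext <- signflip_permutation_test(rep(1, 31), 10000, seed = 5)
  expect_equal(ext$exceedance, 0)
  expect_equal(ext$p_label, "< 1.00e-04")

  # determinism and sign antisymmetry
  d <- rnorm(12, 0.3)
  a <- signflip_permutation_test(d, 2000, seed = 9)
  b <- signflip_permutation_test(d, 2000, seed = 9)
  expect_identical(a, b)
  neg <- signflip_permutation_test(-d, 2000, seed = 9)
  expect_equal(neg$p, a$p)
  expect_equal(neg$mean, -a$mean)
  expect_equal(wilcoxon_signed_rank(-d)$p.value, wilcoxon_signed_rank(d)$p.value)
})

test_that("per-subject comparisons assemble all summary columns", {
  sim <- simulate_cohort(seed = 17)
  reg <- default_clock_registry()
  eaa <- compute_eaa(sim$clock_table, sim$metadata, reg)
  res <- compare_timepoints(eaa, sim$metadata, "L-45", "FD+7",
                            n_permutations = 500, seed = 3)
  expect_equal(nrow(res), 4)
  expect_equal(res$n_clocks, rep(31, 4))
  expect_true(all(res$ci_low < res$mean_diff & res$mean_diff < res$ci_high))
  expect_false(anyNA(res$se))
  # mean equals difference of across-clock means at the two timepoints
  d <- paired_differences(eaa, sim$metadata, "A2", "L-45", "FD+7")
  expect_equal(res$mean_diff[res$subject == "A2"], mean(d))
})

test_that("the crossed random-intercept model recovers a pure fixed effect", {
  # both random-effect variances truly zero, balanced design
  subjects <- sprintf("P%d", 1:4)
  clocks <- sprintf("c%d", 1:10)
  meta <- data.frame(sample = paste0(rep(subjects, 2), "_",
                                     rep(c("t1", "t2"), each = 4)),
                     subject = rep(subjects, 2), sex = 0,
                     age = 50, timepoint = rep(c("t1", "t2"), each = 4),
                     stringsAsFactors = FALSE)
  set.seed(42)
  vals <- matrix(rnorm(8 * 10, 0, 0.01), 8, 10,
                 dimnames = list(meta$sample, clocks))
  vals[meta$timepoint == "t2", ] <- vals[meta$timepoint == "t2", ] + 1.5
  metric <- structure(list(metric = "EAD", values = vals, fit = NULL),
                      class = "age_metric_table")
  fit <- suppressWarnings(fit_lmm(metric, meta, "t1", "t2"))
  grand <- mean(vals[meta$timepoint == "t2", ]) -
    mean(vals[meta$timepoint == "t1", ])
  expect_lt(abs(fit$estimates$estimate[1] - grand), 1e-6)
  expect_lt(fit$estimates$p[1], 1e-6)
})

test_that("REML variance components are recovered in simulation", {
  # subject SD 1, clock SD 2, residual SD 0.5
  n_sub <- 10; n_clk <- 15
  ests <- replicate(60, {
    u <- rnorm(n_sub, 0, 1); cclk <- rnorm(n_clk, 0, 2)
    long <- expand.grid(subject = factor(seq_len(n_sub)),
                        clock = factor(seq_len(n_clk)),
                        timepoint = c("t1", "t2"))
    long$value <- u[as.integer(long$subject)] + cclk[as.integer(long$clock)] +
      (long$timepoint == "t2") * 0.7 + rnorm(nrow(long), 0, 0.5)
    fit <- suppressWarnings(suppressMessages(
      lmerTest::lmer(value ~ timepoint + (1 | subject) + (1 | clock),
                     data = long, REML = TRUE)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    stats::setNames(vc$sdcor, vc$grp)[c("subject", "clock", "Residual")]
  })
  med <- apply(ests, 1, median)
  expect_lt(abs(med["subject"] - 1) / 1, 0.2)
  expect_lt(abs(med["clock"] - 2) / 2, 0.2)
  expect_lt(abs(med["Residual"] - 0.5) / 0.5, 0.2)
})

test_that("the REML objective prefers the fitted variance components to zero", {
  sim <- simulate_cohort(seed = 23)
  reg <- default_clock_registry()
  eaa <- compute_eaa(sim$clock_table, sim$metadata, reg)
  fit <- suppressWarnings(fit_lmm(eaa, sim$metadata, "L-45", "FD+7"))
  devfun <- lme4::lmer(value ~ timepoint + (1 | subject) + (1 | clock),
                       data = fit$fit@frame, REML = TRUE, devFunOnly = TRUE)
  expect_lte(devfun(fit$fit@theta), devfun(c(0, 0)) + 1e-8)
})

test_that("leave-one-out flags exactly the clock that masks significance", {
  # ten concordant clocks plus one extreme discordant clock
  diffs <- c(-6, 0.31, 0.27, 0.24, 0.22, 0.19, 0.26, 0.29, 0.21, 0.23, 0.25)
  clocks <- c("outlier", sprintf("c%d", 1:10))
  subjects <- "A1"
  meta <- data.frame(sample = c("A1_t1", "A1_t2", "A2_t1", "A2_t2"),
                     subject = c("A1", "A1", "A2", "A2"), sex = 0, age = 50,
                     timepoint = rep(c("t1", "t2"), 2),
                     stringsAsFactors = FALSE)
  vals <- matrix(0, 4, 11, dimnames = list(meta$sample, clocks))
  vals["A1_t2", ] <- diffs
  metric <- structure(list(metric = "EAD", values = vals, fit = NULL),
                      class = "age_metric_table")
  res <- leave_one_out_sensitivity(metric, meta, "A1", "t1", "t2",
                                   n_permutations = 20000, seed = 2)
  expect_equal(nrow(res), 11)
  expect_true(res$crosses_alpha[res$excluded_clock == "outlier"])
  expect_false(any(res$crosses_alpha[res$excluded_clock != "outlier"]))
  base <- attr(res, "baseline")
  expect_gt(base$perm_p, 0.5)
  expect_lt(res$perm_p[res$excluded_clock == "outlier"], 0.01)

  # identical differences: every exclusion row has the same mean
  vals2 <- vals; vals2["A1_t2", ] <- 1
  metric2 <- structure(list(metric = "EAD", values = vals2, fit = NULL),
                       class = "age_metric_table")
  res2 <- leave_one_out_sensitivity(metric2, meta, "A1", "t1", "t2",
                                    n_permutations = 200, seed = 2)
  expect_equal(unique(res2$mean_diff), 1)
})
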