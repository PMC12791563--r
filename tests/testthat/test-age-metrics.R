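make_fixture <- function(seed = 1, n = 20, k = 6) {
  set.seed(seed)
  meta <- data.frame(sample = sprintf("s%02d", 1:n),
                     subject = rep(sprintf("P%d", 1:4), length.out = n),
                     sex = rep(c(0, 1), length.out = n),
                     age = runif(n, 30, 70),
                     timepoint = rep(c("L-45", "FD+4", "FD+7", "R+1", "R+7"),
                                     each = n / 5),
                     stringsAsFactors = FALSE)
  clocks <- matrix(rnorm(n * k, 50, 8), n, k,
                   dimnames = list(meta$sample, paste0("clk", 1:k)))
  cells <- rdir <- matrix(rgamma(n * 12, shape = 2), n, 12)
  cells <- cells / rowSums(cells)
  dimnames(cells) <- list(meta$sample, default_cell_types())
  list(meta = meta, clocks = clocks, cells = cells)
}

test_that("EAD is the difference between clock estimate and chronological age", {
  fx <- make_fixture()
  ead <- compute_ead(fx$clocks, fx$meta)
  expect_equal(ead$values, fx$clocks - fx$meta$age)
  one <- matrix(c(67.7, 70.0), 2, 1,
                dimnames = list(fx$meta$sample[1:2], "clk"))
  meta2 <- fx$meta[1:2, ]; meta2$age <- 67.7
  expect_equal(unname(compute_ead(one, meta2)$values[, 1]), c(0, 2.3))
})

test_that("EAA residuals satisfy the OLS normal equations", {
  fx <- make_fixture(2)
  eaa <- compute_eaa(fx$clocks, fx$meta)
  r <- eaa$values
  expect_lt(max(abs(colSums(r))), 1e-8 * nrow(r))
  expect_lt(max(abs(crossprod(fx$meta$age, r))), 1e-6)
  expect_lt(max(abs(crossprod(fx$meta$sex, r))), 1e-6)

  # a perfect affine clock has residuals identically zero
  perfect <- matrix(3 + 0.9 * fx$meta$age, 20, 2,
                    dimnames = list(fx$meta$sample, c("a", "b")))
  expect_lt(max(abs(compute_eaa(perfect, fx$meta)$values)), 1e-9)
})

test_that("EAA/EAD/IEAA match explicit normal-equation solutions", {
  for (seed in 1:5) {
    fx <- make_fixture(seed)
    X_eaa <- cbind(1, fx$meta$age, fx$meta$sex)
    eaa <- compute_eaa(fx$clocks, fx$meta)
    expect_lt(max(abs(eaa$values - normal_eq_resid(fx$clocks, X_eaa))), 1e-8)

    X_ieaa <- cbind(X_eaa, fx$cells[, -12])
    ieaa <- suppressWarnings(compute_ieaa(fx$clocks, fx$meta, fx$cells))
    expect_lt(max(abs(ieaa$values - normal_eq_resid(fx$clocks, X_ieaa))), 1e-8)

    ead <- compute_ead(fx$clocks, fx$meta)
    expect_lt(max(abs(ead$values - (fx$clocks - fx$meta$age))), 1e-12)
  }
})

test_that("adding a constant shifts EAD but leaves EAA and IEAA unchanged", {
  fx <- make_fixture(3)
  eaa1 <- compute_eaa(fx$clocks, fx$meta)
  eaa2 <- compute_eaa(fx$clocks + 7, fx$meta)
  expect_lt(max(abs(eaa1$values - eaa2$values)), 1e-8)
  ieaa1 <- suppressWarnings(compute_ieaa(fx$clocks, fx$meta, fx$cells))
  ieaa2 <- suppressWarnings(compute_ieaa(fx$clocks + 7, fx$meta, fx$cells))
  expect_lt(max(abs(ieaa1$values - ieaa2$values)), 1e-8)
  ead1 <- compute_ead(fx$clocks, fx$meta)
  ead2 <- compute_ead(fx$clocks + 7, fx$meta)
  expect_equal(ead2$values, ead1$values + 7)
})

test_that("IEAA equals EAA when cell fractions are constant across samples", {
  fx <- make_fixture(4)
  flat <- matrix(1 / 12, nrow(fx$cells), 12,
                 dimnames = dimnames(fx$cells))
  eaa <- compute_eaa(fx$clocks, fx$meta)
  expect_warning(ieaa <- compute_ieaa(fx$clocks, fx$meta, flat), "constant")
  expect_lt(max(abs(ieaa$values - eaa$values)), 1e-10)
})

test_that("IEAA residuals are invariant to which simplex cell is dropped", {
  fx <- make_fixture(5)
  cells <- fx$cells / rowSums(fx$cells)
  i1 <- suppressWarnings(compute_ieaa(fx$clocks, fx$meta, cells))
  i2 <- suppressWarnings(compute_ieaa(fx$clocks, fx$meta, cells,
                                      drop_cell = "Bas"))
  expect_lt(max(abs(i1$values - i2$values)), 1e-8)
})

test_that("IEAA guards against saturation and warns on low residual df", {
  fx <- make_fixture(6)
  small <- fx$clocks[1:10, ]
  expect_error(
    suppressWarnings(compute_ieaa(small, fx$meta[1:10, ], fx$cells[1:10, ])),
    "saturated")
  expect_warning(compute_ieaa(fx$clocks, fx$meta, fx$cells), "near-saturated")
})

test_that("pace deltas are zero for constant pace and averaged correctly", {
  fx <- make_fixture(7)
  pace <- stats::setNames(rep(1, 20), fx$meta$sample)
  pc <- compute_pace_changes(pace, fx$meta, reference = "L-45")
  expect_equal(max(abs(pc$deltas$delta)), 0)
  expect_equal(max(abs(pc$cohort_means$mean_delta)), 0)

  pace2 <- stats::setNames(1 + (fx$meta$timepoint == "FD+4") * 0.01 * 2,
                           fx$meta$sample)
  pc2 <- compute_pace_changes(pace2, fx$meta, reference = "L-45")
  expect_equal(pc2$cohort_means$mean_delta[pc2$cohort_means$timepoint == "FD+4"],
               0.02)
})

test_that("category means equal unweighted means over member clocks", {
  fx <- make_fixture(8)
  reg <- clock_registry(colnames(fx$clocks),
                        c("chronological", "chronological", "mortality",
                          "mortality", "stochastic", "organ"),
                        rep("years", 6))
  ead <- compute_ead(fx$clocks, fx$meta, reg)
  cm <- category_means(ead, reg, fx$meta,
                       pairs = list(c("L-45", "FD+4"), c("L-45", "FD+7")))
  ch <- metric_change(ead, fx$meta, "L-45", "FD+4")
  clock_means <- colMeans(ch)
  for (cat in unique(reg$category)) {
    members <- reg$clock[reg$category == cat]
    got <- cm$mean_change[cm$category == cat & cm$t2 == "FD+4"]
    expect_equal(got, mean(clock_means[members]), tolerance = 1e-12)
  }
  gm <- attr(cm, "grand_means")
  expect_equal(gm$grand_mean[gm$t2 == "FD+4"],
               mean(cm$mean_change[cm$t2 == "FD+4"]), tolerance = 1e-12)

  # one category -> category mean is the overall clock mean
  reg1 <- clock_registry(colnames(fx$clocks), rep("organ", 6), rep("years", 6))
  cm1 <- category_means(compute_ead(fx$clocks, fx$meta, reg1), reg1, fx$meta,
                        pairs = list(c("L-45", "FD+7")))
  expect_equal(cm1$mean_change,
               mean(metric_change(ead, fx$meta, "L-45", "FD+7")),
               tolerance = 1e-12)
})

test_that("correlation structure counts pairs and labels strata", {
  fx <- make_fixture(9)
  ead <- compute_ead(fx$clocks, fx$meta)
  cs <- correlation_structure(ead, fx$meta)
  expect_equal(nrow(cs$pairs), 20 * 19 / 2)
  expect_setequal(unique(cs$pairs$stratum),
                  c("same_individual", "same_timepoint", "neither"))

  # duplicated metric vectors correlate exactly 1
  dup <- ead
  dup$values[2, ] <- dup$values[1, ]
  cs2 <- correlation_structure(dup, fx$meta)
  expect_equal(cs2$matrix[1, 2], 1)

  # zero-variance vector recorded as missing, not an error
  flatrow <- ead
  flatrow$values[3, ] <- 5
  cs3 <- correlation_structure(flatrow, fx$meta)
  expect_true(anyNA(cs3$matrix[3, -3]))
  expect_gt(sum(cs3$summary$n_missing), 0)
})

test_that("persistent subject effects raise same-individual correlations", {
  cp <- cohort_params(sigma_u = 0, sigma_us = 3, sigma_eps = 0.3,
                      delta = stats::setNames(rep(0, 5),
                                              cohort_params()$timepoints))
  sim <- simulate_cohort(cp, default_clock_params(noise_sd = 0.3), seed = 31)
  eaa <- compute_eaa(sim$clock_table, sim$metadata, default_clock_registry())
  cs <- correlation_structure(eaa, sim$metadata)
  s <- cs$summary
  expect_gt(s$mean[s$stratum == "same_individual"],
            s$mean[s$stratum == "same_timepoint"])
})

test_that("strict joins reject samples missing from metadata", {
  fx <- make_fixture(10)
  expect_error(compute_ead(fx$clocks, fx$meta[-1, ]), "missing from metadata")
  expect_error(compute_ead(fx$clocks[-1, ], fx$meta), "missing from table")
})
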