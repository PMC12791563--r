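# Independent oracles and fixture builders shared across tests.

# Exhaustive sign-flip p: enumerate all 2^n sign assignments.
enum_signflip_p <- function(d) {
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  mean(abs(signs %*% d / n) >= abs(mean(d)) - 1e-12)
}

# Exact two-sided signed-rank p by enumeration of sign assignments
# (2 * min tail, capped at 1 — the same convention as the implementation).
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- drop(signs %*% r)
  min(1, 2 * min(mean(W <= W_obs + 1e-9), mean(W >= W_obs - 1e-9)))
}

# OLS residuals via explicit normal equations (independent of the package's
# QR path).
normal_eq_resid <- function(Y, X) {
  B <- solve(crossprod(X), crossprod(X, Y))
  Y - X %*% B
}

# All-subsets general dominance by direct lm() fits (independent oracle).
brute_force_dominance <- function(y, X) {
  p <- ncol(X)
  masks <- 1:(2^p - 1)
  r2 <- numeric(2^p)
  for (m in masks) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0L)
    fit <- stats::lm(y ~ X[, idx, drop = FALSE])
    r2[m + 1] <- summary(fit)$r.squared
  }
  gen <- numeric(p)
  all_masks <- 0:(2^p - 1)
  sizes <- vapply(all_masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0L),
                  integer(1))
  for (j in seq_len(p)) {
    bj <- bitwShiftL(1L, j - 1L)
    without <- all_masks[bitwAnd(all_masks, bj) == 0L]
    inc <- r2[without + bj + 1] - r2[without + 1]
    gen[j] <- mean(tapply(inc, sizes[without + 1], mean))
  }
  names(gen) <- colnames(X)
  list(general = gen, full_r2 = r2[2^p])
}

# Small deterministic fixture: a no-noise cohort where every clock is an exact
# affine function of age and sex.
exact_cohort <- function(n_clocks = 5) {
  reg <- clock_registry(paste0("clk", seq_len(n_clocks)),
                        rep("chronological", n_clocks),
                        rep("years", n_clocks))
  cp <- cohort_params(delta = c(`L-45` = 0, `FD+4` = 0, `FD+7` = 0,
                                `R+1` = 0, `R+7` = 0),
                      sigma_u = 0, sigma_us = 0, sigma_eps = 0)
  pars <- clock_params(reg, intercept = seq_len(n_clocks),
                       slope = 0.8 + 0.05 * seq_len(n_clocks),
                       sex_effect = 0.3, noise_sd = 0, gamma = 0,
                       weights = matrix(0, n_clocks, 12,
                                        dimnames = list(reg$clock,
                                                        default_cell_types())))
  sim <- generate_clock_estimates(cp, pars, seed = 1)
  sim$registry <- reg
  sim
}
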