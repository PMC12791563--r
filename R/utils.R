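# Internal helpers shared across modules.

# Derive a per-stage RNG seed from the master seed so that adding a stage never
# perturbs the draws of earlier stages. Result stays below 2^31 - 1.
stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(as.character(stage))
  h <- sum(codes * seq_along(codes)) %% 19997L
  as.integer((abs(as.integer(seed)) %% 100000L) * 20011L + h)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)),
              nrow = n, ncol = k)
  g / rowSums(g)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Full-precision numeric formatting so CSV round-trips are exact.
fmt_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

df_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- fmt_full(df[[j]])
  }
  df
}

log_stage <- function(stage, ...) {
  kv <- c(...)
  msg <- paste0("stage=", stage)
  if (length(kv)) {
    msg <- paste(msg, paste(names(kv), unname(kv), sep = "=", collapse = " "))
  }
  message(msg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
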