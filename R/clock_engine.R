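#' Linear clock model
#'
#' A linear epigenetic clock: an intercept plus a sparse map from CpG IDs to
#' coefficients (years per beta unit). A post-transform hook is reserved for
#' clocks trained on a transformed age scale; only the identity transform ships
#' enabled.
#'
#' @param name clock name.
#' @param intercept intercept in years.
#' @param coefficients named numeric vector, CpG ID -> coefficient; must be
#'   non-empty with unique names.
#' @param transform `"identity"` (the only built-in) or a function applied to
#'   the linear predictor.
#' @return A list of class `clock_model`.
#' @export
clock_model <- function(name, intercept, coefficients, transform = "identity") {
  if (!length(coefficients)) stop("coefficient map must be non-empty")
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients))) {
    stop("coefficients must be uniquely named by CpG ID")
  }
  if (is.character(transform) && transform != "identity") {
    stop("unknown post-transform tag: ", transform)
  }
  structure(list(name = as.character(name), intercept = as.numeric(intercept),
                 coefficients = coefficients, transform = transform),
            class = "clock_model")
}

#' Apply a linear clock to a beta matrix
#'
#' Computes `age(sample) = intercept + sum_j coef_j * beta[j, sample]`. CpGs in
#' the model but absent from the matrix are imputed from a user-supplied
#' per-CpG default (e.g. blood-specific medians); CpGs missing from both are
#' dropped. A coverage report (found / imputed / dropped counts) is attached as
#' attribute `"coverage"`.
#'
#' @param beta CpG x samples matrix with values in `[0, 1]`.
#' @param model a [clock_model()].
#' @param impute optional named numeric of per-CpG fallback beta values.
#' @param max_missing_fraction error if more than this fraction of model CpGs
#'   is absent from `beta` (after imputation lookup fails too, dropped CpGs
#'   still count as missing from the matrix).
#' @return Named numeric vector of per-sample ages (years).
#' @export
apply_linear_clock <- function(beta, model, impute = NULL,
                               max_missing_fraction = 0.2) {
  stopifnot(inherits(model, "clock_model"))
  beta <- as.matrix(beta)
  cpgs <- names(model$coefficients)
  present <- cpgs %in% rownames(beta)
  frac_missing <- mean(!present)
  if (frac_missing > max_missing_fraction) {
    stop(sprintf("%.1f%% of model CpGs absent from beta matrix (limit %.1f%%)",
                 100 * frac_missing, 100 * max_missing_fraction))
  }
  miss <- cpgs[!present]
  imputable <- miss[miss %in% names(impute)]
  dropped <- setdiff(miss, imputable)
  B <- matrix(0, length(cpgs), ncol(beta),
              dimnames = list(cpgs, colnames(beta)))
  B[cpgs[present], ] <- beta[cpgs[present], , drop = FALSE]
  if (length(imputable)) B[imputable, ] <- impute[imputable]
  coefs <- model$coefficients
  coefs[dropped] <- 0
  lp <- model$intercept + drop(crossprod(B, coefs))
  if (is.function(model$transform)) lp <- model$transform(lp)
  names(lp) <- colnames(beta)
  attr(lp, "coverage") <- list(n_model = length(cpgs),
                               n_found = sum(present),
                               n_imputed = length(imputable),
                               n_dropped = length(dropped))
  lp
}

#' Reference-based cell-type deconvolution
#'
#' Estimates each sample's cell composition by non-negative least squares of
#' its methylation profile on the pure-cell reference profiles, followed by
#' sum-to-one renormalisation. Per-sample residual norms (from the NNLS fit,
#' before renormalisation) are attached as attribute `"residuals"`.
#'
#' @param beta CpG x samples matrix.
#' @param reference CpG x cell-type matrix of pure profiles (values in
#'   `[0, 1]`, >= 2 cell types). CpGs shared with `beta` must number at least
#'   the cell types, and the shared reference must be full column rank.
#' @return Samples x cell-types fraction matrix; each row sums to 1.
#' @export
deconvolve_cell_fractions <- function(beta, reference) {
  beta <- as.matrix(beta)
  reference <- as.matrix(reference)
  if (ncol(reference) < 2) stop("reference needs >= 2 cell types")
  if (any(reference < 0 | reference > 1)) stop("reference values must lie in [0, 1]")
  shared <- intersect(rownames(reference), rownames(beta))
  if (length(shared) < ncol(reference)) {
    stop("need at least as many shared CpGs as cell types (have ",
         length(shared), ")")
  }
  R <- reference[shared, , drop = FALSE]
  qrR <- qr(R)
  if (qrR$rank < ncol(R)) {
    dep <- colnames(R)[qrR$pivot[(qrR$rank + 1):ncol(R)]]
    stop("reference is rank-deficient; collinear cell profiles: ",
         paste(dep, collapse = ", "))
  }
  samples <- colnames(beta)
  out <- matrix(NA_real_, length(samples), ncol(R),
                dimnames = list(samples, colnames(R)))
  resid <- stats::setNames(numeric(length(samples)), samples)
  for (s in seq_along(samples)) {
    y <- beta[shared, s]
    fit <- pracma::lsqnonneg(R, y)
    x <- fit$x
    resid[s] <- sqrt(sum((R %*% x - y)^2))
    tot <- sum(x)
    if (tot <= 0) stop("all-zero NNLS solution for sample ", samples[s])
    out[s, ] <- x / tot
  }
  attr(out, "residuals") <- resid
  out
}

#' Read / write a linear clock model CSV
#'
#' Format: a first comment line `#clock=<name>;intercept=<value>` followed by a
#' two-column CSV (`CpG`, `coefficient`).
#'
#' @param path file path.
#' @return [read_clock_model()] returns a [clock_model()].
#' @export
read_clock_model <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^#clock=", header)) {
    stop("clock model file must start with '#clock=<name>;intercept=<value>'")
  }
  fields <- strsplit(sub("^#", "", header), ";")[[1]]
  kv <- strsplit(fields, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)
  clock_model(vals[["clock"]], as.numeric(vals[["intercept"]]),
              stats::setNames(df$coefficient, df$CpG))
}

#' @rdname read_clock_model
#' @param model a [clock_model()] to write.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#clock=%s;intercept=%s", model$name,
                     sprintf("%.17g", model$intercept)), con)
  df <- data.frame(CpG = names(model$coefficients),
                   coefficient = fmt_full(unname(model$coefficients)))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
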