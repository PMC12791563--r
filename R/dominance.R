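#' Build the dominance-analysis dataset from EAA, IEAA and cell fractions
#'
#' The outcome is the difference EAA - IEAA stacked over (sample, clock)
#' observations; the predictors are each sample's 12 cell fractions, repeated
#' across that sample's clock rows and centred. Stacking across clocks matches
#' reporting a single variance share per cell type over the whole clock panel.
#'
#' @param eaa,ieaa `age_metric_table`s over identical samples and clocks.
#' @param cells samples x cell-types fraction matrix.
#' @return List with `outcome` (numeric vector), `predictors` (centred
#'   matrix), `index` (data.frame sample, clock).
#' @export
build_dominance_dataset <- function(eaa, ieaa, cells) {
  stopifnot(inherits(eaa, "age_metric_table"), inherits(ieaa, "age_metric_table"))
  if (!identical(dim(eaa$values), dim(ieaa$values)) ||
      !identical(dimnames(eaa$values), dimnames(ieaa$values))) {
    stop("EAA and IEAA tables must cover identical samples and clocks")
  }
  cells <- as.matrix(cells)
  miss <- setdiff(rownames(eaa$values), rownames(cells))
  if (length(miss)) stop("samples missing from cell table: ",
                         paste(miss, collapse = ", "))
  cells <- cells[rownames(eaa$values), , drop = FALSE]
  n <- nrow(eaa$values); k <- ncol(eaa$values)
  outcome <- as.vector(eaa$values - ieaa$values)
  predictors <- cells[rep(seq_len(n), times = k), , drop = FALSE]
  predictors <- sweep(predictors, 2, colMeans(predictors))
  rownames(predictors) <- NULL
  index <- data.frame(sample = rep(rownames(eaa$values), k),
                      clock = rep(colnames(eaa$values), each = n),
                      stringsAsFactors = FALSE)
  list(outcome = outcome, predictors = predictors, index = index)
}

#' Dominance analysis (general dominance weights)
#'
#' Enumerates all `2^p - 1` non-empty predictor subsets, computes each
#' subset's R-squared by OLS, and reports for every predictor its general
#' dominance weight: the average, over model sizes, of its mean incremental
#' R-squared when added to subsets lacking it. General dominance weights are
#' the Shapley values of the R-squared set function, so they always sum to the
#' full-model R-squared. Conditional dominance (mean increment per subset
#' size) and the complete-dominance pairwise matrix are also returned.
#'
#' Subsets whose cross-product matrix is singular (e.g. the full set of 12
#' simplex-constrained fractions, whose centred columns sum to zero) are fit
#' by the minimum-norm solution; their R-squared, being a projection onto the
#' column space, is still well defined. A single warning reports how many
#' subsets were degenerate.
#'
#' @param outcome numeric response vector.
#' @param predictors numeric matrix of p <= 15 columns; `n > p + 1` required.
#' @return Object of class `dominance_result`: list with `general` (named
#'   weights), `marginal` (single-predictor R-squared), `conditional`
#'   (p x p matrix, predictor x subset size), `complete` (p x p logical
#'   dominance matrix), `full_r2`, `n_models`, `n_degenerate`.
#' @export
dominance_analysis <- function(outcome, predictors) {
  X <- as.matrix(predictors)
  y <- as.numeric(outcome)
  p <- ncol(X)
  n <- length(y)
  if (nrow(X) != n) stop("outcome and predictors have different lengths")
  if (p < 1 || p > 15) stop("between 1 and 15 predictors supported")
  if (n <= p + 1) stop("need more observations than predictors + 1")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  sst <- sum(yc^2)
  if (sst == 0) stop("outcome has zero variance")
  G <- crossprod(Xc)
  g <- drop(crossprod(Xc, yc))
  bits <- bitwShiftL(1L, seq_len(p) - 1L)
  n_masks <- bitwShiftL(1L, p)
  r2 <- numeric(n_masks)            # r2[mask + 1]; empty model = 0
  n_degenerate <- 0L
  for (m in seq_len(n_masks - 1L)) {
    idx <- which(bitwAnd(m, bits) != 0L)
    Gm <- G[idx, idx, drop = FALSE]
    gm <- g[idx]
    b <- tryCatch(solve(Gm, gm), error = function(e) NULL)
    if (is.null(b)) {
      n_degenerate <- n_degenerate + 1L
      b <- drop(MASS::ginv(Gm) %*% gm)
    }
    r2[m + 1L] <- sum(b * gm) / sst
  }
  if (n_degenerate > 0) {
    warning(n_degenerate, " predictor subset(s) were rank-deficient; ",
            "minimum-norm fits used")
  }
  general <- stats::setNames(numeric(p), colnames(X))
  conditional <- matrix(NA_real_, p, p,
                        dimnames = list(colnames(X), paste0("size", 0:(p - 1))))
  all_masks <- 0:(n_masks - 1L)
  sizes <- vapply(all_masks, function(m) sum(bitwAnd(m, bits) != 0L), integer(1))
  for (j in seq_len(p)) {
    bj <- bits[j]
    without_j <- all_masks[bitwAnd(all_masks, bj) == 0L]
    inc <- r2[without_j + bj + 1L] - r2[without_j + 1L]
    sz <- sizes[without_j + 1L]
    by_size <- tapply(inc, sz, mean)
    conditional[j, ] <- as.numeric(by_size)
    general[j] <- mean(by_size)
  }
  # complete dominance: i dominates j if i's increment >= j's for every subset
  # of the remaining predictors
  complete <- matrix(NA, p, p, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      both <- bitwOr(bits[i], bits[j])
      base <- all_masks[bitwAnd(all_masks, both) == 0L]
      inc_i <- r2[base + bits[i] + 1L] - r2[base + 1L]
      inc_j <- r2[base + bits[j] + 1L] - r2[base + 1L]
      complete[i, j] <- all(inc_i >= inc_j)
      complete[j, i] <- all(inc_j >= inc_i)
    }
  }
  structure(list(general = general,
                 marginal = stats::setNames(r2[bits + 1L], colnames(X)),
                 conditional = conditional,
                 complete = complete,
                 full_r2 = r2[n_masks],
                 n_models = n_masks - 1L,
                 n_degenerate = n_degenerate),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("<dominance_result> %d predictors, %d subset models, full R2 = %.4f\n",
              length(x$general), x$n_models, x$full_r2))
  ord <- order(x$general, decreasing = TRUE)
  df <- data.frame(predictor = names(x$general)[ord],
                   general_dominance = x$general[ord],
                   marginal_R2 = x$marginal[ord], row.names = NULL)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export a dominance result as a data.frame
#'
#' @param x a `dominance_result`.
#' @param ... unused.
#' @return data.frame keyed by cell type / predictor with columns
#'   `general_dominance`, `marginal_R2`, `full_model_R2`.
#' @export
as.data.frame.dominance_result <- function(x, ...) {
  data.frame(predictor = names(x$general),
             general_dominance = unname(x$general),
             marginal_R2 = unname(x$marginal),
             full_model_R2 = x$full_r2,
             stringsAsFactors = FALSE)
}
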