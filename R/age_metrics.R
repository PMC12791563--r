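#' @title Age-acceleration metrics
#' @description Computation of the three per-clock biological-age metrics used
#'   throughout the package: EAD (epigenetic age difference, clock estimate
#'   minus chronological age), EAA (residual after regressing the clock
#'   estimate on chronological age and sex over all samples pooled), and IEAA
#'   (residual after additionally adjusting for 12 predicted immune-cell
#'   fractions). Only year-scale clocks are eligible; pace clocks are analysed
#'   with [compute_pace_changes()].
#' @name age_metrics
NULL

# Strictly align metadata rows to the clock-table samples: any unmatched sample
# on either side is an error, because at this cohort size silent drops would
# distort inference.
align_meta <- function(values, meta) {
  if (is.null(rownames(values))) stop("clock table must have sample row names")
  extra <- setdiff(rownames(values), meta$sample)
  if (length(extra)) {
    stop("samples missing from metadata: ", paste(extra, collapse = ", "))
  }
  extra2 <- setdiff(meta$sample, rownames(values))
  if (length(extra2)) {
    stop("metadata samples missing from table: ", paste(extra2, collapse = ", "))
  }
  meta[match(rownames(values), meta$sample), , drop = FALSE]
}

select_year_clocks <- function(values, registry) {
  if (is.null(registry)) return(values)
  keep <- intersect(colnames(values), year_clocks(registry))
  values[, keep, drop = FALSE]
}

new_age_metric <- function(metric, values, fit = NULL) {
  structure(list(metric = metric, values = values, fit = fit),
            class = "age_metric_table")
}

#' @export
print.age_metric_table <- function(x, ...) {
  cat(sprintf("<age_metric_table> metric=%s  %d samples x %d clocks\n",
              x$metric, nrow(x$values), ncol(x$values)))
  if (!is.null(x$fit)) {
    cat(sprintf("  adjusted for: %s (design rank %d)\n",
                paste(x$fit$predictors, collapse = ", "), x$fit$rank))
  }
  invisible(x)
}

# Multi-response OLS residuals via one QR decomposition; audit keeps
# coefficients, rank and retained predictor names.
residual_fit <- function(Y, X, predictors) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dep, collapse = ", "))
  }
  res <- qr.resid(qrX, Y)
  coefs <- qr.coef(qrX, Y)
  list(residuals = res, coefficients = coefs, rank = qrX$rank,
       predictors = predictors)
}

#' Epigenetic age difference (EAD)
#'
#' `EAD(clock, sample) = clock estimate - chronological age`.
#'
#' @param clocks samples x clocks matrix of epigenetic age estimates (years).
#' @param meta metadata data.frame with columns `sample`, `subject`, `sex`,
#'   `age`, `timepoint` (see [read_metadata()]).
#' @param registry optional [clock_registry()]; if given, only year-scale
#'   clocks are used.
#' @return An `age_metric_table` (metric `"EAD"`).
#' @export
compute_ead <- function(clocks, meta, registry = NULL) {
  values <- select_year_clocks(as.matrix(clocks), registry)
  meta <- align_meta(values, meta)
  new_age_metric("EAD", values - meta$age)
}

#' Epigenetic age acceleration (EAA)
#'
#' Per clock, the residual of an ordinary least-squares regression of the
#' clock estimate on chronological age and sex code (Female = 1, Male = 0),
#' fit over all samples pooled. Residuals per clock sum to zero over the
#' fitting samples by construction.
#'
#' @inheritParams compute_ead
#' @return An `age_metric_table` (metric `"EAA"`) whose `fit` element stores
#'   per-clock coefficients, design rank and retained predictors.
#' @export
compute_eaa <- function(clocks, meta, registry = NULL) {
  values <- select_year_clocks(as.matrix(clocks), registry)
  meta <- align_meta(values, meta)
  if (nrow(values) < 4) stop("EAA needs at least 4 samples")
  X <- cbind(`(Intercept)` = 1, age = meta$age, sex = meta$sex)
  preds <- c("age", "sex")
  if (stats::var(meta$sex) == 0) {
    warning("sex is constant across samples; dropping sex from the EAA design")
    X <- X[, colnames(X) != "sex", drop = FALSE]
    preds <- "age"
  }
  fit <- residual_fit(values, X, preds)
  new_age_metric("EAA", fit$residuals,
                 fit[c("coefficients", "rank", "predictors")])
}

#' Intrinsic epigenetic age acceleration (IEAA)
#'
#' Per clock, the residual of an OLS regression of the clock estimate on
#' chronological age, sex, and the predicted fractions of 12 immune cell
#' types. Because fractions sum to one, the last-listed cell type is dropped
#' from the design (residuals are invariant to which one is dropped);
#' zero-variance cell columns are dropped too, so if all fractions are
#' identical across samples IEAA reduces to EAA.
#'
#' @inheritParams compute_ead
#' @param cells samples x cell-types fraction matrix (row names = sample IDs).
#' @param drop_cell cell type to drop for simplex collinearity; default the
#'   last column.
#' @return An `age_metric_table` (metric `"IEAA"`).
#' @export
compute_ieaa <- function(clocks, meta, cells, registry = NULL,
                         drop_cell = NULL) {
  values <- select_year_clocks(as.matrix(clocks), registry)
  meta <- align_meta(values, meta)
  cells <- as.matrix(cells)
  miss <- setdiff(rownames(values), rownames(cells))
  if (length(miss)) {
    stop("samples missing from cell table: ", paste(miss, collapse = ", "))
  }
  cells <- cells[rownames(values), , drop = FALSE]
  drop_cell <- drop_cell %||% colnames(cells)[ncol(cells)]
  if (!drop_cell %in% colnames(cells)) stop("unknown cell type: ", drop_cell)
  keep <- setdiff(colnames(cells), drop_cell)
  cellX <- cells[, keep, drop = FALSE]
  const <- apply(cellX, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    warning("dropping constant cell-fraction column(s): ",
            paste(colnames(cellX)[const], collapse = ", "))
    cellX <- cellX[, !const, drop = FALSE]
  }
  X <- cbind(`(Intercept)` = 1, age = meta$age, sex = meta$sex, cellX)
  preds <- c("age", "sex", colnames(cellX))
  if (stats::var(meta$sex) == 0) {
    warning("sex is constant across samples; dropping sex from the IEAA design")
    X <- X[, colnames(X) != "sex", drop = FALSE]
    preds <- setdiff(preds, "sex")
  }
  if (nrow(X) <= ncol(X)) {
    stop("model saturated: ", nrow(X), " samples for ", ncol(X),
         " design columns")
  }
  if (nrow(X) - ncol(X) < 10) {
    warning("IEAA design is near-saturated: residual df = ", nrow(X) - ncol(X))
  }
  fit <- residual_fit(values, X, preds)
  new_age_metric("IEAA", fit$residuals,
                 fit[c("coefficients", "rank", "predictors")])
}

#' Per-subject metric change between two timepoints
#'
#' @param metric an `age_metric_table`.
#' @param meta sample metadata.
#' @param t1,t2 timepoint labels; the change is value(t2) - value(t1).
#' @return Subjects x clocks matrix of changes.
#' @export
metric_change <- function(metric, meta, t1, t2) {
  stopifnot(inherits(metric, "age_metric_table"))
  meta <- align_meta(metric$values, meta)
  subjects <- unique(meta$subject)
  out <- matrix(NA_real_, length(subjects), ncol(metric$values),
                dimnames = list(subjects, colnames(metric$values)))
  for (s in subjects) {
    r1 <- meta$sample[meta$subject == s & meta$timepoint == t1]
    r2 <- meta$sample[meta$subject == s & meta$timepoint == t2]
    if (length(r1) != 1 || length(r2) != 1) {
      stop("subject ", s, " lacks a unique sample at ", t1, " or ", t2)
    }
    out[s, ] <- metric$values[r2, ] - metric$values[r1, ]
  }
  out
}

#' Pace-of-aging deltas
#'
#' Per subject, the difference between the pace value at each timepoint and at
#' the reference timepoint, plus cohort means per timepoint.
#'
#' @param pace named numeric of per-sample pace values (names = sample IDs).
#' @param meta sample metadata.
#' @param reference reference timepoint label.
#' @return List with `deltas` (subject, timepoint, pace, delta) and
#'   `cohort_means` (timepoint, mean_delta).
#' @export
compute_pace_changes <- function(pace, meta, reference = "L-45") {
  m <- matrix(pace, ncol = 1, dimnames = list(names(pace), "pace"))
  meta <- align_meta(m, meta)
  if (!reference %in% meta$timepoint) stop("reference timepoint not present")
  ref <- stats::setNames(rep(NA_real_, length(unique(meta$subject))),
                         unique(meta$subject))
  at_ref <- meta$timepoint == reference
  ref[meta$subject[at_ref]] <- pace[meta$sample[at_ref]]
  deltas <- data.frame(subject = meta$subject, timepoint = meta$timepoint,
                       pace = unname(pace[meta$sample]),
                       delta = unname(pace[meta$sample] - ref[meta$subject]),
                       stringsAsFactors = FALSE)
  cm <- stats::aggregate(delta ~ timepoint, deltas, mean)
  names(cm)[2] <- "mean_delta"
  list(deltas = deltas, cohort_means = cm)
}

#' Clock-category mean changes
#'
#' For each requested timepoint pair, computes the mean change per clock
#' (averaged over subjects), then the unweighted mean over the clocks of each
#' category. The grand mean across categories per pair is attached as
#' attribute `"grand_means"`.
#'
#' @param metric an `age_metric_table`.
#' @param registry a [clock_registry()]; every clock in the metric table must
#'   be registered.
#' @param meta sample metadata.
#' @param pairs 2-column matrix or list of `c(t1, t2)` timepoint pairs;
#'   default all ordered pairs in metadata order of appearance.
#' @return data.frame (metric, category, t1, t2, mean_change, n_clocks).
#' @export
category_means <- function(metric, registry, meta, pairs = NULL) {
  stopifnot(inherits(metric, "age_metric_table"),
            inherits(registry, "clock_registry"))
  unreg <- setdiff(colnames(metric$values), registry$clock)
  if (length(unreg)) {
    stop("unregistered clock(s): ", paste(unreg, collapse = ", "))
  }
  if (is.null(pairs)) {
    tps <- unique(meta$timepoint)
    pairs <- t(utils::combn(tps, 2))
  }
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  cat_of <- stats::setNames(registry$category, registry$clock)
  rows <- list()
  grand <- list()
  for (i in seq_len(nrow(pairs))) {
    t1 <- pairs[i, 1]; t2 <- pairs[i, 2]
    ch <- metric_change(metric, meta, t1, t2)
    clock_means <- colMeans(ch)
    cats <- cat_of[names(clock_means)]
    agg <- tapply(clock_means, cats, mean)
    rows[[i]] <- data.frame(metric = metric$metric, category = names(agg),
                            t1 = t1, t2 = t2, mean_change = as.numeric(agg),
                            n_clocks = as.integer(table(cats)[names(agg)]),
                            stringsAsFactors = FALSE)
    grand[[i]] <- data.frame(metric = metric$metric, t1 = t1, t2 = t2,
                             grand_mean = mean(agg), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "grand_means") <- do.call(rbind, grand)
  out
}

#' Correlation structure of per-sample metric vectors
#'
#' Pearson correlation between every pair of samples' across-clock metric
#' vectors, with each pair labelled `same_individual`, `same_timepoint`, or
#' `neither`, and a per-stratum summary (mean, median). Zero-variance vectors
#' yield missing correlations, which are recorded and excluded from summaries.
#'
#' @param metric an `age_metric_table` with at least 3 clocks.
#' @param meta sample metadata.
#' @return List with `matrix` (samples x samples), `pairs` (long data.frame)
#'   and `summary` (per-stratum mean/median/n).
#' @export
correlation_structure <- function(metric, meta) {
  stopifnot(inherits(metric, "age_metric_table"))
  V <- metric$values
  if (ncol(V) < 3) stop("need at least 3 clocks for correlation structure")
  meta <- align_meta(V, meta)
  C <- suppressWarnings(stats::cor(t(V)))
  m <- nrow(V)
  idx <- which(upper.tri(C), arr.ind = TRUE)
  s1 <- rownames(V)[idx[, 1]]
  s2 <- rownames(V)[idx[, 2]]
  sub <- stats::setNames(meta$subject, meta$sample)
  tp <- stats::setNames(meta$timepoint, meta$sample)
  stratum <- ifelse(sub[s1] == sub[s2], "same_individual",
                    ifelse(tp[s1] == tp[s2], "same_timepoint", "neither"))
  pairs <- data.frame(sample1 = s1, sample2 = s2,
                      correlation = C[idx], stratum = stratum,
                      stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(pairs$correlation, pairs$stratum),
                                function(v) {
    data.frame(mean = mean(v, na.rm = TRUE), median = stats::median(v, na.rm = TRUE),
               n = length(v), n_missing = sum(is.na(v)))
  }))
  summ <- data.frame(stratum = rownames(summ), summ, row.names = NULL,
                     stringsAsFactors = FALSE)
  list(matrix = C, pairs = pairs, summary = summ)
}

#' Long-format export of a metric table
#'
#' @param metric an `age_metric_table`.
#' @param meta sample metadata.
#' @return data.frame (sample, subject, timepoint, clock, metric, value).
#' @export
metric_long <- function(metric, meta) {
  stopifnot(inherits(metric, "age_metric_table"))
  meta <- align_meta(metric$values, meta)
  n <- nrow(metric$values); k <- ncol(metric$values)
  data.frame(sample = rep(rownames(metric$values), k),
             subject = rep(meta$subject, k),
             timepoint = rep(meta$timepoint, k),
             clock = rep(colnames(metric$values), each = n),
             metric = metric$metric,
             value = as.vector(metric$values),
             stringsAsFactors = FALSE)
}
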