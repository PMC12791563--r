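#' Sample metadata for a cohort design
#'
#' Expands a [cohort_params()] design into one record per (subject, timepoint):
#' sample ID `subject_timepoint`, subject, sex code, chronological age at
#' collection (launch age plus calendar offset in years), timepoint label.
#'
#' @param cohort a [cohort_params()].
#' @return A `data.frame` with columns `sample`, `subject`, `sex`, `age`,
#'   `timepoint`.
#' @export
cohort_metadata <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_params"))
  grid <- expand.grid(subject = cohort$subjects, timepoint = cohort$timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  si <- match(grid$subject, cohort$subjects)
  ti <- match(grid$timepoint, cohort$timepoints)
  data.frame(sample = paste(grid$subject, grid$timepoint, sep = "_"),
             subject = grid$subject,
             sex = cohort$sexes[si],
             age = cohort$ages[si] + cohort$offsets_days[ti] / 365.25,
             timepoint = grid$timepoint,
             stringsAsFactors = FALSE)
}

#' Generate simplex cell fractions for a cohort
#'
#' Draws one Dirichlet vector per sample, applies the configured per-timepoint
#' logit-scale mean shifts to designated cell types, and renormalises, so each
#' row is a valid composition. Fully deterministic given `seed`.
#'
#' @param params a [cell_shift_params()].
#' @param cohort a [cohort_params()].
#' @param seed integer seed.
#' @return A samples x cell-types matrix with rows summing to 1; attribute
#'   `"truth"` carries the realised parameters.
#' @export
generate_cell_fractions <- function(params = cell_shift_params(),
                                    cohort = cohort_params(),
                                    seed = 1) {
  stopifnot(inherits(params, "cell_shift_params"),
            inherits(cohort, "cohort_params"))
  meta <- cohort_metadata(cohort)
  k <- length(params$cell_types)
  set.seed(stage_seed(seed, "cell_fractions"))
  p <- rdirichlet(nrow(meta), params$concentration)
  colnames(p) <- params$cell_types
  rownames(p) <- meta$sample
  for (tp in names(params$shifts)) {
    rows <- which(meta$timepoint == tp)
    if (!length(rows)) next
    sh <- params$shifts[[tp]]
    for (ct in names(sh)) {
      x <- logit(p[rows, ct]) + sh[[ct]]
      p[rows, ct] <- inv_logit(x)
    }
    p[rows, ] <- p[rows, , drop = FALSE] / rowSums(p[rows, , drop = FALSE])
  }
  attr(p, "truth") <- list(params = params, seed = seed)
  p
}

#' Generate clock estimates for a cohort with known ground truth
#'
#' Each year-scale clock value is
#' `a_c + b_c * age + s_c * sex + u_i + v_ic + gamma_c * delta_t +
#'  sum_k w_ck * (pi_ik - mean_k) + eps`, with subject random intercepts
#' `u_i ~ N(0, sigma_u^2)`, persistent subject-by-clock offsets
#' `v_ic ~ N(0, sigma_us^2)` and `eps ~ N(0, sigma_c^2)`. Cell effects enter
#' through fractions centred at the cohort mean so the timepoint acceleration
#' and the cell term are separately identifiable. Pace clocks use the same
#' formula with their own (near-1.0) parameter scale.
#'
#' @param cohort a [cohort_params()].
#' @param clocks a [clock_params()].
#' @param cells samples x cell-types fraction matrix (row names = sample IDs),
#'   e.g. from [generate_cell_fractions()]; its columns must match the weight
#'   matrix columns.
#' @param seed integer seed.
#' @return A list with `clock_table` (samples x clocks matrix), `metadata`
#'   (see [cohort_metadata()]) and `truth` (realised subject effects, cell
#'   fractions, delta, gamma, weights, seed) sufficient to recompute every
#'   value minus its noise draw.
#' @export
generate_clock_estimates <- function(cohort = cohort_params(),
                                     clocks = default_clock_params(),
                                     cells = NULL,
                                     seed = 1) {
  stopifnot(inherits(cohort, "cohort_params"), inherits(clocks, "clock_params"))
  meta <- cohort_metadata(cohort)
  tab <- clocks$table
  W <- clocks$weights
  if (is.null(cells)) {
    cells <- matrix(0, nrow(meta), ncol(W),
                    dimnames = list(meta$sample, colnames(W)))
  }
  if (!all(meta$sample %in% rownames(cells))) {
    stop("cell table rows do not match cohort samples")
  }
  cells <- cells[meta$sample, , drop = FALSE]
  if (ncol(cells) != ncol(W) || !all(colnames(cells) == colnames(W))) {
    stop("dimension mismatch between clock weights and cell types")
  }
  set.seed(stage_seed(seed, "clock_estimates"))
  u <- stats::rnorm(length(cohort$subjects), 0, cohort$sigma_u)
  names(u) <- cohort$subjects
  us <- matrix(stats::rnorm(length(cohort$subjects) * nrow(tab), 0,
                            cohort$sigma_us %||% 0),
               length(cohort$subjects), nrow(tab),
               dimnames = list(cohort$subjects, tab$clock))
  eps <- matrix(stats::rnorm(nrow(meta) * nrow(tab)), nrow(meta), nrow(tab))
  eps <- sweep(eps, 2, tab$noise_sd, `*`)
  centred <- sweep(cells, 2, colMeans(cells))
  delta_s <- cohort$delta[meta$timepoint]
  values <- matrix(rep(tab$intercept, each = nrow(meta)), nrow(meta)) +
    outer(meta$age, tab$slope) +
    outer(meta$sex, tab$sex_effect) +
    u[meta$subject] +
    us[meta$subject, , drop = FALSE] +
    outer(delta_s, tab$gamma) +
    centred %*% t(W) +
    eps
  dimnames(values) <- list(meta$sample, tab$clock)
  truth <- list(u = u, us = us, cell_fractions = cells, delta = cohort$delta,
                gamma = stats::setNames(tab$gamma, tab$clock),
                weights = W, seed = seed)
  list(clock_table = values, metadata = meta, truth = truth)
}

#' Simulate a full mission-like cohort
#'
#' Convenience wrapper chaining [generate_cell_fractions()] and
#' [generate_clock_estimates()] with independent per-stage RNG streams derived
#' from one master seed.
#'
#' @param cohort a [cohort_params()].
#' @param clocks a [clock_params()].
#' @param cells a [cell_shift_params()].
#' @param seed integer master seed.
#' @return A list with `clock_table`, `metadata`, `cells` (fraction matrix) and
#'   `truth`.
#' @export
simulate_cohort <- function(cohort = cohort_params(),
                            clocks = default_clock_params(),
                            cells = cell_shift_params(),
                            seed = 1) {
  frac <- generate_cell_fractions(cells, cohort, seed = seed)
  gen <- generate_clock_estimates(cohort, clocks, cells = frac, seed = seed)
  gen$cells <- frac
  gen
}

#' Generate a beta matrix from cell fractions and a reference
#'
#' Mixes pure cell-type methylation profiles according to each sample's
#' composition: `beta[j, s] = sum_k R[j, k] * pi[s, k] + noise`, truncated to
#' `[0, 1]`. With zero noise, reference-based deconvolution inverts this
#' exactly.
#'
#' @param reference CpG x cell-type matrix of pure-profile beta values in
#'   `[0, 1]`.
#' @param cells samples x cell-types fraction matrix.
#' @param clock_models optional list of [clock_model()]s; it is an error if the
#'   reference does not cover the union of their CpGs.
#' @param noise_sd Gaussian noise SD on the beta scale.
#' @param seed integer seed.
#' @return CpG x samples beta matrix.
#' @export
generate_methylation <- function(reference, cells, clock_models = NULL,
                                 noise_sd = 0, seed = 1) {
  reference <- as.matrix(reference)
  if (any(reference < 0 | reference > 1)) {
    stop("reference values must lie in [0, 1]")
  }
  cells <- as.matrix(cells)
  if (!all(colnames(cells) %in% colnames(reference))) {
    stop("cell types in fractions not present in reference")
  }
  if (!is.null(clock_models)) {
    cpgs <- unique(unlist(lapply(clock_models, function(m) names(m$coefficients))))
    miss <- setdiff(cpgs, rownames(reference))
    if (length(miss)) {
      stop("reference does not cover clock-model CpGs: ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
  }
  beta <- reference[, colnames(cells), drop = FALSE] %*% t(cells)
  if (noise_sd > 0) {
    set.seed(stage_seed(seed, "methylation"))
    beta <- beta + matrix(stats::rnorm(length(beta), 0, noise_sd),
                          nrow(beta), ncol(beta))
  }
  beta[beta < 0] <- 0
  beta[beta > 1] <- 1
  dimnames(beta) <- list(rownames(reference), rownames(cells))
  beta
}

#' Synthetic pure-cell methylation reference
#'
#' Builds a well-conditioned CpG x cell-type reference: a block of CpGs per
#' cell type that are highly methylated only in that type, plus shared CpGs
#' with intermediate levels. Synthetic stand-in for an experimentally derived
#' deconvolution library; useful for testing only.
#'
#' @param n_cpgs number of CpGs (>= 2 per cell type).
#' @param cell_types cell-type labels.
#' @param seed integer seed.
#' @return CpG x cell-type matrix in `[0, 1]`.
#' @export
synthetic_reference <- function(n_cpgs = 240,
                                cell_types = default_cell_types(),
                                seed = 1) {
  k <- length(cell_types)
  if (n_cpgs < 2 * k) stop("need at least 2 CpGs per cell type")
  set.seed(stage_seed(seed, "reference"))
  R <- matrix(stats::runif(n_cpgs * k, 0.3, 0.7), n_cpgs, k)
  block <- floor(n_cpgs / (2 * k))
  for (j in seq_len(k)) {
    rows <- ((j - 1) * block + 1):(j * block)
    R[rows, ] <- 0.1
    R[rows, j] <- 0.9
  }
  dimnames(R) <- list(sprintf("cg%06d", seq_len(n_cpgs)), cell_types)
  R
}
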