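#' Mission cohort parameters
#'
#' Describes the longitudinal design of a (synthetic) mission cohort: subjects
#' with their sexes and chronological ages at launch, the ordered timepoint
#' labels with calendar offsets in days relative to launch, the per-timepoint
#' true acceleration added to every year-scale clock, and the between-subject
#' and residual standard deviations.
#'
#' Chronological age advances across timepoints by `offsets_days / 365.25`
#' because downstream acceleration metrics regress on exact chronological age.
#'
#' @param subjects character vector of subject IDs.
#' @param ages numeric, chronological age in years at launch (day 0), one per
#'   subject.
#' @param sexes numeric sex codes (Female = 1, Male = 0), one per subject.
#' @param timepoints ordered character vector of timepoint labels.
#' @param offsets_days numeric calendar offset of each timepoint from launch.
#' @param reference reference timepoint label; its acceleration is 0 by
#'   convention.
#' @param delta named numeric, true intrinsic biological-age acceleration
#'   (years) at each timepoint, i.e. the part not mediated by cell-composition
#'   shifts (those enter through the clock cell-sensitivity weights);
#'   `delta[reference]` must be 0.
#' @param sigma_u subject random-intercept SD (years), >= 0; shared by all
#'   clocks within a sample.
#' @param sigma_us subject-by-clock random-effect SD (years), >= 0: each
#'   (subject, clock) pair gets a persistent offset, constant across
#'   timepoints, giving subjects clock-specific stable biases (the feature
#'   that makes within-individual across-clock profiles correlate over time).
#'   Paired within-subject differences cancel it.
#' @param sigma_eps default residual SD (years) used by [default_clock_params()]
#'   for year-scale clocks, >= 0.
#'
#' @details Defaults reproduce the mission design this package was built
#'   around: 4 subjects (two in their 60s, two in their 30s, two of each sex)
#'   sampled 45 days before launch, on flight days 4 and 7 of a 9-day orbital
#'   mission, and 1 and 7 days after return, with an intrinsic acceleration
#'   trajectory that rises early in flight and dips below baseline on return;
#'   the default cell shifts and clock sensitivities add a cell-mediated
#'   acceleration that peaks late in flight.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(subjects = c("A1", "A2", "A3", "A4"),
                          ages = c(67.7, 63.2, 31.1, 34.6),
                          sexes = c(0, 1, 0, 1),
                          timepoints = c("L-45", "FD+4", "FD+7", "R+1", "R+7"),
                          offsets_days = c(-45, 4, 7, 10, 16),
                          reference = timepoints[1],
                          delta = c(0, 0.75, 0.22, -0.32, -0.24),
                          sigma_u = 1.5,
                          sigma_us = 0.5,
                          sigma_eps = 0.5) {
  subjects <- as.character(subjects)
  timepoints <- as.character(timepoints)
  if (anyDuplicated(subjects)) stop("subject IDs must be unique")
  if (length(ages) != length(subjects) || length(sexes) != length(subjects)) {
    stop("ages and sexes must have one entry per subject")
  }
  if (any(ages <= 0)) stop("ages must be positive")
  if (!all(sexes %in% c(0, 1))) stop("sexes must be coded Female = 1, Male = 0")
  if (length(unique(timepoints)) < 2) stop("need at least 2 distinct timepoints")
  if (length(offsets_days) != length(timepoints)) {
    stop("offsets_days must have one entry per timepoint")
  }
  if (!reference %in% timepoints) stop("reference timepoint not in timepoint labels")
  if (is.null(names(delta))) names(delta) <- timepoints
  if (!setequal(names(delta), timepoints)) stop("delta must be named by timepoint")
  delta <- delta[timepoints]
  if (abs(delta[[reference]]) > 1e-12) {
    stop("delta at the reference timepoint must be 0")
  }
  if (sigma_u < 0 || sigma_us < 0 || sigma_eps < 0) {
    stop("standard deviations must be >= 0")
  }
  structure(list(subjects = subjects, ages = as.numeric(ages),
                 sexes = as.numeric(sexes), timepoints = timepoints,
                 offsets_days = as.numeric(offsets_days), reference = reference,
                 delta = delta, sigma_u = sigma_u, sigma_us = sigma_us,
                 sigma_eps = sigma_eps),
            class = "cohort_params")
}

#' Default 12 immune cell-type labels
#'
#' Salas-style extended immune panel: basophils, memory/naive B cells,
#' memory/naive CD4 and CD8 T cells, eosinophils, monocytes, neutrophils,
#' NK cells, and regulatory T cells. Overridable everywhere a cell-type vector
#' is accepted.
#'
#' @return Character vector of length 12.
#' @export
default_cell_types <- function() {
  c("Bas", "Bmem", "Bnv", "CD4mem", "CD4nv", "CD8mem", "CD8nv",
    "Eos", "Mono", "Neu", "NK", "Treg")
}

default_cell_means <- function(cell_types = default_cell_types()) {
  means <- c(Bas = 0.005, Bmem = 0.02, Bnv = 0.03, CD4mem = 0.08,
             CD4nv = 0.06, CD8mem = 0.04, CD8nv = 0.04, Eos = 0.025,
             Mono = 0.08, Neu = 0.55, NK = 0.06, Treg = 0.01)
  if (setequal(cell_types, names(means))) return(means[cell_types])
  # custom labels: uniform baseline
  stats::setNames(rep(1 / length(cell_types), length(cell_types)), cell_types)
}

#' Cell-composition shift parameters
#'
#' Samples' cell fractions are drawn from a Dirichlet distribution whose mean
#' is a realistic whole-blood immune profile; designated cell types receive
#' per-timepoint mean shifts on the logit scale before renormalisation, so the
#' generated rows always lie on the simplex.
#'
#' @param cell_types character vector of cell-type labels.
#' @param concentration positive Dirichlet concentration vector (one per cell
#'   type); its normalisation gives the baseline mean fractions and its total
#'   controls sampling noise.
#' @param shifts named list: timepoint label -> named numeric vector of logit
#'   shifts for a subset of cell types. Defaults emulate small early-flight
#'   dips of regulatory and naive CD4 T cells, their rebound late in flight
#'   with a concurrent neutrophil drop, and a post-return reversal.
#' @return A list of class `cell_shift_params`.
#' @export
cell_shift_params <- function(cell_types = default_cell_types(),
                              concentration = 300 * default_cell_means(cell_types),
                              shifts = default_cell_shifts()) {
  cell_types <- as.character(cell_types)
  if (anyDuplicated(cell_types)) stop("cell-type labels must be unique")
  if (length(concentration) != length(cell_types)) {
    stop("concentration must have one entry per cell type")
  }
  if (any(concentration <= 0)) stop("Dirichlet concentration parameters must be > 0")
  shifts <- shifts %||% list()
  for (tp in names(shifts)) {
    bad <- setdiff(names(shifts[[tp]]), cell_types)
    if (length(bad)) stop("shift for unknown cell type(s): ", paste(bad, collapse = ", "))
  }
  structure(list(cell_types = cell_types,
                 concentration = stats::setNames(as.numeric(concentration), cell_types),
                 shifts = shifts),
            class = "cell_shift_params")
}

#' @rdname cell_shift_params
#' @export
default_cell_shifts <- function() {
  list(`FD+4` = c(Treg = -0.05, CD4nv = -0.05, Neu = 0.02),
       `FD+7` = c(Treg = 0.3, CD4nv = 0.3, Neu = -0.4),
       `R+1`  = c(Treg = -0.35, CD4nv = -0.35, Neu = 0.15))
}

#' Per-clock generative parameters
#'
#' Each clock is generated as an affine function of chronological age and sex,
#' plus a subject random intercept, a timepoint acceleration scaled by a
#' clock-specific multiplier, a cell-composition term on centred fractions, and
#' Gaussian noise.
#'
#' @param registry a [clock_registry()].
#' @param intercept,slope,sex_effect,noise_sd,gamma numeric vectors (recycled)
#'   giving, per clock: intercept a_c (years), slope on chronological age b_c
#'   (must be > 0 for year-scale clocks), additive sex effect s_c, residual SD
#'   sigma_c, and acceleration multiplier gamma_c.
#' @param weights numeric matrix (clocks x cell types) of cell sensitivities
#'   w_ck, in years per unit fraction deviation from the cohort mean.
#' @return A list of class `clock_params` with elements `table` (per-clock
#'   data.frame) and `weights`.
#' @export
clock_params <- function(registry, intercept = 0, slope = 1, sex_effect = 0,
                         noise_sd = 0.5, gamma = 1,
                         weights = NULL) {
  stopifnot(inherits(registry, "clock_registry"))
  n <- nrow(registry)
  tab <- data.frame(clock = registry$clock,
                    units = registry$units,
                    intercept = rep_len(as.numeric(intercept), n),
                    slope = rep_len(as.numeric(slope), n),
                    sex_effect = rep_len(as.numeric(sex_effect), n),
                    noise_sd = rep_len(as.numeric(noise_sd), n),
                    gamma = rep_len(as.numeric(gamma), n),
                    stringsAsFactors = FALSE)
  if (any(tab$noise_sd < 0)) stop("noise_sd must be >= 0")
  if (any(tab$slope[tab$units == "years"] <= 0)) {
    stop("year-scale clocks must have positive slope on chronological age")
  }
  if (is.null(weights)) {
    weights <- matrix(0, n, length(default_cell_types()),
                      dimnames = list(tab$clock, default_cell_types()))
  }
  weights <- as.matrix(weights)
  if (nrow(weights) != n) stop("weights must have one row per clock")
  rownames(weights) <- tab$clock
  structure(list(table = tab, weights = weights), class = "clock_params")
}

#' Default clock generative parameters
#'
#' Deterministic, clock-varying defaults: year-scale slopes spread over
#' 0.7-1.1, small intercepts and alternating sex effects, acceleration
#' multiplier 1, and cell-sensitivity weights concentrated on neutrophils,
#' naive CD4 T cells and regulatory T cells with a clock-specific multiplier in
#' 0-2, so that clocks are differentially affected by composition changes. The
#' pace clock is generated on its own scale near 1.0.
#'
#' @param registry a [clock_registry()].
#' @param cell_types cell-type labels for the weight matrix columns.
#' @param noise_sd residual SD (years) for year-scale clocks.
#' @param base_weights named numeric of per-cell sensitivities (years per unit
#'   fraction) shared by all clocks before the clock multiplier; names must be
#'   cell types.
#' @return A `clock_params` object.
#' @export
default_clock_params <- function(registry = default_clock_registry(),
                                 cell_types = default_cell_types(),
                                 noise_sd = 0.5,
                                 base_weights = c(Treg = 95, CD4nv = 32, Neu = -12)) {
  n <- nrow(registry)
  i <- seq_len(n)
  yr <- registry$units == "years"
  intercept <- ifelse(yr, ((i * 3) %% 13) - 6, 0.85)
  slope <- ifelse(yr, 0.7 + 0.4 * ((i - 1) %% 7) / 6, 0.003)
  sex_effect <- ifelse(yr, c(-0.6, 0, 0.6)[(i %% 3) + 1], 0)
  sd_c <- ifelse(yr, noise_sd, 0.02)
  gamma <- ifelse(yr, 1, 0.01)
  base <- stats::setNames(numeric(length(cell_types)), cell_types)
  keep <- intersect(names(base_weights), cell_types)
  base[keep] <- base_weights[keep]
  mult <- ifelse(yr, 2 * ((i - 1) %% 5) / 4, 0.01)
  weights <- outer(mult, base)
  dimnames(weights) <- list(registry$clock, cell_types)
  clock_params(registry, intercept = intercept, slope = slope,
               sex_effect = sex_effect, noise_sd = sd_c, gamma = gamma,
               weights = weights)
}
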