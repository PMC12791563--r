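#' Run configuration
#'
#' Bundles everything [run_pipeline()] needs: input paths, the timepoint
#' ordering and reference label, the permutation count, the RNG seed, the
#' metric list and the output directory.
#'
#' @param clock_table path to the samples x clocks CSV.
#' @param metadata path to the sample metadata CSV.
#' @param cell_table optional path to a samples x cell-fractions CSV.
#' @param beta,reference optional paths to a CpG x samples beta-matrix CSV and
#'   a CpG x cell-types reference CSV; when given (and `cell_table` is not),
#'   fractions are deconvolved.
#' @param registry a [clock_registry()], or a path to a registry CSV;
#'   default [default_clock_registry()].
#' @param timepoints ordered timepoint labels (>= 2 distinct).
#' @param reference_timepoint reference label; must be in `timepoints`.
#' @param metrics subset of `c("EAD", "EAA", "IEAA")`.
#' @param n_permutations sign-flip draws per comparison (>= 1; default 10000).
#' @param seed integer RNG seed.
#' @param output_dir directory for result CSVs and the run manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(clock_table, metadata, cell_table = NULL,
                       beta = NULL, reference = NULL,
                       registry = NULL,
                       timepoints = c("L-45", "FD+4", "FD+7", "R+1", "R+7"),
                       reference_timepoint = timepoints[1],
                       metrics = c("EAD", "EAA", "IEAA"),
                       n_permutations = 10000,
                       seed = 1,
                       output_dir = "spaceclock_results") {
  if (length(unique(timepoints)) < 2) stop("need >= 2 distinct timepoint labels")
  if (!reference_timepoint %in% timepoints) {
    stop("reference timepoint must be one of the ordered labels")
  }
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  metrics <- match.arg(metrics, c("EAD", "EAA", "IEAA"), several.ok = TRUE)
  if (is.character(registry)) registry <- read_clock_registry(registry)
  registry <- registry %||% default_clock_registry()
  structure(list(clock_table = clock_table, metadata = metadata,
                 cell_table = cell_table, beta = beta, reference = reference,
                 registry = registry, timepoints = timepoints,
                 reference_timepoint = reference_timepoint, metrics = metrics,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' YAML keys mirror the [run_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, cfg)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Reads the configured inputs, deconvolves cell fractions when a beta matrix
#' is supplied, computes the requested metrics, runs per-subject Wilcoxon and
#' sign-flip permutation comparisons plus crossed random-intercept mixed
#' models for every ordered timepoint pair, the EAA-vs-IEAA dominance
#' analysis, category summaries, correlation structure and pace deltas, and
#' writes every result table as CSV plus a machine-readable manifest.
#' Deterministic given the configured seed.
#'
#' @param config a [run_config()].
#' @return (Invisibly) a list of all result objects; side effect: files under
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  registry <- config$registry
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   n_permutations = config$n_permutations,
                   metrics = config$metrics,
                   timepoints = config$timepoints,
                   reference_timepoint = config$reference_timepoint,
                   package_version = as.character(utils::packageVersion("spaceclock")),
                   stages = character(0), outputs = character(0),
                   deconvolution = "nnls + sum-to-one renormalisation")
  results <- list()
  emit <- function(name, writer) {
    path <- file.path(config$output_dir, name)
    writer(path)
    manifest$outputs <<- c(manifest$outputs, name)
  }
  done <- function(stage) manifest$stages <<- c(manifest$stages, stage)

  clocks <- with_stage("read_clock_table", read_clock_table(config$clock_table, registry))
  log_stage("read_clock_table", c(rows = nrow(clocks), cols = ncol(clocks)))
  done("read_clock_table")
  meta <- with_stage("read_metadata", read_metadata(config$metadata, config$timepoints))
  log_stage("read_metadata", c(rows = nrow(meta)))
  done("read_metadata")

  cells <- NULL
  if (!is.null(config$cell_table)) {
    cells <- with_stage("read_cell_table", read_cell_table(config$cell_table))
    done("read_cell_table")
  } else if (!is.null(config$beta) && !is.null(config$reference)) {
    beta <- with_stage("read_beta", read_matrix_csv(config$beta, id_col = "CpG"))
    ref <- with_stage("read_reference", read_matrix_csv(config$reference, id_col = "CpG"))
    cells <- with_stage("deconvolve", deconvolve_cell_fractions(beta, ref))
    emit("cell_fractions.csv", function(p) write_matrix_csv(cells, p))
    log_stage("deconvolve", c(samples = nrow(cells)))
    done("deconvolve")
  }
  if ("IEAA" %in% config$metrics && is.null(cells)) {
    stop("[stage config] IEAA requested but no cell table or beta+reference given")
  }

  metrics <- list()
  for (mt in config$metrics) {
    metrics[[mt]] <- with_stage(paste0("compute_", tolower(mt)), switch(mt,
      EAD = compute_ead(clocks, meta, registry),
      EAA = compute_eaa(clocks, meta, registry),
      IEAA = compute_ieaa(clocks, meta, cells, registry)))
    log_stage(paste0("compute_", tolower(mt)),
              c(samples = nrow(metrics[[mt]]$values),
                clocks = ncol(metrics[[mt]]$values), seed = config$seed))
    emit(paste0(tolower(mt), "_long.csv"),
         function(p) write_df_csv(metric_long(metrics[[mt]], meta), p))
    emit(paste0(tolower(mt), "_wide.csv"),
         function(p) write_matrix_csv(metrics[[mt]]$values, p))
    done(paste0("compute_", tolower(mt)))
  }
  results$metrics <- metrics

  tps <- config$timepoints[config$timepoints %in% unique(meta$timepoint)]
  pairs <- t(utils::combn(tps, 2))
  comp <- list(); lmm_rows <- list(); cat_rows <- list()
  for (mt in names(metrics)) {
    for (i in seq_len(nrow(pairs))) {
      t1 <- pairs[i, 1]; t2 <- pairs[i, 2]
      comp[[paste(mt, i)]] <- with_stage("compare_timepoints",
        compare_timepoints(metrics[[mt]], meta, t1, t2,
                           n_permutations = config$n_permutations,
                           seed = config$seed))
      fit <- with_stage("fit_lmm",
                        suppressWarnings(fit_lmm(metrics[[mt]], meta, t1, t2)))
      lmm_rows[[paste(mt, i)]] <- data.frame(
        metric = mt, t1 = t1, t2 = t2,
        estimate = fit$estimates$estimate[1], se = fit$estimates$se[1],
        df = fit$estimates$df[1], p = fit$estimates$p[1],
        sd_subject = unname(fit$varcomp["subject"]),
        sd_clock = unname(fit$varcomp["clock"]),
        sd_residual = unname(fit$varcomp["residual"]),
        singular = fit$singular, method = fit$method,
        stringsAsFactors = FALSE)
    }
    cm <- with_stage("category_means",
                     category_means(metrics[[mt]], registry, meta, pairs))
    cat_rows[[mt]] <- cm
    done(paste0("inference_", tolower(mt)))
  }
  results$comparisons <- do.call(rbind, comp)
  rownames(results$comparisons) <- NULL
  results$lmm <- do.call(rbind, lmm_rows)
  rownames(results$lmm) <- NULL
  results$category_means <- do.call(rbind, cat_rows)
  rownames(results$category_means) <- NULL
  emit("comparisons.csv", function(p) write_df_csv(results$comparisons, p))
  emit("lmm.csv", function(p) write_df_csv(results$lmm, p))
  emit("category_means.csv", function(p) write_df_csv(results$category_means, p))
  log_stage("inference", c(comparisons = nrow(results$comparisons),
                           lmm = nrow(results$lmm), seed = config$seed))

  for (mt in names(metrics)) {
    cs <- with_stage("correlation_structure",
                     correlation_structure(metrics[[mt]], meta))
    results$correlation[[mt]] <- cs
    emit(paste0("correlation_summary_", tolower(mt), ".csv"),
         function(p) write_df_csv(cbind(metric = mt, cs$summary), p))
  }
  done("correlation_structure")

  if (all(c("EAA", "IEAA") %in% names(metrics)) && !is.null(cells)) {
    ds <- with_stage("dominance",
                     build_dominance_dataset(metrics$EAA, metrics$IEAA, cells))
    dom <- with_stage("dominance",
                      suppressWarnings(dominance_analysis(ds$outcome, ds$predictors)))
    results$dominance <- dom
    df <- as.data.frame(dom)
    names(df)[1] <- "cell_type"
    df$outcome <- "EAA_minus_IEAA_stacked_over_clocks"
    emit("dominance.csv", function(p) write_df_csv(df, p))
    log_stage("dominance", c(predictors = length(dom$general),
                             models = dom$n_models))
    done("dominance")
  }

  pace <- intersect(registry$clock[registry$units == "rate"], colnames(clocks))
  if (length(pace)) {
    pc <- with_stage("pace_changes", compute_pace_changes(
      stats::setNames(clocks[, pace[1]], rownames(clocks)), meta,
      reference = config$reference_timepoint))
    results$pace <- pc
    emit("pace_deltas.csv", function(p) write_df_csv(pc$deltas, p))
    emit("pace_cohort_means.csv", function(p) write_df_csv(pc$cohort_means, p))
    done("pace_changes")
  }

  manifest$config <- list(
    clock_table = config$clock_table, metadata = config$metadata,
    cell_table = config$cell_table, beta = config$beta,
    reference = config$reference, output_dir = config$output_dir)
  manifest$complete <- TRUE
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  log_stage("manifest", c(outputs = length(manifest$outputs)))
  results$manifest <- manifest
  invisible(results)
}

#' Write a simulated cohort to CSV files
#'
#' Writes the clock table, metadata, cell fractions and a ground-truth bundle
#' (YAML) produced by [simulate_cohort()] into a directory.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return (Invisibly) the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(sim$clock_table, file.path(dir, "clock_table.csv"))
  write_df_csv(sim$metadata, file.path(dir, "metadata.csv"))
  write_matrix_csv(sim$cells %||% sim$truth$cell_fractions,
                   file.path(dir, "cell_fractions.csv"))
  truth <- list(seed = sim$truth$seed,
                subject_effects = as.list(sim$truth$u),
                delta = as.list(sim$truth$delta),
                gamma = as.list(sim$truth$gamma))
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  write_matrix_csv(sim$truth$weights, file.path(dir, "truth_weights.csv"),
                   id_col = "clock")
  invisible(dir)
}
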