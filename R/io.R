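#' Read a samples x clocks estimate table
#'
#' CSV with a sample-identifier column (named `sample`, else the first column)
#' and one numeric column per registered clock. Unknown clock columns are
#' dropped with a warning; a registered clock missing from the file is an
#' error, as are duplicate sample IDs and non-numeric cells.
#'
#' @param path file path.
#' @param registry a [clock_registry()].
#' @return Samples x clocks numeric matrix (row names = sample IDs), columns
#'   in registry order.
#' @export
read_clock_table <- function(path, registry = default_clock_registry()) {
  stopifnot(inherits(registry, "clock_registry"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  id_col <- if ("sample" %in% names(df)) "sample" else names(df)[1]
  ids <- df[[id_col]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  value_cols <- setdiff(names(df), id_col)
  missing <- setdiff(registry$clock, value_cols)
  if (length(missing)) {
    stop("clock table missing registered clock(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(value_cols, registry$clock)
  if (length(extra)) {
    warning("dropping unregistered column(s): ", paste(extra, collapse = ", "))
  }
  out <- matrix(NA_real_, length(ids), nrow(registry),
                dimnames = list(ids, registry$clock))
  for (cl in registry$clock) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !(df[[cl]] %in% c("NA", "")))
    if (length(bad)) {
      stop("non-numeric value in column '", cl, "', row ", bad[1],
           " (sample ", ids[bad[1]], ")")
    }
    out[, cl] <- v
  }
  out
}

#' Read sample metadata
#'
#' CSV with columns `sample`, `subject`, `sex`, `age`, `timepoint`. Sex is
#' normalised to the numeric coding Female = 1, Male = 0 (accepting `F`/`M`,
#' `Female`/`Male`, `1`/`0`, case-insensitively); timepoint labels are
#' validated against the supplied ordering and returned as given.
#'
#' @param path file path.
#' @param timepoints ordered character vector of admissible timepoint labels.
#' @return data.frame with columns `sample`, `subject`, `sex` (0/1), `age`,
#'   `timepoint`.
#' @export
read_metadata <- function(path,
                          timepoints = c("L-45", "FD+4", "FD+7", "R+1", "R+7")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "subject", "sex", "age", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample IDs: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  sex_raw <- tolower(trimws(as.character(df$sex)))
  sex <- ifelse(sex_raw %in% c("f", "female", "1"), 1,
                ifelse(sex_raw %in% c("m", "male", "0"), 0, NA_real_))
  if (anyNA(sex)) {
    stop("unparseable sex value(s): ",
         paste(unique(df$sex[is.na(sex)]), collapse = ", "))
  }
  age <- as.numeric(df$age)
  if (anyNA(age) || any(age <= 0)) stop("ages must be positive numbers")
  bad_tp <- setdiff(unique(df$timepoint), timepoints)
  if (length(bad_tp)) {
    stop("unknown timepoint label(s): ", paste(bad_tp, collapse = ", "))
  }
  dup <- duplicated(df[c("subject", "timepoint")])
  if (any(dup)) {
    stop("more than one record per (subject, timepoint): ",
         paste(df$sample[dup], collapse = ", "))
  }
  data.frame(sample = as.character(df$sample),
             subject = as.character(df$subject),
             sex = sex, age = age,
             timepoint = as.character(df$timepoint),
             stringsAsFactors = FALSE)
}

#' Read / write a samples x columns numeric matrix CSV
#'
#' Writers emit every double with 17 significant digits so that a write/read
#' round trip reproduces values exactly.
#'
#' @param path file path.
#' @param id_col name of the identifier column (row names).
#' @return [read_matrix_csv()] returns a numeric matrix with row names.
#' @export
read_matrix_csv <- function(path, id_col = "sample") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  idc <- if (id_col %in% names(df)) id_col else names(df)[1]
  ids <- as.character(df[[idc]])
  if (anyDuplicated(ids)) stop("duplicate row IDs in ", path)
  m <- as.matrix(df[setdiff(names(df), idc)])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname read_matrix_csv
#' @param m numeric matrix with row names.
#' @export
write_matrix_csv <- function(m, path, id_col = "sample") {
  df <- data.frame(id = rownames(m), stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- id_col
  for (j in colnames(m)) df[[j]] <- fmt_full(m[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a data.frame CSV at full numeric precision
#'
#' @param df data.frame.
#' @param path file path.
#' @export
write_df_csv <- function(df, path) {
  utils::write.csv(df_full_precision(df), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a cell-composition table
#'
#' Samples x cell-types CSV; validates that every value lies in `[0, 1]` and
#' every row sums to 1 within `1e-6`.
#'
#' @param path file path.
#' @return Samples x cell-types matrix.
#' @export
read_cell_table <- function(path) {
  m <- read_matrix_csv(path)
  if (any(m < -1e-12 | m > 1 + 1e-12)) stop("cell fractions must lie in [0, 1]")
  sums <- rowSums(m)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("cell-fraction rows must sum to 1 (worst deviation ",
         sprintf("%.2e", max(abs(sums - 1))), ")")
  }
  m
}
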