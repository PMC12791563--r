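#' Clock registry
#'
#' A clock registry records, for every epigenetic clock the pipeline knows
#' about, its functional category and its units. Clocks expressed in years
#' participate in cross-clock averaging and significance testing; pace-of-aging
#' clocks (units `"rate"`, category `"pace"`) are analysed separately as raw
#' pace deltas.
#'
#' @param clock character vector of unique clock names.
#' @param category character vector, one of
#'   `"chronological"`, `"mortality"`, `"fitness"`, `"causal"`, `"intrinsic"`,
#'   `"stochastic"`, `"retroelement"`, `"organ"`, `"pace"`.
#' @param units character vector, `"years"` or `"rate"`. A clock has units
#'   `"rate"` if and only if its category is `"pace"`.
#'
#' @return A `data.frame` of class `clock_registry` with columns
#'   `clock`, `category`, `units`.
#' @seealso [default_clock_registry()]
#' @export
clock_registry <- function(clock, category, units) {
  clock <- as.character(clock)
  category <- as.character(category)
  units <- as.character(units)
  if (anyDuplicated(clock)) {
    stop("duplicate clock names: ",
         paste(unique(clock[duplicated(clock)]), collapse = ", "))
  }
  bad <- setdiff(category, clock_category_levels())
  if (length(bad)) stop("unknown clock categories: ", paste(bad, collapse = ", "))
  if (!all(units %in% c("years", "rate"))) stop("units must be 'years' or 'rate'")
  if (any((category == "pace") != (units == "rate"))) {
    stop("category 'pace' must coincide exactly with units 'rate'")
  }
  out <- data.frame(clock = clock, category = category, units = units,
                    stringsAsFactors = FALSE)
  class(out) <- c("clock_registry", "data.frame")
  out
}

clock_category_levels <- function() {
  c("chronological", "mortality", "fitness", "causal", "intrinsic",
    "stochastic", "retroelement", "organ", "pace")
}

#' Default clock registry: 31 year-scale clocks plus DunedinPACE
#'
#' The default panel covers nine functional categories: chronological-age
#' clocks, mortality predictors, a fitness clock, causal-CpG clocks, an
#' intrinsic clock, stochastic clocks, retroelement clocks, twelve organ-system
#' clocks, and the DunedinPACE pace-of-aging clock (the only `"rate"` clock).
#'
#' @return A [clock_registry()].
#' @export
default_clock_registry <- function() {
  defs <- list(
    chronological = c("Horvath", "Hannum", "PCHorvath1", "PCHorvath2", "PCHannum"),
    mortality     = c("PhenoAge", "OMICmAge", "PCPhenoAge", "PCGrimAge"),
    fitness       = "DNAmFitAge",
    causal        = c("AdaptAge", "CausAge", "DamAge"),
    intrinsic     = "IntrinClock",
    stochastic    = c("Stochastic.Zhang", "Stochastic.Horvath", "Stochastic.PhenoAge"),
    retroelement  = c("Retroclock", "Retroclockv2"),
    organ         = c("SystemsAge", "Blood", "Brain", "Inflammation", "Heart",
                      "Hormone", "Immune", "Kidney", "Liver", "Metabolic",
                      "Lung", "MusculoSkeletal"),
    pace          = "DunedinPACE"
  )
  clock <- unlist(defs, use.names = FALSE)
  category <- rep(names(defs), lengths(defs))
  clock_registry(clock, category,
                 units = ifelse(category == "pace", "rate", "years"))
}

#' Names of the year-scale clocks in a registry
#'
#' @param registry a [clock_registry()].
#' @return Character vector of clocks with units `"years"`.
#' @export
year_clocks <- function(registry) {
  stopifnot(inherits(registry, "clock_registry"))
  registry$clock[registry$units == "years"]
}

#' Read / write a clock registry CSV
#'
#' CSV with columns `clock`, `category`, `units`.
#'
#' @param path file path.
#' @return [read_clock_registry()] returns a [clock_registry()].
#' @export
read_clock_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("clock", "category", "units")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("registry file missing columns: ", paste(miss, collapse = ", "))
  clock_registry(df$clock, df$category, df$units)
}

#' @rdname read_clock_registry
#' @param registry a [clock_registry()] to write.
#' @export
write_clock_registry <- function(registry, path) {
  stopifnot(inherits(registry, "clock_registry"))
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE)
  invisible(path)
}
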