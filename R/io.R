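#' Read and write bottle-measurement tables
#'
#' Delimited-text IO for the incubation bottle schema produced by
#' [simulate_experiment()] and consumed by [estimate_rates()] and
#' [attribute_n2o()]. Units are fixed by the format: time in hours,
#' concentrations in uM, N2O amounts in nmol, atom fractions dimensionless
#' in \[0, 1\], molecular ratios dimensionless. Comma and tab delimiters
#' are both accepted on read (sniffed from the header line unless `delim`
#' is given); unknown columns are preserved as passthrough. Validation is
#' loud: every offending row is reported with its row number, and missing
#' values must be empty cells, never zero-filled.
#'
#' @param path File path.
#' @param x A bottle table.
#' @param delim Field delimiter; `NULL` (default) sniffs `,` vs tab on
#'   read, writes comma.
#' @return `read_bottle_table()` returns a validated tibble;
#'   `write_bottle_table()` returns `path` invisibly.
#' @examples
#' b <- simulate_experiment(experiment_design(tracers = "NO2_labeled"),
#'                          ground_truth(noise = 0))
#' f <- tempfile(fileext = ".csv")
#' write_bottle_table(b, f)
#' identical(dim(read_bottle_table(f)), dim(b))
#' @export
read_bottle_table <- function(path, delim = NULL) {
  d <- read_table_guess(path, delim)
  required <- c("tracer", "time_h", "conc_nh4", "conc_no2", "conc_no3",
                "f15_no2", "f15_no3", "n2o_total_nmol", "r45", "r46")
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    abort(paste0("bottle table ", path, " is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  problems <- c(
    check_rows(d, d$time_h < 0, "time_h is negative"),
    check_rows(d, !d$tracer %in% c("NH4_labeled", "NO2_labeled"),
               "tracer must be NH4_labeled or NO2_labeled"),
    check_rows(d, d$conc_nh4 < 0 | d$conc_no2 < 0 | d$conc_no3 < 0,
               "negative concentration"),
    check_rows(d, d$f15_no2 < 0 | d$f15_no2 > 1 | d$f15_no3 < 0 | d$f15_no3 > 1,
               "atom fraction outside [0, 1]"),
    check_rows(d, d$n2o_total_nmol < 0, "negative total N2O"),
    check_rows(d, d$r45 < 0 | d$r46 < 0, "negative molecular ratio")
  )
  if (length(problems)) {
    abort(paste0("invalid bottle table ", path, ":\n",
                 paste0("  ", problems, collapse = "\n")))
  }
  d
}

#' @rdname read_bottle_table
#' @export
write_bottle_table <- function(x, path, delim = NULL) {
  stopifnot(is.data.frame(x))
  readr::write_delim(full_precision(x), path, delim = delim %||% ",", na = "")
  invisible(path)
}

#' Read and write depth-profile tables
#'
#' Delimited-text IO for geochemical depth profiles: depth (m, surface
#' down), hydrography (temperature in C, practical salinity, pH, O2 in
#' uM), nutrient concentrations (uM), dissolved N2O (nM), and the N and O
#' isotopic composition of N2O and NO3- (permil; positional delta15N
#' alpha/beta for N2O). Depths must be non-negative and monotonically
#' increasing.
#'
#' @param path File path.
#' @param x A profile table.
#' @param delim Field delimiter; `NULL` sniffs on read, writes comma.
#' @return `read_profile_table()` returns a validated tibble;
#'   `write_profile_table()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_profile_table(simulate_profile(n_depths = 4), f)
#' read_profile_table(f)$depth_m
#' @export
read_profile_table <- function(path, delim = NULL) {
  d <- read_table_guess(path, delim)
  required <- c("depth_m", "temperature_c", "salinity", "conc_n2o_nm")
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    abort(paste0("profile table ", path, " is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  problems <- c(
    check_rows(d, d$depth_m < 0, "negative depth"),
    check_rows(d, c(FALSE, diff(d$depth_m) <= 0),
               "depths must increase monotonically (surface down)"),
    check_rows(d, d$conc_n2o_nm < 0, "negative N2O concentration")
  )
  if (length(problems)) {
    abort(paste0("invalid profile table ", path, ":\n",
                 paste0("  ", problems, collapse = "\n")))
  }
  d
}

#' @rdname read_profile_table
#' @export
write_profile_table <- function(x, path, delim = NULL) {
  stopifnot(is.data.frame(x))
  readr::write_delim(full_precision(x), path, delim = delim %||% ",", na = "")
  invisible(path)
}

# serialize doubles with 17 significant digits so a write/read round trip
# reproduces every bit; integers and text pass through
full_precision <- function(x) {
  dplyr::mutate(x, across(
    dplyr::where(function(col) is.double(col) && !all(is.na(col))),
    function(col) ifelse(is.na(col), NA_character_,
                         sprintf("%.17g", col))))
}

# shared reader: sniff the delimiter from the header line, C locale so
# numbers are never locale-dependent. Columns come in as text and are
# type-converted through strtod, which (unlike fast float parsers) returns
# the nearest double exactly, so write/read round trips are bit-identical.
read_table_guess <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  d <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  num_re <- "^[+-]?([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?|NaN|Inf|-Inf)$"
  as_tibble(lapply(d, function(col) {
    vals <- col[!is.na(col)]
    if (length(vals) && all(grepl(num_re, vals))) as.numeric(col) else col
  }))
}

# collect row-numbered validation messages; NA comparisons are not flagged
# (missing values are legal, explicit empties)
check_rows <- function(d, bad, msg) {
  bad <- which(!is.na(bad) & bad)
  if (!length(bad)) return(character())
  paste0("row ", bad, ": ", msg)
}
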