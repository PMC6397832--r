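# CSV readers/writers for titration curves and plate tables, and the
# results-JSON writer. All concentrations are molar internally; readers
# convert from a declared unit column when present.

unit_factor <- function(u) {
  f <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)
  u <- trimws(u)
  if (any(!u %in% names(f)))
    stop("unknown concentration unit(s): ",
         paste(unique(setdiff(u, names(f))), collapse = ", "))
  unname(f[u])
}

#' Read a titration curve from CSV
#'
#' Expects columns `titrant_total_M` and `absorbance`. If a `unit` column
#' is present (values among M, mM, uM, nM) the totals are converted to
#' molar. Rows are sorted by titrant total; duplicate totals are an error.
#'
#' @param path CSV file path.
#' @param mode,fixed_conditions,observation_wavelength Passed to
#'   [titration_curve()]; the CSV stores only the measured series.
#' @return A [titration_curve()].
#' @export
read_titration_csv <- function(path, mode = "guest-titration",
                               fixed_conditions,
                               observation_wavelength = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("titrant_total_M", "absorbance")
  if (!all(need %in% names(df)))
    stop("read_titration_csv: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (cl in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cl]]))))
    if (length(bad) > 0)
      stop(sprintf("read_titration_csv: non-numeric '%s' at data row(s) %s",
                   cl, paste(bad, collapse = ", ")))
    df[[cl]] <- as.numeric(df[[cl]])
  }
  if ("unit" %in% names(df))
    df$titrant_total_M <- df$titrant_total_M * unit_factor(df$unit)
  dup <- duplicated(df$titrant_total_M)
  if (any(dup))
    stop("read_titration_csv: duplicate titrant totals at data row(s) ",
         paste(which(dup), collapse = ", "))
  df <- df[order(df$titrant_total_M), ]
  titration_curve(df$titrant_total_M, df$absorbance, mode = mode,
                  fixed_conditions = fixed_conditions,
                  observation_wavelength = observation_wavelength)
}

#' Write a titration curve to CSV
#'
#' @param curve A [titration_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  # %.17g preserves doubles exactly across the round trip
  utils::write.csv(data.frame(
    titrant_total_M = sprintf("%.17g", curve$titrant_totals),
    absorbance = sprintf("%.17g", curve$absorbances)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate table from long-format CSV
#'
#' Expects columns `analyte`, `analyte_total_M`, `channel`, `replicate`,
#' `absorbance`. Duplicate (analyte, channel, replicate) triples are an
#' error.
#'
#' @param path CSV file path.
#' @return A `plate_table` data.frame.
#' @export
read_plate_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("read_plate_csv: cannot parse ", path, ": ",
                        conditionMessage(e)))
  need <- c("analyte", "analyte_total_M", "channel", "replicate", "absorbance")
  if (nrow(df) == 0)
    stop("read_plate_csv: empty plate file")
  if (!all(need %in% names(df)))
    stop("read_plate_csv: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (cl in c("analyte_total_M", "absorbance", "replicate")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cl]]))))
    if (length(bad) > 0)
      stop(sprintf("read_plate_csv: non-numeric '%s' at data row(s) %s",
                   cl, paste(bad, collapse = ", ")))
    df[[cl]] <- as.numeric(df[[cl]])
  }
  key <- paste(df$analyte, df$channel, df$replicate)
  dup <- duplicated(key)
  if (any(dup))
    stop("read_plate_csv: duplicate (analyte, channel, replicate) at data row(s) ",
         paste(which(dup), collapse = ", "))
  class(df) <- c("plate_table", "data.frame")
  df
}

#' Write a plate table to long-format CSV
#'
#' @param plate A `plate_table`.
#' @param path Output path.
#' @param keep_truth Keep the ground-truth `outlier` column (default drops
#'   it, as a real plate export would not have it).
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path, keep_truth = FALSE) {
  stopifnot(is.data.frame(plate))
  cols <- c("analyte", "analyte_total_M", "channel", "replicate", "absorbance")
  if (keep_truth && "outlier" %in% names(plate)) cols <- c(cols, "outlier")
  out <- as.data.frame(plate)[, cols]
  out$analyte_total_M <- sprintf("%.17g", out$analyte_total_M)
  out$absorbance <- sprintf("%.17g", out$absorbance)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis results list as JSON
#'
#' Serialises a named list of results (rates, matrices, fitted constants,
#' the seed used) to pretty-printed JSON, after checking it against the
#' results schema shipped with the package (`inst/schema/results.json`):
#' a `seed` field is required and all numeric fields must be finite or
#' null.
#'
#' @param results Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  check_results_schema(results)
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Validate a results list against the shipped schema
#'
#' A light structural check mirroring `inst/schema/results.json`: the list
#' must be named, carry an integer `seed`, and any field named in the
#' schema's `properties` must have the declared JSON type.
#'
#' @param results Named list about to be serialised.
#' @return `TRUE` invisibly, or an error.
#' @export
check_results_schema <- function(results) {
  if (!is.list(results) || is.null(names(results)) || any(names(results) == ""))
    stop("results must be a fully named list")
  schema_path <- system.file("schema", "results.json", package = "idasense")
  schema <- if (nzchar(schema_path)) jsonlite::read_json(schema_path) else
    list(required = list("seed"), properties = list(seed = list(type = "integer")))
  for (req in unlist(schema$required))
    if (!req %in% names(results))
      stop("results missing required field '", req, "'")
  jstype <- function(v) {
    if (is.numeric(v) && length(v) == 1) {
      if (v == round(v)) "integer" else "number"
    } else if (is.character(v) && length(v) == 1) "string"
    else if (is.logical(v) && length(v) == 1) "boolean"
    else if (is.list(v) && !is.null(names(v))) "object"
    else "array"
  }
  for (nm in intersect(names(results), names(schema$properties))) {
    want <- schema$properties[[nm]]$type
    got <- jstype(results[[nm]])
    ok <- got == want || (want == "number" && got == "integer")
    if (!ok)
      stop(sprintf("results field '%s' has JSON type %s, schema requires %s",
                   nm, got, want))
  }
  invisible(TRUE)
}
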