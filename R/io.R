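#' Read a fermentation trajectory CSV
#'
#' Reads the package's trajectory schema: a mandatory `time_h` first
#' column followed by recognised species columns (`X_gL`, `S_gL`, `PA_gL`,
#' `PYR_gL`, `AA_gL`, `SA_gL`, `V_L`). An `A600` column is converted to
#' `X_gL` when a strain conversion factor is supplied. Unknown columns
#' (lactate, for instance, which is measured but not modelled) are kept
#' and recorded as annotations. Comma-separated, `.` decimal, UTF-8,
#' header mandatory; missing values blank.
#'
#' @param path CSV file path
#' @param dcw_factor optional A600-to-DCW factor (g DCW/L per A600 unit);
#'   see [dcw_factor()]
#' @return a `fermentation_timeseries` data.frame; annotation column names
#'   in `attr(, "annotations")`
#' @export
read_timeseries_csv <- function(path, dcw_factor = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = TRUE, fileEncoding = "UTF-8")
  if (names(df)[1L] != "time_h") {
    stop("first column must be time_h (found '", names(df)[1L], "')")
  }
  if (any(!is.finite(df$time_h))) stop("time_h contains missing values")
  bad <- which(diff(df$time_h) <= 0)
  if (length(bad) > 0L) {
    stop("time_h not strictly increasing at row ", bad[1L] + 1L)
  }
  if ("A600" %in% names(df) && !is.null(dcw_factor)) {
    df$X_gL <- od_to_dcw(df$A600, dcw_factor)
  }
  known <- c("time_h", paste0(state_species(), "_gL"), "V_L")
  annotations <- setdiff(names(df), c(known, "A600"))
  for (v in intersect(names(df), paste0(state_species(), "_gL"))) {
    neg <- which(df[[v]] < 0)
    if (length(neg) > 0L) {
      stop("negative concentration in column ", v, " at row ", neg[1L])
    }
  }
  structure(df,
            class = c("fermentation_timeseries", "data.frame"),
            annotations = annotations, source = "observed")
}

#' @rdname read_timeseries_csv
#' @param series a trajectory data.frame to write
#' @export
write_timeseries_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write kinetic parameter files
#'
#' Flat `key = value` text files carrying exactly the fields of
#' [kinetic_parameters()]. Lines starting with `#` and blank lines are
#' ignored. Unknown keys are an error (they usually indicate a typo that
#' would otherwise silently fall back to a default).
#'
#' @param path file path
#' @return a [kinetic_parameters()] object
#' @export
read_kinetic_parameters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) {
    stop("malformed parameter line: ", lines[lengths(kv) != 2L][1L])
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- suppressWarnings(
    as.numeric(trimws(vapply(kv, `[[`, character(1), 2L))))
  unknown <- setdiff(keys, kinetic_parameter_names())
  if (length(unknown) > 0L) {
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "))
  }
  if (any(is.na(vals))) {
    stop("non-numeric value for key: ", keys[is.na(vals)][1L])
  }
  p <- stats::setNames(vals, keys)
  missing <- setdiff(kinetic_parameter_names(), keys)
  if (length(missing) > 0L) {
    stop("missing parameter keys: ", paste(missing, collapse = ", "))
  }
  do.call(kinetic_parameters, as.list(p))
}

#' @rdname read_kinetic_parameters
#' @param p a [kinetic_parameters()] object
#' @export
write_kinetic_parameters <- function(p, path) {
  validate_kinetic_parameters(p)
  pn <- as.numeric_named(p)[kinetic_parameter_names()]
  writeLines(sprintf("%s = %.17g", names(pn), pn), path)
  invisible(path)
}
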