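#' Read and write registry CSV files
#'
#' The registry interchange format is a UTF-8, comma-delimited CSV with a
#' header and one row per patient; an empty cell means missing. Columns:
#'
#' * `patient_id` (character, unique), `center` (character)
#' * `age` (years), `sex` (`male`/`female`)
#' * `mechanism` (`blunt`/`penetrating`)
#' * `gcs` (GCS total 3-15), `bmr` (GCS motor component 1-6)
#' * `sbp` (mmHg), `rr` (breaths/min), `spo2` (%)
#' * `injuries` (semicolon-delimited `region:severity` pairs, see
#'   [parse_injuries()]; empty string = no recorded injuries)
#' * `survived` (1 = survived, 0 = died)
#'
#' `read_registry()` validates every row; rows with invalid values
#' (severity outside 1-6, unknown mechanism, out-of-range physiology, ...)
#' are dropped with a warning and collected, with their file line numbers
#' and the offending message, in the `problems` attribute of the result.
#' Missing mandatory columns are an error.
#'
#' @param path CSV file path.
#' @param data A registry tibble.
#' @return `read_registry()`: a registry tibble (attribute `problems`
#'   holds rejected rows, if any); `write_registry()`: `data`, invisibly.
#' @export
read_registry <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(), center = readr::col_character(),
      age = readr::col_double(), sex = readr::col_character(),
      mechanism = readr::col_character(), gcs = readr::col_integer(),
      bmr = readr::col_integer(), sbp = readr::col_double(),
      rr = readr::col_double(), spo2 = readr::col_double(),
      injuries = readr::col_character(), survived = readr::col_integer()
    ),
    na = "", progress = FALSE
  )
  missing_cols <- setdiff(names(REGISTRY_COLUMNS), names(raw))
  if (length(missing_cols)) {
    abort(paste0("Registry file lacks mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  msgs <- vapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    err <- function(cond) conditionMessage(cond)
    msg <- tryCatch({
      if (!is.na(r$injuries)) parse_injuries(r$injuries)
      if (!is.na(r$mechanism) &&
          !r$mechanism %in% c("blunt", "penetrating")) {
        stop("mechanism must be 'blunt' or 'penetrating'")
      }
      if (!is.na(r$gcs) && (r$gcs < 3 || r$gcs > 15)) stop("gcs outside 3-15")
      if (!is.na(r$bmr) && (r$bmr < 1 || r$bmr > 6)) stop("bmr outside 1-6")
      if (!is.na(r$sbp) && r$sbp < 0) stop("sbp negative")
      if (!is.na(r$rr) && r$rr < 0) stop("rr negative")
      if (!is.na(r$spo2) && (r$spo2 < 0 || r$spo2 > 100)) {
        stop("spo2 outside 0-100")
      }
      if (!is.na(r$survived) && !r$survived %in% c(0L, 1L)) {
        stop("survived must be 0/1")
      }
      NA_character_
    }, error = err)
    msg
  }, character(1))
  bad <- !is.na(msgs)
  out <- raw[!bad, , drop = FALSE]
  if (any(bad)) {
    problems <- tibble::tibble(
      line = which(bad) + 1L,  # header is line 1
      patient_id = raw$patient_id[bad],
      problem = msgs[bad]
    )
    warn(sprintf("Rejected %d invalid registry row(s); see attr(x, \"problems\").",
                 sum(bad)))
    attr(out, "problems") <- problems
  }
  out
}

#' @rdname read_registry
#' @export
write_registry <- function(data, path) {
  stopifnot(is.data.frame(data))
  out <- data[, names(REGISTRY_COLUMNS)]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(data)
}
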