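#' Physiology coding bands
#'
#' Band tables mapping raw physiology to the small-integer codes 0-4 used
#' inside the survival equations and in the Revised Trauma Score (RTS).
#' GCS, SBP and RR use the standard RTS bands. SpO2 is not part of the
#' classic RTS; the default banding mirrors its structure (>=95 -> 4,
#' 90-94 -> 3, 80-89 -> 2, 1-79 -> 1, unrecordable 0 -> 0) and can be
#' replaced per call. A band table is a data frame with columns `lower`
#' (inclusive), `upper` (inclusive) and `code`.
#'
#' @format A named list of band tables (`gcs`, `sbp`, `rr`, `spo2`).
#' @export
default_bands <- list(
  gcs = data.frame(
    lower = c(13, 9, 6, 4, 3), upper = c(15, 12, 8, 5, 3),
    code  = c(4L, 3L, 2L, 1L, 0L)
  ),
  sbp = data.frame(
    lower = c(90, 76, 50, 1, 0), upper = c(Inf, 89, 75, 49, 0),
    code  = c(4L, 3L, 2L, 1L, 0L)
  ),
  rr = data.frame(
    lower = c(30, 10, 6, 1, 0), upper = c(Inf, 29, 9, 5, 0),
    code  = c(3L, 4L, 2L, 1L, 0L)
  ),
  spo2 = data.frame(
    lower = c(95, 90, 80, 1, 0), upper = c(100, 94, 89, 79, 0),
    code  = c(4L, 3L, 2L, 1L, 0L)
  )
)

# standard RTS weights for (gcs_code, sbp_code, rr_code)
RTS_WEIGHTS <- c(gcs = 0.9368, sbp = 0.7326, rr = 0.2908)

apply_band <- function(x, bands, what) {
  out <- rep(NA_integer_, length(x))
  for (i in seq_len(nrow(bands))) {
    hit <- !is.na(x) & x >= bands$lower[i] & x <= bands$upper[i]
    out[hit & is.na(out)] <- bands$code[i]
  }
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort(sprintf("%s value(s) outside codable range: %s", what,
                  paste(unique(x[bad]), collapse = ", ")))
  }
  out
}

#' Code raw physiology into RTS-style categories
#'
#' Maps raw GCS total, systolic blood pressure, respiratory rate and SpO2
#' to their 0-4 category codes, using [default_bands] unless a replacement
#' band table is supplied. Values are validated against physiologic ranges
#' (GCS 3-15, SBP >= 0, RR >= 0, SpO2 0-100). `NA` inputs propagate.
#'
#' @param gcs,sbp,rr,spo2 Raw physiology vectors (any may be omitted).
#' @param bands A list of band tables like [default_bands]; entries you
#'   provide override the defaults.
#' @return A tibble with one integer code column per supplied input
#'   (`gcs_code`, `sbp_code`, `rr_code`, `spo2_code`).
#' @examples
#' code_physiology(gcs = 15, sbp = 120, rr = 16, spo2 = 99)
#' @export
code_physiology <- function(gcs = NULL, sbp = NULL, rr = NULL, spo2 = NULL,
                            bands = default_bands) {
  # whole-table replacement: a supplied band table overrides that field's
  # default outright (modifyList would merge data frame columns)
  bands <- c(bands, default_bands[setdiff(names(default_bands), names(bands))])
  check_range <- function(x, lo, hi, what) {
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad)) {
      abort(sprintf("%s out of physiologic range [%s, %s]: %s", what, lo, hi,
                    paste(unique(x[bad]), collapse = ", ")))
    }
  }
  out <- list()
  if (!is.null(gcs)) {
    check_range(gcs, 3, 15, "GCS")
    out$gcs_code <- apply_band(gcs, bands$gcs, "GCS")
  }
  if (!is.null(sbp)) {
    check_range(sbp, 0, Inf, "SBP")
    out$sbp_code <- apply_band(sbp, bands$sbp, "SBP")
  }
  if (!is.null(rr)) {
    check_range(rr, 0, Inf, "RR")
    out$rr_code <- apply_band(rr, bands$rr, "RR")
  }
  if (!is.null(spo2)) {
    check_range(spo2, 0, 100, "SpO2")
    out$spo2_code <- apply_band(spo2, bands$spo2, "SpO2")
  }
  tibble::as_tibble(out)
}

#' Revised Trauma Score
#'
#' Weighted sum of the coded GCS, SBP and respiratory-rate categories:
#' `0.9368 * gcs_code + 0.7326 * sbp_code + 0.2908 * rr_code`, range
#' 0 to 7.8408. Used for cohort description, not inside the survival
#' equations.
#'
#' @param gcs_code,sbp_code,rr_code Integer category codes 0-4.
#' @return A numeric vector.
#' @examples
#' rts(4, 4, 4)  # 7.8408, the physiologically intact maximum
#' @export
rts <- function(gcs_code, sbp_code, rr_code) {
  for (x in list(gcs_code, sbp_code, rr_code)) {
    if (any(!is.na(x) & (x < 0 | x > 4))) abort("RTS codes must be 0-4.")
  }
  RTS_WEIGHTS[["gcs"]] * gcs_code + RTS_WEIGHTS[["sbp"]] * sbp_code +
    RTS_WEIGHTS[["rr"]] * rr_code
}

#' Dichotomised age term
#'
#' The survival equations use age as an indicator: 0 if younger than 55
#' years, 1 otherwise. Ages below the study's minimum of 14 years trigger a
#' warning (outside the modelled population) but are still coded.
#'
#' @param age Age in years.
#' @return Integer 0/1 vector.
#' @examples
#' age_index(c(54, 55))
#' @export
age_index <- function(age) {
  if (any(!is.na(age) & age < 14)) {
    warn("age < 14 years is outside the modelled population (inclusion age >= 14).")
  }
  ifelse(is.na(age), NA_integer_, as.integer(age >= 55))
}

#' Add trauma scores to a registry table
#'
#' Computes, per record, the anatomical scores (ISS, NISS from the
#' `injuries` field), the physiology category codes, the RTS and the
#' dichotomised age term, and appends them as columns. This is the single
#' place where raw registry fields are converted into the predictors the
#' survival equations consume.
#'
#' @param data A registry tibble (see [read_registry()] for the schema).
#' @param bands Physiology band tables, as in [code_physiology()].
#' @return `data` with columns `iss`, `niss`, `gcs_code`, `sbp_code`,
#'   `rr_code`, `spo2_code`, `rts`, `age55` appended (inputs already
#'   present are overwritten).
#' @export
add_trauma_scores <- function(data, bands = default_bands) {
  stopifnot(is.data.frame(data))
  scores <- anatomical_scores_batch(data$injuries)
  data$iss <- scores$iss
  data$niss <- scores$niss
  codes <- code_physiology(gcs = data$gcs, sbp = data$sbp, rr = data$rr,
                           spo2 = data$spo2, bands = bands)
  data[names(codes)] <- codes
  data$rts <- rts(data$gcs_code, data$sbp_code, data$rr_code)
  data$age55 <- age_index(data$age)
  tibble::as_tibble(data)
}
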