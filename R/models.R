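#' Model templates
#'
#' The three survival-model templates and their ordered predictors. All
#' three are logistic models `Ps = 1 / (1 + exp(-b))` with
#' `b = b0 + b1*x1 + ...`:
#'
#' * `NTRISS_like`: BMR, SBP, NISS, AgeIndex
#' * `TRISS_SpO2`: GCS, SBP, SpO2, ISS, AgeIndex
#' * `NTRISS_like_SpO2`: BMR, SBP, SpO2, NISS, AgeIndex
#'
#' Predictor conventions (see `vignette("trauma-survival-models")`): BMR is
#' the raw GCS motor component 1-6; GCS, SBP and SpO2 enter as their 0-4
#' category codes; ISS/NISS are raw 0-75; AgeIndex is 0/1 (age >= 55).
#'
#' @format Named list mapping template name to its predictor vector.
#' @export
model_templates <- list(
  NTRISS_like      = c("BMR", "SBP", "NISS", "AgeIndex"),
  TRISS_SpO2       = c("GCS", "SBP", "SpO2", "ISS", "AgeIndex"),
  NTRISS_like_SpO2 = c("BMR", "SBP", "SpO2", "NISS", "AgeIndex")
)

# registry column feeding each predictor symbol (after add_trauma_scores)
PREDICTOR_COLUMNS <- c(
  BMR = "bmr", GCS = "gcs_code", SBP = "sbp_code", SpO2 = "spo2_code",
  ISS = "iss", NISS = "niss", AgeIndex = "age55"
)

check_template <- function(template) {
  if (!template %in% names(model_templates)) {
    abort(paste0("Unknown template ", deparse(template), ". Valid templates: ",
                 paste(names(model_templates), collapse = ", "), "."))
  }
  template
}

#' Construct a coefficient set
#'
#' A coefficient set binds a model template to a numeric coefficient vector
#' `(b0, b1, ..., bk)` for one center and trauma mechanism. The exact
#' decimal strings are retained alongside the numeric values so that
#' published tables survive read/write round trips digit-for-digit.
#'
#' @param template One of `names(model_templates)`.
#' @param center Label for the deriving cohort (e.g. `"HCFMUSP"`,
#'   `"UCSDMC"`, or `"user"`).
#' @param mechanism `"blunt"` or `"penetrating"`.
#' @param b Numeric coefficients, length `1 + number of predictors`, or a
#'   character vector of decimal strings.
#' @return An object of class `triss_coefficients`.
#' @export
coefficient_set <- function(template, center, mechanism, b) {
  check_template(template)
  mechanism <- match.arg(mechanism, c("blunt", "penetrating", "all"))
  k <- length(model_templates[[template]]) + 1L
  if (length(b) != k) {
    abort(sprintf("Template %s needs %d coefficients (b0..b%d), got %d.",
                  template, k, k - 1L, length(b)))
  }
  b_chr <- if (is.character(b)) b else format(b, digits = 15, trim = TRUE,
                                              scientific = FALSE)
  b_num <- as.numeric(b_chr)
  if (anyNA(b_num)) abort("Coefficients must be numeric or decimal strings.")
  names(b_num) <- names(b_chr) <- c("b0", paste0("b", seq_len(k - 1L)))
  structure(
    list(template = template, center = center, mechanism = mechanism,
         predictors = model_templates[[template]], b = b_num, b_chr = b_chr),
    class = "triss_coefficients"
  )
}

#' @export
print.triss_coefficients <- function(x, ...) {
  cat(sprintf("<triss_coefficients> %s | %s | %s\n", x$template, x$center,
              x$mechanism))
  lab <- c("(Intercept)", x$predictors)
  for (i in seq_along(x$b)) {
    cat(sprintf("  %-12s %-10s %s\n", names(x$b)[i], lab[i], x$b_chr[i]))
  }
  invisible(x)
}

published_cache <- new.env(parent = emptyenv())

#' Published two-center coefficient sets
#'
#' Returns the coefficient sets published for the two study centers
#' (HCFMUSP, a Sao Paulo university hospital; UCSDMC, a San Diego level 1
#' trauma center), one per template x center x mechanism (12 in all),
#' reproduced digit-for-digit from the shipped JSON file. Note one
#' anomaly reproduced verbatim: the NTRISS_like_SpO2 / HCFMUSP /
#' penetrating set has a positive age coefficient (+10.7638537), opposite
#' in sign to every other shipped age coefficient; it is shipped as
#' published, not corrected.
#'
#' @param template,center,mechanism If all three are given, the single
#'   matching `triss_coefficients` object; if all `NULL`, the full table of
#'   12 sets as a coefficient table (see [coefficient_table()]).
#' @return A `triss_coefficients` object or a coefficient table tibble.
#' @examples
#' builtin_coefficients("NTRISS_like", "HCFMUSP", "blunt")
#' @export
builtin_coefficients <- function(template = NULL, center = NULL,
                                 mechanism = NULL) {
  if (is.null(published_cache$table)) {
    path <- system.file("extdata", "published_coefficients.json",
                        package = "ntriss", mustWork = TRUE)
    published_cache$table <- read_coefficients(path)
  }
  tab <- published_cache$table
  if (is.null(template) && is.null(center) && is.null(mechanism)) return(tab)
  hit <- tab$template == template & tab$center == center &
    tab$mechanism == mechanism
  if (sum(hit) != 1L) {
    abort(paste0(
      "No published coefficient set for (", template, ", ", center, ", ",
      mechanism, "). Valid keys: template in {",
      paste(names(model_templates), collapse = ", "),
      "}, center in {HCFMUSP, UCSDMC}, mechanism in {blunt, penetrating}."
    ))
  }
  tab$coefficients[[which(hit)]]
}

#' Coefficient tables
#'
#' A coefficient table is a tibble with one row per coefficient set
#' (columns `template`, `center`, `mechanism`, list-column `coefficients`
#' of `triss_coefficients`). `read_coefficients()` / `write_coefficients()`
#' exchange it with the JSON interchange format (an array of objects with
#' keys `template`, `center`, `mechanism` and `b`, the latter an array of
#' decimal strings, preserved verbatim on round trip).
#'
#' @param sets A list of `triss_coefficients` objects.
#' @param path File path of a coefficient JSON file.
#' @param table A coefficient table.
#' @return A coefficient table tibble; `write_coefficients()` returns
#'   `table` invisibly.
#' @export
coefficient_table <- function(sets) {
  stopifnot(all(vapply(sets, inherits, logical(1), "triss_coefficients")))
  tibble::tibble(
    template = vapply(sets, `[[`, character(1), "template"),
    center = vapply(sets, `[[`, character(1), "center"),
    mechanism = vapply(sets, `[[`, character(1), "mechanism"),
    coefficients = sets
  )
}

#' @rdname coefficient_table
#' @export
read_coefficients <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  sets <- lapply(raw, function(x) {
    coefficient_set(x$template, x$center, x$mechanism, as.character(x$b))
  })
  coefficient_table(sets)
}

#' @rdname coefficient_table
#' @export
write_coefficients <- function(table, path) {
  out <- lapply(table$coefficients, function(s) {
    list(template = s$template, center = s$center, mechanism = s$mechanism,
         b = as.list(unname(s$b_chr)))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(table)
}

#' Linear predictor and survival probability
#'
#' `linear_predictor()` evaluates `b0 + sum(b_i * x_i)` for a coefficient
#' set; `survival_probability()` maps a linear predictor to
#' `Ps = 1 / (1 + exp(-b))`, numerically stable for arbitrarily large
#' `|b|` (saturates to 0/1 without overflow).
#'
#' @param coefficients A `triss_coefficients` object.
#' @param x Numeric matrix (rows = records) or vector of predictor values
#'   in template order.
#' @param b Numeric vector of finite linear-predictor values.
#' @return Numeric vector.
#' @examples
#' cs <- builtin_coefficients("NTRISS_like", "HCFMUSP", "blunt")
#' survival_probability(linear_predictor(cs, c(6, 4, 9, 0)))
#' @export
linear_predictor <- function(coefficients, x) {
  stopifnot(inherits(coefficients, "triss_coefficients"))
  k <- length(coefficients$predictors)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != k) {
    abort(sprintf("Template %s expects %d predictors (%s), got %d columns.",
                  coefficients$template, k,
                  paste(coefficients$predictors, collapse = ", "), ncol(x)))
  }
  drop(coefficients$b[1] + x %*% coefficients$b[-1])
}

#' @rdname linear_predictor
#' @export
survival_probability <- function(b) {
  if (any(is.nan(b) | is.infinite(b))) {
    abort("Linear predictor must be finite.")
  }
  plogis(b)
}

#' Score registry records with a survival model
#'
#' Assembles each record's predictor vector under the package's coding
#' conventions (see [model_templates]) and evaluates the survival
#' probability. With a single `triss_coefficients` object, every record is
#' scored with that set and its mechanism must match all records'. With a
#' coefficient table, each record is scored by the set matching
#' (`template`, `origin` center, record's mechanism) so blunt and
#' penetrating records get their mechanism-specific equations.
#'
#' Records missing any required predictor (or, for table scoring, with an
#' unknown mechanism) are not silently dropped: they receive `ps = NA` and
#' `scorable = FALSE`, and the exclusion count is attached as attribute
#' `n_excluded`.
#'
#' @param data A registry tibble; trauma-score columns are added via
#'   [add_trauma_scores()] if absent.
#' @param coefficients A `triss_coefficients` object or a coefficient
#'   table.
#' @param origin When `coefficients` is a table: the center label whose
#'   equations to apply.
#' @param template When `coefficients` is a table: the template to score.
#' @return `data` with columns `lp`, `ps` and `scorable` appended.
#' @export
score_records <- function(data, coefficients, origin = NULL, template = NULL) {
  if (!all(PREDICTOR_COLUMNS %in% names(data))) data <- add_trauma_scores(data)
  if (inherits(coefficients, "triss_coefficients")) {
    known <- if (coefficients$mechanism == "all") rep(TRUE, nrow(data))
             else !is.na(data$mechanism)
    if (coefficients$mechanism != "all" &&
        any(data$mechanism[known] != coefficients$mechanism)) {
      abort(sprintf(
        "Mechanism mismatch: coefficient set is for %s trauma but records include other mechanisms; score blunt and penetrating records with their own sets (pass a coefficient table).",
        coefficients$mechanism))
    }
    sets <- list(coefficients)
    set_of <- rep(1L, nrow(data))
    set_of[!known] <- NA_integer_
  } else {
    stopifnot(is.data.frame(coefficients), !is.null(origin), !is.null(template))
    check_template(template)
    sub <- coefficients[coefficients$template == template &
                          coefficients$center == origin, ]
    if (nrow(sub) == 0L) {
      abort(sprintf("No coefficient sets for template %s and center %s.",
                    template, origin))
    }
    sets <- sub$coefficients
    set_of <- match(data$mechanism, sub$mechanism)
  }
  lp <- rep(NA_real_, nrow(data))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    rows <- which(set_of == i)
    if (!length(rows)) next
    cols <- PREDICTOR_COLUMNS[s$predictors]
    xm <- as.matrix(data[rows, cols, drop = FALSE])
    storage.mode(xm) <- "double"
    lp[rows] <- linear_predictor(s, xm)
  }
  data$lp <- lp
  data$ps <- survival_probability(lp)
  data$scorable <- !is.na(data$ps)
  attr(data, "n_excluded") <- sum(!data$scorable)
  tibble::as_tibble(data)
}
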