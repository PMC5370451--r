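#' Required fields for a "complete" record
#'
#' A record is complete when every field needed to score all three model
#' templates is present: mechanism, outcome, age, GCS total and motor
#' component, SBP, SpO2, and the injury list. Test records are drawn only
#' from complete records.
#' @param data A registry tibble.
#' @return Logical vector, one element per record.
#' @export
is_complete_record <- function(data) {
  !is.na(data$mechanism) & !is.na(data$survived) & !is.na(data$age) &
    !is.na(data$gcs) & !is.na(data$bmr) & !is.na(data$sbp) &
    !is.na(data$spo2) & !is.na(data$injuries)
}

#' Split a cohort into test and derivation databases
#'
#' Draws `n_test` records uniformly at random, without replacement, from
#' the cohort's complete records (see [is_complete_record()]); all
#' remaining records form the derivation database. The draw is reproducible
#' under `seed` and never overlaps the derivation set.
#'
#' @param data A registry tibble with a `patient_id` column.
#' @param n_test Number of test records to hold out (default 300).
#' @param seed Integer seed for the draw.
#' @return A list of class `triss_split` with elements `test_ids`,
#'   `derivation_ids`, `n_test`, `seed`.
#' @export
split_test_derivation <- function(data, n_test = 300, seed = 1) {
  stopifnot(is.data.frame(data), anyDuplicated(data$patient_id) == 0)
  complete <- data$patient_id[is_complete_record(data)]
  if (length(complete) < n_test) {
    abort(sprintf(
      "Cannot hold out %d test records: only %d of %d records are complete.",
      n_test, length(complete), nrow(data)))
  }
  test_ids <- withr::with_seed(seed, sample(complete, n_test))
  structure(
    list(test_ids = sort(test_ids),
         derivation_ids = sort(setdiff(data$patient_id, test_ids)),
         n_test = n_test, seed = seed),
    class = "triss_split"
  )
}

#' Cohort-equalizing record weight
#'
#' When two derivation cohorts of unequal size are pooled, each record of
#' the smaller cohort receives weight `n_large / n_small` (reported to two
#' decimals) so both cohorts carry the same total weight. Note that when
#' cohorts are fitted separately, a constant per-record weight rescales the
#' likelihood uniformly and leaves maximum-likelihood point estimates
#' unchanged; the weight only matters for pooled fits.
#'
#' @param n_small,n_large Derivation cohort sizes (both > 0).
#' @return The weight, rounded to 2 decimals.
#' @examples
#' equalizing_weight(2116, 7872)  # 3.72
#' @export
equalizing_weight <- function(n_small, n_large) {
  if (n_small <= 0 || n_large <= 0) abort("Cohort sizes must be positive.")
  round(n_large / n_small, 2)
}

#' Weighted logistic regression for a survival template
#'
#' Fits `survived ~ template predictors` by weighted maximum likelihood
#' using iteratively reweighted least squares (IRLS). The outcome is coded
#' 1 = survived. Records missing any predictor or the outcome are excluded
#' (listwise) and counted. Convergence is declared when the largest
#' absolute coefficient change falls below `tol`; runaway coefficient
#' growth without convergence (the signature of complete separation) is
#' flagged and the last iterate returned.
#'
#' @param data A registry tibble (scores added if absent).
#' @param template One of `names(model_templates)`.
#' @param mechanism Optional: restrict the fit to `"blunt"` or
#'   `"penetrating"` records.
#' @param weights Optional per-record positive weights (length `nrow(data)`
#'   or scalar); default 1.
#' @param center Label stored on the resulting coefficient set.
#' @param tol,max_iter IRLS convergence tolerance and iteration cap.
#' @return An object of class `triss_fit`: coefficient set, standard
#'   errors, convergence flag, counts, log-likelihood. Use [tidy()] /
#'   [glance()] for tabular views.
#' @export
fit_logistic <- function(data, template, mechanism = NULL, weights = NULL,
                         center = "user", tol = 1e-8, max_iter = 100) {
  check_template(template)
  if (!all(PREDICTOR_COLUMNS %in% names(data))) data <- add_trauma_scores(data)
  n_in <- nrow(data)
  w <- if (is.null(weights)) rep(1, n_in) else rep(weights, length.out = n_in)
  if (any(w <= 0 | is.na(w))) abort("Weights must be positive and non-missing.")
  if (!is.null(mechanism)) {
    keep <- !is.na(data$mechanism) & data$mechanism == mechanism
    data <- data[keep, , drop = FALSE]
    w <- w[keep]
  } else {
    mechanism <- "all"  # label only; stored on the coefficient set
  }
  cols <- PREDICTOR_COLUMNS[model_templates[[template]]]
  y <- data$survived
  X <- cbind(rep(1, nrow(data)), as.matrix(data[, cols, drop = FALSE]))
  storage.mode(X) <- "double"
  usable <- stats::complete.cases(X) & !is.na(y)
  X <- X[usable, , drop = FALSE]
  y <- as.numeric(y[usable])
  w <- w[usable]
  n_used <- length(y)
  n_excluded <- n_in - n_used
  if (n_used == 0L || length(unique(y)) < 2L) {
    abort("Logistic fit needs at least one survivor and one death among usable records.")
  }

  p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  eps <- 1e-12
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, eps), 1 - eps)
    wirls <- w * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    XtW <- t(X * wirls)
    fisher <- XtW %*% X
    beta_new <- tryCatch(
      drop(solve(fisher, XtW %*% z)),
      error = function(e) NULL
    )
    if (is.null(beta_new) || any(!is.finite(beta_new))) {
      separation <- TRUE
      break
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max(abs(beta)) > 30) separation <- TRUE
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(plogis(eta), eps), 1 - eps)
  ll <- sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  fisher <- t(X * (w * mu * (1 - mu))) %*% X
  se <- tryCatch(sqrt(diag(solve(fisher))), error = function(e) rep(NA_real_, p))

  cs <- coefficient_set(template, center, mechanism, beta)
  structure(
    list(coefficients = cs, standard_errors = setNames(se, names(cs$b)),
         converged = converged, separation = separation, iterations = iter,
         n_used = n_used, n_excluded = n_excluded, log_likelihood = ll),
    class = "triss_fit"
  )
}

#' @export
print.triss_fit <- function(x, ...) {
  cat(sprintf(
    "<triss_fit> %s | %s | %s\n  n_used = %d, n_excluded = %d, logLik = %.3f, %s%s\n",
    x$coefficients$template, x$coefficients$center, x$coefficients$mechanism,
    x$n_used, x$n_excluded, x$log_likelihood,
    if (x$converged) sprintf("converged in %d iterations", x$iterations)
    else "DID NOT CONVERGE",
    if (x$separation) " (possible complete separation)" else ""))
  print(tidy(x))
  invisible(x)
}

#' Tidy and glance methods for logistic fits
#'
#' `tidy()` returns one row per coefficient with estimate, standard error,
#' Wald statistic and two-sided p-value; `glance()` returns one row of fit
#' summaries.
#'
#' @param x A `triss_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.triss_fit <- function(x, ...) {
  est <- x$coefficients$b
  se <- x$standard_errors
  z <- est / se
  tibble::tibble(
    term = c("(Intercept)", x$coefficients$predictors),
    estimate = unname(est), std.error = unname(se),
    statistic = unname(z), p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
glance.triss_fit <- function(x, ...) {
  tibble::tibble(
    template = x$coefficients$template, center = x$coefficients$center,
    mechanism = x$coefficients$mechanism, converged = x$converged,
    separation = x$separation, iterations = x$iterations,
    n_used = x$n_used, n_excluded = x$n_excluded,
    logLik = x$log_likelihood
  )
}

#' Derive all coefficient sets from a two-center registry
#'
#' Re-derives the full published-table shape: one fit per template x
#' center x mechanism (12 when both centers have both mechanisms), each on
#' the center's derivation records for that mechanism. Strata with no
#' usable records, or with a single outcome class, are skipped with a
#' warning. Within-center fits use unit weights; the equalizing weight
#' applies only when cohorts are pooled (see [equalizing_weight()]).
#'
#' @param data A registry tibble covering both centers.
#' @param derivation_ids Optional: restrict to these `patient_id`s (e.g.
#'   from [split_test_derivation()] per center).
#' @param templates Templates to fit (default all three).
#' @param ... Passed to [fit_logistic()] (e.g. `tol`, `max_iter`).
#' @return A list of class `triss_derivation`: `fits` (list of
#'   `triss_fit`), `table` (coefficient table of converged fits), `log`
#'   (tibble of per-stratum counts and convergence).
#' @export
derive_all <- function(data, derivation_ids = NULL,
                       templates = names(model_templates), ...) {
  if (!all(PREDICTOR_COLUMNS %in% names(data))) data <- add_trauma_scores(data)
  if (!is.null(derivation_ids)) {
    data <- data[data$patient_id %in% derivation_ids, , drop = FALSE]
  }
  centers <- sort(unique(data$center))
  grid <- expand.grid(template = templates, center = centers,
                      mechanism = c("blunt", "penetrating"),
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  log <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sub <- data[data$center == g$center, , drop = FALSE]
    fit <- tryCatch(
      fit_logistic(sub, g$template, mechanism = g$mechanism,
                   center = g$center, ...),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      warn(sprintf("Skipping %s / %s / %s: %s", g$template, g$center,
                   g$mechanism, conditionMessage(fit)))
      log[[i]] <- tibble::tibble(template = g$template, center = g$center,
                                 mechanism = g$mechanism, fitted = FALSE,
                                 converged = NA, n_used = NA_integer_,
                                 n_excluded = NA_integer_)
    } else {
      fits[[i]] <- fit
      log[[i]] <- tibble::tibble(template = g$template, center = g$center,
                                 mechanism = g$mechanism, fitted = TRUE,
                                 converged = fit$converged,
                                 n_used = fit$n_used,
                                 n_excluded = fit$n_excluded)
    }
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  structure(
    list(fits = fits,
         table = coefficient_table(lapply(fits, `[[`, "coefficients")),
         log = dplyr::bind_rows(log)),
    class = "triss_derivation"
  )
}

#' @export
print.triss_derivation <- function(x, ...) {
  cat(sprintf("<triss_derivation> %d fits\n", length(x$fits)))
  print(x$log)
  invisible(x)
}
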