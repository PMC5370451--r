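#' Configure a full study run
#'
#' Bundles everything [run_full_study()] needs: the synthetic-registry (or
#' user-registry) source, the test/derivation split size, the severity
#' cutoff, and which coefficient sets to validate.
#'
#' @param seed Master seed; stage seeds derive from it deterministically.
#' @param registry Optional pre-built registry tibble; if `NULL` one is
#'   generated from `generator`.
#' @param generator A [registry_config()] used when `registry` is `NULL`
#'   (its seed is overridden by `seed`).
#' @param n_test Held-out test records per center (default 300).
#' @param iss_cutoff ISS severity cutoff for stratified evaluation
#'   (default 16).
#' @param derive If `TRUE` (default) derive fresh coefficients on the
#'   derivation databases; if `FALSE`, validate `coefficients` directly.
#' @param coefficients Coefficient table validated when `derive = FALSE`
#'   (default: the published sets).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, registry = NULL, generator = NULL,
                       n_test = 300, iss_cutoff = 16, derive = TRUE,
                       coefficients = builtin_coefficients()) {
  stopifnot(n_test > 0, iss_cutoff > 0)
  structure(list(seed = as.integer(seed), registry = registry,
                 generator = generator, n_test = n_test,
                 iss_cutoff = iss_cutoff, derive = derive,
                 coefficients = coefficients),
            class = "run_config")
}

#' Run the full study pipeline
#'
#' Orchestrates simulate (optional) -> split -> derive (optional) -> score
#' -> validate -> compare as one reproducible run:
#'
#' 1. generate or accept a two-center registry;
#' 2. hold out `n_test` complete records per center (test databases), the
#'    remainder forming the derivation databases;
#' 3. derive all coefficient sets on the derivation databases (or take the
#'    supplied sets);
#' 4. validate every equation origin on every test database, unstratified
#'    and ISS-stratified;
#' 5. compare the two cohorts descriptively.
#'
#' Test records never enter derivation (the id sets are disjoint by
#' construction and asserted). A manifest records seeds and per-stage
#' counts so a run can be reproduced byte-identically.
#'
#' @param config A [run_config()].
#' @return A list of class `triss_run`: `registry`, `splits` (per center),
#'   `derivation` (or `NULL`), `coefficients`, `validation` (unstratified),
#'   `validation_stratified`, `cohort_comparison`, `manifest`.
#' @export
run_full_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  registry <- config$registry
  if (is.null(registry)) {
    gen <- config$generator %||% registry_config()
    gen$seed <- child_seed(seed, 101L)
    registry <- generate_registry(gen)
  }
  registry <- add_trauma_scores(registry)
  centers <- sort(unique(registry$center))

  splits <- lapply(seq_along(centers), function(k) {
    split_test_derivation(registry[registry$center == centers[k], ],
                          n_test = config$n_test,
                          seed = child_seed(seed, 200L + k))
  })
  names(splits) <- centers
  for (s in splits) {
    stopifnot(length(intersect(s$test_ids, s$derivation_ids)) == 0L)
  }
  derivation_ids <- unlist(lapply(splits, `[[`, "derivation_ids"),
                           use.names = FALSE)
  test_ids <- unlist(lapply(splits, `[[`, "test_ids"), use.names = FALSE)

  derivation <- NULL
  coefficients <- config$coefficients
  if (config$derive) {
    derivation <- derive_all(registry, derivation_ids = derivation_ids)
    coefficients <- derivation$table
  }

  validation <- evaluate_matrix(registry, coefficients, test_ids = test_ids)
  validation_strat <- evaluate_matrix(registry, coefficients,
                                      iss_cutoff = config$iss_cutoff,
                                      test_ids = test_ids)
  cohorts <- compare_cohorts(registry)

  manifest <- list(
    seed = seed,
    centers = centers,
    n_records = nrow(registry),
    n_test_per_center = config$n_test,
    n_derivation = vapply(splits, function(s) length(s$derivation_ids),
                          integer(1)),
    derived = config$derive,
    n_coefficient_sets = nrow(coefficients),
    iss_cutoff = config$iss_cutoff
  )
  structure(
    list(registry = registry, splits = splits, derivation = derivation,
         coefficients = coefficients, validation = validation,
         validation_stratified = validation_strat,
         cohort_comparison = cohorts, manifest = manifest),
    class = "triss_run"
  )
}

#' @export
print.triss_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<triss_run> seed %d | %d records in %s | %d test/center | %s coefficients\n",
    m$seed, m$n_records, paste(m$centers, collapse = " + "),
    m$n_test_per_center,
    if (m$derived) "derived" else "supplied"))
  cat("Unstratified validation:\n")
  print(x$validation[, c("origin", "population", "template", "auc",
                         "ci_low", "ci_high")], n = Inf)
  invisible(x)
}
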