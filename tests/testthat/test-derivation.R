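test_that("the test/derivation split holds out complete records reproducibly", {
  reg <- generate_registry(small_config(2, 600, 400))
  h <- reg[reg$center == "HCFMUSP", ]
  sp <- split_test_derivation(h, n_test = 150, seed = 9)
  expect_length(sp$test_ids, 150)
  expect_length(sp$derivation_ids, nrow(h) - 150)
  expect_length(intersect(sp$test_ids, sp$derivation_ids), 0)
  expect_setequal(c(sp$test_ids, sp$derivation_ids), h$patient_id)
  # only complete records can be drawn into the test database
  complete_ids <- h$patient_id[is_complete_record(h)]
  expect_true(all(sp$test_ids %in% complete_ids))
  # reproducible under the seed, different otherwise
  expect_identical(split_test_derivation(h, 150, seed = 9)$test_ids,
                   sp$test_ids)
  expect_false(identical(split_test_derivation(h, 150, seed = 10)$test_ids,
                         sp$test_ids))
  expect_error(split_test_derivation(h, n_test = nrow(h) + 1),
               "only .* complete")
})

test_that("the equalizing weight is the cohort size ratio to two decimals", {
  expect_identical(equalizing_weight(2116, 7872), 3.72)
  expect_identical(equalizing_weight(500, 500), 1)
  expect_identical(equalizing_weight(100, 250), 2.5)
  expect_error(equalizing_weight(0, 10), "positive")
})

test_that("IRLS matches glm point estimates, unweighted and weighted", {
  reg <- generate_registry(small_config(5, 900, 100))
  h <- add_trauma_scores(reg[reg$center == "HCFMUSP", ])
  fit <- fit_logistic(h, "NTRISS_like", mechanism = "blunt",
                      center = "HCFMUSP")
  hb <- h[!is.na(h$mechanism) & h$mechanism == "blunt", ]
  g <- stats::glm(survived ~ bmr + sbp_code + niss + age55,
                  family = stats::binomial, data = hb)
  expect_equal(unname(fit$coefficients$b), unname(stats::coef(g)),
               tolerance = 1e-8)
  expect_equal(unname(fit$standard_errors),
               unname(summary(g)$coefficients[, "Std. Error"]),
               tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$n_used + fit$n_excluded, nrow(h))

  w <- withr::with_seed(4, runif(nrow(h), 0.5, 3))
  fw <- fit_logistic(h, "NTRISS_like", mechanism = "blunt", weights = w)
  gw <- suppressWarnings(stats::glm(
    survived ~ bmr + sbp_code + niss + age55,
    family = stats::quasibinomial, data = hb,
    weights = w[!is.na(h$mechanism) & h$mechanism == "blunt"]))
  expect_equal(unname(fw$coefficients$b), unname(stats::coef(gw)),
               tolerance = 1e-6)
})

test_that("uniform weights leave the maximum-likelihood estimates unchanged", {
  reg <- generate_registry(small_config(7, 700, 100))
  h <- reg[reg$center == "HCFMUSP", ]
  f1 <- fit_logistic(h, "NTRISS_like", mechanism = "blunt")
  f372 <- fit_logistic(h, "NTRISS_like", mechanism = "blunt", weights = 3.72)
  expect_equal(f1$coefficients$b, f372$coefficients$b, tolerance = 1e-6)
  # ... which is why the cohort-equalizing weight only matters when pooled
})

test_that("degenerate outcomes error and separation is flagged, not hidden", {
  rec <- make_records(20, survived = 1L)
  expect_error(fit_logistic(rec, "NTRISS_like"), "survivor and one death")
  # perfectly separable: survival exactly determined by BMR
  sep <- make_records(40, gcs = rep(c(15L, 3L), 20), bmr = rep(c(6L, 1L), 20),
                      survived = rep(c(1L, 0L), 20))
  fit <- suppressWarnings(fit_logistic(sep, "NTRISS_like"))
  expect_false(fit$converged)
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coefficients$b)))
})

test_that("recovery error shrinks as the derivation cohort grows", {
  p <- default_profiles()[[1]]
  p$blunt_fraction <- 1
  p$missing <- list()
  truth <- builtin_coefficients("NTRISS_like", "HCFMUSP", "blunt")$b
  rmse <- vapply(c(2000L, 20000L), function(n) {
    p$n <- n
    errs <- vapply(c(31, 32, 33), function(seed) {
      reg <- generate_registry(registry_config(profiles = list(p),
                                               seed = seed))
      fit <- fit_logistic(reg, "NTRISS_like", mechanism = "blunt")
      mean((fit$coefficients$b - truth)^2)
    }, numeric(1))
    sqrt(mean(errs))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
})

test_that("derive_all fits every stratum on derivation records only", {
  reg <- generate_registry(small_config(3, 700, 700))
  reg <- add_trauma_scores(reg)
  splits <- lapply(c("HCFMUSP", "UCSDMC"), function(ct) {
    split_test_derivation(reg[reg$center == ct, ], n_test = 100, seed = 5)
  })
  deriv_ids <- unlist(lapply(splits, `[[`, "derivation_ids"))
  test_ids <- unlist(lapply(splits, `[[`, "test_ids"))
  out <- derive_all(reg, derivation_ids = deriv_ids)
  expect_identical(nrow(out$table), 12L)
  expect_identical(nrow(out$log), 12L)
  # blunt and penetrating fits partition each center's usable derivation
  # records: per center, the two NTRISS_like strata together use exactly the
  # mechanism-known records with complete NTRISS_like predictors
  deriv <- reg[reg$patient_id %in% deriv_ids, ]
  for (ct in c("HCFMUSP", "UCSDMC")) {
    d <- deriv[deriv$center == ct, ]
    usable <- sum(!is.na(d$mechanism) & !is.na(d$bmr) & !is.na(d$sbp) &
                    !is.na(d$niss) & !is.na(d$age55) & !is.na(d$survived))
    per <- out$log[out$log$template == "NTRISS_like" & out$log$center == ct, ]
    expect_identical(sum(per$n_used), usable)
  }
  # no test record contributes to any fit
  expect_length(intersect(deriv_ids, test_ids), 0)
  # deterministic: same inputs, identical coefficient strings
  out2 <- derive_all(reg, derivation_ids = deriv_ids)
  for (i in seq_len(12)) {
    expect_identical(out$table$coefficients[[i]]$b_chr,
                     out2$table$coefficients[[i]]$b_chr)
  }
})

test_that("derive_all skips an empty stratum with a warning", {
  reg <- generate_registry(small_config(8, 500, 100))
  reg$mechanism[reg$center == "HCFMUSP"] <- "blunt"  # no penetrating stratum
  w <- testthat::capture_warnings(
    out <- derive_all(reg, templates = "NTRISS_like")
  )
  expect_true(any(grepl("Skipping NTRISS_like / HCFMUSP / penetrating", w)))
  expect_lt(nrow(out$table), 4L)
})

test_that("tidy and glance summarise a fit", {
  reg <- generate_registry(small_config(12, 500, 100))
  fit <- fit_logistic(reg[reg$center == "HCFMUSP", ], "NTRISS_like",
                      mechanism = "blunt", center = "HCFMUSP")
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "BMR", "SBP", "NISS", "AgeIndex"))
  expect_true(all(is.finite(td$std.error)))
  expect_equal(td$statistic, td$estimate / td$std.error)
  gl <- glance(fit)
  expect_identical(gl$center, "HCFMUSP")
  expect_true(gl$converged)
  expect_lt(gl$logLik, 0)
})
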