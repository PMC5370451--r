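test_that("published coefficient sets load for all 12 template/center/mechanism triples", {
  tab <- builtin_coefficients()
  expect_identical(nrow(tab), 12L)
  expect_identical(
    nrow(dplyr::distinct(tab[, c("template", "center", "mechanism")])), 12L)

  cs <- builtin_coefficients("NTRISS_like", "HCFMUSP", "blunt")
  expect_equal(unname(cs$b),
               c(-0.69833769, 0.51106398, 0.79908416, -0.09919555, -1.58444558))
  cs2 <- builtin_coefficients("TRISS_SpO2", "UCSDMC", "penetrating")
  expect_equal(unname(cs2$b),
               c(-13.4424770, 1.1728932, 1.3872589, 2.6946416, -0.1016297,
                 -3.0394087))
  # the anomalous positive age coefficient is reproduced, not corrected
  cs3 <- builtin_coefficients("NTRISS_like_SpO2", "HCFMUSP", "penetrating")
  expect_equal(unname(cs3$b[6]), 10.7638537)
  expect_error(builtin_coefficients("NTRISS_like", "ELSEWHERE", "blunt"),
               "Valid keys")
})

test_that("every published severity coefficient is negative and age negative except the flagged anomaly", {
  tab <- builtin_coefficients()
  for (i in seq_len(nrow(tab))) {
    cs <- tab$coefficients[[i]]
    sev_slot <- which(cs$predictors %in% c("ISS", "NISS")) + 1L
    age_slot <- which(cs$predictors == "AgeIndex") + 1L
    expect_lt(cs$b[sev_slot], 0)
    anomaly <- cs$template == "NTRISS_like_SpO2" && cs$center == "HCFMUSP" &&
      cs$mechanism == "penetrating"
    if (anomaly) expect_gt(cs$b[age_slot], 0) else expect_lt(cs$b[age_slot], 0)
  }
})

test_that("coefficient JSON round-trips digit-for-digit", {
  tab <- builtin_coefficients()
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficients(tab, path)
  back <- read_coefficients(path)
  for (i in seq_len(nrow(tab))) {
    expect_identical(back$coefficients[[i]]$b_chr, tab$coefficients[[i]]$b_chr)
  }
  # derived (numeric) coefficients survive a round trip too
  cs <- coefficient_set("NTRISS_like", "user", "blunt",
                        c(-0.1234567891234, 1, -2, 0.5, -1e-7))
  t2 <- coefficient_table(list(cs))
  write_coefficients(t2, path)
  expect_equal(read_coefficients(path)$coefficients[[1]]$b, cs$b)
})

test_that("the linear predictor is the intercept plus the coefficient dot product", {
  cs <- builtin_coefficients("NTRISS_like", "HCFMUSP", "blunt")
  expect_equal(linear_predictor(cs, c(0, 0, 0, 0)), unname(cs$b[1]))
  # hand-summed from the published set
  expect_equal(linear_predictor(cs, c(1, 1, 1, 1)), -1.07183068)
  zero <- coefficient_set("NTRISS_like", "user", "blunt", rep(0, 5))
  expect_identical(linear_predictor(zero, c(3, 1, 40, 1)), 0)
  expect_error(linear_predictor(cs, c(1, 2, 3)), "expects 4 predictors")
})

test_that("survival probability is the stable logistic transform", {
  expect_identical(survival_probability(0), 0.5)
  expect_equal(survival_probability(-0.69833769), 0.33218, tolerance = 1e-4)
  expect_equal(survival_probability(50), 1, tolerance = 1e-15)
  # no overflow far beyond double exp range
  expect_identical(survival_probability(c(-800, 800)), c(0, 1))
  expect_error(survival_probability(Inf), "finite")
  expect_error(survival_probability(NaN), "finite")
  # inverse of the logit on (0, 1)
  p <- seq(0.001, 0.999, by = 0.007)
  expect_equal(survival_probability(qlogis(p)), p, tolerance = 1e-12)
  # strictly increasing
  b <- seq(-20, 20, by = 0.25)
  expect_true(all(diff(survival_probability(b)) > 0))
})

test_that("record scoring follows the template conventions", {
  rec <- make_records(age = 30, gcs = 15, bmr = 6, sbp = 120, spo2 = 99,
                      injuries = "1:2")  # ISS = NISS = 4
  tab <- builtin_coefficients()
  blunt <- tab[tab$mechanism == "blunt", ]
  for (i in seq_len(nrow(blunt))) {
    ps <- score_records(rec, blunt$coefficients[[i]])$ps
    expect_gt(ps, 0.9)  # a survivor-typical record scores high everywhere
  }
  # determinism
  s1 <- score_records(rec, blunt$coefficients[[1]])$ps
  s2 <- score_records(rec, blunt$coefficients[[1]])$ps
  expect_identical(s1, s2)
})

test_that("ps responds to each predictor with the sign of its coefficient", {
  # NISS sweep under NTRISS_like: coefficient < 0 so ps strictly decreases
  cs <- builtin_coefficients("NTRISS_like", "HCFMUSP", "blunt")
  niss_vals <- c(1, 4, 9, 16, 25, 34, 50, 75)
  recs <- make_records(length(niss_vals),
                       injuries = sprintf("1:%d", c(1:5, 5, 5, 5)))
  recs <- add_trauma_scores(recs)
  recs$niss <- as.integer(niss_vals)  # direct sweep of the NISS slot
  ps <- score_records(recs, cs)$ps
  expect_true(all(diff(ps) < 0))

  # systematic sweeps: each shipped set is monotone in each predictor with
  # the direction given by the coefficient's sign
  tab <- builtin_coefficients()
  base <- add_trauma_scores(make_records(injuries = "1:3"))
  sweep_vals <- list(BMR = 1:6, GCS = 0:4, SBP = 0:4, SpO2 = 0:4,
                     ISS = c(0, 9, 25, 50, 75), NISS = c(0, 9, 25, 50, 75),
                     AgeIndex = 0:1)
  cols <- c(BMR = "bmr", GCS = "gcs_code", SBP = "sbp_code",
            SpO2 = "spo2_code", ISS = "iss", NISS = "niss", AgeIndex = "age55")
  for (i in seq_len(nrow(tab))) {
    cs <- tab$coefficients[[i]]
    for (k in seq_along(cs$predictors)) {
      pred <- cs$predictors[k]
      vals <- sweep_vals[[pred]]
      sw <- base[rep(1, length(vals)), ]
      sw$patient_id <- as.character(seq_along(vals))
      sw$mechanism <- cs$mechanism
      sw[[cols[pred]]] <- vals
      ps <- score_records(sw, cs)$ps
      if (cs$b[k + 1] > 0) expect_true(all(diff(ps) > 0))
      if (cs$b[k + 1] < 0) expect_true(all(diff(ps) < 0))
    }
  }
})

test_that("unscorable records are flagged, not dropped, and mechanisms must match", {
  rec <- make_records(3, spo2 = c(99, NA, 99), mechanism = "blunt")
  cs <- builtin_coefficients("TRISS_SpO2", "HCFMUSP", "blunt")
  out <- score_records(rec, cs)
  expect_identical(nrow(out), 3L)
  expect_identical(out$scorable, c(TRUE, FALSE, TRUE))
  expect_identical(attr(out, "n_excluded"), 1L)
  # SpO2 does not enter NTRISS_like, so the same record is scorable there
  out2 <- score_records(rec, builtin_coefficients("NTRISS_like", "HCFMUSP",
                                                  "blunt"))
  expect_identical(attr(out2, "n_excluded"), 0L)
  pen <- make_records(mechanism = "penetrating")
  expect_error(score_records(pen, cs), "Mechanism mismatch")
})

test_that("table scoring applies mechanism-matched equations per record", {
  rec <- make_records(2, mechanism = c("blunt", "penetrating"),
                      injuries = "1:3")
  out <- score_records(rec, builtin_coefficients(), origin = "HCFMUSP",
                       template = "NTRISS_like")
  by_hand <- vapply(c("blunt", "penetrating"), function(mech) {
    cs <- builtin_coefficients("NTRISS_like", "HCFMUSP", mech)
    score_records(rec[rec$mechanism == mech, ], cs)$ps
  }, numeric(1))
  expect_equal(out$ps, unname(by_hand))
})
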