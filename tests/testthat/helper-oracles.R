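# Independent oracles used across the suite. These deliberately use naive
# enumeration / direct definitions, not the package's algorithms.

# AUC by exhaustive pair counting (concordant = 1, tie = 1/2)
brute_auc <- function(ps, outcome) {
  pos <- ps[outcome == 1]
  neg <- ps[outcome == 0]
  total <- 0
  for (x in pos) for (y in neg) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# DeLong structural components by double loop; returns per-model placement
# values and the AUC covariance matrix
brute_delong <- function(ps_list, outcome) {
  pos <- which(outcome == 1)
  neg <- which(outcome == 0)
  m <- length(pos); n <- length(neg)
  k <- length(ps_list)
  psi <- function(x, y) if (x > y) 1 else if (x == y) 0.5 else 0
  v10 <- matrix(0, m, k); v01 <- matrix(0, n, k)
  theta <- numeric(k)
  for (j in seq_len(k)) {
    p <- ps_list[[j]]
    for (i in seq_len(m)) {
      v10[i, j] <- mean(vapply(p[neg], function(y) psi(p[pos[i]], y), 0))
    }
    for (i in seq_len(n)) {
      v01[i, j] <- mean(vapply(p[pos], function(x) psi(x, p[neg[i]]), 0))
    }
    theta[j] <- mean(v10[, j])
  }
  s10 <- stats::cov(v10); s01 <- stats::cov(v01)
  list(theta = theta, vcov = s10 / m + s01 / n)
}

brute_delong_z <- function(ps_a, ps_b, outcome) {
  o <- brute_delong(list(ps_a, ps_b), outcome)
  vd <- o$vcov[1, 1] + o$vcov[2, 2] - 2 * o$vcov[1, 2]
  (o$theta[1] - o$theta[2]) / sqrt(vd)
}

# analytic mean/sd of a normal truncated to [lo, hi]
tnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  m1 <- mean + sd * (dnorm(a) - dnorm(b)) / z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                 ((dnorm(a) - dnorm(b)) / z)^2)
  c(mean = m1, sd = sqrt(v))
}

# minimal valid registry rows with overridable fields
make_records <- function(n = 1, patient_id = sprintf("P%03d", seq_len(n)),
                         center = "HCFMUSP", age = 30, sex = "male",
                         mechanism = "blunt", gcs = 15L, bmr = 6L,
                         sbp = 120, rr = 16, spo2 = 99,
                         injuries = "3:2", survived = 1L) {
  tibble::tibble(
    patient_id = patient_id, center = center, age = age, sex = sex,
    mechanism = mechanism, gcs = as.integer(gcs), bmr = as.integer(bmr),
    sbp = sbp, rr = rr, spo2 = spo2, injuries = injuries,
    survived = as.integer(survived)
  )
}

# small two-center generator config for fast pipeline tests; both arms use
# the severe profile so every mechanism stratum keeps deaths at small n
small_config <- function(seed = 1, n1 = 400, n2 = 500) {
  p <- default_profiles()
  p[[2]] <- p[[1]]
  p[[2]]$name <- "UCSDMC"
  p[[1]]$n <- as.integer(n1)
  p[[2]]$n <- as.integer(n2)
  registry_config(profiles = p, seed = seed)
}

# random injury list generator for property tests
random_injuries <- function(max_n = 4, max_sev = 5) {
  k <- sample.int(max_n + 1L, 1L) - 1L
  if (k == 0L) return(injury_table())
  injury_table(sample.int(6L, k, replace = TRUE),
               sample.int(max_sev, k, replace = TRUE))
}
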