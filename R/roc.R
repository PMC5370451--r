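#' Area under the ROC curve
#'
#' Nonparametric (trapezoidal / Mann-Whitney) AUC of a score against a
#' binary outcome, with ties counted one half. The positive class is
#' survival (`outcome == 1`): an informative survival probability therefore
#' gives AUC > 0.5.
#'
#' @param ps Numeric scores (predicted survival probabilities).
#' @param outcome Binary outcome vector, 1 = survived, 0 = died.
#' @return The AUC in \[0, 1\].
#' @examples
#' auc(c(0.1, 0.4, 0.4, 0.9), c(0, 0, 1, 1))  # 0.875
#' @export
auc <- function(ps, outcome) {
  ok <- !is.na(ps) & !is.na(outcome)
  ps <- ps[ok]; outcome <- outcome[ok]
  check_two_classes(outcome)
  m <- sum(outcome == 1)
  n <- sum(outcome == 0)
  r <- rank(ps)  # midranks handle ties
  (sum(r[outcome == 1]) - m * (m + 1) / 2) / (m * n)
}

check_two_classes <- function(outcome) {
  if (!all(outcome %in% c(0, 1))) abort("`outcome` must be binary 0/1.")
  if (length(unique(outcome)) < 2L) {
    abort("Both outcome classes (survived and died) must be present.")
  }
  invisible(outcome)
}

# DeLong structural components (placement values) for one or more score
# vectors on a common outcome. Returns list(theta, v10 (m x k), v01 (n x k)).
delong_components <- function(ps_list, outcome) {
  check_two_classes(outcome)
  pos <- which(outcome == 1)
  neg <- which(outcome == 0)
  m <- length(pos); n <- length(neg)
  k <- length(ps_list)
  v10 <- matrix(NA_real_, m, k)
  v01 <- matrix(NA_real_, n, k)
  theta <- numeric(k)
  for (j in seq_len(k)) {
    x <- ps_list[[j]][pos]
    y <- ps_list[[j]][neg]
    if (anyNA(x) || anyNA(y)) abort("Scores must be non-missing for DeLong components.")
    r_all <- rank(c(x, y))
    r_x <- rank(x)
    r_y <- rank(y)
    # placement of each positive among negatives, ties = 1/2
    v10[, j] <- (r_all[seq_len(m)] - r_x) / n
    v01[, j] <- 1 - (r_all[m + seq_len(n)] - r_y) / m
    theta[j] <- mean(v10[, j])
  }
  list(theta = theta, v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong variance and confidence interval for an AUC
#'
#' `delong_variance()` estimates the sampling variance of the AUC from the
#' DeLong structural components (placement values): `S10/m + S01/n`, with
#' `S10`, `S01` the empirical variances of the per-positive and
#' per-negative components. `auc_ci()` builds the normal-approximation
#' interval `auc +/- z * SE`, clipped to \[0, 1\].
#'
#' @inheritParams auc
#' @param level Confidence level (default 0.95).
#' @return `delong_variance()`: a variance; `auc_ci()`: a tibble with
#'   `auc`, `ci_low`, `ci_high`, `se`, `n_pos`, `n_neg`.
#' @export
delong_variance <- function(ps, outcome) {
  ok <- !is.na(ps) & !is.na(outcome)
  comp <- delong_components(list(ps[ok]), outcome[ok])
  if (comp$m < 2 || comp$n < 2) {
    abort("DeLong variance needs at least 2 records in each outcome class.")
  }
  var(comp$v10[, 1]) / comp$m + var(comp$v01[, 1]) / comp$n
}

#' @rdname delong_variance
#' @export
auc_ci <- function(ps, outcome, level = 0.95) {
  ok <- !is.na(ps) & !is.na(outcome)
  ps <- ps[ok]; outcome <- outcome[ok]
  a <- auc(ps, outcome)
  se <- sqrt(delong_variance(ps, outcome))
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    auc = a,
    ci_low = max(0, a - z * se),
    ci_high = min(1, a + z * se),
    se = se,
    n_pos = sum(outcome == 1),
    n_neg = sum(outcome == 0)
  )
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two models scored on the same records (hence
#' correlated) using the covariance of their DeLong structural components:
#' `z = (auc_a - auc_b) / SE(auc_a - auc_b)`, two-sided p-value. Swapping
#' the models flips the sign of `z` and leaves `p` unchanged.
#'
#' @param ps_a,ps_b Scores of the two models on the same records.
#' @inheritParams auc
#' @return A one-row tibble: `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(ps_a, ps_b, outcome) {
  if (length(ps_a) != length(ps_b) || length(ps_a) != length(outcome)) {
    abort("`ps_a`, `ps_b` and `outcome` must have the same length.")
  }
  ok <- !is.na(ps_a) & !is.na(ps_b) & !is.na(outcome)
  comp <- delong_components(list(ps_a[ok], ps_b[ok]), outcome[ok])
  s10 <- stats::cov(comp$v10)
  s01 <- stats::cov(comp$v01)
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / comp$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / comp$n
  d <- comp$theta[1] - comp$theta[2]
  z <- if (var_diff <= 0) {
    if (abs(d) < .Machine$double.eps^0.5) 0 else sign(d) * Inf
  } else {
    d / sqrt(var_diff)
  }
  tibble::tibble(auc_a = comp$theta[1], auc_b = comp$theta[2], z = z,
                 p_value = 2 * pnorm(-abs(z)))
}

#' Sensitivity and specificity at the Youden-optimal threshold
#'
#' Scans candidate thresholds (`-Inf` and the midpoints between
#' consecutive distinct score values; a record is called a survivor when
#' `ps >= threshold`) and returns the operating point maximizing Youden's
#' `J = sensitivity + specificity - 1`. Ties in `J` are broken toward
#' higher specificity (the largest tied threshold). Percentages are
#' reported to one decimal.
#'
#' @inheritParams auc
#' @return A one-row tibble: `sensitivity`, `specificity` (percent),
#'   `threshold`, `youden_j`.
#' @export
sens_spec_at_optimum <- function(ps, outcome) {
  ok <- !is.na(ps) & !is.na(outcome)
  ps <- ps[ok]; outcome <- outcome[ok]
  check_two_classes(outcome)
  v <- sort(unique(ps))
  m <- sum(outcome == 1); n <- sum(outcome == 0)
  pos_at <- vapply(split(outcome, factor(ps, levels = v)),
                   function(o) sum(o == 1), numeric(1))
  neg_at <- tabulate(match(ps, v), length(v)) - pos_at
  # cut k (k >= 1): predict survivor iff ps >= v[k]; cut 0 is -Inf (all called
  # survivors). sens_k = positives at or above v[k]; spec_k = negatives below.
  K <- length(v)
  suffix_pos <- unname(rev(cumsum(rev(pos_at))))  # positives with ps >= v[k]
  prefix_neg <- unname(cumsum(neg_at))            # negatives with ps <= v[k]
  sens <- c(1, suffix_pos[-1] / m)
  spec <- c(0, prefix_neg[-K] / n)
  cuts <- c(-Inf, if (K > 1) (v[-K] + v[-1]) / 2 else NULL)
  j <- sens + spec - 1
  # ties in J break toward higher specificity, i.e. the largest tied cut
  best <- max(which(j >= max(j) - 1e-12))
  tibble::tibble(
    sensitivity = round(100 * sens[best], 1),
    specificity = round(100 * spec[best], 1),
    threshold = cuts[best],
    youden_j = j[best]
  )
}

#' ROC curve points
#'
#' Step-function ROC coordinates (false positive rate, sensitivity) over
#' all distinct thresholds, for plotting.
#'
#' @inheritParams auc
#' @return A tibble of class `triss_roc` with columns `fpr`, `tpr`,
#'   `threshold`; the AUC is attached as attribute `auc`.
#' @export
roc_points <- function(ps, outcome) {
  ok <- !is.na(ps) & !is.na(outcome)
  ps <- ps[ok]; outcome <- outcome[ok]
  check_two_classes(outcome)
  v <- sort(unique(ps))
  cuts <- c(Inf, rev(v))
  m <- sum(outcome == 1); n <- sum(outcome == 0)
  pos_at <- vapply(split(outcome, factor(ps, levels = v)),
                   function(o) sum(o == 1), numeric(1))
  neg_at <- tabulate(match(ps, v), length(v)) - pos_at
  tpr <- unname(c(0, rev(cumsum(rev(pos_at)))[rev(seq_along(v))] / m))
  fpr <- unname(c(0, rev(cumsum(rev(neg_at)))[rev(seq_along(v))] / n))
  out <- tibble::tibble(fpr = fpr, tpr = tpr, threshold = cuts)
  attr(out, "auc") <- auc(ps, outcome)
  class(out) <- c("triss_roc", class(out))
  out
}

#' Plot a ROC curve
#'
#' @param object A `triss_roc` object from [roc_points()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot triss_roc
#' @export
autoplot.triss_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
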