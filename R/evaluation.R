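#' Cross-application validation matrix
#'
#' Reproduces the study's validation design: every equation origin (the
#' center whose derivation data produced the coefficients) is applied to
#' every test population, for every template. Within a cell, blunt and
#' penetrating records are scored with their mechanism-matched equations
#' and evaluated jointly. Each cell reports AUC with DeLong 95% CI and the
#' Youden-optimal sensitivity/specificity; with `iss_cutoff` set, every
#' cell is additionally split into low/high severity strata
#' (`ISS < cutoff` / `ISS >= cutoff`), doubling the rows.
#'
#' @param data A registry tibble covering the test populations (restrict
#'   via `test_ids` to use held-out test databases).
#' @param coefficients A coefficient table (e.g. [builtin_coefficients()]
#'   or a derivation result's `$table`).
#' @param iss_cutoff Optional ISS severity cutoff (the study uses 16).
#' @param test_ids Optional `patient_id`s restricting the evaluation
#'   population.
#' @param level CI level.
#' @return A tibble with one row per origin x population x template
#'   (x stratum): `origin`, `population`, `template`, `stratum`,
#'   `sensitivity`, `specificity`, `auc`, `ci_low`, `ci_high`, `n`,
#'   `n_pos`, `n_neg`, `n_excluded`. Cells with fewer than 2 records per
#'   outcome class are reported with `NA` statistics, not fabricated.
#' @export
evaluate_matrix <- function(data, coefficients, iss_cutoff = NULL,
                            test_ids = NULL, level = 0.95) {
  if (!all(PREDICTOR_COLUMNS %in% names(data))) data <- add_trauma_scores(data)
  if (!is.null(test_ids)) data <- data[data$patient_id %in% test_ids, ]
  origins <- sort(unique(coefficients$center))
  populations <- sort(unique(data$center))
  templates <- intersect(names(model_templates), unique(coefficients$template))
  rows <- list()
  for (origin in origins) {
    for (pop in populations) {
      pop_data <- data[data$center == pop, , drop = FALSE]
      for (tpl in templates) {
        scored <- score_records(pop_data, coefficients, origin = origin,
                                template = tpl)
        strata <- if (is.null(iss_cutoff)) {
          list(all = rep(TRUE, nrow(scored)))
        } else {
          setNames(
            list(!is.na(scored$iss) & scored$iss < iss_cutoff,
                 !is.na(scored$iss) & scored$iss >= iss_cutoff),
            c(sprintf("ISS<%d", iss_cutoff), sprintf("ISS>=%d", iss_cutoff))
          )
        }
        for (s in names(strata)) {
          sub <- scored[strata[[s]] & scored$scorable, , drop = FALSE]
          n_pos <- sum(sub$survived == 1)
          n_neg <- sum(sub$survived == 0)
          if (n_pos >= 2 && n_neg >= 2) {
            ci <- auc_ci(sub$ps, sub$survived, level = level)
            ss <- sens_spec_at_optimum(sub$ps, sub$survived)
            row <- tibble::tibble(
              origin = origin, population = pop, template = tpl, stratum = s,
              sensitivity = ss$sensitivity, specificity = ss$specificity,
              auc = ci$auc, ci_low = ci$ci_low, ci_high = ci$ci_high,
              n = nrow(sub), n_pos = n_pos, n_neg = n_neg,
              n_excluded = sum(strata[[s]] & !scored$scorable)
            )
          } else {
            row <- tibble::tibble(
              origin = origin, population = pop, template = tpl, stratum = s,
              sensitivity = NA_real_, specificity = NA_real_,
              auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              n = nrow(sub), n_pos = n_pos, n_neg = n_neg,
              n_excluded = sum(strata[[s]] & !scored$scorable)
            )
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("triss_evaluation", class(out))
  out
}

#' Plot an evaluation matrix
#'
#' AUC with DeLong CIs per template, faceted by equation origin and test
#' population.
#'
#' @param object A `triss_evaluation` tibble from [evaluate_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot triss_evaluation
#' @export
autoplot.triss_evaluation <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$template, y = .data$auc, colour = .data$stratum)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$origin),
      cols = ggplot2::vars(.data$population),
      labeller = ggplot2::labeller(
        origin = function(x) paste(x, "equations"),
        population = function(x) paste("applied to", x)
      )
    ) +
    ggplot2::labs(x = NULL, y = "AUC (DeLong 95% CI)", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Two-center cohort comparison
#'
#' Descriptive comparison of the two centers in the style of a cohort
#' characteristics table: categorical variables as n (%) per center with a
#' Pearson chi-square test (no continuity correction), continuous
#' variables as mean (SD) per center with a one-way ANOVA F-test.
#' Categories with zero expected counts are collapsed into the nearest
#' non-empty category with a warning.
#'
#' @param data A registry tibble with both centers (scores added if
#'   absent, so ISS/NISS/RTS are summarised too).
#' @param categorical,continuous Column names to compare. Defaults cover
#'   sex, mechanism, GCS band, survival; and age, SBP, RR, SpO2, RTS, ISS,
#'   NISS.
#' @return A tibble with one row per variable level (categorical) or per
#'   variable (continuous): per-center summaries, test used and p-value.
#' @export
compare_cohorts <- function(data,
                            categorical = c("sex", "mechanism", "gcs_band",
                                            "survived"),
                            continuous = c("age", "sbp", "rr", "spo2", "rts",
                                           "iss", "niss")) {
  if (!all(PREDICTOR_COLUMNS %in% names(data))) data <- add_trauma_scores(data)
  centers <- sort(unique(data$center))
  if (length(centers) != 2L) abort("`compare_cohorts()` needs exactly two centers.")
  if ("gcs_band" %in% categorical && !"gcs_band" %in% names(data)) {
    data$gcs_band <- cut(data$gcs, breaks = c(2, 8, 12, 15),
                         labels = c("3-8", "9-12", "13-15"))
  }
  rows <- list()
  for (v in categorical) {
    x <- data[[v]]
    keep <- !is.na(x)
    tab <- table(factor(x[keep]), factor(data$center[keep], levels = centers))
    if (any(rowSums(tab) == 0)) {
      warn(sprintf("Collapsing empty categories of %s.", v))
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    }
    p <- if (nrow(tab) >= 2) {
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    } else NA_real_
    pct <- prop.table(tab, margin = 2) * 100
    for (lev in rownames(tab)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, level = lev, test = "chi-square",
        summary_1 = sprintf("%d (%.1f)", tab[lev, 1], pct[lev, 1]),
        summary_2 = sprintf("%d (%.1f)", tab[lev, 2], pct[lev, 2]),
        statistic = NA_real_, p_value = p
      )
    }
    if (nrow(tab) >= 2) {
      st <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
      rows[[length(rows)]]$statistic <- unname(st)
    }
  }
  for (v in continuous) {
    x <- data[[v]]
    keep <- !is.na(x)
    fit <- aov(x[keep] ~ factor(data$center[keep], levels = centers))
    an <- anova(fit)
    ms <- vapply(centers, function(ct) {
      xx <- x[keep & data$center == ct]
      sprintf("%.1f (+/-%.1f)", mean(xx), sd(xx))
    }, character(1))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, level = "mean (SD)", test = "ANOVA",
      summary_1 = ms[1], summary_2 = ms[2],
      statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1]
    )
  }
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "summary_1"] <- centers[1]
  names(out)[names(out) == "summary_2"] <- centers[2]
  out
}
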