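#' 2x2 contingency table for one drug against one event
#'
#' `contingency_table()` validates raw counts; `cross_tabulate()` counts
#' analysis rows: `n11` rows of the drug with the event, `n12` rows of the
#' drug without it, `n21` event rows of all other drugs, `n22` everything
#' else. The four cells partition the analysis table.
#'
#' @param n11,n12,n21,n22 non-negative integer counts.
#' @return an object of class `"faers_ct"` (a named list of the four counts).
#' @export
contingency_table <- function(n11, n12, n21, n22) {
  cells <- c(n11 = n11, n12 = n12, n21 = n21, n22 = n22)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("contingency cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) {
    stop("contingency table is empty", call. = FALSE)
  }
  structure(as.list(cells), class = "faers_ct")
}

#' @param analysis the analysis tibble (see [build_analysis_table()]).
#' @param drug_name normalised drug name; a drug absent from the table yields
#'   `n11 = n12 = 0`.
#' @param event_pt Preferred Term of interest (case-insensitive exact match).
#' @rdname contingency_table
#' @export
cross_tabulate <- function(analysis, drug_name, event_pt = "Hiccups") {
  if (!nrow(analysis)) {
    stop("analysis table is empty", call. = FALSE)
  }
  ev <- if ("is_event" %in% names(analysis)) {
    analysis$is_event
  } else {
    toupper(analysis$pt) == toupper(event_pt)
  }
  dr <- analysis$drug_name == drug_name
  contingency_table(
    n11 = sum(dr & ev), n12 = sum(dr & !ev),
    n21 = sum(!dr & ev), n22 = sum(!dr & !ev)
  )
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' The ROR is the odds of the event among reports of the drug divided by the
#' odds of the event among all other reports:
#' `ROR = (n11 * n22) / (n12 * n21)`. The 95% CI is Woolf/Wald on the log
#' scale, `exp(ln ROR +/- 1.96 * sqrt(1/n11 + 1/n12 + 1/n21 + 1/n22))`. Any
#' zero cell makes all three values undefined (`NA`) with the `degenerate`
#' flag set; no continuity correction is applied.
#'
#' @param table a `"faers_ct"` contingency table.
#' @return a list with `ror`, `ci_low`, `ci_high`, `degenerate`.
#' @export
compute_ror <- function(table) {
  stopifnot(inherits(table, "faers_ct"))
  cells <- unlist(table)
  if (any(cells == 0)) {
    return(list(
      ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      degenerate = TRUE
    ))
  }
  ror <- (table$n11 * table$n22) / (table$n12 * table$n21)
  se <- sqrt(sum(1 / cells))
  list(
    ror = ror,
    ci_low = exp(log(ror) - 1.96 * se),
    ci_high = exp(log(ror) + 1.96 * se),
    degenerate = FALSE
  )
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditional on both margins, the first cell follows a hypergeometric
#' distribution. The two-sided p-value sums the probabilities of all
#' outcomes whose probability does not exceed that of the observed table; a
#' relative tolerance of 1e-12 absorbs floating-point noise in the tie
#' comparison. Degenerate margins give p = 1.
#'
#' @param table a `"faers_ct"` contingency table.
#' @return the p-value in (0, 1].
#' @export
fisher_exact <- function(table) {
  stopifnot(inherits(table, "faers_ct"))
  r1 <- table$n11 + table$n12
  r2 <- table$n21 + table$n22
  c1 <- table$n11 + table$n21
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2) {
    return(1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  pmf <- dhyper(support, r1, r2, c1)
  p_obs <- pmf[support == table$n11]
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-12)]))
}

#' Per-drug disproportionality statistics
#'
#' Cross-tabulates every drug in the analysis table (or a supplied subset)
#' against the event, computes the ROR with its Wald 95% CI, the two-sided
#' Fisher exact p-value, and the volcano coordinates `ln_ror` and
#' `neg_log10_p`. A drug is flagged as a signal when the lower bound of the
#' ROR's 95% CI exceeds 1.
#'
#' @param analysis the analysis tibble.
#' @param event_pt Preferred Term of interest.
#' @param drugs optional character vector restricting the drugs scored.
#' @return a tibble with one row per drug: the four cells, `ror`, `ci_low`,
#'   `ci_high`, `p_value`, `ln_ror`, `neg_log10_p`, `n_drug_reports`
#'   (`n11 + n12`), `degenerate` and `is_signal`.
#' @export
detect_signals <- function(analysis, event_pt = "Hiccups", drugs = NULL) {
  if (!nrow(analysis)) {
    stop("analysis table is empty", call. = FALSE)
  }
  ev <- if ("is_event" %in% names(analysis)) {
    analysis$is_event
  } else {
    toupper(analysis$pt) == toupper(event_pt)
  }
  counts <- tibble(drug_name = analysis$drug_name, is_event = ev) %>%
    group_by(drug_name) %>%
    summarise(n11 = sum(is_event), n12 = sum(!is_event), .groups = "drop")
  if (!is.null(drugs)) {
    counts <- counts %>% filter(drug_name %in% drugs)
  }
  total_event <- sum(ev)
  total <- length(ev)
  counts <- counts %>%
    mutate(n21 = total_event - n11, n22 = total - total_event - n12) %>%
    arrange(drug_name)
  stats <- lapply(seq_len(nrow(counts)), function(i) {
    ct <- contingency_table(
      counts$n11[i], counts$n12[i], counts$n21[i], counts$n22[i]
    )
    est <- compute_ror(ct)
    c(est, list(p_value = fisher_exact(ct)))
  })
  counts %>%
    mutate(
      ror = vapply(stats, function(s) s$ror, 0),
      ci_low = vapply(stats, function(s) s$ci_low, 0),
      ci_high = vapply(stats, function(s) s$ci_high, 0),
      degenerate = vapply(stats, function(s) s$degenerate, TRUE),
      p_value = vapply(stats, function(s) s$p_value, 0),
      ln_ror = log(ror),
      neg_log10_p = -log10(p_value),
      n_drug_reports = n11 + n12,
      is_signal = !degenerate & ci_low > 1
    )
}

#' Candidate-extraction thresholds
#'
#' Bundles the three thresholds used to pass univariate signals on to the
#' multivariate model: a strict minimum number of reports for the drug
#' (`n_drug_reports > min_reports`), a p-value ceiling and an ROR floor.
#' `default_candidate_criteria()` ships the per-stratum defaults used for
#' the published analysis: all data (5000, 0.001, 1), males (3000, 0.001, 1)
#' and females (5000, 0.05, 1).
#'
#' @param min_reports strict lower bound on the drug's report count.
#' @param max_p p-value threshold (exclusive).
#' @param min_ror ROR threshold (exclusive).
#' @return a list of class `"candidate_criteria"`.
#' @export
candidate_criteria <- function(min_reports, max_p, min_ror = 1) {
  if (!is.numeric(min_reports) || min_reports < 0) {
    stop("min_reports must be a non-negative count", call. = FALSE)
  }
  if (!is.numeric(max_p) || max_p <= 0 || max_p > 1) {
    stop("max_p must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(min_ror) || min_ror < 0) {
    stop("min_ror must be non-negative", call. = FALSE)
  }
  structure(
    list(min_reports = min_reports, max_p = max_p, min_ror = min_ror),
    class = "candidate_criteria"
  )
}

#' @param stratum one of `"all"`, `"male"`, `"female"`.
#' @rdname candidate_criteria
#' @export
default_candidate_criteria <- function(stratum = c("all", "male", "female")) {
  switch(match.arg(stratum),
    all = candidate_criteria(5000, 0.001, 1),
    male = candidate_criteria(3000, 0.001, 1),
    female = candidate_criteria(5000, 0.05, 1)
  )
}

#' Extract candidate drugs from a signal table
#'
#' Returns drugs with more than `min_reports` reports, p-value below `max_p`
#' and ROR above `min_ror`, ordered by descending ROR (ties broken by drug
#' name). Drugs with a degenerate (undefined) ROR are never selected.
#'
#' @param signals a tibble from [detect_signals()].
#' @param criteria a [candidate_criteria()] object.
#' @return the selected subset of `signals`, reordered.
#' @export
select_candidates <- function(signals, criteria) {
  stopifnot(inherits(criteria, "candidate_criteria"))
  signals %>%
    filter(
      !degenerate,
      n_drug_reports > criteria$min_reports,
      p_value < criteria$max_p,
      ror > criteria$min_ror
    ) %>%
    arrange(desc(ror), drug_name)
}

#' Volcano plot of disproportionality signals
#'
#' Plots effect size (`ln ROR`) against significance (`-log10 p`), one point
#' per drug with a defined ROR, coloured by the log10 report count, with the
#' p = 0.05 baseline drawn in red. `volcano_coordinates()` returns the
#' plotted coordinate table.
#'
#' @param signals a tibble from [detect_signals()].
#' @param baseline_p baseline p-value rendered as a horizontal red line.
#' @return `volcano_plot()` a [ggplot2::ggplot] object;
#'   `volcano_coordinates()` a tibble of `drug_name`, `ln_ror`,
#'   `neg_log10_p`, `n_drug_reports`.
#' @export
volcano_plot <- function(signals, baseline_p = 0.05) {
  dat <- volcano_coordinates(signals)
  ggplot(dat, aes(x = ln_ror, y = neg_log10_p)) +
    geom_hline(yintercept = -log10(baseline_p), colour = "red") +
    geom_point(aes(colour = log10(n_drug_reports)), size = 1.6) +
    scale_colour_gradient(
      low = "blue", high = "red",
      name = "log10 reports"
    ) +
    labs(
      x = "ln ROR", y = expression(-log[10] ~ p),
      title = "Disproportionality volcano plot"
    ) +
    theme_minimal()
}

#' @rdname volcano_plot
#' @export
volcano_coordinates <- function(signals) {
  ok <- !signals$degenerate
  if (!any(ok)) {
    stop("no defined signals to plot", call. = FALSE)
  }
  signals[ok, c("drug_name", "ln_ror", "neg_log10_p", "n_drug_reports")]
}
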