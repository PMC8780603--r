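#' Collapse the analysis table to one record per case
#'
#' A case (patient episode) may be represented by several report versions.
#' For demographic statistics, the report with the lexicographically greatest
#' report id (the latest version) supplies gender, age, weight and country;
#' the case counts as an event case when any of its rows carries the event.
#'
#' @param analysis the analysis tibble.
#' @return a tibble with one row per `case_id`: `report_id`, `is_event`,
#'   `gender`, `age_years`, `weight_kg`, `country`.
#' @export
case_table <- function(analysis) {
  demo <- analysis %>%
    distinct(case_id, report_id, gender, age_years, weight_kg, country) %>%
    arrange(case_id, desc(report_id)) %>%
    distinct(case_id, .keep_all = TRUE)
  ev <- analysis %>%
    group_by(case_id) %>%
    summarise(is_event = any(is_event), .groups = "drop")
  demo %>%
    inner_join(ev, by = "case_id") %>%
    arrange(case_id)
}

#' Gender association with the event
#'
#' Builds the 2x2 table of gender (male/female) against event occurrence at
#' the case level and tests it with the two-sided Fisher exact test. The
#' male share is the percentage of *all* event cases that are male — cases
#' with unknown gender stay in the denominator, mirroring how published
#' case tallies are reported — rounded to the nearest integer.
#'
#' @param cases a case-level tibble from [case_table()].
#' @return a list with `table` (`"faers_ct"`: male-event, male-non,
#'   female-event, female-non), `p_value`, `male_share_pct`,
#'   `n_event_cases`, `degenerate` (true when a gender class is empty).
#' @export
gender_association <- function(cases) {
  male <- cases$gender == "male"
  female <- cases$gender == "female"
  ev <- cases$is_event
  ct <- contingency_table(
    n11 = sum(male & ev), n12 = sum(male & !ev),
    n21 = sum(female & ev), n22 = sum(female & !ev)
  )
  degenerate <- (ct$n11 + ct$n12 == 0) || (ct$n21 + ct$n22 == 0)
  list(
    table = ct,
    p_value = fisher_exact(ct),
    male_share_pct = round(100 * ct$n11 / sum(ev)),
    n_event_cases = sum(ev),
    degenerate = degenerate
  )
}

#' Compare a continuous variable between event and non-event cases
#'
#' Complete-case Welch two-sample t-test of age (years) or weight (kg), with
#' group means and standard errors of the mean. Cases missing the variable
#' are excluded; `n_used` reports how many complete cases entered the
#' comparison.
#'
#' @param cases a case-level tibble from [case_table()].
#' @param variable `"age"` or `"weight"`.
#' @return a list of class `"group_comparison"`: `variable`, `n_used`,
#'   `mean_event`, `sem_event`, `n_event`, `mean_non`, `sem_non`, `n_non`,
#'   `p_value` (`NA` with `degenerate = TRUE` when either group has fewer
#'   than two complete cases).
#' @export
continuous_compare <- function(cases, variable = c("age", "weight")) {
  variable <- match.arg(variable)
  x <- switch(variable, age = cases$age_years, weight = cases$weight_kg)
  ok <- !is.na(x)
  x <- x[ok]
  ev <- cases$is_event[ok]
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  res <- list(
    variable = variable,
    n_used = length(x),
    mean_event = if (any(ev)) mean(x[ev]) else NA_real_,
    sem_event = sem(x[ev]),
    n_event = sum(ev),
    mean_non = if (any(!ev)) mean(x[!ev]) else NA_real_,
    sem_non = sem(x[!ev]),
    n_non = sum(!ev),
    p_value = NA_real_,
    degenerate = FALSE
  )
  if (sum(ev) < 2 || sum(!ev) < 2) {
    res$degenerate <- TRUE
  } else if (sd(x[ev]) == 0 && sd(x[!ev]) == 0) {
    # both groups constant: identical means give p = 1, else p -> 0
    res$p_value <- if (isTRUE(all.equal(mean(x[ev]), mean(x[!ev])))) 1 else 0
  } else {
    res$p_value <- t.test(x[ev], x[!ev])$p.value
  }
  class(res) <- "group_comparison"
  res
}

#' Incidence of the event by age decade and gender
#'
#' Bins cases with known gender and age into decade-wide age bins and
#' reports, per bin, the event incidence among male cases, the incidence
#' among female cases (both as percentages of the bin's cases of that
#' gender) and the male share of the bin's event cases. Bins with a zero
#' denominator yield `NA`, not zero.
#'
#' @param cases a case-level tibble from [case_table()].
#' @param bin_width bin width in years (default 10).
#' @return a tibble with `age_bin` (lower edge), `n_male`, `n_female`,
#'   `male_incidence_pct`, `female_incidence_pct`, `male_share_pct`.
#' @export
age_incidence_curve <- function(cases, bin_width = 10) {
  dat <- cases %>%
    filter(gender %in% c("male", "female"), !is.na(age_years)) %>%
    mutate(age_bin = floor(age_years / bin_width) * bin_width)
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  dat %>%
    group_by(age_bin) %>%
    summarise(
      n_male = sum(gender == "male"),
      n_female = sum(gender == "female"),
      male_event = sum(gender == "male" & is_event),
      female_event = sum(gender == "female" & is_event),
      .groups = "drop"
    ) %>%
    mutate(
      male_incidence_pct = pct(male_event, n_male),
      female_incidence_pct = pct(female_event, n_female),
      male_share_pct = pct(male_event, male_event + female_event)
    ) %>%
    arrange(age_bin)
}
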