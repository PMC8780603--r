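#' Pairwise Spearman collinearity screen
#'
#' Computes the squared Spearman rank correlation for every covariate pair on
#' pairwise-complete observations and flags pairs with rho^2 above the
#' threshold. Flagged covariates are reported but never dropped
#' automatically; constant covariates (undefined correlation) are listed
#' separately.
#'
#' @param design a data frame of numeric covariates (at least two).
#' @param threshold rho^2 above which a pair is flagged (default 0.9).
#' @return a list with `rho2` (symmetric matrix), `flagged` (tibble of pairs
#'   with `rho2 > threshold`) and `constant` (character vector of
#'   zero-variance covariates).
#' @export
screen_collinearity <- function(design, threshold = 0.9) {
  design <- as.data.frame(design)
  if (ncol(design) < 2) {
    stop("collinearity screening needs at least two covariates", call. = FALSE)
  }
  constant <- names(design)[vapply(
    design, function(x) sd(x, na.rm = TRUE) == 0 || all(is.na(x)), TRUE
  )]
  rho <- suppressWarnings(
    cor(design, method = "spearman", use = "pairwise.complete.obs")
  )
  rho2 <- rho^2
  idx <- which(upper.tri(rho2) & !is.na(rho2) & rho2 > threshold, arr.ind = TRUE)
  flagged <- tibble(
    covariate_a = rownames(rho2)[idx[, 1L]],
    covariate_b = colnames(rho2)[idx[, 2L]],
    rho2 = rho2[idx]
  )
  list(rho2 = rho2, flagged = flagged, constant = constant)
}

#' Fit a logistic risk model with Wald confidence intervals
#'
#' Nominal (binary) logistic regression of the event indicator on drug
#' exposure indicators and patient covariates, fitted by maximum likelihood
#' via iteratively reweighted least squares (relative convergence tolerance
#' 1e-8, at most 100 iterations). Each covariate is reported as an odds
#' ratio `exp(beta)` with a Wald 95% CI `exp(beta +/- 1.96 * se)` and a
#' significance flag set exactly when the CI excludes 1. Complete separation
#' is flagged heuristically (any |beta| > 15) with a warning rather than a
#' silent estimate.
#'
#' @param data a data frame containing the outcome and covariates.
#' @param outcome name of the binary outcome column (0/1 or logical).
#' @param covariates character vector of covariate column names.
#' @param complete_cases drop rows with any missing value among the used
#'   columns (default `TRUE`, matching the complete-case convention of the
#'   univariate analyses).
#' @return a list of class `"faers_logit"`: `terms` (tibble of `term`,
#'   `estimate`, `odds_ratio`, `ci_low`, `ci_high`, `significant`),
#'   `intercept`, `log_likelihood`, `converged`, `separated`, `auc`,
#'   `n_used`, `fitted` (probabilities), `outcome` (observed 0/1).
#' @export
fit_logistic <- function(data, outcome, covariates, complete_cases = TRUE) {
  used <- c(outcome, covariates)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop(sprintf("column '%s' not found in data", missing_cols[1]), call. = FALSE)
  }
  dat <- as.data.frame(data)[used]
  if (complete_cases) {
    dat <- dat[complete.cases(dat), , drop = FALSE]
  }
  y <- as.integer(dat[[outcome]])
  if (length(unique(y)) < 2) {
    stop("degenerate outcome: only one class present", call. = FALSE)
  }
  if (nrow(dat) < 10 * length(covariates)) {
    stop("too few complete cases for the number of covariates", call. = FALSE)
  }
  const <- covariates[vapply(dat[covariates], function(x) sd(x) == 0, TRUE)]
  if (length(const)) {
    stop(sprintf("covariate '%s' has zero variance", const[1]), call. = FALSE)
  }
  form <- as.formula(paste(
    outcome, "~", paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  # stop at 1e-12 relative deviance change: comfortably inside the 1e-8
  # convergence requirement, and tight enough that a saturated single-binary
  # covariate fit reproduces the closed-form odds ratio to >= 10 significant
  # digits (IRLS is Newton-Raphson here, so the extra iterations are cheap)
  # muffle glm.fit's boundary warnings: separation is detected and reported
  # explicitly below, with the converged flag cleared
  fit <- withCallingHandlers(
    glm(form, data = dat, family = binomial(),
      control = glm.control(epsilon = 1e-12, maxit = 100)
    ),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
        conditionMessage(w)
      )) {
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  separated <- any(abs(beta[-1]) > 15)
  if (separated) {
    warning("possible separation: a coefficient exceeds 15 in absolute value",
      call. = FALSE
    )
  }
  keep <- names(beta) != "(Intercept)"
  term_names <- gsub("`", "", names(beta)[keep])
  terms <- tibble(
    term = term_names,
    estimate = unname(beta[keep]),
    odds_ratio = exp(unname(beta[keep])),
    ci_low = exp(unname(beta[keep] - 1.96 * se[keep])),
    ci_high = exp(unname(beta[keep] + 1.96 * se[keep])),
    significant = exp(unname(beta[keep] - 1.96 * se[keep])) > 1 |
      exp(unname(beta[keep] + 1.96 * se[keep])) < 1
  )
  structure(
    list(
      terms = terms,
      intercept = unname(beta[["(Intercept)"]]),
      log_likelihood = as.numeric(logLik(fit)),
      converged = fit$converged && !separated,
      separated = separated,
      auc = roc_auc(fit$fitted.values, y),
      n_used = nrow(dat),
      fitted = unname(fit$fitted.values),
      outcome = y
    ),
    class = "faers_logit"
  )
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)` where `R1` is the midrank sum of
#' the positive class; midranks give the standard tie correction, so
#' constant scores yield exactly 0.5.
#'
#' @param scores numeric predicted scores or probabilities.
#' @param outcomes binary outcomes (0/1 or logical), both classes present.
#' @return the AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, outcomes) {
  y <- as.integer(outcomes)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("ROC-AUC undefined: only one outcome class present", call. = FALSE)
  }
  r <- rank(scores) # midranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Univariate-to-multivariate pipeline for one stratum
#'
#' Composes the published workflow for the full table or one gender stratum:
#' detect per-drug signals, extract candidate drugs by the stratum's
#' thresholds, build a case-level design matrix (drug exposure indicators
#' plus age, weight and — in the combined stratum only — gender coded
#' male = 1, female = 0), screen collinearity, fit the logistic risk model
#' and compute the in-sample ROC-AUC. The report is sorted by descending
#' odds ratio with a `*` marking covariates whose 95% CI excludes 1.
#'
#' When no drug meets the candidate thresholds the model is fitted on the
#' patient covariates alone and the result notes the empty candidate set.
#'
#' @param analysis the analysis tibble.
#' @param stratum `"all"`, `"male"` or `"female"`.
#' @param criteria a [candidate_criteria()]; defaults to
#'   [default_candidate_criteria()] for the stratum.
#' @param event_pt Preferred Term of interest.
#' @return a list of class `"stratum_report"`: `stratum`, `criteria`,
#'   `signals`, `candidates`, `collinearity`, `fit`, `report` (tibble with
#'   `term`, `odds_ratio`, `ci_low`, `ci_high`, `star`), `auc`, `n_used`.
#' @export
run_stratum <- function(analysis, stratum = c("all", "male", "female"),
                        criteria = NULL, event_pt = "Hiccups") {
  stratum <- match.arg(stratum)
  tbl <- switch(stratum,
    all = analysis,
    male = analysis[analysis$gender == "male", , drop = FALSE],
    female = analysis[analysis$gender == "female", , drop = FALSE]
  )
  if (!nrow(tbl)) {
    stop(sprintf("stratum '%s': analysis table is empty", stratum), call. = FALSE)
  }
  criteria <- criteria %||% default_candidate_criteria(stratum)
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stratum '%s', stage %s: %s", stratum, stage, conditionMessage(e)),
        call. = FALSE
      )
    })
  }
  signals <- step("signal detection", detect_signals(tbl, event_pt = event_pt))
  cands <- step("candidate extraction", select_candidates(signals, criteria))
  cases <- step("case table", case_table(tbl))
  if (stratum == "all") {
    cases <- cases[cases$gender %in% c("male", "female"), , drop = FALSE]
  }

  design <- cases[c("case_id", "is_event", "age_years", "weight_kg")]
  patient_covs <- c("age_years", "weight_kg")
  if (stratum == "all") {
    design$gender_male <- as.integer(cases$gender == "male")
    patient_covs <- c("gender_male", patient_covs)
  }
  exposed <- tbl %>%
    filter(drug_name %in% cands$drug_name) %>%
    distinct(case_id, drug_name)
  for (d in cands$drug_name) {
    design[[d]] <- as.integer(
      design$case_id %in% exposed$case_id[exposed$drug_name == d]
    )
  }
  covariates <- c(cands$drug_name, patient_covs)
  collinearity <- if (length(covariates) >= 2) {
    step("collinearity screen", screen_collinearity(design[covariates]))
  } else {
    NULL
  }
  design$is_event <- as.integer(design$is_event)
  fit <- step("logistic fit", fit_logistic(
    design, outcome = "is_event", covariates = covariates
  ))
  report <- fit$terms %>%
    transmute(
      term = term, odds_ratio = odds_ratio,
      ci_low = ci_low, ci_high = ci_high,
      star = ifelse(significant, "*", "")
    ) %>%
    arrange(desc(odds_ratio), term)
  structure(
    list(
      stratum = stratum, criteria = criteria, signals = signals,
      candidates = cands, collinearity = collinearity, fit = fit,
      report = report, auc = fit$auc, n_used = fit$n_used
    ),
    class = "stratum_report"
  )
}
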