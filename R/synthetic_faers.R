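#' Configure the synthetic spontaneous-report generator
#'
#' Builds and validates the configuration for [generate_faers()]. The
#' generator emulates the relational structure of FAERS quarterly extracts:
#' one DEMO row per report, one or more DRUG rows per report with role codes
#' (PS/SS/C/I), THER rows carrying therapy start/end dates of variable
#' precision, REAC rows with MedDRA Preferred Term strings, and INDI rows with
#' indications. Drug-event associations are planted on the odds scale: for
#' reports exposed to a planted drug the event odds are the background odds
#' multiplied by the target reporting odds ratio, so the planted truth is an
#' exact odds ratio rather than an approximation.
#'
#' @param n_cases number of cases (one report per case) to generate.
#' @param drugs named numeric vector of marginal exposure probabilities, one
#'   per drug name.
#' @param events named numeric vector of background reporting probabilities,
#'   one per MedDRA Preferred Term.
#' @param planted_effects `NULL`, or a data frame with columns `drug`, `event`
#'   and `ror` (target reporting odds ratio, strictly positive) planting an
#'   association between a configured drug and event.
#' @param male_fraction probability that a report's patient is male.
#' @param age_mean,age_sd age distribution (years; normal, truncated to
#'   0.05-105).
#' @param weight_mean,weight_sd weight distribution (kg; normal, truncated to
#'   2-250).
#' @param missingness named numeric vector of missingness rates in `[0, 1]`
#'   for the demographic fields `gender`, `age`, `weight`, `country`.
#' @param duplicate_rate fraction of rows duplicated verbatim in each of the
#'   DRUG, REAC, THER and INDI tables, in `[0, 1)`.
#' @param partial_date_rate fraction of dates truncated to month or year
#'   precision (split evenly), in `[0, 1)`.
#' @param outside_window_rate fraction of event dates placed strictly outside
#'   the therapy window (half before the start, half after the end), in
#'   `[0, 1)`.
#' @param therapy_start_range length-2 character vector of ISO dates bounding
#'   the uniform therapy start distribution.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return a validated list of class `"faers_sim_config"`.
#' @seealso [generate_faers()], [write_faers()]
#' @export
faers_sim_config <- function(n_cases = 10000,
                             drugs = c(
                               DRUGX = 0.05, DRUGY = 0.005, DRUGZ = 0.003,
                               NICOTINE = 0.002, DEXAMETHASONE = 0.003
                             ),
                             events = c(
                               Hiccups = 0.001, Nausea = 0.05,
                               Headache = 0.05, Diarrhoea = 0.04,
                               Rash = 0.03
                             ),
                             planted_effects = NULL,
                             male_fraction = 0.40,
                             age_mean = 55, age_sd = 20,
                             weight_mean = 73, weight_sd = 18,
                             missingness = c(
                               gender = 0.045, age = 0.15,
                               weight = 0.62, country = 0.01
                             ),
                             duplicate_rate = 0.05,
                             partial_date_rate = 0.10,
                             outside_window_rate = 0.30,
                             therapy_start_range = c("2004-01-01", "2019-12-31"),
                             seed = 1L) {
  config <- list(
    n_cases = n_cases, drugs = drugs, events = events,
    planted_effects = planted_effects, male_fraction = male_fraction,
    age_mean = age_mean, age_sd = age_sd,
    weight_mean = weight_mean, weight_sd = weight_sd,
    missingness = missingness, duplicate_rate = duplicate_rate,
    partial_date_rate = partial_date_rate,
    outside_window_rate = outside_window_rate,
    therapy_start_range = therapy_start_range, seed = seed
  )
  class(config) <- "faers_sim_config"
  validate_faers_sim_config(config)
}

validate_faers_sim_config <- function(config) {
  bad <- function(field, why) {
    stop(sprintf("invalid generator configuration: field '%s' %s", field, why),
      call. = FALSE
    )
  }
  cfg <- unclass(config)
  if (!is.numeric(cfg$n_cases) || length(cfg$n_cases) != 1 ||
    is.na(cfg$n_cases) || cfg$n_cases < 1 || cfg$n_cases != floor(cfg$n_cases)) {
    bad("n_cases", "must be a positive integer")
  }
  for (field in c("drugs", "events")) {
    p <- cfg[[field]]
    if (!is.numeric(p) || is.null(names(p)) || any(!nzchar(names(p)))) {
      bad(field, "must be a named numeric vector of probabilities")
    }
    if (anyDuplicated(names(p))) bad(field, "has duplicated names")
    if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
      bad(field, "has probabilities outside [0, 1]")
    }
  }
  pe <- cfg$planted_effects
  if (!is.null(pe)) {
    pe <- as.data.frame(pe, stringsAsFactors = FALSE)
    if (!all(c("drug", "event", "ror") %in% names(pe))) {
      bad("planted_effects", "needs columns drug, event, ror")
    }
    if (!all(pe$drug %in% names(cfg$drugs))) {
      bad("planted_effects", "names a drug absent from 'drugs'")
    }
    if (!all(pe$event %in% names(cfg$events))) {
      bad("planted_effects", "names an event absent from 'events'")
    }
    if (any(!is.finite(pe$ror)) || any(pe$ror <= 0)) {
      bad("planted_effects", "target RORs must be strictly positive")
    }
    if (anyDuplicated(pe[c("drug", "event")])) {
      bad("planted_effects", "has duplicated (drug, event) pairs")
    }
    config$planted_effects <- pe
  }
  if (!is.numeric(cfg$male_fraction) || cfg$male_fraction < 0 ||
    cfg$male_fraction > 1) {
    bad("male_fraction", "must be a probability in [0, 1]")
  }
  if (!is.numeric(cfg$age_sd) || cfg$age_sd <= 0) bad("age_sd", "must be > 0")
  if (!is.numeric(cfg$weight_sd) || cfg$weight_sd <= 0) {
    bad("weight_sd", "must be > 0")
  }
  miss <- cfg$missingness
  need <- c("gender", "age", "weight", "country")
  if (!is.numeric(miss) || !all(need %in% names(miss))) {
    bad("missingness", "must name rates for gender, age, weight, country")
  }
  if (any(miss < 0) || any(miss > 1)) {
    bad("missingness", "has rates outside [0, 1]")
  }
  for (field in c("duplicate_rate", "partial_date_rate", "outside_window_rate")) {
    r <- cfg[[field]]
    if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r >= 1) {
      bad(field, "must lie in [0, 1)")
    }
  }
  rng <- suppressWarnings(as.Date(cfg$therapy_start_range))
  if (length(rng) != 2 || any(is.na(rng)) || rng[1] > rng[2]) {
    bad("therapy_start_range", "must be two ordered ISO dates")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    bad("seed", "must be a single integer")
  }
  config
}

#' Generate a synthetic FAERS-dialect dataset with known ground truth
#'
#' Draws `n_cases` reports under the configured marginals and planted
#' drug-event odds ratios, and returns the five relational tables together
#' with a ground-truth record: the planted ROR for every (drug, event) pair
#' (1 where nothing was planted), the number of duplicate rows injected into
#' each table, and a per-report flag saying whether the event date was
#' generated inside the therapy window.
#'
#' Every report has at least one drug row and at least one reaction row; all
#' drug rows of a report share the report's therapy window. A report exposed
#' to a planted drug carries that drug with role code PS; other role codes
#' are drawn at random, since all four roles count as suspect downstream.
#'
#' @param config a [faers_sim_config()] object.
#' @return a list of class `"faers_dataset"` with elements `bundle` (named
#'   list of tibbles `demo`, `drug`, `reac`, `ther`, `indi`), `truth`
#'   (`planted_ror`, `duplicates`, `inside_window`) and `config`.
#' @examples
#' ds <- generate_faers(faers_sim_config(n_cases = 200, seed = 42))
#' nrow(ds$bundle$demo)
#' @export
generate_faers <- function(config) {
  config <- validate_faers_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_cases)
  drug_names <- names(config$drugs)
  event_names <- names(config$events)
  d <- length(drug_names)
  e <- length(event_names)

  primaryid <- sprintf("%09d", 100000000L + seq_len(n))
  caseid <- sprintf("%08d", 50000000L + seq_len(n))

  ## ---- demographics -------------------------------------------------------
  male <- rbinom(n, 1L, config$male_fraction) == 1L
  sex <- ifelse(male, "M", "F")
  age_years <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 0.05), 105)
  age_cod <- sample(c("YR", "DEC", "MON", "WK", "DY"), n,
    replace = TRUE, prob = c(0.95, 0.01, 0.02, 0.01, 0.01)
  )
  age_val <- round(age_years * c(
    YR = 1, DEC = 0.1, MON = 12, WK = 365.25 / 7, DY = 365.25
  )[age_cod], 1)
  weight <- round(pmin(pmax(rnorm(n, config$weight_mean, config$weight_sd), 2), 250), 1)
  countries <- c(
    US = 0.55, FR = 0.072, JP = 0.071, GB = 0.05, DE = 0.04, CA = 0.035,
    IT = 0.03, ES = 0.025, AU = 0.02, BR = 0.107
  )
  country <- sample(names(countries), n, replace = TRUE, prob = countries)

  miss <- config$missingness
  sex[runif(n) < miss[["gender"]]] <- "UNK"
  age_chr <- as.character(age_val)
  age_missing <- runif(n) < miss[["age"]]
  age_chr[age_missing] <- ""
  age_cod[age_missing] <- ""
  wt_chr <- as.character(weight)
  wt_missing <- runif(n) < miss[["weight"]]
  wt_chr[wt_missing] <- ""
  wt_cod <- ifelse(wt_missing, "", "KG")
  country[runif(n) < miss[["country"]]] <- ""

  ## ---- drug exposures -----------------------------------------------------
  # tracked drugs keep their configured marginals exactly; reports that draw
  # none of them carry one filler drug from a background formulary instead,
  # so filler drugs are true nulls (never co-exposed with a planted drug) and
  # tracked-drug cross-tabulations are not contaminated by forced exposure
  expo <- vapply(config$drugs, function(p) rbinom(n, 1L, p), integer(n))
  expo <- matrix(expo, nrow = n, dimnames = list(NULL, drug_names))
  none <- rowSums(expo) == 0L
  formulary <- c(
    "PARACETAMOL", "OMEPRAZOLE", "LISINOPRIL",
    "METFORMIN", "AMLODIPINE", "ASPIRIN"
  )
  filler <- rep(NA_character_, n)
  filler[none] <- sample(formulary, sum(none), replace = TRUE)

  ## ---- events: planted odds-ratio mechanism -------------------------------
  q <- config$events
  odds <- matrix(rep(q / (1 - q), each = n), nrow = n,
    dimnames = list(NULL, event_names)
  )
  planted_drugs <- character(0)
  pe <- config$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    planted_drugs <- unique(pe$drug)
    for (i in seq_len(nrow(pe))) {
      exposed <- expo[, pe$drug[i]] == 1L
      odds[exposed, pe$event[i]] <- odds[exposed, pe$event[i]] * pe$ror[i]
    }
  }
  pmat <- odds / (1 + odds)
  evmat <- matrix(rbinom(n * e, 1L, as.vector(pmat)), nrow = n,
    dimnames = list(NULL, event_names)
  )
  no_event <- rowSums(evmat) == 0L
  if (any(no_event)) {
    # guarantee >= 1 reaction per report; fall back to a background event not
    # involved in any planted effect so planted odds stay untouched
    pool <- if (!is.null(pe) && nrow(pe)) setdiff(event_names, unique(pe$event)) else event_names
    if (!length(pool) || sum(q[pool]) == 0) pool <- event_names
    forced <- sample(match(pool, event_names), sum(no_event),
      replace = TRUE, prob = q[pool] / sum(q[pool])
    )
    evmat[cbind(which(no_event), forced)] <- 1L
  }

  ## ---- therapy window and event date --------------------------------------
  rng <- as.integer(as.Date(config$therapy_start_range))
  start <- as.Date(rng[1] + floor(runif(n) * (rng[2] - rng[1] + 1L)),
    origin = "1970-01-01"
  )
  duration <- pmax(0L, as.integer(round(rlnorm(n, log(30), 1))))
  end <- start + duration
  inside <- runif(n) >= config$outside_window_rate
  before <- !inside & runif(n) < 0.5
  event_date <- start # placeholder, overwritten below
  event_date[inside] <- start[inside] +
    floor(runif(sum(inside)) * (duration[inside] + 1L))
  event_date[!inside & before] <- start[!inside & before] - 1L -
    floor(runif(sum(!inside & before)) * 180)
  after <- !inside & !before
  event_date[after] <- end[after] + 1L + floor(runif(sum(after)) * 180)

  truncate_dates <- function(dates) {
    x <- format(dates, "%Y%m%d")
    pick <- runif(length(x)) < config$partial_date_rate
    to_month <- pick & runif(length(x)) < 0.5
    to_year <- pick & !to_month
    x[to_month] <- substr(x[to_month], 1L, 6L)
    x[to_year] <- substr(x[to_year], 1L, 4L)
    x
  }
  event_dt <- truncate_dates(event_date)
  start_dt <- truncate_dates(start)
  end_dt <- truncate_dates(end)

  ## ---- assemble tables ----------------------------------------------------
  demo <- tibble(
    primaryid = primaryid, caseid = caseid, event_dt = event_dt,
    age = age_chr, age_cod = age_cod, sex = sex,
    wt = wt_chr, wt_cod = wt_cod, occr_country = country
  )

  idx <- which(expo == 1L, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  rid <- c(idx[ord, 1L], which(none))
  dname <- c(drug_names[idx[ord, 2L]], filler[none])
  reord <- order(rid)
  rid <- rid[reord]
  dname <- dname[reord]
  drug_seq <- stats::ave(rid, rid, FUN = seq_along)
  role <- sample(c("PS", "SS", "C", "I"), length(rid),
    replace = TRUE, prob = c(0.4, 0.2, 0.3, 0.1)
  )
  role[dname %in% planted_drugs] <- "PS"
  drug <- tibble(
    primaryid = primaryid[rid], drug_seq = drug_seq,
    role_cod = role, drugname = dname
  )

  ther <- tibble(
    primaryid = primaryid[rid], dsg_drug_seq = drug_seq,
    start_dt = start_dt[rid], end_dt = end_dt[rid]
  )

  indications <- c(
    "Hypertension", "Diabetes mellitus", "Depression",
    "Smoking cessation therapy", "Neoplasm malignant", "Pain"
  )
  indi <- tibble(
    primaryid = primaryid[rid], indi_drug_seq = drug_seq,
    indi_pt = sample(indications, length(rid), replace = TRUE)
  )

  eidx <- which(evmat == 1L, arr.ind = TRUE)
  eord <- order(eidx[, 1L], eidx[, 2L])
  reac <- tibble(
    primaryid = primaryid[eidx[eord, 1L]],
    pt = event_names[eidx[eord, 2L]]
  )

  inject_duplicates <- function(tbl) {
    m <- floor(config$duplicate_rate * nrow(tbl))
    if (m > 0) {
      tbl <- bind_rows(tbl, tbl[sample.int(nrow(tbl), m, replace = TRUE), ])
    }
    list(tbl = tbl, k = as.integer(m))
  }
  dup_drug <- inject_duplicates(drug)
  dup_reac <- inject_duplicates(reac)
  dup_ther <- inject_duplicates(ther)
  dup_indi <- inject_duplicates(indi)

  grid <- expand.grid(
    drug = drug_names, event = event_names,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$ror <- 1
  if (!is.null(pe) && nrow(pe)) {
    key <- match(
      paste(grid$drug, grid$event, sep = "\r"),
      paste(pe$drug, pe$event, sep = "\r")
    )
    grid$ror[!is.na(key)] <- pe$ror[key[!is.na(key)]]
  }

  structure(
    list(
      bundle = list(
        demo = demo, drug = dup_drug$tbl, reac = dup_reac$tbl,
        ther = dup_ther$tbl, indi = dup_indi$tbl
      ),
      truth = list(
        planted_ror = as_tibble(grid),
        duplicates = c(
          DRUG = dup_drug$k, REAC = dup_reac$k,
          THER = dup_ther$k, INDI = dup_indi$k
        ),
        inside_window = tibble(primaryid = primaryid, inside = inside)
      ),
      config = config
    ),
    class = "faers_dataset"
  )
}

#' Write a synthetic dataset as FAERS-dialect ASCII files
#'
#' Writes the five tables as `"$"`-delimited text with a single header row,
#' named `DEMO<quarter>.txt`, `DRUG<quarter>.txt`, `REAC<quarter>.txt`,
#' `THER<quarter>.txt` and `INDI<quarter>.txt`, plus a key-value ground-truth
#' sidecar `GROUND_TRUTH<quarter>.txt`. Output is byte-identical for a given
#' configuration and seed.
#'
#' @param dataset a `"faers_dataset"` from [generate_faers()].
#' @param dir output directory (created if needed).
#' @param quarter quarter suffix used in the file names.
#' @return invisibly, a named character vector of the file paths written.
#' @export
write_faers <- function(dataset, dir, quarter = "20Q1") {
  stopifnot(inherits(dataset, "faers_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    demo = file.path(dir, paste0("DEMO", quarter, ".txt")),
    drug = file.path(dir, paste0("DRUG", quarter, ".txt")),
    reac = file.path(dir, paste0("REAC", quarter, ".txt")),
    ther = file.path(dir, paste0("THER", quarter, ".txt")),
    indi = file.path(dir, paste0("INDI", quarter, ".txt"))
  )
  for (nm in names(paths)) {
    write.table(dataset$bundle[[nm]], paths[[nm]],
      sep = "$", quote = FALSE, row.names = FALSE, na = ""
    )
  }
  truth_path <- file.path(dir, paste0("GROUND_TRUTH", quarter, ".txt"))
  truth <- dataset$truth
  lines <- c(
    sprintf(
      "planted_ror.%s.%s=%s",
      truth$planted_ror$drug, truth$planted_ror$event,
      formatC(truth$planted_ror$ror, digits = 15, format = "g")
    ),
    sprintf("duplicates.%s=%d", names(truth$duplicates), truth$duplicates),
    sprintf(
      "inside_window.%s=%d",
      truth$inside_window$primaryid, as.integer(truth$inside_window$inside)
    )
  )
  writeLines(lines, truth_path)
  invisible(c(paths, ground_truth = truth_path))
}

#' Read a ground-truth sidecar written by [write_faers()]
#'
#' @param path path to a `GROUND_TRUTH*.txt` file.
#' @return a list with elements `planted_ror`, `duplicates`, `inside_window`
#'   mirroring the `truth` element of a `"faers_dataset"`.
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  key <- sub("=.*$", "", lines)
  val <- sub("^[^=]*=", "", lines)
  planted <- grepl("^planted_ror\\.", key)
  parts <- strsplit(sub("^planted_ror\\.", "", key[planted]), ".", fixed = TRUE)
  dup <- grepl("^duplicates\\.", key)
  inw <- grepl("^inside_window\\.", key)
  list(
    planted_ror = tibble(
      drug = vapply(parts, `[`, "", 1L),
      event = vapply(parts, `[`, "", 2L),
      ror = as.numeric(val[planted])
    ),
    duplicates = setNames(
      as.integer(val[dup]), sub("^duplicates\\.", "", key[dup])
    ),
    inside_window = tibble(
      primaryid = sub("^inside_window\\.", "", key[inw]),
      inside = val[inw] == "1"
    )
  )
}

#' Simulate a cohort from a logistic outcome model
#'
#' Companion generator for coefficient-recovery checks of the risk model:
#' draws a binary drug exposure and a continuous age covariate and simulates
#' the outcome from `logit P(y = 1) = intercept + beta_drug * drug +
#' beta_age * age_years`.
#'
#' @param n cohort size.
#' @param intercept intercept on the logit scale.
#' @param beta_drug log odds ratio of the binary exposure.
#' @param beta_age log odds ratio per year of age.
#' @param p_drug exposure prevalence.
#' @param age_mean,age_sd age distribution (years).
#' @param seed optional integer seed.
#' @return a tibble with columns `drug`, `age_years`, `outcome`.
#' @export
simulate_logistic_cohort <- function(n, intercept = -5, beta_drug = log(8),
                                     beta_age = 0.01, p_drug = 0.1,
                                     age_mean = 55, age_sd = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  drug <- rbinom(n, 1L, p_drug)
  age_years <- pmin(pmax(rnorm(n, age_mean, age_sd), 0), 105)
  p <- plogis(intercept + beta_drug * drug + beta_age * age_years)
  tibble(
    drug = drug, age_years = age_years,
    outcome = rbinom(n, 1L, p)
  )
}
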