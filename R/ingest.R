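#' Parse one FAERS-dialect quarterly table
#'
#' Reads a `"$"`-delimited ASCII file with a single header row and returns
#' typed records. Demographic numerics that fail to parse become missing
#' values, not errors; malformed or impossible dates become missing dates with
#' the row retained. Only the absence of a mandatory key column is an error.
#'
#' @param path path to the file.
#' @param kind one of `"demo"`, `"drug"`, `"reac"`, `"ther"`, `"indi"`.
#' @return a tibble of typed records. Dates are canonical partial-date digit
#'   strings (see [pd_parse()]); drug names are normalised (trimmed,
#'   uppercased, internal whitespace collapsed).
#' @export
parse_faers_table <- function(path, kind = c("demo", "drug", "reac", "ther", "indi")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- read.delim(path,
    sep = "$", colClasses = "character", quote = "",
    check.names = FALSE, na.strings = NULL, stringsAsFactors = FALSE
  )
  names(raw) <- tolower(names(raw))
  keys <- switch(kind,
    demo = c("primaryid", "caseid"),
    drug = c("primaryid", "drug_seq", "drugname", "role_cod"),
    reac = c("primaryid", "pt"),
    ther = c("primaryid", "dsg_drug_seq"),
    indi = c("primaryid", "indi_drug_seq")
  )
  missing_keys <- setdiff(keys, names(raw))
  if (length(missing_keys)) {
    stop(sprintf(
      "format error in %s (header line 1): missing mandatory column '%s'",
      basename(path), missing_keys[1]
    ), call. = FALSE)
  }
  col <- function(nm) if (nm %in% names(raw)) raw[[nm]] else rep(NA_character_, nrow(raw))
  num <- function(x) suppressWarnings(as.numeric(x))
  switch(kind,
    demo = tibble(
      primaryid = raw$primaryid,
      caseid = raw$caseid,
      event_dt = pd_parse(col("event_dt")),
      age = num(col("age")),
      age_cod = toupper(trimws(col("age_cod"))),
      sex = toupper(trimws(col("sex"))),
      wt = num(col("wt")),
      wt_cod = toupper(trimws(col("wt_cod"))),
      occr_country = trimws(col("occr_country"))
    ),
    drug = tibble(
      primaryid = raw$primaryid,
      drug_seq = suppressWarnings(as.integer(raw$drug_seq)),
      role_cod = ifelse(
        toupper(trimws(raw$role_cod)) %in% c("PS", "SS", "C", "I"),
        toupper(trimws(raw$role_cod)), NA_character_
      ),
      drugname = normalize_drug_name(raw$drugname)
    ),
    reac = tibble(primaryid = raw$primaryid, pt = trimws(raw$pt)),
    ther = tibble(
      primaryid = raw$primaryid,
      dsg_drug_seq = suppressWarnings(as.integer(raw$dsg_drug_seq)),
      start_dt = pd_parse(col("start_dt")),
      end_dt = pd_parse(col("end_dt"))
    ),
    indi = tibble(
      primaryid = raw$primaryid,
      indi_drug_seq = suppressWarnings(as.integer(raw$indi_drug_seq)),
      indi_pt = trimws(raw$indi_pt)
    )
  )
}

#' Normalise a verbatim drug name
#'
#' Trims, collapses internal whitespace and uppercases. No ingredient or
#' brand-name harmonisation is attempted: names are matched verbatim.
#' @param x character vector of drug names.
#' @return normalised character vector.
#' @export
normalize_drug_name <- function(x) {
  toupper(gsub("[[:space:]]+", " ", trimws(x)))
}

#' Read a directory of FAERS-dialect quarterly tables
#'
#' Locates `DEMO*`, `DRUG*`, `REAC*`, `THER*` and `INDI*` files (one or more
#' quarters each) and parses and row-binds them per table kind.
#'
#' @param dir directory containing the tables.
#' @return a named list of tibbles: `demo`, `drug`, `reac`, `ther`, `indi`.
#' @export
read_faers_bundle <- function(dir) {
  find <- function(prefix) {
    files <- sort(list.files(dir,
      pattern = paste0("^", prefix, ".*\\.(txt|TXT)$"), full.names = TRUE
    ))
    if (!length(files)) {
      stop(sprintf("no %s* table found in %s", prefix, dir), call. = FALSE)
    }
    files
  }
  kinds <- c(demo = "DEMO", drug = "DRUG", reac = "REAC", ther = "THER", indi = "INDI")
  lapply(kinds, function(prefix) {
    kind <- names(kinds)[kinds == prefix]
    bind_rows(lapply(find(prefix), parse_faers_table, kind = kind))
  })
}

#' Remove exactly duplicated rows from a table
#'
#' Keeps one copy of each fully identical row and reports how many rows were
#' dropped. Applying it twice is a no-op.
#'
#' @param records a data frame of parsed records.
#' @return a list with `records` (deduplicated tibble) and `n_removed`.
#' @export
deduplicate <- function(records) {
  dup <- duplicated(records)
  list(
    records = as_tibble(records[!dup, , drop = FALSE]),
    n_removed = sum(dup)
  )
}

#' Join the five tables into (report, drug, reaction) rows
#'
#' Attaches therapy dates to each drug row (matched on report id and drug
#' sequence number; unmatched pairs keep missing dates), attaches
#' demographics by report id, then expands by the report's reactions so that
#' the result has one row per (report, drug, reaction).
#'
#' @param bundle a named list of deduplicated tables as from
#'   [read_faers_bundle()].
#' @return a tibble of joined rows.
#' @export
join_bundle <- function(bundle) {
  ther <- bundle$ther %>%
    arrange(primaryid, dsg_drug_seq, start_dt, end_dt) %>%
    distinct(primaryid, dsg_drug_seq, .keep_all = TRUE)
  bundle$drug %>%
    left_join(ther, by = c("primaryid", drug_seq = "dsg_drug_seq")) %>%
    inner_join(bundle$demo, by = "primaryid") %>%
    inner_join(bundle$reac, by = "primaryid", relationship = "many-to-many")
}

#' Keep rows whose reaction date lies inside the therapy window
#'
#' Implements conservative containment under partial date precision: the
#' therapy start is expanded to its earliest completion, the therapy end to
#' its latest completion, and a row is retained only when the *entire*
#' completion range of the event date lies inside that widened window. Rows
#' with a missing event or start date are removed. When the end date is
#' missing the event must lie on or after the earliest start completion and
#' its latest completion must not exceed `horizon` (by default the latest
#' date observed anywhere in the input, i.e. the end of the last loaded
#' quarter).
#'
#' @param joined a tibble from [join_bundle()] with `event_dt`, `start_dt`,
#'   `end_dt` partial-date columns.
#' @param horizon optional [Date]; upper bound used when `end_dt` is missing.
#' @return a list with `rows` (retained tibble), `n_input`,
#'   `n_removed_missing` (missing event or start date) and
#'   `n_removed_window` (dated rows failing containment).
#' @export
filter_temporal <- function(joined, horizon = NULL) {
  ev_lo <- pd_earliest(joined$event_dt)
  ev_hi <- pd_latest(joined$event_dt)
  s_lo <- pd_earliest(joined$start_dt)
  e_hi <- pd_latest(joined$end_dt)
  if (is.null(horizon)) {
    pool <- c(ev_hi, e_hi, pd_latest(joined$start_dt))
    horizon <- if (all(is.na(pool))) as.Date("2999-12-31") else max(pool, na.rm = TRUE)
  }
  missing <- is.na(joined$event_dt) | is.na(joined$start_dt)
  has_end <- !is.na(joined$end_dt)
  keep <- !missing & ifelse(
    has_end,
    ev_lo >= s_lo & ev_hi <= e_hi,
    ev_lo >= s_lo & ev_hi <= horizon
  )
  keep[is.na(keep)] <- FALSE
  list(
    rows = joined[keep, , drop = FALSE],
    n_input = nrow(joined),
    n_removed_missing = sum(missing),
    n_removed_window = sum(!keep & !missing)
  )
}

#' Clean demographic fields
#'
#' Converts reported age to years using the age unit code (`YR`, `DEC`,
#' `MON`, `WK`, `DY`, `HR`; a present age with a blank unit is taken as
#' years), converts weight to kilograms (`LBS` supported), masks outliers
#' (age above 119 years, weight above 400 kg; the boundary values themselves
#' are retained) and normalises gender to `male` / `female` / `unknown`.
#' Outlying values are set missing but the row is kept, so drug counts are
#' unaffected. The operation is idempotent.
#'
#' @param rows a tibble with `age`, `age_cod`, `wt`, `wt_cod`, `sex` columns
#'   (or already-cleaned `age_years`, `weight_kg`, `gender` columns).
#' @param max_age_years,max_weight_kg exclusive outlier bounds.
#' @return the tibble with `gender`, `age_years`, `weight_kg`, `country`
#'   columns set.
#' @export
clean_demographics <- function(rows, max_age_years = 119, max_weight_kg = 400) {
  unit <- c(
    YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
    DY = 1 / 365.25, HR = 1 / 8766
  )
  if ("age" %in% names(rows)) {
    f <- unname(unit[rows$age_cod])
    f[is.na(f)] <- 1 # blank or unrecognised unit: assume years
    age_years <- suppressWarnings(as.numeric(rows$age)) * f
  } else {
    age_years <- rows$age_years
  }
  age_years[!is.na(age_years) & (age_years > max_age_years | age_years < 0)] <- NA_real_

  if ("wt" %in% names(rows)) {
    w <- suppressWarnings(as.numeric(rows$wt))
    lbs <- !is.na(rows$wt_cod) & rows$wt_cod == "LBS"
    w[lbs] <- w[lbs] * 0.453592
    weight_kg <- w
  } else {
    weight_kg <- rows$weight_kg
  }
  weight_kg[!is.na(weight_kg) & (weight_kg > max_weight_kg | weight_kg <= 0)] <- NA_real_

  src <- if ("sex" %in% names(rows)) rows$sex else rows$gender
  gender <- dplyr::case_match(
    toupper(trimws(src)),
    c("M", "MALE") ~ "male",
    c("F", "FEMALE") ~ "female",
    .default = "unknown"
  )
  gender[is.na(gender)] <- "unknown"

  rows$gender <- gender
  rows$age_years <- age_years
  rows$weight_kg <- weight_kg
  if ("occr_country" %in% names(rows)) {
    rows$country <- ifelse(
      is.na(rows$occr_country) | !nzchar(rows$occr_country),
      NA_character_, rows$occr_country
    )
  }
  rows
}

#' Build the analysis table
#'
#' Reduces cleaned, temporally filtered rows to the analysis unit — one row
#' per (report, drug, reaction) triple — flags the event of interest by
#' case-insensitive exact Preferred Term match, sorts deterministically, and
#' summarises counts at the row, report and case level, including the
#' per-country tally of event reports.
#'
#' @param rows cleaned joined rows.
#' @param event_pt the MedDRA Preferred Term of interest (default
#'   `"Hiccups"`).
#' @return a list with `table` (the analysis tibble) and `summary` (a list of
#'   counts: `n_rows`, `n_reports`, `n_cases`, `n_event_rows`,
#'   `n_event_reports`, `n_event_cases`, `event_reports_by_country`).
#' @export
build_analysis_table <- function(rows, event_pt = "Hiccups") {
  tbl <- rows %>%
    transmute(
      report_id = primaryid, case_id = caseid,
      drug_name = drugname, pt = pt,
      is_event = toupper(pt) == toupper(event_pt),
      gender = gender, age_years = age_years,
      weight_kg = weight_kg, country = country
    ) %>%
    distinct(report_id, drug_name, pt, .keep_all = TRUE) %>%
    arrange(report_id, drug_name, pt)
  ev <- tbl[tbl$is_event, , drop = FALSE]
  by_country <- ev %>%
    distinct(report_id, country) %>%
    filter(!is.na(country)) %>%
    count(country, name = "n_reports") %>%
    arrange(desc(n_reports), country)
  list(
    table = tbl,
    summary = list(
      n_rows = nrow(tbl),
      n_reports = n_distinct(tbl$report_id),
      n_cases = n_distinct(tbl$case_id),
      n_event_rows = nrow(ev),
      n_event_reports = n_distinct(ev$report_id),
      n_event_cases = n_distinct(ev$case_id),
      event_reports_by_country = by_country
    )
  )
}

#' Split the analysis table by gender
#'
#' Rows with unknown gender appear in neither stratum, so the two tables are
#' disjoint and their union is no larger than the input.
#'
#' @param analysis the analysis tibble.
#' @return a list with elements `male` and `female`.
#' @export
stratify_gender <- function(analysis) {
  list(
    male = analysis[analysis$gender == "male", , drop = FALSE],
    female = analysis[analysis$gender == "female", , drop = FALSE]
  )
}

#' Run the full cleaning pipeline on a raw table bundle
#'
#' Deduplicates the DRUG, INDI, REAC and THER tables, joins, applies the
#' therapy-window filter, cleans demographics and builds the analysis table,
#' recording row counts at every stage.
#'
#' @param bundle raw parsed tables from [read_faers_bundle()] or a generated
#'   dataset's `bundle`.
#' @param event_pt Preferred Term of interest.
#' @param horizon optional [Date] passed to [filter_temporal()].
#' @return a list with `analysis` (tibble), `summary` (from
#'   [build_analysis_table()]), `stages` (named numeric vector of row counts
#'   through the pipeline) and `dedup_removed` (named vector per table).
#' @export
ingest_faers <- function(bundle, event_pt = "Hiccups", horizon = NULL) {
  dd <- lapply(bundle[c("drug", "reac", "ther", "indi")], deduplicate)
  clean_bundle <- list(
    demo = as_tibble(bundle$demo),
    drug = dd$drug$records, reac = dd$reac$records,
    ther = dd$ther$records, indi = dd$indi$records
  )
  joined <- join_bundle(clean_bundle)
  flt <- filter_temporal(joined, horizon = horizon)
  cleaned <- clean_demographics(flt$rows)
  built <- build_analysis_table(cleaned, event_pt = event_pt)
  list(
    analysis = built$table,
    summary = built$summary,
    stages = c(
      raw_drug_rows = nrow(bundle$drug),
      raw_reac_rows = nrow(bundle$reac),
      dedup_drug_rows = nrow(clean_bundle$drug),
      dedup_reac_rows = nrow(clean_bundle$reac),
      joined_rows = nrow(joined),
      temporal_rows = nrow(flt$rows),
      analysis_rows = nrow(built$table)
    ),
    dedup_removed = c(
      DRUG = dd$drug$n_removed, REAC = dd$reac$n_removed,
      THER = dd$ther$n_removed, INDI = dd$indi$n_removed
    ),
    temporal = flt[c("n_input", "n_removed_missing", "n_removed_window")]
  )
}
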