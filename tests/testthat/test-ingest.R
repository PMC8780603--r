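test_that("tables parse with typed fields and graceful degradation", {
  path <- write_faers_file(c(
    "primaryid$caseid$event_dt$age$age_cod$sex$wt$wt_cod$occr_country",
    "100$c1$20190415$73$YR$M$73.1$KG$US",
    "101$c2$201904$abc$YR$F$$KG$JP",
    "102$c3$20190431$24$MON$UNK$350$LBS$"
  ))
  demo <- parse_faers_table(path, "demo")
  expect_equal(demo$wt[1], 73.1)
  expect_true(is.na(demo$age[2])) # unparseable numeric -> missing, row kept
  expect_equal(demo$event_dt[2], "201904")
  expect_true(is.na(demo$event_dt[3])) # invalid day -> missing date, row kept
  expect_equal(nrow(demo), 3)

  drug_path <- write_faers_file(c(
    "primaryid$drug_seq$role_cod$drugname",
    "100$1$ps$ nicotine  patch ",
    "100$2$XX$ASPIRIN"
  ), "DRUG20Q1.txt")
  drug <- parse_faers_table(drug_path, "drug")
  expect_equal(drug$drugname[1], "NICOTINE PATCH")
  expect_equal(drug$role_cod, c("PS", NA))
})

test_that("a missing mandatory key column is a format error naming it", {
  path <- write_faers_file(c("caseid$event_dt", "c1$20190415"))
  expect_error(parse_faers_table(path, "demo"), "primaryid")
  reac_path <- write_faers_file(c("primaryid$reaction", "1$Hiccups"), "REAC.txt")
  expect_error(parse_faers_table(reac_path, "reac"), "'pt'")
})

test_that("deduplication keeps one copy of each row, reports the count, and is idempotent", {
  base <- tibble::tibble(a = c(1:7, 1, 1), b = letters[c(1:7, 1, 1)])
  dd <- deduplicate(base)
  expect_equal(nrow(dd$records), 7)
  expect_equal(dd$n_removed, 2)
  dd2 <- deduplicate(dd$records)
  expect_equal(dd2$n_removed, 0)
  expect_identical(dd2$records, dd$records)

  empty <- deduplicate(base[0, ])
  expect_equal(nrow(empty$records), 0)
  expect_equal(empty$n_removed, 0)

  ds <- generate_faers(small_sim(n_cases = 1500, seed = 4, duplicate_rate = 0.1))
  ing <- ingest_faers(ds$bundle)
  expect_equal(ing$dedup_removed, ds$truth$duplicates[c("DRUG", "REAC", "THER", "INDI")])
})

test_that("joining expands to one row per (report, drug, reaction)", {
  bundle <- list(
    demo = tibble::tibble(
      primaryid = "1", caseid = "c1", event_dt = "20190415",
      age = "60", age_cod = "YR", sex = "M", wt = "80", wt_cod = "KG",
      occr_country = "US"
    ),
    drug = tibble::tibble(
      primaryid = "1", drug_seq = 1:2, role_cod = c("PS", "C"),
      drugname = c("DRUGA", "DRUGB")
    ),
    reac = tibble::tibble(primaryid = "1", pt = c("Hiccups", "Nausea", "Rash")),
    ther = tibble::tibble(
      primaryid = "1", dsg_drug_seq = 1L,
      start_dt = "20190401", end_dt = "20190501"
    ),
    indi = tibble::tibble(primaryid = "1", indi_drug_seq = 1L, indi_pt = "Pain")
  )
  joined <- join_bundle(bundle)
  expect_equal(nrow(joined), 6) # 2 drugs x 3 reactions
  # the drug without a therapy row keeps missing dates
  expect_true(all(is.na(joined$start_dt[joined$drugname == "DRUGB"])))
  expect_true(all(joined$start_dt[joined$drugname == "DRUGA"] == "20190401"))
})

test_that("generator joined row count equals sum over reports of drugs x reactions", {
  ds <- generate_faers(small_sim(n_cases = 800, seed = 6, duplicate_rate = 0))
  joined <- join_bundle(ds$bundle)
  nd <- table(ds$bundle$drug$primaryid)
  nr <- table(ds$bundle$reac$primaryid)
  expect_equal(nrow(joined), sum(as.numeric(nd) * as.numeric(nr[names(nd)])))
})

test_that("temporal filter applies conservative containment for partial dates", {
  rows <- tibble::tibble(
    event_dt = c(
      "20190415", "20190702", "201904", "2019", NA, "20190415", "20190415",
      "20190420"
    ),
    start_dt = c(
      "20190301", "20190301", "20190301", "20190301", "20190301", NA,
      "20190301", "20190301"
    ),
    end_dt = c(
      "20190601", "20190601", "20190601", "20190601", "20190601", "20190601",
      NA, "201905"
    )
  )
  flt <- filter_temporal(rows, horizon = as.Date("2020-03-31"))
  # row 1: exact containment -> kept; row 2: after end -> dropped
  # row 3: April fully inside March..June -> kept
  # row 4: year-precision event spans outside -> dropped
  # row 5: missing event -> dropped; row 6: missing start -> dropped
  # row 7: missing end: event >= start and <= horizon -> kept
  # row 8: end known to month; latest completion 2019-05-31 >= event -> kept
  kept <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)
  expect_identical(flt$rows, rows[kept, ])
  expect_equal(nrow(flt$rows), 4)
  expect_equal(flt$n_removed_missing, 2)
  expect_equal(flt$n_removed_window, 2)
})

test_that("temporal filter removes exactly the reports generated outside the window", {
  cfg <- small_sim(
    n_cases = 8000, seed = 12, partial_date_rate = 0,
    outside_window_rate = 0.3, duplicate_rate = 0
  )
  ds <- generate_faers(cfg)
  joined <- join_bundle(ds$bundle)
  flt <- filter_temporal(joined)
  truth <- ds$truth$inside_window
  inside_ids <- truth$primaryid[truth$inside]
  # with exact dates, conservative containment reduces to the exact rule
  expect_setequal(unique(flt$rows$primaryid), inside_ids)
  frac <- 1 - length(inside_ids) / nrow(truth)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(truth)))
})

test_that("demographic cleaning converts units, masks outliers, and is idempotent", {
  rows <- tibble::tibble(
    age = c("120", "119", "24", "36", "48", "50"),
    age_cod = c("YR", "YR", "MON", "DEC", "WK", ""),
    wt = c("400", "400.5", "70", "154", "", "60"),
    wt_cod = c("KG", "KG", "KG", "LBS", "", "KG"),
    sex = c("M", "F", "UNK", "M", "male", "x")
  )
  out <- clean_demographics(rows)
  expect_true(is.na(out$age_years[1])) # strictly greater than 119 -> masked
  expect_equal(out$age_years[2], 119) # boundary retained
  expect_equal(out$age_years[3], 2) # 24 months
  expect_true(is.na(out$age_years[4])) # 36 decades = 360 years -> outlier
  expect_equal(out$weight_kg[1], 400) # boundary retained
  expect_true(is.na(out$weight_kg[2])) # heavier than 400 kg -> masked
  expect_equal(out$weight_kg[4], 154 * 0.453592, tolerance = 1e-10)
  expect_equal(out$gender, c("male", "female", "unknown", "male", "male", "unknown"))

  again <- clean_demographics(out[setdiff(names(out), c("age", "age_cod", "wt", "wt_cod", "sex"))])
  expect_equal(again$age_years, out$age_years)
  expect_equal(again$weight_kg, out$weight_kg)
  expect_equal(again$gender, out$gender)
})

test_that("analysis table counts rows, cases and events with case-insensitive PT match", {
  rows <- tibble::tibble(
    primaryid = c("1", "1", "2", "2", "3"),
    caseid = c("c1", "c1", "c2", "c2", "c3"),
    drugname = c("DRUGA", "DRUGA", "DRUGA", "DRUGB", "DRUGC"),
    pt = c("HICCUPS", "HICCUPS", "Nausea", "Nausea", "hiccups"),
    gender = "male", age_years = 50, weight_kg = 70, country = c("US", "US", "JP", "JP", "US")
  )
  built <- build_analysis_table(rows)
  # duplicate (report, drug, pt) triple collapses to one row
  expect_equal(built$summary$n_rows, 4)
  expect_equal(built$summary$n_cases, 3)
  expect_equal(built$summary$n_event_rows, 2) # both case variants counted
  expect_equal(built$summary$n_event_cases, 2)
  tally <- built$summary$event_reports_by_country
  expect_equal(tally$n_reports[tally$country == "US"], 2)

  none <- build_analysis_table(rows[rows$pt == "Nausea", ])
  expect_equal(none$summary$n_event_rows, 0)
  expect_equal(none$summary$n_event_cases, 0)
})

test_that("gender stratification is disjoint and drops unknowns", {
  tbl <- toy_analysis() # genders: 3 male, 2 female, 1 unknown
  strata <- stratify_gender(tbl)
  expect_equal(nrow(strata$male), 3)
  expect_equal(nrow(strata$female), 2)
  expect_equal(length(intersect(strata$male$report_id, strata$female$report_id)), 0)
  expect_lte(nrow(strata$male) + nrow(strata$female), nrow(tbl))

  empty <- stratify_gender(tbl[0, ])
  expect_equal(nrow(empty$male), 0)
  expect_equal(nrow(empty$female), 0)
})

test_that("the pipeline is invariant to input row order", {
  ds <- generate_faers(small_sim(n_cases = 600, seed = 8))
  ing1 <- ingest_faers(ds$bundle)
  shuffled <- lapply(ds$bundle, function(tbl) {
    tbl[sample.int(nrow(tbl)), , drop = FALSE]
  })
  ing2 <- ingest_faers(shuffled)
  expect_equal(ing1$analysis, ing2$analysis)
  expect_equal(ing1$summary, ing2$summary)
})
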