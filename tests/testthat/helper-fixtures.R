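# shared fixtures and independent oracles, all built in code

# six-row toy analysis table: DRUGA has 2 event rows and 1 other,
# DRUGB has 0 event rows and 3 others
toy_analysis <- function() {
  tibble::tibble(
    report_id = sprintf("R%02d", 1:6),
    case_id = sprintf("C%02d", 1:6),
    drug_name = c("DRUGA", "DRUGA", "DRUGA", "DRUGB", "DRUGB", "DRUGB"),
    pt = c("Hiccups", "Hiccups", "Nausea", "Nausea", "Rash", "Headache"),
    is_event = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    gender = c("male", "male", "female", "female", "male", "unknown"),
    age_years = c(60, 55, 40, 35, 70, NA),
    weight_kg = c(80, 75, 60, 55, 90, NA),
    country = "US"
  )
}

# case-level table from per-cell counts (gender x event), plus unknown-gender
# cases, for gender_association tests
make_case_counts <- function(male_ev, male_non, female_ev, female_non,
                             unk_ev = 0, unk_non = 0) {
  tibble::tibble(
    gender = rep(
      c("male", "male", "female", "female", "unknown", "unknown"),
      c(male_ev, male_non, female_ev, female_non, unk_ev, unk_non)
    ),
    is_event = rep(
      c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
      c(male_ev, male_non, female_ev, female_non, unk_ev, unk_non)
    )
  )
}

# independent Fisher oracle: full hypergeometric enumeration from log
# binomial coefficients, no dhyper
oracle_fisher <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12
  r2 <- n21 + n22
  c1 <- n11 + n21
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2) {
    return(1)
  }
  ks <- max(0, c1 - r2):min(r1, c1)
  p <- exp(lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(r1 + r2, c1))
  min(1, sum(p[p <= p[ks == n11] * (1 + 1e-12)]))
}

# direct 2x2 arithmetic on an analysis table using base R only
oracle_counts <- function(analysis, drug) {
  dr <- analysis$drug_name == drug
  ev <- analysis$is_event
  c(
    n11 = sum(dr & ev), n12 = sum(dr & !ev),
    n21 = sum(!dr & ev), n22 = sum(!dr & !ev)
  )
}

# small generator configuration with overridable pieces
small_sim <- function(n_cases = 2000, seed = 1, ...) {
  faers_sim_config(n_cases = n_cases, seed = seed, ...)
}

# write a hand-rolled "$"-delimited table to a temp file
write_faers_file <- function(lines, name = "DEMO20Q1.txt") {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}
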