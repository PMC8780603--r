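test_that("cross-tabulation partitions the analysis table", {
  tbl <- toy_analysis()
  a <- cross_tabulate(tbl, "DRUGA")
  expect_equal(unlist(a), c(n11 = 2, n12 = 1, n21 = 0, n22 = 3))
  b <- cross_tabulate(tbl, "DRUGB")
  expect_equal(unlist(b), c(n11 = 0, n12 = 3, n21 = 2, n22 = 1))
  absent <- cross_tabulate(tbl, "NOSUCHDRUG")
  expect_equal(absent$n11 + absent$n12, 0)
  for (d in unique(tbl$drug_name)) {
    ct <- cross_tabulate(tbl, d)
    expect_equal(ct$n11 + ct$n12 + ct$n21 + ct$n22, nrow(tbl))
    expect_equal(ct$n11 + ct$n21, sum(tbl$is_event))
  }
  expect_error(cross_tabulate(tbl[0, ], "DRUGA"), "empty")
})

test_that("ROR and Wald CI follow the cross-tabulation formula", {
  est <- compute_ror(contingency_table(622, 544997, 193, 803041))
  expect_equal(est$ror, 4.749, tolerance = 1e-3)
  expect_equal(est$ror, 622 * 803041 / (544997 * 193), tolerance = 1e-12)
  se <- sqrt(1 / 622 + 1 / 544997 + 1 / 193 + 1 / 803041)
  expect_equal(est$ci_low, exp(log(est$ror) - 1.96 * se), tolerance = 1e-12)

  flat <- compute_ror(contingency_table(5, 5, 5, 5))
  expect_equal(flat$ror, 1)
  expect_true(flat$ci_low < 1 && flat$ci_high > 1)

  degen <- compute_ror(contingency_table(3, 0, 10, 10))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$ror) && is.na(degen$ci_low) && is.na(degen$ci_high))
})

test_that("Fisher exact p-values match closed forms and full enumeration", {
  expect_equal(fisher_exact(contingency_table(5, 5, 5, 5)), 1)
  # support probabilities {1, 9, 9, 1}/20 -> two-sided mass 2/20
  expect_equal(fisher_exact(contingency_table(3, 0, 0, 3)), 0.1, tolerance = 1e-12)
  expect_lt(fisher_exact(contingency_table(622, 544997, 193, 803041)), 0.001)

  # oracle equivalence on every 2x2 table with total <= 40
  worst <- 0
  for (n in 1:40) {
    for (r1 in 0:n) {
      for (c1 in 0:n) {
        lo <- max(0, c1 - (n - r1))
        hi <- min(r1, c1)
        if (lo > hi) next
        for (x in lo:hi) {
          ct <- list(n11 = x, n12 = r1 - x, n21 = c1 - x, n22 = n - r1 - c1 + x)
          class(ct) <- "faers_ct"
          worst <- max(worst, abs(
            fisher_exact(ct) - oracle_fisher(ct$n11, ct$n12, ct$n21, ct$n22)
          ))
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("Fisher p agrees with the reference implementation on random tables", {
  set.seed(42)
  for (i in 1:60) {
    ct <- contingency_table(
      rpois(1, 20), rpois(1, 300), rpois(1, 40), rpois(1, 600)
    )
    m <- matrix(c(ct$n11, ct$n21, ct$n12, ct$n22), 2)
    expect_equal(
      fisher_exact(ct), stats::fisher.test(m)$p.value,
      tolerance = 1e-7
    )
  }
})

test_that("column reciprocity and cell scaling behave as expected", {
  set.seed(7)
  for (i in 1:50) {
    cells <- rpois(4, c(15, 200, 30, 400)) + 1
    ct <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    swapped <- contingency_table(cells[2], cells[1], cells[4], cells[3])
    expect_equal(compute_ror(swapped)$ror, 1 / compute_ror(ct)$ror,
      tolerance = 1e-12
    )
    expect_equal(fisher_exact(swapped), fisher_exact(ct), tolerance = 1e-12)
    est <- compute_ror(ct)
    if (est$degenerate || est$ror <= 1) next
    expect_equal(is.na(est$ror), FALSE)
  }
  # monotone significance: scaling all cells by k >= 2 never increases p
  base <- c(2, 8, 5, 5)
  p_prev <- Inf
  for (k in 1:5) {
    p_k <- fisher_exact(contingency_table(
      base[1] * k, base[2] * k, base[3] * k, base[4] * k
    ))
    expect_lte(p_k, p_prev + 1e-14)
    p_prev <- p_k
  }
})

test_that("signal flag requires the CI lower bound to exceed unity", {
  set.seed(11)
  for (i in 1:100) {
    cells <- rpois(4, c(5, 60, 10, 120))
    if (sum(cells) == 0) next
    ct <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    est <- compute_ror(ct)
    is_sig <- !est$degenerate && est$ci_low > 1
    if (is_sig) expect_gt(est$ror, 1)
  }
})

test_that("candidate extraction applies strict thresholds and ROR ordering", {
  signals <- tibble::tibble(
    drug_name = c("A", "B", "C", "D", "E"),
    ror = c(2, 2, 0.5, 4, NA),
    p_value = c(1e-5, 1e-5, 1e-9, 1e-9, 1e-9),
    n_drug_reports = c(6000, 5000, 9000, 7000, 8000),
    degenerate = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  crit <- candidate_criteria(5000, 0.001, 1)
  picked <- select_candidates(signals, crit)
  # B rejected at the boundary (strictly more than 5000), C below min ROR,
  # E degenerate; ordering by descending ROR
  expect_equal(picked$drug_name, c("D", "A"))

  expect_error(candidate_criteria(-1, 0.01), "min_reports")
  expect_error(candidate_criteria(10, 0), "max_p")
  crit_all <- default_candidate_criteria("all")
  expect_equal(crit_all$min_reports, 5000)
  expect_equal(default_candidate_criteria("male")$min_reports, 3000)
  expect_equal(default_candidate_criteria("female")$max_p, 0.05)
})

test_that("volcano coordinates are ln ROR against -log10 p with a p=0.05 baseline", {
  tbl <- dplyr::bind_rows(
    toy_analysis(),
    tibble::tibble(
      report_id = sprintf("R%02d", 7:10), case_id = sprintf("C%02d", 7:10),
      drug_name = c("DRUGA", "DRUGB", "DRUGB", "DRUGB"),
      pt = c("Rash", "Hiccups", "Hiccups", "Nausea"),
      is_event = c(FALSE, TRUE, TRUE, FALSE),
      gender = "male", age_years = 50, weight_kg = 70, country = "US"
    )
  )
  signals <- detect_signals(tbl)
  expect_true(any(!signals$degenerate))
  coords <- volcano_coordinates(signals)
  expect_equal(coords$ln_ror, log(signals$ror[!signals$degenerate]))
  one <- tibble::tibble(
    drug_name = "X", ror = 1, p_value = 0.05, ln_ror = log(1),
    neg_log10_p = -log10(0.05), n_drug_reports = 10, degenerate = FALSE
  )
  expect_equal(volcano_coordinates(one)$ln_ror, 0)
  expect_equal(volcano_coordinates(one)$neg_log10_p, 1.301, tolerance = 1e-3)

  plt <- volcano_plot(signals)
  expect_s3_class(plt, "ggplot")
  layer_classes <- vapply(plt$layers, function(l) class(l$geom)[1], "")
  expect_true("GeomHline" %in% layer_classes)

  all_degen <- tibble::tibble(
    drug_name = "X", ror = NA_real_, p_value = 1, ln_ror = NA_real_,
    neg_log10_p = 0, n_drug_reports = 3, degenerate = TRUE
  )
  expect_error(volcano_plot(all_degen), "no defined signals")
})
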