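test_that("percentages recompute printed-table style with half-up rounding", {
  # published-table worked examples: counts -> printed percentage
  expect_equal(percent(19306, 35158), 54.91)
  expect_equal(percent(26204, 32203), 81.37)
  expect_equal(percent(18229, 32203), 56.61)
  expect_equal(percent(9560, 35158), 27.19)
  expect_equal(percent(0, 100), 0)
  # half-up at the boundary (banker's rounding would give 0.12)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(percent(1, 16), 6.25)
  expect_error(percent(1, 0), class = "adcvigil_input_error")
})

test_that("Cramer's V follows the chi-square oracle and its invariances", {
  expect_equal(cramers_v(matrix(c(10, 0, 0, 10), 2))$v, 1)
  ind <- cramers_v(matrix(c(5, 5, 5, 5), 2))
  expect_equal(ind$v, 0)
  expect_equal(ind$p, 1)

  # 3x2 gender-style table checked against an independent Pearson oracle
  tab <- matrix(c(8210, 1350, 18229, 1077, 5764, 528), ncol = 2,
                byrow = TRUE)
  got <- cramers_v(tab)
  orc <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(got$chi2, unname(orc$statistic))
  expect_equal(got$v, sqrt(unname(orc$statistic) / sum(tab)),
               tolerance = 1e-12)
  expect_lt(got$p, 0.001)

  # range and permutation invariance
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(rpois(6, 40), 2)
    v1 <- cramers_v(m)$v
    expect_gte(v1, 0); expect_lte(v1, 1)
    expect_equal(cramers_v(m[, c(2, 1, 3)])$v, v1)
    expect_equal(cramers_v(m[c(2, 1), ])$v, v1)
  }
  # degenerate margins are undefined-marked
  expect_true(is.na(cramers_v(matrix(c(5, 5, 0, 0), 2))$v))
})

test_that("onset time is date arithmetic with exclusion accounting", {
  rows <- dplyr::bind_rows(
    report_rows("c1", "belantamab mafodotin", "pt_01",
                therapy_start_date = as.Date("2020-01-01"),
                event_date = as.Date("2020-01-24")),
    report_rows("c2", "belantamab mafodotin", "pt_01",
                therapy_start_date = as.Date("2020-05-10"),
                event_date = as.Date("2020-05-01")),    # implausible
    report_rows("c3", "belantamab mafodotin", "pt_01",
                therapy_start_date = as.Date(NA)),      # missing
    report_rows("c4", "aspirin", "pt_01")
  )
  ann <- annotate_components(rows)
  ot <- onset_times(ann, "belantamab mafodotin")
  expect_equal(ot$n_eligible, 3)
  expect_equal(ot$n_used, 1)
  expect_equal(ot$n_excluded_missing, 1)
  expect_equal(ot$n_excluded_implausible, 1)
  expect_equal(ot$median, 23)
  expect_equal(ot$n_used + ot$n_excluded_missing +
                 ot$n_excluded_implausible, ot$n_eligible)
})

test_that("onset quantiles interpolate order statistics", {
  dates <- as.Date("2020-01-01")
  rows <- report_rows(sprintf("c%d", 1:5), "belantamab mafodotin", "pt_01",
                      therapy_start_date = dates,
                      event_date = dates + c(1, 2, 3, 4, 100))
  ot <- onset_times(annotate_components(rows), "belantamab mafodotin")
  expect_equal(c(ot$q1, ot$median, ot$q3), c(2, 3, 4))
  expect_true(ot$min <= ot$q1 && ot$q1 <= ot$median &&
                ot$median <= ot$q3 && ot$q3 <= ot$max)
  # empty stratum: undefined-marked summary
  empty <- onset_times(annotate_components(rows), "no such drug")
  expect_equal(empty$n_used, 0)
  expect_true(is.na(empty$median))
})

test_that("the continuous comparison gates on Shapiro-Wilk normality", {
  # identical tiny samples skip the gate: Mann-Whitney, p = 1
  got <- group_compare_continuous(c(1, 2), c(1, 2))
  expect_equal(got$test, "mann_whitney")
  expect_equal(got$p, 1)
  # complete separation below the gate size: U = 0 for x
  sep <- group_compare_continuous(c(1, 2), c(4, 5))
  expect_equal(sep$test, "mann_whitney")
  expect_equal(unname(sep$statistic), 0)
  # rank-enumeration oracle on clearly non-normal samples
  x <- c(0.1, 0.2, 0.3, 0.4, 50, 0.15, 0.22, 60)
  y <- c(0.25, 0.35, 0.5, 45, 0.12, 0.18, 70, 0.3)
  u_oracle <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  got2 <- group_compare_continuous(x, y)
  expect_equal(got2$test, "mann_whitney")
  expect_equal(unname(got2$statistic), u_oracle)
  # two large normal samples take the t branch
  withr::with_seed(5, {
    a <- rnorm(500); b <- rnorm(500, 0.2)
  })
  expect_equal(group_compare_continuous(a, b)$test, "t")
  # skewed samples stay nonparametric
  withr::with_seed(6, {
    a2 <- rexp(300); b2 <- rexp(300)
  })
  expect_equal(group_compare_continuous(a2, b2)$test, "mann_whitney")
  expect_error(group_compare_continuous(numeric(0), 1:3),
               class = "adcvigil_input_error")
})

test_that("descriptive tallies count both reporting units and age bins", {
  rows <- dplyr::bind_rows(
    report_rows(sprintf("f%d", 1:6), "aspirin", "pt_01", sex = "female"),
    report_rows(sprintf("m%d", 1:4), "aspirin",
                rep(c("pt_01", "pt_02"), 2), sex = "male")
  )
  tl <- descriptive_tallies(rows)
  expect_equal(tl$totals$n_reports, 10)
  # f1..f6 have one PT each; m1..m4 alternate two PTs -> 6 + 4 = 10 pairs
  expect_equal(tl$totals$n_pt_events, 10)
  fem <- tl$by_sex$pct[tl$by_sex$level == "female"]
  expect_equal(fem, 60)
  # age-bin edges: 64.5 is 18-64; 65 is 65-85; 85 in; 85.5 above; NA unspecified
  bins <- adcvigil:::age_bin(c(17.9, 18, 64.5, 65, 85, 85.5, NA))
  expect_equal(bins, c("<18", "18-64", "18-64", "65-85", "65-85", ">85",
                       "unspecified"))
})

test_that("baseline tables are internally consistent per stratum", {
  sim <- null_sim(1200, seed = 61)
  ann <- annotate_components(dedup_reports(sim$reports))
  bt <- baseline_table(ann, "antibody")
  # counts within each variable and stratum sum to the stratum total
  sums <- bt$counts %>%
    dplyr::group_by(variable, stratum) %>%
    dplyr::summarise(total = sum(count), n_stratum = n_stratum[1],
                     .groups = "drop") %>%
    dplyr::filter(variable != "outcome")   # outcomes: one per case here
  expect_true(all(sums$total == sums$n_stratum))
  # percentages recompute from their own counts
  recomputed <- percent(bt$counts$count, bt$counts$n_stratum)
  expect_equal(bt$counts$pct, recomputed)
  # association statistics are defined and in range
  expect_true(all(bt$stats$v >= 0 & bt$stats$v <= 1, na.rm = TRUE))
  # continuous summaries respect quantile ordering
  cont <- bt$continuous
  ok <- !is.na(cont$ot_median)
  expect_true(all(cont$ot_q1[ok] <= cont$ot_median[ok] &
                    cont$ot_median[ok] <= cont$ot_q3[ok]))
})
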