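#' Round half-up
#'
#' Decimal rounding where exact halves round away from zero (the style of
#' printed percentage tables), unlike base `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count, rounded half-up
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param dp Decimal places (default 2, the printed table style).
#' @return `100 * numerator / denominator` rounded half-up to `dp` places.
#' @examples
#' percent(19306, 35158)  # 54.91
#' @export
percent <- function(numerator, denominator, dp = 2) {
  if (any(denominator <= 0)) {
    abort("percent() requires a positive denominator",
          class = "adcvigil_input_error")
  }
  round_half_up(100 * numerator / denominator, dp)
}

#' Cramer's V association measure for an r x c contingency table
#'
#' `V = sqrt(chi2 / (N * min(r - 1, c - 1)))` with the Pearson chi-square
#' (no continuity correction); the p-value comes from the chi-square
#' distribution with `(r-1)(c-1)` degrees of freedom. Degenerate margins
#' (a zero row or column, or a single row/column) give `NA`.
#'
#' @param tab Matrix (or table) of non-negative counts.
#' @return One-row tibble with `v`, `chi2`, `df`, `p`, `n`.
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  tab2 <- tab[keep_r, keep_c, drop = FALSE]
  if (n == 0 || nrow(tab2) < 2 || ncol(tab2) < 2) {
    return(tibble(v = NA_real_, chi2 = NA_real_, df = NA_integer_,
                  p = NA_real_, n = n))
  }
  ct <- suppressWarnings(chisq.test(tab2, correct = FALSE))
  v <- sqrt(unname(ct$statistic) /
              (n * (min(nrow(tab2), ncol(tab2)) - 1)))
  tibble(v = v, chi2 = unname(ct$statistic),
         df = as.integer(unname(ct$parameter)), p = unname(ct$p.value),
         n = n)
}

#' Onset-time summary for one stratum
#'
#' Onset time (OT) is the interval in days from the earliest therapy start
#' among the stratum's suspect drugs to the earliest recorded event date of
#' the case. Cases with either date missing are excluded and counted in
#' `n_excluded_missing`; negative intervals (event before therapy) are
#' implausible and counted in `n_excluded_implausible`. Quantiles use
#' linear interpolation between order statistics.
#'
#' @param reports Deduplicated, annotated report tibble.
#' @param member_drugs Normalized drug names defining the stratum.
#' @return One-row tibble `n_eligible`, `n_used`, `n_excluded_missing`,
#'   `n_excluded_implausible`, `median`, `q1`, `q3`, `min`, `max` (days).
#' @export
onset_times <- function(reports, member_drugs) {
  per_case <- reports %>%
    dplyr::filter(.data$drug_role %in% SUSPECT_ROLES,
                  .data$drug_norm %in% member_drugs) %>%
    group_by(.data$case_id) %>%
    summarise(
      start = if (all(is.na(.data$therapy_start_date))) as.Date(NA) else
        min(.data$therapy_start_date, na.rm = TRUE),
      event = if (all(is.na(.data$event_date))) as.Date(NA) else
        min(.data$event_date, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(ot = as.numeric(.data$event - .data$start))
  n_eligible <- nrow(per_case)
  missing <- is.na(per_case$ot)
  implausible <- !missing & per_case$ot < 0
  used <- per_case$ot[!missing & !implausible]
  qs <- if (length(used) > 0) {
    quantile(used, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  } else {
    c(NA_real_, NA_real_, NA_real_)
  }
  tibble(
    n_eligible = n_eligible, n_used = length(used),
    n_excluded_missing = sum(missing),
    n_excluded_implausible = sum(implausible),
    median = qs[2], q1 = qs[1], q3 = qs[3],
    min = if (length(used)) min(used) else NA_real_,
    max = if (length(used)) max(used) else NA_real_
  )
}

#' Compare a continuous variable between two groups
#'
#' A Shapiro-Wilk gate at alpha = 0.05 on each sample (subsampled to at
#' most 5000 values for the gate) selects the test: both samples normal
#' gives Welch's two-sample t-test, otherwise the Mann-Whitney U test with
#' normal approximation and tie correction. Samples smaller than 3 skip
#' the gate and use Mann-Whitney.
#'
#' @param x,y Numeric vectors (non-empty; `NA` dropped).
#' @return One-row tibble `test`, `statistic`, `p`.
#' @export
group_compare_continuous <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be non-empty", class = "adcvigil_input_error")
  }
  gate <- function(v) {
    if (length(v) < 3) return(FALSE)
    v_sub <- if (length(v) > 5000) {
      v[seq(1, length(v), length.out = 5000)]
    } else {
      v
    }
    if (length(unique(v_sub)) < 3) return(FALSE)
    shapiro.test(v_sub)$p.value > 0.05
  }
  if (gate(x) && gate(y)) {
    ht <- t.test(x, y)
    tibble(test = "t", statistic = unname(ht$statistic),
           p = ht$p.value)
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                       correct = FALSE))
    tibble(test = "mann_whitney", statistic = unname(ht$statistic),
           p = ht$p.value)
  }
}

age_bin_levels <- c("<18", "18-64", "65-85", ">85", "unspecified")

# <18: age < 18; 18-64: 18 <= age < 65; 65-85: 65 <= age <= 85; >85: above
age_bin <- function(age) {
  dplyr::case_when(
    is.na(age) ~ "unspecified",
    age < 18 ~ "<18",
    age < 65 ~ "18-64",
    age <= 85 ~ "65-85",
    TRUE ~ ">85"
  )
}

#' Report- and event-level descriptive tallies
#'
#' Counts deduplicated reports by sex, age bin, seriousness, outcome,
#' reporter type, country and receipt year, plus the two reporting units
#' that are easy to conflate: `n_reports` (deduplicated case reports) and
#' `n_pt_events` (distinct report x PT pairs, the "PT-level AE" unit).
#'
#' @param reports Deduplicated report tibble.
#' @return A list of tibbles: `totals`, `by_sex`, `by_age`, `by_serious`,
#'   `by_outcome`, `by_reporter`, `by_country`, `by_year`.
#' @export
descriptive_tallies <- function(reports) {
  cases <- reports %>%
    group_by(.data$case_id) %>%
    slice(1) %>%
    ungroup()
  n_reports <- nrow(cases)
  tally_by <- function(v) {
    tibble(level = v) %>%
      count(.data$level, name = "count") %>%
      mutate(pct = percent(.data$count, n_reports))
  }
  outcome_cases <- distinct(
    dplyr::filter(reports, !is.na(.data$outcome)),
    .data$case_id, .data$outcome
  )
  list(
    totals = tibble(
      n_reports = n_reports,
      n_pt_events = nrow(distinct(reports, .data$case_id, .data$event_pt))
    ),
    by_sex = tally_by(cases$sex),
    by_age = tally_by(factor(age_bin(cases$age_years),
                             levels = age_bin_levels)) %>%
      mutate(level = as.character(.data$level)),
    by_serious = tally_by(if_else(cases$serious, "serious", "non_serious")),
    by_outcome = outcome_cases %>%
      count(.data$outcome, name = "count") %>%
      rename(level = "outcome") %>%
      mutate(pct = percent(.data$count, n_reports)),
    by_reporter = tally_by(cases$reporter_type),
    by_country = tally_by(dplyr::coalesce(cases$country, "unspecified")),
    by_year = tally_by(format(cases$receipt_date, "%Y"))
  )
}

#' Stratified baseline characteristics table
#'
#' For each stratum of one kind, tabulates sex, age bins, seriousness and
#' outcomes as `count (pct)` per stratum with a per-variable Cramer's V
#' association statistic, plus continuous age and onset-time summaries as
#' median (Q1, Q3). Percentages recompute from counts at two decimals.
#'
#' @param reports Deduplicated, annotated report tibble.
#' @param kind Stratification kind.
#' @param registry Component registry.
#' @return A list with `counts` (long tibble: `variable`, `level`,
#'   `stratum`, `count`, `pct`), `stats` (per-variable Cramer's V), and
#'   `continuous` (per-stratum age and onset-time summaries).
#' @export
baseline_table <- function(reports, kind, registry = adc_registry()) {
  strata <- build_strata(registry, kind)
  case_level <- reports %>%
    group_by(.data$case_id) %>%
    slice(1) %>%
    ungroup()
  assign_stratum <- function(member_drugs) {
    case_level$case_id %in% exposed_case_ids(reports, member_drugs)
  }
  long <- purrr::pmap(strata, function(kind, stratum, member_drugs) {
    sub <- case_level[assign_stratum(member_drugs), ]
    n_sub <- nrow(sub)
    if (n_sub == 0) return(NULL)
    var_tbl <- function(variable, values) {
      tibble(variable = variable, level = values) %>%
        count(.data$variable, .data$level, name = "count") %>%
        mutate(stratum = stratum, n_stratum = n_sub,
               pct = percent(.data$count, n_sub))
    }
    bind_rows(
      var_tbl("sex", sub$sex),
      var_tbl("age_bin", age_bin(sub$age_years)),
      var_tbl("serious", if_else(sub$serious, "serious", "non_serious")),
      var_tbl("outcome", dplyr::coalesce(sub$outcome, "none_reported"))
    )
  }) %>% bind_rows()

  stats <- long %>%
    group_by(.data$variable) %>%
    dplyr::group_modify(function(df, key) {
      wide <- tidyr::pivot_wider(
        select(df, "level", "stratum", "count"),
        names_from = "stratum", values_from = "count", values_fill = 0L
      )
      cramers_v(as.matrix(wide[, -1, drop = FALSE]))
    }) %>%
    ungroup()

  continuous <- purrr::pmap(strata, function(kind, stratum, member_drugs) {
    sub <- case_level[assign_stratum(member_drugs), ]
    ages <- sub$age_years[!is.na(sub$age_years)]
    aq <- if (length(ages) > 0) {
      quantile(ages, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    } else {
      rep(NA_real_, 3)
    }
    ot <- onset_times(reports, member_drugs)
    tibble(
      stratum = stratum, n_stratum = nrow(sub),
      age_median = aq[2], age_q1 = aq[1], age_q3 = aq[3],
      age_min = if (length(ages)) min(ages) else NA_real_,
      age_max = if (length(ages)) max(ages) else NA_real_,
      ot_median = ot$median, ot_q1 = ot$q1, ot_q3 = ot$q3,
      ot_n_used = ot$n_used,
      ot_n_excluded_missing = ot$n_excluded_missing,
      ot_n_excluded_implausible = ot$n_excluded_implausible
    )
  }) %>% bind_rows()

  list(counts = long, stats = stats, continuous = continuous)
}
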