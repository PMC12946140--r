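# in-code fixture builders shared across test files

# one simplified-dialect row per (case, drug, event); sensible defaults
report_rows <- function(case_id, drug_name, event_pt,
                        version_id = "1",
                        receipt_date = as.Date("2022-01-10"),
                        sex = "female", age_years = 60,
                        reporter_type = "healthcare_professional",
                        serious = TRUE, outcome = "hospitalization",
                        country = "US", drug_role = "primary_suspect",
                        therapy_start_date = as.Date("2021-12-01"),
                        event_date = as.Date("2022-01-01")) {
  tibble::tibble(
    case_id = case_id, version_id = version_id,
    receipt_date = receipt_date, sex = sex, age_years = age_years,
    reporter_type = reporter_type, serious = serious, outcome = outcome,
    country = country, drug_name = drug_name, drug_role = drug_role,
    therapy_start_date = therapy_start_date, event_pt = event_pt,
    event_date = event_date
  )
}

# four-report collection: 2 exposed (one with the event), 2 comparator
tiny_collection <- function(drug = "belantamab mafodotin",
                            other = "aspirin", pt = "pt_01",
                            other_pt = "pt_02") {
  dplyr::bind_rows(
    report_rows("c1", drug, pt),
    report_rows("c2", drug, other_pt),
    report_rows("c3", other, pt),
    report_rows("c4", other, other_pt)
  )
}

annotated_tiny <- function(...) {
  adcvigil::annotate_components(tiny_collection(...))
}

# brute-force O(cases x events) 2x2 recount, independent of the dplyr path
brute_force_cells <- function(reports, member_drugs, event,
                              event_col = "event_pt") {
  suspects <- c("primary_suspect", "secondary_suspect")
  cases <- unique(reports$case_id)
  a <- b <- c <- d <- 0L
  for (cs in cases) {
    sub <- reports[reports$case_id == cs, ]
    exposed <- any(sub$drug_norm %in% member_drugs &
                     sub$drug_role %in% suspects)
    has_event <- any(sub[[event_col]] == event)
    if (exposed && has_event) a <- a + 1L
    else if (exposed) b <- b + 1L
    else if (has_event) c <- c + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c, d = d)
}

# brute-force Benjamini-Hochberg step-up definition
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    q[i] <- min(1, min(p[ord][rank_i:m] * m / (rank_i:m)))
  }
  q
}

# default null simulation used by several files (small, fast)
null_sim <- function(n_cases = 1500, seed = 101) {
  adcvigil::simulate_reports(adcvigil::sim_config(
    n_cases = n_cases, seed = seed
  ))
}
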