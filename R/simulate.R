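#' Configuration for the synthetic report generator
#'
#' Builds a validated configuration for [simulate_reports()]. The defaults
#' emulate the marginal structure of ADC-related spontaneous reports:
#' roughly 55% female reporters, ~80% serious reports, three quarters
#' reported by healthcare professionals, an onset-time median of 26 days,
#' and ~63% of onset dates missing. Effects are planted as multiplicative
#' relative reporting rates (RRR) on (target, PT) pairs, where the target is
#' a single drug or a whole component class.
#'
#' @param n_cases Number of distinct cases to simulate.
#' @param n_background_drugs Number of non-study background drugs.
#' @param n_events Size of the preferred-term vocabulary (`pt_01`, ...).
#' @param background_event_law `"zipf"` (rank-frequency skew with exponent
#'   `zipf_s`) or `"uniform"` background event frequencies.
#' @param zipf_s Zipf exponent (> 0), used when the law is `"zipf"`.
#' @param events_per_case_lambda Mean of the truncated Poisson (minimum 1)
#'   for events listed per case.
#' @param adc_exposure_prob Probability that a case's suspect drug is a
#'   study ADC (uniform over the included registry) rather than background.
#' @param planted_effects Tibble with columns `kind` (one of `drug`,
#'   `antibody`, `linker`, `payload`, `dar`), `target` (label within the
#'   kind), `pt`, `rrr` (>= 1). `NULL` for a null (no-effect) collection.
#' @param duplicate_fraction Fraction of cases re-emitted as an extra,
#'   later case version (removed again by [dedup_reports()]).
#' @param missing_date_fraction Fraction of cases with blanked onset dates.
#' @param implausible_date_fraction Fraction of cases given an event date
#'   before therapy start (excluded by the onset-time rules).
#' @param onset_median_days Target median of the simulated onset-time
#'   distribution (exponential), in days.
#' @param sex_probs,outcome_probs,reporter_probs,country_probs Named
#'   probability vectors for the demographic marginals.
#' @param serious_prob Probability that a report is serious.
#' @param age_mean,age_sd,age_missing_prob Age marginal (years, truncated to
#'   [0.2, 110]) and its missingness rate.
#' @param registry Component registry for study-drug exposure (default:
#'   included ADCs of [adc_registry()]).
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cases = 5000,
                       n_background_drugs = 25,
                       n_events = 30,
                       background_event_law = c("zipf", "uniform"),
                       zipf_s = 1,
                       events_per_case_lambda = 3,
                       adc_exposure_prob = 0.3,
                       planted_effects = NULL,
                       duplicate_fraction = 0.05,
                       missing_date_fraction = 0.63,
                       implausible_date_fraction = 0.02,
                       onset_median_days = 26,
                       sex_probs = c(male = 0.272, female = 0.549,
                                     unspecified = 0.179),
                       serious_prob = 0.794,
                       outcome_probs = c(death = 0.2266, disability = 0.0083,
                                         hospitalization = 0.2174,
                                         life_threatening = 0.0327,
                                         other_serious = 0.5150),
                       reporter_probs = c(healthcare_professional = 0.764,
                                          consumer = 0.18,
                                          unspecified = 0.056),
                       country_probs = c(US = 0.365, JP = 0.14, FR = 0.077,
                                         CA = 0.063, CN = 0.038, DE = 0.08,
                                         GB = 0.08, IT = 0.06, ES = 0.05,
                                         AU = 0.047),
                       age_mean = 57, age_sd = 18, age_missing_prob = 0.467,
                       registry = adc_registry(include_only = TRUE),
                       seed = 1L) {
  background_event_law <- match.arg(background_event_law)
  cfg <- list(
    n_cases = as.integer(n_cases),
    n_background_drugs = as.integer(n_background_drugs),
    n_events = as.integer(n_events),
    background_event_law = background_event_law, zipf_s = zipf_s,
    events_per_case_lambda = events_per_case_lambda,
    adc_exposure_prob = adc_exposure_prob,
    planted_effects = planted_effects,
    duplicate_fraction = duplicate_fraction,
    missing_date_fraction = missing_date_fraction,
    implausible_date_fraction = implausible_date_fraction,
    onset_median_days = onset_median_days,
    sex_probs = sex_probs, serious_prob = serious_prob,
    outcome_probs = outcome_probs, reporter_probs = reporter_probs,
    country_probs = country_probs,
    age_mean = age_mean, age_sd = age_sd,
    age_missing_prob = age_missing_prob,
    registry = registry, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  cfg_err <- function(msg) abort(msg, class = "adcvigil_config_error")
  if (cfg$n_cases < 1 || cfg$n_background_drugs < 1 || cfg$n_events < 1) {
    cfg_err("n_cases, n_background_drugs and n_events must be positive")
  }
  for (fld in c("duplicate_fraction", "missing_date_fraction",
                "implausible_date_fraction")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || v < 0 || v >= 1) {
      cfg_err(paste0(fld, " must lie in [0, 1)"))
    }
  }
  if (cfg$events_per_case_lambda <= 0) {
    cfg_err("events_per_case_lambda must be > 0")
  }
  if (cfg$zipf_s <= 0) cfg_err("zipf_s must be > 0")
  if (cfg$adc_exposure_prob < 0 || cfg$adc_exposure_prob > 1) {
    cfg_err("adc_exposure_prob must lie in [0, 1]")
  }
  pe <- cfg$planted_effects
  if (!is.null(pe) && nrow(pe) > 0) {
    stopifnot(all(c("kind", "target", "pt", "rrr") %in% names(pe)))
    if (any(pe$rrr < 1)) cfg_err("planted rrr values must be >= 1")
    if (!all(pe$kind %in% STRATUM_KINDS)) {
      cfg_err("planted effect kind must be one of drug/antibody/linker/payload/dar")
    }
    vocab <- sprintf("pt_%02d", seq_len(cfg$n_events))
    if (!all(pe$pt %in% vocab)) {
      cfg_err("planted PT outside the event vocabulary (increase n_events)")
    }
    if (cfg$n_events < dplyr::n_distinct(pe$pt)) {
      cfg_err("n_events smaller than the number of distinct planted PTs")
    }
    expanded <- expand_planted_effects(pe, cfg$registry)
    if (nrow(expanded) == 0) {
      cfg_err("planted effects match no registry drug")
    }
  }
  invisible(cfg)
}

# expand component-class targets to their member drugs
expand_planted_effects <- function(pe, registry) {
  if (is.null(pe) || nrow(pe) == 0) {
    return(tibble(drug_name = character(), pt = character(), rrr = numeric()))
  }
  rows <- purrr::pmap(pe, function(kind, target, pt, rrr, ...) {
    drugs <- if (kind == "drug") {
      registry$drug_name[normalize_drug_name(registry$drug_name) ==
                           normalize_drug_name(target)]
    } else {
      col <- c(antibody = "antibody", linker = "linker",
               payload = "payload", dar = "dar_class")[[kind]]
      registry$drug_name[registry[[col]] == target]
    }
    tibble(drug_name = drugs, pt = pt, rrr = rrr)
  })
  out <- bind_rows(rows)
  # a drug hit by several planted effects on the same PT takes the max RRR
  out %>%
    group_by(.data$drug_name, .data$pt) %>%
    summarise(rrr = max(.data$rrr), .groups = "drop")
}

#' Simulate a FAERS-like report collection with known ground truth
#'
#' Each case draws a single suspect drug (study ADC with probability
#' `adc_exposure_prob`, otherwise a background drug), then a truncated
#' Poisson number of distinct preferred terms. For exposed cases, the
#' sampling weight of a planted PT is multiplied by its relative reporting
#' rate, which is the multiplicative disproportionality the downstream
#' estimators target. Demographics follow the configured marginals.
#' Duplicate case versions, missing onset dates, and implausible
#' (event-before-therapy) dates are injected at the configured rates.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `reports` (tibble, simplified dialect,
#'   including duplicate versions), `truth` (list with `planted` effects
#'   expanded to drug level, per-case `exposure` labels, and the config),
#'   and `meddra` (the PT to SOC map covering the vocabulary).
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_reports_impl(config))
}

simulate_reports_impl <- function(cfg) {
  n <- cfg$n_cases
  case_id <- sprintf("case%06d", seq_len(n))
  study_drugs <- cfg$registry$drug_name
  bg_drugs <- sprintf("bg_drug_%02d", seq_len(cfg$n_background_drugs))

  exposed <- runif(n) < cfg$adc_exposure_prob
  drug <- character(n)
  if (any(exposed)) {
    drug[exposed] <- sample(study_drugs, sum(exposed), replace = TRUE)
  }
  if (any(!exposed)) {
    drug[!exposed] <- sample(bg_drugs, sum(!exposed), replace = TRUE)
  }

  # events per case: Poisson truncated to >= 1 by inverse CDF
  lam <- cfg$events_per_case_lambda
  k <- qpois(runif(n, dpois(0, lam), 1), lam)
  k[k < 1] <- 1L

  base_w <- if (cfg$background_event_law == "zipf") {
    (seq_len(cfg$n_events))^(-cfg$zipf_s)
  } else {
    rep(1, cfg$n_events)
  }
  base_w <- base_w / sum(base_w)
  vocab <- sprintf("pt_%02d", seq_len(cfg$n_events))

  planted <- expand_planted_effects(cfg$planted_effects, cfg$registry)
  effect_drugs <- unique(planted$drug_name)

  draw_group <- function(case_idx, w) {
    reps <- k[case_idx]
    ev <- sample.int(cfg$n_events, sum(reps), replace = TRUE, prob = w)
    tibble(case = rep(case_idx, reps), pt_i = ev)
  }
  plain_idx <- which(!drug %in% effect_drugs)
  pieces <- list(draw_group(plain_idx, base_w))
  for (d in effect_drugs) {
    w <- base_w
    hits <- planted[planted$drug_name == d, ]
    w[match(hits$pt, vocab)] <- w[match(hits$pt, vocab)] * hits$rrr
    pieces[[length(pieces) + 1L]] <- draw_group(which(drug == d), w / sum(w))
  }
  events <- distinct(bind_rows(pieces))   # a case lists each PT at most once

  sex <- sample(names(cfg$sex_probs), n, TRUE, prob = cfg$sex_probs)
  serious <- runif(n) < cfg$serious_prob
  outcome <- rep(NA_character_, n)
  outcome[serious] <- sample(names(cfg$outcome_probs), sum(serious), TRUE,
                             prob = cfg$outcome_probs)
  reporter <- sample(names(cfg$reporter_probs), n, TRUE,
                     prob = cfg$reporter_probs)
  country <- sample(names(cfg$country_probs), n, TRUE,
                    prob = cfg$country_probs)
  age <- pmin(pmax(rnorm(n, cfg$age_mean, cfg$age_sd), 0.2), 110)
  age[runif(n) < cfg$age_missing_prob] <- NA_real_

  start <- as.Date("2014-01-01") + sample.int(3653L, n, replace = TRUE) - 1L
  onset <- round(rexp(n, rate = log(2) / cfg$onset_median_days))
  event_date <- start + onset
  n_implausible <- floor(cfg$implausible_date_fraction * n)
  if (n_implausible > 0) {
    idx <- sample.int(n, n_implausible)
    event_date[idx] <- start[idx] - sample.int(30L, n_implausible,
                                               replace = TRUE)
  }
  n_missing <- floor(cfg$missing_date_fraction * n)
  if (n_missing > 0) {
    idx <- sample.int(n, n_missing)
    event_date[idx] <- NA
    start[idx[seq_len(n_missing %/% 2)]] <- NA
  }
  receipt <- dplyr::coalesce(event_date, start,
                             as.Date("2020-01-01")) +
    sample.int(61L, n, replace = TRUE) - 1L

  per_case <- tibble(
    case = seq_len(n), case_id = case_id, version_id = "1",
    receipt_date = receipt, sex = sex, age_years = age,
    reporter_type = reporter, serious = serious, outcome = outcome,
    country = country, drug_name = drug, drug_role = "primary_suspect",
    therapy_start_date = start, event_date = event_date
  )
  reports <- events %>%
    mutate(event_pt = vocab[.data$pt_i]) %>%
    inner_join(per_case, by = "case") %>%
    select(dplyr::all_of(SIMPLE_DIALECT_COLS))

  n_dup <- floor(cfg$duplicate_fraction * n)
  if (n_dup > 0) {
    dup_cases <- case_id[sample.int(n, n_dup)]
    dups <- reports %>%
      dplyr::filter(.data$case_id %in% dup_cases) %>%
      mutate(version_id = "2", receipt_date = .data$receipt_date + 7L)
    reports <- bind_rows(mutate(reports, version_id = "1"), dups)
  }
  reports <- arrange(reports, .data$case_id, .data$version_id,
                     .data$event_pt)

  truth <- list(
    planted = planted,
    exposure = tibble(case_id = case_id, drug_name = drug,
                      is_study_drug = exposed, onset_days = onset),
    config = cfg
  )
  list(reports = reports, truth = truth,
       meddra = make_meddra_map(cfg$n_events))
}
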