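#' Build analysis strata from the component registry
#'
#' A stratum is either a single ADC (`kind = "drug"`) or the pooled set of
#' ADCs sharing one component class: antibody subtype (2 strata), linker
#' type (2), payload category (3), or DAR class (3). Strata of one kind
#' partition the included ADCs.
#'
#' @param registry Component registry tibble; rows with `include = FALSE`
#'   are dropped.
#' @param kind One of `"drug"`, `"antibody"`, `"linker"`, `"payload"`,
#'   `"dar"`.
#' @return A tibble with columns `kind`, `stratum`, `member_drugs`
#'   (list-column of normalized drug names).
#' @export
build_strata <- function(registry = adc_registry(), kind) {
  if (!kind %in% STRATUM_KINDS) {
    abort(paste0("unknown stratum kind: ", kind),
          class = "adcvigil_config_error")
  }
  if ("include" %in% names(registry)) {
    registry <- dplyr::filter(registry, .data$include)
  }
  drugs <- normalize_drug_name(registry$drug_name)
  if (kind == "drug") {
    return(tibble(kind = "drug", stratum = drugs,
                  member_drugs = as.list(drugs)))
  }
  col <- c(antibody = "antibody", linker = "linker", payload = "payload",
           dar = "dar_class")[[kind]]
  levels_of <- list(
    antibody = c("IgG1", "IgG4"),
    linker = c("cleavable", "non_cleavable"),
    payload = c("dna_damaging", "microtubule_inhibitor", "other"),
    dar = c("lt3", "3to5", "gt5")
  )[[kind]]
  members <- lapply(levels_of, function(lv) drugs[registry[[col]] == lv])
  keep <- lengths(members) > 0
  tibble(kind = kind, stratum = levels_of[keep],
         member_drugs = members[keep])
}

# cases exposed to a member drug through a suspect role
exposed_case_ids <- function(reports, member_drugs) {
  unique(reports$case_id[
    reports$drug_role %in% SUSPECT_ROLES &
      reports$drug_norm %in% member_drugs
  ])
}

#' Build 2x2 contingency tables for every stratum-event pair
#'
#' Counting is report-level: a deduplicated report contributes to cell `a`
#' of a stratum-event pair if any of its suspect drugs belongs to the
#' stratum and the event is among its preferred terms (each report counted
#' once per pair; listing a PT twice has no effect). The comparator is all
#' other reports in the collection (`comparator = "full"`), or only other
#' ADC reports (`comparator = "adc_only"`). At the SOC level a report
#' contributes to `a` if at least one of its events maps to the SOC.
#'
#' Tables with `a = 0` are retained (they can never become signals); pairs
#' with `a + c = 0` are flagged `degenerate`.
#'
#' @param reports Deduplicated, component-annotated report tibble (from
#'   [annotate_components()]).
#' @param strata Strata tibble from [build_strata()].
#' @param level `"pt"` (preferred terms) or `"soc"` (system organ classes).
#' @param meddra PT to SOC map, required for `level = "soc"`; SOCs present
#'   in the map but absent from the data yield degenerate all-comparator
#'   tables.
#' @param meddra_mode `"strict"` or `"lenient"` (see [map_events_to_soc()]).
#' @param comparator `"full"` or `"adc_only"`.
#' @return A tibble with one row per stratum-event pair: `kind`, `stratum`,
#'   `event`, cells `a`, `b`, `c`, `d`, `n` (= a+b+c+d), `expected`
#'   (= (a+b)(a+c)/n), and `degenerate`.
#' @export
count_contingency <- function(reports, strata, level = c("pt", "soc"),
                              meddra = NULL,
                              meddra_mode = c("strict", "lenient"),
                              comparator = c("full", "adc_only")) {
  level <- match.arg(level)
  comparator <- match.arg(comparator)
  meddra_mode <- match.arg(meddra_mode)
  if (nrow(reports) == 0) {
    abort("cannot build contingency tables from an empty report collection",
          class = "adcvigil_input_error")
  }
  if (!"drug_norm" %in% names(reports)) {
    abort("reports must be annotated first (see annotate_components())",
          class = "adcvigil_input_error")
  }
  if (comparator == "adc_only") {
    adc_cases <- unique(reports$case_id[reports$is_study_drug &
                                          reports$drug_role %in% SUSPECT_ROLES])
    reports <- dplyr::filter(reports, .data$case_id %in% adc_cases)
  }

  if (level == "soc") {
    if (is.null(meddra)) {
      abort("level = 'soc' requires a MedDRA map", class = "adcvigil_config_error")
    }
    reports <- map_events_to_soc(reports, meddra, mode = meddra_mode)
    case_event <- distinct(tibble(case_id = reports$case_id,
                                  event = reports$event_soc))
    all_events <- sort(unique(c(meddra$soc, case_event$event)))
  } else {
    case_event <- distinct(tibble(case_id = reports$case_id,
                                  event = reports$event_pt))
    all_events <- sort(unique(case_event$event))
  }
  n_total <- dplyr::n_distinct(reports$case_id)
  event_tot <- count(case_event, .data$event, name = "event_total")

  one_stratum <- function(kind, stratum, member_drugs) {
    exp_ids <- exposed_case_ids(reports, member_drugs)
    n_exp <- length(exp_ids)
    a_tbl <- case_event %>%
      dplyr::filter(.data$case_id %in% exp_ids) %>%
      count(.data$event, name = "a")
    tibble(kind = kind, stratum = stratum, event = all_events) %>%
      left_join(a_tbl, by = "event") %>%
      left_join(event_tot, by = "event") %>%
      mutate(
        a = dplyr::coalesce(.data$a, 0L),
        event_total = dplyr::coalesce(.data$event_total, 0L),
        b = n_exp - .data$a,
        c = .data$event_total - .data$a,
        d = n_total - n_exp - .data$c
      ) %>%
      select(-"event_total")
  }
  out <- purrr::pmap(strata, one_stratum) %>% bind_rows()
  out %>%
    mutate(
      n = .data$a + .data$b + .data$c + .data$d,
      expected = (.data$a + .data$b) * (.data$a + .data$c) / .data$n,
      degenerate = (.data$a + .data$c) == 0
    )
}
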