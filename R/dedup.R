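#' Deduplicate case versions
#'
#' Spontaneous-report databases carry several versions of the same case
#' (follow-up reports). Exactly one record per `case_id` is kept: the one
#' with the greatest `version_id` (numeric comparison when all versions
#' parse as numbers, lexicographic otherwise), ties broken by the latest
#' `receipt_date`. The rule is order-independent and idempotent. The number
#' of removed duplicate versions is available as `attr(x, "n_removed")`.
#'
#' @param reports Report tibble in the simplified dialect.
#' @return Deduplicated report tibble (all rows of the winning version of
#'   each case), sorted by `case_id`.
#' @export
dedup_reports <- function(reports) {
  if (nrow(reports) == 0) {
    out <- reports
    attr(out, "n_removed") <- 0L
    return(out)
  }
  versions <- distinct(reports, .data$case_id, .data$version_id,
                       .data$receipt_date)
  vnum <- suppressWarnings(as.numeric(versions$version_id))
  versions$.vkey <- if (anyNA(vnum)) {
    rank(versions$version_id, ties.method = "min")
  } else {
    vnum
  }
  winners <- versions %>%
    group_by(.data$case_id) %>%
    arrange(desc(.data$.vkey), desc(.data$receipt_date),
            .by_group = TRUE) %>%
    slice_head(n = 1) %>%
    ungroup()
  n_removed <- nrow(versions) - nrow(winners)
  out <- reports %>%
    semi_join(winners, by = c("case_id", "version_id", "receipt_date")) %>%
    arrange(.data$case_id, .data$drug_name, .data$event_pt)
  attr(out, "n_removed") <- n_removed
  out
}

#' Annotate suspect drugs with ADC component classes
#'
#' Joins each drug entry to the component registry after drug-name
#' normalization (exact alias match against generic and brand names; no
#' fuzzy matching). Registry drugs gain the four component labels
#' (`antibody`, `linker`, `payload`, `dar_class`) and `is_study_drug = TRUE`;
#' all other drugs are background (`is_study_drug = FALSE`, labels `NA`).
#'
#' @param reports Report tibble in the simplified dialect.
#' @param registry Component registry tibble (default [adc_registry()]).
#' @param study_drugs Optional character vector of drug names that must be
#'   resolvable through the registry; any that are not raise a
#'   configuration error.
#' @return The report tibble with added columns `drug_norm`, `is_study_drug`,
#'   `antibody`, `linker`, `payload`, `dar_class`.
#' @export
annotate_components <- function(reports, registry = adc_registry(),
                                study_drugs = NULL) {
  aliases <- registry_aliases(registry)
  if (!is.null(study_drugs)) {
    missing_drugs <- setdiff(normalize_drug_name(study_drugs), aliases$alias)
    if (length(missing_drugs) > 0) {
      abort(
        paste0("study drug(s) absent from the component registry: ",
               paste(missing_drugs, collapse = ", ")),
        class = "adcvigil_config_error"
      )
    }
  }
  lab <- registry %>%
    select("drug_name", "antibody", "linker", "payload", "dar_class") %>%
    rename(registry_name = "drug_name")
  lookup <- aliases %>%
    rename(registry_name = "drug_name") %>%
    left_join(lab, by = "registry_name")
  out <- reports %>%
    mutate(drug_norm = normalize_drug_name(.data$drug_name)) %>%
    left_join(lookup, by = c(drug_norm = "alias")) %>%
    mutate(
      is_study_drug = !is.na(.data$registry_name),
      drug_norm = if_else(.data$is_study_drug, .data$registry_name,
                          .data$drug_norm)
    ) %>%
    select(-"registry_name")
  out
}
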