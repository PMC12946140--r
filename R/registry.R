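#' Component-class registry of FDA-approved antibody-drug conjugates
#'
#' Returns the built-in registry of the 14 antibody-drug conjugates (ADCs)
#' approved by the FDA through 2024, with the four structural component
#' classes used for stratified analysis: antibody subtype (IgG1 vs IgG4),
#' linker cleavability, payload category, and drug-to-antibody ratio (DAR).
#' Component classes are transcribed from public FDA prescribing information;
#' the `include` flag marks the 13 drugs entering the analysis (datopotamab
#' deruxtecan is excluded by default). DAR classes derive from `dar_value`
#' with boundaries `lt3`: DAR < 3, `3to5`: 3 <= DAR <= 5, `gt5`: DAR > 5.
#'
#' @param include_only Drop rows with `include = FALSE`? Default `FALSE`.
#' @return A tibble with columns `drug_name`, `brand_name`, `antibody`,
#'   `linker`, `payload`, `dar_value`, `dar_class`, `include`.
#' @examples
#' adc_registry()
#' @export
adc_registry <- function(include_only = FALSE) {
  reg <- tibble::tribble(
    ~drug_name,                    ~brand_name, ~antibody, ~linker,         ~payload,                 ~dar_value, ~include,
    "gemtuzumab ozogamicin",       "mylotarg",  "IgG4",    "cleavable",     "dna_damaging",           2.5,        TRUE,
    "brentuximab vedotin",         "adcetris",  "IgG1",    "cleavable",     "microtubule_inhibitor",  4.0,        TRUE,
    "ado-trastuzumab emtansine",   "kadcyla",   "IgG1",    "non_cleavable", "microtubule_inhibitor",  3.5,        TRUE,
    "inotuzumab ozogamicin",       "besponsa",  "IgG4",    "cleavable",     "dna_damaging",           6.0,        TRUE,
    "moxetumomab pasudotox",       "lumoxiti",  "IgG1",    "cleavable",     "other",                  1.0,        TRUE,
    "polatuzumab vedotin",         "polivy",    "IgG1",    "cleavable",     "microtubule_inhibitor",  3.5,        TRUE,
    "enfortumab vedotin",          "padcev",    "IgG1",    "cleavable",     "microtubule_inhibitor",  3.8,        TRUE,
    "fam-trastuzumab deruxtecan",  "enhertu",   "IgG1",    "cleavable",     "dna_damaging",           8.0,        TRUE,
    "sacituzumab govitecan",       "trodelvy",  "IgG1",    "cleavable",     "dna_damaging",           7.6,        TRUE,
    "belantamab mafodotin",        "blenrep",   "IgG1",    "non_cleavable", "microtubule_inhibitor",  4.0,        TRUE,
    "loncastuximab tesirine",      "zynlonta",  "IgG1",    "cleavable",     "dna_damaging",           2.3,        TRUE,
    "tisotumab vedotin",           "tivdak",    "IgG1",    "cleavable",     "microtubule_inhibitor",  4.0,        TRUE,
    "mirvetuximab soravtansine",   "elahere",   "IgG1",    "cleavable",     "microtubule_inhibitor",  3.4,        TRUE,
    "datopotamab deruxtecan",      "datroway",  "IgG1",    "cleavable",     "dna_damaging",           4.0,        FALSE
  )
  reg <- dplyr::mutate(reg, dar_class = dar_class_of(.data$dar_value))
  reg <- dplyr::select(
    reg, "drug_name", "brand_name", "antibody", "linker", "payload",
    "dar_value", "dar_class", "include"
  )
  if (include_only) reg <- dplyr::filter(reg, .data$include)
  reg
}

#' DAR class from a numeric drug-to-antibody ratio
#'
#' Boundaries: `lt3` for DAR < 3, `3to5` for 3 <= DAR <= 5 (closed middle
#' interval), `gt5` for DAR > 5.
#'
#' @param dar_value Numeric vector of average drug-to-antibody ratios.
#' @return Character vector of class labels (`NA` for missing input).
#' @export
dar_class_of <- function(dar_value) {
  dplyr::case_when(
    is.na(dar_value)  ~ NA_character_,
    dar_value < 3     ~ "lt3",
    dar_value <= 5    ~ "3to5",
    TRUE              ~ "gt5"
  )
}

#' Normalize a drug name for registry matching
#'
#' Lowercases, trims, collapses internal whitespace, and strips trailing
#' salt/format qualifiers (the FDA four-letter suffixes such as "-nxki",
#' and formulation words). Matching against the registry is exact after
#' normalization; there is no fuzzy matching.
#'
#' @param x Character vector of drug names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_drug_name("Fam-Trastuzumab Deruxtecan-nxki ")
#' @export
normalize_drug_name <- function(x) {
  out <- stringr::str_to_lower(stringr::str_squish(x))
  # FDA nonproprietary-name suffixes: "-xxxx" four-letter tags
  out <- stringr::str_remove(out, "-[a-z]{4}$")
  out <- stringr::str_remove(
    out, "\\s+(injection|for injection|intravenous|iv|tablets?)$"
  )
  out
}

#' Read a component registry from CSV
#'
#' Expected header: `drug_name,antibody,linker,payload,dar_value,dar_class`
#' (optional extra columns `brand_name`, `include` are kept). `dar_class`
#' may be blank, in which case it is derived from `dar_value`. An
#' inconsistent pair (stated class differing from the class implied by
#' `dar_value`) is an error.
#'
#' @param path Path to a CSV file.
#' @return Registry tibble as in [adc_registry()].
#' @export
read_component_registry <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("registry file not found: ", path), class = "adcvigil_io_error")
  }
  reg <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("drug_name", "antibody", "linker", "payload", "dar_value")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols) > 0) {
    abort(
      paste0("registry is missing mandatory column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "adcvigil_format_error"
    )
  }
  reg <- dplyr::mutate(
    reg,
    drug_name = normalize_drug_name(.data$drug_name),
    dar_value = as.numeric(.data$dar_value)
  )
  implied <- dar_class_of(reg$dar_value)
  if (!"dar_class" %in% names(reg) || all(is.na(reg$dar_class))) {
    reg$dar_class <- implied
  } else {
    bad <- !is.na(reg$dar_value) & !is.na(reg$dar_class) &
      reg$dar_class != implied
    if (any(bad)) {
      abort(
        paste0("dar_class inconsistent with dar_value for: ",
               paste(reg$drug_name[bad], collapse = ", ")),
        class = "adcvigil_format_error"
      )
    }
  }
  if (!"include" %in% names(reg)) reg$include <- TRUE
  as_tibble(reg)
}

#' Alias table mapping brand and generic spellings to registry names
#'
#' @param registry A registry tibble (default [adc_registry()]).
#' @return A tibble with columns `alias`, `drug_name`; aliases are already
#'   normalized.
#' @export
registry_aliases <- function(registry = adc_registry()) {
  al <- tibble(
    alias = normalize_drug_name(registry$drug_name),
    drug_name = registry$drug_name
  )
  if ("brand_name" %in% names(registry)) {
    al <- bind_rows(
      al,
      tibble(
        alias = normalize_drug_name(registry$brand_name),
        drug_name = registry$drug_name
      )
    )
  }
  dplyr::distinct(al)
}
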