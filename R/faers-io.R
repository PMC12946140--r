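#' Read spontaneous reports from the simplified tabular dialect
#'
#' The simplified dialect is a CSV with one row per (case, drug, event)
#' combination and fixed columns `case_id, version_id, receipt_date, sex,
#' age_years, reporter_type, serious, outcome, country, drug_name, drug_role,
#' therapy_start_date, event_pt, event_date`. Multiple outcomes for a case
#' appear as multiple values of `outcome` across its rows. Dates are ISO
#' `YYYY-MM-DD`; missing values are empty fields.
#'
#' Rows failing basic validation (empty `case_id` or `event_pt`, age outside
#' [0, 120], unknown enum level) are counted and dropped with a message; the
#' count is available as `attr(x, "n_malformed")`.
#'
#' @param path Path to a CSV file.
#' @return A report tibble in the simplified dialect, one row per
#'   (case, drug, event).
#' @seealso [write_reports_csv()], [read_faers_ascii()]
#' @export
read_reports_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read report file: ", path),
          class = "adcvigil_io_error")
  }
  hdr <- names(readr::read_csv(path, n_max = 0,
                               col_types = readr::cols(.default = "c"),
                               progress = FALSE))
  missing_cols <- setdiff(SIMPLE_DIALECT_COLS, hdr)
  if (length(missing_cols) > 0) {
    abort(
      paste0("simplified dialect is missing mandatory column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "adcvigil_format_error"
    )
  }
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      case_id = readr::col_character(),
      version_id = readr::col_character(),
      receipt_date = readr::col_date(),
      sex = readr::col_character(),
      age_years = readr::col_double(),
      reporter_type = readr::col_character(),
      serious = readr::col_logical(),
      outcome = readr::col_character(),
      country = readr::col_character(),
      drug_name = readr::col_character(),
      drug_role = readr::col_character(),
      therapy_start_date = readr::col_date(),
      event_pt = readr::col_character(),
      event_date = readr::col_date()
    ),
    progress = FALSE
  )
  validate_report_rows(as_tibble(x[SIMPLE_DIALECT_COLS]))
}

# shared row-level validation for both dialects: malformed rows are counted
# (attr "n_malformed") and excluded, never silently dropped
validate_report_rows <- function(x) {
  bad <- is.na(x$case_id) | x$case_id == "" |
    is.na(x$event_pt) | x$event_pt == "" |
    is.na(x$drug_name) | x$drug_name == "" |
    (!is.na(x$age_years) & (x$age_years < 0 | x$age_years > 120)) |
    !(x$sex %in% SEX_LEVELS) |
    !(x$reporter_type %in% REPORTER_LEVELS) |
    !(x$drug_role %in% ROLE_LEVELS)
  n_bad <- sum(bad)
  if (n_bad > 0) {
    inform(paste0(n_bad, " malformed report row(s) excluded during read"))
  }
  out <- x[!bad, , drop = FALSE]
  attr(out, "n_malformed") <- n_bad
  out
}

#' Write reports in the simplified tabular dialect
#'
#' @param reports Report tibble (simplified dialect columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reports_csv <- function(reports, path) {
  stopifnot(all(SIMPLE_DIALECT_COLS %in% names(reports)))
  readr::write_csv(reports[SIMPLE_DIALECT_COLS], path, progress = FALSE)
  invisible(path)
}

# FAERS ASCII code maps ---------------------------------------------------

faers_sex_to   <- c(male = "M", female = "F", unspecified = "UNK")
faers_role_to  <- c(primary_suspect = "PS", secondary_suspect = "SS",
                    concomitant = "C", interacting = "I")
faers_outc_to  <- c(death = "DE", disability = "DS", hospitalization = "HO",
                    life_threatening = "LT", other_serious = "OT")
faers_occp_to  <- c(healthcare_professional = "MD", consumer = "CN",
                    unspecified = "UNK")

invert_map <- function(m) setNames(names(m), unname(m))

faers_date <- function(d) {
  ifelse(is.na(d), "", format(d, "%Y%m%d"))
}

parse_faers_date <- function(s) {
  s <- ifelse(is.na(s) | s == "", NA_character_, s)
  as.Date(s, format = "%Y%m%d")
}

#' Read FAERS-style quarterly ASCII files
#'
#' Reads the dollar-delimited DEMO/DRUG/REAC/OUTC/THER tables (each with a
#' header line) and joins them on `primaryid` into the simplified report
#' dialect. Fields are split naively on `$` (embedded delimiters are not
#' escaped, following FAERS convention). DRUG/REAC/OUTC/THER rows whose
#' `primaryid` has no DEMO row are orphans: they are counted in
#' `attr(x, "n_orphans")` and excluded, not silently dropped.
#'
#' @param paths Named list or character vector with elements `demo`, `drug`,
#'   `reac`, and optionally `outc`, `ther`, giving file paths.
#' @return Report tibble in the simplified dialect with attributes
#'   `n_orphans` and `n_malformed`.
#' @export
read_faers_ascii <- function(paths) {
  paths <- as.list(paths)
  for (part in c("demo", "drug", "reac")) {
    if (is.null(paths[[part]])) {
      abort(paste0("FAERS dialect requires a '", part, "' file"),
            class = "adcvigil_format_error")
    }
  }
  read_part <- function(path, needed) {
    if (!file.exists(path)) {
      abort(paste0("cannot read FAERS file: ", path),
            class = "adcvigil_io_error")
    }
    x <- readr::read_delim(
      path, delim = "$", col_types = readr::cols(.default = "c"),
      progress = FALSE
    )
    missing_cols <- setdiff(needed, names(x))
    if (length(missing_cols) > 0) {
      abort(
        paste0(basename(path), " is missing mandatory column(s): ",
               paste(missing_cols, collapse = ", ")),
        class = "adcvigil_format_error"
      )
    }
    as_tibble(x)
  }

  demo <- read_part(paths$demo, c("primaryid", "caseid", "caseversion",
                                  "fda_dt", "sex", "age", "age_cod",
                                  "occp_cod", "reporter_country", "event_dt"))
  drug <- read_part(paths$drug, c("primaryid", "drug_seq", "role_cod",
                                  "drugname"))
  reac <- read_part(paths$reac, c("primaryid", "pt"))
  outc <- if (!is.null(paths$outc)) {
    read_part(paths$outc, c("primaryid", "outc_cod"))
  } else {
    tibble(primaryid = character(), outc_cod = character())
  }
  ther <- if (!is.null(paths$ther)) {
    read_part(paths$ther, c("primaryid", "dsg_drug_seq", "start_dt"))
  } else {
    tibble(primaryid = character(), dsg_drug_seq = character(),
           start_dt = character())
  }

  known <- demo$primaryid
  n_orphans <- sum(!drug$primaryid %in% known) +
    sum(!reac$primaryid %in% known) +
    sum(!outc$primaryid %in% known) +
    sum(!ther$primaryid %in% known)
  if (n_orphans > 0) {
    inform(paste0(n_orphans,
                  " orphan row(s) without a DEMO record excluded"))
  }
  drug <- dplyr::filter(drug, .data$primaryid %in% known)
  reac <- dplyr::filter(reac, .data$primaryid %in% known)
  outc <- dplyr::filter(outc, .data$primaryid %in% known)
  ther <- dplyr::filter(ther, .data$primaryid %in% known)

  sex_from  <- invert_map(faers_sex_to)
  role_from <- invert_map(faers_role_to)
  outc_from <- invert_map(faers_outc_to)
  occp_from <- c(MD = "healthcare_professional", HP = "healthcare_professional",
                 PH = "healthcare_professional", CN = "consumer",
                 LW = "unspecified", OT = "unspecified", UNK = "unspecified")

  demo2 <- dplyr::transmute(
    demo,
    primaryid = .data$primaryid,
    case_id = .data$caseid,
    version_id = .data$caseversion,
    receipt_date = parse_faers_date(.data$fda_dt),
    sex = unname(sex_from[.data$sex]) %|NA|% "unspecified",
    age_years = suppressWarnings(as.numeric(.data$age)),
    reporter_type = unname(occp_from[.data$occp_cod]) %|NA|% "unspecified",
    country = dplyr::na_if(.data$reporter_country, ""),
    event_date = parse_faers_date(.data$event_dt)
  )

  outc2 <- dplyr::transmute(
    outc, primaryid = .data$primaryid,
    outcome = unname(outc_from[.data$outc_cod])
  )
  outc_nested <- dplyr::summarise(
    dplyr::group_by(outc2, .data$primaryid),
    outcome = paste(sort(unique(stats::na.omit(.data$outcome))),
                    collapse = ";"),
    .groups = "drop"
  )

  drug2 <- dplyr::transmute(
    drug,
    primaryid = .data$primaryid, drug_seq = .data$drug_seq,
    drug_name = .data$drugname,
    drug_role = unname(role_from[.data$role_cod]) %|NA|% "concomitant"
  )
  drug2 <- left_join(
    drug2,
    dplyr::transmute(ther, primaryid = .data$primaryid,
                     drug_seq = .data$dsg_drug_seq,
                     therapy_start_date = parse_faers_date(.data$start_dt)),
    by = c("primaryid", "drug_seq")
  )

  out <- inner_join(demo2, drug2, by = "primaryid")
  out <- inner_join(out,
                    dplyr::transmute(reac, primaryid = .data$primaryid,
                                     event_pt = .data$pt),
                    by = "primaryid", relationship = "many-to-many")
  out <- left_join(out, outc_nested, by = "primaryid")
  out <- mutate(
    out,
    serious = !is.na(.data$outcome) & .data$outcome != "",
    outcome = dplyr::na_if(.data$outcome %||% "", "")
  )
  # multi-outcome cases: keep the first outcome per row, the full set is
  # recoverable from OUTC; seriousness is what downstream consumes
  out$outcome <- ifelse(
    is.na(out$outcome), NA_character_,
    vapply(strsplit(out$outcome, ";"), `[`, character(1), 1)
  )
  out <- out[order(out$case_id, out$version_id, out$drug_seq, out$event_pt), ]
  res <- validate_report_rows(as_tibble(out[SIMPLE_DIALECT_COLS]))
  attr(res, "n_orphans") <- n_orphans
  res
}

`%|NA|%` <- function(x, default) ifelse(is.na(x), default, x)

#' Write reports as FAERS-style quarterly ASCII files
#'
#' Emits dollar-delimited DEMO/DRUG/REAC/OUTC/THER files with header lines
#' into `dir`. One DEMO row per case version; `primaryid` is
#' `<case_id>-<version_id>`.
#'
#' @param reports Report tibble in the simplified dialect.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_faers_ascii <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- mutate(reports, primaryid = paste0(.data$case_id, "-", .data$version_id))

  demo <- distinct(
    r, .data$primaryid, .data$case_id, .data$version_id, .data$receipt_date,
    .data$sex, .data$age_years, .data$reporter_type, .data$country,
    .data$event_date
  )
  demo_out <- tibble(
    primaryid = demo$primaryid, caseid = demo$case_id,
    caseversion = demo$version_id, fda_dt = faers_date(demo$receipt_date),
    sex = unname(faers_sex_to[demo$sex]),
    age = ifelse(is.na(demo$age_years), "", format(demo$age_years)),
    age_cod = ifelse(is.na(demo$age_years), "", "YR"),
    occp_cod = unname(faers_occp_to[demo$reporter_type]),
    reporter_country = demo$country %|NA|% "",
    event_dt = faers_date(demo$event_date)
  )

  drugs <- distinct(r, .data$primaryid, .data$drug_name, .data$drug_role,
                    .data$therapy_start_date)
  drugs <- mutate(group_by(drugs, .data$primaryid),
                  drug_seq = as.character(row_number()))
  drugs <- ungroup(drugs)
  drug_out <- tibble(
    primaryid = drugs$primaryid, drug_seq = drugs$drug_seq,
    role_cod = unname(faers_role_to[drugs$drug_role]),
    drugname = drugs$drug_name
  )
  ther_out <- tibble(
    primaryid = drugs$primaryid, dsg_drug_seq = drugs$drug_seq,
    start_dt = faers_date(drugs$therapy_start_date)
  )
  reac_out <- distinct(tibble(primaryid = r$primaryid, pt = r$event_pt))
  outc <- distinct(
    dplyr::filter(r, !is.na(.data$outcome)),
    .data$primaryid, .data$outcome
  )
  outc_out <- tibble(primaryid = outc$primaryid,
                     outc_cod = unname(faers_outc_to[outc$outcome]))

  paths <- c(
    demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
    reac = file.path(dir, "REAC.txt"), outc = file.path(dir, "OUTC.txt"),
    ther = file.path(dir, "THER.txt")
  )
  readr::write_delim(demo_out, paths["demo"], delim = "$", progress = FALSE)
  readr::write_delim(drug_out, paths["drug"], delim = "$", progress = FALSE)
  readr::write_delim(reac_out, paths["reac"], delim = "$", progress = FALSE)
  readr::write_delim(outc_out, paths["outc"], delim = "$", progress = FALSE)
  readr::write_delim(ther_out, paths["ther"], delim = "$", progress = FALSE)
  invisible(paths)
}

#' Validate a report collection
#'
#' Row-level schema and plausibility checks producing a tidy issue list:
#' empty identifiers, enum levels outside the vocabulary, ages outside
#' [0, 120], event dates before therapy start, and outcome/seriousness
#' inconsistencies (reported, not enforced).
#'
#' @param reports Report tibble in the simplified dialect.
#' @return A tibble with columns `row`, `case_id`, `issue`.
#' @export
validate_reports <- function(reports) {
  r <- reports
  issue <- function(mask, label) {
    tibble(row = which(mask), case_id = r$case_id[which(mask)], issue = label)
  }
  bind_rows(
    issue(is.na(r$case_id) | r$case_id == "", "empty case_id"),
    issue(is.na(r$event_pt) | r$event_pt == "", "empty event_pt"),
    issue(!is.na(r$age_years) & (r$age_years < 0 | r$age_years > 120),
          "age outside [0, 120]"),
    issue(!r$sex %in% SEX_LEVELS, "unknown sex level"),
    issue(!r$drug_role %in% ROLE_LEVELS, "unknown drug role"),
    issue(!r$reporter_type %in% REPORTER_LEVELS, "unknown reporter type"),
    issue(!is.na(r$outcome) & !r$outcome %in% OUTCOME_LEVELS,
          "unknown outcome code"),
    issue(!is.na(r$therapy_start_date) & !is.na(r$event_date) &
            r$event_date < r$therapy_start_date,
          "event date before therapy start"),
    issue(!is.na(r$outcome) & !r$serious & r$outcome != "other_serious",
          "serious outcome on non-serious report")
  )
}
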