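#' Run configuration for a full analysis
#'
#' Collects every knob of the pipeline in one validated list. May be read
#' from a YAML file with [read_run_config()]; unknown fields are an error.
#'
#' @param input Path to a report file (simplified CSV) or a named list of
#'   FAERS ASCII paths, or `NULL` when reports are passed directly.
#' @param dialect `"simple"` or `"faers"`.
#' @param registry_path Optional CSV registry path (default: built-in).
#' @param meddra_path Optional PT-to-SOC CSV path.
#' @param kinds Stratification kinds to run (default: all five).
#' @param levels Event levels to run (`"pt"`, optionally `"soc"`).
#' @param cfg An [algorithm_config()].
#' @param comparator,fdr_family,fdr_q See [detect_signals()].
#' @param top_k,small_class_threshold See [prioritize_signals()].
#' @param meddra_mode `"strict"` or `"lenient"`.
#' @param seed Seed for the simulation subcommand.
#' @param out_dir Output directory for [write_run_outputs()].
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, dialect = c("simple", "faers"),
                       registry_path = NULL, meddra_path = NULL,
                       kinds = STRATUM_KINDS, levels = "pt",
                       cfg = algorithm_config(),
                       comparator = "full", fdr_family = "scheme",
                       fdr_q = 0.05, top_k = 20,
                       small_class_threshold = 10,
                       meddra_mode = "strict", seed = 1L,
                       out_dir = NULL) {
  dialect <- match.arg(dialect)
  if (!all(kinds %in% STRATUM_KINDS)) {
    abort("unknown stratification kind in 'kinds'",
          class = "adcvigil_config_error")
  }
  if (!all(levels %in% c("pt", "soc"))) {
    abort("levels must be 'pt' and/or 'soc'",
          class = "adcvigil_config_error")
  }
  for (p in c(registry_path, meddra_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("configured path does not exist: ", p),
            class = "adcvigil_config_error")
    }
  }
  structure(
    list(input = input, dialect = dialect, registry_path = registry_path,
         meddra_path = meddra_path, kinds = kinds, levels = levels,
         cfg = cfg, comparator = comparator, fdr_family = fdr_family,
         fdr_q = fdr_q, top_k = top_k,
         small_class_threshold = small_class_threshold,
         meddra_mode = meddra_mode, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Top-level YAML keys mirror the arguments of [run_config()]; the
#' `algorithm` block maps onto [algorithm_config()].
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  alg <- do.call(algorithm_config, y$algorithm %||% list())
  y$algorithm <- NULL
  known <- setdiff(names(formals(run_config)), "cfg")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ",
                 paste(unknown, collapse = ", ")),
          class = "adcvigil_config_error")
  }
  do.call(run_config, c(y, list(cfg = alg)))
}

#' Simulate a dataset and write it to disk
#'
#' Writes the simplified CSV dialect, the FAERS ASCII dialect, and the
#' ground truth as JSON into `dir`. Identical seed and configuration give
#' byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return Named list of file paths, invisibly.
#' @export
run_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_reports(config)
  csv_path <- file.path(dir, "reports.csv")
  write_reports_csv(sim$reports, csv_path)
  faers_paths <- write_faers_ascii(sim$reports, file.path(dir, "faers"))
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(planted = sim$truth$planted,
         exposure = sim$truth$exposure,
         seed = config$seed),
    truth_path, dataframe = "columns", digits = NA
  )
  meddra_path <- file.path(dir, "meddra_map.csv")
  readr::write_csv(sim$meddra, meddra_path, progress = FALSE)
  invisible(list(reports = csv_path, faers = faers_paths,
                 truth = truth_path, meddra = meddra_path))
}

#' Run the full component-stratified analysis
#'
#' Orchestrates the pipeline: read (or accept) reports, deduplicate,
#' annotate components, fit the database-wide EBGM prior once, detect
#' signals for every requested stratification kind and level, prioritize
#' strong signals per stratum, compute the sensitivity concordance, and
#' build baseline descriptive tables. A run manifest records counts at
#' every filtering step.
#'
#' @param config A [run_config()].
#' @param reports Optional report tibble (overrides `config$input`).
#' @return A `run_result` list: `signals` (named by `kind.level`),
#'   `strong` (strong-signal tibbles per kind), `concordance`,
#'   `baseline` (per kind), `tallies`, `prior`, `manifest`, `config`.
#' @export
run_analysis <- function(config, reports = NULL) {
  stopifnot(inherits(config, "run_config"))
  registry <- if (is.null(config$registry_path)) {
    adc_registry()
  } else {
    read_component_registry(config$registry_path)
  }
  meddra <- if (!is.null(config$meddra_path)) {
    read_meddra_map(config$meddra_path)
  } else {
    NULL
  }
  if (is.null(reports)) {
    if (is.null(config$input)) {
      abort("no input reports: supply config$input or `reports`",
            class = "adcvigil_config_error")
    }
    reports <- if (config$dialect == "faers") {
      read_faers_ascii(config$input)
    } else {
      read_reports_csv(config$input)
    }
  }
  n_raw <- dplyr::n_distinct(paste(reports$case_id, reports$version_id))
  dedup <- dedup_reports(reports)
  n_dedup <- dplyr::n_distinct(dedup$case_id)
  ann <- annotate_components(dedup, registry)
  n_annotated <- n_dedup
  prior <- fit_collection_prior(ann, config$cfg)

  signals <- list()
  strong <- list()
  conc <- list()
  baseline <- list()
  n_tables <- 0L
  for (kind in config$kinds) {
    for (level in config$levels) {
      if (level == "soc" && is.null(meddra)) next
      sg <- detect_signals(
        ann, kind, registry = registry, level = level, meddra = meddra,
        cfg = config$cfg, prior = prior, comparator = config$comparator,
        fdr_family = config$fdr_family, fdr_q = config$fdr_q
      )
      key <- paste(kind, level, sep = ".")
      signals[[key]] <- sg
      n_tables <- n_tables + nrow(sg)
      if (level == "pt") {
        pos <- apply_mcc(sg, positives_only = TRUE)
        strong[[kind]] <- pos %>%
          group_by(.data$stratum) %>%
          dplyr::group_modify(~ prioritize_signals(
            .x, top_k = config$top_k,
            small_class_threshold = config$small_class_threshold
          )) %>%
          ungroup()
        conc[[kind]] <- mutate(sensitivity_concordance(sg, config$fdr_q),
                               kind = kind, .before = 1)
      }
    }
    baseline[[kind]] <- baseline_table(ann, kind, registry)
  }
  concordance_tbl <- bind_rows(conc)
  n_mcc <- sum(vapply(signals, function(s) sum(s$mcc), integer(1)))
  n_strong <- sum(vapply(strong, nrow, integer(1)))
  n_fdr <- sum(vapply(signals,
                      function(s) sum(s$mcc & s$fdr_sig %in% TRUE),
                      integer(1)))
  manifest <- list(
    counts = list(
      retrieved = n_raw, deduplicated = n_dedup, annotated = n_annotated,
      tables_built = n_tables, mcc_positive = n_mcc, strong = n_strong,
      fdr_significant = n_fdr
    ),
    kinds = config$kinds, levels = config$levels,
    comparator = config$comparator, fdr_family = config$fdr_family,
    prior = prior[c("alpha1", "beta1", "alpha2", "beta2", "p", "fitted")]
  )
  structure(
    list(signals = signals, strong = strong, concordance = concordance_tbl,
         baseline = baseline,
         tallies = descriptive_tallies(dedup), prior = prior,
         manifest = manifest, config = config),
    class = "run_result"
  )
}

#' Write a run's outputs as CSV and JSON
#'
#' Per-stratification signal tables and strong-signal tables as CSV, the
#' concordance table, tallies and the run manifest as JSON.
#'
#' @param result A `run_result` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(result$signals)) {
    readr::write_csv(as_tibble(result$signals[[key]]),
                     file.path(dir, paste0("signals_", key, ".csv")),
                     progress = FALSE)
  }
  for (kind in names(result$strong)) {
    readr::write_csv(result$strong[[kind]],
                     file.path(dir, paste0("strong_", kind, ".csv")),
                     progress = FALSE)
  }
  readr::write_csv(result$concordance, file.path(dir, "concordance.csv"),
                   progress = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$tallies, file.path(dir, "tallies.json"),
                       dataframe = "columns", digits = NA, pretty = TRUE)
  invisible(dir)
}
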