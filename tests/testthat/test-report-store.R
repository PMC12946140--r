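test_that("simplified-dialect CSV groups rows into cases and round-trips", {
  rows <- dplyr::bind_rows(
    report_rows("c1", "brentuximab vedotin", c("pt_01", "pt_02", "pt_03")),
    report_rows("c2", "aspirin", c("pt_01", "pt_04"), sex = "male",
                serious = FALSE, outcome = NA_character_),
    report_rows("c2", "ibuprofen", "pt_04", sex = "male",
                serious = FALSE, outcome = NA_character_,
                drug_role = "concomitant")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_reports_csv(rows, path)
  back <- read_reports_csv(path)
  expect_equal(nrow(back), 6)
  expect_equal(dplyr::n_distinct(back$case_id), 2)
  # round-trip identity on the canonical column set and order
  expect_equal(
    dplyr::arrange(back, case_id, drug_name, event_pt),
    dplyr::arrange(rows, case_id, drug_name, event_pt),
    ignore_attr = TRUE
  )
  # per-case nesting reconstructs: c1 has 1 drug and 3 events
  c1 <- dplyr::filter(back, case_id == "c1")
  expect_equal(dplyr::n_distinct(c1$drug_name), 1)
  expect_equal(sort(unique(c1$event_pt)), c("pt_01", "pt_02", "pt_03"))
})

test_that("missing mandatory column raises a format error naming it", {
  rows <- tiny_collection()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(rows, -event_pt), path)
  expect_error(read_reports_csv(path), "event_pt",
               class = "adcvigil_format_error")
  expect_error(read_reports_csv(file.path(tempdir(), "nope.csv")),
               class = "adcvigil_io_error")
})

test_that("malformed rows are counted and excluded, not silently dropped", {
  rows <- dplyr::bind_rows(
    tiny_collection(),
    report_rows("c5", "aspirin", "pt_01", age_years = 300),   # bad age
    report_rows("",   "aspirin", "pt_01"),                    # empty id
    report_rows("c6", "aspirin", "pt_01", sex = "unknown")    # bad enum
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_reports_csv(rows, path)
  expect_message(back <- read_reports_csv(path), "3 malformed")
  expect_equal(attr(back, "n_malformed"), 3)
  expect_equal(nrow(back), 4)
})

test_that("FAERS ASCII joins DEMO/DRUG/REAC on primaryid and counts orphans", {
  rows <- tiny_collection()
  dir <- withr::local_tempdir()
  paths <- write_faers_ascii(rows, dir)
  back <- read_faers_ascii(as.list(paths))
  expect_equal(dplyr::n_distinct(back$case_id), 4)
  expect_equal(nrow(back), nrow(rows))
  expect_equal(sort(unique(back$event_pt)), c("pt_01", "pt_02"))
  expect_true(all(back$serious))

  # inject an orphan REAC row (no matching DEMO) -> counted, excluded
  reac <- readLines(paths[["reac"]])
  writeLines(c(reac, "ghost-1$pt_09"), paths[["reac"]])
  expect_message(back2 <- read_faers_ascii(as.list(paths)), "1 orphan")
  expect_equal(attr(back2, "n_orphans"), 1)
  expect_false("pt_09" %in% back2$event_pt)

  # missing mandatory column in DRUG -> format error naming the column
  drug_lines <- readLines(paths[["drug"]])
  writeLines(sub("role_cod", "rolecode", drug_lines), paths[["drug"]])
  expect_error(read_faers_ascii(as.list(paths)), "role_cod",
               class = "adcvigil_format_error")
})

test_that("deduplication keeps the greatest version, ties to latest receipt", {
  base <- report_rows("C", "aspirin", "pt_01")
  v1 <- dplyr::mutate(base, version_id = "1")
  v2 <- dplyr::mutate(base, version_id = "2", event_pt = "pt_02")
  out <- dedup_reports(dplyr::bind_rows(v1, v2))
  expect_equal(unique(out$version_id), "2")
  expect_equal(out$event_pt, "pt_02")
  expect_equal(attr(out, "n_removed"), 1)

  # equal version, receipt dates 2020-01-01 vs 2021-01-01 -> later retained
  r1 <- dplyr::mutate(base, receipt_date = as.Date("2020-01-01"),
                      event_pt = "pt_03")
  r2 <- dplyr::mutate(base, receipt_date = as.Date("2021-01-01"),
                      event_pt = "pt_04")
  out2 <- dedup_reports(dplyr::bind_rows(r1, r2))
  expect_equal(out2$event_pt, "pt_04")
})

test_that("deduplication drops duplicate case versions on a mixed fixture", {
  # 10 records over 7 cases: A, B and C carry an extra version each
  recs <- dplyr::bind_rows(
    report_rows("A", "aspirin", "pt_01", version_id = c("1", "2")),
    report_rows("B", "aspirin", "pt_01", version_id = c("1", "3")),
    report_rows("C", "aspirin", "pt_01", version_id = c("2", "10")),
    report_rows(c("D", "E", "F", "G"), "aspirin", "pt_01")
  )
  out <- dedup_reports(recs)
  expect_equal(dplyr::n_distinct(out$case_id), 7)
  expect_equal(nrow(out), 7)
  expect_equal(attr(out, "n_removed"), 3)
  # numeric comparison: version "10" beats "2"
  expect_equal(out$version_id[out$case_id == "C"], "10")
})

test_that("deduplication is idempotent and order-independent", {
  sim <- null_sim(400, seed = 5)
  once <- dedup_reports(sim$reports)
  twice <- dedup_reports(once)
  expect_equal(once, twice, ignore_attr = TRUE)
  expect_equal(attr(twice, "n_removed"), 0)
  set.seed(9)
  shuffled <- sim$reports[sample.int(nrow(sim$reports)), ]
  expect_equal(dedup_reports(shuffled), once, ignore_attr = TRUE)
})

test_that("component annotation labels study drugs and backgrounds", {
  rows <- dplyr::bind_rows(
    report_rows("c1", "Belantamab Mafodotin-blmf", "pt_01"),
    report_rows("c2", "BLENREP", "pt_01"),
    report_rows("c3", "aspirin", "pt_01")
  )
  ann <- annotate_components(rows)
  bm <- dplyr::filter(ann, case_id %in% c("c1", "c2"))
  expect_true(all(bm$is_study_drug))
  expect_true(all(bm$drug_norm == "belantamab mafodotin"))
  expect_equal(unique(bm$antibody), "IgG1")
  expect_equal(unique(bm$linker), "non_cleavable")
  expect_equal(unique(bm$payload), "microtubule_inhibitor")
  expect_equal(unique(bm$dar_class), "3to5")
  bg <- dplyr::filter(ann, case_id == "c3")
  expect_false(bg$is_study_drug)
  expect_true(is.na(bg$antibody))

  expect_error(
    annotate_components(rows, study_drugs = c("belantamab mafodotin",
                                              "notadrugumab")),
    "notadrugumab", class = "adcvigil_config_error"
  )
})

test_that("shipped registry file matches the built-in registry", {
  path <- system.file("extdata", "adc_component_registry.csv",
                      package = "adcvigil")
  reg <- read_component_registry(path)
  expect_equal(nrow(reg), 14)
  expect_equal(sum(reg$include), 13)
  expect_equal(sort(unique(reg$antibody)), c("IgG1", "IgG4"))
  # dar_class always consistent with dar_value
  expect_equal(reg$dar_class, dar_class_of(reg$dar_value))
})

test_that("PT->SOC mapping is total in strict mode and routed when lenient", {
  rows <- tiny_collection()
  map <- meddra_map(c("pt_01"), c("soc_1"))   # pt_02 unmapped
  expect_error(map_events_to_soc(rows, map, mode = "strict"),
               class = "adcvigil_meddra_error")
  expect_message(
    out <- map_events_to_soc(rows, map, mode = "lenient"),
    "Unmapped"
  )
  expect_equal(sort(unique(out$event_soc)), c("Unmapped", "soc_1"))
  # a PT with two primary SOCs is rejected at construction
  expect_error(meddra_map(c("pt_01", "pt_01"), c("soc_1", "soc_2")),
               class = "adcvigil_format_error")
})
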