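#' Read a preferred-term to system-organ-class map
#'
#' CSV with header `pt,soc`; every preferred term (PT) must map to exactly
#' one primary system organ class (SOC).
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `pt`, `soc`.
#' @export
read_meddra_map <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("MedDRA map file not found: ", path),
          class = "adcvigil_io_error")
  }
  m <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!all(c("pt", "soc") %in% names(m))) {
    abort("MedDRA map requires columns 'pt' and 'soc'",
          class = "adcvigil_format_error")
  }
  meddra_map(m$pt, m$soc)
}

#' Construct a PT to SOC map
#'
#' @param pt Character vector of preferred terms.
#' @param soc Character vector of primary system organ classes, same length.
#' @return A tibble with columns `pt`, `soc`; duplicate PTs with conflicting
#'   SOCs are an error (each PT has exactly one primary SOC).
#' @export
meddra_map <- function(pt, soc) {
  m <- distinct(tibble(pt = as.character(pt), soc = as.character(soc)))
  dup <- unique(m$pt[duplicated(m$pt)])
  if (length(dup) > 0) {
    abort(
      paste0("PT mapped to more than one primary SOC: ",
             paste(head(dup, 5), collapse = ", ")),
      class = "adcvigil_format_error"
    )
  }
  m
}

#' Synthetic PT vocabulary and SOC map matching the report generator
#'
#' Generates `n_events` preferred terms named `pt_01`, `pt_02`, ... assigned
#' round-robin to `n_soc` synthetic organ classes `soc_1`, ... . This is the
#' vocabulary the synthetic report generator emits, so simulated collections
#' are always fully mapped.
#'
#' @param n_events Number of preferred terms.
#' @param n_soc Number of system organ classes (default: one per 10 PTs).
#' @return A tibble with columns `pt`, `soc`.
#' @export
make_meddra_map <- function(n_events, n_soc = max(1L, n_events %/% 10L)) {
  pts <- sprintf("pt_%02d", seq_len(n_events))
  meddra_map(pts, sprintf("soc_%d", ((seq_len(n_events) - 1L) %% n_soc) + 1L))
}

#' Attach SOC labels to report events
#'
#' @param reports Report tibble with an `event_pt` column.
#' @param map PT to SOC map tibble.
#' @param mode `"strict"` refuses to run if any event PT lacks a SOC;
#'   `"lenient"` routes unmapped PTs to the label `"Unmapped"`. Never both
#'   silently: lenient mode emits a message with the unmapped count.
#' @return `reports` with an added `event_soc` column.
#' @export
map_events_to_soc <- function(reports, map, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  out <- left_join(reports, rename(map, event_soc = "soc"),
                   by = c(event_pt = "pt"))
  n_unmapped <- sum(is.na(out$event_soc))
  if (n_unmapped > 0) {
    if (mode == "strict") {
      abort(
        paste0(n_unmapped, " event row(s) carry a PT with no SOC mapping; ",
               "supply a total map or use mode = 'lenient'"),
        class = "adcvigil_meddra_error"
      )
    }
    inform(paste0(n_unmapped,
                  " event row(s) with unmapped PT routed to 'Unmapped'"))
    out$event_soc[is.na(out$event_soc)] <- "Unmapped"
  }
  out
}
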