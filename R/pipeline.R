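#' Two-sided Fisher exact p-value for 2x2 tables
#'
#' Point-probability method: the p-value is the sum of the probabilities of
#' all hypergeometric outcomes (at fixed margins) whose probability does
#' not exceed that of the observed table (with the customary relative
#' tolerance `1 + 1e-7`). Degenerate margins (`a + c = 0`, or empty
#' exposure/comparator) give p = 1. Vectorised over rows.
#'
#' @param a,b,c,d Integer vectors of cell counts.
#' @return Numeric vector of p-values in (0, 1].
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + c[i]          # event margin
    m2 <- b[i] + d[i]
    k  <- a[i] + b[i]          # exposed margin
    if (m1 == 0 || k == 0 || m2 + m1 == 0 || c[i] + d[i] == 0) {
      out[i] <- 1
      next
    }
    support <- max(0, k - m2):min(k, m1)
    dens <- dhyper(support, m1, m2, k)
    p_obs <- dhyper(a[i], m1, m2, k)
    out[i] <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`: step-up adjusted
#' values with enforced monotonicity, clipped at 1.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Multi-method consensus filter
#'
#' A stratum-event pair is a consensus (MCC) signal only when all four
#' per-method flags hold simultaneously; any undefined flag disqualifies
#' the pair. Returns the scored tibble with the `mcc` column (re)computed,
#' or only the positive subset.
#'
#' @param scored Scored signal tibble (from [score_tables()]).
#' @param positives_only Return only MCC-positive rows?
#' @return Tibble with logical `mcc` column.
#' @export
apply_mcc <- function(scored, positives_only = FALSE) {
  flags <- cbind(scored$ror_flag, scored$prr_flag, scored$ic_flag,
                 scored$ebgm_flag)
  flags[is.na(flags)] <- FALSE
  scored$mcc <- rowSums(flags) == 4L
  if (positives_only) scored <- dplyr::filter(scored, .data$mcc)
  scored
}

#' Prioritize strong signals by ROR rank
#'
#' MCC-positive signals within one stratum are ordered by descending ROR,
#' ties broken by larger `a`, then lexicographic event name, and the top
#' `top_k` are returned. When the total number of positives does not exceed
#' `small_class_threshold`, all are returned (the small-class exception;
#' `exception_applied` attribute set).
#'
#' @param signals Signal tibble for one stratum, MCC-positive rows.
#' @param top_k Rank cutoff (default 20).
#' @param small_class_threshold Positives at or below this count skip the
#'   cutoff (default 10).
#' @return Ordered tibble of strong signals with attributes
#'   `exception_applied` and `rank_cutoff`; a `rank` column is added.
#' @export
prioritize_signals <- function(signals, top_k = 20,
                               small_class_threshold = 10) {
  ord <- signals %>%
    arrange(desc(.data$ror), desc(.data$a), .data$event) %>%
    mutate(rank = row_number())
  exception <- nrow(ord) <= small_class_threshold
  if (!exception) ord <- slice_head(ord, n = top_k)
  attr(ord, "exception_applied") <- exception
  attr(ord, "rank_cutoff") <- top_k
  ord
}

#' Concordance between the consensus and FDR-significant signal sets
#'
#' @param mcc_ids,fdr_ids Character vectors of pair identifiers (any
#'   consistent encoding of (stratum, event)).
#' @return One-row tibble `n_mcc`, `n_fdr`, `n_both`, `jaccard`. Two empty
#'   sets are identical, so their Jaccard index is 1.
#' @export
concordance <- function(mcc_ids, fdr_ids) {
  mcc_ids <- unique(mcc_ids)
  fdr_ids <- unique(fdr_ids)
  n_both <- length(intersect(mcc_ids, fdr_ids))
  n_union <- length(union(mcc_ids, fdr_ids))
  tibble(
    n_mcc = length(mcc_ids), n_fdr = length(fdr_ids), n_both = n_both,
    jaccard = if (n_union == 0) 1 else n_both / n_union
  )
}

#' Detect signals for one stratification scheme
#'
#' End-to-end detection on a deduplicated, annotated collection: builds
#' the strata of `kind`, the 2x2 table for every stratum-event pair,
#' scores all four disproportionality statistics (the EBGM prior is fitted
#' once on the per-drug tables of the whole collection unless supplied),
#' applies the consensus criterion, and adds the Fisher/Benjamini-Hochberg
#' sensitivity layer. The BH family is all pairs within this stratification
#' scheme (`fdr_family = "scheme"`) or may be deferred for global
#' adjustment (`"none"`).
#'
#' @param reports Deduplicated, annotated report tibble.
#' @param kind Stratification kind (see [build_strata()]).
#' @param registry Component registry.
#' @param level `"pt"` or `"soc"`.
#' @param meddra PT to SOC map (required for `level = "soc"`).
#' @param cfg An [algorithm_config()].
#' @param prior Optional prefitted `ebgm_prior`; default fits on the
#'   collection's per-drug tables (all suspect drugs, study and background).
#' @param comparator Comparator definition (see [count_contingency()]).
#' @param fdr_family `"scheme"` (default) or `"none"`.
#' @param fdr_q Significance level on q (default 0.05, strict inequality).
#' @return An `adc_signals` tibble: one row per stratum-event pair with the
#'   table cells, all statistics, per-method flags, `mcc`, `fisher_p`, `q`,
#'   and `fdr_sig`.
#' @export
detect_signals <- function(reports, kind, registry = adc_registry(),
                           level = c("pt", "soc"), meddra = NULL,
                           cfg = algorithm_config(), prior = NULL,
                           comparator = c("full", "adc_only"),
                           fdr_family = c("scheme", "none"),
                           fdr_q = 0.05) {
  level <- match.arg(level)
  comparator <- match.arg(comparator)
  fdr_family <- match.arg(fdr_family)
  strata <- build_strata(registry, kind)
  tables <- count_contingency(reports, strata, level = level,
                              meddra = meddra, comparator = comparator)
  if (is.null(prior)) {
    prior <- fit_collection_prior(reports, cfg)
  }
  scored <- score_tables(tables, prior = prior, cfg = cfg)
  scored <- apply_mcc(scored)
  scored$fisher_p <- fisher_exact_p(scored$a, scored$b, scored$c, scored$d)
  if (fdr_family == "scheme") {
    scored$q <- bh_adjust(scored$fisher_p)
    scored$fdr_sig <- scored$q < fdr_q
  } else {
    scored$q <- NA_real_
    scored$fdr_sig <- NA
  }
  attr(scored, "prior") <- prior
  class(scored) <- c("adc_signals", class(scored))
  scored
}

#' Fit the database-wide EBGM prior from per-drug tables
#'
#' Builds one 2x2 table per (suspect drug, event) pair over the whole
#' collection — study ADCs and background drugs alike — and fits the
#' gamma-Poisson mixture on them. This mirrors a database-wide shrinkage
#' model reused across component strata.
#'
#' @param reports Deduplicated, annotated report tibble.
#' @param cfg An [algorithm_config()].
#' @return An `ebgm_prior`.
#' @export
fit_collection_prior <- function(reports, cfg = algorithm_config()) {
  drugs <- sort(unique(reports$drug_norm[reports$drug_role %in%
                                           SUSPECT_ROLES]))
  strata <- tibble(kind = "drug", stratum = drugs,
                   member_drugs = as.list(drugs))
  tabs <- count_contingency(reports, strata, level = "pt")
  fit_ebgm_prior(tabs, cfg)
}

pair_id <- function(x) paste(x$stratum, x$event, sep = "||")

#' Sensitivity concordance for a detected signal set
#'
#' Compares the MCC-positive set with its FDR-significant subset
#' (q < `fdr_q`), the robustness check of the sensitivity layer: complete
#' overlap (Jaccard 1) means no consensus signal is lost after
#' multiple-testing adjustment.
#'
#' @param signals An `adc_signals` tibble from [detect_signals()].
#' @param fdr_q Significance level (default 0.05).
#' @return One-row concordance tibble (see [concordance()]).
#' @export
sensitivity_concordance <- function(signals, fdr_q = 0.05) {
  mcc_set <- pair_id(dplyr::filter(signals, .data$mcc))
  fdr_set <- pair_id(dplyr::filter(signals, .data$mcc & .data$q < fdr_q))
  concordance(mcc_set, fdr_set)
}
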