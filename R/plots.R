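#' Forest-style plot of detected signals
#'
#' Shows the strongest consensus signals per stratum as points at the
#' reporting odds ratio (log scale) with their 95% confidence intervals,
#' coloured by consensus status.
#'
#' @param object An `adc_signals` tibble from [detect_signals()].
#' @param top_n Signals shown per stratum (by descending ROR among
#'   MCC-positive pairs; if none are positive, the largest finite RORs).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot adc_signals
#' @export
autoplot.adc_signals <- function(object, top_n = 10, ...) {
  dat <- as_tibble(object) %>%
    dplyr::filter(is.finite(.data$ror), .data$ror > 0)
  pick <- dat %>%
    dplyr::filter(.data$mcc) %>%
    group_by(.data$stratum) %>%
    arrange(desc(.data$ror), .by_group = TRUE) %>%
    slice_head(n = top_n) %>%
    ungroup()
  if (nrow(pick) == 0) {
    pick <- dat %>%
      group_by(.data$stratum) %>%
      arrange(desc(.data$ror), .by_group = TRUE) %>%
      slice_head(n = top_n) %>%
      ungroup()
  }
  ggplot2::ggplot(
    pick,
    ggplot2::aes(x = .data$ror,
                 y = stats::reorder(paste(.data$stratum, .data$event,
                                          sep = ": "), .data$ror),
                 colour = .data$mcc)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ror_lo, xmax = .data$ror_hi), height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Reporting odds ratio (95% CI)", y = NULL,
                  colour = "Consensus signal") +
    ggplot2::theme_minimal()
}

#' Density plot of a fitted EBGM prior
#'
#' @param object An `ebgm_prior`.
#' @param xlim Upper plotting limit for the relative reporting rate.
#' @param ... Unused.
#' @return A ggplot object showing the two gamma components and the
#'   mixture density of the relative reporting rate.
#' @method autoplot ebgm_prior
#' @export
autoplot.ebgm_prior <- function(object, xlim = 5, ...) {
  x <- seq(1e-3, xlim, length.out = 400)
  dat <- bind_rows(
    tibble(x = x, density = object$p *
             stats::dgamma(x, object$alpha1, rate = object$beta1),
           component = "component 1"),
    tibble(x = x, density = (1 - object$p) *
             stats::dgamma(x, object$alpha2, rate = object$beta2),
           component = "component 2")
  )
  mix <- dat %>%
    group_by(.data$x) %>%
    summarise(density = sum(.data$density), .groups = "drop") %>%
    mutate(component = "mixture")
  ggplot2::ggplot(bind_rows(dat, mix),
                  ggplot2::aes(.data$x, .data$density,
                               colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Relative reporting rate", y = "Prior density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Onset-time distribution plot per stratum
#'
#' Boxplots of per-case onset times (days, log1p scale) for the strata of
#' one kind, after the missing/implausible exclusions.
#'
#' @param reports Deduplicated, annotated report tibble.
#' @param kind Stratification kind.
#' @param registry Component registry.
#' @return A ggplot object.
#' @export
plot_onset_times <- function(reports, kind, registry = adc_registry()) {
  strata <- build_strata(registry, kind)
  dat <- purrr::pmap(strata, function(kind, stratum, member_drugs) {
    per_case <- reports %>%
      dplyr::filter(.data$drug_role %in% SUSPECT_ROLES,
                    .data$drug_norm %in% member_drugs) %>%
      group_by(.data$case_id) %>%
      summarise(
        ot = as.numeric(min(.data$event_date) -
                          min(.data$therapy_start_date)),
        .groups = "drop"
      ) %>%
      dplyr::filter(!is.na(.data$ot), .data$ot >= 0)
    mutate(per_case, stratum = stratum)
  }) %>% bind_rows()
  ggplot2::ggplot(dat, ggplot2::aes(.data$stratum, .data$ot + 1)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Onset time + 1 (days)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
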