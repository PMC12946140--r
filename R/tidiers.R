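#' @importFrom generics tidy glance
NULL

#' Tidy an EBGM prior fit
#'
#' @param x An `ebgm_prior` from [fit_ebgm_prior()].
#' @param ... Unused.
#' @return A tibble with one row per hyperparameter (`alpha1`, `beta1`,
#'   `alpha2`, `beta2`, `p`) and its estimate.
#' @method tidy ebgm_prior
#' @export
tidy.ebgm_prior <- function(x, ...) {
  tibble(
    term = c("alpha1", "beta1", "alpha2", "beta2", "p"),
    estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$p)
  )
}

#' Glance at an EBGM prior fit
#'
#' @param x An `ebgm_prior`.
#' @param ... Unused.
#' @return One-row tibble: `logLik`, `n_tables`, `prior_mean`, `fitted`,
#'   `n_evaluations`.
#' @method glance ebgm_prior
#' @export
glance.ebgm_prior <- function(x, ...) {
  tibble(
    logLik = x$loglik, n_tables = x$n_tables, prior_mean = x$prior_mean,
    fitted = x$fitted,
    n_evaluations = as.integer(x$counts[["function"]])
  )
}

#' @export
generics::tidy

#' @export
generics::glance
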