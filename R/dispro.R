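#' Thresholds and hyperparameters for the four disproportionality methods
#'
#' Defaults are the canonical published criteria: ROR requires at least
#' `ror_min_count` co-reports and a 95% CI lower bound above 1; PRR requires
#' at least 3 co-reports, PRR >= 2 and Pearson chi-square >= 4 (no Yates
#' correction); the information component requires its lower 2.5% credible
#' bound IC025 > 0; the empirical Bayes geometric mean requires its 5%
#' posterior quantile EB05 > 2. The EBGM prior defaults to the classic
#' two-component gamma mixture (0.2, 0.1, 2, 4) with mixing weight 1/3,
#' refitted from the data by [fit_ebgm_prior()] when enough tables exist.
#'
#' @param ror_min_count Minimum `a` for an ROR flag (default 3).
#' @param z Two-sided normal quantile for the ROR CI (default 1.959964).
#' @param prr_min,prr_chi2_min,prr_min_count PRR flag thresholds.
#' @param ic_shrinkage Additive shrinkage constant of the IC (default 0.5).
#' @param ic025_min IC flag threshold on IC025 (default 0).
#' @param ebgm_prior Named numeric vector `(alpha1, beta1, alpha2, beta2, p)`.
#' @param eb05_min EBGM flag threshold on EB05 (default 2).
#' @param em_tol Relative log-likelihood convergence tolerance of the prior
#'   fit.
#' @param em_max_iter Maximum likelihood evaluations for the prior fit.
#' @param yates Apply Yates continuity correction to the PRR chi-square?
#' @return An `algorithm_config` list.
#' @export
algorithm_config <- function(ror_min_count = 3, z = 1.959964,
                             prr_min = 2, prr_chi2_min = 4,
                             prr_min_count = 3,
                             ic_shrinkage = 0.5, ic025_min = 0,
                             ebgm_prior = c(alpha1 = 0.2, beta1 = 0.1,
                                            alpha2 = 2, beta2 = 4,
                                            p = 1 / 3),
                             eb05_min = 2, em_tol = 1e-8,
                             em_max_iter = 10000, yates = FALSE) {
  stopifnot(
    ror_min_count >= 0, z > 0, prr_min > 0, prr_chi2_min >= 0,
    ic_shrinkage > 0, length(ebgm_prior) == 5, all(ebgm_prior[1:4] > 0),
    ebgm_prior[5] >= 0, ebgm_prior[5] <= 1, eb05_min > 0, em_tol > 0,
    em_max_iter > 0
  )
  names(ebgm_prior) <- c("alpha1", "beta1", "alpha2", "beta2", "p")
  structure(
    list(ror_min_count = ror_min_count, z = z, prr_min = prr_min,
         prr_chi2_min = prr_chi2_min, prr_min_count = prr_min_count,
         ic_shrinkage = ic_shrinkage, ic025_min = ic025_min,
         ebgm_prior = ebgm_prior, eb05_min = eb05_min, em_tol = em_tol,
         em_max_iter = em_max_iter, yates = yates),
    class = "algorithm_config"
  )
}

#' Reporting odds ratio with Wald confidence interval
#'
#' ROR = (a d)/(b c); the CI is `exp(log ROR +/- z * sqrt(1/a+1/b+1/c+1/d))`.
#' A table with `a = 0` yields ROR 0 with an undefined CI; any other zero
#' cell marks the statistic undefined (`NA`). The flag requires
#' `a >= ror_min_count` and a lower CI bound above 1.
#'
#' @param tables Tibble with columns `a`, `b`, `c`, `d` (one row per table).
#' @param cfg An [algorithm_config()].
#' @return `tables` with added columns `ror`, `ror_lo`, `ror_hi`, `ror_flag`.
#' @export
add_ror <- function(tables, cfg = algorithm_config()) {
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  c <- as.numeric(tables$c); d <- as.numeric(tables$d)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ifelse(a == 0, 0, ifelse(ok, a * d / (b * c), NA_real_))
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  lo <- ifelse(ok, exp(log(ror) - cfg$z * se), NA_real_)
  hi <- ifelse(ok, exp(log(ror) + cfg$z * se), NA_real_)
  tables$ror <- ror
  tables$ror_lo <- lo
  tables$ror_hi <- hi
  tables$ror_flag <- !is.na(lo) & a >= cfg$ror_min_count & lo > 1
  tables
}

#' Proportional reporting ratio with Pearson chi-square
#'
#' PRR = `[a/(a+b)] / [c/(c+d)]`; the chi-square is Pearson's on the 2x2
#' without continuity correction (Yates optional via the config). A table
#' with `c = 0` (event absent from the comparator) has an infinite PRR; the
#' flag can still fire on the count and chi-square conditions but the pair
#' is marked `prr_unstable`.
#'
#' @inheritParams add_ror
#' @return `tables` with added columns `prr`, `chi2`, `prr_flag`,
#'   `prr_unstable`.
#' @export
add_prr <- function(tables, cfg = algorithm_config()) {
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  c <- as.numeric(tables$c); d <- as.numeric(tables$d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  prr <- ifelse(r1 > 0 & r2 > 0 & c1 > 0,
                ifelse(c == 0, Inf, (a / r1) / (c / r2)), NA_real_)
  ok_chi <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  dev <- abs(a * d - b * c)
  if (cfg$yates) dev <- pmax(0, dev - n / 2)
  chi2 <- ifelse(ok_chi, n * dev^2 / (r1 * r2 * c1 * c2), NA_real_)
  tables$prr <- prr
  tables$chi2 <- chi2
  tables$prr_flag <- !is.na(prr) & !is.na(chi2) &
    a >= cfg$prr_min_count & prr >= cfg$prr_min & chi2 >= cfg$prr_chi2_min
  tables$prr_unstable <- !is.na(prr) & is.infinite(prr)
  tables
}

#' Information component with gamma credible bound
#'
#' IC = `log2((a + s)/(E + s))` with shrinkage constant `s` and expected
#' count `E = (a+b)(a+c)/N`. The lower credible bound IC025 is the 2.5%
#' quantile of `log2(lambda)` where `lambda ~ Gamma(a + s, rate = E + s)`
#' is the shrunk observed/expected reporting-rate posterior. The flag
#' requires IC025 above `ic025_min`. Pairs with `E = 0` (event absent) are
#' undefined.
#'
#' @inheritParams add_ror
#' @return `tables` with added columns `ic`, `ic025`, `ic_flag`.
#' @export
add_ic <- function(tables, cfg = algorithm_config()) {
  s <- cfg$ic_shrinkage
  a <- tables$a
  e <- expected_of(tables)
  ok <- e > 0
  ic <- ifelse(ok, log2((a + s) / (e + s)), NA_real_)
  ic025 <- ifelse(ok, log2(qgamma(0.025, shape = a + s, rate = e + s)),
                  NA_real_)
  tables$ic <- ic
  tables$ic025 <- ic025
  tables$ic_flag <- !is.na(ic025) & ic025 > cfg$ic025_min
  tables
}

expected_of <- function(tables) {
  if ("expected" %in% names(tables)) return(tables$expected)
  with(tables, (a + b) * (a + c) / (a + b + c + d))
}

# log marginal likelihood of counts a with exposures e under the
# two-component gamma-Poisson mixture (negative binomial marginals)
ebgm_loglik <- function(par, a, e) {
  lw1 <- log(par[["p"]]) +
    dnbinom(a, size = par[["alpha1"]],
            prob = par[["beta1"]] / (par[["beta1"]] + e), log = TRUE)
  lw2 <- log1p(-par[["p"]]) +
    dnbinom(a, size = par[["alpha2"]],
            prob = par[["beta2"]] / (par[["beta2"]] + e), log = TRUE)
  m <- pmax(lw1, lw2)
  sum(m + log(exp(lw1 - m) + exp(lw2 - m)))
}

#' Fit the EBGM two-component gamma-Poisson prior by marginal likelihood
#'
#' The observed counts `a_i` of all drug-event tables are modelled as
#' Poisson with mean `lambda_i E_i`, where the relative reporting rate
#' `lambda_i` follows a two-component gamma mixture prior
#' `p Gamma(alpha1, beta1) + (1-p) Gamma(alpha2, beta2)` (rate
#' parameterisation). Marginally each `a_i` is a mixture of negative
#' binomials; the five hyperparameters maximise this marginal likelihood by
#' direct numerical optimisation (Nelder-Mead on log/logit-transformed
#' parameters, relative tolerance `em_tol`). With fewer than 50 usable
#' tables (`E > 0`) the configured default prior is returned with a warning.
#'
#' @param tables Tibble of contingency tables (`a`, `b`, `c`, `d`, and
#'   optionally `expected`).
#' @param cfg An [algorithm_config()]; its `ebgm_prior` is the starting
#'   point and the fallback.
#' @return An object of class `ebgm_prior`: a list with `alpha1`, `beta1`,
#'   `alpha2`, `beta2`, `p`, `loglik`, `n_tables`, `fitted` (FALSE for the
#'   fallback), `counts` (optimiser evaluation counts), and `prior_mean`.
#' @export
fit_ebgm_prior <- function(tables, cfg = algorithm_config()) {
  e <- expected_of(tables)
  keep <- !is.na(e) & e > 0 & !is.na(tables$a)
  a <- tables$a[keep]
  e <- e[keep]
  default <- cfg$ebgm_prior
  if (length(a) < 50) {
    warn(paste0("only ", length(a),
                " usable tables (E > 0); returning the default prior"))
    return(new_ebgm_prior(default, loglik = NA_real_, n_tables = length(a),
                          fitted = FALSE, counts = c(`function` = 0L)))
  }
  to_par <- function(theta) {
    c(alpha1 = exp(theta[1]), beta1 = exp(theta[2]),
      alpha2 = exp(theta[3]), beta2 = exp(theta[4]),
      p = stats::plogis(theta[5]))
  }
  nll <- function(theta) -ebgm_loglik(to_par(theta), a, e)
  start <- c(log(default[["alpha1"]]), log(default[["beta1"]]),
             log(default[["alpha2"]]), log(default[["beta2"]]),
             stats::qlogis(default[["p"]]))
  fit <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = cfg$em_max_iter, reltol = cfg$em_tol))
  # Nelder-Mead simplexes can degenerate (code 10); restart from the last
  # iterate, which re-expands the simplex around it
  restarts <- 0L
  while (fit$convergence == 10 && restarts < 5L) {
    fit <- optim(fit$par, nll, method = "Nelder-Mead",
                 control = list(maxit = cfg$em_max_iter,
                                reltol = cfg$em_tol))
    restarts <- restarts + 1L
  }
  if (fit$convergence != 0) {
    abort(
      paste0("EBGM prior fit did not converge (code ", fit$convergence,
             "); last log-likelihood ", format(-fit$value)),
      class = "adcvigil_convergence_error",
      last_iterate = to_par(fit$par)
    )
  }
  new_ebgm_prior(to_par(fit$par), loglik = -fit$value,
                 n_tables = length(a), fitted = TRUE, counts = fit$counts)
}

new_ebgm_prior <- function(par, loglik, n_tables, fitted, counts) {
  structure(
    list(alpha1 = unname(par[["alpha1"]]), beta1 = unname(par[["beta1"]]),
         alpha2 = unname(par[["alpha2"]]), beta2 = unname(par[["beta2"]]),
         p = unname(par[["p"]]), loglik = loglik, n_tables = n_tables,
         fitted = fitted, counts = counts,
         prior_mean = unname(par[["p"]] * par[["alpha1"]] / par[["beta1"]] +
                               (1 - par[["p"]]) * par[["alpha2"]] / par[["beta2"]])),
    class = "ebgm_prior"
  )
}

#' @export
print.ebgm_prior <- function(x, ...) {
  cat("Two-component gamma-Poisson prior",
      if (x$fitted) "(fitted)" else "(default, fallback)", "\n")
  cat(sprintf("  Gamma(%.4g, %.4g) w = %.3f | Gamma(%.4g, %.4g) w = %.3f\n",
              x$alpha1, x$beta1, x$p, x$alpha2, x$beta2, 1 - x$p))
  cat(sprintf("  prior mean %.4g, n_tables %d, logLik %.4g\n",
              x$prior_mean, x$n_tables, x$loglik))
  invisible(x)
}

# posterior mixture weights and component parameters for one (a, E)
ebgm_posterior <- function(a, e, prior) {
  lw1 <- log(prior$p) +
    dnbinom(a, size = prior$alpha1,
            prob = prior$beta1 / (prior$beta1 + e), log = TRUE)
  lw2 <- log1p(-prior$p) +
    dnbinom(a, size = prior$alpha2,
            prob = prior$beta2 / (prior$beta2 + e), log = TRUE)
  m <- pmax(lw1, lw2)
  q1 <- exp(lw1 - m) / (exp(lw1 - m) + exp(lw2 - m))
  list(q1 = q1, shape1 = prior$alpha1 + a, rate1 = prior$beta1 + e,
       shape2 = prior$alpha2 + a, rate2 = prior$beta2 + e)
}

#' Empirical Bayes geometric mean and EB05
#'
#' The posterior of the relative reporting rate is a two-component gamma
#' mixture with components `Gamma(alpha_j + a, beta_j + E)` and weights
#' proportional to the prior weights times the negative binomial evidence.
#' EBGM is the geometric mean `exp(E[log lambda])` computed from the
#' digamma function; EB05 is the 5% posterior quantile found by monotone
#' root-finding on the mixture CDF (bracket `[1e-8, 10 max(a/E, prior
#' mean)]`, bisection to 1e-10 relative tolerance). The flag requires EB05
#' above `eb05_min`. Pairs with `E = 0` are undefined.
#'
#' @inheritParams add_ror
#' @param prior An `ebgm_prior` object (from [fit_ebgm_prior()]) or `NULL`
#'   to use the config default.
#' @return `tables` with added columns `ebgm`, `eb05`, `ebgm_flag`.
#' @export
add_ebgm <- function(tables, prior = NULL, cfg = algorithm_config()) {
  if (is.null(prior)) {
    prior <- new_ebgm_prior(cfg$ebgm_prior, loglik = NA_real_,
                            n_tables = 0L, fitted = FALSE,
                            counts = c(`function` = 0L))
  }
  a <- tables$a
  e <- expected_of(tables)
  ok <- !is.na(e) & e > 0 & !is.na(a)
  ebgm <- rep(NA_real_, length(a))
  eb05 <- rep(NA_real_, length(a))
  if (any(ok)) {
    po <- ebgm_posterior(a[ok], e[ok], prior)
    ebgm[ok] <- exp(
      po$q1 * (digamma(po$shape1) - log(po$rate1)) +
        (1 - po$q1) * (digamma(po$shape2) - log(po$rate2))
    )
    eb05[ok] <- mixture_gamma_quantile(0.05, po$q1, po$shape1, po$rate1,
                                       po$shape2, po$rate2,
                                       upper0 = 10 * pmax(a[ok] / e[ok],
                                                          prior$prior_mean))
  }
  tables$ebgm <- ebgm
  tables$eb05 <- eb05
  tables$ebgm_flag <- !is.na(eb05) & eb05 > cfg$eb05_min
  tables
}

# vectorised quantile of a two-component gamma mixture by root-finding
mixture_gamma_quantile <- function(prob, q1, shape1, rate1, shape2, rate2,
                                   upper0) {
  n <- length(q1)
  out <- numeric(n)
  for (i in seq_len(n)) {
    cdf <- function(x) {
      q1[i] * pgamma(x, shape1[i], rate = rate1[i]) +
        (1 - q1[i]) * pgamma(x, shape2[i], rate = rate2[i]) - prob
    }
    lo <- 1e-8
    while (cdf(lo) > 0 && lo > .Machine$double.xmin * 1e4) lo <- lo / 100
    hi <- max(upper0[i], 1e-6)
    while (cdf(hi) < 0) hi <- hi * 10
    out[i] <- uniroot(cdf, c(lo, hi), tol = 1e-10 * max(1, hi))$root
  }
  out
}

#' Score tables with all four disproportionality methods
#'
#' Convenience wrapper applying [add_ror()], [add_prr()], [add_ic()] and
#' [add_ebgm()], then the multi-method consensus flag `mcc` (the
#' conjunction of the four per-method flags; any undefined flag makes the
#' pair non-consensus).
#'
#' @inheritParams add_ebgm
#' @return The scored tibble with all statistic, flag and `mcc` columns.
#' @export
score_tables <- function(tables, prior = NULL, cfg = algorithm_config()) {
  tables %>%
    add_ror(cfg) %>%
    add_prr(cfg) %>%
    add_ic(cfg) %>%
    add_ebgm(prior, cfg) %>%
    mutate(mcc = .data$ror_flag & .data$prr_flag & .data$ic_flag &
             .data$ebgm_flag)
}
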