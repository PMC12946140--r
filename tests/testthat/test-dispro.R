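tbl <- function(a, b, c, d) tibble::tibble(a = a, b = b, c = c, d = d)

test_that("ROR matches cross-product arithmetic and the log-OR interval", {
  t1 <- add_ror(tbl(5, 5, 5, 5))
  expect_equal(t1$ror, 1)
  expect_false(t1$ror_flag)

  t2 <- add_ror(tbl(10, 90, 100, 9900))
  expect_equal(t2$ror, 11)
  # independent log-odds-ratio oracle for the Wald interval
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(t2$ror_lo, exp(log(11) - qnorm(0.975) * se),
               tolerance = 1e-6)
  expect_equal(t2$ror_hi, exp(log(11) + qnorm(0.975) * se),
               tolerance = 1e-6)
  expect_true(t2$ror_flag)

  # count threshold: ror = 20 but a < 3 blocks the flag
  t3 <- add_ror(tbl(2, 10, 10, 1000))
  expect_equal(t3$ror, 20)
  expect_false(t3$ror_flag)

  # undefined cells: a = 0 gives ror 0; zero b/c/d marks NA
  t4 <- add_ror(tbl(c(0, 5, 5), c(5, 0, 5), c(5, 5, 0), c(5, 5, 5)))
  expect_equal(t4$ror[1], 0)
  expect_true(all(is.na(t4$ror[2:3])))
  expect_false(any(t4$ror_flag))
})

test_that("ROR is invariant under table transposition", {
  set.seed(42)
  for (i in 1:25) {
    cells <- rpois(4, 20) + 1
    orig <- add_ror(tbl(cells[1], cells[2], cells[3], cells[4]))
    tran <- add_ror(tbl(cells[1], cells[3], cells[2], cells[4]))
    expect_equal(orig$ror, tran$ror)
  }
})

test_that("PRR matches ratio arithmetic and the Pearson chi-square oracle", {
  t1 <- add_prr(tbl(20, 80, 20, 80))
  expect_equal(t1$prr, 1)
  expect_equal(t1$chi2, 0)
  expect_false(t1$prr_flag)

  t2 <- add_prr(tbl(10, 90, 100, 9900))
  expect_equal(t2$prr, 10)
  oracle <- suppressWarnings(
    chisq.test(matrix(c(10, 90, 100, 9900), 2, byrow = TRUE),
               correct = FALSE)
  )
  expect_equal(t2$chi2, unname(oracle$statistic))
  expect_true(t2$prr_flag)

  # c = 0: PRR infinite-marked, chi-square still computed, pair unstable
  t3 <- add_prr(tbl(3, 0, 1, 1000))
  expect_equal(t3$prr, (3 / 3) / (1 / 1001))
  expect_false(t3$prr_unstable)
  t4 <- add_prr(tbl(3, 7, 0, 1000))
  expect_true(is.infinite(t4$prr))
  expect_true(t4$prr_unstable)
  expect_false(is.na(t4$chi2))

  # random tables agree with the chisq.test oracle
  set.seed(7)
  for (i in 1:20) {
    cells <- rpois(4, 15) + 1
    mine <- add_prr(tbl(cells[1], cells[2], cells[3], cells[4]))
    orc <- suppressWarnings(chisq.test(matrix(cells, 2, byrow = TRUE),
                                       correct = FALSE))
    expect_equal(mine$chi2, unname(orc$statistic), tolerance = 1e-10)
  }
  # Yates option matches the corrected oracle
  y <- add_prr(tbl(12, 5, 7, 30), algorithm_config(yates = TRUE))
  orc_y <- suppressWarnings(chisq.test(matrix(c(12, 5, 7, 30), 2,
                                               byrow = TRUE),
                                     correct = TRUE))
  expect_equal(y$chi2, unname(orc_y$statistic), tolerance = 1e-10)
})

test_that("IC follows the shrinkage closed form with gamma credible bound", {
  # a = E exactly -> IC 0
  t0 <- add_ic(tbl(10, 90, 10, 890))   # E = 100*20/1000 = 2 ... build exact
  # construct a table with a = E: a=5,b=45,c=95,d=855 -> E = 50*100/1000 = 5
  te <- add_ic(tbl(5, 45, 95, 855))
  expect_equal(te$ic, 0)

  # closed-form worked example: a=8, E=1 -> log2(8.5/1.5)
  t1 <- tibble::tibble(a = 8, b = 2, c = 2, d = 28,
                       expected = 1)
  r1 <- add_ic(t1)
  expect_equal(r1$ic, log2(8.5 / 1.5), tolerance = 1e-12)

  # deficit direction: a=0, E=4 -> negative, never flagged
  t2 <- tibble::tibble(a = 0, b = 10, c = 40, d = 50, expected = 4)
  r2 <- add_ic(t2)
  expect_equal(r2$ic, log2(0.5 / 4.5))
  expect_false(r2$ic_flag)
  expect_lt(r2$ic025, r2$ic)
})

test_that("IC025 and EB05 match Monte-Carlo posterior quantiles", {
  # grid of (a, E); 1e6 draws per point; agreement within 0.01
  grid <- expand.grid(a = c(1, 3, 10, 100), e = c(0.1, 1, 10))
  cfg <- algorithm_config()
  prior <- adcvigil:::new_ebgm_prior(cfg$ebgm_prior, NA_real_, 0L, FALSE,
                                     c(`function` = 0L))
  withr::with_seed(99, {
    for (i in seq_len(nrow(grid))) {
      a <- grid$a[i]; e <- grid$e[i]
      t <- tibble::tibble(a = a, b = 10, c = 10, d = 10, expected = e)
      r <- add_ic(t, cfg)
      draws <- rgamma(1e6, shape = a + 0.5, rate = e + 0.5)
      mc_ic025 <- log2(quantile(draws, 0.025, names = FALSE))
      expect_equal(r$ic025, mc_ic025, tolerance = 0.01,
                   info = paste("ic025 a,E =", a, e))

      r2 <- add_ebgm(t, prior = prior, cfg = cfg)
      po <- adcvigil:::ebgm_posterior(a, e, prior)
      comp <- rbinom(1e6, 1, po$q1)
      draws2 <- ifelse(comp == 1,
                       rgamma(1e6, po$shape1, rate = po$rate1),
                       rgamma(1e6, po$shape2, rate = po$rate2))
      mc_eb05 <- quantile(draws2, 0.05, names = FALSE)
      expect_equal(r2$eb05, mc_eb05, tolerance = 0.012,
                   info = paste("eb05 a,E =", a, e))
      mc_ebgm <- exp(mean(log(draws2)))
      expect_equal(r2$ebgm, mc_ebgm, tolerance = 0.02,
                   info = paste("ebgm a,E =", a, e))
    }
  })
})

test_that("EBGM degenerate-prior closed form and large-count limit hold", {
  # single-component prior Gamma(1,1), a=0, E=1 -> posterior Gamma(1,2):
  # geometric mean exp(digamma(1) - log 2)
  prior <- adcvigil:::new_ebgm_prior(
    c(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1, p = 1),
    NA_real_, 0L, FALSE, c(`function` = 0L)
  )
  t <- tibble::tibble(a = 0, b = 1, c = 1, d = 1, expected = 1)
  r <- add_ebgm(t, prior = prior)
  expect_equal(r$ebgm, exp(digamma(1) - log(2)), tolerance = 1e-8)

  # large counts: shrinkage vanishes, EBGM -> a/E
  t2 <- tibble::tibble(a = 1000, b = 1, c = 1, d = 1, expected = 100)
  r2 <- add_ebgm(t2, prior = prior)
  expect_equal(r2$ebgm, 10, tolerance = 0.02)

  # small-count strong shrinkage: a=1, E=0.1 stays far below a/E = 10
  cfg <- algorithm_config()
  dprior <- adcvigil:::new_ebgm_prior(cfg$ebgm_prior, NA_real_, 0L, FALSE,
                                      c(`function` = 0L))
  r3 <- add_ebgm(tibble::tibble(a = 1, b = 1, c = 1, d = 1,
                                expected = 0.1), prior = dprior)
  expect_lt(r3$ebgm, 5)
})

test_that("statistics are monotone in a at fixed b, c, d", {
  cfg <- algorithm_config()
  prior <- adcvigil:::new_ebgm_prior(cfg$ebgm_prior, NA_real_, 0L, FALSE,
                                     c(`function` = 0L))
  a_seq <- 1:30
  t <- tibble::tibble(a = a_seq, b = 50, c = 40, d = 800)
  scored <- add_ebgm(add_ic(add_prr(add_ror(t, cfg), cfg), cfg),
                     prior, cfg)
  expect_true(all(diff(scored$ror) > 0))
  expect_true(all(diff(scored$prr) > 0))
  expect_true(all(diff(scored$ic) > 0))
  expect_true(all(diff(scored$ebgm) > 0))
})

test_that("shrinkage ordering: eb05 <= ebgm, between prior mean and a/E", {
  prior <- adcvigil:::new_ebgm_prior(
    c(alpha1 = 2, beta1 = 4, alpha2 = 2, beta2 = 4, p = 1),
    NA_real_, 0L, FALSE, c(`function` = 0L)
  )
  set.seed(11)
  for (i in 1:20) {
    a <- rpois(1, 10) + 1
    e <- runif(1, 0.5, 20)
    r <- add_ebgm(tibble::tibble(a = a, b = 1, c = 1, d = 1,
                                 expected = e), prior = prior)
    expect_lte(r$eb05, r$ebgm)
    # EBGM is a geometric mean, so the relevant prior anchor is the prior
    # geometric mean exp(digamma(alpha))/beta, not the arithmetic mean
    prior_geo <- exp(digamma(2)) / 4
    lo <- min(prior_geo, a / e)
    hi <- max(prior$prior_mean, a / e)
    expect_gte(r$ebgm, lo * 0.999)
    expect_lte(r$ebgm, hi * 1.001)
  }
})

test_that("the gamma-Poisson prior fit recovers a single-gamma truth", {
  # tables drawn from lambda ~ Gamma(2, rate 4) (prior mean 0.5)
  withr::with_seed(123, {
    n <- 20000
    e <- exp(runif(n, log(0.5), log(20)))
    lam <- rgamma(n, 2, rate = 4)
    a <- rpois(n, lam * e)
  })
  tabs <- tibble::tibble(a = a, b = 1, c = 1, d = 1, expected = e)
  fit <- fit_ebgm_prior(tabs)
  expect_true(fit$fitted)
  expect_equal(fit$prior_mean, 0.5, tolerance = 0.1)
  # tidiers expose the fit
  td <- tidy(fit)
  expect_equal(td$term, c("alpha1", "beta1", "alpha2", "beta2", "p"))
  gl <- glance(fit)
  expect_equal(gl$n_tables, n)
  expect_true(is.finite(gl$logLik))
})

test_that("a Poisson(E) world fits to a prior mean near 1", {
  withr::with_seed(124, {
    n <- 5000
    e <- exp(runif(n, log(1), log(30)))
    a <- rpois(n, e)
  })
  fit <- fit_ebgm_prior(tibble::tibble(a = a, expected = e,
                                       b = 1, c = 1, d = 1))
  expect_equal(fit$prior_mean, 1, tolerance = 0.05)
})

test_that("too few usable tables fall back to the default prior", {
  tabs <- tibble::tibble(a = rep(1, 10), b = 1, c = 1, d = 1,
                         expected = rep(1, 10))
  expect_warning(fit <- fit_ebgm_prior(tabs), "default prior")
  expect_false(fit$fitted)
  expect_equal(fit$alpha1, 0.2)
  expect_equal(fit$p, 1 / 3)
})
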