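test_that("bridge sampling matches the analytic conjugate marginal likelihood", {
  tab <- toy_regression_table(n = 30, beta = 0.3, sigma = 2, seed = 41)
  spec <- toy_spec(prior_spec("normal", 0, 0.2), sigma = 2)
  fit <- fit_model(tab, spec, chains = 2, iterations = 2000, warmup = 500,
                   seed = 42)
  ev <- log_marginal_likelihood(fit, spec, tab, seed = 43)
  lml <- conjugate_lml_oracle(tab$amplitude, cbind(1, tab$xx), 2, c(25, 0.04))
  expect_lt(abs(ev$log_ml - lml), 0.05)
  expect_gt(ev$log_ml_mc_error, 0)
})

test_that("the truncated-prior marginal likelihood carries the normalization", {
  tab <- toy_regression_table(n = 30, beta = -0.3, sigma = 2, seed = 44)
  spec <- toy_spec(bf_prior(0.2, "negative_only"), sigma = 2)
  fit <- fit_model(tab, spec, chains = 2, iterations = 2000, warmup = 500,
                   seed = 45)
  ev <- log_marginal_likelihood(fit, spec, tab, seed = 46)
  lml <- conjugate_lml_oracle(tab$amplitude, cbind(1, tab$xx), 2, c(25, 0.04),
                              side = "negative_only")
  expect_lt(abs(ev$log_ml - lml), 0.05)
})

test_that("a model compared with itself gives BF 1 within MC error", {
  tab <- toy_regression_table(n = 30, seed = 47)
  spec <- toy_spec(sigma = 2)
  fit <- fit_model(tab, spec, chains = 2, iterations = 1500, warmup = 400,
                   seed = 48)
  ev1 <- log_marginal_likelihood(fit, spec, tab, seed = 49)
  ev2 <- log_marginal_likelihood(fit, spec, tab, seed = 50)
  bf <- bayes_factor(ev1, ev2)
  tol <- 2 * (ev1$log_ml_mc_error + ev2$log_ml_mc_error) + 1e-3
  expect_lt(abs(bf$log_bf), tol)
  expect_equal(bf$classification, "inconclusive")
})

test_that("more posterior draws reduce the bridge MC error", {
  tab <- toy_regression_table(n = 30, seed = 51)
  spec <- toy_spec(sigma = 2)
  small <- fit_model(tab, spec, chains = 2, iterations = 450, warmup = 200,
                     seed = 52)
  big <- fit_model(tab, spec, chains = 2, iterations = 4200, warmup = 200,
                   seed = 52)
  e_small <- log_marginal_likelihood(small, spec, tab, seed = 53)
  e_big <- log_marginal_likelihood(big, spec, tab, seed = 53)
  expect_lt(e_big$log_ml_mc_error, e_small$log_ml_mc_error)
})

test_that("bridge estimate is invariant to posterior-draw thinning", {
  tab <- toy_regression_table(n = 30, seed = 54)
  spec <- toy_spec(sigma = 2)
  fit <- fit_model(tab, spec, chains = 2, iterations = 4200, warmup = 200,
                   seed = 55)
  ev_full <- log_marginal_likelihood(fit, spec, tab, seed = 56)
  thinned <- fit
  thinned$draws <- fit$draws[seq(1, 4000, by = 4), , , drop = FALSE]
  ev_thin <- log_marginal_likelihood(thinned, spec, tab, seed = 56)
  tol <- 3 * (ev_full$log_ml_mc_error + ev_thin$log_ml_mc_error) + 0.01
  expect_lt(abs(ev_full$log_ml - ev_thin$log_ml), tol)
})

test_that("bayes_factor classifications follow the evidence scale", {
  mk <- function(lml) structure(list(log_ml = lml, log_ml_mc_error = 0.01,
                                     fingerprint = c(n = 1)),
                                class = "evidence_result")
  expect_equal(bayes_factor(mk(-100), mk(-100))$bf10, 1)
  expect_equal(bayes_factor(mk(-100), mk(-100))$classification,
               "inconclusive")
  b10 <- bayes_factor(mk(-90), mk(-90 - log(10)))
  expect_equal(b10$bf10, 10)
  expect_equal(b10$classification, "strong H1")
  expect_equal(bayes_factor(mk(0), mk(log(1 / 17.17)))$classification,
               "strong H1")
  expect_equal(bayes_factor(mk(log(0.76)), mk(0))$classification,
               "inconclusive")
  expect_equal(bayes_factor(mk(log(0.2)), mk(0))$classification,
               "supports H0")
  expect_equal(bayes_factor(mk(log(25)), mk(0))$classification, "strong H1")
  bad <- mk(-1); bad$fingerprint <- c(n = 2)
  expect_error(bayes_factor(mk(-1), bad), "fingerprints")
})

test_that("BF decreases with prior scale on null data (Occam factor)", {
  set.seed(57)
  n <- 80
  x <- rnorm(n)
  tab <- data.frame(amplitude = rnorm(n, 0, 0.5), xx = x,
                    subject_id = "s1", item_id = "i1")
  bfs <- vapply(c(0.2, 0.8, 2), function(sc) {
    spec <- toy_spec(prior_spec("normal", 0, sc), sigma = 0.5)
    bf_for_term(tab, spec, "xx", chains = 2, iterations = 1200,
                warmup = 300, seed = 58)$bf10
  }, 0)
  expect_true(all(diff(bfs) < 0))
  ## and the analytic oracle agrees with each point within 10%
  for (i in seq_along(bfs)) {
    sc <- c(0.2, 0.8, 2)[i]
    lml1 <- conjugate_lml_oracle(tab$amplitude, cbind(1, x), 0.5, c(25, sc^2))
    lml0 <- conjugate_lml_oracle(tab$amplitude, matrix(1, nrow(tab), 1), 0.5, 25)
    expect_equal(bfs[i], exp(lml1 - lml0), tolerance = 0.1)
  }
})

test_that("a truncated prior on the effect's side beats the untruncated one", {
  set.seed(59)
  n <- 80
  x <- rnorm(n)
  tab <- data.frame(amplitude = -0.4 * x + rnorm(n, 0, 0.5), xx = x,
                    subject_id = "s1", item_id = "i1")
  bf_t <- bf_for_term(tab, toy_spec(bf_prior(0.4, "negative_only"), 0.5),
                      "xx", chains = 2, iterations = 1200, warmup = 300,
                      seed = 60)$bf10
  bf_u <- bf_for_term(tab, toy_spec(bf_prior(0.4, "none"), 0.5),
                      "xx", chains = 2, iterations = 1200, warmup = 300,
                      seed = 60)$bf10
  expect_gt(bf_t, bf_u)
  ## analytically the one-sided BF is twice the two-sided one here (the
  ## posterior mass on the favoured side is ~1)
  expect_equal(bf_t / bf_u, 2, tolerance = 0.1)
})

test_that("sensitivity sweep single point agrees with a direct BF call", {
  sim <- simulate_study(6, 12, seed = 61)
  tab <- sim$trials
  spec <- model_spec()
  sw <- sensitivity_sweep(tab, spec, "entropy_centered", scales = 0.3,
                          variants = "truncated", chains = 2,
                          iterations = 900, warmup = 300, seed = 62)
  expect_equal(nrow(sw), 1)
  direct <- bf_for_term(tab, set_term_prior(spec, "entropy_centered",
                                            bf_prior(0.3, "negative_only")),
                        "entropy_centered", chains = 2, iterations = 900,
                        warmup = 300, seed = 63)
  ## two MC estimates of the same quantity
  expect_equal(log(sw$bf10), log(direct$bf10), tolerance = 0.25)
})

test_that("Savage-Dickey agrees with the analytic and bridge Bayes factors", {
  tab <- toy_regression_table(n = 50, beta = 0.15, sigma = 2, seed = 64)
  spec <- toy_spec(prior_spec("normal", 0, 0.2), sigma = 2)
  fit <- fit_model(tab, spec, chains = 2, iterations = 4200, warmup = 700,
                   seed = 65)
  sd_bf <- savage_dickey_check(fit, prior_spec("normal", 0, 0.2), "xx")
  lml1 <- conjugate_lml_oracle(tab$amplitude, cbind(1, tab$xx), 2,
                               c(25, 0.04))
  lml0 <- conjugate_lml_oracle(tab$amplitude, matrix(1, nrow(tab), 1), 2, 25)
  bf_analytic <- exp(lml1 - lml0)
  expect_equal(sd_bf$bf10, bf_analytic, tolerance = 0.1)
  ev1 <- log_marginal_likelihood(fit, spec, tab, seed = 66)
  ## bridge BF via the package route
  spec0 <- drop_term(spec, "xx")
  f0 <- fit_model(tab, spec0, chains = 2, iterations = 2000, warmup = 400,
                  seed = 67)
  ev0 <- log_marginal_likelihood(f0, spec0, tab, seed = 67)
  bf_bridge <- exp(ev1$log_ml - ev0$log_ml)
  expect_equal(sd_bf$bf10, bf_bridge, tolerance = 0.15)
  ## truncated priors are rejected
  expect_error(savage_dickey_check(fit, bf_prior(0.2, "negative_only"), "xx"),
               "untruncated")
})

test_that("Savage-Dickey BF10 vanishes as the prior widens on null data", {
  tab <- toy_regression_table(n = 60, beta = 0, sigma = 1, seed = 68)
  bfs <- vapply(c(0.5, 5, 50), function(sc) {
    spec <- toy_spec(prior_spec("normal", 0, sc), sigma = 1)
    fit <- fit_model(tab, spec, chains = 2, iterations = 1500, warmup = 400,
                     seed = 69)
    savage_dickey_check(fit, prior_spec("normal", 0, sc), "xx")$bf10
  }, 0)
  expect_true(all(diff(bfs) < 0))
  expect_lt(bfs[3], 0.1)
})

test_that("one-sided prior densities integrate to one (quadrature)", {
  for (sc in c(0.2, 1, 2)) {
    pneg <- bf_prior(sc, "negative_only")
    q <- stats::integrate(function(x) exp(prior_logdens(x, pneg)),
                          -Inf, 0, rel.tol = 1e-10)
    expect_lt(abs(q$value - 1), 1e-8)
    ppos <- prior_spec("truncated_normal", 8, 2, "positive_only")
    q2 <- stats::integrate(function(x) exp(prior_logdens(x, ppos)),
                           0, Inf, rel.tol = 1e-10)
    expect_lt(abs(q2$value - 1), 1e-8)
  }
  ## the CPC prior for LKJ(2), q = 3, integrates to 1 per component
  a <- cpc_alpha(3, 2)
  for (m in 1:3) {
    q3 <- stats::integrate(function(z)
      exp(dbeta((z + 1) / 2, a[m], a[m], log = TRUE) - log(2)), -1, 1,
      rel.tol = 1e-10)
    expect_lt(abs(q3$value - 1), 1e-8)
  }
})

test_that("adding an irrelevant wide-prior predictor lowers the log ML", {
  wins <- 0
  for (s in 1:5) {
    set.seed(70 + s)
    n <- 60
    x <- rnorm(n)
    tab <- data.frame(amplitude = rnorm(n, 0, 1), xx = x,
                      subject_id = "s1", item_id = "i1")
    spec1 <- toy_spec(prior_spec("normal", 0, 2), sigma = 1)
    f1 <- fit_model(tab, spec1, chains = 2, iterations = 1200, warmup = 300,
                    seed = 71 + s)
    e1 <- log_marginal_likelihood(f1, spec1, tab, seed = 72 + s)
    spec0 <- drop_term(spec1, "xx")
    f0 <- fit_model(tab, spec0, chains = 2, iterations = 1200, warmup = 300,
                    seed = 73 + s)
    e0 <- log_marginal_likelihood(f0, spec0, tab, seed = 74 + s)
    if (e1$log_ml <= e0$log_ml) wins <- wins + 1
  }
  expect_gte(wins, 3)  # majority criterion over seeds
})
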