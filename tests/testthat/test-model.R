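test_that("posterior matches the conjugate closed form without random effects", {
  tab <- toy_regression_table(n = 60, beta = 0.4, sigma = 2, seed = 21)
  spec <- toy_spec(prior_spec("normal", 0, 0.2), sigma = 2)
  fit <- fit_model(tab, spec, chains = 2, iterations = 3000, warmup = 500,
                   seed = 22)
  o <- conjugate_oracle(tab$amplitude, cbind(1, tab$xx), 2, c(25, 0.04))
  s <- summarize_posterior(fit)
  got_mean <- s$mean[match(c("b_Intercept", "b_xx"), s$parameter)]
  got_sd <- s$sd[match(c("b_Intercept", "b_xx"), s$parameter)]
  ## means agree to 5% of the posterior SD (the MC-error scale); SDs to 2%
  expect_true(all(abs(got_mean - o$mean) < 0.05 * o$sd))
  expect_equal(got_sd, o$sd, tolerance = 0.02)
})

test_that("hierarchical fit recovers a strong slope and the residual SD", {
  truth <- truth_params(beta_constraint = -2, sigma_residual = 3,
                        sigma_subject = c(0.8, 0.2, 0.2), sigma_item = 0.4)
  sim <- simulate_study(12, 24, truth, seed = 23)
  fit <- fit_model(sim$trials, model_spec(), chains = 2, iterations = 1200,
                   warmup = 400, seed = 24)
  s <- summarize_posterior(fit)
  b <- s[s$parameter == "b_entropy_centered", ]
  expect_lt(b$lower, -2 + 3 * b$sd)
  expect_gt(b$upper, -2 - 3 * b$sd)
  sres <- s[s$parameter == "sigma_res", ]
  expect_lt(abs(sres$mean - 3), 4 * sres$sd)
  ## lme4 as an independent point-estimate oracle for the slope
  skip_if_not_installed("lme4")
  lf <- lme4::lmer(
    amplitude ~ entropy_centered + log2_cloze_centered +
      (1 + entropy_centered + log2_cloze_centered | subject_id) +
      (1 | item_id),
    data = sim$trials,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore"))
  b_lmer <- lme4::fixef(lf)[["entropy_centered"]]
  expect_lt(abs(b$mean - b_lmer), 3 * b$sd)
})

test_that("truncated effect priors constrain the posterior support", {
  tab <- toy_regression_table(n = 40, beta = 0.05, sigma = 2, seed = 25)
  spec <- toy_spec(bf_prior(0.2, "negative_only"), sigma = 2)
  fit <- fit_model(tab, spec, chains = 2, iterations = 1000, warmup = 300,
                   seed = 26)
  expect_true(all(fit$draws[, , "b_xx"] < 0))
})

test_that("subject-label exchange leaves fixed-effect posteriors unchanged", {
  sim <- simulate_study(8, 16, seed = 27)
  tab <- sim$trials
  fit1 <- fit_model(tab, model_spec(), chains = 2, iterations = 1200,
                    warmup = 400, seed = 28)
  tab2 <- tab
  perm <- setNames(sample(unique(tab$subject_id)), unique(tab$subject_id))
  tab2$subject_id <- unname(perm[tab$subject_id])
  fit2 <- fit_model(tab2, model_spec(), chains = 2, iterations = 1200,
                    warmup = 400, seed = 28)
  for (p in c("b_Intercept", "b_entropy_centered")) {
    m1 <- mean(fit1$draws[, , p]); m2 <- mean(fit2$draws[, , p])
    mcse <- sd(fit1$draws[, , p]) / sqrt(ess(fit1$draws[, , p])[["bulk"]])
    expect_lt(abs(m1 - m2), 6 * mcse)
  }
})

test_that("with well-identified data, 10x wider priors barely move the
          posterior (likelihood dominance)", {
  truth <- truth_params(beta_constraint = -1.5, sigma_residual = 1,
                        sigma_subject = c(0.3, 0.1, 0.1), sigma_item = 0.2)
  sim <- simulate_study(10, 20, truth, seed = 29)
  spec_narrow <- model_spec()
  wide <- default_priors()
  wide$intercept$scale <- 50
  wide$beta <- lapply(wide$beta, function(p) { p$scale <- 10; p })
  spec_wide <- model_spec(priors = wide)
  f1 <- fit_model(sim$trials, spec_narrow, chains = 2, iterations = 1200,
                  warmup = 400, seed = 30)
  f2 <- fit_model(sim$trials, spec_wide, chains = 2, iterations = 1200,
                  warmup = 400, seed = 31)
  for (p in c("b_entropy_centered", "b_log2_cloze_centered")) {
    d1 <- f1$draws[, , p]
    expect_lt(abs(mean(d1) - mean(f2$draws[, , p])), sd(d1))
  }
})

test_that("check_convergence verdicts follow the Rhat and ESS thresholds", {
  set.seed(32)
  ## two well-mixed chains of white noise at high n: pass
  good <- array(rnorm(2 * 6000), c(3000, 2, 1),
                dimnames = list(NULL, NULL, "theta"))
  rep_good <- check_convergence(good, rhat_max = 1.01, ess_min = 2000)
  expect_true(attr(rep_good, "overall"))
  ## one chain offset by a constant: rhat blows past 1.01
  bad <- good
  bad[, 2, 1] <- bad[, 2, 1] + 3
  rep_bad <- check_convergence(bad)
  expect_false(attr(rep_bad, "overall"))
  expect_gt(rep_bad$rhat[1], 1.01)
  ## far too few draws: ESS failure even with perfect mixing
  tiny <- array(rnorm(20), c(10, 2, 1), dimnames = list(NULL, NULL, "t"))
  rep_tiny <- check_convergence(tiny, ess_min = 2000)
  expect_false(attr(rep_tiny, "overall"))
  expect_error(check_convergence(good[, 1, , drop = FALSE]), "2 chains")
})

test_that("rhat detects an offset chain on constructed draws", {
  set.seed(33)
  x <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(x), 1.01)
  x[, 3] <- x[, 3] + 1
  expect_gt(rhat(x), 1.05)
})

test_that("summarize_posterior uses linear-interpolation quantiles", {
  arr <- array(NA_real_, c(50, 2, 1), dimnames = list(NULL, NULL, "d"))
  arr[, 1, 1] <- 1:50; arr[, 2, 1] <- 51:100
  s <- summarize_posterior(fake_samples(arr))
  expect_equal(s$mean, 50.5)
  expect_equal(c(s$lower, s$upper), c(3.475, 97.525))
  ## constant draws: zero-width interval
  cst <- array(2, c(20, 2, 1), dimnames = list(NULL, NULL, "c"))
  sc <- summarize_posterior(fake_samples(cst))
  expect_equal(sc$lower, sc$upper)
  ## symmetric draws about zero
  sym <- array(c(-(1:100), 1:100), c(100, 2, 1),
               dimnames = list(NULL, NULL, "s"))
  expect_equal(summarize_posterior(fake_samples(sym))$mean, 0)
})

test_that("fit_model convergence retry errors with diagnostics attached", {
  tab <- toy_regression_table(n = 20, seed = 34)
  spec <- toy_spec(sigma = 2)
  err <- tryCatch(
    fit_model(tab, spec, chains = 2, iterations = 150, warmup = 50,
              seed = 35, check = TRUE, ess_min = 1e7),
    erpbf_convergence_error = function(e) e)
  expect_s3_class(err, "erpbf_convergence_error")
  expect_s3_class(err$diagnostics, "data.frame")
  expect_true(any(!err$diagnostics$pass))
})

test_that("the CPC construction reproduces the LKJ marginal law", {
  ## under LKJ(2) with q = 3, every off-diagonal correlation is marginally
  ## 2*Beta(2.5, 2.5) - 1; check the derived entry r_32 against that law
  set.seed(36)
  r32 <- replicate(4000, rlkj(3, 2)[3, 2])
  ks <- suppressWarnings(stats::ks.test((r32 + 1) / 2,
                                        stats::pbeta, 2.5, 2.5))
  expect_gt(ks$p.value, 0.001)
  ## matrices are valid correlation matrices
  for (i in 1:20) {
    R <- rlkj(4, 2)
    expect_equal(diag(R), rep(1, 4))
    expect_true(is_pd(R))
  }
})

test_that("prior predictive reflects the prior set", {
  sim <- simulate_study(4, 8, seed = 37)
  spec <- model_spec()
  pp <- prior_predictive(spec, sim$trials, n_draws = 150, seed = 38)
  ## predictive amplitude SD of the order of the residual prior location
  expect_gt(mean(pp$amplitude_sd), 5)
  expect_lt(mean(pp$amplitude_sd), 12)
  ## reproducibility
  pp2 <- prior_predictive(spec, sim$trials, n_draws = 150, seed = 38)
  expect_identical(pp$predictive, pp2$predictive)
  ## near-degenerate priors collapse the predictive onto the intercept draw
  tight <- default_priors()
  tight$beta <- lapply(tight$beta, function(p) { p$scale <- 1e-8; p })
  tight$sigma_subject$scale <- 1e-8
  tight$sigma_item$scale <- 1e-8
  tight$sigma_residual <- prior_spec("truncated_normal", 0, 1e-8,
                                     "positive_only")
  spec_t <- model_spec(priors = tight)
  pp_t <- prior_predictive(spec_t, sim$trials, n_draws = 200, seed = 39)
  expect_lt(max(pp_t$amplitude_sd), 1e-4)
  ## spread across draws follows the intercept prior N(0, 5)
  expect_lt(abs(sd(pp_t$amplitude_mean) - 5), 1)
})

test_that("model_spec validates terms and priors", {
  expect_error(model_spec(fixed_terms = "nope",
                          priors = default_priors("other")),
               "no prior")
  expect_error(model_spec(random_subject = "extra"), "subset")
  spec <- model_spec()
  expect_error(set_term_prior(spec, "bogus", bf_prior()), "unknown term")
  null <- drop_term(spec, "entropy_centered")
  expect_false("entropy_centered" %in% null$fixed_terms)
  ## random slope for the dropped term is retained
  expect_true("entropy_centered" %in% null$random_subject)
})
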