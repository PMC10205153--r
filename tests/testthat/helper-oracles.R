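## Independent oracles used across the suite. These deliberately avoid the
## package's own computational paths.

## Conjugate Gaussian regression with known residual SD:
## y ~ N(X b, sigma^2 I), b ~ N(0, diag(prior_var)). Closed-form posterior
## and log marginal likelihood (y ~ N(0, sigma^2 I + X S0 X')).
conjugate_oracle <- function(y, X, sigma, prior_var) {
  n <- length(y)
  S0 <- diag(prior_var, ncol(X))
  P <- crossprod(X) / sigma^2 + diag(1 / prior_var, ncol(X))
  V <- solve(P)
  m <- V %*% (crossprod(X, y) / sigma^2)
  Vy <- sigma^2 * diag(n) + X %*% S0 %*% t(X)
  ld <- determinant(Vy, logarithm = TRUE)$modulus
  lml <- -0.5 * (n * log(2 * pi) + as.numeric(ld) +
                   as.numeric(t(y) %*% solve(Vy, y)))
  list(mean = as.vector(m), sd = sqrt(diag(V)), log_ml = lml)
}

## Analytic log ML for the conjugate model, with an optional one-sided
## (half-normal) prior on the LAST column's coefficient: the one-sided
## marginal likelihood equals the two-sided one times 2 * P(b < 0 | y)
## (or > 0), P taken from the untruncated Gaussian posterior.
conjugate_lml_oracle <- function(y, X, sigma, prior_var, side = "none") {
  o <- conjugate_oracle(y, X, sigma, prior_var)
  if (side == "none") return(o$log_ml)
  k <- ncol(X)
  mass <- if (side == "negative_only") pnorm(0, o$mean[k], o$sd[k])
          else 1 - pnorm(0, o$mean[k], o$sd[k])
  o$log_ml + log(2) + log(mass)
}

## quick OLS slope + standard error (stats::lm kept as the oracle engine)
ols_oracle <- function(y, x) {
  f <- stats::lm(y ~ x)
  c(coef(f)[["x"]], sqrt(diag(vcov(f)))[["x"]])
}

## construct a posterior_samples object from a plain draws array
fake_samples <- function(arr, spec = NULL) {
  structure(list(draws = arr, chains = dim(arr)[2], warmup = 0,
                 iterations = dim(arr)[1], spec = spec,
                 fingerprint = c(n = 0, ysum = 0, yss = 0)),
            class = "posterior_samples")
}

## small deterministic trial table for model tests: no random effects
toy_regression_table <- function(n = 50, beta = 0.5, sigma = 2, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  data.frame(amplitude = beta * x + rnorm(n, 0, sigma), xx = x,
             subject_id = "s1", item_id = "i1",
             stringsAsFactors = FALSE)
}

## spec for the toy regression (known sigma, no random effects)
toy_spec <- function(prior = prior_spec("normal", 0, 0.2), sigma = 2) {
  pri <- default_priors("xx")
  pri$beta$xx <- prior
  model_spec(fixed_terms = "xx", random_subject = NULL, random_item = FALSE,
             priors = pri, sigma_fixed = sigma)
}
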