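## ---- collapsed likelihood --------------------------------------------------
##
## For the Gaussian mixed model the random effects can be integrated out
## analytically: y ~ N(X beta, V) with V = sigma_e^2 I + Z G Z'. The bridge
## sampler operates on this collapsed posterior over the ~10 structural
## parameters (the fast path for Gaussian models), using Woodbury/determinant
## identities so each evaluation costs one Cholesky of a q_total x q_total
## matrix rather than n x n.

build_collapsed_loglik <- function(md, spec) {
  n <- md$n
  if (md$q == 0 && md$I == 0) {
    y <- md$y; X <- md$X
    return(function(beta, sigma_u, z, sigma_w, sigma_e) {
      sum(dnorm(y, as.vector(X %*% beta), sigma_e, log = TRUE))
    })
  }
  q <- md$q; J <- md$J; I <- md$I
  qtot <- J * q + I
  Z <- matrix(0, n, qtot)
  if (q > 0) for (k in seq_len(q))
    Z[cbind(seq_len(n), (md$js - 1) * q + k)] <- md$Zs[, k]
  if (I > 0) Z[cbind(seq_len(n), J * q + md$is_)] <- 1
  ZtZ <- crossprod(Z)
  ZtX <- crossprod(Z, md$X)
  Zty <- crossprod(Z, md$y)[, 1]
  XtX <- crossprod(md$X)
  Xty <- crossprod(md$X, md$y)[, 1]
  yty <- sum(md$y^2)
  m_z <- if (q > 1) q * (q - 1) / 2 else 0

  function(beta, sigma_u, z, sigma_w, sigma_e) {
    C <- ZtZ / sigma_e^2
    logdetG <- 0
    if (q > 0) {
      R <- if (m_z) cpc_to_cor(z, q) else diag(1, q)
      Sig <- R * tcrossprod(sigma_u)
      Ls <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(Ls)) return(-Inf)
      Sinv <- chol2inv(Ls)
      logdetG <- logdetG + 2 * J * sum(log(diag(Ls)))
      for (g in seq_len(J)) {
        ix <- ((g - 1) * q + 1):(g * q)
        C[ix, ix] <- C[ix, ix] + Sinv
      }
    }
    if (I > 0) {
      ix <- (J * q + 1):qtot
      diag(C)[ix] <- diag(C)[ix] + 1 / sigma_w^2
      logdetG <- logdetG + 2 * I * log(sigma_w)
    }
    Lc <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(Lc)) return(-Inf)
    Ztr <- Zty - as.vector(ZtX %*% beta)
    rtr <- yty - 2 * sum(Xty * beta) + sum(beta * (XtX %*% beta))
    v <- forwardsolve(t(Lc), Ztr)
    quad <- rtr / sigma_e^2 - sum(v^2) / sigma_e^4
    logdetV <- n * log(sigma_e^2) + logdetG + 2 * sum(log(diag(Lc)))
    -0.5 * (n * log(2 * pi) + logdetV + quad)
  }
}

## ---- parameter packing / unconstrained transform ---------------------------

## Structural parameters, their order and their transforms, derived from the
## spec: free scale for untruncated betas, log(-beta) / log(beta) for
## one-sided betas, log for SDs, atanh for canonical partial correlations.
evidence_param_map <- function(spec, q) {
  pri <- spec$priors
  beta_names <- c("b_Intercept",
                  if (length(spec$fixed_terms))
                    paste0("b_", spec$fixed_terms))
  beta_priors <- c(list(pri$intercept), pri$beta[spec$fixed_terms])
  pars <- data.frame(name = beta_names,
                     kind = vapply(beta_priors, function(sp)
                       switch(sp$truncation, none = "free",
                              negative_only = "logneg",
                              positive_only = "logpos"), ""),
                     stringsAsFactors = FALSE)
  if (q > 0) {
    pars <- rbind(pars, data.frame(
      name = paste0("sigma_subj_", c("Intercept", spec$random_subject)),
      kind = "log"))
    if (q > 1) {
      m_z <- q * (q - 1) / 2
      pars <- rbind(pars, data.frame(name = paste0("zcpc_", seq_len(m_z)),
                                     kind = "atanh"))
    }
  }
  if (spec$random_item)
    pars <- rbind(pars, data.frame(name = "sigma_item", kind = "log"))
  if (is.null(spec$sigma_fixed))
    pars <- rbind(pars, data.frame(name = "sigma_res", kind = "log"))
  pars$prior_i <- NA_integer_
  pars
}

to_unconstrained <- function(theta, kind) {
  switch(kind,
         free = theta,
         log = log(theta),
         logneg = log(-theta),
         logpos = log(theta),
         atanh = atanh(theta))
}

from_unconstrained <- function(v, kind) {
  switch(kind,
         free = v,
         log = exp(v),
         logneg = -exp(v),
         logpos = exp(v),
         atanh = tanh(v))
}

## log |d theta / d v|
transform_logjac <- function(theta, kind) {
  switch(kind,
         free = 0,
         log = log(theta),
         logneg = log(-theta),
         logpos = log(theta),
         atanh = log1p(-theta^2))
}

## Normalized log prior of the structural parameter vector (natural scale).
structural_logprior <- function(theta, map, spec, q) {
  pri <- spec$priors
  lp <- 0
  beta_priors <- c(list(pri$intercept), pri$beta[spec$fixed_terms])
  nb <- length(beta_priors)
  for (j in seq_len(nb))
    lp <- lp + prior_logdens(theta[j], beta_priors[[j]])
  k <- nb
  if (q > 0) {
    for (s in seq_len(q))
      lp <- lp + prior_logdens(theta[k + s], pri$sigma_subject)
    k <- k + q
    if (q > 1) {
      m_z <- q * (q - 1) / 2
      lp <- lp + lkj_cpc_logprior(theta[(k + 1):(k + m_z)], q,
                                  pri$rho$lkj_eta)
      k <- k + m_z
    }
  }
  if (spec$random_item) {
    lp <- lp + prior_logdens(theta[k + 1], pri$sigma_item)
    k <- k + 1
  }
  if (is.null(spec$sigma_fixed))
    lp <- lp + prior_logdens(theta[k + 1], pri$sigma_residual)
  lp
}

## unpack a structural vector into the pieces the collapsed likelihood wants
unpack_theta <- function(theta, spec, q) {
  nb <- 1 + length(spec$fixed_terms)
  beta <- theta[seq_len(nb)]
  k <- nb
  sigma_u <- numeric(0); z <- numeric(0)
  if (q > 0) {
    sigma_u <- theta[(k + 1):(k + q)]; k <- k + q
    if (q > 1) {
      m_z <- q * (q - 1) / 2
      z <- theta[(k + 1):(k + m_z)]; k <- k + m_z
    }
  }
  sigma_w <- if (spec$random_item) { k <- k + 1; theta[k] } else 1
  sigma_e <- if (is.null(spec$sigma_fixed)) theta[k + 1] else spec$sigma_fixed
  list(beta = beta, sigma_u = sigma_u, z = z, sigma_w = sigma_w,
       sigma_e = sigma_e)
}

dmvnorm_chol_log <- function(V, mean, L) {
  ## V: rows are points; L: upper Cholesky of covariance
  d <- ncol(V)
  z <- forwardsolve(t(L), t(V) - mean)
  -0.5 * d * log(2 * pi) - sum(log(diag(L))) - 0.5 * colSums(z^2)
}

#' Log marginal likelihood by iterative bridge sampling
#'
#' Uses the optimal (Meng-Wong) bridge with a moment-matched multivariate
#' normal proposal on the unconstrained parameter scale. Posterior draws are
#' split in half: one half fits the proposal, the other half enters the
#' bridge iteration, avoiding the optimistic bias of reusing draws. The
#' posterior density is the collapsed one (random effects integrated
#' analytically; see the methods vignette), with all priors normalized --
#' including one-sided truncation factors, on which the marginal likelihood
#' depends.
#'
#' @param samples a `posterior_samples` object for `spec` fitted on `table`.
#' @param spec the [model_spec()] that produced `samples`.
#' @param table the trial table the model was fitted on.
#' @param seed RNG seed for the proposal draws.
#' @param max_iter,tol bridge iteration controls (relative tolerance).
#' @return object of class `evidence_result` with `log_ml`,
#'   `log_ml_mc_error`, `n_posterior_draws`, `n_proposal_draws`,
#'   `prior_set_id`, `fingerprint`.
#' @export
log_marginal_likelihood <- function(samples, spec, table, seed = 1,
                                    max_iter = 1000, tol = 1e-8) {
  md <- prepare_model_data(table, spec)
  if (!isTRUE(all.equal(md$fingerprint, samples$fingerprint)))
    stop("table does not match the data the samples were fitted on")
  loglik <- build_collapsed_loglik(md, spec)
  q <- md$q
  map <- evidence_param_map(spec, q)
  arr <- samples$draws
  have <- dimnames(arr)[[3]]
  miss <- setdiff(map$name, have)
  if (length(miss)) stop("samples lack parameter(s): ",
                         paste(miss, collapse = ", "))
  M <- do.call(cbind, lapply(map$name, function(p) as.vector(arr[, , p])))
  colnames(M) <- map$name

  logpost_v <- function(vrow) {
    theta <- vapply(seq_along(vrow), function(i)
      from_unconstrained(vrow[i], map$kind[i]), 0)
    pieces <- unpack_theta(theta, spec, q)
    lp <- structural_logprior(theta, map, spec, q)
    if (!is.finite(lp)) return(-Inf)
    jac <- sum(vapply(seq_along(vrow), function(i)
      transform_logjac(theta[i], map$kind[i]), 0))
    loglik(pieces$beta, pieces$sigma_u, pieces$z, pieces$sigma_w,
           pieces$sigma_e) + lp + jac
  }

  V <- M
  for (i in seq_len(ncol(M))) V[, i] <- to_unconstrained(M[, i], map$kind[i])
  N <- nrow(V)
  i1 <- seq(1, N, by = 2)   # fits the proposal
  i2 <- seq(2, N, by = 2)   # enters the bridge
  mu <- colMeans(V[i1, , drop = FALSE])
  S <- var(V[i1, , drop = FALSE]) + diag(1e-10, ncol(V))
  L <- chol(S)

  set.seed(split_seed(seed, "evidence"))
  n2 <- length(i2)
  prop <- matrix(rnorm(n2 * ncol(V)), n2) %*% L +
    matrix(mu, n2, ncol(V), byrow = TRUE)

  lp_post <- apply(V[i2, , drop = FALSE], 1, logpost_v)
  if (any(!is.finite(lp_post))) {
    bad <- which(!is.finite(lp_post))[1]
    theta_bad <- vapply(seq_len(ncol(V)), function(i)
      from_unconstrained(V[i2[bad], i], map$kind[i]), 0)
    stop("non-finite posterior density at draw ", i2[bad], " (",
         paste(map$name, "=", signif(theta_bad, 4), collapse = ", "), ")")
  }
  lq_post <- dmvnorm_chol_log(V[i2, , drop = FALSE], mu, L)
  lp_prop <- apply(prop, 1, logpost_v)
  lq_prop <- dmvnorm_chol_log(prop, mu, L)

  l1 <- lp_post - lq_post          # at posterior draws
  l2 <- lp_prop - lq_prop          # at proposal draws
  ok2 <- is.finite(l2)             # proposal may land outside support
  lstar <- median(l1)
  n1 <- length(l1); n2e <- length(l2)
  s1 <- n1 / (n1 + n2e); s2 <- n2e / (n1 + n2e)
  r <- 1
  for (it in seq_len(max_iter)) {
    e2 <- exp(l2[ok2] - lstar)
    num <- (sum(e2 / (s1 * e2 + s2 * r))) / n2e
    e1 <- exp(l1 - lstar)
    den <- mean(1 / (s1 * e1 + s2 * r))
    r_new <- num / den
    if (abs(r_new - r) / r < tol) { r <- r_new; break }
    r <- r_new
  }
  log_ml <- log(r) + lstar
  f1 <- exp(l2[ok2] - lstar) / (s1 * exp(l2[ok2] - lstar) + s2 * r)
  f2 <- 1 / (s1 * exp(l1 - lstar) + s2 * r)
  re2 <- var(f1) / (n2e * mean(f1)^2) + var(f2) / (n1 * mean(f2)^2)
  structure(list(log_ml = log_ml, log_ml_mc_error = sqrt(max(re2, 0)),
                 n_posterior_draws = n1, n_proposal_draws = n2e,
                 prior_set_id = prior_set_id(spec),
                 fingerprint = samples$fingerprint),
            class = "evidence_result")
}

prior_set_id <- function(spec) {
  bits <- vapply(spec$fixed_terms, function(t) {
    sp <- spec$priors$beta[[t]]
    sprintf("%s:%s(%g,%g)%s", t, sp$family, sp$loc, sp$scale,
            switch(sp$truncation, none = "", negative_only = "-",
                   positive_only = "+"))
  }, "")
  paste(bits, collapse = ";")
}

#' Bayes factor BF10 from two marginal likelihoods
#'
#' `BF10 = exp(log_ml_full - log_ml_null)`. Classification follows the
#' conventional evidence scale: 3:1 is the minimum meaningful support,
#' 10:1 and beyond is strong evidence (for either hypothesis).
#'
#' @param full,null `evidence_result` objects fitted on the same data.
#' @return object of class `bayes_factor`: `bf10`, `log_bf`,
#'   `classification`.
#' @export
bayes_factor <- function(full, null) {
  if (!isTRUE(all.equal(full$fingerprint, null$fingerprint)))
    stop("mismatched data fingerprints: the two models were not fitted on ",
         "the same data")
  log_bf <- full$log_ml - null$log_ml
  bf <- exp(log_bf)
  structure(list(bf10 = bf, log_bf = log_bf,
                 classification = classify_bf(bf),
                 full = full, null = null),
            class = "bayes_factor")
}

classify_bf <- function(bf) {
  if (bf >= 10) "strong H1"
  else if (bf >= 3) "supports H1"
  else if (bf <= 1 / 10) "strong H0"
  else if (bf <= 1 / 3) "supports H0"
  else "inconclusive"
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("BF10 = %.4g (%s)\n", x$bf10, x$classification))
  invisible(x)
}

#' Fit full and null models for one tested term and return the Bayes factor
#'
#' The null is the full model with the tested fixed effect removed; all
#' other fixed terms and the complete random-effect structure (including the
#' random slope of the tested term) are retained.
#'
#' @param table trial table.
#' @param spec full-model [model_spec()] (the tested term's prior should be
#'   the hypothesis-test prior, e.g. [bf_prior()]).
#' @param term tested fixed term.
#' @param chains,iterations,warmup,seed passed to [fit_model()].
#' @return a `bayes_factor` object; the fitted models are attached as
#'   `fit_full` / `fit_null`.
#' @export
bf_for_term <- function(table, spec, term, chains = 2, iterations = 1500,
                        warmup = 500, seed = 1) {
  fit1 <- fit_model(table, spec, chains, iterations, warmup, seed = seed)
  ev1 <- log_marginal_likelihood(fit1, spec, table, seed = seed)
  spec0 <- drop_term(spec, term)
  fit0 <- fit_model(table, spec0, chains, iterations, warmup,
                    seed = seed + 1)
  ev0 <- log_marginal_likelihood(fit0, spec0, table, seed = seed + 1)
  out <- bayes_factor(ev1, ev0)
  out$fit_full <- fit1
  out$fit_null <- fit0
  out
}

#' Prior sensitivity sweep of the Bayes factor
#'
#' Recomputes BF10 for a grid of prior SDs on the tested term, truncated
#' and/or untruncated, holding every other prior constant. The null model
#' does not involve the tested term's prior and is fitted once.
#'
#' @param table trial table.
#' @param spec full-model [model_spec()].
#' @param term tested term.
#' @param scales prior SD grid (the pre-registered sweep spans 0.2 to 2).
#' @param variants subset of `c("truncated", "untruncated")`.
#' @param truncation side used for the truncated variant.
#' @param chains,iterations,warmup,seed passed to [fit_model()].
#' @return data.frame of class `sensitivity_curve`: `scale`, `variant`,
#'   `bf10`.
#' @export
sensitivity_sweep <- function(table, spec, term,
                              scales = seq(0.2, 2, by = 0.2),
                              variants = c("truncated", "untruncated"),
                              truncation = "negative_only",
                              chains = 2, iterations = 1500, warmup = 500,
                              seed = 1) {
  variants <- match.arg(variants, several.ok = TRUE)
  spec0 <- drop_term(spec, term)
  fit0 <- fit_model(table, spec0, chains, iterations, warmup, seed = seed)
  ev0 <- log_marginal_likelihood(fit0, spec0, table, seed = seed)
  grid <- expand.grid(scale = scales, variant = variants,
                      stringsAsFactors = FALSE)
  grid$bf10 <- NA_real_
  for (g in seq_len(nrow(grid))) {
    pr <- if (grid$variant[g] == "truncated")
      bf_prior(grid$scale[g], truncation)
    else bf_prior(grid$scale[g], "none")
    spec_g <- set_term_prior(spec, term, pr)
    fit1 <- fit_model(table, spec_g, chains, iterations, warmup,
                      seed = seed + g)
    ev1 <- log_marginal_likelihood(fit1, spec_g, table, seed = seed + g)
    grid$bf10[g] <- bayes_factor(ev1, ev0)$bf10
  }
  class(grid) <- c("sensitivity_curve", "data.frame")
  grid
}

#' Savage-Dickey density ratio check
#'
#' Independent cross-check of the bridge-sampling Bayes factor for a point
#' null at zero under an untruncated continuous prior:
#' `BF10 = prior(0) / posterior(0)`, the posterior density estimated by a
#' Gaussian kernel (Sheather-Jones bandwidth). If few draws fall near zero
#' the bandwidth is doubled with a warning.
#'
#' @param samples `posterior_samples` containing the tested coefficient.
#' @param prior the (untruncated) [prior_spec()] on the coefficient.
#' @param term fixed term name.
#' @return list with `bf10`, `prior_density0`, `posterior_density0`,
#'   `bandwidth`.
#' @export
savage_dickey_check <- function(samples, prior, term) {
  if (prior$truncation != "none")
    stop("Savage-Dickey requires an untruncated prior on the tested term")
  par <- paste0("b_", term)
  if (!par %in% dimnames(samples$draws)[[3]])
    stop("parameter not found: ", par)
  x <- as.vector(samples$draws[, , par])
  bw <- tryCatch(stats::bw.SJ(x), error = function(e) stats::bw.nrd0(x))
  near <- sum(abs(x) < 2 * bw)
  if (near < 10) {
    warning("few posterior draws near zero; widening kernel bandwidth")
    bw <- 2 * bw
  }
  d <- stats::density(x, bw = bw, n = 1024,
                      from = min(x, -4 * bw), to = max(x, 4 * bw))
  post0 <- stats::approx(d$x, d$y, xout = 0, rule = 2)$y
  prior0 <- exp(prior_logdens(0, prior))
  list(bf10 = prior0 / post0, prior_density0 = prior0,
       posterior_density0 = post0, bandwidth = bw)
}
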