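#' Prior specification
#'
#' Truncated normal priors are normalized on their half-line (the truncation
#' factor matters for marginal likelihoods, so it is never dropped):
#' `negative_only` restricts to `x < 0`, `positive_only` to `x > 0`.
#' `family = "lkj"` is the LKJ prior over correlation matrices with shape
#' `lkj_eta`.
#'
#' @param family `"normal"`, `"truncated_normal"` or `"lkj"`.
#' @param loc,scale location and scale (scale > 0).
#' @param truncation `"none"`, `"negative_only"` or `"positive_only"`.
#' @param lkj_eta LKJ shape (> 0).
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(family = c("normal", "truncated_normal", "lkj"),
                       loc = 0, scale = 1,
                       truncation = c("none", "negative_only",
                                      "positive_only"),
                       lkj_eta = 2) {
  family <- match.arg(family)
  truncation <- match.arg(truncation)
  if (family != "lkj" && scale <= 0) stop("scale must be > 0")
  if (family == "lkj" && lkj_eta <= 0) stop("lkj_eta must be > 0")
  if (family == "normal") truncation <- "none"
  if (family == "truncated_normal" && truncation == "none")
    stop("truncated_normal requires a truncation side")
  structure(list(family = family, loc = loc, scale = scale,
                 truncation = truncation, lkj_eta = lkj_eta),
            class = "prior_spec")
}

prior_bounds <- function(spec) {
  switch(spec$truncation,
         none = c(-Inf, Inf),
         negative_only = c(-Inf, 0),
         positive_only = c(0, Inf))
}

prior_logdens <- function(x, spec) {
  b <- prior_bounds(spec)
  dtnorm_log(x, spec$loc, spec$scale, b[1], b[2])
}

prior_sample <- function(n, spec) {
  b <- prior_bounds(spec)
  rtnorm(n, spec$loc, spec$scale, b[1], b[2])
}

#' The estimation-model prior set
#'
#' Intercept N(0, 5); every slope N(0, 1); by-subject and by-item SDs
#' half-normal N+(0, 0.5); residual SD N+(8, 2); LKJ(2) on the random-slope
#' correlation matrix. Units are microvolts.
#'
#' @param fixed_terms names of the slope predictors.
#' @return named list of [prior_spec()] objects (`beta` is itself a named
#'   list over `fixed_terms`).
#' @export
default_priors <- function(fixed_terms = c("entropy_centered",
                                           "log2_cloze_centered")) {
  beta <- lapply(fixed_terms, function(t) prior_spec("normal", 0, 1))
  names(beta) <- fixed_terms
  list(intercept = prior_spec("normal", 0, 5),
       beta = beta,
       sigma_subject = prior_spec("truncated_normal", 0, 0.5,
                                  "positive_only"),
       sigma_item = prior_spec("truncated_normal", 0, 0.5, "positive_only"),
       sigma_residual = prior_spec("truncated_normal", 8, 2,
                                   "positive_only"),
       rho = prior_spec("lkj", lkj_eta = 2))
}

#' A hypothesis-test (Bayes factor) prior for one effect
#'
#' The pre-registered directional tests use narrow, possibly one-sided
#' priors: `N_-(0, 0.2)` for effects expected to be negative, `N_+(0, 0.2)`
#' for positive, plain `N(0, 0.2)` for two-sided tests. The sensitivity
#' sweep varies `scale` between 0.2 and 2.
#'
#' @param scale prior SD (uV).
#' @param truncation side, as in [prior_spec()].
#' @return a [prior_spec()].
#' @export
bf_prior <- function(scale = 0.2, truncation = c("negative_only",
                                                 "positive_only", "none")) {
  truncation <- match.arg(truncation)
  if (truncation == "none") prior_spec("normal", 0, scale)
  else prior_spec("truncated_normal", 0, scale, truncation)
}
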