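#' @importFrom stats dnorm pnorm qnorm rnorm runif rbeta dbeta quantile sd var
#'   density median rbinom rgamma aggregate complete.cases fft nextn setNames
#' @importFrom utils head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from a single
#' master seed so that stages can be re-run independently and the whole run
#' stays reproducible. The scheme is `(master * 48271 + index) mod (2^31 - 1)`
#' where `index` is a fixed per-stage offset (a documented lookup, not a hash),
#' keeping all derived seeds valid 32-bit integers.
#'
#' @param master integer master seed.
#' @param stage stage name (one of the names in `erpbf_stage_index()`) or a
#'   non-negative integer offset.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(master, stage) {
  idx <- if (is.character(stage)) {
    tab <- erpbf_stage_index()
    if (!stage %in% names(tab)) stop("unknown stage: ", stage)
    tab[[stage]]
  } else {
    as.integer(stage)
  }
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 + idx + 1
  as.integer(s %% m)
}

#' @rdname split_seed
#' @export
erpbf_stage_index <- function() {
  c(design = 0L, cloze = 1L, trials = 2L, epochs = 3L, stopsignal = 4L,
    fit = 5L, evidence = 6L, sequential = 7L, design_analysis = 8L,
    prior_predictive = 9L)
}

## Truncated normal draws by inverse CDF; adequate for the bounds used here
## (truncation points within a few prior SDs of the location).
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (any(phi - plo < 1e-14)) {
    ## numerically degenerate tail: fall back to the nearer bound
    out <- numeric(n)
    bad <- phi - plo < 1e-14
    u <- runif(n)
    out[!bad] <- qnorm(plo[!bad] + u[!bad] * (phi - plo)[!bad], mean, sd)
    out[bad] <- ifelse(is.finite(lower), lower, upper)[bad]
    return(out)
  }
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

## log density of a normal truncated to (lower, upper), normalized
dtnorm_log <- function(x, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  lz <- log(pnorm(upper, mean, sd) - pnorm(lower, mean, sd))
  out <- dnorm(x, mean, sd, log = TRUE) - lz
  out[x < lower | x > upper] <- -Inf
  out
}

## Univariate slice sampler (Neal 2003, stepping out + shrinkage).
## logf must be finite at x0; -Inf encodes support boundaries.
slice_sample1 <- function(x0, logf, w = 1, max_steps = 30,
                          lower = -Inf, upper = Inf) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice_sample1: log density not finite at x0")
  logy <- f0 + log(runif(1))
  u <- runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(max_steps * runif(1))
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && logf(L) > logy) { L <- L - w; j <- j - 1 }
  while (k > 0 && R < upper && logf(R) > logy) { R <- R + w; k <- k - 1 }
  L <- max(L, lower)
  R <- min(R, upper)
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

## ---- LKJ correlation machinery (canonical partial correlations) -----------
##
## A q x q correlation matrix is parameterized by m = q(q-1)/2 canonical
## partial correlations z in (-1,1) via the C-vine / Cholesky construction.
## Under z[i,j] ~ 2*Beta(a_j, a_j) - 1 with a_j = eta + (q - 1 - j)/2
## (independent; j = column index of the lower-triangular slot), the implied
## matrix R = L L' is exactly LKJ(eta) distributed, and the prior density of
## z is fully normalized -- which bridge sampling requires.

cpc_alpha <- function(q, eta) {
  idx <- cpc_index(q)
  eta + (q - 1 - idx$col) / 2
}

cpc_index <- local({
  cache <- list()
  function(q) {
    key <- as.character(q)
    if (is.null(cache[[key]])) {
      row <- integer(0); col <- integer(0)
      for (i in seq_len(q)[-1]) for (j in seq_len(i - 1)) {
        row <- c(row, i); col <- c(col, j)
      }
      cache[[key]] <<- list(row = row, col = col)
    }
    cache[[key]]
  }
})

## CPC vector -> lower Cholesky factor of the correlation matrix
cpc_to_chol <- function(z, q) {
  L <- matrix(0, q, q)
  L[1, 1] <- 1
  idx <- cpc_index(q)
  for (m in seq_along(z)) {
    i <- idx$row[m]; j <- idx$col[m]
    L[i, j] <- z[m] * sqrt(max(0, 1 - sum(L[i, seq_len(j - 1)]^2)))
  }
  for (i in seq_len(q)[-1]) {
    L[i, i] <- sqrt(max(0, 1 - sum(L[i, seq_len(i - 1)]^2)))
  }
  L
}

cpc_to_cor <- function(z, q) {
  L <- cpc_to_chol(z, q)
  R <- L %*% t(L)
  ## enforce exact unit diagonal against rounding
  diag(R) <- 1
  R
}

## recover CPCs from a correlation matrix (inverse of cpc_to_cor)
cor_to_cpc <- function(R) {
  q <- nrow(R)
  L <- t(chol(R))
  idx <- cpc_index(q)
  z <- numeric(length(idx$row))
  for (m in seq_along(z)) {
    i <- idx$row[m]; j <- idx$col[m]
    denom <- sqrt(max(1e-300, 1 - sum(L[i, seq_len(j - 1)]^2)))
    z[m] <- L[i, j] / denom
  }
  z
}

## normalized log prior density of the CPC vector under LKJ(eta)
lkj_cpc_logprior <- function(z, q, eta) {
  a <- cpc_alpha(q, eta)
  ## z = 2*B - 1, B ~ Beta(a, a): density dbeta((z+1)/2, a, a) / 2
  sum(dbeta((z + 1) / 2, a, a, log = TRUE) - log(2))
}

rlkj_cpc <- function(q, eta) {
  a <- cpc_alpha(q, eta)
  2 * rbeta(length(a), a, a) - 1
}

## Draw a correlation matrix from LKJ(eta)
rlkj <- function(q, eta) cpc_to_cor(rlkj_cpc(q, eta), q)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

is_pd <- function(S, tol = 1e-10) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev)))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(name, " must be a finite numeric scalar")
  invisible(x)
}
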