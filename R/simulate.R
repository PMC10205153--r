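#' Generative truth parameters for the hierarchical amplitude model
#'
#' The defaults mirror the scale of the study this package models: a
#' constraint effect of -0.26 uV per bit of entropy and a residual SD of 8 uV
#' (single-trial EEG noise dominates). Random-effect SDs are not reported by
#' the source study; the defaults are plausible ERP values anchored to the
#' model's prior scales (intercept variability larger than slope
#' variability) and are fixed once -- see the methods vignette.
#'
#' @param alpha grand mean amplitude (uV).
#' @param beta_constraint effect of entropy, uV per bit.
#' @param beta_predictability effect of log2 cloze, uV per log2-cloze unit.
#' @param sigma_subject SDs of by-subject random intercept, constraint slope,
#'   predictability slope (uV).
#' @param rho 3x3 correlation matrix of the by-subject effects.
#' @param sigma_item by-item intercept SD (uV).
#' @param sigma_residual trial-level residual SD (uV).
#' @return object of class `truth_params`.
#' @export
truth_params <- function(alpha = 2, beta_constraint = -0.26,
                         beta_predictability = -0.11,
                         sigma_subject = c(1.0, 0.25, 0.25),
                         rho = NULL, sigma_item = 0.5, sigma_residual = 8) {
  if (is.null(rho)) {
    rho <- matrix(0.3, 3, 3); diag(rho) <- 1
  }
  if (any(sigma_subject < 0) || sigma_item < 0 || sigma_residual < 0)
    stop("SDs must be nonnegative")
  if (!isTRUE(all.equal(rho, t(rho))) || any(abs(diag(rho) - 1) > 1e-12))
    stop("rho must be symmetric with unit diagonal")
  if (!is_pd(rho)) stop("rho must be positive definite")
  structure(list(alpha = alpha, beta_constraint = beta_constraint,
                 beta_predictability = beta_predictability,
                 sigma_subject = sigma_subject, rho = rho,
                 sigma_item = sigma_item, sigma_residual = sigma_residual),
            class = "truth_params")
}

#' Latin-square design layout
#'
#' Items are assigned to the four conditions (a--d) in a Latin square: every
#' subject sees every item exactly once, and each subject's condition counts
#' are equal (`n_items / 4` each). Trial order is randomized within subject
#' and 50% of trials carry a post-sentence comprehension question flag.
#'
#' @param n_subjects number of subjects.
#' @param n_items number of items; must be divisible by 4.
#' @param seed RNG seed.
#' @return data.frame of class `design_layout` with columns `subject_id`,
#'   `item_id`, `condition`, `trial_order`, `post_question`.
#' @export
build_design <- function(n_subjects, n_items, seed = NULL) {
  if (n_items %% 4 != 0) stop("n_items must be divisible by 4")
  if (!is.null(seed)) set.seed(seed)
  conds <- letters[1:4]
  rows <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    grp <- (seq_len(n_items) - 1) %% 4          # item group in its quartet
    cond <- conds[((grp + (s - 1)) %% 4) + 1]   # rotate list by subject
    ord <- sample.int(n_items)
    pq <- logical(n_items)
    pq[sample.int(n_items, floor(n_items / 2))] <- TRUE
    rows[[s]] <- data.frame(
      subject_id = sprintf("S%03d", s),
      item_id = sprintf("I%03d", seq_len(n_items)),
      condition = cond, trial_order = ord, post_question = pq,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("design_layout", "data.frame")
  out
}

## Default symmetric Dirichlet concentrations for the two constraint
## profiles, calibrated once by Monte Carlo so that the mean sample entropy
## over many items matches the study's condition means (strong ~0.68 bits,
## weak ~2.44 bits at 60 respondents, 30 response types). See the methods
## vignette; these are fixed constants, not tuning knobs.
.cloze_profile_defaults <- list(
  strong = list(concentration = 0.0135, vocab_size = 30L),
  weak   = list(concentration = 0.1170, vocab_size = 30L)
)

#' Generate a synthetic cloze response set
#'
#' Responses are drawn from a Dirichlet-categorical law: a completion
#' distribution over `vocab_size` response types is drawn from a symmetric
#' Dirichlet with the given concentration, then `n_respondents` completions
#' are sampled from it. Small concentrations give peaked distributions
#' (strong constraint, low entropy); large ones approach uniform.
#'
#' @param condition_profile `"strong"` or `"weak"`; chooses the default
#'   concentration calibrated to the study's condition mean entropies.
#' @param n_respondents number of simulated respondents (>= 2).
#' @param vocab_size number of potential response types (>= 2).
#' @param concentration symmetric Dirichlet concentration; overrides the
#'   profile default.
#' @param seed RNG seed.
#' @param item_id,condition_label identifiers carried on the result.
#' @return a `cloze_responses` object (see [collapse_responses()]).
#' @export
generate_cloze_responses <- function(condition_profile = c("strong", "weak"),
                                     n_respondents = 60, vocab_size = NULL,
                                     concentration = NULL, seed = NULL,
                                     item_id = NA_character_,
                                     condition_label = NA_character_) {
  profile <- match.arg(condition_profile)
  defaults <- .cloze_profile_defaults[[profile]]
  vocab_size <- vocab_size %||% defaults$vocab_size
  concentration <- concentration %||% defaults$concentration
  if (n_respondents < 2) stop("n_respondents must be >= 2")
  if (vocab_size < 2) stop("vocab_size must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  g <- rgamma(vocab_size, shape = concentration, rate = 1)
  if (all(g == 0)) g[sample.int(vocab_size, 1)] <- 1  # concentration -> 0 limit
  p <- g / sum(g)
  types <- sprintf("w%02d", seq_len(vocab_size))
  tok <- sample(types, n_respondents, replace = TRUE, prob = p)
  collapse_responses(tok, NULL, item_id = item_id,
                     condition_label = condition_label)
}

## Pick a target stem for a response set: "high" predictability targets take
## the modal completion; "low" targets take the stem whose count is nearest
## 5% of respondents (the study's low-cloze conditions sit near 5% cloze).
pick_target <- function(set, predictability = c("high", "low")) {
  predictability <- match.arg(predictability)
  counts <- set$counts
  if (predictability == "high") return(names(counts)[which.max(counts)])
  goal <- 0.05 * set$n_respondents
  names(counts)[which.min(abs(counts - goal))]
}

#' Generate trial-level ERP amplitudes from the hierarchical truth
#'
#' One amplitude per layout row:
#' `y = alpha + b_c * entropy_c + b_p * cloze_c + u_s[1] + u_s[2] * entropy_c
#'  + u_s[3] * cloze_c + w_item + eps`,
#' with by-subject effects `u_s` drawn from a multivariate normal with
#' covariance `diag(sigma_subject) %*% rho %*% diag(sigma_subject)`, by-item
#' intercepts `w ~ N(0, sigma_item^2)` and residuals `N(0, sigma_residual^2)`.
#' Predictors are centered over the rows of the generated table.
#'
#' @param truth a [truth_params()] object.
#' @param layout a [build_design()] layout.
#' @param predictors a predictor table covering all (item, condition) pairs
#'   in the layout.
#' @param seed RNG seed.
#' @return data.frame of class `trial_table` with the amplitude DV,
#'   centered predictors, and design columns.
#' @export
generate_trial_amplitudes <- function(truth, layout, predictors, seed = NULL) {
  stopifnot(inherits(truth, "truth_params"))
  if (!is.null(seed)) set.seed(seed)
  key <- paste(layout$item_id, layout$condition)
  pkey <- paste(predictors$item_id, predictors$condition)
  idx <- match(key, pkey)
  if (anyNA(idx))
    stop("predictors missing for pairs: ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  ent <- predictors$entropy_bits[idx]
  clz <- predictors$log2_cloze_smoothed[idx]
  ent_c <- center_predictor(ent)
  clz_c <- center_predictor(clz)

  subj <- factor(layout$subject_id)
  item <- factor(layout$item_id)
  J <- nlevels(subj); I <- nlevels(item)
  if (!is_pd(truth$rho)) stop("rho must be positive definite")
  Lu <- diag(truth$sigma_subject, 3) %*% t(chol(truth$rho))
  u <- matrix(rnorm(J * 3), J, 3) %*% t(Lu)
  w <- rnorm(I, 0, truth$sigma_item)
  eps <- rnorm(nrow(layout), 0, truth$sigma_residual)
  js <- as.integer(subj); is_ <- as.integer(item)
  y <- truth$alpha + truth$beta_constraint * ent_c +
    truth$beta_predictability * clz_c +
    u[js, 1] + u[js, 2] * ent_c + u[js, 3] * clz_c + w[is_] + eps
  out <- data.frame(
    subject_id = layout$subject_id, item_id = layout$item_id,
    condition = layout$condition, trial_order = layout$trial_order,
    post_question = layout$post_question,
    entropy_bits = ent, log2_cloze_smoothed = clz,
    entropy_centered = ent_c, log2_cloze_centered = clz_c,
    amplitude = y, stringsAsFactors = FALSE)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Simulate a full study: design, cloze predictors and trial amplitudes
#'
#' Convenience wrapper used by the design analysis and the end-to-end
#' pipeline. Conditions a and b take the strong-constraint cloze profile,
#' c and d the weak one; condition a targets are high-predictability (modal
#' completion), the rest low.
#'
#' @inheritParams build_design
#' @param truth a [truth_params()] object.
#' @param n_respondents cloze respondents per item/condition.
#' @param seed master seed; stage seeds are derived via [split_seed()].
#' @return list with `layout`, `predictors`, `trials`.
#' @export
simulate_study <- function(n_subjects, n_items, truth = truth_params(),
                           seed = 1, n_respondents = 60) {
  layout <- build_design(n_subjects, n_items,
                         seed = split_seed(seed, "design"))
  set.seed(split_seed(seed, "cloze"))
  pairs <- unique(layout[, c("item_id", "condition")])
  sets <- vector("list", nrow(pairs))
  tgt <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    cond <- pairs$condition[r]
    profile <- if (cond %in% c("a", "b")) "strong" else "weak"
    sets[[r]] <- generate_cloze_responses(profile, n_respondents,
                                          item_id = pairs$item_id[r],
                                          condition_label = cond)
    tgt[r] <- pick_target(sets[[r]], if (cond == "a") "high" else "low")
  }
  targets <- data.frame(item_id = pairs$item_id, condition = pairs$condition,
                        target_token = tgt, stringsAsFactors = FALSE)
  predictors <- build_predictor_table(sets, targets)
  trials <- generate_trial_amplitudes(truth, layout, predictors,
                                      seed = split_seed(seed, "trials"))
  list(layout = layout, predictors = predictors, trials = trials)
}

#' Simulate a stop-signal session under the independent race model
#'
#' Go reaction times are lognormal; on stop trials a response occurs iff the
#' go finishing time is below `SSD + true_ssrt` (deterministic race with all
#' stop variability absorbed into the go RT distribution). The stop-signal
#' delay follows the standard one-up/one-down staircase: start 250 ms,
#' +50 ms after a successful stop, -50 ms after a failed stop, clamped to
#' [50, 1000] ms.
#'
#' @param true_ssrt latent stop-signal reaction time (ms).
#' @param go_rt_distribution list with `meanlog`, `sdlog` (lognormal RT in
#'   ms) and `omission_rate` (probability of no response on a go trial).
#' @param tracking staircase parameters `start`, `step`, `min`, `max` (ms).
#' @param n_trials total trials (>= 8); one in four is a stop trial, as in
#'   the study's 2-in-8 block structure.
#' @param seed RNG seed.
#' @param participant_id identifier carried on the session.
#' @return object of class `stop_signal_session` with `go_trials`
#'   (`rt`, `omission`) and `stop_trials` (`ssd`, `responded`, `rt`).
#' @export
generate_stop_signal_session <- function(
    true_ssrt = 245,
    go_rt_distribution = list(meanlog = log(550), sdlog = 0.18,
                              omission_rate = 0.02),
    tracking = list(start = 250, step = 50, min = 50, max = 1000),
    n_trials = 24, seed = NULL, participant_id = "P001") {
  if (n_trials < 8) stop("n_trials must be >= 8")
  if (!is.null(seed)) set.seed(seed)
  ## 2 stop trials per block of 8, positions randomized within block
  is_stop <- logical(n_trials)
  for (b in seq_len(ceiling(n_trials / 8))) {
    lo <- (b - 1) * 8 + 1
    hi <- min(b * 8, n_trials)
    pos <- sample(seq(lo, hi), min(2, hi - lo + 1))
    is_stop[pos] <- TRUE
  }
  ssd <- tracking$start
  go_rt <- numeric(0); go_om <- logical(0)
  st_ssd <- numeric(0); st_resp <- logical(0); st_rt <- numeric(0)
  for (t in seq_len(n_trials)) {
    finish <- exp(rnorm(1, go_rt_distribution$meanlog,
                        go_rt_distribution$sdlog))
    if (is_stop[t]) {
      responded <- finish < ssd + true_ssrt
      st_ssd <- c(st_ssd, ssd)
      st_resp <- c(st_resp, responded)
      st_rt <- c(st_rt, if (responded) finish else NA_real_)
      delta <- if (responded) -tracking$step else tracking$step
      ssd <- min(tracking$max, max(tracking$min, ssd + delta))
    } else {
      om <- runif(1) < (go_rt_distribution$omission_rate %||% 0)
      go_rt <- c(go_rt, if (om) NA_real_ else finish)
      go_om <- c(go_om, om)
    }
  }
  structure(
    list(participant_id = participant_id,
         go_trials = data.frame(rt = go_rt, omission = go_om),
         stop_trials = data.frame(ssd = st_ssd, responded = st_resp,
                                  rt = st_rt),
         true_ssrt = true_ssrt),
    class = "stop_signal_session")
}
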