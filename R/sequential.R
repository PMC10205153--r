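#' Construct a sequential Bayes factor trace
#'
#' A trace is the ordered sequence of (number of subjects, BF10) pairs that
#' the sequential design monitors. Traces can be built directly (for example
#' from an external monitoring log) or computed by [sequential_bf_trace()].
#'
#' @param n_subjects increasing integer vector.
#' @param bf10 Bayes factors at each evaluation point.
#' @return data.frame of class `sequential_trace`.
#' @export
sequential_trace <- function(n_subjects, bf10) {
  if (length(n_subjects) != length(bf10)) stop("length mismatch")
  if (is.unsorted(n_subjects, strictly = TRUE))
    stop("n_subjects must be strictly increasing")
  structure(data.frame(n_subjects = n_subjects, bf10 = bf10),
            class = c("sequential_trace", "data.frame"))
}

#' Apply the sequential stopping rule to a trace
#'
#' Recruitment stops at the earliest evaluation point where BF10 reaches the
#' evidence threshold in either direction -- `bf10 >= threshold` (stop for
#' H1) or `bf10 <= 1/threshold` (stop for H0) -- or when the participant cap
#' is reached. Threshold comparisons are inclusive (the rule fires at a BF
#' of exactly 10).
#'
#' @param trace a [sequential_trace()].
#' @param threshold evidence threshold (default 10).
#' @param cap maximum number of participants (default 150).
#' @return list with `decision` (`"stop_H1"`, `"stop_H0"` or
#'   `"cap_reached"`), `decision_n`, `threshold`, `cap`.
#' @export
apply_stopping_rule <- function(trace, threshold = 10, cap = 150) {
  if (nrow(trace) == 0) stop("empty trace")
  keep <- trace$n_subjects <= cap
  tr <- trace[keep, , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    if (tr$bf10[i] >= threshold)
      return(list(decision = "stop_H1", decision_n = tr$n_subjects[i],
                  threshold = threshold, cap = cap))
    if (tr$bf10[i] <= 1 / threshold)
      return(list(decision = "stop_H0", decision_n = tr$n_subjects[i],
                  threshold = threshold, cap = cap))
  }
  list(decision = "cap_reached",
       decision_n = min(max(trace$n_subjects), cap),
       threshold = threshold, cap = cap)
}

#' Sequential Bayes factor monitoring over a growing subject pool
#'
#' Refits the full and null models on the first `n` subjects (in order of
#' first appearance in the table) at each evaluation point and recomputes
#' BF10, stopping early once the stopping rule fires. Evaluation points
#' beyond the available number of subjects are truncated with a warning.
#'
#' @param table subject-ordered trial table.
#' @param spec full-model [model_spec()] with the test prior on `term`.
#' @param term tested fixed term.
#' @param eval_points increasing subject counts at which to evaluate
#'   (default every 5 subjects up to the pool).
#' @param threshold,cap stopping-rule parameters.
#' @param chains,iterations,warmup,seed passed to [fit_model()].
#' @return a `sequential_trace` with attribute `decision` (the
#'   [apply_stopping_rule()] result).
#' @export
sequential_bf_trace <- function(table, spec, term, eval_points = NULL,
                                threshold = 10, cap = 150,
                                chains = 2, iterations = 1500, warmup = 500,
                                seed = 1) {
  subjects <- unique(table$subject_id)
  eval_points <- eval_points %||% seq(5, length(subjects), by = 5)
  if (is.unsorted(eval_points, strictly = TRUE))
    stop("eval_points must be increasing")
  if (any(eval_points > length(subjects))) {
    warning("evaluation points beyond available subjects truncated")
    eval_points <- eval_points[eval_points <= length(subjects)]
  }
  ns <- integer(0); bfs <- numeric(0)
  for (k in seq_along(eval_points)) {
    n <- eval_points[k]
    sub <- table[table$subject_id %in% subjects[seq_len(n)], , drop = FALSE]
    bf <- bf_for_term(sub, spec, term, chains, iterations, warmup,
                      seed = split_seed(seed, 7) + k)
    ns <- c(ns, n); bfs <- c(bfs, bf$bf10)
    if (bf$bf10 >= threshold || bf$bf10 <= 1 / threshold || n >= cap) break
  }
  tr <- sequential_trace(ns, bfs)
  attr(tr, "decision") <- apply_stopping_rule(tr, threshold, cap)
  tr
}

#' Simulation-based design analysis: Bayes factor as a function of N
#'
#' For each sample size in `n_grid` and each replicate, simulates a full
#' study from the assumed truth, fits the full and null models and computes
#' BF10 with the hypothesis-test prior. The reference analysis simulated one
#' data set per sample size over 100-700 participants; `reps > 1` exposes
#' the replicate noise that single-run design analyses hide.
#'
#' @param truth a [truth_params()] object taken as ground truth.
#' @param n_grid subject counts to simulate.
#' @param n_items items per simulated study.
#' @param reps replicates per grid point.
#' @param term tested fixed term.
#' @param test_prior prior on the tested term (default the pre-registered
#'   truncated `N_-(0, 0.2)`).
#' @param chains,iterations,warmup MCMC settings per fit.
#' @param seed master seed.
#' @return object of class `design_curve`: list with `results` (one row per
#'   fit: `n_subjects`, `rep`, `bf10`, `converged`) and `summary` (per-n
#'   median BF and decision fractions over converged fits).
#' @export
design_analysis <- function(truth, n_grid, n_items = 40, reps = 5,
                            term = "entropy_centered",
                            test_prior = bf_prior(0.2, "negative_only"),
                            chains = 2, iterations = 1500, warmup = 500,
                            seed = 1) {
  if (reps < 1) stop("reps must be >= 1")
  spec <- model_spec(fixed_terms = c("entropy_centered",
                                     "log2_cloze_centered"))
  spec <- set_term_prior(spec, term, test_prior)
  rows <- list()
  base <- split_seed(seed, "design_analysis")
  for (gi in seq_along(n_grid)) {
    for (r in seq_len(reps)) {
      s <- (base + 131 * gi + r) %% 2147483647
      sim <- simulate_study(n_grid[gi], n_items, truth, seed = s)
      bf <- tryCatch(
        bf_for_term(sim$trials, spec, term, chains, iterations, warmup,
                    seed = s),
        error = function(e) NULL)
      conv <- FALSE; bf10 <- NA_real_
      if (!is.null(bf)) {
        bf10 <- bf$bf10
        rh <- rhat(bf$fit_full$draws[, , paste0("b_", term)])
        conv <- is.finite(rh) && rh < 1.1
      }
      rows[[length(rows) + 1]] <- data.frame(
        n_subjects = n_grid[gi], rep = r, bf10 = bf10, converged = conv)
    }
  }
  res <- do.call(rbind, rows)
  ok <- res[res$converged, , drop = FALSE]
  summ <- do.call(rbind, lapply(split(ok, ok$n_subjects), function(d) {
    data.frame(n_subjects = d$n_subjects[1],
               n_converged = nrow(d),
               n_excluded = sum(res$n_subjects == d$n_subjects[1]) - nrow(d),
               median_bf10 = median(d$bf10),
               frac_stop_H1 = mean(d$bf10 >= 10),
               frac_stop_H0 = mean(d$bf10 <= 0.1))
  }))
  rownames(summ) <- NULL
  structure(list(results = res, summary = summ), class = "design_curve")
}
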