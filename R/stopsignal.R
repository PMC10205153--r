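#' Screen a stop-signal session for analysability
#'
#' A session is excluded when the mean go-trial response time is more than
#' two standard deviations faster or slower than the mean response time on
#' (failed) stop trials, which violates the assumptions of the SSRT
#' calculation. A caution flag is raised when the probability of responding
#' on stop trials falls outside [0.25, 0.75] (it should sit near 0.5 for
#' the staircase to track properly).
#'
#' @param session a `stop_signal_session` (see
#'   [generate_stop_signal_session()] or [read_stop_signal_session()]).
#' @return list with `exclude`, `caution`, `p_respond_stop`, `mean_go_rt`,
#'   `mean_stop_rt`, `sd_stop_rt`, `reasons`.
#' @export
screen_session <- function(session) {
  go <- session$go_trials
  st <- session$stop_trials
  if (nrow(go) < 1 || nrow(st) < 1) stop("need at least 1 go and 1 stop trial")
  go_rt <- go$rt[!is.na(go$rt)]
  stop_rt <- st$rt[st$responded & !is.na(st$rt)]
  p_resp <- mean(st$responded)
  reasons <- character(0)
  exclude <- FALSE
  if (length(stop_rt) >= 2) {
    gap <- abs(mean(go_rt) - mean(stop_rt))
    if (gap > 2 * sd(stop_rt)) {
      exclude <- TRUE
      reasons <- c(reasons, "go/stop RT separation exceeds 2 SD")
    }
  } else {
    reasons <- c(reasons, "too few responded stop trials to screen RTs")
  }
  caution <- p_resp < 0.25 || p_resp > 0.75
  if (caution)
    reasons <- c(reasons, sprintf("p(respond|stop) = %.2f outside [0.25, 0.75]",
                                  p_resp))
  list(exclude = exclude, caution = caution, p_respond_stop = p_resp,
       mean_go_rt = mean(go_rt),
       mean_stop_rt = if (length(stop_rt)) mean(stop_rt) else NA_real_,
       sd_stop_rt = if (length(stop_rt) >= 2) sd(stop_rt) else NA_real_,
       reasons = reasons)
}

#' Stop-signal reaction time by the integration method
#'
#' Go omissions are replaced by the maximum observed go RT, go RTs are
#' sorted, and the RT at rank `ceiling(p(respond|stop) * n_go)` is taken
#' (no interpolation; ties resolved by first occurrence). SSRT is that
#' quantile minus the mean stop-signal delay.
#'
#' @param session a `stop_signal_session`.
#' @param warn_caution warn (rather than fail) on screening caution flags.
#' @return SSRT in ms.
#' @export
ssrt_integration <- function(session, warn_caution = TRUE) {
  scr <- screen_session(session)
  if (scr$exclude)
    stop("session fails screening: ", paste(scr$reasons, collapse = "; "))
  if (scr$caution && warn_caution)
    warning("screening caution: ", paste(scr$reasons, collapse = "; "))
  p <- scr$p_respond_stop
  if (p == 0) stop("SSRT undefined at zero response rate")
  go <- session$go_trials
  rt <- go$rt
  if (all(is.na(rt))) stop("no observed go RTs")
  rt[is.na(rt)] <- max(rt, na.rm = TRUE)  # omission replacement
  rt <- sort(rt)
  rank <- min(length(rt), ceiling(p * length(rt)))
  rt[rank] - mean(session$stop_trials$ssd)
}

#' Cohort summary of stop-signal sessions
#'
#' Means with normal-approximation 95% confidence intervals
#' (`mean +/- 1.96 * sd / sqrt(k)`) across sessions for the quantities the
#' task reports: omission rate on go trials, response rate on stop trials,
#' mean stop-signal delay, SSRT, and mean go / stop-trial RTs. With a
#' single session the interval collapses to the point estimate.
#'
#' @param sessions list of `stop_signal_session` objects.
#' @return data.frame with `measure`, `mean`, `ci_lower`, `ci_upper`.
#' @export
stop_signal_summary <- function(sessions) {
  if (length(sessions) < 1) stop("need at least one session")
  per <- lapply(sessions, function(s) {
    go <- s$go_trials; st <- s$stop_trials
    stop_rt <- st$rt[st$responded & !is.na(st$rt)]
    c(p_no_response_go = mean(go$omission),
      p_respond_stop = mean(st$responded),
      mean_ssd = mean(st$ssd),
      ssrt = tryCatch(suppressWarnings(ssrt_integration(s)),
                      error = function(e) NA_real_),
      go_rt = mean(go$rt, na.rm = TRUE),
      stop_rt = if (length(stop_rt)) mean(stop_rt) else NA_real_)
  })
  M <- do.call(rbind, per)
  out <- data.frame(measure = colnames(M),
                    mean = colMeans(M, na.rm = TRUE))
  k <- colSums(!is.na(M))
  se <- apply(M, 2, sd, na.rm = TRUE) / sqrt(pmax(k, 1))
  se[k < 2] <- 0  # single observation: point interval
  out$ci_lower <- out$mean - 1.96 * se
  out$ci_upper <- out$mean + 1.96 * se
  rownames(out) <- NULL
  out
}

#' Read / write stop-signal sessions (TSV)
#'
#' One row per trial: `trial_type` (`go`/`stop`), `rt_ms` (blank for
#' omissions), `ssd_ms` (stop trials only), `responded` (stop trials only).
#'
#' @param file path.
#' @param participant_id identifier for the session.
#' @return a `stop_signal_session`.
#' @export
read_stop_signal_session <- function(file, participant_id = NULL) {
  d <- data.table::fread(file, sep = "\t", data.table = FALSE)
  go <- d[d$trial_type == "go", , drop = FALSE]
  st <- d[d$trial_type == "stop", , drop = FALSE]
  structure(
    list(participant_id = participant_id %||% basename(file),
         go_trials = data.frame(rt = as.numeric(go$rt_ms),
                                omission = is.na(as.numeric(go$rt_ms))),
         stop_trials = data.frame(ssd = as.numeric(st$ssd_ms),
                                  responded = as.logical(st$responded),
                                  rt = as.numeric(st$rt_ms))),
    class = "stop_signal_session")
}

#' @rdname read_stop_signal_session
#' @param session a `stop_signal_session`.
#' @export
write_stop_signal_session <- function(session, file) {
  go <- session$go_trials; st <- session$stop_trials
  d <- rbind(
    data.frame(trial_type = "go", rt_ms = go$rt, ssd_ms = NA_real_,
               responded = NA),
    data.frame(trial_type = "stop", rt_ms = st$rt, ssd_ms = st$ssd,
               responded = st$responded))
  data.table::fwrite(d, file, sep = "\t")
  invisible(file)
}
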