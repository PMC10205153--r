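## 29-channel scalp montage (10-20 names) used by the synthetic generator.
erpbf_montage <- c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                   "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
                   "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
                   "POz", "O1", "O2")

#' Construct an epoch set
#'
#' Container for segmented EEG: a trials x channels x samples array in
#' microvolts plus sampling metadata. `time0` is the 1-based sample index of
#' stimulus onset, so sample `k` has time `(k - time0) / srate * 1000` ms.
#'
#' @param data numeric array `trials x channels x samples` (uV).
#' @param srate sampling rate in Hz.
#' @param time0 sample index of stimulus onset (1-based).
#' @param channel_labels unique channel names (10-20 system).
#' @param reject optional data.frame with `flag` (logical) and `reason`.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, srate, time0, channel_labels, reject = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[2] != length(channel_labels))
    stop("channel_labels length does not match data")
  if (anyDuplicated(channel_labels)) stop("channel_labels must be unique")
  n <- dim(data)[1]
  if (is.null(reject))
    reject <- data.frame(flag = rep(FALSE, n), reason = rep("", n),
                         stringsAsFactors = FALSE)
  structure(list(data = data, srate = srate, time0 = time0,
                 channel_labels = channel_labels, reject = reject),
            class = "epoch_set")
}

#' @rdname epoch_set
#' @param x an `epoch_set`.
#' @return `epoch_times`: sample times in ms relative to stimulus onset.
#' @export
epoch_times <- function(x) {
  ((seq_len(dim(x$data)[3]) - x$time0) / x$srate) * 1000
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tm <- range(epoch_times(x))
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$srate))
  cat(sprintf("  window %.1f..%.1f ms; %d flagged\n", tm[1], tm[2],
              sum(x$reject$flag)))
  invisible(x)
}

#' Generate synthetic epochs with injected components and artifacts
#'
#' One epoch per layout row. Each component template adds a flat (rectangular)
#' deflection of the given amplitude over its time window on its electrodes,
#' so the window mean over the template's region of interest equals the
#' injected amplitude exactly in the noise-free case (after baseline
#' correction; templates are zero in the baseline). Gaussian sensor noise is
#' added everywhere. Artifacts are injected at the requested rates and exceed
#' the standard rejection thresholds by construction: blinks are frontal
#' half-cosine deflections (default 150 uV peak over 300 ms), steps are
#' single-sample DC offsets (default 150 uV, i.e. ~76.8 uV/ms at 512 Hz).
#'
#' @param layout a [build_design()] layout; one epoch per row.
#' @param component_spec list of components, each a list with `name`,
#'   `electrodes`, `window` (ms), and `amplitude`: a single number or a
#'   named vector by condition (uV).
#' @param artifact_spec list with `blink_rate`, `step_rate` (per-trial
#'   probabilities), `blink_amp`, `step_amp` (uV); alternatively
#'   `blink_trials` / `step_trials` give explicit trial indices for
#'   deterministic fixtures (rates are then ignored).
#' @param srate sampling rate (Hz).
#' @param window epoch span in ms; must cover `[-200, 1000]`.
#' @param noise_sd Gaussian sensor noise SD (uV); 0 gives exact fixtures.
#' @param channel_labels montage to simulate.
#' @param seed RNG seed.
#' @return an `epoch_set` with attributes `true_means` (data.frame `trial`,
#'   `component`, `true_mean`: the pre-noise window means) and `injected`
#'   (per-trial artifact type, `""` if clean).
#' @export
generate_epochs <- function(layout, component_spec = list(),
                            artifact_spec = list(blink_rate = 0,
                                                 step_rate = 0,
                                                 blink_amp = 150,
                                                 step_amp = 150),
                            srate = 512, window = c(-200, 1200),
                            noise_sd = 0, channel_labels = erpbf_montage,
                            seed = NULL) {
  if (window[1] > -200 || window[2] < 1000)
    stop("epoch window must cover [-200, 1000] ms")
  if (!is.null(seed)) set.seed(seed)
  n_trials <- nrow(layout)
  s0 <- floor(window[1] * srate / 1000)
  s1 <- ceiling(window[2] * srate / 1000)
  n_samp <- s1 - s0 + 1
  time0 <- -s0 + 1
  tms <- ((seq_len(n_samp) - time0) / srate) * 1000
  n_ch <- length(channel_labels)
  dat <- array(if (noise_sd > 0) rnorm(n_trials * n_ch * n_samp, 0, noise_sd)
               else 0, dim = c(n_trials, n_ch, n_samp))

  true_rows <- list()
  for (cmp in component_spec) {
    ch <- match(cmp$electrodes, channel_labels)
    if (anyNA(ch)) stop("component electrodes not in montage: ",
                        paste(cmp$electrodes[is.na(ch)], collapse = ", "))
    sm <- which(tms >= cmp$window[1] & tms < cmp$window[2])
    amp <- if (is.null(names(cmp$amplitude))) {
      if (length(cmp$amplitude) == 1) rep(cmp$amplitude, n_trials)
      else if (length(cmp$amplitude) == n_trials) cmp$amplitude
      else stop("component '", cmp$name, "': amplitude must be scalar, ",
                "per-trial, or named by condition")
    } else as.numeric(cmp$amplitude[layout$condition])
    if (anyNA(amp)) stop("component '", cmp$name,
                         "' lacks an amplitude for some condition")
    for (t in seq_len(n_trials))
      dat[t, ch, sm] <- dat[t, ch, sm] + amp[t]
    true_rows[[cmp$name]] <- data.frame(trial = seq_len(n_trials),
                                        component = cmp$name,
                                        true_mean = amp,
                                        stringsAsFactors = FALSE)
  }

  injected <- rep("", n_trials)
  blink_ch <- intersect(c("Fp1", "Fpz", "Fp2", "F3", "Fz", "F4", "F7", "F8"),
                        channel_labels)
  br <- artifact_spec$blink_rate %||% 0
  sr <- artifact_spec$step_rate %||% 0
  bamp <- artifact_spec$blink_amp %||% 150
  samp <- artifact_spec$step_amp %||% 150
  ## explicit trial lists override the stochastic rates (fixture mode)
  forced_blink <- artifact_spec$blink_trials %||% integer(0)
  forced_step <- artifact_spec$step_trials %||% integer(0)
  for (t in seq_len(n_trials)) {
    if (t %in% forced_blink || (!length(forced_blink) &&
                                !length(forced_step) && runif(1) < br)) {
      onset <- runif(1, 0, 700)
      idx <- which(tms >= onset & tms < onset + 300)
      bump <- bamp * sin(pi * seq_along(idx) / length(idx))^2
      ci <- match(blink_ch, channel_labels)
      dat[t, ci, idx] <- dat[t, ci, idx] +
        matrix(bump, length(ci), length(idx), byrow = TRUE)
      injected[t] <- "blink"
    } else if (t %in% forced_step || (!length(forced_blink) &&
                                      !length(forced_step) &&
                                      runif(1) < sr)) {
      at <- sample(which(tms >= 0 & tms <= 900), 1)
      ci <- sample(n_ch, 1)
      dat[t, ci, at:n_samp] <- dat[t, ci, at:n_samp] + samp
      injected[t] <- "step"
    }
  }

  es <- epoch_set(dat, srate, time0, channel_labels)
  attr(es, "true_means") <- if (length(true_rows))
    do.call(rbind, c(true_rows, list(make.row.names = FALSE))) else NULL
  attr(es, "injected") <- injected
  es
}

#' Read and write the epoch container
#'
#' A plain-text container: the first line holds a JSON metadata block
#' (sampling rate, onset sample, channel labels, rejection flags), the rest
#' is a tab-separated table with one row per trial x channel and one column
#' per sample, written at 17 significant digits so the round trip is
#' lossless.
#'
#' @param x an `epoch_set`.
#' @param file path.
#' @export
write_epochs <- function(x, file) {
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$data)
  meta <- list(format = "erpbf_epochs_v1", n_trials = d[1], n_channels = d[2],
               n_samples = d[3], srate = x$srate, time0 = x$time0,
               channel_labels = x$channel_labels,
               reject_flag = x$reject$flag, reject_reason = x$reject$reason)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 ncol = d[3], byrow = TRUE)
  hdr <- c("trial", "channel", paste0("s", seq_len(d[3])))
  writeLines(paste(hdr, collapse = "\t"), con)
  tr <- rep(seq_len(d[1]), each = d[2])
  ch <- rep(x$channel_labels, d[1])
  body <- apply(flat, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = "\t"))
  writeLines(paste(tr, ch, body, sep = "\t"), con)
  invisible(file)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(file) {
  first <- readLines(file, n = 1)
  if (!startsWith(first, "#")) stop("not an erpbf epoch container")
  meta <- jsonlite::fromJSON(substring(first, 2))
  if (!identical(meta$format, "erpbf_epochs_v1"))
    stop("unknown epoch container format")
  tab <- data.table::fread(file, skip = 1, sep = "\t", data.table = FALSE)
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  d <- c(meta$n_trials, meta$n_channels, meta$n_samples)
  arr <- aperm(array(t(vals), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  epoch_set(arr, meta$srate, meta$time0, meta$channel_labels,
            reject = data.frame(flag = as.logical(meta$reject_flag),
                                reason = as.character(meta$reject_reason),
                                stringsAsFactors = FALSE))
}
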