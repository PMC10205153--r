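## ---- filter design ---------------------------------------------------------

## Hamming-windowed sinc lowpass kernel; cutoff is the -6 dB point.
## Kernel length from the transition width: L ~ 3.3 / (trans / srate).
fir_lowpass_kernel <- function(cutoff, srate, trans) {
  L <- ceiling(3.3 * srate / trans)
  if (L %% 2 == 0) L <- L + 1
  m <- (L - 1) / 2
  k <- seq(-m, m)
  fc <- cutoff / srate
  h <- 2 * fc * sinc(2 * fc * k)
  w <- 0.54 + 0.46 * cos(pi * k / m)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Design a zero-phase FIR bandpass kernel
#'
#' Windowed-sinc (Hamming) design. The highpass edge is obtained by spectral
#' inversion of a lowpass at the low cutoff; the band is the cascade
#' (convolution) of the two kernels. Each edge gets its own transition width,
#' so the low edge's very narrow default (0.01 Hz) produces a long kernel
#' intended for continuous recordings, not short epochs.
#'
#' @param srate sampling rate (Hz).
#' @param low,high band edges (Hz), -6 dB points.
#' @param l_trans,h_trans transition widths at the low/high edge (Hz).
#' @return numeric kernel (odd length, symmetric).
#' @export
fir_design <- function(srate, low = 0.01, high = 30,
                       l_trans = 0.01, h_trans = 7.5) {
  lp <- fir_lowpass_kernel(high, srate, h_trans)
  lp_low <- fir_lowpass_kernel(low, srate, l_trans)
  hp <- -lp_low
  hp[(length(hp) + 1) / 2] <- hp[(length(hp) + 1) / 2] + 1
  stats::convolve(hp, rev(lp), type = "open")
}

#' Frequency response magnitude of an FIR kernel
#'
#' @param kernel FIR coefficients.
#' @param freqs frequencies (Hz).
#' @param srate sampling rate (Hz).
#' @return magnitude of the transfer function at `freqs`.
#' @export
fir_freq_response <- function(kernel, freqs, srate) {
  k <- seq_along(kernel) - 1
  vapply(freqs, function(f) {
    Mod(sum(kernel * exp(-2i * pi * f * k / srate)))
  }, 0)
}

apply_fir <- function(signal, kernel) {
  L <- length(kernel)
  n <- length(signal)
  if (n < L) stop("signal shorter than filter settling length (", L,
                  " samples)")
  m <- (L - 1) / 2
  ## reflect-pad so the symmetric kernel introduces no phase shift or edge
  ## discontinuity
  pad_l <- 2 * signal[1] - signal[seq(m + 1, 2)]
  pad_r <- 2 * signal[n] - signal[seq(n - 1, n - m)]
  x <- c(pad_l, signal, pad_r)
  nf <- stats::nextn(length(x) + L - 1)
  X <- stats::fft(c(x, numeric(nf - length(x))))
  H <- stats::fft(c(kernel, numeric(nf - L)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nf
  y[(2 * m + 1):(2 * m + n)]
}

## ---- Butterworth IIR (second-order sections) -------------------------------

## Analog Butterworth prototype -> digital biquads via bilinear transform
## with frequency prewarping. `order` must be even; order/2 sections.
butter_sos <- function(order, cutoff, srate, type = c("low", "high")) {
  type <- match.arg(type)
  if (order %% 2 != 0) stop("order must be even")
  wc <- 2 * srate * tan(pi * cutoff / srate)  # prewarped analog cutoff
  K <- 2 * srate
  sections <- list()
  for (k in seq_len(order / 2)) {
    theta <- pi * (2 * k - 1) / (2 * order) + pi / 2
    p <- complex(modulus = 1, argument = theta)   # prototype pole, Re < 0
    a1s <- -2 * Re(p)   # analog section: s^2 + a1s * s + 1 (|p| = 1)
    ## scaled section s^2 + a1s*wc*s + wc^2; numerator wc^2 (low) or s^2 (high)
    a <- c(1, a1s * wc, wc^2)
    num <- if (type == "low") c(wc^2, 2 * wc^2, wc^2)   # wc^2 (1 + z^-1)^2
           else c(K^2, -2 * K^2, K^2)                   # K^2  (1 - z^-1)^2
    den <- c(a[1] * K^2 + a[2] * K + a[3],
             -2 * a[1] * K^2 + 2 * a[3],
             a[1] * K^2 - a[2] * K + a[3])
    sections[[k]] <- c(b0 = num[1] / den[1], b1 = num[2] / den[1],
                       b2 = num[3] / den[1], a1 = den[2] / den[1],
                       a2 = den[3] / den[1])
  }
  sections
}

sos_freq_response <- function(sections, freqs, srate) {
  vapply(freqs, function(f) {
    z1 <- exp(-2i * pi * f / srate)
    h <- 1 + 0i
    for (s in sections) {
      h <- h * (s["b0"] + s["b1"] * z1 + s["b2"] * z1^2) /
        (1 + s["a1"] * z1 + s["a2"] * z1^2)
    }
    Mod(h)
  }, 0)
}

sosfilt <- function(sections, x) {
  for (s in sections) {
    ## start each section in its DC steady state for x[1] (no step transient)
    x0 <- x[1]
    h1 <- (s["b0"] + s["b1"] + s["b2"]) / (1 + s["a1"] + s["a2"])
    xx <- x - x0
    xp <- c(0, 0, xx)
    n <- length(x)
    u <- s["b0"] * xp[3:(n + 2)] + s["b1"] * xp[2:(n + 1)] +
      s["b2"] * xp[1:n]
    x <- as.numeric(stats::filter(u, -c(s["a1"], s["a2"]),
                                  method = "recursive")) + h1 * x0
  }
  unname(x)
}

## forward-backward (zero-phase) SOS filtering with odd reflection padding
filtfilt_sos <- function(sections, x, padlen = NULL) {
  n <- length(x)
  padlen <- padlen %||% min(n - 1, 3 * (2 * length(sections) + 1) * 4)
  xl <- 2 * x[1] - x[seq(padlen + 1, 2)]
  xr <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  y <- sosfilt(sections, c(xl, x, xr))
  y <- rev(sosfilt(sections, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Bandpass filter an EEG signal (zero phase)
#'
#' `variant = "fir"` uses the Hamming windowed-sinc design of [fir_design()]
#' applied by symmetric convolution (exact zero phase). `variant = "iir"`
#' uses a Butterworth cascade (order `iir_order` per direction, so twice
#' that effectively) run forward and backward; cutoffs are -3.01 dB per
#' pass, -6.02 dB total.
#'
#' @param signal numeric vector (one channel).
#' @param srate sampling rate; must exceed `2 * high`.
#' @param low,high band edges (Hz).
#' @param variant `"fir"` or `"iir"`.
#' @param l_trans,h_trans FIR transition widths (Hz).
#' @param iir_order per-pass Butterworth order of each edge (even).
#' @return filtered signal, same length.
#' @export
bandpass_filter <- function(signal, srate, low = 0.01, high = 30,
                            variant = c("fir", "iir"),
                            l_trans = 0.01, h_trans = 7.5, iir_order = 8) {
  variant <- match.arg(variant)
  if (srate <= 2 * high) stop("srate must exceed twice the high cutoff")
  if (variant == "fir") {
    kernel <- fir_design(srate, low, high, l_trans, h_trans)
    apply_fir(signal, kernel)
  } else {
    hp <- butter_sos(iir_order, low, srate, "high")
    lp <- butter_sos(iir_order, high, srate, "low")
    ## padding must cover the slow highpass settling (~3 cycles of the low
    ## cutoff) or edge transients bleed into the signal
    pad <- min(length(signal) - 1, ceiling(3 * srate / low))
    filtfilt_sos(lp, filtfilt_sos(hp, signal, padlen = pad))
  }
}

## ---- epoch-level operations ------------------------------------------------

#' Segment a continuous recording into epochs
#'
#' @param continuous samples x channels matrix (or a vector for one channel).
#' @param srate sampling rate (Hz).
#' @param event_samples 1-based sample indices of stimulus onsets.
#' @param window integer vector `c(before, after)` in samples, inclusive at
#'   both ends (`c(-102, 614)` gives 717-sample epochs).
#' @param channel_labels channel names.
#' @return an `epoch_set`; events whose window falls outside the recording
#'   are skipped with a warning.
#' @export
segment_epochs <- function(continuous, srate, event_samples, window,
                           channel_labels = NULL) {
  if (is.null(dim(continuous))) continuous <- matrix(continuous, ncol = 1)
  n <- nrow(continuous)
  nc <- ncol(continuous)
  channel_labels <- channel_labels %||% paste0("ch", seq_len(nc))
  ok <- event_samples + window[1] >= 1 & event_samples + window[2] <= n
  if (any(!ok))
    warning(sum(!ok), " event(s) too close to the recording edge; skipped")
  ev <- event_samples[ok]
  n_samp <- window[2] - window[1] + 1
  dat <- array(0, dim = c(length(ev), nc, n_samp))
  for (i in seq_along(ev)) {
    idx <- (ev[i] + window[1]):(ev[i] + window[2])
    dat[i, , ] <- t(continuous[idx, , drop = FALSE])
  }
  epoch_set(dat, srate, time0 = -window[1] + 1, channel_labels)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline interval
#' (default the 200 ms preceding stimulus onset). Idempotent.
#'
#' @param epochs an `epoch_set`.
#' @param baseline `c(start, end)` in ms, `[start, end)`.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline = c(-200, 0)) {
  tms <- epoch_times(epochs)
  idx <- which(tms >= baseline[1] & tms < baseline[2])
  if (length(idx) == 0) stop("baseline interval outside epoch span")
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over samples
  epochs
}

#' Flag artifact trials
#'
#' A trial is flagged if, on any channel, the peak-to-peak amplitude within
#' any sliding window of `p2p_window` ms (stepped one sample at a time)
#' exceeds `p2p_limit` uV, or any successive-sample difference divided by
#' the inter-sample interval exceeds `step_limit` uV/ms. Flags record which
#' rule fired. Flags are monotone in amplitude: scaling an epoch up never
#' un-flags it.
#'
#' @param epochs an `epoch_set`.
#' @param p2p_limit peak-to-peak limit (uV).
#' @param p2p_window sliding window length (ms).
#' @param step_limit voltage-step limit (uV/ms).
#' @return the `epoch_set` with updated `reject` flags.
#' @export
reject_artifacts <- function(epochs, p2p_limit = 100, p2p_window = 150,
                             step_limit = 50) {
  d <- dim(epochs$data)
  wlen <- max(2L, round(p2p_window * epochs$srate / 1000))
  dt_ms <- 1000 / epochs$srate
  flag <- logical(d[1]); reason <- character(d[1])
  for (t in seq_len(d[1])) {
    hit_p2p <- FALSE; hit_step <- FALSE
    for (c in seq_len(d[2])) {
      x <- epochs$data[t, c, ]
      if (!hit_step && max(abs(diff(x))) / dt_ms > step_limit)
        hit_step <- TRUE
      if (!hit_p2p) {
        nw <- d[3] - wlen + 1
        rmax <- x[seq_len(nw)]; rmin <- rmax
        for (o in seq_len(wlen - 1)) {
          xi <- x[seq_len(nw) + o]
          rmax <- pmax(rmax, xi); rmin <- pmin(rmin, xi)
        }
        if (max(rmax - rmin) > p2p_limit) hit_p2p <- TRUE
      }
      if (hit_p2p && hit_step) break
    }
    flag[t] <- hit_p2p || hit_step
    reason[t] <- paste(c(if (hit_p2p) "p2p", if (hit_step) "step"),
                       collapse = "+")
  }
  epochs$reject <- data.frame(flag = flag, reason = reason,
                              stringsAsFactors = FALSE)
  epochs
}

#' Region-of-interest specification
#'
#' @param name ROI name (e.g. `"N400"`, `"PNP"`, `"P600"`).
#' @param electrodes channel labels.
#' @param window `c(start, end)` in ms, `[start, end)`.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(name, electrodes, window) {
  structure(list(name = name, electrodes = electrodes, window = window),
            class = "roi_spec")
}

#' The study's three analysis regions
#'
#' N400: centro-parietal, 300-500 ms. PNP: anterior, 600-1000 ms.
#' P600: posterior (same electrodes as the N400 ROI), 600-1000 ms.
#'
#' @return named list of [roi_spec()] objects.
#' @export
default_rois <- function() {
  posterior <- c("Cz", "CP1", "CP2", "P3", "Pz", "P4", "POz")
  list(
    N400 = roi_spec("N400", posterior, c(300, 500)),
    PNP = roi_spec("PNP", c("Fpz", "Fp1", "Fp2", "F3", "Fz", "F4"),
                   c(600, 1000)),
    P600 = roi_spec("P600", posterior, c(600, 1000))
  )
}

#' Mean amplitude over an ROI's electrodes and time window
#'
#' @param epochs an `epoch_set`.
#' @param roi a [roi_spec()].
#' @return numeric vector, one mean (uV) per trial (including flagged
#'   trials; exclusion happens when the trial table is built).
#' @export
roi_window_mean <- function(epochs, roi) {
  ch <- match(roi$electrodes, epochs$channel_labels)
  if (anyNA(ch))
    stop("ROI channel(s) missing from epochs: ",
         paste(roi$electrodes[is.na(ch)], collapse = ", "))
  tms <- epoch_times(epochs)
  sm <- which(tms >= roi$window[1] & tms < roi$window[2])
  if (length(sm) == 0) stop("ROI window outside epoch span")
  apply(epochs$data[, ch, sm, drop = FALSE], 1, mean)
}

#' Assemble the trial-level amplitude table from epochs
#'
#' Joins ROI window means with the cloze predictors and the design layout:
#' one row per retained (unflagged) trial per ROI. Epoch `t` must correspond
#' to layout row `t`. Predictor columns are centered over the emitted rows
#' (per ROI subset the rows are identical, so one centering serves all).
#' The rejected fraction is reported via `message()`.
#'
#' @param epochs an `epoch_set` (run [reject_artifacts()] first).
#' @param rois list of [roi_spec()] objects.
#' @param predictors a predictor table (see [build_predictor_table()]).
#' @param layout the design layout that produced the epochs.
#' @return a `trial_table` data.frame with `roi_name` and `amplitude`.
#' @export
build_trial_table <- function(epochs, rois, predictors, layout) {
  if (dim(epochs$data)[1] != nrow(layout))
    stop("epoch count (", dim(epochs$data)[1],
         ") does not match layout rows (", nrow(layout), ")")
  key <- paste(layout$item_id, layout$condition)
  pkey <- paste(predictors$item_id, predictors$condition)
  idx <- match(key, pkey)
  if (anyNA(idx))
    stop("unmatched (item, condition) keys: ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  keep <- !epochs$reject$flag
  message(sprintf("artifact rejection: %d/%d trials rejected (%.1f%%)",
                  sum(!keep), length(keep), 100 * mean(!keep)))
  if (!any(keep)) {
    warning("no trials retained after artifact rejection")
    return(structure(data.frame(), class = c("trial_table", "data.frame")))
  }
  ent <- center_predictor(predictors$entropy_bits[idx][keep])
  clz <- center_predictor(predictors$log2_cloze_smoothed[idx][keep])
  base <- data.frame(
    subject_id = layout$subject_id[keep], item_id = layout$item_id[keep],
    condition = layout$condition[keep],
    trial_order = layout$trial_order[keep],
    post_question = layout$post_question[keep],
    entropy_bits = predictors$entropy_bits[idx][keep],
    log2_cloze_smoothed = predictors$log2_cloze_smoothed[idx][keep],
    entropy_centered = ent, log2_cloze_centered = clz,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(rois, function(r) {
    amp <- roi_window_mean(epochs, r)[keep]
    cbind(base, data.frame(roi_name = r$name, amplitude = amp,
                           stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}
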