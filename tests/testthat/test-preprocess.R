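srate <- 512

test_that("FIR design meets its frequency-response contract", {
  ## default transitions (0.01 Hz low edge, 7.5 Hz high edge)
  k <- fir_design(srate)
  resp <- fir_freq_response(k, c(10, 45), srate)
  expect_lt(abs(resp[1] - 1), 0.01)                  # passband within 1%
  expect_lt(20 * log10(resp[2]), -20)                # >= 20 dB down at 45 Hz
  ## -6 dB at the band edges by design
  edge <- fir_freq_response(k, c(0.01, 30), srate)
  expect_equal(20 * log10(edge), c(-6.02, -6.02), tolerance = 0.15)
})

test_that("FIR application is zero-phase and errors on short signals", {
  ## wider low transition so the kernel fits in a short test signal
  tsec <- seq(0, 4, by = 1 / srate)
  x <- sin(2 * pi * 10 * tsec)
  y <- bandpass_filter(x, srate, low = 1, high = 30, l_trans = 1,
                       variant = "fir")
  ## steady-state gain ~1 and no phase shift: compare mid-signal
  mid <- 800:1200
  expect_lt(max(abs(y[mid] - x[mid])), 0.02)
  ## symmetric input about its midpoint -> symmetric output
  n <- 2049
  xs <- dnorm(seq(-3, 3, length.out = n))
  ys <- bandpass_filter(xs, srate, low = 1, high = 30, l_trans = 1,
                        variant = "fir")
  expect_equal(ys, rev(ys), tolerance = 1e-9)
  kern <- fir_design(srate, low = 1, high = 30, l_trans = 1, h_trans = 7.5)
  expect_error(bandpass_filter(numeric(100), srate, low = 1, l_trans = 1,
                               variant = "fir"),
               "settling")
  expect_error(bandpass_filter(x, 50, high = 30), "twice the high cutoff")
})

test_that("Butterworth sections give -3 dB per pass at cutoffs and strong
          stopband attenuation", {
  lp <- butter_sos(8, 30, srate, "low")
  expect_equal(20 * log10(sos_freq_response(lp, 30, srate)), -3.01,
               tolerance = 0.05)
  expect_lt(20 * log10(sos_freq_response(lp, 45, srate)), -20)
  expect_equal(sos_freq_response(lp, 1, srate), 1, tolerance = 1e-6)
  hp <- butter_sos(8, 1, srate, "high")
  expect_equal(20 * log10(sos_freq_response(hp, 1, srate)), -3.01,
               tolerance = 0.05)
  expect_equal(sos_freq_response(hp, 30, srate), 1, tolerance = 1e-6)
})

test_that("IIR variant is zero-phase with -6.02 dB two-pass cutoffs", {
  tsec <- seq(0, 6, by = 1 / srate)
  x10 <- sin(2 * pi * 10 * tsec)
  y10 <- bandpass_filter(x10, srate, low = 0.1, high = 30, variant = "iir")
  mid <- 1500:1900
  expect_lt(max(abs(y10[mid] - x10[mid])), 0.02)     # unity gain, no shift
  x45 <- sin(2 * pi * 45 * tsec)
  y45 <- bandpass_filter(x45, srate, low = 0.1, high = 30, variant = "iir")
  expect_lt(max(abs(y45[mid])), 10^(-40 / 20))       # two passes: >= 40 dB
  ## two-pass cutoff attenuation
  x30 <- sin(2 * pi * 30 * tsec)
  y30 <- bandpass_filter(x30, srate, low = 0.1, high = 30, variant = "iir")
  g30 <- max(abs(y30[mid]))
  expect_equal(20 * log10(g30), -6.02, tolerance = 0.2)
})

test_that("filtering then baseline-correcting a DC signal leaves < 0.01 uV", {
  lay <- build_design(1, 4, seed = 1)
  ep <- generate_epochs(lay, list(), noise_sd = 0, seed = 1)
  ep$data[] <- 5  # pure DC on every channel
  for (t in 1:4) for (c in seq_along(ep$channel_labels))
    ep$data[t, c, ] <- bandpass_filter(ep$data[t, c, ], srate,
                                       low = 0.1, high = 30,
                                       variant = "iir")
  ep <- baseline_correct(ep)
  tms <- epoch_times(ep)
  win <- tms >= 300 & tms < 1000
  expect_lt(max(abs(ep$data[, , win])), 0.01)
})

test_that("segment_epochs extracts exact windows and skips edge events", {
  x <- matrix(rnorm(3000 * 2), ncol = 2)
  es <- segment_epochs(x, srate, 1000, c(-102, 614))
  expect_equal(dim(es$data), c(1, 2, 717))
  expect_equal(es$data[1, 1, ], x[898:1614, 1])
  expect_equal(es$time0, 103)
  ## zero events -> empty set
  e0 <- segment_epochs(x, srate, integer(0), c(-102, 614))
  expect_equal(dim(e0$data)[1], 0)
  ## overlapping events both extracted
  e2 <- segment_epochs(x, srate, c(1000, 1010), c(-102, 614))
  expect_equal(dim(e2$data)[1], 2)
  expect_equal(e2$data[2, 1, ], x[908:1624, 1])
  ## event too close to the edge is skipped with a warning
  expect_warning(e3 <- segment_epochs(x, srate, c(50, 1000), c(-102, 614)),
                 "skipped")
  expect_equal(dim(e3$data)[1], 1)
})

test_that("baseline correction subtracts the prestim mean and is idempotent", {
  lay <- build_design(1, 4, seed = 2)
  ep <- generate_epochs(lay, list(), noise_sd = 0)
  ep$data[1, , ] <- 5                       # constant channel -> all zeros
  tms <- epoch_times(ep)
  ep$data[2, , ] <- ifelse(tms >= 0, 7, 3)[col(ep$data[2, , ])]
  bc <- baseline_correct(ep)
  expect_equal(max(abs(bc$data[1, , ])), 0)
  expect_equal(unique(round(bc$data[2, 1, tms < 0], 9)), 0)
  expect_equal(unique(round(bc$data[2, 1, tms >= 0], 9)), 4)
  ## post-hoc baseline mean is 0 within 1e-9; applying twice changes nothing
  bl <- tms >= -200 & tms < 0
  expect_lt(max(abs(apply(bc$data[, , bl], c(1, 2), mean))), 1e-9)
  bc2 <- baseline_correct(bc)
  expect_equal(bc2$data, bc$data, tolerance = 1e-12)
})

test_that("artifact rejection applies the p2p and step rules", {
  lay <- build_design(1, 8, seed = 3)
  ep <- generate_epochs(lay, list(), noise_sd = 0)
  tms <- epoch_times(ep)
  ## trial 2: ramp 0 -> 120 uV over 100 ms (p2p rule: 120 > 100 in 150 ms)
  ramp <- which(tms >= 100 & tms < 200)
  ep$data[2, 3, ramp] <- seq(0, 120, length.out = length(ramp))
  ep$data[2, 3, tms >= 200] <- 120
  ## trial 3: single-sample 150 uV jump: 150 / (1000/512) = 76.8 uV/ms
  ep$data[3, 5, tms >= 400] <- ep$data[3, 5, tms >= 400] + 150
  ## trial 4: slow drift of 80 uV over the whole epoch: neither rule
  ep$data[4, 1, ] <- seq(0, 80, length.out = dim(ep$data)[3])
  rj <- reject_artifacts(ep)
  expect_false(rj$reject$flag[1])            # flat epoch retained
  expect_true(rj$reject$flag[2])
  expect_match(rj$reject$reason[2], "p2p")
  expect_true(rj$reject$flag[3])
  expect_match(rj$reject$reason[3], "step")
  expect_false(rj$reject$flag[4])
  ## hand arithmetic: the jump slope
  expect_gt(150 / (1000 / 512), 50)
  ## monotonicity: scaling up never un-flags
  ep_big <- rj; ep_big$data <- ep_big$data * 1.7
  rj2 <- reject_artifacts(ep_big)
  expect_true(all(rj2$reject$flag[rj$reject$flag]))
})

test_that("roi_window_mean averages the right channels and samples", {
  lay <- build_design(1, 4, seed = 4)
  ep <- generate_epochs(lay, list(), noise_sd = 0)
  ep$data[] <- 1
  rois <- default_rois()
  expect_equal(roi_window_mean(ep, rois$N400), rep(1, 4))
  ## linear-in-time signal: mean equals the value at the mean sample time
  tms <- epoch_times(ep)
  a <- 0.5; b <- 0.01
  for (c in seq_along(ep$channel_labels)) ep$data[1, c, ] <- a + b * tms
  win <- tms >= 600 & tms < 1000
  expected <- a + b * mean(tms[win])
  expect_equal(roi_window_mean(ep, rois$PNP)[1], expected,
               tolerance = 1e-12)
  expect_equal(expected, a + b * 800, tolerance = b * 2)  # ~ midpoint value
  bad <- roi_spec("bad", c("Cz", "NOPE"), c(300, 500))
  expect_error(roi_window_mean(ep, bad), "NOPE")
})

test_that("no-noise template epochs recover injected ROI means exactly", {
  lay <- build_design(2, 8, seed = 5)
  rois <- default_rois()
  comp <- list(list(name = "PNP", electrodes = rois$PNP$electrodes,
                    window = c(600, 1000), amplitude = 2),
               list(name = "N400", electrodes = rois$N400$electrodes,
                    window = c(300, 500),
                    amplitude = c(a = -1, b = -3, c = -3, d = -3)))
  ep <- generate_epochs(lay, comp, noise_sd = 0, seed = 6)
  ep <- baseline_correct(ep)
  expect_lt(max(abs(roi_window_mean(ep, rois$PNP) - 2)), 1e-9)
  tm <- attr(ep, "true_means")
  n400 <- roi_window_mean(ep, rois$N400)
  expect_lt(max(abs(n400 - tm$true_mean[tm$component == "N400"])), 1e-9)
  expect_error(generate_epochs(lay, window = c(-100, 1200)), "cover")
})

test_that("stochastic artifact injection matches its binomial oracle", {
  lay <- build_design(5, 200, seed = 7)
  ep <- generate_epochs(lay, list(),
                        artifact_spec = list(blink_rate = 0.1, step_rate = 0,
                                             blink_amp = 150),
                        noise_sd = 0,
                        channel_labels = c("Fp1", "Fpz", "Fp2", "F3", "Fz",
                                           "F4", "Cz", "Pz"),
                        seed = 8)
  rj <- reject_artifacts(ep)
  frac <- mean(rj$reject$flag)
  ## injected trials and flagged trials coincide exactly (clean data is flat)
  expect_identical(rj$reject$flag, attr(ep, "injected") == "blink")
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.1) / 1000
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("epoch container round-trips losslessly", {
  lay <- build_design(1, 4, seed = 9)
  ep <- generate_epochs(lay, list(list(name = "PNP",
                                       electrodes = c("Fz", "F3"),
                                       window = c(600, 1000),
                                       amplitude = 1.5)),
                        noise_sd = 3, seed = 10)
  ep$reject$flag[2] <- TRUE; ep$reject$reason[2] <- "p2p"
  f <- withr::local_tempfile(fileext = ".tsv")
  write_epochs(ep, f)
  back <- read_epochs(f)
  expect_identical(back$data, ep$data)
  expect_identical(back$channel_labels, ep$channel_labels)
  expect_identical(back$reject, ep$reject)
  expect_equal(back$srate, ep$srate)
  expect_equal(back$time0, ep$time0)
})

test_that("build_trial_table joins, excludes flagged trials and re-centers", {
  sim <- simulate_study(1, 12, seed = 11)
  lay <- sim$layout[1:10, ]
  rois <- default_rois()[c("N400", "PNP")]
  comp <- lapply(rois, function(r)
    list(name = r$name, electrodes = r$electrodes, window = r$window,
         amplitude = 2))
  ep <- generate_epochs(lay, comp,
                        artifact_spec = list(step_trials = c(3, 8),
                                             step_amp = 150),
                        noise_sd = 0, seed = 12)
  ep <- baseline_correct(ep)
  ep <- reject_artifacts(ep)
  expect_message(tab <- build_trial_table(ep, rois, sim$predictors, lay),
                 "2/10")
  expect_equal(nrow(tab), 16)                     # (10 - 2) trials x 2 ROIs
  expect_equal(mean(tab$entropy_centered), 0, tolerance = 1e-10)
  expect_equal(mean(tab$log2_cloze_centered), 0, tolerance = 1e-10)
  expect_false(any(tab$item_id %in% lay$item_id[c(3, 8)]))
  ## determinism: identical inputs, identical tables
  tab2 <- suppressMessages(build_trial_table(ep, rois, sim$predictors, lay))
  expect_identical(tab, tab2)
  ## unmatched keys error
  bad_pred <- sim$predictors[-1, ]
  expect_error(suppressMessages(
    build_trial_table(ep, rois, bad_pred, lay)), "unmatched")
  ## everything rejected: empty table with a warning
  ep_all <- ep; ep_all$reject$flag[] <- TRUE
  expect_warning(suppressMessages(
    empty <- build_trial_table(ep_all, rois, sim$predictors, lay)),
    "no trials")
  expect_equal(nrow(empty), 0)
})
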