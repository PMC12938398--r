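test_that("markov hypnogram respects absorbing and stationary structure", {
  # absorbing chain: identity transition keeps the start stage forever
  hyp <- markov_hypnogram(diag(5), n_epochs = 10, seed = 1, start = "N2")
  expect_equal(hyp, rep("N2", 10))

  # law of large numbers under the uniform chain
  un <- matrix(0.2, 5, 5)
  hyp <- markov_hypnogram(un, n_epochs = 50000, seed = 1)
  freqs <- table(factor(hyp, levels = sleep_stages())) / 50000
  expect_true(all(abs(freqs - 0.2) < 0.01))

  # chain tuned to the published ISRUC-S1 stage mix recovers the N2 share
  tab <- isruc_stage_table()
  s1 <- unlist(tab[tab$dataset == "S1", sleep_stages()])
  tm <- stationary_transition(stage_proportions(s1))
  hyp <- markov_hypnogram(tm, n_epochs = 100000, seed = 2)
  expect_equal(mean(hyp == "N2"), 27511 / 87187, tolerance = 0.01 / 0.3)

  bad <- diag(5); bad[3, 3] <- 0.5
  expect_error(markov_hypnogram(bad, 10, 1), "row")
})

test_that("stage waveforms carry the configured spectral signatures", {
  bp <- matrix(0, 5, 5,
    dimnames = list(sleep_stages(),
                    c("delta", "theta", "alpha", "sigma", "beta")))
  bp["N3", "delta"] <- 1
  spec <- cohort_spec(stage_band_power = bp,
                      event_rates = matrix(0, 2, 5,
                        dimnames = list(c("spindle", "kcomplex"),
                                        sleep_stages())),
                      shared_gain = stats::setNames(numeric(5), sleep_stages()),
                      noise_sd = 0)
  sig <- stage_waveform("N3", spec, seed = 4)
  px <- Mod(stats::fft(sig[1, ]))^2
  freqs <- (seq_along(px) - 1) * spec$fs / length(px)
  half <- freqs <= spec$fs / 2
  in_delta <- half & freqs >= 0.5 & freqs <= 4
  expect_gt(sum(px[in_delta]) / sum(px[half & freqs > 0]), 0.8)

  # everything off -> silence
  spec0 <- cohort_spec(stage_band_power = bp * 0,
                       event_rates = spec$event_rates,
                       shared_gain = spec$shared_gain, noise_sd = 0)
  expect_equal(stage_waveform("W", spec0, seed = 1),
               matrix(0, 6, 6000))

  expect_error(stage_waveform("N9", spec), "arg")
})

test_that("N2 epochs contain detectable sigma-band spindle bursts", {
  er <- matrix(0, 2, 5, dimnames = list(c("spindle", "kcomplex"),
                                        sleep_stages()))
  er["spindle", "N2"] <- 6
  # modest sigma baseline so the burst stands out from the background
  bp <- default_band_power(); bp["N2", "sigma"] <- 0.3
  spec <- cohort_spec(stage_band_power = bp, event_rates = er,
                      shared_gain = stats::setNames(numeric(5), sleep_stages()),
                      noise_sd = 0.1)
  for (sd in c(21, 22, 23)) {
    sig <- stage_waveform("N2", spec, seed = sd)
    env <- oracle_sigma_envelope(sig[1, ], spec$fs)
    runs <- rle(env > 3 * stats::median(env))
    long <- runs$lengths[runs$values] / spec$fs
    expect_true(any(long >= 0.3 & long <= 2),
                info = "no contiguous high-sigma-envelope burst found")
  }
})

test_that("propagation lags shift the shared component by whole samples", {
  x <- matrix(rnorm(2 * 1000), 2, 1000)
  zero <- matrix(0, 2, 2)
  expect_identical(apply_propagation_lag(x, zero, fs = 200), x)

  xcorr_argmax <- function(a, b, max_lag = 40) {
    lags <- -max_lag:max_lag
    cc <- vapply(lags, function(l) {
      if (l >= 0) sum(a[seq_len(length(a) - l)] * b[seq_len(length(b) - l) + l])
      else sum(b[seq_len(length(b) + l)] * a[seq_len(length(a) + l) - l])
    }, 0)
    lags[which.max(cc)]
  }
  for (lag_ms in c(50, 100)) {
    src <- rnorm(2000)
    shared <- rbind(src, src)
    lm <- matrix(c(0, lag_ms, lag_ms, 0), 2, 2)
    out <- apply_propagation_lag(shared, lm, fs = 200)
    expect_equal(xcorr_argmax(out[1, ], out[2, ]), lag_ms * 200 / 1000)
  }
  big <- matrix(c(0, 1e7, 1e7, 0), 2, 2)
  expect_error(apply_propagation_lag(x, big, fs = 200), "exceeds")
})

test_that("cohort generation is reproducible and subject-structured", {
  spec <- tiny_spec()
  co <- generate_cohort(spec)
  expect_length(co$records, 6L)
  expect_length(unique(vapply(co$records, `[[`, "", "subject_id")), 2L)
  co2 <- generate_cohort(spec)
  expect_identical(co, co2)

  # multiplicative subject gains dominate between-subject RMS variance
  spec2 <- cohort_spec(n_subjects = 8, epochs_per_subject = 6,
                       epoch_len_s = 4, subject_shift_sd = 0.5,
                       seed = 5)
  ds <- as_dataset(generate_cohort(spec2))
  rms <- apply(ds$signals, 3, function(m) sqrt(mean(m^2)))
  fit <- stats::aov(rms ~ subj, data.frame(rms = rms, subj = ds$subject_id))
  ms <- summary(fit)[[1]]$`Mean Sq`
  expect_gt(ms[1], ms[2])
})

test_that("the dominant configured band carries the most periodogram power", {
  spec <- cohort_spec(n_subjects = 1, epochs_per_subject = 120,
                      stage_transition = matrix(0.2, 5, 5),
                      epoch_len_s = 10, seed = 8)
  ds <- as_dataset(generate_cohort(spec))
  bands <- eeg_bands()
  S <- dim(ds$signals)[2]
  freqs <- (seq_len(S) - 1) * ds$fs / S
  bidx <- lapply(bands, function(b)
    which(freqs >= b[1] & freqs <= b[2] & freqs <= ds$fs / 2))
  for (st in sleep_stages()) {
    idx <- which(ds$labels == st)
    tot <- numeric(length(bands))
    for (e in idx) for (c in seq_len(dim(ds$signals)[1])) {
      px <- Mod(stats::fft(ds$signals[c, , e]))^2
      tot <- tot + vapply(bidx, function(ii) sum(px[ii]), 0)
    }
    expect_equal(which.max(tot),
                 which.max(spec$stage_band_power[st, ]),
                 info = paste("stage", st))
  }
})

test_that("synthetic signatures are linearly learnable, and only then", {
  skip_if_not_installed("nnet")
  uni <- matrix(0.2, 5, 5)
  spec <- cohort_spec(n_subjects = 1, epochs_per_subject = 700,
                      stage_transition = uni, epoch_len_s = 6, seed = 31)
  ds <- as_dataset(generate_cohort(spec))
  X <- band_power_features(ds)
  df <- data.frame(y = ds$labels, X)
  tr <- 1:500; te <- 501:700
  fit <- nnet::multinom(y ~ ., df[tr, ], trace = FALSE, MaxNWts = 5000)
  acc <- mean(predict(fit, df[te, ]) == df$y[te])
  expect_gt(acc, 0.7)

  # flat signatures: identical band powers, no events, equal shared gain
  bp <- spec$stage_band_power
  bp[] <- rep(bp["W", ], each = 5)
  spec0 <- cohort_spec(n_subjects = 1, epochs_per_subject = 700,
                       stage_transition = uni, epoch_len_s = 6,
                       stage_band_power = bp,
                       event_rates = spec$event_rates * 0,
                       shared_gain = stats::setNames(rep(0.5, 5),
                                                     sleep_stages()),
                       seed = 32)
  ds0 <- as_dataset(generate_cohort(spec0))
  X0 <- band_power_features(ds0)
  df0 <- data.frame(y = ds0$labels, X0)
  fit0 <- nnet::multinom(y ~ ., df0[tr, ], trace = FALSE, MaxNWts = 5000)
  acc0 <- mean(predict(fit0, df0[te, ]) == df0$y[te])
  expect_lt(abs(acc0 - 0.2), 0.07)
})

test_that("cohorts round-trip through the CSV writer", {
  co <- generate_cohort(tiny_spec())
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  co2 <- read_cohort(dir, fs = 200, epoch_len_s = 6)
  expect_equal(vapply(co2$records, `[[`, "", "label"),
               vapply(co$records, `[[`, "", "label"))
  err <- max(abs(co2$records[[4]]$signal - co$records[[4]]$signal))
  expect_lt(err, 1e-4)   # CSV keeps ~7 significant digits
})
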