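# Synthetic polysomnography cohorts with the statistical structure the model
# assumes: stage-dependent spectral signatures, transient events (spindles,
# K-complexes), inter-channel propagation lags, Markovian stage sequences and
# subject-level baseline shifts.

#' Sleep stage labels in fixed order
#'
#' Wake, N1, N2, N3, REM; encoded 0..4 throughout the package.
#' @export
sleep_stages <- function() c("W", "N1", "N2", "N3", "R")

#' Canonical EEG frequency bands (Hz)
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, sigma 11-16, beta 13-30.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       sigma = c(11, 16), beta = c(13, 30))
}

# Run code under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default stage-transition matrix
#'
#' 0.85 self-transition with physiologically ordered off-diagonals (N3
#' returns through N2, REM is entered mostly from N2, and so on).
#' @export
default_transition <- function() {
  s <- sleep_stages()
  tm <- matrix(0, 5, 5, dimnames = list(s, s))
  diag(tm) <- 0.85
  tm["W",  c("N1", "N2", "N3", "R")] <- c(0.100, 0.020, 0.005, 0.025)
  tm["N1", c("W", "N2", "N3", "R")]  <- c(0.040, 0.090, 0.005, 0.015)
  tm["N2", c("W", "N1", "N3", "R")]  <- c(0.020, 0.030, 0.070, 0.030)
  tm["N3", c("W", "N1", "N2", "R")]  <- c(0.010, 0.005, 0.120, 0.015)
  tm["R",  c("W", "N1", "N2", "N3")] <- c(0.050, 0.050, 0.045, 0.005)
  tm
}

#' Default per-stage band amplitudes
#'
#' Stage x band (delta, theta, alpha, sigma, beta) oscillation amplitudes:
#' delta-dominant N3, sigma-rich N2, theta-dominant N1, alpha Wake, mixed
#' theta/beta REM.
#' @export
default_band_power <- function() {
  s <- sleep_stages()
  bp <- rbind(
    W  = c(delta = 0.30, theta = 0.30, alpha = 1.00, sigma = 0.20, beta = 0.60),
    N1 = c(delta = 0.40, theta = 1.00, alpha = 0.40, sigma = 0.20, beta = 0.30),
    N2 = c(delta = 0.70, theta = 0.50, alpha = 0.30, sigma = 1.00, beta = 0.20),
    N3 = c(delta = 1.50, theta = 0.30, alpha = 0.15, sigma = 0.20, beta = 0.10),
    R  = c(delta = 0.30, theta = 0.90, alpha = 0.50, sigma = 0.20, beta = 0.55))
  rownames(bp) <- s
  bp
}

#' Default transient-event rates (expected count per 30 s epoch)
#' @export
default_event_rates <- function() {
  s <- sleep_stages()
  rbind(spindle   = c(W = 0, N1 = 0, N2 = 3.0, N3 = 0.5, R = 0),
        kcomplex  = c(W = 0, N1 = 0, N2 = 1.5, N3 = 0.5, R = 0))[, s]
}

#' Default propagation-lag matrix (ms)
#'
#' Linear anterior-to-posterior propagation: 15 ms per channel step.
#' @param n_channels number of channels.
#' @export
default_lag_matrix <- function(n_channels) {
  # anterior-to-posterior propagation from channel 1, 15 ms per step
  lg <- outer(seq_len(n_channels), seq_len(n_channels),
              function(i, j) 15 * abs(j - i))
  diag(lg) <- 0
  lg
}

#' Specify a synthetic polysomnography cohort
#'
#' Bundles every knob of the generator: cohort shape, Markov stage dynamics,
#' per-stage band amplitudes, transient-event rates, inter-channel propagation
#' lags, subject-level gain variability and additive noise. Amplitudes are in
#' arbitrary units; downstream processing z-scores each epoch.
#'
#' @param n_subjects number of subjects.
#' @param epochs_per_subject 30 s epochs generated per subject.
#' @param fs sampling rate in Hz.
#' @param epoch_len_s epoch duration in seconds; `fs * epoch_len_s` must be a
#'   whole number of samples.
#' @param n_channels number of EEG-like channels.
#' @param stage_transition 5x5 row-stochastic Markov matrix over
#'   W, N1, N2, N3, R (rows must sum to 1 within 1e-9).
#' @param stage_band_power 5x5 matrix, stages x bands
#'   (delta, theta, alpha, sigma, beta), of oscillation amplitudes.
#' @param event_rates 2x5 matrix (spindle, kcomplex) x stages of expected
#'   event counts per epoch.
#' @param lag_matrix channel x channel propagation delay in milliseconds,
#'   zero diagonal; row `i` holds the delays of the shared component from
#'   source channel `i` to every channel.
#' @param shared_gain per-stage amplitude of the lag-propagated shared
#'   broadband source (drives inter-channel correlation).
#' @param subject_shift_sd SD (log scale) of the per-subject multiplicative
#'   amplitude gain; subjects also receive a small alpha-peak frequency
#'   offset (SD 0.4 Hz).
#' @param noise_sd SD of additive white noise.
#' @param spindle_amp,kcomplex_amp peak amplitudes of the transient events.
#' @param seed integer seed; the cohort is a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 2L, epochs_per_subject = 100L,
                        fs = 200, epoch_len_s = 30, n_channels = 6L,
                        stage_transition = default_transition(),
                        stage_band_power = default_band_power(),
                        event_rates = default_event_rates(),
                        lag_matrix = default_lag_matrix(n_channels),
                        shared_gain = c(W = 0.8, N1 = 0.5, N2 = 0.5,
                                        N3 = 0.2, R = 0.5),
                        subject_shift_sd = 0.2, noise_sd = 0.3,
                        spindle_amp = 3, kcomplex_amp = 4, seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               epochs_per_subject = as.integer(epochs_per_subject),
               fs = fs, epoch_len_s = epoch_len_s,
               n_channels = as.integer(n_channels),
               stage_transition = stage_transition,
               stage_band_power = stage_band_power,
               event_rates = event_rates, lag_matrix = lag_matrix,
               shared_gain = shared_gain,
               subject_shift_sd = subject_shift_sd, noise_sd = noise_sd,
               spindle_amp = spindle_amp, kcomplex_amp = kcomplex_amp,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  check_stochastic(spec$stage_transition)
  ns <- spec$fs * spec$epoch_len_s
  if (abs(ns - round(ns)) > 1e-9)
    stop("fs * epoch_len_s must be an integer number of samples, got ", ns)
  if (any(diag(spec$lag_matrix) != 0))
    stop("lag_matrix must have a zero diagonal")
  if (!all(dim(spec$lag_matrix) == spec$n_channels))
    stop("lag_matrix must be n_channels x n_channels")
  invisible(spec)
}

check_stochastic <- function(tm) {
  if (!is.matrix(tm) || any(dim(tm) != 5L))
    stop("stage transition matrix must be 5x5")
  rs <- rowSums(tm)
  bad <- which(abs(rs - 1) > 1e-9 | apply(tm < 0, 1L, any))
  if (length(bad))
    stop("transition rows not stochastic: row(s) ",
         paste(bad, collapse = ", "))
  invisible(tm)
}

#' Build a transition matrix with a prescribed stationary distribution
#'
#' Returns `self * I + (1 - self) * 1 p^T`, whose stationary distribution is
#' exactly `p` for any self-transition weight in \[0, 1).
#'
#' @param p length-5 probability vector over W, N1, N2, N3, R.
#' @param self self-transition inertia.
#' @export
stationary_transition <- function(p, self = 0.85) {
  stopifnot(length(p) == 5L, all(p >= 0), abs(sum(p) - 1) < 1e-9)
  tm <- self * diag(5) + (1 - self) * matrix(p, 5, 5, byrow = TRUE)
  dimnames(tm) <- list(sleep_stages(), sleep_stages())
  tm
}

#' Simulate a Markovian hypnogram
#'
#' Draws a stage sequence from a first-order Markov chain; with no `start`
#' the initial stage is drawn from the chain's stationary distribution.
#'
#' @param transition 5x5 row-stochastic matrix over W, N1, N2, N3, R.
#' @param n_epochs sequence length.
#' @param seed integer seed.
#' @param start optional initial stage (label or index 1..5).
#' @return character vector of stage labels.
#' @export
markov_hypnogram <- function(transition, n_epochs, seed = 1L, start = NULL) {
  check_stochastic(transition)
  st <- sleep_stages()
  n_epochs <- as.integer(n_epochs)
  if (n_epochs <= 0L) return(character(0))
  pi0 <- markov_stationary(transition)
  with_seed(seed, {
    cur <- if (is.null(start)) sample.int(5L, 1L, prob = pi0)
           else if (is.character(start)) match(start, st)
           else as.integer(start)
    if (is.na(cur) || cur < 1L || cur > 5L) stop("invalid start stage")
    out <- integer(n_epochs)
    out[1L] <- cur
    if (n_epochs > 1L) for (t in 2:n_epochs) {
      cur <- sample.int(5L, 1L, prob = transition[cur, ])
      out[t] <- cur
    }
    st[out]
  })
}

markov_stationary <- function(tm) {
  ev <- eigen(t(tm))
  i <- which.min(abs(ev$values - 1))
  v <- abs(Re(ev$vectors[, i]))
  v / sum(v)
}

# Band-limited oscillation: superposition of sinusoids with random in-band
# frequencies and phases, unit RMS before amplitude scaling.
band_oscillation <- function(n, fs, band, n_sin = 12L) {
  tt <- seq_len(n) / fs
  f <- stats::runif(n_sin, band[1], band[2])
  ph <- stats::runif(n_sin, 0, 2 * pi)
  x <- colSums(sin(outer(f, tt, function(fr, ti) 2 * pi * fr * ti) + ph))
  x * sqrt(2 / n_sin)
}

spindle_template <- function(dur_s, fs, f0) {
  n <- max(2L, round(dur_s * fs))
  tt <- seq_len(n) / fs
  env <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))  # Hann envelope
  env * sin(2 * pi * f0 * tt)
}

kcomplex_template <- function(dur_s, fs) {
  n <- max(2L, round(dur_s * fs))
  u <- seq_len(n) / n
  # sharp negative deflection followed by a slower positive rebound
  -1.0 * exp(-((u - 0.3) / 0.08)^2) + 0.7 * exp(-((u - 0.62) / 0.18)^2)
}

place_events <- function(x, rate, amp, template_fn, fs, ...) {
  if (rate <= 0) return(x)
  n_ev <- stats::rpois(1L, rate)
  if (n_ev == 0L) return(x)
  n <- length(x)
  for (k in seq_len(n_ev)) {
    tpl <- amp * template_fn(...)
    if (length(tpl) >= n) next
    at <- sample.int(n - length(tpl), 1L)
    idx <- at:(at + length(tpl) - 1L)
    x[idx] <- x[idx] + tpl
  }
  x
}

# One channel's stage-specific content (no shared source, no noise).
channel_waveform <- function(stage, spec, alpha_offset = 0) {
  n <- round(spec$fs * spec$epoch_len_s)
  bands <- eeg_bands()
  amps <- spec$stage_band_power[stage, ]
  x <- numeric(n)
  for (b in seq_along(bands)) {
    if (amps[b] == 0) next
    band <- bands[[b]]
    if (names(bands)[b] == "alpha") band <- band + alpha_offset
    x <- x + amps[b] * band_oscillation(n, spec$fs, band)
  }
  x <- place_events(x, spec$event_rates["spindle", stage], spec$spindle_amp,
                    function() spindle_template(stats::runif(1, 0.5, 1.5),
                                                spec$fs,
                                                stats::runif(1, 11, 16)))
  x <- place_events(x, spec$event_rates["kcomplex", stage], spec$kcomplex_amp,
                    function() kcomplex_template(stats::runif(1, 0.5, 2),
                                                 spec$fs))
  x
}

#' Generate one synthetic epoch for a given stage
#'
#' The signal is a per-channel sum of band-limited oscillations weighted by
#' the stage's band amplitudes, sparse transient events (sigma-band spindle
#' bursts of 0.5-1.5 s; biphasic K-complexes of 0.5-2 s), a shared broadband
#' component propagated across channels with the spec's lags, and white
#' noise. Deterministic under a fixed seed.
#'
#' @param stage one of W, N1, N2, N3, R.
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return channels x samples matrix.
#' @export
stage_waveform <- function(stage, spec, seed = 1L) {
  stage <- match.arg(stage, sleep_stages())
  with_seed(seed, gen_epoch_signal(stage, spec, gain = 1, alpha_offset = 0))
}

gen_epoch_signal <- function(stage, spec, gain, alpha_offset) {
  n <- round(spec$fs * spec$epoch_len_s)
  C <- spec$n_channels
  sig <- matrix(0, C, n)
  for (c in seq_len(C))
    sig[c, ] <- channel_waveform(stage, spec, alpha_offset)
  sg <- spec$shared_gain[stage]
  if (!is.na(sg) && sg > 0) {
    shared <- sg * (band_oscillation(n, spec$fs, c(0.5, 30), n_sin = 24L))
    shared_mat <- matrix(rep(shared, each = C), C, n, byrow = FALSE)
    sig <- sig + apply_propagation_lag(shared_mat, spec$lag_matrix, spec$fs)
  }
  if (spec$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(C * n, 0, spec$noise_sd), C, n)
  gain * sig
}

#' Delay each channel's shared component by the configured propagation lag
#'
#' Channel `j` of the output is channel `j` of the input shifted right by
#' `lag_matrix[src, j]` milliseconds (rounded to whole samples at `fs`),
#' zero-padded at the leading edge. A zero lag matrix returns the input
#' unchanged.
#'
#' @param signal channels x samples matrix.
#' @param lag_matrix channel x channel delays in ms (zero diagonal).
#' @param fs sampling rate in Hz.
#' @param src source-channel row of `lag_matrix` to use.
#' @return matrix of the same shape.
#' @export
apply_propagation_lag <- function(signal, lag_matrix, fs, src = 1L) {
  n <- ncol(signal)
  out <- signal
  for (j in seq_len(nrow(signal))) {
    d <- round(lag_matrix[src, j] * fs / 1000)
    if (d == 0) next
    if (abs(d) >= n) stop("lag of ", lag_matrix[src, j],
                          " ms exceeds the epoch length")
    if (d > 0) out[j, ] <- c(numeric(d), signal[j, seq_len(n - d)])
    else out[j, ] <- c(signal[j, (1 - d):n], numeric(-d))
  }
  out
}

#' Generate a labelled synthetic cohort
#'
#' Simulates `n_subjects * epochs_per_subject` epochs. Each subject receives
#' a Markovian hypnogram, one multiplicative amplitude gain
#' (log-normal, sdlog = `subject_shift_sd`) and a small alpha-peak frequency
#' offset, giving the domain discriminator a real subject signal to remove.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A `psg_cohort`: list with `records` (each holding `signal`,
#'   `label`, `subject_id`, `fs`) and the generating `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  records <- with_seed(spec$seed, {
    recs <- vector("list", spec$n_subjects * spec$epochs_per_subject)
    k <- 0L
    for (s in seq_len(spec$n_subjects)) {
      gain <- exp(stats::rnorm(1, 0, spec$subject_shift_sd))
      alpha_offset <- stats::rnorm(1, 0, 0.4)
      hyp_seed <- sample.int(.Machine$integer.max, 1L)
      hyp <- markov_hypnogram(spec$stage_transition,
                              spec$epochs_per_subject, seed = hyp_seed)
      for (e in seq_len(spec$epochs_per_subject)) {
        k <- k + 1L
        recs[[k]] <- list(
          signal = gen_epoch_signal(hyp[e], spec, gain, alpha_offset),
          label = hyp[e],
          subject_id = sprintf("S%02d", s),
          fs = spec$fs)
      }
    }
    recs
  })
  structure(list(records = records, spec = spec), class = "psg_cohort")
}

#' @export
print.psg_cohort <- function(x, ...) {
  n <- length(x$records)
  subj <- unique(vapply(x$records, `[[`, "", "subject_id"))
  cat("psg_cohort:", n, "epochs,", length(subj), "subjects,",
      x$spec$n_channels, "channels @", x$spec$fs, "Hz\n")
  print(table(factor(vapply(x$records, `[[`, "", "label"),
                     levels = sleep_stages())))
  invisible(x)
}

#' Write a cohort to a directory of per-subject CSVs plus a hypnogram TSV
#'
#' Signals are written one CSV per subject (rows = channels, columns =
#' concatenated samples, header = channel names); labels go to
#' `hypnogram.tsv` with columns epoch_index, stage, subject_id.
#'
#' @param cohort a `psg_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subj <- vapply(cohort$records, `[[`, "", "subject_id")
  for (s in unique(subj)) {
    sig <- do.call(cbind, lapply(cohort$records[subj == s], `[[`, "signal"))
    write_recording_csv(sig, file.path(dir, paste0(s, ".csv")))
  }
  hyp <- data.frame(
    epoch_index = seq_along(cohort$records),
    stage = vapply(cohort$records, `[[`, "", "label"),
    subject_id = subj)
  utils::write.table(hyp, file.path(dir, "hypnogram.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing per-subject CSVs and `hypnogram.tsv`.
#' @param fs sampling rate of the stored signals.
#' @param epoch_len_s epoch length in seconds.
#' @return a `psg_cohort` (spec slot carries only the reread geometry).
#' @export
read_cohort <- function(dir, fs = 200, epoch_len_s = 30) {
  hyp <- utils::read.delim(file.path(dir, "hypnogram.tsv"),
                           stringsAsFactors = FALSE)
  ns <- round(fs * epoch_len_s)
  records <- vector("list", nrow(hyp))
  for (s in unique(hyp$subject_id)) {
    sig <- read_recording(file.path(dir, paste0(s, ".csv")), format = "csv",
                          fs = fs)$signals
    rows <- which(hyp$subject_id == s)
    for (k in seq_along(rows)) {
      records[[rows[k]]] <- list(
        signal = sig[, ((k - 1) * ns + 1):(k * ns), drop = FALSE],
        label = hyp$stage[rows[k]],
        subject_id = s, fs = fs)
    }
  }
  structure(list(records = records,
                 spec = list(n_channels = nrow(records[[1]]$signal),
                             fs = fs, epoch_len_s = epoch_len_s)),
            class = "psg_cohort")
}
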