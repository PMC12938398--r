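# Reading recordings (CSV / EDF), 30 s epoch segmentation, per-epoch
# z-scoring, and subject-wise train/val/test splitting.

#' Read a multichannel recording
#'
#' CSV dialect: one row per channel, a header row of channel names,
#' comma-separated samples. EDF/EDF+: standard 16-bit format, read by the
#' built-in parser ([read_edf()]).
#'
#' @param path file path.
#' @param format "csv" or "edf".
#' @param channels optional character vector: channels to keep, in the
#'   requested order. Missing channels raise an error listing what is
#'   available.
#' @param fs sampling rate for CSV input (EDF carries its own).
#' @param subject_id identifier attached to the recording (defaults to the
#'   file name).
#' @return A `psg_recording`: list with `signals` (channels x samples),
#'   `channel_names`, `fs`, `subject_id`.
#' @export
read_recording <- function(path, format = c("csv", "edf"), channels = NULL,
                           fs = 200, subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]+$", "", basename(path))
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    sig <- unname(as.matrix(df[, -1, drop = FALSE]))  # rows are channels
    nm <- as.character(df[[1]])
    rec <- list(signals = unname(sig), channel_names = nm, fs = fs,
                subject_id = subject_id)
  } else {
    rec <- read_edf(path)
    rec$subject_id <- subject_id
  }
  if (!is.null(channels)) {
    idx <- match(channels, rec$channel_names)
    if (anyNA(idx))
      stop("channel(s) not found: ",
           paste(channels[is.na(idx)], collapse = ", "),
           "; available: ", paste(rec$channel_names, collapse = ", "))
    rec$signals <- rec$signals[idx, , drop = FALSE]
    rec$channel_names <- channels
  }
  rownames(rec$signals) <- NULL
  class(rec) <- "psg_recording"
  rec
}

#' Write a channels x samples matrix as the package's CSV dialect
#'
#' @param signals channels x samples matrix.
#' @param path output path.
#' @param channel_names header names (defaults to ch1..chC).
#' @export
write_recording_csv <- function(signals, path, channel_names = NULL) {
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(signals)))
  df <- data.frame(channel = channel_names, signals, check.names = FALSE)
  colnames(df) <- c("channel", seq_len(ncol(signals)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Segment a recording into fixed-length labelled epochs
#'
#' Cuts consecutive non-overlapping epochs of `epoch_len_s` seconds from the
#' start of the recording; the trailing remainder is discarded. One label per
#' epoch is required.
#'
#' @param rec a `psg_recording`.
#' @param labels stage labels (W, N1, N2, N3, R), one per epoch.
#' @param epoch_len_s epoch length in seconds.
#' @return A `psg_dataset` (see [psg_dataset()]).
#' @export
segment_epochs <- function(rec, labels, epoch_len_s = 30) {
  ns <- round(rec$fs * epoch_len_s)
  avail <- floor(ncol(rec$signals) / ns)
  if (length(labels) > avail)
    stop("labels (", length(labels), ") exceed available epochs (", avail, ")")
  n <- length(labels)
  sig <- array(0, dim = c(nrow(rec$signals), ns, n))
  for (e in seq_len(n))
    sig[, , e] <- rec$signals[, ((e - 1) * ns + 1):(e * ns)]
  psg_dataset(sig, labels, rep(rec$subject_id, n), rec$fs)
}

#' Construct a labelled epoch dataset
#'
#' The canonical container of the package: a 3-D array of epochs plus
#' aligned stage labels and subject identifiers. Class names are fixed in
#' the order W, N1, N2, N3, R (encoded 0..4).
#'
#' @param signals channels x samples x epochs array.
#' @param labels stage labels, one per epoch.
#' @param subject_id one identifier per epoch.
#' @param fs sampling rate in Hz.
#' @export
psg_dataset <- function(signals, labels, subject_id, fs = 200) {
  stages <- sleep_stages()
  if (length(dim(signals)) != 3L) stop("signals must be a 3-D array")
  n <- dim(signals)[3]
  labels <- as.character(labels)
  if (length(labels) != n || length(subject_id) != n)
    stop("labels and subject_id must have one entry per epoch")
  if (!all(labels %in% stages))
    stop("invalid stage label(s): ",
         paste(unique(setdiff(labels, stages)), collapse = ", "))
  structure(list(signals = signals,
                 labels = factor(labels, levels = stages),
                 subject_id = as.character(subject_id), fs = fs),
            class = "psg_dataset")
}

#' @export
print.psg_dataset <- function(x, ...) {
  d <- dim(x$signals)
  cat("psg_dataset:", d[3], "epochs,", d[1], "channels x", d[2],
      "samples @", x$fs, "Hz,", length(unique(x$subject_id)), "subjects\n")
  print(table(x$labels))
  invisible(x)
}

#' Number of epochs in a dataset
#' @param dataset a `psg_dataset`.
#' @export
n_epochs <- function(dataset) dim(dataset$signals)[3]

#' Subset a dataset by epoch index
#' @param dataset a `psg_dataset`.
#' @param idx epoch indices to keep.
#' @export
dataset_subset <- function(dataset, idx) {
  psg_dataset(dataset$signals[, , idx, drop = FALSE],
              as.character(dataset$labels[idx]),
              dataset$subject_id[idx], dataset$fs)
}

#' Convert a generated cohort to a `psg_dataset`
#' @param cohort a `psg_cohort` from [generate_cohort()].
#' @export
as_dataset <- function(cohort) {
  recs <- cohort$records
  d1 <- dim(recs[[1]]$signal)
  sig <- array(0, dim = c(d1[1], d1[2], length(recs)))
  for (e in seq_along(recs)) sig[, , e] <- recs[[e]]$signal
  psg_dataset(sig, vapply(recs, `[[`, "", "label"),
              vapply(recs, `[[`, "", "subject_id"), recs[[1]]$fs)
}

#' Per-epoch, per-channel z-scoring
#'
#' Each channel of each epoch is centred and scaled to unit SD; constant
#' channels map to all zeros. Idempotent up to floating-point error.
#'
#' @param dataset a `psg_dataset`.
#' @export
zscore_normalize <- function(dataset) {
  sig <- dataset$signals
  for (e in seq_len(dim(sig)[3])) {
    x <- sig[, , e]
    mu <- rowMeans(x)
    sdv <- sqrt(rowMeans((x - mu)^2))
    sdv[sdv < 1e-12] <- Inf   # constant channel -> zeros
    sig[, , e] <- (x - mu) / sdv
  }
  dataset$signals <- sig
  dataset
}

#' Subject-wise train/validation/test split
#'
#' Subjects (never epochs) are partitioned, so no subject contributes to
#' more than one split. With `loso = TRUE` the result is a list of
#' leave-one-subject-out folds instead.
#'
#' @param dataset a `psg_dataset`.
#' @param fractions numeric vector of subject fractions (e.g. c(.7,.15,.15));
#'   names train/val/test are attached in order.
#' @param loso if TRUE, return `n_subjects` folds, each testing on exactly
#'   one held-out subject.
#' @param seed integer seed for the subject shuffle.
#' @return list of epoch-index vectors (`train`, `val`, `test`), or a list
#'   of `n_subjects` folds with `train`/`test` for LOSO.
#' @export
subject_split <- function(dataset, fractions = c(0.7, 0.15, 0.15),
                          loso = FALSE, seed = 1L) {
  subj <- unique(dataset$subject_id)
  if (loso) {
    return(lapply(subj, function(s) list(
      train = which(dataset$subject_id != s),
      test = which(dataset$subject_id == s),
      held_out = s)))
  }
  k <- length(fractions)
  if (length(subj) < k)
    stop(length(subj), " subjects cannot be split ", k, " ways")
  perm <- with_seed(seed, sample(subj))
  counts <- floor(fractions / sum(fractions) * length(subj))
  counts[1] <- length(subj) - sum(counts[-1])
  groups <- rep(seq_len(k), counts)
  out <- lapply(seq_len(k), function(g)
    which(dataset$subject_id %in% perm[groups == g]))
  names(out) <- c("train", "val", "test")[seq_len(k)]
  out
}

#' Log band-power features per epoch
#'
#' Average periodogram power in the five canonical bands, per channel,
#' log-transformed: the simple feature set used to verify that synthetic
#' stage signatures are linearly learnable.
#'
#' @param dataset a `psg_dataset`.
#' @return epochs x (channels * 5 bands) matrix.
#' @export
band_power_features <- function(dataset) {
  bands <- eeg_bands()
  d <- dim(dataset$signals)
  n <- d[3]; C <- d[1]; S <- d[2]
  freqs <- (seq_len(S) - 1) * dataset$fs / S
  bidx <- lapply(bands, function(b) which(freqs >= b[1] & freqs <= b[2]))
  out <- matrix(0, n, C * length(bands))
  for (e in seq_len(n)) {
    for (c in seq_len(C)) {
      px <- Mod(stats::fft(dataset$signals[c, , e]))^2 / S
      out[e, ((c - 1) * length(bands) + 1):(c * length(bands))] <-
        log(vapply(bidx, function(ii) mean(px[ii]), 0) + 1e-12)
    }
  }
  colnames(out) <- unlist(lapply(seq_len(C), function(c)
    paste0("ch", c, "_", names(bands))))
  out
}

#' Read a hypnogram TSV (epoch_index, stage, subject_id)
#' @param path TSV path.
#' @export
read_hypnogram <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
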