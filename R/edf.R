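# Minimal EDF/EDF+ support: fixed-width ASCII header, 16-bit little-endian
# samples, one-second data records. Covers continuous equal-rate signals,
# which is all polysomnography export needs here.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' Signals are scaled per channel to the full 16-bit digital range; the
#' physical range is stored in the header, so the round-trip error is
#' bounded by one digital quantization step.
#'
#' @param signals channels x samples matrix.
#' @param path output path.
#' @param fs sampling rate in Hz (samples per one-second data record);
#'   `ncol(signals)` must be a multiple of `fs`.
#' @param channel_names channel labels (max 16 characters each).
#' @export
write_edf <- function(signals, path, fs = 200, channel_names = NULL) {
  C <- nrow(signals); n <- ncol(signals)
  if (n %% fs != 0) stop("sample count must be a multiple of fs")
  n_rec <- n %/% fs
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(C))
  pmin <- apply(signals, 1L, min); pmax <- apply(signals, 1L, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(pad_field("0", 8L))                       # version
  wr(pad_field("X X X X", 80L))                # patient id
  wr(pad_field("Startdate X X X X", 80L))      # recording id
  wr(pad_field("01.01.00", 8L)); wr(pad_field("00.00.00", 8L))
  wr(pad_field(256L * (1L + C), 8L))           # header bytes
  wr(pad_field("", 44L))
  wr(pad_field(n_rec, 8L)); wr(pad_field("1", 8L))
  wr(pad_field(C, 4L))
  for (nm in channel_names) wr(pad_field(nm, 16L))
  for (i in seq_len(C)) wr(pad_field("", 80L))        # transducer
  for (i in seq_len(C)) wr(pad_field("uV", 8L))       # dimension
  for (i in seq_len(C)) wr(pad_field(sprintf("%.6g", pmin[i]), 8L))
  for (i in seq_len(C)) wr(pad_field(sprintf("%.6g", pmax[i]), 8L))
  for (i in seq_len(C)) wr(pad_field(dmin, 8L))
  for (i in seq_len(C)) wr(pad_field(dmax, 8L))
  for (i in seq_len(C)) wr(pad_field("", 80L))        # prefiltering
  for (i in seq_len(C)) wr(pad_field(fs, 8L))
  for (i in seq_len(C)) wr(pad_field("", 32L))
  # header physical range reparsed so stored/decoded gains agree exactly
  pmin_h <- as.numeric(sprintf("%.6g", pmin))
  pmax_h <- as.numeric(sprintf("%.6g", pmax))
  gain <- (dmax - dmin) / (pmax_h - pmin_h)
  dig <- matrix(0L, C, n)
  for (i in seq_len(C)) {
    d <- round((signals[i, ] - pmin_h[i]) * gain[i]) + dmin
    dig[i, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(C))
      writeBin(dig[i, idx], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF/EDF+ file
#'
#' Continuous recordings with one common sampling rate are supported;
#' annotation channels ("EDF Annotations") are dropped.
#'
#' @param path EDF path.
#' @return list with `signals` (channels x samples), `channel_names`, `fs`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  rd(8L)                                  # version
  rd(80L); rd(80L); rd(8L); rd(8L)
  header_bytes <- as.integer(rd(8L))
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  C <- as.integer(rd(4L))
  labels <- vapply(seq_len(C), function(i) rd(16L), "")
  for (i in seq_len(C)) rd(80L)
  for (i in seq_len(C)) rd(8L)
  pmin <- vapply(seq_len(C), function(i) as.numeric(rd(8L)), 0)
  pmax <- vapply(seq_len(C), function(i) as.numeric(rd(8L)), 0)
  dmin <- vapply(seq_len(C), function(i) as.numeric(rd(8L)), 0)
  dmax <- vapply(seq_len(C), function(i) as.numeric(rd(8L)), 0)
  for (i in seq_len(C)) rd(80L)
  spr <- vapply(seq_len(C), function(i) as.integer(rd(8L)), 0L)
  for (i in seq_len(C)) rd(32L)
  seek(con, header_bytes)
  keep <- labels != "EDF Annotations"
  sig <- vector("list", C)
  for (i in which(keep)) sig[[i]] <- numeric(n_rec * spr[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(C)) {
      d <- readBin(con, "integer", spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      if (keep[i]) {
        gain <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
        sig[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
          pmin[i] + (d - dmin[i]) * gain
      }
    }
  }
  sig <- sig[keep]
  if (length(unique(spr[keep])) != 1L)
    stop("channels with differing sampling rates are not supported")
  fs <- spr[keep][1] / rec_dur
  list(signals = do.call(rbind, sig), channel_names = labels[keep], fs = fs)
}
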