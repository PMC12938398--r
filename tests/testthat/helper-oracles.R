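# Shared fixtures and independent brute-force oracles used across the suite.
# Oracles are written directly from the printed formulas and never call the
# package's own implementations.

tiny_spec <- function(...) {
  cohort_spec(n_subjects = 2L, epochs_per_subject = 3L, epoch_len_s = 6,
              seed = 99L, ...)
}

# Direct two-pass Pearson correlation of two vectors.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_pearson_matrix <- function(W) {
  C <- nrow(W)
  A <- diag(C)
  for (i in seq_len(C)) for (j in seq_len(C)) if (i != j)
    A[i, j] <- oracle_pearson(W[i, ], W[j, ])
  A
}

# Explicit double loop over Eq-style fused message passing.
oracle_fuse <- function(x, maskS, maskF, alpha, beta) {
  C <- nrow(x)
  out <- x
  for (i in seq_len(C)) for (j in seq_len(C)) {
    out[i, ] <- out[i, ] + alpha[j] * maskS[i, j] * x[j, ] +
      beta[j] * maskF[i, j] * x[j, ]
  }
  out
}

# Scalar transcription of one GRU step.
oracle_gru_step <- function(e, h, p) {
  sg <- function(v) 1 / (1 + exp(-v))
  z <- sg(p$Wz %*% e + p$Uz %*% h + p$bz)
  r <- sg(p$Wr %*% e + p$Ur %*% h + p$br)
  cand <- tanh(p$Wh %*% e + p$Uh %*% (r * h) + p$bh)
  as.numeric((1 - z) * h + z * cand)
}

# Loop implementation of Q/K/V scaled dot-product attention.
oracle_attention <- function(M, p) {
  n <- nrow(M)
  Q <- M %*% p$WQ; K <- M %*% p$WK; V <- M %*% p$WV
  for (r in seq_len(n)) {
    Q[r, ] <- Q[r, ] + p$bQ; K[r, ] <- K[r, ] + p$bK; V[r, ] <- V[r, ] + p$bV
  }
  Z <- matrix(0, n, ncol(V))
  for (r in seq_len(n)) {
    s <- numeric(n)
    for (cidx in seq_len(n)) s[cidx] <- sum(Q[r, ] * K[cidx, ]) / sqrt(p$d_k)
    w <- exp(s - max(s)); w <- w / sum(w)
    for (cidx in seq_len(n)) Z[r, ] <- Z[r, ] + w[cidx] * V[cidx, ]
  }
  Z
}

# Term-by-term transcription of the bilinear attention score.
oracle_st_attention <- function(H, p) {
  score <- (H %*% p$W1) %*% p$W2 %*% t(H %*% p$W3) + p$b
  act <- p$V %*% (1 / (1 + exp(-score)))
  out <- act
  for (r in seq_len(nrow(act))) {
    w <- exp(act[r, ] - max(act[r, ]))
    out[r, ] <- w / sum(w)
  }
  out
}

# Explicit K-term Chebyshev graph convolution with dense products.
oracle_graph_conv <- function(H, Satt, Lsc, theta) {
  C <- ncol(Lsc)
  Tk <- list(diag(C))
  if (length(theta) >= 2) Tk[[2]] <- Lsc
  if (length(theta) >= 3) for (k in 3:length(theta))
    Tk[[k]] <- 2 * Lsc %*% Tk[[k - 1]] - Tk[[k - 2]]
  out <- 0
  for (k in seq_along(theta)) out <- out + Tk[[k]] %*% (Satt %*% H) %*% theta[[k]]
  out
}

# Per-sample tally of multiclass metrics.
oracle_metrics <- function(yt, yp) {
  k <- 5L
  cm <- matrix(0, k, k)
  for (i in seq_along(yt)) cm[yt[i], yp[i]] <- cm[yt[i], yp[i]] + 1
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  f1 <- numeric(k)
  for (cc in seq_len(k)) {
    tp <- cm[cc, cc]; fp <- sum(cm[, cc]) - tp; fn <- sum(cm[cc, ]) - tp
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[cc] <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  list(cm = cm, accuracy = acc, f1 = f1, macro_f1 = mean(f1),
       kappa = (acc - pe) / (1 - pe))
}

# Sigma-band Hilbert envelope via FFT (analytic-signal construction).
oracle_sigma_envelope <- function(x, fs, band = c(11, 16)) {
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs[freqs > fs / 2] <- freqs[freqs > fs / 2] - fs
  X[abs(freqs) < band[1] | abs(freqs) > band[2]] <- 0
  filt <- Re(stats::fft(X, inverse = TRUE)) / n
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(filt) * h, inverse = TRUE) / n)
}

# Small random labelled dataset with given subjects (fast fake epochs).
fake_dataset <- function(n_subjects, epochs_each, C = 2L, S = 20L,
                         fs = 10, seed = 1L) {
  set.seed(seed)
  n <- n_subjects * epochs_each
  sig <- array(rnorm(C * S * n), dim = c(C, S, n))
  psg_dataset(sig, sample(sleep_stages(), n, replace = TRUE),
              rep(sprintf("P%02d", seq_len(n_subjects)), each = epochs_each),
              fs = fs)
}
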