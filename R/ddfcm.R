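# Dynamic dual-scale functional connectivity: per-second Pearson graphs at a
# 1 s (fast) and trailing 5 s (slow) window, top-k sparsity masks, learnable
# fused message passing, and a GRU encoding of the graph-feature sequence.

#' Pearson correlation adjacency of a signal window
#'
#' Entry (i, j) is the Pearson correlation of channels i and j over the
#' window. Constant channels get 0 off-diagonal (their correlation is 0/0)
#' and 1 on the diagonal.
#'
#' @param window channels x samples matrix with at least 2 samples.
#' @return channels x channels symmetric matrix with unit diagonal,
#'   entries in \[-1, 1\].
#' @export
pearson_adjacency <- function(window) {
  if (ncol(window) < 2L) stop("window must have at least 2 samples")
  sdv <- apply(window, 1L, stats::sd)
  A <- suppressWarnings(stats::cor(t(window)))
  dimnames(A) <- NULL
  A[is.na(A)] <- 0
  A[A > 1] <- 1; A[A < -1] <- -1
  diag(A) <- 1
  const <- sdv < 1e-14
  if (any(const)) {
    A[const, ] <- 0; A[, const] <- 0
    diag(A) <- 1
  }
  A
}

#' Per-row top-k sparsity mask
#'
#' For each row, marks the k off-diagonal entries of largest absolute value
#' (anti-correlated coupling counts); ties are broken toward the lower
#' column index. Diagonal is always 0.
#'
#' @param A square matrix.
#' @param k edges kept per row, 1 <= k <= ncol(A) - 1.
#' @return binary matrix of the same shape.
#' @export
sparsify <- function(A, k = 3L) {
  C <- ncol(A)
  if (k < 1L || k > C - 1L) stop("k must be in 1..", C - 1L)
  M <- matrix(0, C, C)
  for (i in seq_len(C)) {
    v <- abs(A[i, ])
    v[i] <- -Inf
    ord <- order(-v, seq_len(C))
    M[i, ord[seq_len(k)]] <- 1
  }
  M
}

#' Dual-scale graph sequence of one epoch
#'
#' Steps second-by-second through the epoch. At step t, the fast adjacency
#' is the Pearson graph of second t and the slow adjacency that of seconds
#' max(1, t-4)..t (truncated at the epoch start, never padded). Each scale
#' carries its own top-k sparsity mask.
#'
#' @param signal channels x samples matrix (one epoch).
#' @param fs sampling rate in Hz.
#' @param fast_s,slow_s window lengths in seconds.
#' @param k sparsity degree per row.
#' @return list of `dual_scale_graph` objects (fields `A_fast`, `A_slow`,
#'   `mask_fast`, `mask_slow`, `t`), one per second.
#' @export
dual_scale_sequence <- function(signal, fs = 200, fast_s = 1, slow_s = 5,
                                k = 3L) {
  n <- ncol(signal)
  wf <- round(fast_s * fs)
  if (n < wf) stop("epoch shorter than the fast window")
  n_steps <- n %/% wf
  lapply(seq_len(n_steps), function(t) {
    i_hi <- t * wf
    A_fast <- pearson_adjacency(signal[, (i_hi - wf + 1):i_hi, drop = FALSE])
    i_lo <- max(1L, i_hi - round(slow_s * fs) + 1L)
    A_slow <- pearson_adjacency(signal[, i_lo:i_hi, drop = FALSE])
    structure(list(A_fast = A_fast, A_slow = A_slow,
                   mask_fast = sparsify(A_fast, k),
                   mask_slow = sparsify(A_slow, k), t = t),
              class = "dual_scale_graph")
  })
}

# Fused message-passing matrix I + mask_slow diag(alpha) + mask_fast diag(beta):
# column j of each mask is scaled by the source-channel gain of j.
fusion_matrix <- function(graph, alpha, beta) {
  diag(ncol(graph$mask_slow)) +
    sweep(graph$mask_slow, 2L, alpha, "*") +
    sweep(graph$mask_fast, 2L, beta, "*")
}

#' Fuse node features over the dual-scale neighbourhood
#'
#' e'_i = x_i + sum_j alpha_j mask_slow\[i,j\] x_j + beta_j mask_fast\[i,j\] x_j:
#' adaptive message passing with per-source-channel gains on each timescale.
#'
#' @param x channels x features matrix (node features of the current step).
#' @param graph a `dual_scale_graph`.
#' @param alpha,beta length-C gains for the slow and fast scales.
#' @return channels x features matrix.
#' @export
fuse_node_features <- function(x, graph, alpha, beta) {
  C <- nrow(x)
  if (ncol(graph$mask_slow) != C || length(alpha) != C || length(beta) != C)
    stop("shape mismatch between node features, masks and gains")
  fusion_matrix(graph, alpha, beta) %*% x
}

#' Initialise GRU parameters (Glorot uniform)
#'
#' @param input_dim width of the per-step input vector.
#' @param hidden_dim hidden-state width.
#' @param seed integer seed.
#' @return list with Wz, Uz, bz, Wr, Ur, br, Wh, Uh, bh, hidden_dim.
#' @export
gru_params <- function(input_dim, hidden_dim = 128L, seed = 1L) {
  with_seed(seed, {
    gl <- function(nr, nc) {
      lim <- sqrt(6 / (nr + nc))
      matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
    }
    list(Wz = gl(hidden_dim, input_dim), Uz = gl(hidden_dim, hidden_dim),
         bz = numeric(hidden_dim),
         Wr = gl(hidden_dim, input_dim), Ur = gl(hidden_dim, hidden_dim),
         br = numeric(hidden_dim),
         Wh = gl(hidden_dim, input_dim), Uh = gl(hidden_dim, hidden_dim),
         bh = numeric(hidden_dim), hidden_dim = as.integer(hidden_dim))
  })
}

#' Encode a feature sequence with a GRU
#'
#' Gates: z_t = sigma(Wz e_t + Uz h_(t-1) + bz),
#' r_t = sigma(Wr e_t + Ur h_(t-1) + br); state update
#' h_t = (1 - z_t) * h_(t-1) + z_t * tanh(Wh e_t + Uh (r_t * h_(t-1)) + bh).
#' The connectivity embedding is the final hidden state.
#'
#' @param inputs list of per-step input vectors (or a T x D matrix).
#' @param params from [gru_params()].
#' @param h0 initial hidden state (default zeros).
#' @return list with `h` (final hidden state) and `hs`
#'   (T x hidden matrix of all states).
#' @export
gru_encode <- function(inputs, params, h0 = NULL) {
  if (is.matrix(inputs)) inputs <- lapply(seq_len(nrow(inputs)),
                                          function(i) inputs[i, ])
  if (length(inputs) == 0L) stop("empty input sequence")
  H <- params$hidden_dim
  h <- if (is.null(h0)) numeric(H) else h0
  hs <- matrix(0, length(inputs), H)
  sig <- function(x) 1 / (1 + exp(-x))
  for (t in seq_along(inputs)) {
    e <- inputs[[t]]
    z <- sig(params$Wz %*% e + params$Uz %*% h + params$bz)
    r <- sig(params$Wr %*% e + params$Ur %*% h + params$br)
    cand <- tanh(params$Wh %*% e + params$Uh %*% (r * h) + params$bh)
    h <- as.numeric((1 - z) * h + z * cand)
    hs[t, ] <- h
  }
  list(h = h, hs = hs)
}

#' Per-stage mean correlation profile
#'
#' Averages [pearson_adjacency()] over all epochs of each stage, at the
#' requested timescale. Stages without epochs yield NaN matrices and are
#' listed in the `missing_stages` attribute.
#'
#' @param dataset a `psg_dataset`.
#' @param scale "epoch" (whole-epoch window), "fast" (mean over 1 s windows)
#'   or "slow" (mean over trailing 5 s windows).
#' @return named list of channels x channels matrices, one per stage.
#' @export
stage_correlation_profile <- function(dataset,
                                      scale = c("epoch", "fast", "slow")) {
  scale <- match.arg(scale)
  if (n_epochs(dataset) == 0L) stop("empty dataset")
  stages <- sleep_stages()
  C <- dim(dataset$signals)[1]
  out <- stats::setNames(vector("list", 5L), stages)
  missing <- character(0)
  for (st in stages) {
    idx <- which(dataset$labels == st)
    if (length(idx) == 0L) {
      out[[st]] <- matrix(NaN, C, C)
      missing <- c(missing, st)
      next
    }
    acc <- matrix(0, C, C)
    for (e in idx) {
      sig <- dataset$signals[, , e]
      acc <- acc + switch(scale,
        epoch = pearson_adjacency(sig),
        fast = {
          gs <- dual_scale_sequence(sig, dataset$fs)
          Reduce(`+`, lapply(gs, `[[`, "A_fast")) / length(gs)
        },
        slow = {
          gs <- dual_scale_sequence(sig, dataset$fs)
          Reduce(`+`, lapply(gs, `[[`, "A_slow")) / length(gs)
        })
    }
    out[[st]] <- acc / length(idx)
  }
  attr(out, "missing_stages") <- missing
  out
}
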