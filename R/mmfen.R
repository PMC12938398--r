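# Multi-scale morphological feature extraction: six parallel 1-D convolution
# branches (kernel widths 50..1000 samples = 0.25..5 s at 200 Hz), each
# batch-normalised, rectified, max-pooled, refined by scaled dot-product
# self-attention over time, then globally pooled and concatenated.

#' Default branch kernel widths (samples)
#'
#' 50, 100, 200, 400, 700, 1000 samples: receptive fields of 0.25, 0.5, 1,
#' 2, 3.5 and 5 s at 200 Hz, spanning beta transients to slow waves.
#' @export
branch_widths <- function() c(50L, 100L, 200L, 400L, 700L, 1000L)

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Parameters of one convolution branch
#'
#' @param width kernel width in samples.
#' @param out_channels filters per branch (64 so that six branches
#'   concatenate to the 384-wide morphological embedding).
#' @param seed integer seed (Glorot-uniform kernels).
#' @return list with `kernels` (width x out_channels), normalisation scale
#'   `gamma` / shift `beta`, and `width`.
#' @export
branch_params <- function(width, out_channels = 64L, seed = 1L) {
  with_seed(seed, list(
    kernels = glorot(width, out_channels),
    gamma = rep(1, out_channels), beta = numeric(out_channels),
    width = as.integer(width)))
}

# Window-index matrix for a strided valid convolution.
conv_positions <- function(L, width, stride = 1L) {
  if (L < width) stop("kernel wider than the input")
  seq.int(1L, L - width + 1L, by = stride)
}

# Strided im2col of one channel: rows are length-`width` windows.
im2col <- function(x, width, stride = 1L) {
  pos <- conv_positions(length(x), width, stride)
  outer(pos, seq_len(width) - 1L, function(p, o) x[p + o])
}

#' Valid 1-D convolution of every channel with a shared filter bank
#'
#' Plain sliding inner products (no padding, no bias): row block c of the
#' result holds channel c's feature map, positions x filters.
#'
#' @param X channels x samples matrix.
#' @param kernels width x filters matrix.
#' @param stride convolution stride in samples.
#' @return (channels * positions) x filters matrix, channel-major row blocks.
#' @export
conv1d_branch <- function(X, kernels, stride = 1L) {
  do.call(rbind, lapply(seq_len(nrow(X)), function(c)
    im2col(X[c, ], nrow(kernels), stride) %*% kernels))
}

#' One MMFEN branch: convolution, normalisation, ReLU, max-pool
#'
#' In order: valid stride-1 convolution with the branch's kernels,
#' per-feature normalisation over the sample's positions (scaled/shifted by
#' the branch's gamma/beta), ReLU, and max-pooling over adjacent position
#' pairs (stride 2), leaving floor((L - width + 1) / 2) positions per
#' channel.
#'
#' @param X channels x samples matrix.
#' @param params from [branch_params()].
#' @param stride convolution stride (1 per the layer contract; larger
#'   values are a compute-reduction knob for reduced models).
#' @param normalize apply the normalisation stage (FALSE bypasses it, e.g.
#'   for closed-form checks).
#' @return list with `map` ((channels * pooled positions) x filters matrix),
#'   `n_pos` pooled positions per channel, `n_channels`.
#' @export
branch_conv <- function(X, params, stride = 1L, normalize = TRUE) {
  C <- nrow(X)
  M <- conv1d_branch(X, params$kernels, stride)
  Tc <- nrow(M) / C
  if (normalize) {
    mu <- colMeans(M)
    sdv <- sqrt(colMeans(sweep(M, 2L, mu)^2) + 1e-5)
    M <- sweep(sweep(sweep(M, 2L, mu), 2L, sdv, "/"), 2L, params$gamma, "*")
    M <- sweep(M, 2L, params$beta, "+")
  }
  M <- pmax(M, 0)
  Tp <- floor(Tc / 2)
  if (Tp < 1L) stop("feature map too short to max-pool")
  base <- rep((seq_len(C) - 1L) * Tc, each = Tp)
  i1 <- base + rep(seq.int(1L, by = 2L, length.out = Tp), C)
  P <- pmax(M[i1, , drop = FALSE], M[i1 + 1L, , drop = FALSE])
  list(map = P, n_pos = as.integer(Tp), n_channels = C)
}

#' Attention parameters shared by a branch
#'
#' @param d_in input feature width.
#' @param d_k latent/scaling dimension of the Q/K/V projections.
#' @param seed integer seed.
#' @export
attention_params <- function(d_in, d_k = 64L, seed = 1L) {
  with_seed(seed, list(
    WQ = glorot(d_in, d_k), bQ = numeric(d_k),
    WK = glorot(d_in, d_k), bK = numeric(d_k),
    WV = glorot(d_in, d_k), bV = numeric(d_k), d_k = as.integer(d_k)))
}

#' Scaled dot-product self-attention over temporal positions
#'
#' Q = M WQ + bQ, K = M WK + bK, V = M WV + bV;
#' Z = Softmax(Q K^T / sqrt(d_k)) V with the softmax over the key axis.
#'
#' @param M positions x features matrix.
#' @param params from [attention_params()].
#' @return positions x d_k matrix.
#' @export
branch_attention <- function(M, params) {
  Q <- sweep(M %*% params$WQ, 2L, params$bQ, "+")
  K <- sweep(M %*% params$WK, 2L, params$bK, "+")
  V <- sweep(M %*% params$WV, 2L, params$bV, "+")
  S <- Q %*% t(K) / sqrt(params$d_k)
  W <- exp(S - apply(S, 1L, max))
  W <- W / rowSums(W)
  W %*% V
}

#' Full morphological-feature parameter set
#'
#' @param n_channels input channels.
#' @param widths kernel widths (one branch each).
#' @param out_channels filters per branch.
#' @param seed integer seed.
#' @export
mmfen_params <- function(n_channels = 6L, widths = branch_widths(),
                         out_channels = 64L, seed = 1L) {
  branches <- lapply(seq_along(widths), function(i)
    branch_params(widths[i], out_channels, seed = seed + i))
  att <- lapply(seq_along(widths), function(i)
    attention_params(out_channels, d_k = out_channels, seed = seed + 100L + i))
  list(branches = branches, attention = att,
       out_channels = as.integer(out_channels))
}

# Average-pool each channel's row block down to at most n_frames rows.
frame_pool_index <- function(n_pos, n_channels, n_frames) {
  nf <- min(n_frames, n_pos)
  cuts <- floor(seq(0L, n_pos, length.out = nf + 1L))
  lapply(seq_len(n_channels), function(c)
    lapply(seq_len(nf), function(f)
      ((c - 1L) * n_pos) + (cuts[f] + 1L):cuts[f + 1L]))
}

#' Morphological embedding of one epoch
#'
#' Runs all branches, applies per-branch self-attention over (frame-pooled)
#' temporal positions of each channel, pools globally over positions and
#' channels, and concatenates the six 64-wide branch vectors into the
#' 384-wide embedding.
#'
#' @param X channels x samples matrix.
#' @param params from [mmfen_params()].
#' @param stride convolution stride (see [branch_conv()]).
#' @param n_frames frames per channel entering attention.
#' @param normalize apply branch normalisation.
#' @return numeric vector of width `6 * out_channels`.
#' @export
morph_features <- function(X, params, stride = 1L, n_frames = 25L,
                           normalize = TRUE) {
  out <- lapply(seq_along(params$branches), function(i) {
    bc <- branch_conv(X, params$branches[[i]], stride, normalize)
    idx <- frame_pool_index(bc$n_pos, bc$n_channels, n_frames)
    zsum <- numeric(params$out_channels)
    cnt <- 0L
    for (c in seq_len(bc$n_channels)) {
      Fm <- do.call(rbind, lapply(idx[[c]], function(ii)
        colMeans(bc$map[ii, , drop = FALSE])))
      Z <- branch_attention(Fm, params$attention[[i]])
      zsum <- zsum + colSums(Z)
      cnt <- cnt + nrow(Z)
    }
    zsum / cnt
  })
  unlist(out, use.names = FALSE)
}
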