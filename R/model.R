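# Model assembly: configuration, Glorot-uniform parameter initialisation,
# per-epoch input precomputation, and the differentiable forward pass that
# chains the connectivity encoder, the morphological branches, the
# spatio-temporal graph convolution experts and the two heads.

#' Model configuration
#'
#' Defaults give the full-size architecture: 64 filters per branch
#' (6 x 64 = 384 morphological features), a 128-unit GRU, 256-wide experts,
#' Chebyshev order 3 and top-3 graph sparsity. `conv_stride = "half"` and
#' `window_decim > 1` are compute-reduction knobs for desk-scale models;
#' they change arithmetic cost, not the architecture.
#'
#' @param n_channels,fs,epoch_len_s input geometry.
#' @param widths branch kernel widths in samples.
#' @param branch_filters filters per morphological branch.
#' @param gru_hidden connectivity-embedding width.
#' @param expert_width width of each expert output (the final embedding).
#' @param att_latent latent width of the bilinear attention scores.
#' @param cheb_K Chebyshev polynomial order.
#' @param topk edges kept per row in the sparsity masks.
#' @param n_frames temporal frames per channel entering branch attention.
#' @param conv_stride "unit" (stride-1 convolution) or "half"
#'   (stride = kernel width / 2).
#' @param window_decim decimation factor of the 1 s node-feature windows
#'   entering the fusion/GRU stage.
#' @param disc_hidden hidden width of the subject discriminator.
#' @param dropout dropout rate before the classifier.
#' @return list of class `sleepgcn_config`.
#' @export
sleepgcn_config <- function(n_channels = 6L, fs = 200, epoch_len_s = 30,
                            widths = branch_widths(), branch_filters = 64L,
                            gru_hidden = 128L, expert_width = 256L,
                            att_latent = 16L, cheb_K = 3L, topk = 3L,
                            n_frames = 25L, conv_stride = c("unit", "half"),
                            window_decim = 1L, disc_hidden = 64L,
                            dropout = 0.5) {
  conv_stride <- match.arg(conv_stride)
  cfg <- list(n_channels = as.integer(n_channels), fs = fs,
              epoch_len_s = epoch_len_s, widths = as.integer(widths),
              branch_filters = as.integer(branch_filters),
              gru_hidden = as.integer(gru_hidden),
              expert_width = as.integer(expert_width),
              att_latent = as.integer(att_latent),
              cheb_K = as.integer(cheb_K), topk = as.integer(topk),
              n_frames = as.integer(n_frames), conv_stride = conv_stride,
              window_decim = as.integer(window_decim),
              disc_hidden = as.integer(disc_hidden), dropout = dropout)
  cfg$n_branches <- length(cfg$widths)
  cfg$n_steps <- as.integer(epoch_len_s)           # 1 s stepping
  cfg$win_samples <- as.integer(round(fs) %/% cfg$window_decim)
  cfg$gru_input <- cfg$n_channels * cfg$win_samples
  cfg$morph_width <- cfg$n_branches * cfg$branch_filters
  cfg$joint_width <- cfg$morph_width + cfg$gru_hidden
  class(cfg) <- "sleepgcn_config"
  cfg
}

#' Reduced configuration for desk-scale experiments
#'
#' Hidden widths divided by four relative to the full model (16 filters per
#' branch, 32-unit GRU, 64-wide experts), strided kernel evaluation and 4x
#' window decimation.
#' @param ... overrides passed to [sleepgcn_config()].
#' @export
sleepgcn_config_reduced <- function(...) {
  args <- list(branch_filters = 16L, gru_hidden = 32L, expert_width = 64L,
               disc_hidden = 16L, conv_stride = "half", window_decim = 4L,
               n_frames = 8L)
  do.call(sleepgcn_config, utils::modifyList(args, list(...)))
}

branch_stride <- function(cfg, i) {
  if (cfg$conv_stride == "unit") 1L else max(1L, cfg$widths[i] %/% 2L)
}

#' Initialise a model
#'
#' All weight matrices are Glorot-uniform; biases start at zero and the
#' dual-scale fusion gains alpha/beta at 0.1 (near-identity message
#' passing early in training).
#'
#' @param config a [sleepgcn_config()].
#' @param n_domains number of training subjects the discriminator
#'   distinguishes (0 disables the adversarial head).
#' @param seed integer seed.
#' @return object of class `sleepgcn_model` (config + named parameter list).
#' @export
sleepgcn_model <- function(config = sleepgcn_config(), n_domains = 0L,
                           seed = 1L) {
  cfg <- config
  C <- cfg$n_channels; nf <- cfg$branch_filters; H <- cfg$gru_hidden
  Tn <- cfg$n_steps; d <- cfg$att_latent
  P <- with_seed(seed, {
    p <- list(alpha = rep(0.1, C), beta = rep(0.1, C))
    D <- cfg$gru_input
    p <- c(p, list(
      gru_Wz = glorot(H, D), gru_Uz = glorot(H, H), gru_bz = numeric(H),
      gru_Wr = glorot(H, D), gru_Ur = glorot(H, H), gru_br = numeric(H),
      gru_Wh = glorot(H, D), gru_Uh = glorot(H, H), gru_bh = numeric(H)))
    for (i in seq_len(cfg$n_branches)) {
      p[[paste0("br", i, "_kern")]] <- glorot(cfg$widths[i], nf)
      p[[paste0("br", i, "_gamma")]] <- rep(1, nf)
      p[[paste0("br", i, "_beta")]] <- numeric(nf)
      for (w in c("WQ", "WK", "WV"))
        p[[paste0("br", i, "_", w)]] <- glorot(nf, nf)
      for (b in c("bQ", "bK", "bV"))
        p[[paste0("br", i, "_", b)]] <- numeric(nf)
    }
    p$sa_V <- glorot(C, C); p$sa_W1 <- glorot(nf, d)
    p$sa_W2 <- glorot(d, d); p$sa_W3 <- glorot(nf, d)
    p$sa_b <- matrix(0, C, C)
    p$ta_V <- glorot(Tn, Tn); p$ta_U1 <- glorot(H, d)
    p$ta_U2 <- glorot(d, d); p$ta_U3 <- glorot(H, d)
    p$ta_b <- matrix(0, Tn, Tn)
    for (i in seq_len(cfg$n_branches)) {
      for (k in seq_len(cfg$cheb_K))
        p[[paste0("th", i, "_", k)]] <- glorot(nf, nf)
      p[[paste0("ex", i, "_W")]] <- glorot(cfg$expert_width, nf + H)
      p[[paste0("ex", i, "_b")]] <- numeric(cfg$expert_width)
    }
    p$gate_W <- glorot(cfg$n_branches, cfg$joint_width)
    p$gate_b <- numeric(cfg$n_branches)
    p$cls_W <- glorot(5L, cfg$expert_width)
    p$cls_b <- numeric(5L)
    if (n_domains > 0L) {
      p$disc_W1 <- glorot(cfg$disc_hidden, cfg$expert_width)
      p$disc_b1 <- numeric(cfg$disc_hidden)
      p$disc_W2 <- glorot(n_domains, cfg$disc_hidden)
      p$disc_b2 <- numeric(n_domains)
    }
    p
  })
  structure(list(config = cfg, params = P, n_domains = as.integer(n_domains),
                 class_names = sleep_stages()),
            class = "sleepgcn_model")
}

#' @export
print.sleepgcn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat("sleepgcn_model:", np, "parameters;",
      x$config$n_branches, "branches x", x$config$branch_filters,
      "filters; GRU", x$config$gru_hidden, "; experts",
      x$config$expert_width, "wide; domains:", x$n_domains, "\n")
  invisible(x)
}

#' Precompute the parameter-independent inputs of every epoch
#'
#' For each epoch: the decimated 1 s node-feature windows, the dual-scale
#' sparsity masks per step, and the Chebyshev basis of the epoch-level
#' graph (mean absolute slow adjacency under its mask). These depend only
#' on the data, so they are computed once per dataset.
#'
#' @param dataset a z-scored `psg_dataset`.
#' @param config a [sleepgcn_config()].
#' @return list of per-epoch input lists.
#' @export
precompute_inputs <- function(dataset, config) {
  cfg <- config
  wf <- as.integer(round(cfg$fs))
  keep <- seq.int(1L, wf, by = cfg$window_decim)
  lapply(seq_len(n_epochs(dataset)), function(e) {
    sig <- dataset$signals[, , e]
    gs <- dual_scale_sequence(sig, cfg$fs, k = cfg$topk)
    Xw <- lapply(seq_along(gs), function(t)
      sig[, ((t - 1L) * wf) + keep, drop = FALSE])
    A <- Reduce(`+`, lapply(gs, function(g) abs(g$A_slow) * g$mask_slow)) /
      length(gs)
    A <- (A + t(A)) / 2
    basis <- chebyshev_basis(
      suppressWarnings(scaled_laplacian(A)$L_scaled), cfg$cheb_K)
    list(Xw = Xw,
         maskS = lapply(gs, `[[`, "mask_slow"),
         maskF = lapply(gs, `[[`, "mask_fast"),
         basis = basis,
         label = as.integer(dataset$labels[e]),
         subject = dataset$subject_id[e])
  })
}

# Fused dual-scale fusion + GRU over the whole step sequence as one tape
# node: the forward loop runs in plain R and the backward closure is
# hand-written backpropagation-through-time, which keeps the tape small.
# Parents: alpha, beta, then the nine GRU parameter groups.
ad_fuse_gru <- function(tp, smp, alpha, beta, gp) {
  av <- ad_value(alpha); bv <- ad_value(beta)
  Wz <- ad_value(gp$Wz); Uz <- ad_value(gp$Uz); bz <- ad_value(gp$bz)
  Wr <- ad_value(gp$Wr); Ur <- ad_value(gp$Ur); br <- ad_value(gp$br)
  Wh <- ad_value(gp$Wh); Uh <- ad_value(gp$Uh); bh <- ad_value(gp$bh)
  Tn <- length(smp$Xw); H <- length(bz)
  sig <- function(x) 1 / (1 + exp(-x))
  E <- vector("list", Tn); Z <- vector("list", Tn)
  R <- vector("list", Tn); Cc <- vector("list", Tn)
  hs <- matrix(0, Tn, H)
  h <- numeric(H)
  for (t in seq_len(Tn)) {
    Xt <- smp$Xw[[t]]
    Et <- Xt + smp$maskS[[t]] %*% (av * Xt) + smp$maskF[[t]] %*% (bv * Xt)
    e <- as.numeric(Et)
    z <- as.numeric(sig(Wz %*% e + Uz %*% h + bz))
    r <- as.numeric(sig(Wr %*% e + Ur %*% h + br))
    cand <- as.numeric(tanh(Wh %*% e + Uh %*% (r * h) + bh))
    hnew <- (1 - z) * h + z * cand
    E[[t]] <- e; Z[[t]] <- z; R[[t]] <- r; Cc[[t]] <- cand
    hs[t, ] <- hnew
    h <- hnew
  }
  parents <- list(alpha, beta, gp$Wz, gp$Uz, gp$bz, gp$Wr, gp$Ur, gp$br,
                  gp$Wh, gp$Uh, gp$bh)
  track <- vapply(parents, is_adnode, logical(1))
  if (!any(track)) return(hs)
  node_parents <- parents[track]
  new_adnode(tp, hs, node_parents, function(g) {
    C <- nrow(smp$Xw[[1]])
    dal <- numeric(length(av)); dbe <- numeric(length(bv))
    dWz <- Wz * 0; dUz <- Uz * 0; dbz <- bz * 0
    dWr <- Wr * 0; dUr <- Ur * 0; dbr <- br * 0
    dWh <- Wh * 0; dUh <- Uh * 0; dbh <- bh * 0
    dh_next <- numeric(length(bz))
    for (t in seq(length(smp$Xw), 1L)) {
      dh <- g[t, ] + dh_next
      h_prev <- if (t == 1L) numeric(length(bz)) else hs[t - 1L, ]
      z <- Z[[t]]; r <- R[[t]]; cand <- Cc[[t]]; e <- E[[t]]
      dz <- dh * (cand - h_prev)
      dc <- dh * z
      dh_prev <- dh * (1 - z)
      da_c <- dc * (1 - cand^2)
      dWh <- dWh + tcrossprod(da_c, e)
      dUh <- dUh + tcrossprod(da_c, r * h_prev)
      dbh <- dbh + da_c
      uc <- as.numeric(crossprod(Uh, da_c))
      dr <- uc * h_prev
      dh_prev <- dh_prev + uc * r
      da_z <- dz * z * (1 - z)
      dWz <- dWz + tcrossprod(da_z, e); dbz <- dbz + da_z
      dUz <- dUz + tcrossprod(da_z, h_prev)
      dh_prev <- dh_prev + as.numeric(crossprod(Uz, da_z))
      da_r <- dr * r * (1 - r)
      dWr <- dWr + tcrossprod(da_r, e); dbr <- dbr + da_r
      dUr <- dUr + tcrossprod(da_r, h_prev)
      dh_prev <- dh_prev + as.numeric(crossprod(Ur, da_r))
      de <- as.numeric(crossprod(Wz, da_z) + crossprod(Wr, da_r) +
                         crossprod(Wh, da_c))
      dEt <- matrix(de, nrow = C)
      Xt <- smp$Xw[[t]]
      dal <- dal + rowSums(crossprod(smp$maskS[[t]], dEt) * Xt)
      dbe <- dbe + rowSums(crossprod(smp$maskF[[t]], dEt) * Xt)
      dh_next <- dh_prev
    }
    all_grads <- list(dal, dbe, dWz, dUz, dbz, dWr, dUr, dbr, dWh, dUh, dbh)
    all_grads[track]
  })
}

# Attention score shared by the spatial and temporal blocks (tape form).
tape_st_attention <- function(tp, H, V, W1, W2, W3, b) {
  s1 <- ad_matmul(tp, ad_matmul(tp, H, W1), W2)
  score <- ad_add(tp, ad_matmul(tp, s1, ad_t(tp, ad_matmul(tp, H, W3))), b)
  ad_softmax_rows(tp, ad_matmul(tp, V, ad_sigmoid(tp, score)))
}

# Forward pass of one epoch. `P` is a named list of parameters given either
# as plain arrays (pure evaluation) or tape nodes (training); the ops
# dispatch on that, so one implementation serves both paths.
forward_sample <- function(tp, P, smp, cfg, lambda = 0, drop_mask = NULL,
                           with_domain = FALSE) {
  C <- cfg$n_channels; nf <- cfg$branch_filters; H <- cfg$gru_hidden
  # --- dual-scale fusion + GRU over the 30-step sequence --------------------
  gp <- list(Wz = P$gru_Wz, Uz = P$gru_Uz, bz = P$gru_bz,
             Wr = P$gru_Wr, Ur = P$gru_Ur, br = P$gru_br,
             Wh = P$gru_Wh, Uh = P$gru_Uh, bh = P$gru_bh)
  S <- ad_fuse_gru(tp, smp, P$alpha, P$beta, gp)   # T x H hidden states
  Hconn <- ad_vec(tp, ad_rows(tp, S, cfg$n_steps))
  # --- temporal attention over the step sequence ----------------------------
  Tatt <- tape_st_attention(tp, S, P$ta_V, P$ta_U1, P$ta_U2, P$ta_U3, P$ta_b)
  Htemp <- ad_colmeans(tp, ad_matmul(tp, Tatt, S))
  # --- morphological branches ----------------------------------------------
  branch_vecs <- vector("list", cfg$n_branches)
  node_feats <- vector("list", cfg$n_branches)
  for (i in seq_len(cfg$n_branches)) {
    M <- ad_matmul(tp, smp$im2col[[i]],
                   P[[paste0("br", i, "_kern")]])
    M <- ad_affine_cols(tp, ad_colnorm(tp, M),
                        P[[paste0("br", i, "_gamma")]],
                        P[[paste0("br", i, "_beta")]])
    M <- ad_relu(tp, M)
    Tc <- nrow(ad_value(M)) / C
    Tp <- floor(Tc / 2)
    if (Tp < 1L)
      stop("branch ", i, " (width ", cfg$widths[i], "): feature map too ",
           "short to max-pool; epoch too short for this kernel/stride")
    base <- rep((seq_len(C) - 1L) * Tc, each = Tp)
    i1 <- base + rep(seq.int(1L, by = 2L, length.out = Tp), C)
    M <- ad_maxpool_pairs(tp, M, i1, i1 + 1L)
    Pl <- frame_pool_matrix(Tp, C, cfg$n_frames)
    Fm <- ad_matmul(tp, Pl, M)           # (C * n_fr) x nf
    n_fr <- nrow(Pl) / C
    # channels attend in one batch; a block mask confines the softmax to
    # each channel's own frames
    Q <- ad_add_rowvec(tp, ad_matmul(tp, Fm, P[[paste0("br", i, "_WQ")]]),
                       P[[paste0("br", i, "_bQ")]])
    K <- ad_add_rowvec(tp, ad_matmul(tp, Fm, P[[paste0("br", i, "_WK")]]),
                       P[[paste0("br", i, "_bK")]])
    V <- ad_add_rowvec(tp, ad_matmul(tp, Fm, P[[paste0("br", i, "_WV")]]),
                       P[[paste0("br", i, "_bV")]])
    sc <- ad_add(tp, ad_mul(tp, ad_matmul(tp, Q, ad_t(tp, K)), 1 / sqrt(nf)),
                 block_mask_matrix(n_fr, C))
    Z <- ad_matmul(tp, ad_softmax_rows(tp, sc), V)
    Hi <- ad_matmul(tp, block_mean_matrix(n_fr, C), Z)   # C x nf node feats
    node_feats[[i]] <- Hi
    branch_vecs[[i]] <- ad_colmeans(tp, Hi)
  }
  Hmorph <- ad_cat(tp, branch_vecs)
  Hjoint <- ad_cat(tp, list(Hmorph, Hconn))
  # --- expert streams: spatial attention + Chebyshev graph conv -------------
  experts <- vector("list", cfg$n_branches)
  for (i in seq_len(cfg$n_branches)) {
    Hi <- node_feats[[i]]
    Satt <- tape_st_attention(tp, Hi, P$sa_V, P$sa_W1, P$sa_W2, P$sa_W3,
                              P$sa_b)
    Hmod <- ad_matmul(tp, Satt, Hi)
    Y <- NULL
    for (k in seq_len(cfg$cheb_K)) {
      term <- ad_matmul(tp, ad_matmul(tp, smp$basis[[k]], Hmod),
                        P[[paste0("th", i, "_", k)]])
      Y <- if (is.null(Y)) term else ad_add(tp, Y, term)
    }
    pooled <- ad_colmeans(tp, Y)
    ui <- ad_cat(tp, list(pooled, Htemp))
    experts[[i]] <- ad_relu(
      tp, ad_add(tp, ad_matmul(tp, P[[paste0("ex", i, "_W")]], ui),
                 P[[paste0("ex", i, "_b")]]))
  }
  G <- ad_softmax_rows(tp, ad_vec(tp, ad_add(tp,
    ad_matmul(tp, P$gate_W, Hjoint), P$gate_b)))
  Yfinal <- NULL
  for (i in seq_len(cfg$n_branches)) {
    term <- ad_mul(tp, ad_vec(tp, experts[[i]]), ad_slice(tp, G, i))
    Yfinal <- if (is.null(Yfinal)) term else ad_add(tp, Yfinal, term)
  }
  feat <- if (is.null(drop_mask)) Yfinal else ad_mul(tp, Yfinal, drop_mask)
  logits <- ad_vec(tp, ad_add(tp, ad_matmul(tp, P$cls_W, feat), P$cls_b))
  out <- list(logits = logits, Yfinal = Yfinal, gate = G, Hjoint = Hjoint)
  if (with_domain) {
    fd <- grl(tp, Yfinal, lambda)
    d1 <- ad_relu(tp, ad_add(tp, ad_matmul(tp, P$disc_W1, fd), P$disc_b1))
    out$dlogits <- ad_vec(tp, ad_add(tp, ad_matmul(tp, P$disc_W2, d1),
                                     P$disc_b2))
  }
  out
}

# Additive softmax mask confining attention to each channel's frame block.
block_mask_matrix <- function(n_fr, C) {
  n <- n_fr * C
  Mk <- matrix(-1e30, n, n)
  for (c in seq_len(C)) {
    rows <- ((c - 1L) * n_fr + 1L):(c * n_fr)
    Mk[rows, rows] <- 0
  }
  Mk
}

# Averaging matrix collapsing each channel's frame block to one row.
block_mean_matrix <- function(n_fr, C) {
  Bm <- matrix(0, C, n_fr * C)
  for (c in seq_len(C))
    Bm[c, ((c - 1L) * n_fr + 1L):(c * n_fr)] <- 1 / n_fr
  Bm
}

# Constant frame-averaging matrix mapping (C * Tp) rows to (C * n_fr) rows.
frame_pool_matrix <- function(Tp, C, n_frames) {
  nf <- min(n_frames, Tp)
  cuts <- floor(seq(0L, Tp, length.out = nf + 1L))
  Pl <- matrix(0, C * nf, C * Tp)
  for (c in seq_len(C)) for (f in seq_len(nf)) {
    cols <- ((c - 1L) * Tp) + (cuts[f] + 1L):cuts[f + 1L]
    Pl[(c - 1L) * nf + f, cols] <- 1 / length(cols)
  }
  Pl
}

# Per-branch im2col matrices of one epoch (constants of the forward pass).
sample_im2col <- function(sig, cfg) {
  lapply(seq_len(cfg$n_branches), function(i)
    do.call(rbind, lapply(seq_len(nrow(sig)), function(c)
      im2col(sig[c, ], cfg$widths[i], branch_stride(cfg, i)))))
}

#' Predict stage probabilities
#'
#' Deterministic forward pass (no dropout); probabilities per epoch sum
#' to one.
#'
#' @param object a `sleepgcn_model`.
#' @param dataset a `psg_dataset` (z-scored internally if `normalize`).
#' @param normalize apply [zscore_normalize()] first.
#' @param ... unused.
#' @return list with `prob` (epochs x 5 matrix) and `label`
#'   (factor of predicted stages).
#' @export
predict.sleepgcn_model <- function(object, dataset, normalize = TRUE, ...) {
  cfg <- object$config
  if (normalize) dataset <- zscore_normalize(dataset)
  inputs <- precompute_inputs(dataset, cfg)
  prob <- matrix(0, length(inputs), 5L,
                 dimnames = list(NULL, sleep_stages()))
  for (e in seq_along(inputs)) {
    smp <- inputs[[e]]
    smp$im2col <- sample_im2col(dataset$signals[, , e], cfg)
    lg <- ad_value(forward_sample(NULL, object$params, smp, cfg)$logits)
    ex <- exp(lg - max(lg))
    prob[e, ] <- ex / sum(ex)
  }
  list(prob = prob,
       label = factor(sleep_stages()[max.col(prob)], levels = sleep_stages()))
}
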