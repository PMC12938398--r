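test_that("pearson adjacency matches the direct two-pass formula", {
  x <- rnorm(100)
  expect_equal(pearson_adjacency(rbind(x, x))[1, 2], 1)
  expect_equal(pearson_adjacency(rbind(x, -x))[1, 2], -1)
  set.seed(10)
  for (r in 1:50) {
    W <- matrix(rnorm(3 * 100), 3, 100)
    expect_equal(pearson_adjacency(W), oracle_pearson_matrix(W),
                 tolerance = 1e-10)
  }
  expect_error(pearson_adjacency(matrix(1, 3, 1)), "2 samples")
})

test_that("pearson adjacency is affine-invariant and degenerate-safe", {
  set.seed(11)
  W <- matrix(rnorm(4 * 80), 4, 80)
  A <- pearson_adjacency(W)
  W2 <- W * c(2, 0.5, 10, 3) + c(-1, 4, 0, 100)
  expect_equal(pearson_adjacency(W2), A, tolerance = 1e-9)

  Wc <- W; Wc[2, ] <- 5
  Ac <- pearson_adjacency(Wc)
  expect_equal(Ac[2, -2], rep(0, 3))
  expect_equal(diag(Ac), rep(1, 4))
})

test_that("dual-scale sequences step per second with truncated slow windows", {
  set.seed(12)
  sig <- matrix(rnorm(6 * 6000), 6, 6000)
  gs <- dual_scale_sequence(sig, fs = 200)
  expect_length(gs, 30L)   # epoch_len / fast window, exactly
  for (t in c(1, 3, 7, 30)) {
    hi <- t * 200
    lo <- max(1, hi - 1000 + 1)
    expect_equal(gs[[t]]$A_fast,
                 oracle_pearson_matrix(sig[, (hi - 199):hi]),
                 tolerance = 1e-10)
    expect_equal(gs[[t]]$A_slow, oracle_pearson_matrix(sig[, lo:hi]),
                 tolerance = 1e-10)
  }
  expect_true(all(vapply(gs, function(g)
    isSymmetric(g$A_fast, tol = 1e-9) && all(abs(g$A_slow) <= 1 + 1e-12) &&
      all(diag(g$mask_fast) == 0), TRUE)))

  src <- rnorm(6000)
  same <- rbind(src, src + 0, src * 1)
  gs2 <- dual_scale_sequence(same, fs = 200, k = 2)
  expect_equal(gs2[[5]]$A_fast, matrix(1, 3, 3))
  expect_error(dual_scale_sequence(sig[, 1:100, drop = FALSE], fs = 200),
               "shorter")
})

test_that("top-k sparsification keeps the largest absolute edges", {
  A <- matrix(1, 4, 4)
  expect_equal(sparsify(A, 3), matrix(1, 4, 4) - diag(4))
  A2 <- rbind(c(1, 0.9, 0.1, -0.95), c(0.9, 1, 0, 0), c(0.1, 0, 1, 0),
              c(-0.95, 0, 0, 1))
  m <- sparsify(A2, 1)
  expect_equal(which(m[1, ] == 1), 4L)   # |-0.95| beats 0.9
  A3 <- matrix(c(1, 0.5, 0.5, 0.5, 1, 0.1, 0.5, 0.1, 1), 3, 3)
  expect_equal(which(sparsify(A3, 1)[1, ] == 1), 2L)  # tie -> lower column
  expect_error(sparsify(A, 0), "k must")
  expect_error(sparsify(A, 4), "k must")
})

test_that("dual-scale fusion matches an explicit double loop", {
  set.seed(13)
  g <- list(mask_slow = matrix(0, 5, 5), mask_fast = matrix(0, 5, 5))
  x <- matrix(rnorm(5 * 7), 5, 7)
  expect_equal(fuse_node_features(x, g, rep(1, 5), rep(1, 5)), x)
  for (r in 1:50) {
    x <- matrix(rnorm(5 * 7), 5, 7)
    g <- list(mask_slow = matrix(rbinom(25, 1, 0.4), 5, 5),
              mask_fast = matrix(rbinom(25, 1, 0.4), 5, 5))
    al <- rnorm(5); be <- rnorm(5)
    expect_equal(fuse_node_features(x, g, al, be),
                 oracle_fuse(x, g$mask_slow, g$mask_fast, al, be),
                 tolerance = 1e-10)
    expect_equal(fuse_node_features(x, g, numeric(5), numeric(5)), x)
  }
  expect_error(fuse_node_features(x, g, rnorm(3), rnorm(5)), "mismatch")
})

test_that("the GRU follows the printed gate equations", {
  p0 <- gru_params(4, 3)
  for (nm in setdiff(names(p0), "hidden_dim")) p0[[nm]] <- p0[[nm]] * 0
  out <- gru_encode(list(rnorm(4), rnorm(4)), p0)
  expect_equal(out$h, numeric(3))   # h_t = 0.5 h_(t-1) from h0 = 0

  set.seed(14)
  for (r in 1:50) {
    p <- gru_params(4, 3, seed = r)
    e <- rnorm(4)
    expect_equal(gru_encode(list(e), p)$h,
                 oracle_gru_step(e, numeric(3), p), tolerance = 1e-10)
  }

  # identical inputs converge to a fixed point; states stay inside (-1, 1)
  p <- gru_params(4, 6, seed = 3)
  e <- rnorm(4)
  out <- gru_encode(rep(list(e), 400), p)
  expect_lt(sqrt(sum((out$hs[400, ] - out$hs[399, ])^2)), 1e-6)
  expect_true(all(abs(out$hs) < 1))
  expect_error(gru_encode(list(), p), "empty")
})

test_that("stage correlation profiles average per stage", {
  src <- rnorm(400)
  sig <- array(0, dim = c(3, 400, 2))
  for (e in 1:2) sig[, , e] <- rbind(src, src, src) + rnorm(3) * 0
  ds <- psg_dataset(sig, c("W", "W"), c("a", "a"), fs = 100)
  prof <- stage_correlation_profile(ds, "epoch")
  expect_equal(prof$W, matrix(1, 3, 3))
  expect_true(all(is.nan(prof$N3)))
  expect_equal(attr(prof, "missing_stages"),
               c("N1", "N2", "N3", "R"))

  set.seed(15)
  sig2 <- array(rnorm(3 * 400 * 2), dim = c(3, 400, 2))
  ds2 <- psg_dataset(sig2, c("N2", "R"), c("a", "a"), fs = 100)
  prof2 <- stage_correlation_profile(ds2, "epoch")
  expect_equal(prof2$N2, oracle_pearson_matrix(sig2[, , 1]),
               tolerance = 1e-10)

  # shared broadband drive (Wake) couples channels more than
  # channel-independent delta (N3)
  sg <- stats::setNames(c(1.2, 0, 0, 0, 0), sleep_stages())
  spec <- cohort_spec(n_subjects = 1, epochs_per_subject = 30,
                      stage_transition = matrix(0.2, 5, 5),
                      epoch_len_s = 6, shared_gain = sg, seed = 16)
  ds3 <- as_dataset(generate_cohort(spec))
  prof3 <- stage_correlation_profile(ds3, "epoch")
  off <- function(M) mean(abs(M[upper.tri(M)]))
  expect_gt(off(prof3$W), off(prof3$N3))
})
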