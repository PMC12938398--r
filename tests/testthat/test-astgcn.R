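test_that("joint features concatenate with width checks", {
  expect_equal(joint_features(numeric(384), numeric(128)), numeric(512))
  hm <- rnorm(384); hc <- rnorm(128)
  hj <- joint_features(hm, hc)
  expect_length(hj, 512L)
  expect_equal(hj[1:384], hm)
  expect_error(joint_features(numeric(100), numeric(128)), "mismatch")
  expect_length(joint_features(numeric(96), numeric(32), c(96L, 32L)), 128L)
})

test_that("spatial and temporal attention are row-stochastic transcriptions", {
  set.seed(30)
  for (r in 1:50) {
    C <- sample(3:6, 1); Fd <- sample(2:5, 1)
    p <- st_attention_params(C, Fd, d = 3, seed = r)
    H <- matrix(rnorm(C * Fd), C, Fd)
    S <- spatial_attention(H, p)
    expect_equal(S, oracle_st_attention(H, p), tolerance = 1e-8)
    expect_equal(rowSums(S), rep(1, C), tolerance = 1e-6)
    expect_true(all(S >= 0))
  }
  # all-zero input with zero V rows in play: uniform rows
  p0 <- st_attention_params(4, 3, seed = 1)
  p0$V <- p0$V * 0; p0$b <- p0$b * 0
  expect_equal(spatial_attention(matrix(0, 4, 3), p0),
               matrix(0.25, 4, 4))

  pT <- st_attention_params(1, 2, d = 2, seed = 2)
  expect_equal(temporal_attention(matrix(rnorm(2), 1, 2), pT),
               matrix(1, 1, 1))
  for (r in 1:10) {
    Tn <- sample(2:8, 1)
    pT <- st_attention_params(Tn, 3, seed = r)
    S <- matrix(rnorm(Tn * 3), Tn, 3)
    Ta <- temporal_attention(S, pT)
    expect_equal(Ta, oracle_st_attention(S, pT), tolerance = 1e-8)
    expect_equal(rowSums(Ta), rep(1, Tn), tolerance = 1e-6)
  }
})

test_that("the scaled Laplacian has its spectrum in [-1, 1]", {
  # complete graph with self-loops on 2 nodes: normalised Laplacian
  # eigenvalues {0, 1}, scaled to {-1, 1}
  A <- matrix(1, 2, 2)
  sl <- scaled_laplacian(A)
  expect_equal(sort(eigen(sl$L_scaled)$values), c(-1, 1), tolerance = 1e-6)
  # without self-loops: L eigenvalues {0, 2}, scaled again to {-1, 1}
  A2 <- A - diag(2)
  sl2 <- scaled_laplacian(A2)
  expect_equal(sl2$lambda_max, 2, tolerance = 1e-6)
  expect_equal(sort(eigen(sl2$L_scaled)$values), c(-1, 1), tolerance = 1e-6)

  # empty graph: isolated-node rule sets unit degrees, L = I, lambda = 1
  expect_warning(sl0 <- scaled_laplacian(matrix(0, 3, 3)), "isolated")
  expect_equal(sl0$L_scaled, diag(3), tolerance = 1e-9)
  # pure self-loops: L = 0 exactly, the 1e-6 floor takes over, L~ = -I
  expect_equal(scaled_laplacian(diag(3))$L_scaled, -diag(3))

  set.seed(31)
  for (r in 1:50) {
    C <- sample(3:7, 1)
    A <- abs(matrix(rnorm(C * C), C, C)); A <- A + t(A); diag(A) <- 0
    sl <- scaled_laplacian(A)
    ev <- eigen(sl$L_scaled, symmetric = TRUE, only.values = TRUE)$values
    expect_lt(max(abs(ev)), 1 + 1e-6)
    expect_equal(sl$lambda_max, max(eigen(sl$L, symmetric = TRUE,
                                          only.values = TRUE)$values),
                 tolerance = 1e-6)
  }
})

test_that("the Chebyshev basis satisfies the recurrence and cosine identity", {
  L <- matrix(c(0.5, -0.2, -0.2, 0.1), 2, 2)
  b <- chebyshev_basis(L, 3)
  expect_equal(b[[1]], diag(2))
  expect_equal(b[[2]], L)
  # scalar closed form: T2(0.5) = 2 * 0.5 * 0.5 - 1
  expect_equal(chebyshev_basis(matrix(0.5), 3)[[3]][1, 1], -0.5)

  set.seed(32)
  for (x in seq(-1, 1, length.out = 25)) {
    b <- chebyshev_basis(matrix(x), 7)
    for (k in seq_len(7))
      expect_equal(b[[k]][1, 1], cos((k - 1) * acos(x)), tolerance = 1e-10)
  }

  # path graph on 3 nodes: basis equals independently assembled matrix
  # powers from the recurrence
  A <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  Ls <- scaled_laplacian(A)$L_scaled
  b <- chebyshev_basis(Ls, 4)
  man <- list(diag(3), Ls)
  man[[3]] <- 2 * Ls %*% man[[2]] - man[[1]]
  man[[4]] <- 2 * Ls %*% man[[3]] - man[[2]]
  for (k in 1:4) expect_equal(b[[k]], man[[k]], tolerance = 1e-9)
  expect_error(chebyshev_basis(Ls, 0), "K must")
})

test_that("graph convolution matches the explicit dense loop", {
  set.seed(33)
  C <- 4; Fd <- 3
  A <- abs(matrix(rnorm(C * C), C, C)); A <- A + t(A); diag(A) <- 0
  H <- matrix(rnorm(C * Fd), C, Fd)
  Su <- matrix(1 / C, C, C)
  y <- graph_conv(H, Su, A, list(diag(Fd)))
  expect_equal(y, Su %*% H, tolerance = 1e-10)   # K = 1, theta0 = I

  for (r in 1:50) {
    C <- sample(3:5, 1); Fd <- sample(2:4, 1); K <- sample(1:4, 1)
    A <- abs(matrix(rnorm(C * C), C, C)); A <- A + t(A); diag(A) <- 0
    H <- matrix(rnorm(C * Fd), C, Fd)
    p <- st_attention_params(C, Fd, seed = r)
    Satt <- spatial_attention(H, p)
    theta <- lapply(seq_len(K), function(k) matrix(rnorm(Fd * Fd), Fd, Fd))
    Lsc <- scaled_laplacian(A)$L_scaled
    expect_equal(graph_conv(H, Satt, A, theta),
                 oracle_graph_conv(H, Satt, Lsc, theta), tolerance = 1e-8)
  }
  expect_equal(graph_conv(H, Satt <- matrix(1 / C, C, C), A,
                          list(matrix(0, Fd, Fd))),
               matrix(0, C, Fd))
  expect_error(graph_conv(matrix(0, 2, 2), matrix(0, 3, 3),
                          matrix(0, 3, 3), list(diag(2))), "mismatch")
})

test_that("mixture-of-experts gating and fusion are convex", {
  expect_equal(moe_gate(rnorm(8), matrix(0, 6, 8), numeric(6)), rep(1 / 6, 6))
  g <- moe_gate(rnorm(8), matrix(0, 6, 8), c(50, 0, 0, 0, 0, 0))
  expect_gt(g[1], 1 - 1e-6)
  set.seed(34)
  for (r in 1:50) {
    Wg <- matrix(rnorm(48), 6, 8); bg <- rnorm(6); h <- rnorm(8)
    z <- as.numeric(Wg %*% h + bg)
    expect_equal(moe_gate(h, Wg, bg), exp(z) / sum(exp(z)),
                 tolerance = 1e-10)
    expect_equal(sum(moe_gate(h, Wg, bg)), 1, tolerance = 1e-6)
  }

  experts <- lapply(1:6, function(i) rnorm(7))
  expect_equal(moe_fuse(experts, c(0, 0, 1, 0, 0, 0)), experts[[3]])
  same <- rep(list(experts[[1]]), 6)
  g <- moe_gate(rnorm(8), matrix(rnorm(48), 6, 8), rnorm(6))
  expect_equal(moe_fuse(same, g), experts[[1]], tolerance = 1e-12)
  y <- moe_fuse(experts, g)
  loop <- numeric(7)
  for (i in 1:6) loop <- loop + g[i] * experts[[i]]
  expect_equal(y, loop, tolerance = 1e-10)
  lo <- do.call(pmin, experts); hi <- do.call(pmax, experts)
  expect_true(all(y >= lo - 1e-12 & y <= hi + 1e-12))
  expect_error(moe_fuse(experts[1:5], g), "expected 6")
})
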