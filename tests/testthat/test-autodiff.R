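# Gradient checks for every tape operation against central differences.

fd_check <- function(build, val0, eps = 1e-6, tol = 1e-6) {
  ns <- asNamespace("sleepgcn")
  tp <- ns$ad_tape()
  x <- ns$ad_param(tp, val0)
  L <- build(tp, x)
  ns$ad_backward(tp, L)
  g <- as.numeric(x$g)
  fd <- vapply(seq_along(val0), function(i) {
    v <- val0; v[i] <- v[i] + eps
    tpu <- ns$ad_tape()
    up <- ns$ad_value(build(tpu, ns$ad_param(tpu, v)))
    v[i] <- v[i] - 2 * eps
    tpd <- ns$ad_tape()
    dn <- ns$ad_value(build(tpd, ns$ad_param(tpd, v)))
    (up - dn) / (2 * eps)
  }, 0)
  expect_equal(g, fd, tolerance = tol)
}

test_that("elementary tape operations differentiate correctly", {
  ns <- asNamespace("sleepgcn")
  set.seed(60)
  A <- matrix(rnorm(6), 2, 3); B <- matrix(rnorm(12), 3, 4)
  v <- rnorm(3)
  # fixed readout constants (the builds are re-evaluated during FD)
  w2 <- rnorm(2); w3 <- rnorm(3); w6 <- matrix(rnorm(6), 2, 3)
  w9 <- matrix(rnorm(9), 3, 3); w12 <- matrix(rnorm(12), 3, 4)
  m24 <- matrix(rnorm(8), 2, 4); m43 <- matrix(rnorm(12), 4, 3)

  fd_check(function(tp, x) ns$ad_sum(tp, ns$ad_matmul(tp, x, B)), A)
  fd_check(function(tp, x) ns$ad_sum(tp, ns$ad_matmul(tp, A, x)), w12)
  fd_check(function(tp, x) ns$ad_mean(tp, ns$ad_mul(tp, x, x)), v)
  fd_check(function(tp, x) ns$ad_sum(tp, ns$ad_sigmoid(tp, x)), v)
  fd_check(function(tp, x) ns$ad_sum(tp, ns$ad_tanh(tp, x)), v)
  fd_check(function(tp, x)
    ns$ad_sum(tp, ns$ad_mul(tp, ns$ad_relu(tp, x), w3)), v + 2)
  fd_check(function(tp, x) {
    S <- ns$ad_softmax_rows(tp, x)
    ns$ad_sum(tp, ns$ad_mul(tp, S, w6))
  }, A)
  fd_check(function(tp, x) ns$ad_crossent(tp, x, 2L), v)
  fd_check(function(tp, x)
    ns$ad_sum(tp, ns$ad_mul_rows(tp, m24, x)), w2)
  fd_check(function(tp, x)
    ns$ad_sum(tp, ns$ad_mul(tp, ns$ad_colnorm(tp, x), w6)),
    A, eps = 1e-5, tol = 1e-3)
  fd_check(function(tp, x)
    ns$ad_sum(tp, ns$ad_mul(tp, ns$ad_affine_cols(tp, A, x, w3), w6)), w3)
  fd_check(function(tp, x)
    ns$ad_sum(tp, ns$ad_mul(tp, ns$ad_add_rowvec(tp, A, x), w6)), w3)
  fd_check(function(tp, x) {
    M <- ns$ad_maxpool_pairs(tp, x, c(1L, 3L), c(2L, 4L))
    ns$ad_sum(tp, ns$ad_mul(tp, M, w6))
  }, m43)
  fd_check(function(tp, x) {
    parts <- list(ns$ad_slice(tp, x, 1:2), ns$ad_slice(tp, x, 3))
    ns$ad_sum(tp, ns$ad_mul(tp, ns$ad_cat(tp, parts), c(1, 2, 3)))
  }, v)
  fd_check(function(tp, x)
    ns$ad_sum(tp, ns$ad_mul(tp, ns$ad_rows(tp, x, c(2L, 1L)), w6)), w9)
  fd_check(function(tp, x) {
    S <- ns$ad_stack_rows(tp, list(ns$ad_vec(tp, x), w3))
    ns$ad_sum(tp, ns$ad_mul(tp, S, w6))
  }, v)
  fd_check(function(tp, x)
    ns$ad_sum(tp, ns$ad_mul(tp, ns$ad_t(tp, x), t(A))), A)
  fd_check(function(tp, x)
    ns$ad_mean(tp, ns$ad_mul(tp, ns$ad_colmeans(tp, x), w3)), A)
  fd_check(function(tp, x)
    ns$ad_mean(tp, ns$ad_mul(tp, ns$ad_rowmeans(tp, x), w2)), A)
})

test_that("gradients accumulate over shared subexpressions", {
  ns <- asNamespace("sleepgcn")
  tp <- ns$ad_tape()
  x <- ns$ad_param(tp, 2)
  y <- ns$ad_mul(tp, x, x)           # x^2
  z <- ns$ad_add(tp, y, ns$ad_mul(tp, x, 3))  # x^2 + 3x
  ns$ad_backward(tp, z)
  expect_equal(as.numeric(x$g), 2 * 2 + 3)
})

test_that("the fused fusion+GRU node matches its unfused building blocks", {
  ns <- asNamespace("sleepgcn")
  set.seed(61)
  C <- 3L; w <- 5L; H <- 4L; Tn <- 6L
  smp <- list(
    Xw = lapply(seq_len(Tn), function(t) matrix(rnorm(C * w), C, w)),
    maskS = lapply(seq_len(Tn), function(t)
      matrix(rbinom(C * C, 1, 0.5), C, C)),
    maskF = lapply(seq_len(Tn), function(t)
      matrix(rbinom(C * C, 1, 0.5), C, C)))
  al <- rnorm(C) * 0.3; be <- rnorm(C) * 0.3
  gp <- gru_params(C * w, H, seed = 3)
  gpl <- gp[c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wh", "Uh", "bh")]
  hs <- ns$ad_fuse_gru(NULL, smp, al, be, gpl)
  # reference: public fuse + GRU ops
  ein <- lapply(seq_len(Tn), function(t) as.numeric(fuse_node_features(
    smp$Xw[[t]], list(mask_slow = smp$maskS[[t]], mask_fast = smp$maskF[[t]]),
    al, be)))
  ref <- gru_encode(ein, gp)
  expect_equal(hs, ref$hs, tolerance = 1e-12)

  # gradient of a scalar readout, checked by finite differences
  read <- matrix(rnorm(Tn * H), Tn, H)
  val <- function(a, b, gpx) sum(ns$ad_fuse_gru(NULL, smp, a, b, gpx) * read)
  tp <- ns$ad_tape()
  an <- ns$ad_param(tp, al); bn <- ns$ad_param(tp, be)
  gn <- lapply(gpl, function(p) ns$ad_param(tp, p))
  out <- ns$ad_fuse_gru(tp, smp, an, bn, gn)
  L <- ns$ad_sum(tp, ns$ad_mul(tp, out, read))
  ns$ad_backward(tp, L)
  eps <- 1e-6
  for (i in seq_len(C)) {
    a2 <- al; a2[i] <- a2[i] + eps
    a3 <- al; a3[i] <- a3[i] - eps
    expect_equal(as.numeric(an$g)[i],
                 (val(a2, be, gpl) - val(a3, be, gpl)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (nm in c("Wz", "Uh", "bh")) {
    for (i in c(1L, length(gpl[[nm]]))) {
      g2 <- gpl; g2[[nm]][i] <- g2[[nm]][i] + eps
      g3 <- gpl; g3[[nm]][i] <- g3[[nm]][i] - eps
      expect_equal(as.numeric(gn[[nm]]$g)[i],
                   (val(al, be, g2) - val(al, be, g3)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})
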