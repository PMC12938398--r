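# Adaptive spatio-temporal graph convolution: joint feature space, spatial
# and temporal attention, Chebyshev spectral filtering on the scaled
# normalised Laplacian, and mixture-of-experts fusion of the six streams.

#' Concatenate morphological and connectivity embeddings
#'
#' Hjoint = \[Hmorph (+) Hconn\]; widths are checked (384 + 128 = 512 for the
#' full-size model).
#'
#' @param Hmorph morphological embedding.
#' @param Hconn connectivity embedding.
#' @param widths expected widths of the two parts.
#' @return numeric vector of width `sum(widths)`.
#' @export
joint_features <- function(Hmorph, Hconn, widths = c(384L, 128L)) {
  if (length(Hmorph) != widths[1] || length(Hconn) != widths[2])
    stop("width mismatch: got ", length(Hmorph), "+", length(Hconn),
         ", expected ", widths[1], "+", widths[2])
  c(as.numeric(Hmorph), as.numeric(Hconn))
}

#' Parameters of one attention block (spatial or temporal)
#'
#' @param n rows of the attended axis (nodes C, or steps T).
#' @param f feature width per row.
#' @param d latent width of the bilinear score.
#' @param seed integer seed.
#' @return list with V (n x n), W1 (f x d), W2 (d x d), W3 (f x d),
#'   b (n x n).
#' @export
st_attention_params <- function(n, f, d = 16L, seed = 1L) {
  with_seed(seed, list(V = glorot(n, n), W1 = glorot(f, d),
                       W2 = glorot(d, d), W3 = glorot(f, d),
                       b = matrix(0, n, n)))
}

st_attention_core <- function(H, p) {
  score <- (H %*% p$W1) %*% p$W2 %*% t(H %*% p$W3) + p$b
  act <- p$V %*% (1 / (1 + exp(-score)))
  W <- exp(act - apply(act, 1L, max))
  W / rowSums(W)
}

#' Spatial attention over channels
#'
#' Row-stochastic C x C matrix
#' Softmax(V sigma((H W1) W2 (H W3)^T + b)) with sigma the logistic
#' function and the softmax taken per row.
#'
#' @param H nodes x features matrix.
#' @param params from [st_attention_params()].
#' @export
spatial_attention <- function(H, params) st_attention_core(H, params)

#' Temporal attention over the step sequence
#'
#' Same bilinear form evaluated on the transposed arrangement: rows are the
#' T time steps, yielding a row-stochastic T x T matrix capturing
#' long-range dependencies between steps.
#'
#' @param S steps x features matrix.
#' @param params from [st_attention_params()].
#' @export
temporal_attention <- function(S, params) st_attention_core(S, params)

#' Scaled normalised graph Laplacian
#'
#' L = I - D^(-1/2) A D^(-1/2), rescaled to Ltilde = 2 L / lambda_max - I so
#' its spectrum lies in \[-1, 1\] as Chebyshev filtering requires. Isolated
#' nodes (zero degree) have their degree replaced by 1, with a warning;
#' lambda_max is found by power iteration and floored at 1e-6.
#'
#' @param A symmetric non-negative adjacency (e.g. absolute masked
#'   correlations).
#' @return list with `L` (normalised Laplacian), `L_scaled`, `lambda_max`.
#' @export
scaled_laplacian <- function(A) {
  C <- ncol(A)
  deg <- rowSums(A)
  if (any(deg == 0)) {
    warning("isolated node(s) ", paste(which(deg == 0), collapse = ", "),
            ": degree set to 1")
    deg[deg == 0] <- 1
  }
  dinv <- 1 / sqrt(deg)
  L <- diag(C) - (dinv * A) %*% diag(dinv)
  L <- (L + t(L)) / 2
  lmax <- max(power_lambda_max(L), 1e-6)
  list(L = L, L_scaled = 2 * L / lmax - diag(C), lambda_max = lmax)
}

power_lambda_max <- function(M, iters = 2000L, tol = 1e-14) {
  # deterministic start with unequal entries, so it is not orthogonal to
  # the dominant eigenspace of the graph Laplacians seen here
  v <- seq_len(ncol(M)) + 0.5
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(iters)) {
    w <- M %*% v
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) return(0)   # M annihilates the iterate: spectrum ~ 0
    v_new <- as.numeric(w / nw)
    lam_new <- as.numeric(t(v_new) %*% M %*% v_new)
    if (abs(lam_new - lam) < tol) return(lam_new)
    lam <- lam_new; v <- v_new
  }
  lam
}

#' Chebyshev polynomial basis of a matrix
#'
#' T0 = I, T1 = X, Tk = 2 X T(k-1) - T(k-2); on a scaled Laplacian these
#' span the K-term spectral filter space.
#'
#' @param L_scaled square matrix with spectrum in \[-1, 1\].
#' @param K number of basis terms (>= 1).
#' @return list of K matrices.
#' @export
chebyshev_basis <- function(L_scaled, K = 3L) {
  if (K < 1L) stop("K must be >= 1")
  C <- ncol(L_scaled)
  basis <- vector("list", K)
  basis[[1]] <- diag(C)
  if (K >= 2L) basis[[2]] <- L_scaled
  if (K >= 3L) for (k in 3:K)
    basis[[k]] <- 2 * L_scaled %*% basis[[k - 1]] - basis[[k - 2]]
  basis
}

#' Chebyshev graph convolution with spatial attention
#'
#' Y = sum_k theta_k T_k(Ltilde) (Satt H): the node signals are first mixed
#' by the row-stochastic attention matrix, then filtered by the K-term
#' Chebyshev polynomial of the scaled Laplacian of `A`, each term mapped
#' through its own coefficient matrix theta_k.
#'
#' @param H nodes x features signal.
#' @param Satt row-stochastic spatial attention (C x C).
#' @param A symmetric non-negative adjacency.
#' @param theta list of K feature-mapping matrices (features x out).
#' @return nodes x out matrix.
#' @export
graph_conv <- function(H, Satt, A, theta) {
  if (nrow(H) != ncol(Satt) || nrow(H) != ncol(A))
    stop("node-count mismatch between H, Satt and A")
  basis <- chebyshev_basis(scaled_laplacian(A)$L_scaled, length(theta))
  Hmod <- Satt %*% H
  out <- 0
  for (k in seq_along(theta))
    out <- out + basis[[k]] %*% Hmod %*% theta[[k]]
  out
}

#' Mixture-of-experts gate
#'
#' G = Softmax(Wg Hjoint + bg): non-negative weights over the experts,
#' summing to one.
#'
#' @param Hjoint joint feature vector.
#' @param Wg n_experts x width gating matrix.
#' @param bg length n_experts bias.
#' @export
moe_gate <- function(Hjoint, Wg, bg) {
  z <- as.numeric(Wg %*% Hjoint + bg)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Mixture-of-experts fusion
#'
#' Yfinal = sum_i G_i Y_i: the gated convex combination of the expert
#' outputs (six streams, one per morphological branch scale).
#'
#' @param experts list of equal-width expert output vectors.
#' @param G gate weights from [moe_gate()].
#' @param n_experts required expert count.
#' @export
moe_fuse <- function(experts, G, n_experts = 6L) {
  if (length(experts) != n_experts)
    stop("expected ", n_experts, " experts, got ", length(experts))
  if (length(G) != length(experts)) stop("gate width mismatch")
  out <- 0
  for (i in seq_along(experts)) out <- out + G[i] * as.numeric(experts[[i]])
  out
}
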