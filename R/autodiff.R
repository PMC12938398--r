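# Minimal reverse-mode automatic differentiation on a linear tape.
#
# Values are plain numeric vectors/matrices. A node is an environment holding
# the forward value (`v`), an accumulated gradient (`g`), integer parent ids
# and a backward closure that maps the node's gradient to per-parent
# contributions. Operations accept either nodes or plain numerics; plain
# numerics are treated as constants and receive no gradient.

#' Create a fresh autodiff tape
#'
#' A tape records every differentiable operation in creation order so that
#' [ad_backward()] can run reverse-mode accumulation. One tape is typically
#' built per loss evaluation (per mini-batch) and discarded afterwards.
#'
#' @return An environment of class `ad_tape`.
#' @keywords internal
ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

is_adnode <- function(x) inherits(x, "adnode")

ad_value <- function(x) if (is_adnode(x)) x$v else x

new_adnode <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$pid <- vapply(parents, function(p) p$id, integer(1))
  nd$bw <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  class(nd) <- "adnode"
  nd
}

#' Declare a learnable leaf on the tape
#' @keywords internal
ad_param <- function(tape, value) new_adnode(tape, value)

# Wrap a constant as a node only when an op genuinely needs node parents.
ad_accum <- function(nd, g) {
  if (is.null(nd$g)) nd$g <- g else nd$g <- nd$g + g
  invisible(nd)
}

#' Reverse-mode sweep from a scalar node
#'
#' Seeds `node` with gradient 1 and propagates to every ancestor on the tape.
#' Gradients of leaves are read from their `g` field afterwards.
#' @keywords internal
ad_backward <- function(tape, node) {
  stopifnot(length(node$v) == 1L)
  node$g <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$g) || is.null(nd$bw)) next
    contrib <- nd$bw(nd$g)
    for (k in seq_along(nd$pid)) {
      if (!is.null(contrib[[k]])) ad_accum(tape$nodes[[nd$pid[k]]], contrib[[k]])
    }
  }
  invisible(NULL)
}

# --- binary arithmetic -------------------------------------------------------

ad_add <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  out <- av + bv
  if (!is_adnode(a) && !is_adnode(b)) return(out)
  parents <- list(); slots <- c(NA_integer_, NA_integer_)
  if (is_adnode(a)) { parents <- c(parents, list(a)); slots[1] <- length(parents) }
  if (is_adnode(b)) { parents <- c(parents, list(b)); slots[2] <- length(parents) }
  new_adnode(tape, out, parents, function(g) {
    res <- vector("list", length(parents))
    if (!is.na(slots[1])) res[[slots[1]]] <- if (length(av) == 1L && length(out) > 1L) sum(g) else g
    if (!is.na(slots[2])) {
      gb <- if (length(bv) == 1L && length(out) > 1L) sum(g) else g
      if (!is.na(slots[1]) && slots[1] == slots[2]) res[[slots[1]]] <- res[[slots[1]]] + gb else res[[slots[2]]] <- gb
    }
    res
  })
}

ad_neg <- function(tape, a) {
  if (!is_adnode(a)) return(-a)
  new_adnode(tape, -a$v, list(a), function(g) list(-g))
}

ad_sub <- function(tape, a, b) ad_add(tape, a, ad_neg(tape, b))

ad_mul <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  out <- av * bv
  if (!is_adnode(a) && !is_adnode(b)) return(out)
  parents <- list(); slots <- c(NA_integer_, NA_integer_)
  if (is_adnode(a)) { parents <- c(parents, list(a)); slots[1] <- length(parents) }
  if (is_adnode(b)) { parents <- c(parents, list(b)); slots[2] <- length(parents) }
  new_adnode(tape, out, parents, function(g) {
    res <- vector("list", length(parents))
    if (!is.na(slots[1])) {
      ga <- g * bv
      if (length(av) == 1L && length(out) > 1L) ga <- sum(ga)
      res[[slots[1]]] <- ga
    }
    if (!is.na(slots[2])) {
      gb <- g * av
      if (length(bv) == 1L && length(out) > 1L) gb <- sum(gb)
      res[[slots[2]]] <- gb
    }
    res
  })
}

ad_matmul <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  out <- av %*% bv
  if (!is_adnode(a) && !is_adnode(b)) return(out)
  parents <- list(); slots <- c(NA_integer_, NA_integer_)
  if (is_adnode(a)) { parents <- c(parents, list(a)); slots[1] <- length(parents) }
  if (is_adnode(b)) { parents <- c(parents, list(b)); slots[2] <- length(parents) }
  new_adnode(tape, out, parents, function(g) {
    res <- vector("list", length(parents))
    if (!is.na(slots[1])) res[[slots[1]]] <- g %*% t(bv)
    if (!is.na(slots[2])) res[[slots[2]]] <- t(av) %*% g
    res
  })
}

# --- elementwise nonlinearities ---------------------------------------------

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-ad_value(a)))
  if (!is_adnode(a)) return(s)
  new_adnode(tape, s, list(a), function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(tape, a) {
  th <- tanh(ad_value(a))
  if (!is_adnode(a)) return(th)
  new_adnode(tape, th, list(a), function(g) list(g * (1 - th^2)))
}

ad_relu <- function(tape, a) {
  av <- ad_value(a)
  out <- pmax(av, 0)
  if (!is_adnode(a)) return(out)
  new_adnode(tape, out, list(a), function(g) list(g * (av > 0)))
}

# Row-wise softmax of a matrix (or of a single vector treated as one row).
ad_softmax_rows <- function(tape, a) {
  av <- ad_value(a)
  vec <- is.null(dim(av))
  m <- if (vec) matrix(av, nrow = 1L) else av
  e <- exp(m - apply(m, 1L, max))
  p <- e / rowSums(e)
  out <- if (vec) as.numeric(p) else p
  if (!is_adnode(a)) return(out)
  new_adnode(tape, out, list(a), function(g) {
    gm <- if (vec) matrix(g, nrow = 1L) else g
    gx <- p * (gm - rowSums(gm * p))
    list(if (vec) as.numeric(gx) else gx)
  })
}

# --- reductions and reshaping ------------------------------------------------

ad_sum <- function(tape, a) {
  av <- ad_value(a)
  if (!is_adnode(a)) return(sum(av))
  new_adnode(tape, sum(av), list(a), function(g) {
    gr <- array(g, dim = if (is.null(dim(av))) length(av) else dim(av))
    list(if (is.null(dim(av))) as.numeric(gr) else gr)
  })
}

ad_mean <- function(tape, a) {
  n <- length(ad_value(a))
  ad_mul(tape, ad_sum(tape, a), 1 / n)
}

ad_colmeans <- function(tape, a) {
  av <- ad_value(a)
  if (!is_adnode(a)) return(colMeans(av))
  nr <- nrow(av)
  new_adnode(tape, colMeans(av), list(a), function(g) {
    list(matrix(g / nr, nrow = nr, ncol = ncol(av), byrow = TRUE))
  })
}

ad_rowmeans <- function(tape, a) {
  av <- ad_value(a)
  if (!is_adnode(a)) return(rowMeans(av))
  nc <- ncol(av)
  new_adnode(tape, rowMeans(av), list(a), function(g) {
    list(matrix(g / nc, nrow = nrow(av), ncol = nc))
  })
}

ad_vec <- function(tape, a) {
  av <- ad_value(a)
  if (!is_adnode(a)) return(as.numeric(av))
  if (is.null(dim(av))) return(a)   # already a plain vector node
  new_adnode(tape, as.numeric(av), list(a), function(g) {
    list(array(g, dim = dim(av)))
  })
}

ad_t <- function(tape, a) {
  if (!is_adnode(a)) return(t(a))
  new_adnode(tape, t(a$v), list(a), function(g) list(t(g)))
}

# Concatenate a list of vectors (nodes or constants) into one vector node.
ad_cat <- function(tape, parts) {
  vals <- lapply(parts, ad_value)
  lens <- vapply(vals, length, integer(1))
  out <- unlist(vals, use.names = FALSE)
  idx_node <- which(vapply(parts, is_adnode, logical(1)))
  if (length(idx_node) == 0L) return(out)
  offs <- cumsum(c(0L, lens))
  parents <- parts[idx_node]
  new_adnode(tape, out, parents, function(g) {
    lapply(idx_node, function(i) g[(offs[i] + 1L):offs[i + 1L]])
  })
}

ad_slice <- function(tape, a, idx) {
  av <- ad_value(a)
  if (!is_adnode(a)) return(av[idx])
  new_adnode(tape, av[idx], list(a), function(g) {
    gr <- numeric(length(av))
    gr[idx] <- g
    list(gr)
  })
}

ad_rows <- function(tape, a, rows) {
  av <- ad_value(a)
  if (!is_adnode(a)) return(av[rows, , drop = FALSE])
  new_adnode(tape, av[rows, , drop = FALSE], list(a), function(g) {
    gr <- matrix(0, nrow(av), ncol(av))
    gr[rows, ] <- gr[rows, ] + g
    list(gr)
  })
}

# --- column-wise affine (used for feature-map normalisation) -----------------

# y[, j] = a[, j] * gamma[j] + beta[j]; gamma/beta length-ncol vectors.
ad_affine_cols <- function(tape, a, gamma, beta) {
  av <- ad_value(a); gv <- ad_value(gamma); bv <- ad_value(beta)
  out <- sweep(sweep(av, 2L, gv, "*"), 2L, bv, "+")
  parents <- list(); slots <- c(NA_integer_, NA_integer_, NA_integer_)
  if (is_adnode(a)) { parents <- c(parents, list(a)); slots[1] <- length(parents) }
  if (is_adnode(gamma)) { parents <- c(parents, list(gamma)); slots[2] <- length(parents) }
  if (is_adnode(beta)) { parents <- c(parents, list(beta)); slots[3] <- length(parents) }
  if (length(parents) == 0L) return(out)
  new_adnode(tape, out, parents, function(g) {
    res <- vector("list", length(parents))
    if (!is.na(slots[1])) res[[slots[1]]] <- sweep(g, 2L, gv, "*")
    if (!is.na(slots[2])) res[[slots[2]]] <- colSums(g * av)
    if (!is.na(slots[3])) res[[slots[3]]] <- colSums(g)
    res
  })
}

# Normalise each column to zero mean / unit variance over rows (biased SD).
ad_colnorm <- function(tape, a, eps = 1e-5) {
  av <- ad_value(a)
  n <- nrow(av)
  mu <- colMeans(av)
  xc <- sweep(av, 2L, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  out <- sweep(xc, 2L, inv, "*")
  if (!is_adnode(a)) return(out)
  new_adnode(tape, out, list(a), function(g) {
    gm <- colMeans(g)
    gxm <- colMeans(g * out)
    gx <- sweep(sweep(g, 2L, gm), 2L, inv, "*") - sweep(out, 2L, gxm * inv, "*")
    list(gx)
  })
}

# --- pooling -----------------------------------------------------------------

# Max over row pairs: out[i, ] = pmax(a[i1[i], ], a[i2[i], ]).
ad_maxpool_pairs <- function(tape, a, i1, i2) {
  av <- ad_value(a)
  x1 <- av[i1, , drop = FALSE]; x2 <- av[i2, , drop = FALSE]
  take1 <- x1 >= x2
  out <- ifelse(take1, x1, x2)
  if (!is_adnode(a)) return(out)
  new_adnode(tape, out, list(a), function(g) {
    gr <- matrix(0, nrow(av), ncol(av))
    gr[i1, ] <- g * take1      # i1 and i2 are disjoint row sets
    gr[i2, ] <- g * !take1
    list(gr)
  })
}

# Scale row i of matrix `a` by v[i].
ad_mul_rows <- function(tape, a, v) {
  av <- ad_value(a); vv <- ad_value(v)
  out <- av * vv   # column-major recycling scales rows
  if (!is_adnode(a) && !is_adnode(v)) return(out)
  parents <- list(); slots <- c(NA_integer_, NA_integer_)
  if (is_adnode(a)) { parents <- c(parents, list(a)); slots[1] <- length(parents) }
  if (is_adnode(v)) { parents <- c(parents, list(v)); slots[2] <- length(parents) }
  new_adnode(tape, out, parents, function(g) {
    res <- vector("list", length(parents))
    if (!is.na(slots[1])) res[[slots[1]]] <- g * vv
    if (!is.na(slots[2])) res[[slots[2]]] <- rowSums(g * av)
    res
  })
}

# Add a row vector to every row of a matrix.
ad_add_rowvec <- function(tape, a, v) {
  av <- ad_value(a); vv <- ad_value(v)
  out <- sweep(av, 2L, vv, "+")
  if (!is_adnode(a) && !is_adnode(v)) return(out)
  parents <- list(); slots <- c(NA_integer_, NA_integer_)
  if (is_adnode(a)) { parents <- c(parents, list(a)); slots[1] <- length(parents) }
  if (is_adnode(v)) { parents <- c(parents, list(v)); slots[2] <- length(parents) }
  new_adnode(tape, out, parents, function(g) {
    res <- vector("list", length(parents))
    if (!is.na(slots[1])) res[[slots[1]]] <- g
    if (!is.na(slots[2])) res[[slots[2]]] <- colSums(g)
    res
  })
}

# Stack a list of equal-length vectors as the rows of a matrix.
ad_stack_rows <- function(tape, parts) {
  vals <- lapply(parts, function(p) as.numeric(ad_value(p)))
  out <- do.call(rbind, vals)
  idx_node <- which(vapply(parts, is_adnode, logical(1)))
  if (length(idx_node) == 0L) return(out)
  parents <- parts[idx_node]
  new_adnode(tape, out, parents, function(g) {
    lapply(idx_node, function(i) {
      gi <- g[i, ]
      pv <- ad_value(parents[[match(i, idx_node)]])
      if (!is.null(dim(pv))) dim(gi) <- dim(pv)
      gi
    })
  })
}

# --- losses and special layers ----------------------------------------------

# Fused softmax + cross-entropy for one sample; logits is a vector node,
# label an integer in 1..length(logits).
ad_crossent <- function(tape, logits, label) {
  lv <- ad_value(logits)
  m <- max(lv)
  lse <- m + log(sum(exp(lv - m)))
  loss <- lse - lv[label]
  if (!is_adnode(logits)) return(loss)
  p <- exp(lv - lse)
  new_adnode(tape, loss, list(logits), function(g) {
    gr <- p * g
    gr[label] <- gr[label] - g
    list(gr)
  })
}

#' Gradient reversal layer
#'
#' Identity in the forward pass; multiplies the incoming gradient by
#' `-lambda` in the backward pass. Inserting it between a feature extractor
#' and a domain discriminator turns joint minimisation into the minimax game
#' of domain-adversarial training.
#'
#' @param tape an `ad_tape` (ignored when `x` is a plain numeric).
#' @param x node or numeric.
#' @param lambda non-negative adversarial strength.
#' @return `x` unchanged in value; gradient contract as described.
#' @export
grl <- function(tape, x, lambda) {
  stopifnot(lambda >= 0)
  if (!is_adnode(x)) return(x)
  new_adnode(tape, x$v, list(x), function(g) list(-lambda * g))
}
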