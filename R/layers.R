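#' Symmetric renormalized adjacency
#'
#' Adds self-loops to a binary symmetric adjacency A with zero diagonal and
#' returns `D^(-1/2) (A + I) D^(-1/2)` where D is the degree matrix of
#' A + I. The self-loop keeps the row of an isolated node well-defined
#' (its only entry is 1), and the spectral radius of the result is <= 1.
#'
#' @param A binary symmetric matrix (dense or sparse), zero diagonal.
#' @return sparse symmetric Matrix.
#' @export
normalize_adjacency <- function(A) {
  A <- Matrix::Matrix(A, sparse = TRUE)
  if (!Matrix::isSymmetric(A)) stop("adjacency must be symmetric")
  if (any(Matrix::diag(A) != 0)) stop("adjacency must have a zero diagonal")
  At <- A + Matrix::Diagonal(nrow(A))
  d <- Matrix::rowSums(At)
  Dm <- Matrix::Diagonal(x = 1 / sqrt(d))
  Dm %*% At %*% Dm
}

# directed edge list (src -> dst) with self-loops from a symmetric adjacency
adjacency_to_edges <- function(A, add_self_loops = TRUE) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  nz <- A@x != 0
  src <- A@i[nz] + 1L; dst <- A@j[nz] + 1L
  if (add_self_loops) {
    src <- c(src, seq_len(nrow(A)))
    dst <- c(dst, seq_len(nrow(A)))
  }
  ord <- order(dst, src)
  list(src = src[ord], dst = dst[ord], n = nrow(A))
}

complete_edges <- function(n) {
  g <- expand.grid(src = seq_len(n), dst = seq_len(n))
  list(src = g$src, dst = g$dst, n = n)
}

# ---- tape-level layer builders (shared by the user-facing functions and
# ---- the trainable models) ------------------------------------------------

gcn_layer_t <- function(tape, h, Ahat, W, b = NULL,
                        activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  out <- t_matmul(tape, t_spmm(tape, Ahat, h), W)
  if (!is.null(b)) out <- t_add_bias(tape, out, b)
  if (activation == "relu") out <- t_relu(tape, out) else out
}

# one GAT head: returns list(out = node features, alpha = per-edge coef)
gat_head_t <- function(tape, h, edges, W, a_vec, negative_slope = 0.2) {
  Wh <- t_matmul(tape, h, W)
  dh <- ncol(W$value)
  # the two halves of `a` act as slices of the single parameter vector
  s_dst <- t_matmul_slice(tape, Wh, a_vec, seq_len(dh))
  s_src <- t_matmul_slice(tape, Wh, a_vec, dh + seq_len(dh))
  logits <- t_add(tape,
                  t_gather(tape, s_dst, edges$dst),
                  t_gather(tape, s_src, edges$src))
  logits <- t_leaky_relu(tape, logits, negative_slope)
  alpha <- t_edge_softmax(tape, logits, edges$dst, edges$n)
  msg <- t_scale_rows(tape, t_gather(tape, Wh, edges$src), alpha)
  out <- t_scatter_sum(tape, msg, edges$dst, edges$n)
  list(out = out, alpha = alpha, Wh = Wh)
}

# matrix product with a slice of a column-vector parameter: Wh %*% a[slice]
t_matmul_slice <- function(tape, a, vec, slice) {
  w <- matrix(as.vector(vec$value)[slice], ncol = 1)
  tnode(tape, a$value %*% w, list(a, vec), function(g) {
    t_accum(a, g %*% t(w))
    dv <- matrix(0, nrow(vec$value), ncol(vec$value))
    dv[slice] <- crossprod(a$value, g)
    t_accum(vec, dv)
  })
}

# one scaled-dot-product attention layer restricted to the edge set
gtn_layer_t <- function(tape, h, edges, WQ, WK, WV) {
  dk <- ncol(WK$value)
  if (dk == 0) stop("d_k must be positive")
  Q <- t_matmul(tape, h, WQ)
  K <- t_matmul(tape, h, WK)
  V <- t_matmul(tape, h, WV)
  sc <- t_edge_dot(tape, Q, K, edges$src, edges$dst, scale = 1 / sqrt(dk))
  alpha <- t_edge_softmax(tape, sc, edges$dst, edges$n)
  msg <- t_scale_rows(tape, t_gather(tape, V, edges$src), alpha)
  list(out = t_scatter_sum(tape, msg, edges$dst, edges$n), alpha = alpha)
}

# ---- user-facing single-layer forward passes ------------------------------

#' Graph-convolution layer forward pass
#'
#' Computes `sigma(Ahat %*% H %*% W)` with `Ahat` a normalized adjacency
#' from [normalize_adjacency()].
#'
#' @param H node-feature matrix (n x d_in).
#' @param Ahat normalized adjacency (n x n).
#' @param W weight matrix (d_in x d_out).
#' @param activation `"relu"` (default) or `"identity"`.
#' @return node-feature matrix (n x d_out).
#' @export
gcn_forward <- function(H, Ahat, W, activation = c("relu", "identity")) {
  if (ncol(H) != nrow(W)) stop("dimension mismatch: ncol(H) != nrow(W)")
  tp <- tape_new()
  gcn_layer_t(tp, t_const(tp, H), Ahat, t_const(tp, W),
              activation = match.arg(activation))$value
}

#' Graph-attention coefficients
#'
#' Softmax-normalized attention coefficients per directed edge and head:
#' `alpha_ij = softmax_j(LeakyReLU(a^T [W h_i || W h_j]))`, normalized over
#' the attended set of destination node i. Every node attends over its
#' neighbourhood plus itself (self-loops are appended), so no attended set
#' is empty.
#'
#' @param H node-feature matrix.
#' @param edges either a symmetric adjacency matrix or a list with `src`,
#'   `dst`, `n` (self-loops appended when an adjacency is given).
#' @param W projection matrix (d_in x d_head).
#' @param a attention vector of length 2 * d_head (destination half first).
#' @param negative_slope LeakyReLU slope (default 0.2).
#' @return data.frame `src`, `dst`, `alpha`; coefficients sum to 1 per
#'   destination node.
#' @export
gat_attention <- function(H, edges, W, a, negative_slope = 0.2) {
  ed <- if (is.list(edges) && !is.data.frame(edges)) edges else
    adjacency_to_edges(edges)
  if (ncol(H) != nrow(W)) stop("dimension mismatch: ncol(H) != nrow(W)")
  if (length(a) != 2 * ncol(W)) stop("attention vector must have length 2*d_head")
  tp <- tape_new()
  hd <- gat_head_t(tp, t_const(tp, H), ed, t_const(tp, W),
                   t_const(tp, matrix(a, ncol = 1)), negative_slope)
  data.frame(src = ed$src, dst = ed$dst, alpha = as.vector(hd$alpha$value))
}

#' Graph-attention layer forward pass
#'
#' Per-head attention-weighted neighbourhood sums (Eqs. 4-5 style), heads
#' concatenated (`combine = "concat"`, hidden layers) or averaged
#' (`combine = "mean"`, final attention layer). No activation is applied
#' here; the model wrapper adds batch normalization and LeakyReLU.
#'
#' @inheritParams gat_attention
#' @param Ws list of per-head projection matrices.
#' @param as list of per-head attention vectors (length 2 * d_head each).
#' @param combine `"concat"` or `"mean"`.
#' @return node-feature matrix.
#' @export
gat_forward <- function(H, edges, Ws, as, combine = c("concat", "mean"),
                        negative_slope = 0.2) {
  combine <- match.arg(combine)
  ed <- if (is.list(edges) && !is.data.frame(edges)) edges else
    adjacency_to_edges(edges)
  tp <- tape_new()
  hn <- t_const(tp, H)
  heads <- lapply(seq_along(Ws), function(k) {
    if (ncol(H) != nrow(Ws[[k]])) stop("dimension mismatch in head ", k)
    gat_head_t(tp, hn, ed, t_const(tp, Ws[[k]]),
               t_const(tp, matrix(as[[k]], ncol = 1)), negative_slope)$out
  })
  if (combine == "concat") {
    t_cbind(tp, heads)$value
  } else {
    Reduce(`+`, lapply(heads, function(nd) nd$value)) / length(heads)
  }
}

#' Graph-transformer layer forward pass
#'
#' Masked scaled-dot-product self-attention restricted to each node's
#' neighbourhood plus itself: `softmax(Q K^T / sqrt(d_k)) V` with the
#' softmax taken over the attended set. With `global = TRUE` every node
#' attends to every node (unrestricted self-attention).
#'
#' @inheritParams gat_attention
#' @param WQ,WK,WV query/key/value projections (d_in x d_k / d_k / d_out).
#' @param global unrestricted attention over all node pairs.
#' @return node-feature matrix (n x d_out).
#' @export
gtn_forward <- function(H, edges, WQ, WK, WV, global = FALSE) {
  ed <- if (global) complete_edges(nrow(H)) else
    if (is.list(edges) && !is.data.frame(edges)) edges else
      adjacency_to_edges(edges)
  if (ncol(WK) == 0 || ncol(WQ) == 0) stop("d_k must be positive")
  tp <- tape_new()
  gtn_layer_t(tp, t_const(tp, H), ed, t_const(tp, WQ), t_const(tp, WK),
              t_const(tp, WV))$out$value
}
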