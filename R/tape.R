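# Minimal reverse-mode automatic differentiation over matrices.
#
# A "tape" is an environment collecting nodes in creation order; each node
# holds its value, a gradient accumulator and a backward closure that
# pushes gradients to its parents. Values are computed eagerly, so forward
# results can be read off any node; calling tape_backward() on a scalar
# loss node fills in gradients in reverse order. The op set is exactly
# what the message-passing layers need: dense and sparse matrix products,
# elementwise nonlinearities, dropout, batch normalization, row
# gather/scatter for edge lists, a per-destination edge softmax, and a
# masked cross-entropy loss. Gradients are verified against central finite
# differences in the test suite.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp
}

tnode <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tape$nodes[[length(tape$nodes) + 1L]] <- nd
  nd
}

t_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

t_const <- function(tape, x) tnode(tape, x)

tape_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_along(tape$nodes))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
}

t_matmul <- function(tape, a, b) {
  tnode(tape, a$value %*% b$value, list(a, b), function(g) {
    t_accum(a, g %*% t(b$value))
    t_accum(b, crossprod(a$value, g))
  })
}

# sparse constant matrix (e.g. normalized adjacency) times node; S must be
# symmetric or the caller supplies its transpose semantics implicitly
t_spmm <- function(tape, S, h) {
  tnode(tape, as.matrix(S %*% h$value), list(h), function(g) {
    t_accum(h, as.matrix(Matrix::t(S) %*% g))
  })
}

t_add <- function(tape, a, b) {
  tnode(tape, a$value + b$value, list(a, b), function(g) {
    t_accum(a, g); t_accum(b, g)
  })
}

# add a 1 x d bias row to every row of a
t_add_bias <- function(tape, a, b) {
  tnode(tape, sweep(a$value, 2, as.vector(b$value), `+`), list(a, b),
        function(g) {
          t_accum(a, g)
          t_accum(b, matrix(colSums(g), 1))
        })
}

t_relu <- function(tape, a) {
  tnode(tape, pmax(a$value, 0), list(a), function(g) {
    t_accum(a, g * (a$value > 0))
  })
}

t_leaky_relu <- function(tape, a, slope = 0.2) {
  v <- ifelse(a$value > 0, a$value, slope * a$value)
  tnode(tape, v, list(a), function(g) {
    t_accum(a, g * ifelse(a$value > 0, 1, slope))
  })
}

t_dropout <- function(tape, a, p, training) {
  if (!training || p <= 0) return(a)
  mask <- (matrix(stats::runif(length(a$value)), nrow(a$value)) >= p) / (1 - p)
  tnode(tape, a$value * mask, list(a), function(g) t_accum(a, g * mask))
}

t_scale <- function(tape, a, s) {
  tnode(tape, a$value * s, list(a), function(g) t_accum(a, g * s))
}

t_gather <- function(tape, a, idx) {
  tnode(tape, a$value[idx, , drop = FALSE], list(a), function(g) {
    agg <- rowsum(g, group = idx)
    dA <- matrix(0, nrow(a$value), ncol(a$value))
    dA[as.integer(rownames(agg)), ] <- agg
    t_accum(a, dA)
  })
}

t_scatter_sum <- function(tape, a, idx, n) {
  agg <- rowsum(a$value, group = idx)
  v <- matrix(0, n, ncol(a$value))
  v[as.integer(rownames(agg)), ] <- agg
  tnode(tape, v, list(a), function(g) {
    t_accum(a, g[idx, , drop = FALSE])
  })
}

# multiply row e of a (E x d) by scalar s_e (E x 1 node)
t_scale_rows <- function(tape, a, s) {
  sv <- as.vector(s$value)
  tnode(tape, a$value * sv, list(a, s), function(g) {
    t_accum(a, g * sv)
    t_accum(s, matrix(rowSums(g * a$value), ncol = 1))
  })
}

# e_k = scale * sum_d Q[dst_k, d] * K[src_k, d]   (E x 1)
t_edge_dot <- function(tape, q, k, src, dst, scale = 1) {
  v <- matrix(rowSums(q$value[dst, , drop = FALSE] *
                      k$value[src, , drop = FALSE]) * scale, ncol = 1)
  tnode(tape, v, list(q, k), function(g) {
    gs <- as.vector(g) * scale
    dq <- rowsum(gs * k$value[src, , drop = FALSE], group = dst)
    dQ <- matrix(0, nrow(q$value), ncol(q$value))
    dQ[as.integer(rownames(dq)), ] <- dq
    t_accum(q, dQ)
    dk <- rowsum(gs * q$value[dst, , drop = FALSE], group = src)
    dK <- matrix(0, nrow(k$value), ncol(k$value))
    dK[as.integer(rownames(dk)), ] <- dk
    t_accum(k, dK)
  })
}

# softmax over edges grouped by destination node: alpha_e =
# exp(l_e) / sum_{e': dst(e') = dst(e)} exp(l_e')
t_edge_softmax <- function(tape, logits, dst, n) {
  l <- as.vector(logits$value)
  mx <- tapply(l, dst, max)[as.character(dst)]
  ex <- exp(l - mx)
  denom <- tapply(ex, dst, sum)[as.character(dst)]
  alpha <- matrix(ex / denom, ncol = 1)
  tnode(tape, alpha, list(logits), function(g) {
    gv <- as.vector(g); av <- as.vector(alpha)
    s <- tapply(av * gv, dst, sum)[as.character(dst)]
    t_accum(logits, matrix(av * (gv - s), ncol = 1))
  })
}

t_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(nd) ncol(nd$value), 1L)
  tnode(tape, do.call(cbind, lapply(nodes, function(nd) nd$value)), nodes,
        function(g) {
          off <- 0L
          for (i in seq_along(nodes)) {
            t_accum(nodes[[i]], g[, off + seq_len(widths[i]), drop = FALSE])
            off <- off + widths[i]
          }
        })
}

# batch normalization over rows, per column; `state` is an environment
# holding running_mean / running_var for evaluation mode
t_batchnorm <- function(tape, a, gamma, beta, state, training,
                        momentum = 0.1, eps = 1e-5) {
  x <- a$value
  n <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    va <- colMeans(sweep(x, 2, mu)^2)
    if (is.null(state$running_mean)) {
      state$running_mean <- mu
      state$running_var <- va
    } else {
      state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
      state$running_var <- (1 - momentum) * state$running_var + momentum * va
    }
  } else {
    mu <- if (is.null(state$running_mean)) colMeans(x) else state$running_mean
    va <- if (is.null(state$running_var))
      colMeans(sweep(x, 2, mu)^2) else state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, istd, `*`)
  v <- sweep(sweep(xhat, 2, as.vector(gamma$value), `*`), 2,
             as.vector(beta$value), `+`)
  tnode(tape, v, list(a, gamma, beta), function(g) {
    t_accum(gamma, matrix(colSums(g * xhat), 1))
    t_accum(beta, matrix(colSums(g), 1))
    dxhat <- sweep(g, 2, as.vector(gamma$value), `*`)
    if (training) {
      # standard batch-norm backward through the batch statistics
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), `*`)
      t_accum(a, sweep(t1 - t2, 2, istd, `*`))
    } else {
      t_accum(a, sweep(dxhat, 2, istd, `*`))
    }
  })
}

# mean pooling of node rows into graph rows by batch index (graph mode)
t_mean_pool <- function(tape, a, batch, n_graphs) {
  cnt <- as.vector(table(factor(batch, levels = seq_len(n_graphs))))
  agg <- rowsum(a$value, group = batch)
  v <- matrix(0, n_graphs, ncol(a$value))
  v[as.integer(rownames(agg)), ] <- agg
  v <- v / cnt
  tnode(tape, v, list(a), function(g) {
    t_accum(a, (g / cnt)[batch, , drop = FALSE])
  })
}

# mean cross-entropy of softmax(logits) against integer labels, restricted
# to rows in `rows`; returns a scalar node
t_cross_entropy <- function(tape, logits, y, rows) {
  L <- logits$value[rows, , drop = FALSE]
  yr <- y[rows]
  mx <- apply(L, 1, max)
  ex <- exp(L - mx)
  p <- ex / rowSums(ex)
  m <- length(rows)
  loss <- -mean(log(pmax(p[cbind(seq_len(m), yr)], 1e-300)))
  tnode(tape, loss, list(logits), function(g) {
    dL <- p
    dL[cbind(seq_len(m), yr)] <- dL[cbind(seq_len(m), yr)] - 1
    dAll <- matrix(0, nrow(logits$value), ncol(logits$value))
    dAll[rows, ] <- g * dL / m
    t_accum(logits, dAll)
  })
}

softmax_rows <- function(L) {
  mx <- apply(L, 1, max)
  ex <- exp(L - mx)
  ex / rowSums(ex)
}
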