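# Shared fixtures, built in code at test time.

# small random undirected graph as a dense 0/1 adjacency
random_adjacency <- function(n, p_edge = 0.2) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- up[stats::runif(length(up)) < p_edge]
  A[on] <- 1
  A + t(A)
}

# dense-matrix reference for one GCN layer: relu(D^-1/2 (A+I) D^-1/2 H W)
dense_gcn_oracle <- function(A, H, W) {
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  Ahat <- diag(1 / sqrt(d)) %*% At %*% diag(1 / sqrt(d))
  pmax(Ahat %*% H %*% W, 0)
}

# dense masked-softmax reference for one GAT head (no activation)
dense_gat_oracle <- function(A, H, W, a, slope = 0.2) {
  n <- nrow(A)
  M <- A + diag(n)            # attended set: neighbours plus self
  Wh <- H %*% W
  dh <- ncol(W)
  s_dst <- Wh %*% a[seq_len(dh)]
  s_src <- Wh %*% a[dh + seq_len(dh)]
  E <- outer(as.vector(s_dst), rep(1, n)) + outer(rep(1, n), as.vector(s_src))
  E <- ifelse(E > 0, E, slope * E)
  E[M == 0] <- -Inf
  P <- exp(E - apply(E, 1, max))
  P <- P / rowSums(P)
  P %*% Wh
}

# dense masked scaled-dot-product reference for one transformer layer
dense_gtn_oracle <- function(A, H, WQ, WK, WV) {
  n <- nrow(A)
  M <- A + diag(n)
  Q <- H %*% WQ; K <- H %*% WK; V <- H %*% WV
  S <- Q %*% t(K) / sqrt(ncol(WK))
  S[M == 0] <- -Inf
  P <- exp(S - apply(S, 1, max))
  P <- P / rowSums(P)
  P %*% V
}

# tiny labelled sample graph for training tests
toy_sample_graph <- function(n_per = 10, k = 3, d_signal = 6, d_noise = 4,
                             sep = 3, seed = 1) {
  set.seed(seed)
  n <- n_per * k
  lab <- factor(rep(paste0("c", seq_len(k)), each = n_per))
  centers <- matrix(stats::rnorm(k * d_signal, sd = sep), k, d_signal)
  X <- centers[as.integer(lab), ] + matrix(stats::rnorm(n * d_signal), n)
  X <- cbind(X, matrix(stats::rnorm(n * d_noise), n))
  rownames(X) <- sprintf("S%03d", seq_len(n))
  names(lab) <- rownames(X)
  integ <- structure(list(X = X,
                          feature_origin = rep("toy", ncol(X)),
                          labels = lab),
                     class = "integrated_dataset")
  suppressWarnings(build_sample_graph(integ, threshold = 0.4))
}

# modularity of a partition on an undirected 0/1 adjacency
modularity_of <- function(A, membership) {
  A <- as.matrix(A)
  m2 <- sum(A)
  if (m2 == 0) return(NA_real_)
  k <- rowSums(A)
  same <- outer(membership, membership, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}
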