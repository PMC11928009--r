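# --- adjacency normalization -------------------------------------------------

test_that("normalization handles isolated nodes and tiny graphs exactly", {
  # all-isolated graph: self-loops only, identity
  expect_equal(as.matrix(normalize_adjacency(matrix(0, 3, 3))), diag(3))
  # two nodes, one edge: A+I all ones, degrees 2 -> all entries 1/2
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(as.matrix(normalize_adjacency(A)), matrix(0.5, 2, 2))
  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  expect_error(normalize_adjacency(diag(2)), "zero diagonal")
})

test_that("normalized adjacency has spectral radius at most one", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    A <- random_adjacency(n, 0.15)
    ev <- eigen(as.matrix(normalize_adjacency(A)), symmetric = TRUE,
                only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-8)
  }
})

# --- GCN ---------------------------------------------------------------------

test_that("sparse GCN layer matches the dense oracle on random graphs", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(5:50, 1); din <- sample(2:8, 1); dout <- sample(2:8, 1)
    A <- random_adjacency(n)
    H <- matrix(rnorm(n * din), n)
    W <- matrix(rnorm(din * dout), din)
    got <- gcn_forward(H, normalize_adjacency(A), W)
    expect_lt(max(abs(got - dense_gcn_oracle(A, H, W))), 1e-5)
  }
})

test_that("GCN layer honours trivial identities and dimension checks", {
  H <- matrix(c(1, 2), 1, 2)
  Ahat <- normalize_adjacency(matrix(0, 1, 1))
  expect_equal(gcn_forward(H, Ahat, diag(2)), H, ignore_attr = TRUE)
  expect_equal(gcn_forward(H, Ahat, matrix(0, 2, 3)), matrix(0, 1, 3))
  expect_error(gcn_forward(H, Ahat, diag(3)), "dimension mismatch")
})

# --- GAT ---------------------------------------------------------------------

test_that("attention is uniform for identical features and sums to one", {
  set.seed(43)
  A <- random_adjacency(10, 0.4)
  H <- matrix(1, 10, 3)          # identical node features
  W <- matrix(rnorm(3 * 4), 3)
  a <- rnorm(8)
  att <- gat_attention(H, A, W, a)
  # per-destination sums
  sums <- tapply(att$alpha, att$dst, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # uniform over each attended set
  deg <- table(att$dst)
  expect_true(all(abs(att$alpha - (1 / deg[as.character(att$dst)])) < 1e-10))
})

test_that("attention coefficients match a by-hand evaluation on a 3-node path", {
  # path 1-2-3; hand-set projections
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  H <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2)
  W <- diag(2)
  a <- c(1, -1, 0.5, 0.5)
  att <- gat_attention(H, A, W, a, negative_slope = 0.2)
  lrelu <- function(z) ifelse(z > 0, z, 0.2 * z)
  Wh <- H %*% W
  # destination node 1 attends over {1, 2}
  e11 <- lrelu(sum(a[1:2] * Wh[1, ]) + sum(a[3:4] * Wh[1, ]))
  e12 <- lrelu(sum(a[1:2] * Wh[1, ]) + sum(a[3:4] * Wh[2, ]))
  expected <- exp(c(e11, e12)) / sum(exp(c(e11, e12)))
  got <- att[att$dst == 1, ]
  got <- got[order(got$src), ]
  expect_equal(got$alpha, expected[order(c(1, 2))], tolerance = 1e-10)
})

test_that("sparse GAT forward matches the dense masked-softmax oracle", {
  set.seed(44)
  for (i in 1:30) {
    n <- sample(5:50, 1); din <- sample(2:6, 1); dh <- sample(2:5, 1)
    A <- random_adjacency(n)
    H <- matrix(rnorm(n * din), n)
    W <- matrix(rnorm(din * dh), din)
    a <- rnorm(2 * dh)
    got <- gat_forward(H, A, list(W), list(a), combine = "concat")
    expect_lt(max(abs(got - dense_gat_oracle(A, H, W, a))), 1e-5)
  }
})

test_that("multi-head combination follows the concat/average contract", {
  set.seed(45)
  n <- 8; din <- 4; dh <- 3; n_heads <- 3
  A <- random_adjacency(n, 0.4)
  H <- matrix(rnorm(n * din), n)
  Ws <- replicate(n_heads, matrix(rnorm(din * dh), din), simplify = FALSE)
  as <- replicate(n_heads, rnorm(2 * dh), simplify = FALSE)
  cc <- gat_forward(H, A, Ws, as, combine = "concat")
  expect_equal(dim(cc), c(n, n_heads * dh))
  mm <- gat_forward(H, A, Ws, as, combine = "mean")
  expect_equal(dim(mm), c(n, dh))
  singles <- lapply(seq_len(n_heads), function(k)
    gat_forward(H, A, Ws[k], as[k], combine = "concat"))
  expect_equal(mm, Reduce(`+`, singles) / n_heads, tolerance = 1e-12)
  # single node, single head: alpha_ii = 1 so output = W' h
  H1 <- matrix(c(2, -1), 1, 2)
  W1 <- matrix(rnorm(4), 2)
  expect_equal(gat_forward(H1, matrix(0, 1, 1), list(W1), list(rnorm(4))),
               H1 %*% W1, tolerance = 1e-12)
})

# --- GTN ---------------------------------------------------------------------

test_that("sparse transformer layer matches the dense masked oracle", {
  set.seed(46)
  for (i in 1:30) {
    n <- sample(5:50, 1); din <- sample(2:6, 1)
    dk <- sample(2:5, 1); dv <- sample(2:5, 1)
    A <- random_adjacency(n)
    H <- matrix(rnorm(n * din), n)
    WQ <- matrix(rnorm(din * dk), din); WK <- matrix(rnorm(din * dk), din)
    WV <- matrix(rnorm(din * dv), din)
    got <- gtn_forward(H, A, WQ, WK, WV)
    expect_lt(max(abs(got - dense_gtn_oracle(A, H, WQ, WK, WV))), 1e-5)
  }
})

test_that("identical keys average the attended values", {
  set.seed(47)
  n <- 6
  A <- random_adjacency(n, 0.5)
  H <- matrix(rnorm(n * 3), n)
  WQ <- matrix(rnorm(6), 3, 2)
  WK <- matrix(0, 3, 2)          # all keys identical (zero)
  WV <- matrix(rnorm(6), 3, 2)
  got <- gtn_forward(H, A, WQ, WK, WV)
  V <- H %*% WV
  M <- A + diag(n)
  expected <- (M %*% V) / rowSums(M)
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("attention weights are invariant to compensating Q/K rescaling", {
  set.seed(48)
  n <- 7
  A <- random_adjacency(n, 0.5)
  H <- matrix(rnorm(n * 3), n)
  WQ <- matrix(rnorm(9), 3, 3); WK <- matrix(rnorm(9), 3, 3)
  WV <- matrix(rnorm(9), 3, 3)
  c <- 2.5
  # Q K^T unchanged when Q scales by c and K by 1/c
  expect_equal(gtn_forward(H, A, WQ * c, WK / c, WV),
               gtn_forward(H, A, WQ, WK, WV), tolerance = 1e-10)
})

test_that("global attention attends across components", {
  # two disconnected nodes: neighbourhood attention keeps them separate,
  # global attention mixes them
  H <- matrix(c(1, -1), 2, 1)
  A <- matrix(0, 2, 2)
  WQ <- matrix(1, 1, 1); WK <- matrix(0, 1, 1); WV <- matrix(1, 1, 1)
  local <- gtn_forward(H, A, WQ, WK, WV)
  expect_equal(local, H)                     # self-attention only
  glob <- gtn_forward(H, A, WQ, WK, WV, global = TRUE)
  expect_equal(glob, matrix(0, 2, 1))        # uniform over both nodes
})

# --- gradient correctness ----------------------------------------------------

test_that("tape gradients match central finite differences for every model", {
  set.seed(49)
  n <- 10; d <- 4; K <- 3
  A <- random_adjacency(n, 0.3)
  H <- matrix(rnorm(n * d), n)
  y <- sample(seq_len(K), n, replace = TRUE)
  graph <- list(adjacency = Matrix::Matrix(A, sparse = TRUE), X = H,
                labels = factor(paste0("c", y)))
  for (arch in c("gcn", "gat", "gtn")) {
    hid <- list(gcn = c(5, 5, 5), gat = c(6, 4, 4, 4), gtn = 5)[[arch]]
    hds <- if (arch == "gat") c(2, 2, 2, 1) else NULL
    spec <- model_spec(arch, in_dim = d, n_classes = K, hidden = hid,
                       heads = hds, dropout = 0)
    model <- build_model(spec, seed = 2)
    gin <- mognn:::node_graph_input(graph, spec)
    lossfn <- function(params) {
      m <- model; m$params <- params
      tp <- mognn:::tape_new()
      fw <- mognn:::forward_gnn(tp, m, H, gin, training = TRUE)
      mognn:::t_cross_entropy(tp, fw$logits, y, seq_len(n))$value
    }
    tp <- mognn:::tape_new()
    fw <- mognn:::forward_gnn(tp, model, H, gin, training = TRUE)
    ln <- mognn:::t_cross_entropy(tp, fw$logits, y, seq_len(n))
    mognn:::tape_backward(tp, ln)
    for (nm in names(model$params)) {
      g <- fw$params[[nm]]$grad
      if (is.null(g)) next
      for (i in seq_len(min(length(g), 6))) {
        e <- 1e-5
        p1 <- model$params; p1[[nm]][i] <- p1[[nm]][i] + e
        p2 <- model$params; p2[[nm]][i] <- p2[[nm]][i] - e
        num <- (lossfn(p1) - lossfn(p2)) / (2 * e)
        expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-5)
      }
    }
  }
})

test_that("forward passes are bit-stable with dropout disabled", {
  set.seed(50)
  g <- toy_sample_graph()
  spec <- model_spec("gat", in_dim = ncol(g$X), n_classes = 3,
                     hidden = c(8, 4, 4, 4), heads = c(2, 2, 2, 1),
                     dropout = 0)
  model <- build_model(spec, seed = 3)
  gin <- mognn:::node_graph_input(g, spec)
  H <- apply_scaler(g$X, fit_scaler(g$X))
  run <- function() {
    tp <- mognn:::tape_new()
    mognn:::forward_gnn(tp, model, H, gin, training = FALSE)$logits$value
  }
  expect_identical(run(), run())
})

test_that("node permutation permutes every architecture's output identically", {
  set.seed(51)
  n <- 12; d <- 5
  A <- random_adjacency(n, 0.3)
  H <- matrix(rnorm(n * d), n)
  perm <- sample(n)
  W <- matrix(rnorm(d * 4), d)
  # GCN layer
  o1 <- gcn_forward(H, normalize_adjacency(A), W)
  o2 <- gcn_forward(H[perm, ], normalize_adjacency(A[perm, perm]), W)
  expect_equal(o2, o1[perm, ], tolerance = 1e-12)
  # GAT layer
  a <- rnorm(8)
  g1 <- gat_forward(H, A, list(W), list(a))
  g2 <- gat_forward(H[perm, ], A[perm, perm], list(W), list(a))
  expect_equal(g2, g1[perm, ], tolerance = 1e-10)
  # GTN layer
  WQ <- matrix(rnorm(d * 3), d); WK <- matrix(rnorm(d * 3), d)
  WV <- matrix(rnorm(d * 3), d)
  t1 <- gtn_forward(H, A, WQ, WK, WV)
  t2 <- gtn_forward(H[perm, ], A[perm, perm], WQ, WK, WV)
  expect_equal(t2, t1[perm, ], tolerance = 1e-10)
})
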