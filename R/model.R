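#' Architecture specification for a graph neural network classifier
#'
#' Encodes the three architectures with their reference configurations:
#' \describe{
#'   \item{gcn}{three graph-convolution layers (default width 1024 each),
#'     ReLU, dropout after each layer, linear classifier head.}
#'   \item{gat}{four attention layers (default widths 1024/512/256/32 with
#'     8/4/2/1 heads; width = total channels, split across heads), each
#'     followed by batch normalization, LeakyReLU and dropout; heads are
#'     concatenated in hidden layers and averaged in the last attention
#'     layer; linear classifier head.}
#'   \item{gtn}{two neighbourhood-restricted transformer layers (default
#'     1024 then `n_classes` channels, the second emitting logits), ReLU
#'     and dropout between them; optional unrestricted attention via
#'     `global_attention`.}
#' }
#' Smaller `hidden`/`heads` can be supplied for reduced-scale experiments.
#'
#' @param architecture `"gcn"`, `"gat"` or `"gtn"`.
#' @param in_dim input feature dimension.
#' @param n_classes number of classes (output logits).
#' @param hidden integer vector of layer widths (defaults above).
#' @param heads integer vector of head counts (gat only).
#' @param dropout dropout rate (default 0.5).
#' @param task `"node"` (transductive node classification) or `"graph"`
#'   (per-sample graph classification with global mean-pool readout).
#' @param global_attention gtn only: attend over all node pairs instead of
#'   the neighbourhood.
#' @param negative_slope LeakyReLU slope (default 0.2).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(architecture = c("gcn", "gat", "gtn"),
                       in_dim, n_classes,
                       hidden = NULL, heads = NULL, dropout = 0.5,
                       task = c("node", "graph"),
                       global_attention = FALSE, negative_slope = 0.2) {
  architecture <- match.arg(architecture)
  task <- match.arg(task)
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (architecture == "gcn") {
    if (is.null(hidden)) hidden <- c(1024, 1024, 1024)
  } else if (architecture == "gat") {
    if (is.null(hidden)) hidden <- c(1024, 512, 256, 32)
    if (is.null(heads)) heads <- c(8, 4, 2, 1)
    if (length(heads) != length(hidden))
      stop("heads must match hidden in length")
    if (any(hidden %% heads != 0))
      stop("each layer width must be divisible by its head count")
  } else {
    if (is.null(hidden)) hidden <- 1024
    hidden <- c(hidden[1], n_classes)  # second transformer layer emits logits
  }
  if (any(hidden < 1) || (!is.null(heads) && any(heads < 1)))
    stop("widths and head counts must be positive")
  structure(list(architecture = architecture, in_dim = in_dim,
                 n_classes = n_classes, hidden = hidden, heads = heads,
                 dropout = dropout, task = task,
                 global_attention = global_attention,
                 negative_slope = negative_slope),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("%s model spec (%s mode): in %d -> [%s] -> %d classes%s\n",
              toupper(x$architecture), x$task, x$in_dim,
              paste(x$hidden, collapse = ", "), x$n_classes,
              if (!is.null(x$heads))
                paste0(", heads [", paste(x$heads, collapse = ", "), "]")
              else ""))
  invisible(x)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build a trainable graph neural network
#'
#' Instantiates the parameters of a [model_spec()] with seeded
#' Glorot-uniform initialization. The returned model is an S3 object whose
#' parameters are updated in place by [train_model()].
#'
#' @param spec a [model_spec()].
#' @param seed RNG seed for initialization.
#' @return object of class `gnn_model`: `spec`, `params` (named list of
#'   matrices), `bn_state` (batch-norm running statistics, gat only).
#' @export
build_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  p <- list()
  arch <- spec$architecture
  dims <- c(spec$in_dim, spec$hidden)
  bn_state <- list()
  if (arch == "gcn") {
    for (l in seq_along(spec$hidden)) {
      p[[paste0("W", l)]] <- glorot(dims[l], dims[l + 1])
      p[[paste0("b", l)]] <- matrix(0, 1, dims[l + 1])
    }
    p$W_head <- glorot(dims[length(dims)], spec$n_classes)
    p$b_head <- matrix(0, 1, spec$n_classes)
  } else if (arch == "gat") {
    for (l in seq_along(spec$hidden)) {
      dh <- spec$hidden[l] / spec$heads[l]
      for (k in seq_len(spec$heads[l])) {
        p[[sprintf("W%d_h%d", l, k)]] <- glorot(dims[l], dh)
        p[[sprintf("a%d_h%d", l, k)]] <- glorot(2 * dh, 1)
      }
      # last attention layer averages heads, so its width is dh not hidden
      out_w <- if (l == length(spec$hidden)) dh else spec$hidden[l]
      p[[paste0("bn_gamma", l)]] <- matrix(1, 1, out_w)
      p[[paste0("bn_beta", l)]] <- matrix(0, 1, out_w)
      bn_state[[paste0("bn", l)]] <- new.env(parent = emptyenv())
      dims[l + 1] <- out_w
    }
    p$W_head <- glorot(dims[length(dims)], spec$n_classes)
    p$b_head <- matrix(0, 1, spec$n_classes)
  } else {
    for (l in seq_along(spec$hidden)) {
      p[[paste0("WQ", l)]] <- glorot(dims[l], dims[l + 1])
      p[[paste0("WK", l)]] <- glorot(dims[l], dims[l + 1])
      p[[paste0("WV", l)]] <- glorot(dims[l], dims[l + 1])
    }
  }
  structure(list(spec = spec, params = p, bn_state = bn_state,
                 seed = seed, trained = FALSE),
            class = "gnn_model")
}

#' @export
print.gnn_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  print(x$spec)
  cat(sprintf("  %d parameter tensors, %d parameters%s\n",
              length(x$params), n_par,
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

# forward pass on the tape; returns list(logits = node, params = node map)
forward_gnn <- function(tape, model, H, graph_input, training) {
  spec <- model$spec
  pn <- lapply(model$params, function(m) t_const(tape, m))
  h <- t_const(tape, H)
  if (spec$architecture == "gcn") {
    Ahat <- graph_input$Ahat
    for (l in seq_along(spec$hidden)) {
      h <- gcn_layer_t(tape, h, Ahat, pn[[paste0("W", l)]],
                       pn[[paste0("b", l)]], activation = "relu")
      h <- t_dropout(tape, h, spec$dropout, training)
    }
  } else if (spec$architecture == "gat") {
    ed <- graph_input$edges
    for (l in seq_along(spec$hidden)) {
      heads <- lapply(seq_len(spec$heads[l]), function(k)
        gat_head_t(tape, h, ed, pn[[sprintf("W%d_h%d", l, k)]],
                   pn[[sprintf("a%d_h%d", l, k)]],
                   spec$negative_slope)$out)
      h <- if (l == length(spec$hidden)) {
        # average heads at the last attention layer
        acc <- heads[[1]]
        if (length(heads) > 1)
          for (k in 2:length(heads)) acc <- t_add(tape, acc, heads[[k]])
        t_scale(tape, acc, 1 / length(heads))
      } else t_cbind(tape, heads)
      h <- t_batchnorm(tape, h, pn[[paste0("bn_gamma", l)]],
                       pn[[paste0("bn_beta", l)]],
                       model$bn_state[[paste0("bn", l)]], training)
      h <- t_leaky_relu(tape, h, spec$negative_slope)
      h <- t_dropout(tape, h, spec$dropout, training)
    }
  } else {
    ed <- graph_input$edges
    for (l in seq_along(spec$hidden)) {
      h <- gtn_layer_t(tape, h, ed, pn[[paste0("WQ", l)]],
                       pn[[paste0("WK", l)]], pn[[paste0("WV", l)]])$out
      if (l < length(spec$hidden)) {
        h <- t_relu(tape, h)
        h <- t_dropout(tape, h, spec$dropout, training)
      }
    }
  }
  if (spec$task == "graph")
    h <- t_mean_pool(tape, h, graph_input$batch, graph_input$n_graphs)
  logits <- if (is.null(pn$W_head)) h else
    t_add_bias(tape, t_matmul(tape, h, pn$W_head), pn$b_head)
  list(logits = logits, params = pn)
}

# prepare the architecture-specific graph input from a sample_graph
node_graph_input <- function(graph, spec) {
  if (spec$architecture == "gcn") {
    list(Ahat = normalize_adjacency(graph$adjacency))
  } else if (spec$global_attention && spec$architecture == "gtn") {
    list(edges = complete_edges(nrow(graph$adjacency)))
  } else {
    list(edges = adjacency_to_edges(graph$adjacency))
  }
}

# stack per-sample feature graphs block-diagonally for batched forward
batch_graph_input <- function(fg, sample_idx, spec) {
  nn <- length(fg$nodes)
  B <- length(sample_idx)
  H <- do.call(rbind, lapply(sample_idx, function(s)
    matrix(fg$tensors[, , s], nrow = nn)))
  src0 <- c(fg$edge_index[, 1], fg$edge_index[, 2])
  dst0 <- c(fg$edge_index[, 2], fg$edge_index[, 1])
  src <- unlist(lapply(seq_len(B) - 1L, function(b) src0 + b * nn))
  dst <- unlist(lapply(seq_len(B) - 1L, function(b) dst0 + b * nn))
  batch <- rep(seq_len(B), each = nn)
  if (spec$architecture == "gcn") {
    A1 <- Matrix::sparseMatrix(i = c(fg$edge_index[, 1], fg$edge_index[, 2]),
                               j = c(fg$edge_index[, 2], fg$edge_index[, 1]),
                               x = 1, dims = c(nn, nn))
    A1 <- (A1 != 0) * 1
    Ahat1 <- normalize_adjacency(A1)
    Ahat <- Matrix::bdiag(rep(list(Ahat1), B))
    list(Ahat = Ahat, batch = batch, n_graphs = B, H = H)
  } else {
    src <- c(src, seq_len(B * nn))
    dst <- c(dst, seq_len(B * nn))
    ord <- order(dst, src)
    list(edges = list(src = src[ord], dst = dst[ord], n = B * nn),
         batch = batch, n_graphs = B, H = H)
  }
}

#' Save / load a model checkpoint
#'
#' Serializes the architecture spec and all weight matrices to a single
#' JSON file (plain text, exactly reproducible); `spec_to_yaml()` renders
#' the spec alone as YAML.
#'
#' @param model a `gnn_model`.
#' @param path file to write / read.
#' @return `load_model()` returns the restored `gnn_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gnn_model"))
  payload <- list(
    spec = unclass(model$spec),
    trained = model$trained,
    params = lapply(model$params, function(m)
      list(dim = dim(m), values = as.vector(m))),
    bn = lapply(model$bn_state, function(e)
      list(running_mean = e$running_mean, running_var = e$running_var)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- pl$spec
  if (is.null(spec$heads)) spec["heads"] <- list(NULL)
  if (is.null(spec$hidden)) stop("corrupt checkpoint: no hidden widths")
  class(spec) <- "model_spec"
  params <- lapply(pl$params, function(p)
    matrix(p$values, nrow = p$dim[1], ncol = p$dim[2]))
  bn_state <- list()
  for (nm in names(pl$bn)) {
    e <- new.env(parent = emptyenv())
    e$running_mean <- pl$bn[[nm]]$running_mean
    e$running_var <- pl$bn[[nm]]$running_var
    bn_state[[nm]] <- e
  }
  structure(list(spec = spec, params = params, bn_state = bn_state,
                 seed = NA_integer_, trained = isTRUE(pl$trained)),
            class = "gnn_model")
}

#' @rdname save_model
#' @param spec a `model_spec`.
#' @export
spec_to_yaml <- function(spec) yaml::as.yaml(unclass(spec))
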