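#' Training configuration
#'
#' The reference optimization protocol: Adam with initial learning rate
#' 0.001, 100 epochs, and a reduce-on-plateau schedule that halves the
#' learning rate when validation accuracy stops improving.
#'
#' @param learning_rate initial Adam learning rate (> 0, default 0.001).
#' @param epochs training epochs (>= 1, default 100).
#' @param factor learning-rate reduction factor on plateau (default 0.5).
#' @param patience epochs without validation-accuracy improvement before
#'   reducing the rate (default 10).
#' @param min_lr lower bound for the learning rate.
#' @param seed RNG seed controlling initialization order and dropout.
#' @param verbose print per-epoch progress.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 100, factor = 0.5,
                         patience = 10, min_lr = 1e-6, seed = 1,
                         verbose = FALSE) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 factor = factor, patience = as.integer(patience),
                 min_lr = min_lr, seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

#' Stratified cross-validation fold masks
#'
#' Splits samples into k stratified test folds; within each fold, the
#' remaining samples are split 80/20 (stratified) into training and
#' validation sets. Masks are disjoint and their union covers all samples.
#'
#' @param labels factor of class labels.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return object of class `fold_masks`: list of k folds, each with logical
#'   `train`, `val`, `test` masks.
#' @export
make_folds <- function(labels, k = 5, seed = 1) {
  labels <- as.factor(labels)
  tab <- table(labels)
  small <- names(tab)[tab < k]
  if (length(small))
    stop("class(es) smaller than k = ", k, ": ", paste(small, collapse = ", "))
  set.seed(seed)
  n <- length(labels)
  fold_of <- integer(n)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds <- lapply(seq_len(k), function(f) {
    test <- fold_of == f
    rest <- which(!test)
    val <- logical(n)
    for (cl in levels(labels)) {
      ridx <- sample(rest[labels[rest] == cl])
      n_val <- max(1L, round(0.2 * length(ridx)))
      val[ridx[seq_len(n_val)]] <- TRUE
    }
    list(train = !test & !val, val = val, test = test)
  })
  structure(folds, class = "fold_masks", seed = seed, k = k)
}

# Adam update; state is an environment with m, v, t
adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}

#' Train a graph neural network classifier
#'
#' Minimises cross-entropy on the training mask with Adam, monitoring
#' validation accuracy for the reduce-on-plateau learning-rate schedule.
#' In `"node"` mode the graph is a [build_sample_graph()] result and
#' training is transductive (one fixed graph, masked loss); in `"graph"`
#' mode the graph is a [build_feature_graph()] result and per-sample graphs
#' (shared topology) are batched block-diagonally. Node features are
#' standardized with a scaler fitted on the training mask only.
#'
#' @param model a [build_model()] result (left unmodified; a trained copy
#'   is returned).
#' @param graph a `sample_graph` or `feature_graph`.
#' @param masks one fold of [make_folds()]: list with `train`, `val`,
#'   `test` logical masks.
#' @param config a [train_config()].
#' @return object of class `mognn_fit`: the trained `model`, `history`
#'   (per-epoch data.frame: loss, val_accuracy, lr), `masks`, `config`,
#'   `classes`, and the fitted `scaler`.
#' @export
train_model <- function(model, graph, masks, config = train_config()) {
  stopifnot(inherits(model, "gnn_model"))
  spec <- model$spec
  set.seed(config$seed)
  node_mode <- spec$task == "node"
  labels <- graph$labels
  y <- as.integer(labels)
  classes <- levels(labels)
  if (spec$n_classes != length(classes))
    stop("spec$n_classes (", spec$n_classes, ") != observed classes (",
         length(classes), ")")

  if (node_mode) {
    scaler <- fit_scaler(graph$X, which(masks$train))
    H <- apply_scaler(graph$X, scaler)
    gin <- node_graph_input(graph, spec)
    if (ncol(H) != spec$in_dim) stop("spec$in_dim != graph feature width")
  } else {
    nn <- length(graph$nodes)
    flat <- t(apply(graph$tensors, 3, function(m) as.vector(m)))
    scaler <- fit_scaler(flat, which(masks$train))
    flat_z <- apply_scaler(flat, scaler)
    fg <- graph
    for (s in seq_len(dim(fg$tensors)[3]))
      fg$tensors[, , s] <- matrix(flat_z[s, ], nrow = nn)
    gin_all <- batch_graph_input(fg, seq_along(y), spec)
    if (dim(fg$tensors)[2] != spec$in_dim)
      stop("spec$in_dim != number of channels")
  }
  train_idx <- which(masks$train)
  val_idx <- which(masks$val)

  # deep-copy params so the input model is untouched
  params <- model$params
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(m) m * 0)
  st$v <- st$m
  fit_model <- model
  lr <- config$learning_rate
  best_val <- -Inf; wait <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_accuracy = numeric(0), lr = numeric(0))

  forward_once <- function(params, training) {
    fit_model$params <- params
    tp <- tape_new()
    if (node_mode) {
      fw <- forward_gnn(tp, fit_model, H, gin, training)
      rows <- if (training) train_idx else seq_along(y)
    } else {
      fw <- forward_gnn(tp, fit_model, gin_all$H, gin_all, training)
      rows <- if (training) train_idx else seq_along(y)
    }
    list(tp = tp, fw = fw, rows = rows)
  }

  for (epoch in seq_len(config$epochs)) {
    fo <- forward_once(params, training = TRUE)
    loss_nd <- t_cross_entropy(fo$tp, fo$fw$logits, y, train_idx)
    loss <- loss_nd$value
    if (!is.finite(loss))
      stop("NaN/Inf training loss at epoch ", epoch,
           "; learning rate ", lr, ", architecture ", spec$architecture)
    if (lr > 0) {
      tape_backward(fo$tp, loss_nd)
      grads <- lapply(fo$fw$params, function(nd) nd$grad)
      params <- adam_step(params, grads, st, lr)
    }
    # validation accuracy with dropout off and current batch-norm stats
    fe <- forward_once(params, training = FALSE)
    pred <- max.col(fe$fw$logits$value, ties.method = "first")
    val_acc <- if (length(val_idx)) mean(pred[val_idx] == y[val_idx]) else NA
    hist <- rbind(hist, data.frame(epoch = epoch, loss = loss,
                                   val_accuracy = val_acc, lr = lr))
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  val acc %.3f  lr %.2g",
                      epoch, loss, val_acc, lr))
    if (!is.na(val_acc)) {
      if (val_acc > best_val + 1e-12) { best_val <- val_acc; wait <- 0L }
      else {
        wait <- wait + 1L
        if (wait >= config$patience) {
          lr <- max(lr * config$factor, config$min_lr)
          wait <- 0L
        }
      }
    }
  }
  fit_model$params <- params
  fit_model$trained <- TRUE
  structure(list(model = fit_model, history = hist, masks = masks,
                 config = config, classes = classes, scaler = scaler,
                 graph = graph),
            class = "mognn_fit")
}

#' @export
print.mognn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("Trained %s (%s mode): %d epochs, final loss %.4f, val accuracy %.3f\n",
              toupper(x$model$spec$architecture), x$model$spec$task,
              nrow(h), h$loss[nrow(h)], h$val_accuracy[nrow(h)]))
  invisible(x)
}

#' @export
summary.mognn_fit <- function(object, ...) {
  print(object)
  ev <- evaluate(object, object$masks$test)
  cat("Test-mask metrics:\n")
  print(round(unlist(ev$metrics), 4))
  invisible(ev)
}

#' @export
plot.mognn_fit <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  graphics::plot(h$epoch, h$val_accuracy, type = "l", xlab = "epoch",
                 ylab = "validation accuracy", ...)
  invisible(x)
}

#' Predict classes or probabilities from a trained model
#'
#' @param object a `mognn_fit`.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return factor of predicted classes, or a samples x classes probability
#'   matrix.
#' @export
predict.mognn_fit <- function(object, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  spec <- object$model$spec
  graph <- object$graph
  tp <- tape_new()
  if (spec$task == "node") {
    H <- apply_scaler(graph$X, object$scaler)
    gin <- node_graph_input(graph, spec)
    fw <- forward_gnn(tp, object$model, H, gin, training = FALSE)
  } else {
    nn <- length(graph$nodes)
    flat <- t(apply(graph$tensors, 3, function(m) as.vector(m)))
    flat_z <- apply_scaler(flat, object$scaler)
    fg <- graph
    for (s in seq_len(dim(fg$tensors)[3]))
      fg$tensors[, , s] <- matrix(flat_z[s, ], nrow = nn)
    gin <- batch_graph_input(fg, seq_len(dim(fg$tensors)[3]), spec)
    fw <- forward_gnn(tp, object$model, gin$H, gin, training = FALSE)
  }
  prob <- softmax_rows(fw$logits$value)
  colnames(prob) <- object$classes
  if (type == "prob") return(prob)
  factor(object$classes[max.col(prob, ties.method = "first")],
         levels = object$classes)
}
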