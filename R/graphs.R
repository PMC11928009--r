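#' Build a sample-correlation graph
#'
#' Nodes are samples; an undirected edge joins samples i and j (i != j)
#' when the Pearson correlation of their feature profiles meets the
#' threshold. The rule is signed by default (`r >= threshold`, as the
#' thresholded-correlation construction is usually stated); set
#' `absolute = TRUE` for `|r| >= threshold`. Profiles are z-scored per
#' feature before correlating by default (correlation across features is
#' otherwise dominated by between-feature scale differences). Self-loops
#' are not stored; they are injected at normalization time
#' ([normalize_adjacency()]).
#'
#' @param data an `integrated_dataset` (or any list with `X` and `labels`).
#' @param threshold correlation cutoff in [-1, 1]; default 0.9.
#' @param absolute threshold on |r| instead of signed r.
#' @param standardize z-score features before correlating (default TRUE).
#' @return object of class `sample_graph`: `adjacency` (sparse symmetric
#'   0/1 Matrix, zero diagonal), `node_ids`, `X` (node features, the
#'   unstandardized integrated matrix), `labels`, and a `density`
#'   attribute with edge-count diagnostics.
#' @export
build_sample_graph <- function(data, threshold = 0.9, absolute = FALSE,
                               standardize = TRUE) {
  if (threshold < -1 || threshold > 1) stop("threshold must lie in [-1, 1]")
  X <- data$X
  if (nrow(X) < 2) stop("need at least 2 samples")
  Z <- if (standardize) apply_scaler(X, fit_scaler(X)) else X
  keep <- apply(Z, 1, stats::sd) > 0
  if (!all(keep))
    stop("zero-variance sample profile(s): ",
         paste(rownames(X)[!keep], collapse = ", "))
  R <- stats::cor(t(Z))
  A <- if (absolute) abs(R) >= threshold else R >= threshold
  diag(A) <- FALSE
  A <- Matrix::Matrix(A * 1, sparse = TRUE)
  dimnames(A) <- list(rownames(X), rownames(X))
  deg <- Matrix::rowSums(A)
  if (any(deg == 0))
    warning(sum(deg == 0), " isolated node(s) in the sample graph ",
            "(no correlation >= ", threshold, ")")
  g <- structure(list(adjacency = A, node_ids = rownames(X), X = X,
                      labels = data$labels, threshold = threshold,
                      absolute = absolute),
                 class = "sample_graph")
  attr(g, "density") <- c(nodes = nrow(A), edges = sum(A) / 2,
                          density = sum(A) / (nrow(A) * (nrow(A) - 1)),
                          isolated = sum(deg == 0))
  g
}

#' @export
print.sample_graph <- function(x, ...) {
  d <- attr(x, "density")
  cat(sprintf(
    "Sample-correlation graph: %d nodes, %d edges (density %.3f, %d isolated), threshold %s%.2f\n",
    d["nodes"], d["edges"], d["density"], d["isolated"],
    if (x$absolute) "|r| >= " else "r >= ", x$threshold))
  invisible(x)
}

#' Build a protein-interaction feature graph
#'
#' Nodes are gene/protein identifiers carrying at least one selected
#' feature through `gene_map`; edges are interaction pairs with score at
#' or above `score_threshold` whose endpoints are both nodes. Every sample
#' is represented on the shared topology by a node x channel matrix: one
#' channel per omics layer, holding the arithmetic mean of the sample's
#' mapped features of that layer at that gene (zero where the gene has no
#' mapped feature of the layer, with a channel mask recording coverage).
#'
#' @param edges data.frame with columns `node1`, `node2`, `score` (an
#'   interaction edge list, e.g. STRING-flavoured).
#' @param gene_map data.frame with columns `feature`, `gene`.
#' @param data an `integrated_dataset` (columns named `<layer>.<feature>`).
#' @param score_threshold minimum interaction score to keep an edge.
#' @return object of class `feature_graph`: `nodes`, `edge_index`
#'   (2-column matrix of node indices, undirected, deduplicated),
#'   `edge_score`, `tensors` (array node x channel x sample), `channel_mask`
#'   (node x channel), `labels` (per sample), `dropped_edges` (count of
#'   edges referencing unmapped genes).
#' @export
build_feature_graph <- function(edges, gene_map, data, score_threshold = 0) {
  stopifnot(all(c("node1", "node2", "score") %in% names(edges)),
            all(c("feature", "gene") %in% names(gene_map)))
  feats <- colnames(data$X)
  layer_of <- data$feature_origin
  bare <- sub("^[^.]+\\.", "", feats)
  gene_of <- gene_map$gene[match(bare, gene_map$feature)]
  mapped <- !is.na(gene_of)
  if (!any(mapped)) stop("gene_map covers none of the selected features")
  nodes <- sort(unique(gene_of[mapped]))
  layers <- unique(layer_of)

  e <- edges[edges$score >= score_threshold, , drop = FALSE]
  known <- e$node1 %in% nodes & e$node2 %in% nodes & e$node1 != e$node2
  dropped <- sum(!known)
  e <- e[known, , drop = FALSE]
  if (nrow(e) > 0) {
    key <- paste(pmin(e$node1, e$node2), pmax(e$node1, e$node2))
    e <- e[!duplicated(key), , drop = FALSE]
  }
  if (nrow(e) == 0)
    stop("empty feature graph: no interaction edge survives the score ",
         "threshold among mapped genes")
  edge_index <- cbind(match(e$node1, nodes), match(e$node2, nodes))

  n <- nrow(data$X)
  tensors <- array(0, dim = c(length(nodes), length(layers), n),
                   dimnames = list(nodes, layers, rownames(data$X)))
  channel_mask <- matrix(FALSE, length(nodes), length(layers),
                         dimnames = list(nodes, layers))
  for (ch in seq_along(layers)) {
    in_layer <- which(layer_of == layers[ch] & mapped)
    if (!length(in_layer)) next
    grp <- gene_of[in_layer]
    agg <- rowsum(t(data$X[, in_layer, drop = FALSE]), group = grp)
    cnt <- as.vector(table(grp)[rownames(agg)])
    agg <- agg / cnt
    idx <- match(rownames(agg), nodes)
    tensors[idx, ch, ] <- agg
    channel_mask[idx, ch] <- TRUE
  }
  structure(list(nodes = nodes, edge_index = edge_index,
                 edge_score = e$score, tensors = tensors,
                 channel_mask = channel_mask, labels = data$labels,
                 dropped_edges = dropped),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  cat(sprintf(
    "Feature graph: %d nodes, %d edges, %d channels, %d samples (%d unmapped edges dropped)\n",
    length(x$nodes), nrow(x$edge_index), dim(x$tensors)[2], dim(x$tensors)[3],
    x$dropped_edges))
  invisible(x)
}
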