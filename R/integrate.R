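#' Pearson product-moment correlation
#'
#' The textbook coefficient `cov(a, b) / (sd(a) sd(b))`. Unlike
#' [stats::cor()], zero-variance input is an error rather than NA, since a
#' correlation-thresholded graph must not silently treat undefined
#' correlations as absent signal.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return scalar in [-1, 1].
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("Pearson correlation undefined for zero-variance input")
  as.numeric(stats::cor(a, b))
}

#' Inner-join multi-omics integration
#'
#' Retains only samples present in every requested omics layer (and in the
#' label table), concatenating features column-wise in layer order with a
#' per-feature layer tag. Classes left without any retained sample drop out
#' of the label factor. Feature standardization is deliberately NOT applied
#' here: per-fold scalers are fitted on training samples only at training
#' time (see [fit_scaler()]).
#'
#' @param layers named list of samples x features matrices with sample-ID
#'   rownames.
#' @param labels named factor/character of class labels keyed by sample ID.
#' @return object of class `integrated_dataset`: `X` (samples x features),
#'   `feature_origin` (layer tag per column), `labels` (factor aligned to
#'   rows of X).
#' @export
integrate_omics <- function(layers, labels) {
  if (length(layers) < 1) stop("need at least one omics layer")
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("layers must be a named list")
  ids <- Reduce(intersect, lapply(layers, rownames))
  ids <- intersect(ids, names(labels))
  if (length(ids) == 0)
    stop("no sample is present in all requested layers (",
         paste(names(layers), collapse = ", "), ") and the label table")
  X <- do.call(cbind, lapply(layers, function(m) m[ids, , drop = FALSE]))
  origin <- rep(names(layers), vapply(layers, ncol, 1L))
  colnames(X) <- unlist(lapply(names(layers), function(nm)
    paste0(nm, ".", colnames(layers[[nm]]))))
  lab <- droplevels(as.factor(labels[ids]))
  names(lab) <- ids
  structure(list(X = X, feature_origin = origin, labels = lab),
            class = "integrated_dataset")
}

#' @export
print.integrated_dataset <- function(x, ...) {
  cat(sprintf("Integrated dataset: %d samples x %d features (%s), %d classes\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s:%d", names(table(x$feature_origin)),
                            table(x$feature_origin)), collapse = ", "),
              nlevels(x$labels)))
  invisible(x)
}

#' Fit / apply a per-feature z-score scaler
#'
#' `fit_scaler()` computes column means and standard deviations from the
#' given rows only (the training samples); `apply_scaler()` standardizes
#' any matrix with those fixed statistics, so test rows never influence
#' the scaling. Constant columns are centred and left at zero.
#'
#' @param X samples x features matrix.
#' @param rows indices (or logical mask) of the rows the scaler may see.
#' @return `fit_scaler`: list with `mean` and `sd`. `apply_scaler`: matrix.
#' @export
fit_scaler <- function(X, rows = seq_len(nrow(X))) {
  Xt <- X[rows, , drop = FALSE]
  mu <- colMeans(Xt)
  sdv <- apply(Xt, 2, stats::sd)
  list(mean = mu, sd = sdv)
}

#' @rdname fit_scaler
#' @param scaler a scaler from [fit_scaler()].
#' @export
apply_scaler <- function(X, scaler) {
  Z <- sweep(X, 2, scaler$mean)
  ok <- scaler$sd > 0 & is.finite(scaler$sd)
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, scaler$sd[ok], `/`)
  Z[, !ok] <- 0
  Z
}
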