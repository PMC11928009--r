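#' L1-penalised least squares objective
#'
#' `(1/(2n)) * sum((y - X b)^2) + lambda * sum(|b|)`.
#'
#' @param X design matrix (n x p).
#' @param y response vector (length n).
#' @param beta coefficient vector (length p).
#' @param lambda penalty, >= 0.
#' @return scalar objective value.
#' @export
lasso_objective <- function(X, y, beta, lambda) {
  r <- y - drop(X %*% beta)
  sum(r^2) / (2 * length(y)) + lambda * sum(abs(beta))
}

#' Smallest penalty with an all-zero solution
#'
#' `lambda_max = max_j |x_j . y| / n`; at or above it, the lasso solution
#' is exactly zero (KKT condition at beta = 0).
#'
#' @inheritParams lasso_objective
#' @return scalar lambda_max.
#' @export
lasso_lambda_max <- function(X, y) {
  max(abs(crossprod(X, y))) / length(y)
}

#' Lasso by cyclic coordinate descent
#'
#' Minimises `(1/(2n))||y - X b||^2 + lambda ||b||_1` by cyclic coordinate
#' descent with soft-thresholding. Columns of `X` are expected standardized
#' (zero mean, unit variance) and `y` centered; the objective is
#' non-increasing across sweeps and iteration stops when the largest
#' coefficient change in a sweep falls below `tol`.
#'
#' @inheritParams lasso_objective
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_iter maximum number of full sweeps.
#' @param beta0 optional warm start.
#' @return list of class `lasso_fit`: `beta` (named if X has colnames),
#'   `lambda`, `objective` (value per sweep), `iterations`, `converged`.
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-8, max_iter = 10000, beta0 = NULL) {
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite entries in X or y")
  if (lambda < 0) stop("lambda must be >= 0")
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  beta <- if (is.null(beta0)) numeric(p) else beta0
  cj <- colSums(X^2) / n                      # = 1 for standardized columns
  r <- y - drop(X %*% beta)
  obj <- lasso_objective(X, y, beta, lambda)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    delta_max <- 0
    for (j in seq_len(p)) {
      if (cj[j] == 0) next                    # constant column stays at 0
      bj <- beta[j]
      rho <- sum(X[, j] * r) / n + cj[j] * bj
      bnew <- soft(rho, lambda) / cj[j]
      if (bnew != bj) {
        r <- r - X[, j] * (bnew - bj)
        beta[j] <- bnew
        delta_max <- max(delta_max, abs(bnew - bj))
      }
    }
    obj <- c(obj, lasso_objective(X, y, beta, lambda))
    if (delta_max < tol) { converged <- TRUE; break }
  }
  names(beta) <- colnames(X)
  structure(list(beta = beta, lambda = lambda, objective = obj,
                 iterations = it, converged = converged),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("Lasso fit: lambda = %.4g, %d/%d nonzero, %d sweeps%s\n",
              x$lambda, sum(x$beta != 0), length(x$beta), x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# standardize columns to zero mean / unit (population) variance; constant
# columns are zeroed and flagged
standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  keep <- sdv > 0
  Z <- sweep(X, 2, mu)
  Z[, keep] <- sweep(Z[, keep, drop = FALSE], 2, sdv[keep], `/`)
  Z[, !keep] <- 0
  list(Z = Z, mean = mu, sd = sdv, nonconstant = keep)
}

#' Multiclass lasso feature selection (one-vs-rest)
#'
#' For each class, fits a 0/1 one-vs-rest linear lasso on standardized
#' features at a penalty chosen by internal k-fold cross-validation
#' (minimum mean squared error) over a log-spaced grid, then returns the
#' union over classes of features with nonzero coefficients. Constant
#' (zero-variance) columns can never be selected.
#'
#' @param X samples x features numeric matrix (typically the pre-filtered
#'   features from [nb_wald_dge()] / [moderated_t_dm()]).
#' @param labels factor of class labels (>= 2 classes).
#' @param lambda_grid optional penalty grid; default is 30 values from
#'   lambda_max down to lambda_max * 1e-3 per class.
#' @param nfolds folds for internal cross-validation (default 5).
#' @param seed RNG seed for the fold split.
#' @return list of class `lasso_selection`: `selected` (character vector of
#'   feature ids), `per_class` (list with chosen lambda and support per
#'   class), `n_input`.
#' @export
lasso_select <- function(X, labels, lambda_grid = NULL, nfolds = 5, seed = 1) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("labels must contain at least 2 classes")
  X <- as.matrix(X)
  std <- standardize_columns(X)
  Z <- std$Z
  n <- nrow(Z)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(nfolds), length.out = n))
  per_class <- list()
  selected <- character(0)
  for (cl in levels(labels)) {
    y <- as.numeric(labels == cl)
    y <- y - mean(y)
    grid <- lambda_grid
    if (is.null(grid)) {
      lmax <- lasso_lambda_max(Z, y)
      grid <- lmax * 10^seq(0, -3, length.out = 30)
    }
    grid <- sort(grid, decreasing = TRUE)
    cv_mse <- numeric(length(grid))
    for (f in seq_len(nfolds)) {
      tr <- fold_id != f
      ztr <- Z[tr, , drop = FALSE]; ytr <- y[tr]
      zte <- Z[!tr, , drop = FALSE]; yte <- y[!tr]
      b <- numeric(ncol(Z))
      for (g in seq_along(grid)) {        # warm starts down the path
        fit <- lasso_fit(ztr, ytr, grid[g], tol = 1e-6, beta0 = b)
        b <- fit$beta
        cv_mse[g] <- cv_mse[g] + mean((yte - drop(zte %*% b))^2) / nfolds
      }
    }
    lam <- grid[which.min(cv_mse)]
    full <- lasso_fit(Z, y, lam, tol = 1e-7)
    support <- colnames(X)[full$beta != 0 & std$nonconstant]
    per_class[[cl]] <- list(lambda = lam, support = support, cv_mse = cv_mse,
                            grid = grid)
    selected <- union(selected, support)
  }
  structure(list(selected = selected, per_class = per_class,
                 n_input = ncol(X)),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf("Lasso selection: %d of %d features (union over %d classes)\n",
              length(x$selected), x$n_input, length(x$per_class)))
  invisible(x)
}

#' Per-stage feature-count report for the selection pipeline
#'
#' Runs the full selection cascade on a dataset: NB-Wald screening of mRNA
#' counts (class 1 of `labels` versus the rest), moderated-t screening of
#' methylation, lasso refinement of each screened layer, and pass-through
#' of miRNA (no screening stage is defined for it). Returns the per-stage
#' feature counts and the selected ids.
#'
#' @param ds a `synthetic_dataset` (or list with the same fields).
#' @param dge_alpha,dm_alpha screening thresholds (defaults 0.001 / 0.05).
#' @param seed seed for the lasso internal cross-validation.
#' @param meth_scale `"beta"` (as generated) or `"mvalue"` (logit).
#' @return list of class `selection_report`: `counts` (data.frame with
#'   original / screened / lasso counts per layer), `selected` (named list
#'   of feature ids per layer).
#' @export
select_features <- function(ds, dge_alpha = 0.001, dm_alpha = 0.05,
                            seed = 1, meth_scale = c("beta", "mvalue")) {
  meth_scale <- match.arg(meth_scale)
  binary <- function(labels) factor(ifelse(labels == levels(labels)[1],
                                           "ref", "alt"), c("ref", "alt"))
  out_counts <- list(); selected <- list()

  lab_m <- ds$labels[rownames(ds$omics$mrna)]
  dge <- nb_wald_dge(ds$omics$mrna, binary(lab_m), alpha = dge_alpha,
                     dispersion_groups = droplevels(lab_m))
  screened <- dge$feature[dge$selected]
  las_m <- if (length(screened) >= 2) {
    lasso_select(ds$omics$mrna[, screened, drop = FALSE],
                 droplevels(lab_m), seed = seed)$selected
  } else screened
  out_counts$mrna <- c(original = ncol(ds$omics$mrna),
                       screened = length(screened), lasso = length(las_m))
  selected$mrna <- las_m

  meth <- ds$omics$meth
  if (meth_scale == "mvalue") meth <- beta_to_mvalues(meth)
  lab_me <- ds$labels[rownames(meth)]
  dm <- moderated_t_dm(meth, binary(lab_me), alpha = dm_alpha)
  screened_me <- dm$feature[dm$selected]
  las_me <- if (length(screened_me) >= 2) {
    lasso_select(meth[, screened_me, drop = FALSE],
                 droplevels(lab_me), seed = seed)$selected
  } else screened_me
  out_counts$meth <- c(original = ncol(meth),
                       screened = length(screened_me), lasso = length(las_me))
  selected$meth <- las_me

  # miRNA passes through unscreened
  out_counts$mirna <- c(original = ncol(ds$omics$mirna),
                        screened = NA, lasso = NA)
  selected$mirna <- colnames(ds$omics$mirna)

  ord <- c("mrna", "mirna", "meth")   # follow the dataset's layer order
  counts <- do.call(rbind, out_counts[ord])
  structure(list(counts = as.data.frame(counts), selected = selected[ord],
                 dge = dge, dm = dm),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Feature-selection pipeline (per-stage feature counts):\n")
  print(x$counts)
  invisible(x)
}

#' Write a selection report to a TSV file
#'
#' One row per omics layer with original / screened / lasso-selected
#' feature counts; selected feature ids are written alongside as
#' one-id-per-line text files.
#'
#' @param report a `selection_report`.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_selection_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- file.path(dir, "selection_report.tsv")
  utils::write.table(cbind(layer = rownames(report$counts), report$counts),
                     f, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- f
  for (nm in names(report$selected)) {
    f <- file.path(dir, paste0("selected_", nm, ".txt"))
    writeLines(report$selected[[nm]], f)
    files <- c(files, f)
  }
  invisible(files)
}
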