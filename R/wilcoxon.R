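#' Wilcoxon signed-rank test with exact small-sample null distribution
#'
#' Two-sided paired signed-rank test. Zero differences are handled by the
#' Pratt method (they enter the ranking, then drop out of the statistic);
#' ties receive mid-ranks. For `n <= exact_limit` nonzero differences the
#' null distribution of W+ is computed exactly by convolution over the
#' (possibly tied, Pratt-inflated) rank multiset, which reproduces full
#' sign-flip enumeration; larger samples use the normal approximation with
#' tie and zero corrections and a 0.5 continuity correction.
#'
#' @param x,y equal-length paired observation vectors.
#' @param exact_limit maximum number of nonzero differences for the exact
#'   distribution (default 25).
#' @return list of class `wilcoxon_result`: `statistic` (W+), `p_value`,
#'   `n_nonzero`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  d <- x - y
  d <- d[is.finite(d)]
  N <- length(d)
  if (N == 0) stop("no finite paired differences")
  if (all(d == 0))
    return(structure(list(statistic = 0, p_value = 1, n_nonzero = 0L,
                          method = "all differences zero"),
                     class = "wilcoxon_result"))
  r <- rank(abs(d))                       # Pratt: zeros are ranked too
  nz <- d != 0
  W <- sum(r[nz & d > 0])
  n <- sum(nz)
  if (n <= exact_limit) {
    # exact null distribution of W+ over sign assignments of the nonzero
    # ranks; doubled ranks keep mid-ranks integral
    r2 <- round(2 * r[nz])
    total <- sum(r2)
    f <- numeric(total + 1)               # f[w+1] = #assignments with 2W = w
    f[1] <- 1
    for (rk in r2) {
      g <- f
      g[(rk + 1):(total + 1)] <- g[(rk + 1):(total + 1)] + f[1:(total + 1 - rk)]
      f <- g
    }
    probs <- f / sum(f)
    w2 <- round(2 * W)
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact (rank-multiset convolution, Pratt zeros)"
  } else {
    n0 <- N - n
    EW <- (N * (N + 1) - n0 * (n0 + 1)) / 4
    VW <- (N * (N + 1) * (2 * N + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24
    ties <- table(r[nz])
    VW <- VW - sum(ties^3 - ties) / 48
    z <- (W - EW - sign(W - EW) * 0.5) / sqrt(VW)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (Pratt zeros, tie correction)"
  }
  structure(list(statistic = W, p_value = p, n_nonzero = n, method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W+ = %g, p = %.4g (%s, n nonzero = %d)\n",
              x$statistic, x$p_value, x$method, x$n_nonzero))
  invisible(x)
}

#' Compare paired metric vectors across conditions
#'
#' Runs a two-sided Wilcoxon signed-rank test per metric on paired
#' observations (e.g. per-fold-per-class metric values for a multi-omics
#' versus a single-omics model), adjusts p-values across metrics with
#' Benjamini-Hochberg, and flags rejections at adjusted p < `level`.
#'
#' @param paired_a,paired_b data.frames (or matrices) with one column per
#'   metric and one row per paired unit; columns matched by name.
#' @param metrics which metric columns to compare (default: the
#'   intersection of column names).
#' @param level rejection level on the adjusted p-value (default 0.05).
#' @return data.frame of class `comparison_result`: per metric the W+
#'   statistic, `p_value`, `adjusted_p_value` (BH) and `reject`.
#' @export
wilcoxon_compare <- function(paired_a, paired_b,
                             metrics = intersect(colnames(paired_a),
                                                 colnames(paired_b)),
                             level = 0.05) {
  paired_a <- as.data.frame(paired_a)
  paired_b <- as.data.frame(paired_b)
  if (nrow(paired_a) != nrow(paired_b))
    stop("paired inputs must have equal row counts")
  if (!length(metrics)) stop("no shared metric columns")
  res <- lapply(metrics, function(m)
    wilcoxon_signed_rank(paired_a[[m]], paired_b[[m]]))
  p <- vapply(res, `[[`, 1.0, "p_value")
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(metric = metrics,
                    statistic = vapply(res, `[[`, 1.0, "statistic"),
                    p_value = p,
                    adjusted_p_value = padj,
                    reject = padj < level,
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_result", "data.frame")
  out
}
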