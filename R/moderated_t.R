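# Invert the trigamma function by Newton iteration (monotone decreasing);
# used to match the variance of log residual variances to its theoretical
# value under a scaled inverse-chi-square prior.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated t-test for differential methylation
#'
#' Fits a two-group linear model per feature and shrinks the per-feature
#' residual variances toward a pooled prior estimated from the distribution
#' of variances across features (a scaled inverse-chi-square prior fitted by
#' moment matching on log variances, with trigamma inversion for the prior
#' degrees of freedom). The moderated t-statistic uses the posterior
#' variance and is referred to a t distribution with residual + prior
#' degrees of freedom; an infinite prior df degenerates to a normal
#' reference, a zero prior df to the ordinary two-sample t-test.
#'
#' @param methylation samples x features numeric matrix (beta-values or
#'   M-values; see [beta_to_mvalues()]).
#' @param groups binary factor/vector over samples; >= 2 samples per group.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param prior_df optional override of the estimated prior degrees of
#'   freedom; `0` disables moderation, `Inf` forces full shrinkage to the
#'   prior variance.
#' @return a data.frame of class `modt_result`: `feature`, `effect`
#'   (group mean difference, group 2 minus group 1), `moderated_t`,
#'   `p_value`, `selected`; attributes `prior_df` and `prior_var`.
#' @export
moderated_t_dm <- function(methylation, groups, alpha = 0.05, prior_df = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (min(n1, n2) < 2) stop("each group needs at least 2 samples")
  X <- as.matrix(methylation)
  if (is.null(colnames(X))) colnames(X) <- paste0("feature_", seq_len(ncol(X)))
  n <- nrow(X); df_res <- n - 2
  i1 <- groups == levels(groups)[1]
  mean1 <- colMeans(X[i1, , drop = FALSE])
  mean2 <- colMeans(X[!i1, , drop = FALSE])
  effect <- mean2 - mean1
  rss <- colSums(sweep(X[i1, , drop = FALSE], 2, mean1)^2) +
    colSums(sweep(X[!i1, , drop = FALSE], 2, mean2)^2)
  s2 <- rss / df_res

  # prior fit on log variances; features with exactly zero variance are
  # excluded from prior estimation
  pos <- s2 > 0
  if (!any(pos)) stop("all features have zero residual variance")
  e <- log(s2[pos]) - digamma(df_res / 2) + log(df_res / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - trigamma(df_res / 2)
  if (is.null(prior_df)) {
    if (is.na(excess) || excess <= 0) {
      d0 <- Inf
    } else {
      d0 <- 2 * trigamma_inverse(excess)
    }
  } else {
    d0 <- prior_df
  }
  s0sq <- if (is.infinite(d0) || d0 == 0) exp(emean) else
    exp(emean + digamma(d0 / 2) - log(d0 / 2))
  # at d0 = 0 the prior variance is irrelevant to the statistic

  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2)) else
    (d0 * s0sq + df_res * s2) / (d0 + df_res)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- effect / se
  df_total <- df_res + d0
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  # zero-variance, zero-effect features are uninformative
  degenerate <- !is.finite(tstat)
  tstat[degenerate] <- 0
  pval[degenerate] <- 1
  res <- data.frame(
    feature = colnames(X),
    effect = effect,
    moderated_t = tstat,
    p_value = pval,
    stringsAsFactors = FALSE
  )
  res$selected <- res$p_value < alpha
  attr(res, "alpha") <- alpha
  attr(res, "prior_df") <- d0
  attr(res, "prior_var") <- s0sq
  attr(res, "df_residual") <- df_res
  class(res) <- c("modt_result", "data.frame")
  res
}

#' @export
print.modt_result <- function(x, ...) {
  cat(sprintf(
    "Moderated t differential methylation: %d features, %d selected at p < %g (prior df %.3g)\n",
    nrow(x), sum(x$selected), attr(x, "alpha"), attr(x, "prior_df")))
  NextMethod()
}
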