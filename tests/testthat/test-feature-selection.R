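# --- NB-Wald differential expression ---------------------------------------

test_that("nb_wald_dge handles degenerate features and thresholds", {
  set.seed(1)
  n <- 20
  groups <- factor(rep(c("a", "b"), each = n / 2))
  # both features repeat the same per-group pattern, so size factors are
  # equal across groups and identical counts mean exactly no fold change
  half <- cbind(same = c(5L, 9L, 12L, 7L, 6L, 8L, 10L, 6L, 9L, 11L),
                same2 = c(30L, 22L, 28L, 31L, 26L, 27L, 29L, 24L, 33L, 25L))
  counts <- cbind(rbind(half, half), zero = rep(0L, n))
  res <- nb_wald_dge(counts, groups, alpha = 0.05)
  expect_equal(res$log2fc[res$feature == "same"], 0, tolerance = 1e-6)
  expect_false(res$selected[res$feature == "same"])
  expect_true(res$flagged[res$feature == "zero"])
  expect_equal(res$p_value[res$feature == "zero"], 1)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # a strongly shifted feature is picked up, alpha = 0 selects nothing
  counts_de <- cbind(counts[, 1:2],
                     de = c(rpois(n / 2, 10), rpois(n / 2, 80)))
  res_de <- nb_wald_dge(counts_de, groups, alpha = 0.05)
  expect_true(res_de$selected[res_de$feature == "de"])
  res0 <- nb_wald_dge(counts_de, groups, alpha = 0)
  expect_equal(sum(res0$selected), 0)
  expect_error(nb_wald_dge(counts, factor(rep("a", n))), "2 levels")
  expect_error(nb_wald_dge(counts, factor(c("a", rep("b", n - 1)))),
               "at least 2 samples")
})

test_that("NB GLM coefficient and Wald SE match an independent GLM fit", {
  skip_if_not_installed("MASS")
  set.seed(4)
  n <- 30
  groups <- factor(rep(c("a", "b"), each = n / 2))
  x <- as.numeric(groups == "b")
  counts <- cbind(f1 = rnbinom(n, mu = 50 * exp(0.8 * x), size = 5),
                  f2 = rnbinom(n, mu = 20, size = 5),
                  f3 = rnbinom(n, mu = 100 * exp(-0.5 * x), size = 5))
  res <- nb_wald_dge(counts, groups, alpha = 0.05)
  sf <- attr(res, "size_factors")
  for (j in 1:3) {
    theta <- 1 / res$dispersion[j]
    fit <- suppressWarnings(stats::glm(
      counts[, j] ~ x + offset(log(sf)),
      family = MASS::negative.binomial(theta = theta)))
    sm <- summary(fit, dispersion = 1)
    expect_equal(res$log2fc[j] * log(2), unname(coef(fit)[2]),
                 tolerance = 1e-4)
    expect_equal(res$wald[j],
                 unname(coef(fit)[2] / sm$coefficients[2, 2]),
                 tolerance = 1e-3)
  }
})

test_that("NB-Wald type-I error is near nominal on null simulations", {
  cfg <- sim_config(n_samples_per_class = 30, n_classes = 2,
                    n_features = c(mrna = 600, mirna = 1, meth = 1),
                    effect_size = 0, seed = 1)
  ds <- simulate_null(cfg)
  lab <- droplevels(ds$labels[rownames(ds$omics$mrna)])
  res <- nb_wald_dge(ds$omics$mrna, lab, alpha = 0.05)
  rate <- mean(res$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(rate - 0.05), 3 * se)
})

# --- moderated t ------------------------------------------------------------

test_that("moderated t reduces to the ordinary t when prior df is 0", {
  set.seed(2)
  X <- matrix(rnorm(10 * 40), 10, 40)
  groups <- factor(rep(c("a", "b"), each = 5))
  res <- moderated_t_dm(X, groups, prior_df = 0)
  ref <- apply(X, 2, function(v)
    stats::t.test(v[6:10], v[1:5], var.equal = TRUE)$statistic)
  expect_equal(res$moderated_t, unname(ref), tolerance = 1e-10)
})

test_that("infinite prior df shares one variance across all features", {
  set.seed(3)
  X <- matrix(rnorm(12 * 30, sd = rep(c(1, 4), each = 180)), 12, 30)
  groups <- factor(rep(c("a", "b"), each = 6))
  res <- moderated_t_dm(X, groups, prior_df = Inf)
  # t proportional to effect with one shared scale
  expect_equal(res$moderated_t / res$effect,
               rep((res$moderated_t / res$effect)[1], 30), tolerance = 1e-10)
})

test_that("moderated t matches an independent empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(5)
  X <- matrix(rnorm(6 * 120, sd = sqrt(rchisq(120, 4) / 4)), 6, 120,
              byrow = FALSE)
  groups <- factor(rep(c("a", "b"), each = 3))
  res <- moderated_t_dm(X, groups)
  fit <- limma::eBayes(limma::lmFit(t(X), stats::model.matrix(~groups)))
  expect_equal(attr(res, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "prior_var"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$moderated_t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("moderated-t type-I error is near nominal and degenerates safely", {
  cfg <- sim_config(n_samples_per_class = 30, n_classes = 2,
                    n_features = c(mrna = 1, mirna = 1, meth = 600),
                    effect_size = 0, seed = 2)
  ds <- simulate_null(cfg)
  lab <- droplevels(ds$labels[rownames(ds$omics$meth)])
  res <- moderated_t_dm(ds$omics$meth, lab, alpha = 0.05)
  rate <- mean(res$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(rate - 0.05), 3 * se)
  # zero-variance zero-effect feature
  X <- cbind(const = rep(1, 10), ok = rnorm(10))
  g <- factor(rep(c("a", "b"), each = 5))
  r2 <- moderated_t_dm(X, g)
  expect_equal(r2$p_value[r2$feature == "const"], 1)
})

# --- lasso ------------------------------------------------------------------

test_that("lasso null-model threshold and unpenalised limit are exact", {
  set.seed(6)
  n <- 50; p <- 8
  X <- scale(matrix(rnorm(n * p), n, p)) * sqrt(n / (n - 1))
  y <- as.vector(scale(rnorm(n), scale = FALSE))
  lmax <- lasso_lambda_max(X, y)
  expect_equal(lasso_fit(X, y, lmax)$beta, setNames(rep(0, p), colnames(X)))
  expect_equal(sum(lasso_fit(X, y, lmax * 1.1)$beta != 0), 0)
  # lambda = 0 recovers least squares
  f0 <- lasso_fit(X, y, 0, tol = 1e-12)
  ols <- qr.solve(X, y)
  expect_equal(unname(f0$beta), unname(ols), tolerance = 1e-6)
  expect_error(lasso_fit(X * NA, y, 1), "non-finite")
})

test_that("orthonormal design reproduces the soft-threshold closed form", {
  set.seed(7)
  n <- 64; p <- 6
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)  # X'X/n = I
  y <- rnorm(n)
  bols <- drop(crossprod(Q, y)) / n
  for (lam in c(0.05, 0.2, 0.5)) {
    fit <- lasso_fit(Q, y, lam, tol = 1e-12)
    expect_equal(unname(fit$beta),
                 sign(bols) * pmax(abs(bols) - lam, 0), tolerance = 1e-8)
  }
})

test_that("objective is non-increasing across coordinate-descent sweeps", {
  set.seed(8)
  X <- scale(matrix(rnorm(40 * 15), 40, 15))
  y <- drop(X[, 1] - 2 * X[, 3] + rnorm(40))
  y <- y - mean(y)
  fit <- lasso_fit(X, y, 0.1)
  expect_true(all(diff(fit$objective) <= 1e-12))
})

test_that("solutions agree with an independent solver along a path", {
  skip_if_not_installed("glmnet")
  set.seed(9)
  n <- 80; p <- 12
  X <- scale(matrix(rnorm(n * p), n, p)) * sqrt(n / (n - 1))  # population sd
  b_true <- c(2, -1.5, rep(0, p - 2))
  y <- drop(X %*% b_true + rnorm(n)); y <- y - mean(y)
  for (lam in c(0.02, 0.1, 0.4)) {
    ours <- lasso_fit(X, y, lam, tol = 1e-10)$beta
    g <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-12)
    expect_equal(unname(ours), as.vector(g$beta), tolerance = 1e-4)
  }
})

test_that("support size is monotone non-increasing in lambda", {
  set.seed(10)
  X <- scale(matrix(rnorm(60 * 20), 60, 20))
  y <- drop(X %*% c(rep(1.5, 5), rep(0, 15)) + rnorm(60)); y <- y - mean(y)
  sizes <- vapply(c(0.01, 0.05, 0.1, 0.3, 0.6, 1),
                  function(l) sum(lasso_fit(X, y, l)$beta != 0), 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("multiclass selection behaves at the null and degenerate edges", {
  set.seed(11)
  n <- 60
  labels <- factor(rep(c("a", "b", "c"), each = n / 3))
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  X <- cbind(X, dupzero = rep(1, n))   # constant column
  # strong penalty: empty or near-empty selection on null data
  sel <- lasso_select(X, labels, lambda_grid = c(10), seed = 1)
  expect_lte(length(sel$selected), 1)
  expect_false("dupzero" %in% sel$selected)
  sel2 <- lasso_select(X, labels, seed = 1)
  expect_false("dupzero" %in% sel2$selected)
  expect_error(lasso_select(X, factor(rep("a", n))), "2 classes")
})

test_that("selection cascade shrinks feature counts stage by stage", {
  cfg <- sim_config(n_samples_per_class = 20, n_classes = 3,
                    n_features = c(mrna = 150, mirna = 30, meth = 150),
                    frac_informative = 0.15, effect_size = 2, seed = 12)
  ds <- simulate_multiomics(cfg)
  rep <- select_features(ds, seed = 12)
  cnt <- rep$counts
  for (layer in c("mrna", "meth")) {
    expect_lt(cnt[layer, "lasso"], cnt[layer, "original"])
    expect_lte(cnt[layer, "lasso"], cnt[layer, "screened"])
    expect_lt(cnt[layer, "screened"], cnt[layer, "original"])
  }
  dir <- withr::local_tempdir()
  files <- write_selection_report(rep, dir)
  expect_true(file.exists(file.path(dir, "selection_report.tsv")))
  expect_gt(length(readLines(file.path(dir, "selected_mrna.txt"))), 0)
})
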