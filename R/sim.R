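#' Simulation configuration for synthetic multi-omics data
#'
#' Bundles and validates the parameters of the synthetic multi-omics
#' generator. The generator emulates the statistical structure of a
#' pan-cancer multi-omics study: negative-binomial mRNA and miRNA counts,
#' bounded (0,1) methylation beta-values, class-dependent signal restricted
#' to a sparse subset of "informative" features, and partially overlapping
#' sample sets across layers so that inner-join integration is nontrivial.
#'
#' @param n_samples_per_class samples simulated per class (before per-layer
#'   dropout); must be >= 1.
#' @param n_classes number of classes; must be >= 2. The first class plays
#'   the role of the normal/reference group in two-group contrasts.
#' @param n_features named integer vector with elements `mrna`, `mirna`,
#'   `meth`: features per omics layer.
#' @param frac_informative fraction of features per layer carrying
#'   class-dependent signal, in [0, 1].
#' @param effect_size signal scale: log2 fold change for count layers,
#'   and `effect_size / 2` logit-scale mean shift for methylation.
#' @param dispersion negative-binomial dispersion alpha, so that
#'   Var(Y) = mu + alpha * mu^2; must be > 0.
#' @param missing_frac fraction of samples dropped (independently per
#'   layer) to emulate incomplete per-platform coverage, in [0, 1).
#' @param class_weights optional vector of relative class sizes (defaults
#'   to balanced classes).
#' @param signal_mode `"shared"` (default): every informative feature gets
#'   its own random non-constant class sign pattern, so each layer alone
#'   can separate all classes. `"complementary"`: each layer's informative
#'   features encode one layer-specific balanced class bipartition (three
#'   distinct bipartitions across the three layers), so no single layer
#'   resolves all classes but their combination does — the regime where
#'   multi-omics integration genuinely pays off.
#' @param seed integer RNG seed; every draw derives from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples_per_class = 30,
                       n_classes = 4,
                       n_features = c(mrna = 500, mirna = 100, meth = 500),
                       frac_informative = 0.1,
                       effect_size = 2,
                       dispersion = 0.2,
                       missing_frac = 0.1,
                       class_weights = NULL,
                       signal_mode = c("shared", "complementary"),
                       seed = 1) {
  signal_mode <- match.arg(signal_mode)
  stopifnot(length(n_samples_per_class) == 1, n_samples_per_class >= 1)
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (!all(c("mrna", "mirna", "meth") %in% names(n_features)))
    stop("n_features must name 'mrna', 'mirna' and 'meth'")
  if (any(n_features < 1)) stop("all feature counts must be >= 1")
  if (frac_informative < 0 || frac_informative > 1)
    stop("frac_informative must lie in [0, 1]")
  if (frac_informative == 0 && effect_size != 0)
    stop("frac_informative = 0 is incompatible with a requested class signal ",
         "(effect_size != 0); set effect_size = 0 for a pure null")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (missing_frac < 0 || missing_frac >= 1)
    stop("missing_frac must lie in [0, 1)")
  if (!is.null(class_weights)) {
    stopifnot(length(class_weights) == n_classes, all(class_weights > 0))
  }
  structure(list(
    n_samples_per_class = as.integer(n_samples_per_class),
    n_classes = as.integer(n_classes),
    n_features = vapply(n_features[c("mrna", "mirna", "meth")], as.integer, 1L),
    frac_informative = frac_informative,
    effect_size = effect_size,
    dispersion = dispersion,
    missing_frac = missing_frac,
    class_weights = class_weights,
    signal_mode = signal_mode,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Non-constant per-class sign pattern in {-1, +1}^K. Besides
# non-constancy (usefulness for K-class discrimination), the pattern must
# leave a detectable class-1-vs-rest contrast on the mean-ratio scale the
# count screen operates on: the rest group is a mixture of classes, so its
# mean is mean(2^(eff*s_c)), and patterns like (+1, +1, +1, -1) shrink the
# ratio toward 1. Planted features are by construction differentially
# expressed in the reference-vs-rest contrast at half the nominal effect
# or more, matching what the two-group screen is meant to detect.
sample_sign_pattern <- function(K, eff = 2) {
  repeat {
    s <- sample(c(-1, 1), K, replace = TRUE)
    if (length(unique(s)) < 2) next
    if (eff == 0) return(s)
    contrast <- abs(log2(2^(eff * s[1]) / mean(2^(eff * s[-1]))))
    if (contrast >= eff / 2) return(s)
  }
}

# Layer-specific balanced class bipartition as a +/-1 vector: layer 1 splits
# on the low bit of the class index, layer 2 on the next bit, layer 3 on
# their parity, so distinct layers carry complementary class information
# (any two of the three determine the class for K = 3 or 4). Falls back to
# the low bit when a split would be constant over the observed classes.
class_partition <- function(K, layer_idx) {
  c0 <- seq_len(K) - 1
  b1 <- c0 %% 2
  b2 <- (c0 %/% 2) %% 2
  s <- switch(((layer_idx - 1) %% 3) + 1, b1, b2, as.integer(xor(b1, b2)))
  if (length(unique(s)) < 2) s <- b1
  2 * s - 1
}

simulate_count_layer <- function(n, classes, p, n_inf, effect, alpha, prefix,
                                 partition = NULL) {
  base_mu <- exp(stats::rnorm(p, mean = log(100), sd = 1))
  sf <- exp(stats::rnorm(n, mean = 0, sd = 0.3))
  inf_idx <- if (n_inf > 0) sort(sample.int(p, n_inf)) else integer(0)
  K <- nlevels(classes)
  # per-feature per-class log2 shifts; zero for background features
  lfc <- matrix(0, nrow = p, ncol = K)
  for (j in inf_idx) lfc[j, ] <- effect *
    (if (is.null(partition)) sample_sign_pattern(K, effect)
     else partition * sample(c(-1, 1), 1))
  mu <- outer(sf, base_mu) * 2^(lfc[, as.integer(classes), drop = FALSE] |> t())
  y <- matrix(stats::rnbinom(n * p, mu = mu, size = 1 / alpha), nrow = n, ncol = p)
  colnames(y) <- paste0(prefix, "_", seq_len(p))
  list(counts = y, informative = colnames(y)[inf_idx], lfc = lfc)
}

simulate_meth_layer <- function(n, classes, p, n_inf, effect, prefix,
                                partition = NULL) {
  base <- stats::runif(p, 0.1, 0.9)
  inf_idx <- if (n_inf > 0) sort(sample.int(p, n_inf)) else integer(0)
  K <- nlevels(classes)
  shift <- matrix(0, nrow = p, ncol = K)
  # mean shifts act on the logit scale, where any non-constant pattern
  # keeps a usable two-group contrast; no ratio-scale restriction needed
  for (j in inf_idx) shift[j, ] <- (effect / 2) *
    (if (is.null(partition)) sample_sign_pattern(K, eff = 0)
     else partition * sample(c(-1, 1), 1))
  eta <- matrix(stats::qlogis(base), nrow = n, ncol = p, byrow = TRUE) +
    t(shift[, as.integer(classes), drop = FALSE]) +
    matrix(stats::rnorm(n * p, sd = 1), nrow = n, ncol = p)
  b <- stats::plogis(eta)
  b <- pmin(pmax(b, 1e-6), 1 - 1e-6)
  colnames(b) <- paste0(prefix, "_", seq_len(p))
  list(beta = b, informative = colnames(b)[inf_idx])
}

#' Simulate a synthetic multi-omics dataset
#'
#' Draws three omics layers over a shared sample population: mRNA and miRNA
#' as negative-binomial counts with sample-specific library-size factors and
#' class-dependent log2 fold changes on a sparse informative subset, and
#' methylation as logit-normal beta-values in (0,1) with class-dependent
#' logit-scale mean shifts. Each layer then loses `missing_frac` of samples
#' (independently per layer, without replacement). A protein-interaction
#' style edge list is planted among genes mapped to informative mRNA
#' features, on top of random background edges; a feature-to-gene mapping
#' table covers all three layers. Everything is reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `synthetic_dataset`: list with `omics`
#'   (named list of sample x feature matrices with sample-ID rownames),
#'   `labels` (named factor, all simulated samples), `truth` (named list of
#'   informative feature IDs per layer), `ppi_edges` (data.frame node1,
#'   node2, score), `gene_map` (data.frame feature, gene), and `config`.
#' @export
simulate_multiomics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_classes
  w <- config$class_weights
  n_per <- if (is.null(w)) rep(config$n_samples_per_class, K) else {
    pmax(1L, round(config$n_samples_per_class * K * w / sum(w)))
  }
  n <- sum(n_per)
  classes <- factor(rep(paste0("class", seq_len(K)), times = n_per),
                    levels = paste0("class", seq_len(K)))
  ids <- sprintf("S%04d", seq_len(n))
  names(classes) <- ids

  pf <- config$n_features
  n_inf <- vapply(pf, function(p) as.integer(round(config$frac_informative * p)), 1L)
  if (config$effect_size == 0) n_inf[] <- 0L

  comp <- identical(config$signal_mode, "complementary")
  part <- function(l) if (comp) class_partition(K, l) else NULL
  mrna <- simulate_count_layer(n, classes, pf["mrna"], n_inf["mrna"],
                               config$effect_size, config$dispersion, "gene",
                               partition = part(1))
  mirna <- simulate_count_layer(n, classes, pf["mirna"], n_inf["mirna"],
                                config$effect_size, config$dispersion, "mir",
                                partition = part(2))
  meth <- simulate_meth_layer(n, classes, pf["meth"], n_inf["meth"],
                              config$effect_size, "cpg",
                              partition = part(3))
  omics <- list(mrna = mrna$counts, mirna = mirna$counts, meth = meth$beta)
  for (nm in names(omics)) rownames(omics[[nm]]) <- ids

  # per-layer sample dropout, independent across layers
  n_drop <- as.integer(floor(config$missing_frac * n))
  for (nm in names(omics)) {
    if (n_drop > 0) {
      keep <- sort(sample.int(n, n - n_drop))
      omics[[nm]] <- omics[[nm]][keep, , drop = FALSE]
    }
  }

  # gene map: mRNA features map 1:1 to gene nodes; each CpG and each miRNA
  # maps to a random gene node (mapping tables are inputs in real use)
  genes <- sub("^gene", "G", colnames(mrna$counts))
  gene_map <- rbind(
    data.frame(feature = colnames(mrna$counts), gene = genes,
               stringsAsFactors = FALSE),
    data.frame(feature = colnames(meth$beta),
               gene = sample(genes, pf["meth"], replace = TRUE),
               stringsAsFactors = FALSE),
    data.frame(feature = colnames(mirna$counts),
               gene = sample(genes, pf["mirna"], replace = TRUE),
               stringsAsFactors = FALSE)
  )

  # interaction network: planted edges among informative-mRNA genes plus
  # random background; no self-pairs, no duplicates
  inf_genes <- sub("^gene", "G", mrna$informative)
  planted <- NULL
  if (length(inf_genes) >= 2) {
    m <- length(inf_genes)
    n_pl <- min(3L * m, m * (m - 1L) %/% 2L)
    all_pairs <- utils::combn(inf_genes, 2)
    pick <- sample.int(ncol(all_pairs), n_pl)
    planted <- data.frame(node1 = all_pairs[1, pick], node2 = all_pairs[2, pick],
                          score = stats::runif(n_pl, 0.6, 1.0),
                          stringsAsFactors = FALSE)
  }
  n_bg <- max(10L, as.integer(pf["mrna"] / 5L))
  bg1 <- sample(genes, n_bg, replace = TRUE)
  bg2 <- sample(genes, n_bg, replace = TRUE)
  ok <- bg1 != bg2
  background <- data.frame(node1 = bg1[ok], node2 = bg2[ok],
                           score = stats::runif(sum(ok), 0.1, 0.95),
                           stringsAsFactors = FALSE)
  ppi <- rbind(planted, background)
  key <- paste(pmin(ppi$node1, ppi$node2), pmax(ppi$node1, ppi$node2))
  ppi <- ppi[!duplicated(key), , drop = FALSE]
  rownames(ppi) <- NULL

  structure(list(
    omics = omics,
    labels = classes,
    truth = list(mrna = mrna$informative, mirna = mirna$informative,
                 meth = meth$informative),
    ppi_edges = ppi,
    gene_map = gene_map,
    planted_edges = planted,
    config = config
  ), class = "synthetic_dataset")
}

#' Simulate a pure-null multi-omics dataset
#'
#' Identical to [simulate_multiomics()] with `effect_size` forced to 0:
#' no feature carries class signal, so downstream test statistics are
#' draws from their null distributions. Used for type-I-error calibration.
#'
#' @inheritParams simulate_multiomics
#' @return a `synthetic_dataset` whose `truth` sets are all empty.
#' @export
simulate_null <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$effect_size <- 0
  simulate_multiomics(config)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic multi-omics dataset\n")
  cat(sprintf("  classes: %d (%s)\n", nlevels(x$labels),
              paste(table(x$labels), collapse = "/")))
  for (nm in names(x$omics))
    cat(sprintf("  %-5s: %d samples x %d features (%d informative)\n", nm,
                nrow(x$omics[[nm]]), ncol(x$omics[[nm]]), length(x$truth[[nm]])))
  cat(sprintf("  interaction edges: %d\n", nrow(x$ppi_edges)))
  invisible(x)
}

#' Convert methylation beta-values to M-values
#'
#' M-values are the logit of beta-values, `log2(b / (1 - b))`; they are
#' unbounded and closer to homoscedastic, which suits linear modelling.
#' The generator produces beta-values; either scale can be fed to
#' [moderated_t_dm()].
#'
#' @param beta matrix of beta-values strictly inside (0, 1).
#' @return matrix of M-values, same shape.
#' @export
beta_to_mvalues <- function(beta) {
  if (any(beta <= 0 | beta >= 1)) stop("beta-values must lie strictly in (0,1)")
  log2(beta / (1 - beta))
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes each omics layer as CSV (first column `sample_id`, remaining
#' columns features), labels as a two-column CSV, the interaction network
#' as a three-column TSV and the gene map as a two-column TSV, plus the
#' truth sets as JSON (synthetic data only; real data have no truth).
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(ds$omics)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    df <- data.frame(sample_id = rownames(ds$omics[[nm]]),
                     ds$omics[[nm]], check.names = FALSE)
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(sample_id = names(ds$labels),
                              class = as.character(ds$labels)),
                   f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "ppi_edges.tsv")
  utils::write.table(ds$ppi_edges, f, row.names = FALSE, sep = "\t", quote = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "gene_map.tsv")
  utils::write.table(ds$gene_map, f, row.names = FALSE, sep = "\t", quote = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(ds$truth, f, pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the files.
#' @return a `synthetic_dataset`-shaped list (config is not recoverable
#'   from disk and is NULL).
#' @export
read_dataset <- function(dir) {
  read_layer <- function(f) {
    df <- utils::read.csv(f, check.names = FALSE)
    if (anyDuplicated(df$sample_id))
      stop("duplicate sample id in ", f, ": ",
           df$sample_id[duplicated(df$sample_id)][1])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$sample_id
    m
  }
  omics <- list()
  for (nm in c("mrna", "mirna", "meth")) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) omics[[nm]] <- read_layer(f)
  }
  lab_df <- utils::read.csv(file.path(dir, "labels.csv"))
  if (anyDuplicated(lab_df$sample_id))
    stop("duplicate sample id in labels.csv: ",
         lab_df$sample_id[duplicated(lab_df$sample_id)][1])
  labels <- factor(lab_df$class)
  names(labels) <- lab_df$sample_id
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- lapply(jsonlite::read_json(tf), unlist)
  ppi <- utils::read.table(file.path(dir, "ppi_edges.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  gm <- utils::read.table(file.path(dir, "gene_map.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  structure(list(omics = omics, labels = labels, truth = truth,
                 ppi_edges = ppi, gene_map = gm, config = NULL),
            class = "synthetic_dataset")
}
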