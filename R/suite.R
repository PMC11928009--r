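#' Cross-validated multi- versus single-omics comparison suite
#'
#' Trains every requested architecture on every requested omics combination
#' over stratified k-fold cross-validation with the correlation-graph
#' (node classification) or interaction-network (graph classification)
#' structure, collects the six test-set metrics per fold, and runs the
#' Wilcoxon signed-rank comparison of each multi-layer combination against
#' each single-layer combination per architecture.
#'
#' Pairing for the Wilcoxon test (`pairing`):
#' \describe{
#'   \item{fold_class}{(default) paired units are per-(fold x class)
#'     one-vs-rest metric values, pooled over the single-omics layers being
#'     compared against; sign-symmetric under the null hypothesis and
#'     powerful under genuine separation.}
#'   \item{fold}{paired units are the k per-fold aggregate metrics (too few
#'     pairs to reject below ~0.06 at k = 5; offered for completeness).}
#'   \item{bootstrap}{paired units are per-test-sample bootstrap metric
#'     replicates; anticonservative under the null (the replicates inherit
#'     the sign of the observed chance difference) and therefore not the
#'     default.}
#' }
#'
#' @param ds a `synthetic_dataset` (or list with `omics` and `labels`).
#' @param graph_type `"correlation"` or `"ppi"`.
#' @param omics_combinations list of character vectors of layer names;
#'   default: the three single layers and the full triple.
#' @param architectures character vector among gcn/gat/gtn.
#' @param config a [train_config()].
#' @param k folds (default 5).
#' @param hidden,heads optional reduced layer widths passed to
#'   [model_spec()] (named list per architecture).
#' @param correlation_threshold threshold for [build_sample_graph()].
#' @param ppi_score_threshold score threshold for [build_feature_graph()].
#' @param pairing Wilcoxon pairing scheme, see Details.
#' @param n_boot bootstrap replicates when `pairing = "bootstrap"`.
#' @param select run the feature-selection cascade per layer first
#'   (default FALSE: use all features, selection is a separate stage).
#' @param seed root seed; per-fold and per-model seeds derive from it.
#' @return list of class `comparison_suite`: `metrics` (one row per fold x
#'   combination x architecture), `summary` (mean +/- sd), `comparisons`
#'   (named list of [wilcoxon_compare()] tables, multi vs single), `seeds`.
#' @export
run_comparison_suite <- function(ds,
                                 graph_type = c("correlation", "ppi"),
                                 omics_combinations = NULL,
                                 architectures = c("gcn", "gat", "gtn"),
                                 config = train_config(),
                                 k = 5,
                                 hidden = NULL, heads = NULL,
                                 correlation_threshold = 0.9,
                                 ppi_score_threshold = 0,
                                 pairing = c("fold_class", "fold", "bootstrap"),
                                 n_boot = 1000,
                                 select = FALSE,
                                 seed = 1) {
  graph_type <- match.arg(graph_type)
  pairing <- match.arg(pairing)
  layers <- names(ds$omics)
  if (is.null(omics_combinations))
    omics_combinations <- c(as.list(layers), list(layers))
  combo_name <- vapply(omics_combinations, paste, "", collapse = "+")

  sel <- NULL
  omics <- ds$omics
  if (select) {
    rep <- select_features(ds, seed = seed)
    for (nm in names(omics)) {
      keep <- intersect(colnames(omics[[nm]]), rep$selected[[nm]])
      if (length(keep) >= 2)
        omics[[nm]] <- omics[[nm]][, keep, drop = FALSE]
    }
    sel <- rep
  }

  rows <- list(); per_class_rows <- list()
  for (ci in seq_along(omics_combinations)) {
    combo <- omics_combinations[[ci]]
    integ <- integrate_omics(omics[combo], ds$labels)
    folds <- make_folds(integ$labels, k = k, seed = seed)
    if (graph_type == "correlation") {
      graph <- suppressWarnings(
        build_sample_graph(integ, threshold = correlation_threshold))
      task <- "node"
    } else {
      graph <- build_feature_graph(ds$ppi_edges, ds$gene_map, integ,
                                   score_threshold = ppi_score_threshold)
      task <- "graph"
    }
    in_dim <- if (task == "node") ncol(integ$X) else dim(graph$tensors)[2]
    for (arch in architectures) {
      spec <- model_spec(arch, in_dim = in_dim,
                         n_classes = nlevels(integ$labels),
                         hidden = hidden[[arch]], heads = heads[[arch]],
                         task = task)
      for (f in seq_len(k)) {
        fit_seed <- seed + 1000L * ci + 100L * match(arch, architectures) + f
        model <- build_model(spec, seed = fit_seed)
        cfg <- config; cfg$seed <- fit_seed
        fit <- train_model(model, graph, folds[[f]], cfg)
        ev <- evaluate(fit, folds[[f]]$test)
        rows[[length(rows) + 1L]] <- data.frame(
          graph = graph_type, combination = combo_name[ci],
          architecture = arch, fold = f,
          as.data.frame(ev$metrics), stringsAsFactors = FALSE)
        pc <- ev$per_class
        pc$fold <- f; pc$architecture <- arch
        pc$combination <- combo_name[ci]
        per_class_rows[[length(per_class_rows) + 1L]] <- pc
        if (pairing == "bootstrap") {
          prob <- predict(fit, type = "prob")
          idx <- which(folds[[f]]$test)
          attr(rows[[length(rows)]], "boot") <-
            list(prob = prob[idx, , drop = FALSE],
                 truth = integ$labels[idx], fold = f)
        }
      }
    }
  }
  metrics <- do.call(rbind, rows)
  per_class <- do.call(rbind, per_class_rows)
  summary <- aggregate_metrics(metrics,
                               by = c("graph", "combination", "architecture"))

  multi <- combo_name[vapply(omics_combinations, length, 1L) > 1]
  single <- combo_name[vapply(omics_combinations, length, 1L) == 1]
  comparisons <- list()
  for (arch in architectures) {
    for (mc in multi) {
      pa <- pb <- NULL
      if (pairing == "fold_class") {
        a0 <- per_class[per_class$architecture == arch &
                          per_class$combination == mc, ]
        for (sc in single) {
          b0 <- per_class[per_class$architecture == arch &
                            per_class$combination == sc, ]
          key <- c("fold", "class")
          mm <- merge(a0, b0, by = key, suffixes = c(".a", ".b"))
          pa <- rbind(pa, stats::setNames(
            mm[paste0(metric_names(), ".a")], metric_names()))
          pb <- rbind(pb, stats::setNames(
            mm[paste0(metric_names(), ".b")], metric_names()))
        }
      } else if (pairing == "fold") {
        a0 <- metrics[metrics$architecture == arch &
                        metrics$combination == mc, ]
        for (sc in single) {
          b0 <- metrics[metrics$architecture == arch &
                          metrics$combination == sc, ]
          mm <- merge(a0, b0, by = "fold", suffixes = c(".a", ".b"))
          pa <- rbind(pa, stats::setNames(
            mm[paste0(metric_names(), ".a")], metric_names()))
          pb <- rbind(pb, stats::setNames(
            mm[paste0(metric_names(), ".b")], metric_names()))
        }
      } else {
        bp <- bootstrap_pairs(rows, arch, mc, single, n_boot, seed)
        pa <- bp$a; pb <- bp$b
      }
      comparisons[[paste(arch, mc, "vs single", sep = " | ")]] <-
        wilcoxon_compare(pa, pb)
    }
  }
  structure(list(metrics = metrics, per_class = per_class, summary = summary,
                 comparisons = comparisons, selection = sel,
                 seeds = list(root = seed), graph_type = graph_type,
                 pairing = pairing),
            class = "comparison_suite")
}

# paired bootstrap metric replicates: same resampled test indices for both
# models within a fold
bootstrap_pairs <- function(rows, arch, multi_combo, single_combos,
                            n_boot, seed) {
  grab <- function(combo) Filter(function(r)
    r$architecture[1] == arch && r$combination[1] == combo &&
      !is.null(attr(r, "boot")), rows)
  ra <- grab(multi_combo)
  set.seed(seed + 7919L)
  a <- b <- NULL
  for (sc in single_combos) {
    rb <- grab(sc)
    for (f in seq_along(ra)) {
      ba <- attr(ra[[f]], "boot"); bb <- attr(rb[[f]], "boot")
      n <- length(ba$truth)
      for (r in seq_len(ceiling(n_boot / length(ra) / length(single_combos)))) {
        idx <- sample.int(n, n, replace = TRUE)
        ma <- classification_metrics(ba$truth[idx], ba$prob[idx, , drop = FALSE])
        mb <- classification_metrics(bb$truth[idx], bb$prob[idx, , drop = FALSE])
        a <- rbind(a, as.data.frame(ma$metrics))
        b <- rbind(b, as.data.frame(mb$metrics))
      }
    }
  }
  list(a = a, b = b)
}

#' @export
print.comparison_suite <- function(x, ...) {
  cat(sprintf("Comparison suite (%s graph, %s pairing): %d result rows\n",
              x$graph_type, x$pairing, nrow(x$metrics)))
  cat("\nMean accuracy by combination x architecture:\n")
  s <- x$summary
  print(s[order(s$architecture, -s$accuracy_mean),
          c("combination", "architecture", "accuracy_mean", "accuracy_sd")],
        row.names = FALSE)
  for (nm in names(x$comparisons)) {
    cat("\n", nm, "\n", sep = "")
    print(as.data.frame(x$comparisons[[nm]]), row.names = FALSE)
  }
  invisible(x)
}

#' Write suite results to disk
#'
#' Tidy per-fold CSV, a markdown summary of mean +/- sd per combination and
#' architecture with the Wilcoxon comparisons, and a JSON manifest with
#' seeds and configuration.
#'
#' @param suite a `comparison_suite`.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_suite_results <- function(suite, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f1 <- file.path(dir, "metrics_per_fold.csv")
  utils::write.csv(suite$metrics, f1, row.names = FALSE)
  f2 <- file.path(dir, "summary.md")
  con <- file(f2, "w")
  s <- suite$summary
  writeLines("# Cross-validated performance (mean ± sd)\n", con)
  writeLines(paste("| combination | architecture |",
                   paste(metric_names(), collapse = " | "), "|"), con)
  writeLines(paste("|", paste(rep("---", 2 + length(metric_names())),
                              collapse = " | "), "|"), con)
  for (i in seq_len(nrow(s))) {
    cells <- vapply(metric_names(), function(m)
      sprintf("%.4f ± %.4f", s[[paste0(m, "_mean")]][i],
              s[[paste0(m, "_sd")]][i]), "")
    writeLines(paste("|", s$combination[i], "|", s$architecture[i], "|",
                     paste(cells, collapse = " | "), "|"), con)
  }
  writeLines("\n# Wilcoxon signed-rank comparisons\n", con)
  for (nm in names(suite$comparisons)) {
    writeLines(paste0("## ", nm, "\n"), con)
    cmp <- suite$comparisons[[nm]]
    writeLines("| metric | W+ | p | adjusted p | reject |", con)
    writeLines("| --- | --- | --- | --- | --- |", con)
    for (i in seq_len(nrow(cmp)))
      writeLines(sprintf("| %s | %g | %.3g | %.3g | %s |", cmp$metric[i],
                         cmp$statistic[i], cmp$p_value[i],
                         cmp$adjusted_p_value[i], cmp$reject[i]), con)
    writeLines("", con)
  }
  close(con)
  f3 <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seeds = suite$seeds, graph_type = suite$graph_type,
                            pairing = suite$pairing,
                            r_version = R.version.string),
                       f3, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(f1, f2, f3))
}
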