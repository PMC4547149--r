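#' Run the load-filter-predict-visualize pipeline
#'
#' Executes the full analysis on matched miRNA/mRNA datasets: (1) filter —
#' two-sample data are reduced to entities passing the p-value/fold-change
#' thresholds, multisample data to entities passing the mean-expression
#' threshold; (2) predict — candidate pairs (all filtered pairs, optionally
#' intersected with a sequence candidate database and a fold-change
#' direction filter) are scored by each requested algorithm and the top
#' `top_n` (or thresholded) pairs selected per algorithm; (3) combine — the
#' per-algorithm selections are merged into one interaction table; (4)
#' visualize — the bipartite network, a node-link layout and a treemap are
#' computed, and all artifacts are optionally written to a directory.
#'
#' @param mirna_ds,mrna_ds [expression_dataset()] objects over identical
#'   ordered samples.
#' @param algorithms Character vector from `"pearson"`, `"spearman"`,
#'   `"mutual_information"`, `"mic"`, `"genmir"`.
#' @param p_max,min_abs_fc Two-sample filter thresholds (used when the data
#'   kind is two-sample).
#' @param min_mean Multisample filter threshold.
#' @param top_n Pairs kept per algorithm (or use `threshold`).
#' @param threshold Optional named numeric vector of per-algorithm score
#'   thresholds used instead of `top_n`.
#' @param direction Fold-change [direction_filter()] option (two-sample
#'   kinds only; multisample data use `"all"`).
#' @param combine `"intersection"` or `"union"`.
#' @param candidates Optional sequence candidate tibble (`mirna_id`,
#'   `mrna_id` or `gene_symbol`) restricting the scored pairs.
#' @param genmir Optional [genmir_config()].
#' @param mi_k,mic_alpha,mic_c Association parameters.
#' @param layout_method Node-link layout for the visualize stage.
#' @param canvas Treemap canvas `c(width, height)`.
#' @param values_are_log2 Passed to [diff_stats()].
#' @param seed Integer seed for the layout stage.
#' @param out_dir Optional output directory; when given, all stage artifacts
#'   are written as TSV/GraphML and the manifest lists them.
#' @return A `mirtar_pipeline` list: `mirna_stats`, `mrna_stats`, kept id
#'   sets, `scores` (per algorithm), `selections` (per algorithm),
#'   `interactions`, `network`, `layout`, `treemap`, and a `manifest` tibble
#'   of artifacts with row counts.
#' @export
run_pipeline <- function(mirna_ds, mrna_ds,
                         algorithms = c("pearson", "mic", "genmir"),
                         p_max = 0.05, min_abs_fc = 1, min_mean = 0,
                         top_n = 50, threshold = NULL,
                         direction = "opposite", combine = "intersection",
                         candidates = NULL, genmir = genmir_config(),
                         mi_k = 3, mic_alpha = 0.6, mic_c = 15,
                         layout_method = "isom_modified",
                         canvas = c(800, 600), values_are_log2 = FALSE,
                         seed = 1L, out_dir = NULL) {
  ok <- c("pearson", "spearman", "mutual_information", "mic", "genmir")
  bad <- setdiff(algorithms, ok)
  if (length(bad)) {
    stop_param("unknown algorithm(s): %s", paste(bad, collapse = ", "))
  }
  stopifnot(is_expression_dataset(mirna_ds), is_expression_dataset(mrna_ds))
  two_sample <- mirna_ds$data_kind %in% c("paired2", "unpaired2")

  # ---- filter ----
  if (two_sample) {
    mirna_stats <- diff_stats(mirna_ds, values_are_log2 = values_are_log2)
    mrna_stats <- diff_stats(mrna_ds, values_are_log2 = values_are_log2)
    mirna_keep <- filter_two_sample(mirna_stats, p_max, min_abs_fc)
    mrna_keep <- filter_two_sample(mrna_stats, p_max, min_abs_fc)
  } else {
    mirna_stats <- NULL; mrna_stats <- NULL
    mirna_keep <- filter_multisample(mirna_ds, min_mean)
    mrna_keep <- filter_multisample(mrna_ds, min_mean)
  }
  inform(sprintf("filter: kept %d miRNAs, %d mRNAs",
                 length(mirna_keep), length(mrna_keep)))
  if (!length(mirna_keep) || !length(mrna_keep)) {
    stop_design("filter stage removed every miRNA or every mRNA")
  }

  # ---- candidate pair set (direction filter precedes selection) ----
  pair_set <- tidyr::expand_grid(mirna_id = mirna_keep, mrna_id = mrna_keep)
  if (!is.null(candidates)) {
    cand <- as_tibble(candidates)
    if ("gene_symbol" %in% names(cand) && !"mrna_id" %in% names(cand)) {
      cand <- rename(cand, mrna_id = "gene_symbol")
    }
    pair_set <- semi_join(pair_set, cand, by = c("mirna_id", "mrna_id"))
  }
  if (two_sample && direction != "all") {
    pair_set <- direction_filter(pair_set, mirna_stats, mrna_stats,
                                 option = direction)
  }
  inform(sprintf("predict: %d candidate pairs", nrow(pair_set)))
  if (!nrow(pair_set)) stop_design("no candidate pairs after direction filtering")

  # ---- predict ----
  scores <- list(); selections <- list()
  for (alg in algorithms) {
    sc <- if (alg == "genmir") {
      fit <- genmir_fit(mirna_ds, mrna_ds, pair_set, config = genmir)
      new_score_table(
        transmute(fit$beta, mirna_id, mrna_id, score = beta),
        "genmir", list(pi = genmir$pi))
    } else {
      params <- switch(alg,
        mutual_information = list(k = mi_k),
        mic = list(alpha = mic_alpha, c = mic_c),
        list())
      score_pairs(mirna_ds, mrna_ds, method = alg, params = params,
                  candidates = pair_set,
                  mirna_ids = mirna_keep, mrna_ids = mrna_keep)
    }
    scores[[alg]] <- sc
    selections[[alg]] <- if (!is.null(threshold)) {
      select_interactions(sc, threshold = threshold[[alg]], algorithm = alg)
    } else {
      select_interactions(sc, top_n = top_n, algorithm = alg)
    }
    inform(sprintf("predict[%s]: selected %d of %d pairs",
                   alg, nrow(selections[[alg]]), nrow(sc)))
  }

  # ---- combine ----
  interactions <- combine_results(selections, mode = combine,
                                  mirna_stats = mirna_stats,
                                  mrna_stats = mrna_stats)
  inform(sprintf("combine[%s]: %d interactions", combine, nrow(interactions)))

  # ---- visualize ----
  network <- NULL; layout <- NULL; treemap <- NULL
  if (nrow(interactions)) {
    network <- build_network(interactions)
    layout <- layout_network(network, method = layout_method, seed = seed)
    treemap <- treemap_layout(network, canvas[1], canvas[2])
  } else {
    warn("empty interaction table; visualize stage skipped")
  }

  res <- structure(
    list(mirna_stats = mirna_stats, mrna_stats = mrna_stats,
         mirna_keep = mirna_keep, mrna_keep = mrna_keep,
         scores = scores, selections = selections,
         interactions = interactions, network = network,
         layout = layout, treemap = treemap, manifest = NULL),
    class = "mirtar_pipeline")
  res$manifest <- if (is.null(out_dir)) pipeline_manifest(res) else {
    write_pipeline(res, out_dir)
  }
  res
}

pipeline_manifest <- function(res, paths = NULL) {
  items <- list(
    mirna_stats = res$mirna_stats, mrna_stats = res$mrna_stats,
    interactions = res$interactions, layout = res$layout,
    treemap = res$treemap)
  if (!is.null(res$network)) {
    items$nodes <- tibble(id = c(res$network$mirna_nodes,
                                 res$network$mrna_nodes))
    items$edges <- res$network$edges
    items$network_graphml <- res$network$edges
  }
  for (a in names(res$scores)) items[[paste0("scores_", a)]] <- res$scores[[a]]
  for (a in names(res$selections)) {
    items[[paste0("selection_", a)]] <- res$selections[[a]]
  }
  keep <- !vapply(items, is.null, logical(1))
  tibble(artifact = names(items)[keep],
         rows = vapply(items[keep], nrow, integer(1)),
         path = if (is.null(paths)) NA_character_
                else unname(paths[names(items)[keep]]))
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wt <- function(obj, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(as_tibble(obj), p, progress = FALSE)
    paths[name] <<- p
  }
  if (!is.null(res$mirna_stats)) wt(res$mirna_stats, "mirna_stats")
  if (!is.null(res$mrna_stats)) wt(res$mrna_stats, "mrna_stats")
  for (a in names(res$scores)) wt(res$scores[[a]], paste0("scores_", a))
  for (a in names(res$selections)) {
    wt(res$selections[[a]], paste0("selection_", a))
  }
  if (nrow(res$interactions)) {
    p <- file.path(out_dir, "interactions.tsv")
    write_interaction_table(res$interactions, p)
    paths["interactions"] <- p
  }
  if (!is.null(res$network)) {
    paths["network_graphml"] <- file.path(out_dir, "network.graphml")
    write_network_graphml(res$network, paths["network_graphml"])
    np <- write_network_tsv(res$network,
                            file.path(out_dir, "nodes.tsv"),
                            file.path(out_dir, "edges.tsv"))
    paths["nodes"] <- np[1]; paths["edges"] <- np[2]
    wt(res$layout, "layout")
    wt(res$treemap, "treemap")
  }
  mf <- pipeline_manifest(res, paths)
  readr::write_tsv(mf, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  mf
}

#' @export
print.mirtar_pipeline <- function(x, ...) {
  cat("<mirtar_pipeline>\n")
  print(x$manifest)
  invisible(x)
}
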