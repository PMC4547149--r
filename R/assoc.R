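#' Correlation between two expression profiles
#'
#' Pearson product-moment or Spearman rank correlation; Spearman is Pearson
#' on average-ranked data. A constant vector leaves the coefficient
#' undefined: `NA` is returned with a warning so the pair can be excluded
#' upstream.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation coefficient in \[-1, 1\], or `NA` if undefined.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_param("x and y must have equal length")
  if (length(x) < 3) stop_param("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector: correlation undefined, returning NA")
    return(NA_real_)
  }
  cor(x, y, method = method)
}

#' Score miRNA-mRNA pairs by an expression-based association measure
#'
#' Computes the chosen association score for every (miRNA, mRNA) pair in the
#' Cartesian product of the two id sets — optionally restricted to a supplied
#' candidate pair set, e.g. sequence-predicted candidates — across matched
#' samples. Both datasets must carry expression values over identical,
#' identically ordered samples; `stats_only` data cannot support
#' expression-based prediction.
#'
#' @param mirna_ds,mrna_ds Expression-bearing [expression_dataset()] objects
#'   with identical ordered sample ids.
#' @param method One of `"pearson"`, `"spearman"`, `"mutual_information"`,
#'   `"mic"`.
#' @param params Method parameters: `k` for mutual information (default 3);
#'   `alpha`, `c` for MIC (defaults 0.6, 15).
#' @param candidates Optional tibble/data frame with columns `mirna_id`,
#'   `mrna_id` restricting which pairs are scored.
#' @param mirna_ids,mrna_ids Optional id subsets (e.g. the output of a filter
#'   step); default all entities.
#' @return A `score_table` tibble with columns `mirna_id`, `mrna_id`,
#'   `score`, and attributes `method` and `params`. Pairs with undefined
#'   scores (constant profiles) are dropped with a warning.
#' @export
score_pairs <- function(mirna_ds, mrna_ds,
                        method = c("pearson", "spearman",
                                   "mutual_information", "mic"),
                        params = list(), candidates = NULL,
                        mirna_ids = NULL, mrna_ids = NULL) {
  method <- match.arg(method)
  stopifnot(is_expression_dataset(mirna_ds), is_expression_dataset(mrna_ds))
  if (mirna_ds$data_kind == "stats_only" || mrna_ds$data_kind == "stats_only") {
    stop_capability(
      "expression-based prediction needs per-sample expression levels; p-value/fold-change data cannot be scored")
  }
  if (!identical(mirna_ds$sample_ids, mrna_ds$sample_ids)) {
    stop_design("miRNA and mRNA datasets must share identically ordered sample ids")
  }
  if (is.null(mirna_ids)) mirna_ids <- mirna_ds$entity_ids
  if (is.null(mrna_ids)) mrna_ids <- mrna_ds$entity_ids
  miss_m <- setdiff(mirna_ids, mirna_ds$entity_ids)
  miss_g <- setdiff(mrna_ids, mrna_ds$entity_ids)
  if (length(miss_m) || length(miss_g)) {
    stop_design("unknown entity id(s): %s",
                paste(head(c(miss_m, miss_g), 5), collapse = ", "))
  }

  if (is.null(candidates)) {
    pairs <- tidyr::expand_grid(mirna_id = mirna_ids, mrna_id = mrna_ids)
  } else {
    pairs <- as_tibble(candidates)[, c("mirna_id", "mrna_id")] |>
      distinct() |>
      filter(mirna_id %in% mirna_ids, mrna_id %in% mrna_ids)
  }
  if (!nrow(pairs)) {
    out <- tibble(mirna_id = character(), mrna_id = character(),
                  score = numeric())
    return(new_score_table(out, method, params))
  }

  Zm <- mirna_ds$values
  Zg <- mrna_ds$values

  if (method %in% c("pearson", "spearman")) {
    cm <- suppressWarnings(
      cor(t(Zm[unique(pairs$mirna_id), , drop = FALSE]),
          t(Zg[unique(pairs$mrna_id), , drop = FALSE]),
          method = method))
    pairs$score <- cm[cbind(match(pairs$mirna_id, rownames(cm)),
                            match(pairs$mrna_id, colnames(cm)))]
  } else if (method == "mutual_information") {
    k <- params$k %||% 3
    pairs$score <- purrr::map2_dbl(pairs$mirna_id, pairs$mrna_id, function(m, g) {
      ksg_mutual_information(Zm[m, ], Zg[g, ], k = k)
    })
  } else {
    alpha <- params$alpha %||% 0.6
    cc <- params$c %||% 15
    pairs$score <- purrr::map2_dbl(pairs$mirna_id, pairs$mrna_id, function(m, g) {
      mic(Zm[m, ], Zg[g, ], alpha = alpha, c = cc)
    })
  }

  bad <- is.na(pairs$score)
  if (any(bad)) {
    warn(sprintf("%d pair(s) with undefined score dropped", sum(bad)))
    pairs <- pairs[!bad, ]
  }
  new_score_table(arrange(pairs, mirna_id, mrna_id), method, params)
}

new_score_table <- function(df, method, params) {
  out <- as_tibble(df)
  attr(out, "method") <- method
  attr(out, "params") <- params
  class(out) <- c("score_table", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
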