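#' Filter candidate pairs by fold-change direction
#'
#' Keeps the pairs whose miRNA and mRNA fold-change signs match one of the
#' four search options. Because miRNAs down-regulate their targets, the
#' biologically strongest option is up-regulated miRNA with down-regulated
#' mRNA; `"opposite"` is the union of the two one-sided options and `"all"`
#' keeps every pair. "Up" means `fc > +1` and "down" means `fc < -1`; an
#' unchanged entity (`fc = +1`) matches no directional option.
#'
#' @param pairs Tibble/data frame with columns `mirna_id`, `mrna_id`.
#' @param mirna_stats,mrna_stats [diff_stats()] tables covering the pair
#'   members (required unless `option = "all"`).
#' @param option One of `"up_mir_down_mrna"`, `"down_mir_up_mrna"`,
#'   `"opposite"`, `"all"`.
#' @return The retained rows of `pairs`.
#' @export
direction_filter <- function(pairs, mirna_stats = NULL, mrna_stats = NULL,
                             option = c("opposite", "up_mir_down_mrna",
                                        "down_mir_up_mrna", "all")) {
  option <- match.arg(option)
  pairs <- as_tibble(pairs)
  if (option == "all") return(pairs)
  if (is.null(mirna_stats) || is.null(mrna_stats)) {
    stop_design("directional filtering requires both statistics tables")
  }
  fm <- mirna_stats$fc[match(pairs$mirna_id, mirna_stats$entity_id)]
  fg <- mrna_stats$fc[match(pairs$mrna_id, mrna_stats$entity_id)]
  if (any(is.na(fm)) || any(is.na(fg))) {
    stop_design("statistics tables must cover every pair member under option '%s'",
                option)
  }
  keep <- switch(option,
    up_mir_down_mrna = fm > 1 & fg < -1,
    down_mir_up_mrna = fm < -1 & fg > 1,
    opposite = (fm > 1 & fg < -1) | (fm < -1 & fg > 1))
  pairs[keep, ]
}

#' Select interactions from a score table by threshold or top N
#'
#' Orders the scored pairs by prediction strength and keeps either the pairs
#' on the accepted side of a score threshold or the top `n`. Correlation
#' scores order ascending (most negative correlation = strongest predicted
#' down-regulation, so a threshold keeps `score <= threshold`); mutual
#' information, MIC and posterior target probabilities order descending
#' (threshold keeps `score >= threshold`). Ties break deterministically by
#' score then `(mirna_id, mrna_id)`.
#'
#' @param scores A `score_table` from [score_pairs()], a `genmir_fit`, or any
#'   tibble with `mirna_id`, `mrna_id`, `score` columns.
#' @param threshold Score threshold (exclusive with `top_n`).
#' @param top_n Number of pairs to keep (exclusive with `threshold`); if
#'   larger than the number available, all are kept.
#' @param ordering `"ascending"` or `"descending"`; default chosen from the
#'   score table's method as above.
#' @param algorithm Label recorded on the result; defaults to the score
#'   table's method.
#' @return A `prediction_result` tibble (`mirna_id`, `mrna_id`, `score`).
#' @export
select_interactions <- function(scores, threshold = NULL, top_n = NULL,
                                ordering = NULL, algorithm = NULL) {
  if (inherits(scores, "genmir_fit")) {
    algorithm <- algorithm %||% "genmir"
    scores <- transmute(scores$beta, mirna_id, mrna_id, score = beta)
    method <- "genmir"
  } else {
    method <- attr(scores, "method") %||% "score"
    algorithm <- algorithm %||% method
    scores <- as_tibble(scores)[, c("mirna_id", "mrna_id", "score")]
  }
  if (is.null(threshold) == is.null(top_n)) {
    stop_param("supply exactly one of threshold or top_n")
  }
  if (is.null(ordering)) {
    ordering <- if (method %in% c("pearson", "spearman")) "ascending" else "descending"
  }
  ordering <- match.arg(ordering, c("ascending", "descending"))

  if (!is.null(threshold)) {
    keep <- if (ordering == "ascending") scores$score <= threshold
            else scores$score >= threshold
    out <- scores[keep, ]
    out <- arrange(out, if (ordering == "ascending") score else desc(score),
                   mirna_id, mrna_id)
  } else {
    if (!is.numeric(top_n) || top_n < 1) stop_param("top_n must be a positive integer")
    out <- arrange(scores,
                   if (ordering == "ascending") score else desc(score),
                   mirna_id, mrna_id)
    out <- head(out, top_n)
  }
  new_prediction_result(out, algorithm)
}

new_prediction_result <- function(df, algorithm) {
  out <- as_tibble(df)
  if (anyDuplicated(out[, c("mirna_id", "mrna_id")])) {
    stop_format("duplicate pair in prediction result")
  }
  attr(out, "algorithm") <- algorithm
  class(out) <- c("prediction_result", class(out))
  out
}

#' Combine per-algorithm predictions into one interaction table
#'
#' Merges prediction results from several algorithms into a table with one
#' row per (miRNA, mRNA) pair and a TRUE/FALSE support flag per algorithm —
#' the shape of a published multi-evidence interaction table. `"intersection"`
#' keeps only pairs predicted by every *selected* algorithm; `"union"` keeps
#' pairs predicted by any. Either way, each retained row records the flag for
#' every supplied algorithm, so non-selected algorithms still show their
#' TRUE/FALSE evidence.
#'
#' @param results Named list of `prediction_result` tibbles (names are the
#'   algorithm labels; unnamed lists use each result's recorded algorithm).
#' @param mode `"intersection"` or `"union"`.
#' @param selected Algorithms whose agreement defines membership; defaults to
#'   all supplied.
#' @param mirna_stats,mrna_stats Optional [diff_stats()] tables used to
#'   annotate per-node fold changes (`fc_mirna`, `fc_mrna` columns).
#' @return An `interaction_table` tibble: `mirna_id`, `mrna_id`, one logical
#'   column per algorithm, `support` (number of TRUE flags), and optional
#'   fold-change columns.
#' @export
combine_results <- function(results, mode = c("intersection", "union"),
                            selected = NULL, mirna_stats = NULL,
                            mrna_stats = NULL) {
  mode <- match.arg(mode)
  if (!length(results)) stop_design("no prediction results supplied")
  algs <- names(results)
  if (is.null(algs) || any(!nzchar(algs))) {
    algs <- vapply(results, function(r) attr(r, "algorithm") %||% "score",
                   character(1))
    names(results) <- algs
  }
  if (anyDuplicated(algs)) stop_design("duplicate algorithm labels")
  if (is.null(selected)) selected <- algs
  if (!length(selected) || !all(selected %in% algs)) {
    stop_design("selected algorithms must be a non-empty subset of those supplied")
  }

  pair_sets <- lapply(results, function(r) {
    paste(r$mirna_id, r$mrna_id, sep = "\r")
  })
  keys <- if (mode == "union") {
    Reduce(union, pair_sets[selected])
  } else {
    Reduce(intersect, pair_sets[selected])
  }
  if (!length(keys)) {
    out <- tibble(mirna_id = character(), mrna_id = character())
    for (a in algs) out[[a]] <- logical()
    out$support <- integer()
    return(new_interaction_table(out, algs))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- tibble(mirna_id = vapply(parts, `[[`, "", 1),
                mrna_id = vapply(parts, `[[`, "", 2))
  for (a in algs) {
    out[[a]] <- keys %in% pair_sets[[a]]
    sc <- results[[a]]$score
    if (!all(is.na(sc))) {
      idx <- match(keys, pair_sets[[a]])
      out[[paste0("score_", a)]] <- sc[idx]
    }
  }
  out$support <- rowSums(as.matrix(out[algs]))
  if (!is.null(mirna_stats)) {
    out$fc_mirna <- mirna_stats$fc[match(out$mirna_id, mirna_stats$entity_id)]
  }
  if (!is.null(mrna_stats)) {
    out$fc_mrna <- mrna_stats$fc[match(out$mrna_id, mrna_stats$entity_id)]
  }
  out <- arrange(out, mirna_id, mrna_id)
  new_interaction_table(out, algs)
}

#' Construct an interaction table from a data frame
#'
#' Low-level constructor for a table with one row per (miRNA, mRNA) pair and
#' one logical support-flag column per algorithm; [combine_results()] is the
#' usual way to produce one. The `support` column is added if missing.
#'
#' @param df Data frame with `mirna_id`, `mrna_id` and the flag columns.
#' @param algorithms Names of the logical flag columns, in display order.
#' @return An `interaction_table` tibble.
#' @export
interaction_table <- function(df, algorithms) {
  df <- as_tibble(df)
  miss <- setdiff(c("mirna_id", "mrna_id", algorithms), names(df))
  if (length(miss)) stop_format("missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(vapply(df[algorithms], is.logical, logical(1)))) {
    stop_format("algorithm flag columns must be logical")
  }
  if (!"support" %in% names(df)) {
    df$support <- rowSums(as.matrix(df[algorithms]))
  }
  if (any(df$support < 1)) stop_format("every pair needs at least one TRUE flag")
  new_interaction_table(df, algorithms)
}

new_interaction_table <- function(df, algorithms) {
  out <- as_tibble(df)
  if (anyDuplicated(out[, c("mirna_id", "mrna_id")])) {
    stop_format("duplicate (miRNA, mRNA) pair in interaction table")
  }
  attr(out, "algorithms") <- algorithms
  class(out) <- c("interaction_table", class(out))
  out
}

#' Write an interaction table as TSV with TRUE/FALSE flags
#'
#' @param table An `interaction_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(table, path) {
  df <- as.data.frame(table)
  algs <- attr(table, "algorithms")
  for (a in algs) df[[a]] <- ifelse(df[[a]], "TRUE", "FALSE")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
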