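#' Signed fold change between two group means
#'
#' Reports the ratio of group means in the signed convention used throughout
#' differential-expression tables: `+r` means the second group is `r`-fold
#' above the first, `-r` means `r`-fold below, so `|fc| >= 1` always and equal
#' means give `+1`.
#'
#' @param mean_g1,mean_g2 Positive group means (vectorised).
#' @return Signed ratio(s).
#' @examples
#' signed_fold_change(4, 8)   # +2
#' signed_fold_change(8, 4)   # -2
#' @export
signed_fold_change <- function(mean_g1, mean_g2) {
  if (any(!is.finite(mean_g1)) || any(!is.finite(mean_g2)) ||
      any(mean_g1 <= 0) || any(mean_g2 <= 0)) {
    stop_domain("group means must be positive and finite")
  }
  ifelse(mean_g2 >= mean_g1, mean_g2 / mean_g1, -mean_g1 / mean_g2)
}

# signed fold change when means are on the log2 scale: 2^|diff| with the sign
# of the difference, +1 at equality
signed_fold_change_log2 <- function(mean_g1, mean_g2) {
  d <- mean_g2 - mean_g1
  ifelse(d >= 0, 2^d, -2^(-d))
}

#' Two-sample differential statistics per entity
#'
#' Computes, for every entity of a two-sample expression dataset, the group
#' means, t statistic, two-tailed p-value and signed fold change. Paired
#' designs use the paired t-test on per-pair differences; unpaired designs use
#' Welch's t-test (unequal variances). A `stats_only` dataset passes its
#' loaded statistics through unchanged.
#'
#' Entities with zero variance are handled as follows: if the group means are
#' also equal the entity is kept with `t = 0`, `p = 1`; otherwise the t
#' statistic is undefined and the entity is dropped with a warning (a
#' zero-variance difference with unequal means would otherwise produce an
#' artificial p of 0 and a spurious top hit).
#'
#' @param dataset An [expression_dataset()] of kind `paired2`, `unpaired2` or
#'   `stats_only`.
#' @param values_are_log2 If `TRUE`, expression values are treated as log2
#'   intensities: means are compared on the log scale and the fold change is
#'   `2^(mean difference)` in the signed convention.
#' @param adjust_p If `TRUE`, adds a Benjamini-Hochberg adjusted `p_adj`
#'   column (filtering still uses raw `p`).
#' @return A tibble with columns `entity_id`, `mean_g1`, `mean_g2`, `t`, `p`,
#'   `fc` (and optionally `p_adj`).
#' @examples
#' m <- rbind(a = c(1, 2, 3, 2, 3, 4))
#' colnames(m) <- paste0("s", 1:6)
#' ds <- expression_dataset(m, "mRNA", "paired2",
#'   groups = setNames(rep(c("G1", "G2"), each = 3), paste0("s", 1:6)),
#'   pairs = setNames(paste0("s", 4:6), paste0("s", 1:3)))
#' diff_stats(ds)
#' @export
diff_stats <- function(dataset, values_are_log2 = FALSE, adjust_p = FALSE) {
  stopifnot(is_expression_dataset(dataset))
  if (dataset$data_kind == "stats_only") return(dataset$stats)
  if (!dataset$data_kind %in% c("paired2", "unpaired2")) {
    stop_design("differential statistics need a two-sample dataset (got %s)",
                dataset$data_kind)
  }
  v <- dataset$values
  g1 <- names(dataset$groups)[dataset$groups == "G1"]
  g2 <- names(dataset$groups)[dataset$groups == "G2"]
  if (length(g1) < 2 || length(g2) < 2) {
    stop_design("need at least 2 samples per group")
  }

  if (dataset$data_kind == "paired2") {
    a <- v[, g1, drop = FALSE]
    b <- v[, dataset$pairs[g1], drop = FALSE]
    d <- b - a
    n <- ncol(d)
    md <- rowMeans(d)
    sdd <- apply(d, 1, sd)
    tt <- ifelse(sdd > 0, md / (sdd / sqrt(n)), ifelse(md == 0, 0, NA_real_))
    df <- n - 1
    m1 <- rowMeans(a); m2 <- rowMeans(b)
  } else {
    a <- v[, g1, drop = FALSE]
    b <- v[, g2, drop = FALSE]
    n1 <- ncol(a); n2 <- ncol(b)
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    v1 <- apply(a, 1, var); v2 <- apply(b, 1, var)
    se2 <- v1 / n1 + v2 / n2
    tt <- ifelse(se2 > 0, (m2 - m1) / sqrt(se2),
                 ifelse(m2 == m1, 0, NA_real_))
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 n1 + n2 - 2)
  }

  p <- ifelse(is.na(tt), NA_real_,
              ifelse(tt == 0, 1, 2 * pt(-abs(tt), df)))
  fc <- if (values_are_log2) signed_fold_change_log2(m1, m2) else signed_fold_change(m1, m2)

  out <- tibble(entity_id = dataset$entity_ids,
                mean_g1 = unname(m1), mean_g2 = unname(m2),
                t = unname(tt), p = unname(p), fc = unname(fc))
  drop <- is.na(out$t)
  if (any(drop)) {
    warn(sprintf("%d zero-variance entit%s with unequal means excluded: %s",
                 sum(drop), if (sum(drop) == 1) "y" else "ies",
                 paste(head(out$entity_id[drop], 5), collapse = ", ")))
    out <- out[!drop, ]
  }
  if (adjust_p) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Filter a two-sample statistics table by p-value and fold change
#'
#' Keeps entities significant at `p <= p_max` whose fold-change magnitude is
#' at least `min_abs_fc`; the conjunction of the two thresholds.
#'
#' @param stats A tibble as returned by [diff_stats()].
#' @param p_max Maximum raw two-tailed p-value, in (0, 1].
#' @param min_abs_fc Minimum `|fc|`, at least 1.
#' @return Character vector of retained entity ids.
#' @export
filter_two_sample <- function(stats, p_max = 0.05, min_abs_fc = 1) {
  if (!is.numeric(p_max) || p_max <= 0 || p_max > 1) {
    stop_param("p_max must lie in (0, 1]")
  }
  if (!is.numeric(min_abs_fc) || min_abs_fc < 1) {
    stop_param("min_abs_fc must be >= 1")
  }
  stats$entity_id[stats$p <= p_max & abs(stats$fc) >= min_abs_fc]
}

#' Filter a multisample dataset by mean expression
#'
#' Removes poorly expressed entities (e.g. rows whose expression is mostly
#' zero) by requiring the row mean to reach `min_mean`.
#'
#' @param dataset A `multisample` or `tcga` [expression_dataset()].
#' @param min_mean Minimum row mean.
#' @return Character vector of retained entity ids.
#' @export
filter_multisample <- function(dataset, min_mean = 0) {
  stopifnot(is_expression_dataset(dataset))
  if (!dataset$data_kind %in% c("multisample", "tcga")) {
    stop_design("mean-expression filtering applies to multisample/tcga data")
  }
  rm <- rowMeans(dataset$values)
  dataset$entity_ids[rm >= min_mean]
}
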