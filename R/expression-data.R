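#' Construct an expression dataset
#'
#' An `expression_dataset` bundles an entity-by-sample expression matrix with
#' the design metadata the downstream pipeline needs: what kind of entities the
#' rows are (miRNAs or mRNAs), which of the five supported data kinds the
#' matrix represents, the two-group assignment of samples and, for paired
#' designs, the sample pairing. A `stats_only` dataset carries no matrix at
#' all, only a per-entity table of p-values and signed fold changes.
#'
#' @param values Numeric matrix, entities in rows (rownames = entity ids),
#'   samples in columns (colnames = sample ids). `NULL` for `stats_only`.
#' @param entity_kind `"miRNA"` or `"mRNA"`.
#' @param data_kind One of `"paired2"`, `"unpaired2"`, `"stats_only"`,
#'   `"multisample"`, `"tcga"`.
#' @param groups Named character vector mapping sample id to `"G1"`/`"G2"`
#'   (two-sample kinds only).
#' @param pairs Named character vector mapping each G1 sample id to its G2
#'   partner (`paired2` only).
#' @param stats For `stats_only`: a tibble with columns `entity_id`, `p`, `fc`.
#' @return An object of class `expression_dataset`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
#' expression_dataset(m, "mRNA", "multisample")
#' @export
expression_dataset <- function(values, entity_kind, data_kind,
                               groups = NULL, pairs = NULL, stats = NULL) {
  entity_kind <- match.arg(entity_kind, c("miRNA", "mRNA"))
  data_kind <- match.arg(data_kind,
    c("paired2", "unpaired2", "stats_only", "multisample", "tcga"))

  if (data_kind == "stats_only") {
    if (!is.null(values)) stop_design("stats_only datasets carry no expression matrix")
    if (is.null(stats)) stop_design("stats_only datasets require a stats table")
    stats <- as_tibble(stats)
    need <- c("entity_id", "p", "fc")
    if (!all(need %in% names(stats))) {
      stop_format("stats table must have columns %s", paste(need, collapse = ", "))
    }
    if (anyDuplicated(stats$entity_id)) stop_format("duplicate entity id in stats table")
    if (any(!is.finite(stats$p)) || any(stats$p < 0 | stats$p > 1)) {
      stop_format("p-values must lie in [0, 1]")
    }
    if (any(!is.finite(stats$fc)) || any(abs(stats$fc) < 1)) {
      stop_format("signed fold changes must satisfy |fc| >= 1")
    }
    out <- structure(
      list(values = NULL, entity_kind = entity_kind, data_kind = data_kind,
           entity_ids = stats$entity_id, sample_ids = character(),
           groups = NULL, pairs = NULL, stats = stats),
      class = "expression_dataset")
    return(out)
  }

  if (!is.matrix(values) || !is.numeric(values)) {
    stop_format("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_format("values must have entity rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop_format("duplicate entity id: %s", dup)
  }
  if (anyDuplicated(colnames(values))) stop_format("duplicate sample id")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop_format("non-finite value at row %s, column %s",
                rownames(values)[bad[1]], colnames(values)[bad[2]])
  }

  if (data_kind %in% c("paired2", "unpaired2")) {
    if (is.null(groups)) stop_design("two-sample datasets require a group assignment")
    if (!setequal(names(groups), colnames(values))) {
      stop_design("group assignment must cover exactly the sample ids")
    }
    groups <- groups[colnames(values)]
    if (!all(groups %in% c("G1", "G2"))) stop_design("groups must be G1 or G2")
    n1 <- sum(groups == "G1"); n2 <- sum(groups == "G2")
    if (n1 == 0L || n2 == 0L) stop_design("both groups must be non-empty")
    if (data_kind == "paired2") {
      if (n1 != n2) stop_design("paired design needs equal group sizes (got %d vs %d)", n1, n2)
      g1 <- names(groups)[groups == "G1"]; g2 <- names(groups)[groups == "G2"]
      if (is.null(pairs)) stop_design("paired design requires a pairing")
      if (!setequal(names(pairs), g1) || !setequal(unname(pairs), g2) ||
          anyDuplicated(unname(pairs))) {
        stop_design("pairing must be a bijection between G1 and G2 samples")
      }
      pairs <- pairs[g1]
    } else {
      pairs <- NULL
    }
  } else {
    groups <- NULL; pairs <- NULL
  }

  structure(
    list(values = values, entity_kind = entity_kind, data_kind = data_kind,
         entity_ids = rownames(values), sample_ids = colnames(values),
         groups = groups, pairs = pairs, stats = NULL),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset: %s, %s, %d entities x %d samples>\n",
              x$entity_kind, x$data_kind, length(x$entity_ids),
              length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) {
  c(length(x$entity_ids), length(x$sample_ids))
}

#' @export
as_tibble.expression_dataset <- function(x, ...) {
  if (x$data_kind == "stats_only") return(x$stats)
  bind_cols(tibble(entity_id = x$entity_ids),
            as_tibble(x$values, .name_repair = "minimal"))
}

is_expression_dataset <- function(x) inherits(x, "expression_dataset")

#' Read an expression dataset from a TSV file
#'
#' The canonical on-disk dialect is a tab-separated file whose first column
#' holds the entity id and whose remaining columns are samples (header row =
#' sample ids). For the `stats_only` kind the file instead has one row per
#' entity with columns `p` (two-tailed p-value) and `fc` (signed fold change).
#' Group membership and pairing are supplied by the caller, not inferred from
#' the file. TCGA-style matrices are read the same way; their barcode columns
#' are matched across datasets with [match_tcga_samples()].
#'
#' @param path Path to a TSV file.
#' @param data_kind,entity_kind See [expression_dataset()].
#' @param groups,pairs Design declaration for two-sample kinds.
#' @return An [expression_dataset()].
#' @seealso [write_expression_dataset()]
#' @export
read_expression_dataset <- function(path, data_kind, entity_kind,
                                    groups = NULL, pairs = NULL) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  data_kind <- match.arg(data_kind,
    c("paired2", "unpaired2", "stats_only", "multisample", "tcga"))
  # cells are read as text and converted with R's correctly rounded parser,
  # so written datasets read back bit-identically
  df <- readr::read_tsv(path,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2) stop_format("expected at least an id column and one data column")

  if (data_kind == "stats_only") {
    nm <- tolower(names(df))
    pcol <- match(TRUE, nm %in% c("p", "p_value", "p-value", "pvalue"))
    fcol <- match(TRUE, nm %in% c("fc", "fold_change", "fold-change", "foldchange"))
    if (is.na(pcol) || is.na(fcol)) {
      stop_format("stats_only file needs a p-value and a fold-change column")
    }
    stats <- tibble(entity_id = as.character(df[[1]]),
                    p = as.numeric(df[[pcol]]),
                    fc = as.numeric(df[[fcol]]))
    ds <- expression_dataset(NULL, entity_kind, "stats_only", stats = stats)
    inform(sprintf("read %d entities (stats only) from %s", nrow(stats), path))
    return(ds)
  }

  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2, as.numeric))) &
                   !is.na(mat), arr.ind = TRUE)
    if (nrow(bad)) {
      stop_format("non-numeric cell at row %s, column %s",
                  ids[bad[1, 1]], colnames(mat)[bad[1, 2]])
    }
    mat <- apply(mat, 2, as.numeric)
  }
  rownames(mat) <- ids
  ds <- expression_dataset(mat, entity_kind, data_kind,
                           groups = groups, pairs = pairs)
  inform(sprintf("read %d entities x %d samples from %s",
                 nrow(mat), ncol(mat), path))
  ds
}

#' Write an expression dataset to the canonical TSV dialect
#'
#' @param dataset An [expression_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_dataset <- function(dataset, path) {
  stopifnot(is_expression_dataset(dataset))
  df <- if (dataset$data_kind == "stats_only") dataset$stats else as_tibble(dataset)
  # %.17g round-trips doubles exactly, so write/read preserves values bit-wise
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else col
  })
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Match TCGA-style barcode columns between two datasets
#'
#' TCGA sample barcodes identify the same specimen at a common prefix even
#' when the full barcodes differ between the miRNA and mRNA assays. Samples
#' are matched by truncating every barcode to `prefix_len` characters and
#' intersecting; both datasets are returned restricted to the shared
#' specimens, columns aligned in the same order and renamed to the prefix.
#'
#' @param mirna_ds,mrna_ds `tcga`-kind [expression_dataset()] objects.
#' @param prefix_len Barcode prefix length used for matching (default 15,
#'   the TCGA sample-level prefix).
#' @return A list with elements `mirna` and `mrna`.
#' @export
match_tcga_samples <- function(mirna_ds, mrna_ds, prefix_len = 15) {
  stopifnot(is_expression_dataset(mirna_ds), is_expression_dataset(mrna_ds))
  if (mirna_ds$data_kind != "tcga" || mrna_ds$data_kind != "tcga") {
    stop_design("barcode matching applies to tcga-kind datasets")
  }
  cut1 <- substr(mirna_ds$sample_ids, 1, prefix_len)
  cut2 <- substr(mrna_ds$sample_ids, 1, prefix_len)
  if (anyDuplicated(cut1) || anyDuplicated(cut2)) {
    stop_design("barcode prefix of length %d is not unique within a dataset", prefix_len)
  }
  shared <- intersect(cut1, cut2)
  if (!length(shared)) stop_design("no shared barcodes at prefix length %d", prefix_len)
  take <- function(ds, cut) {
    m <- ds$values[, match(shared, cut), drop = FALSE]
    colnames(m) <- shared
    expression_dataset(m, ds$entity_kind, "tcga")
  }
  list(mirna = take(mirna_ds, cut1), mrna = take(mrna_ds, cut2))
}
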