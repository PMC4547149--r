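#' Supported species for sequence target databases
#'
#' The nine species covered by the embedded conserved-target tables.
#' @export
sequence_db_species <- c("human", "mouse", "rat", "rhesus", "frog",
                         "dog", "cow", "chimpanzee", "chicken")

#' Read a sequence-based candidate target database
#'
#' Reads a TSV of sequence-predicted miRNA-target candidates in one of two
#' dialects. TargetScan-style tables carry `mirna_id`, `gene_symbol` and
#' `species` (conserved seed matches; no score). microRNA.org-style tables
#' additionally carry `mirsvr_score`, the regression score attached to each
#' prediction (more negative = stronger predicted down-regulation). Exact
#' duplicate records are dropped; an unrecognised species string triggers a
#' warning but the record is kept.
#'
#' @param path Path to a TSV file.
#' @param source `"targetscan"` or `"microrna_org"`.
#' @return A tibble of class `sequence_target_db` with columns `mirna_id`,
#'   `gene_symbol`, `species`, `source`, `score` (`NA` for targetscan).
#' @export
read_sequence_target_db <- function(path, source = c("targetscan", "microrna_org")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  need <- c("mirna_id", "gene_symbol", "species")
  if (source == "microrna_org") need <- c(need, "mirsvr_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_format("missing column(s): %s", paste(miss, collapse = ", "))
  score <- if (source == "microrna_org") as.numeric(df$mirsvr_score) else NA_real_
  db <- tibble(
    mirna_id = as.character(df$mirna_id),
    gene_symbol = as.character(df$gene_symbol),
    species = as.character(df$species),
    source = source,
    score = score
  )
  unknown <- setdiff(unique(db$species), sequence_db_species)
  if (length(unknown)) {
    warn(sprintf("unknown species kept: %s", paste(unknown, collapse = ", ")))
  }
  db <- distinct(db, mirna_id, .data$gene_symbol, .data$species, source,
                 .keep_all = TRUE)
  inform(sprintf("read %d %s candidate records from %s", nrow(db), source, path))
  class(db) <- c("sequence_target_db", class(db))
  db
}

#' Turn a sequence database into a prediction result
#'
#' Collapses a candidate database to its unique (miRNA, gene) pairs so that
#' sequence evidence can be combined with expression-based predictions. The
#' pairs carry no association score: in the combined interaction table they
#' act as boolean support columns.
#'
#' @param db A `sequence_target_db` tibble (or any tibble with `mirna_id` and
#'   `gene_symbol` columns).
#' @param algorithm Name recorded for the evidence column, default taken from
#'   the `source` column.
#' @return A `prediction_result` tibble (`mirna_id`, `mrna_id`, `score = NA`).
#' @export
sequence_prediction <- function(db, algorithm = NULL) {
  if (is.null(algorithm)) {
    algorithm <- if ("source" %in% names(db)) db$source[1] else "sequence"
  }
  out <- db |>
    transmute(mirna_id = .data$mirna_id, mrna_id = .data$gene_symbol,
              score = NA_real_) |>
    distinct(mirna_id, mrna_id, .keep_all = TRUE)
  new_prediction_result(out, algorithm)
}
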