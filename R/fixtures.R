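#' Published fibroblast case-study interaction tables
#'
#' Interaction tables from a published case study in which miRNAs carried by
#' obese visceral adipocyte-derived exosomes were profiled together with mRNA
#' responses of human airway fibroblasts from a nonasthmatic and an asthmatic
#' donor. Each table has one row per predicted (miRNA, mRNA) pair with a
#' TRUE/FALSE support flag per prediction algorithm (Pearson correlation,
#' GenMiR++ Bayesian inference, MINE/MIC, TargetScan, microRNA.org), the shape
#' produced by [combine_results()]. The tables are shipped verbatim as
#' packaged TSV files.
#'
#' @return A named list of two `interaction_table` tibbles,
#'   `nonasthmatic` (45 pairs) and `asthmatic` (61 pairs), each with columns
#'   `mirna_id`, `mrna_id`, the five algorithm flags, and `support`.
#' @examples
#' fx <- fibroblast_interactions()
#' nrow(fx$nonasthmatic)
#' shared_target_genes(fx)
#' @export
fibroblast_interactions <- function() {
  read_one <- function(name) {
    path <- system.file("extdata", name, package = "mirtarget", mustWork = TRUE)
    df <- readr::read_tsv(path, col_types = "cclllll", progress = FALSE,
                          show_col_types = FALSE)
    algs <- c("correlation", "genmir", "mine", "targetscan", "microrna_org")
    df$support <- rowSums(as.matrix(df[algs]))
    new_interaction_table(df, algs)
  }
  list(nonasthmatic = read_one("fibroblast_nonasthmatic_interactions.tsv"),
       asthmatic = read_one("fibroblast_asthmatic_interactions.tsv"))
}

#' Target genes shared between interaction tables
#'
#' Intersects the mRNA sets of two or more interaction tables; used in the
#' case study to find genes targeted under both conditions.
#'
#' @param tables A list of `interaction_table` tibbles.
#' @return Sorted character vector of shared mRNA ids.
#' @export
shared_target_genes <- function(tables) {
  stopifnot(length(tables) >= 2)
  sets <- lapply(tables, function(t) unique(t$mrna_id))
  sort(Reduce(intersect, sets))
}
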