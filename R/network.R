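#' Build the bipartite miRNA-target network
#'
#' Converts an interaction table into a bipartite network: one node per
#' miRNA and per mRNA, one edge per table row, with edge `support` equal to
#' the number of algorithms that predicted the pair (this drives link width
#' in the node-link rendering). Node fold changes are carried over when the
#' table has `fc_mirna` / `fc_mrna` columns.
#'
#' @param table A non-empty `interaction_table`.
#' @return An object of class `mirtar_network` with elements `mirna_nodes`,
#'   `mrna_nodes`, `edges` (tibble: `mirna_id`, `mrna_id`, `support`,
#'   `algorithms` list-column) and `node_fc` (named numeric or `NULL`).
#' @export
build_network <- function(table) {
  tbl <- as_tibble(table)
  if (!nrow(tbl)) stop_design("cannot build a network from an empty interaction table")
  if (anyDuplicated(tbl[, c("mirna_id", "mrna_id")])) {
    stop_format("duplicate (miRNA, mRNA) pair")
  }
  algs <- attr(table, "algorithms")
  if (is.null(algs)) {
    algs <- intersect(names(tbl)[vapply(tbl, is.logical, logical(1))], names(tbl))
  }
  flags <- as.matrix(tbl[, algs, drop = FALSE])
  support <- if ("support" %in% names(tbl)) tbl$support else rowSums(flags)
  if (any(support < 1)) stop_design("every edge needs support from at least one algorithm")
  edges <- tibble(
    mirna_id = tbl$mirna_id, mrna_id = tbl$mrna_id,
    support = as.integer(support),
    algorithms = lapply(seq_len(nrow(flags)), function(i) algs[flags[i, ]]))

  node_fc <- NULL
  if (all(c("fc_mirna", "fc_mrna") %in% names(tbl))) {
    node_fc <- c(
      setNames(tbl$fc_mirna, tbl$mirna_id)[!duplicated(tbl$mirna_id)],
      setNames(tbl$fc_mrna, tbl$mrna_id)[!duplicated(tbl$mrna_id)])
  }
  structure(list(mirna_nodes = sort(unique(tbl$mirna_id)),
                 mrna_nodes = sort(unique(tbl$mrna_id)),
                 edges = edges, node_fc = node_fc),
            class = "mirtar_network")
}

#' @export
print.mirtar_network <- function(x, ...) {
  cat(sprintf("<mirtar_network: %d miRNAs, %d mRNAs, %d edges>\n",
              length(x$mirna_nodes), length(x$mrna_nodes), nrow(x$edges)))
  invisible(x)
}

is_mirtar_network <- function(x) inherits(x, "mirtar_network")

#' Convert a bipartite network to an igraph object
#'
#' @param network A `mirtar_network`.
#' @return An [igraph::graph] with vertex attribute `type` (`"miRNA"` /
#'   `"mRNA"`) and edge attribute `support`.
#' @export
as_igraph <- function(network) {
  stopifnot(is_mirtar_network(network))
  verts <- tibble(
    name = c(network$mirna_nodes, network$mrna_nodes),
    type = rep(c("miRNA", "mRNA"),
               c(length(network$mirna_nodes), length(network$mrna_nodes))))
  igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$mirna_id, to = network$edges$mrna_id,
                   support = network$edges$support),
    directed = FALSE, vertices = as.data.frame(verts))
}

#' Common targets of a set of miRNAs
#'
#' Intersects the neighbour (target) sets of the selected miRNAs; mRNAs
#' regulated by all of them are often of particular biological interest.
#'
#' @param network A `mirtar_network`.
#' @param mirna_ids miRNA node ids.
#' @return Sorted character vector of common target mRNA ids.
#' @export
common_targets <- function(network, mirna_ids) {
  stopifnot(is_mirtar_network(network))
  unknown <- setdiff(mirna_ids, network$mirna_nodes)
  if (length(unknown)) {
    abort(sprintf("unknown miRNA node(s): %s", paste(unknown, collapse = ", ")),
          class = "mirtarget_lookup_error")
  }
  sets <- lapply(mirna_ids, function(m) {
    network$edges$mrna_id[network$edges$mirna_id == m]
  })
  sort(Reduce(intersect, sets))
}

#' Map signed fold changes to diverging colors
#'
#' Two-sample networks colour nodes by fold change: up-regulation in red,
#' down-regulation in blue, with saturation encoding the fold-change
#' magnitude — `(|fc| - 1) / (cap - 1)` clamped to \[0, 1\], so an unchanged
#' entity (`fc = +1`) is white and `|fc| >= cap` is fully saturated.
#'
#' @param fc Signed fold change(s) (`|fc| >= 1` convention).
#' @param cap Fold change at full saturation (> 1, default 4).
#' @return Character vector of hex colours.
#' @examples
#' fold_change_color(c(1, 2.31, -2.47), cap = 4)
#' @export
fold_change_color <- function(fc, cap = 4) {
  if (!is.numeric(cap) || cap <= 1) stop_param("cap must be > 1")
  s <- pmin(pmax((abs(fc) - 1) / (cap - 1), 0), 1)
  up <- fc >= 0
  grDevices::rgb(ifelse(up, 1, 1 - s), 1 - s, ifelse(up, 1 - s, 1))
}

#' Fixed node colours for multisample networks
#'
#' Multisample data have no fold change, so nodes take fixed hues: miRNAs in
#' orange and mRNAs in dark blue.
#' @export
multisample_node_colors <- c(miRNA = "#E69500", mRNA = "#00008B")

#' Export a network to GraphML
#'
#' @param network A `mirtar_network`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Export a network as node and edge TSV tables
#'
#' @param network A `mirtar_network`.
#' @param nodes_path,edges_path Output paths.
#' @return A character vector of the two paths, invisibly.
#' @export
write_network_tsv <- function(network, nodes_path, edges_path) {
  nodes <- tibble(
    id = c(network$mirna_nodes, network$mrna_nodes),
    type = rep(c("miRNA", "mRNA"),
               c(length(network$mirna_nodes), length(network$mrna_nodes))))
  if (!is.null(network$node_fc)) nodes$fc <- network$node_fc[nodes$id]
  readr::write_tsv(nodes, nodes_path, progress = FALSE)
  edges <- network$edges
  edges$algorithms <- vapply(edges$algorithms, paste, "", collapse = ",")
  readr::write_tsv(edges, edges_path, progress = FALSE)
  invisible(c(nodes_path, edges_path))
}
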