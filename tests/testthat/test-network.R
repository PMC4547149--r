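star_table <- function(n_leaves, extra = NULL) {
  df <- tibble::tibble(mirna_id = "hub",
                       mrna_id = paste0("g", seq_len(n_leaves)),
                       alg_a = TRUE, alg_b = FALSE)
  if (!is.null(extra)) df <- dplyr::bind_rows(df, extra)
  interaction_table(df, c("alg_a", "alg_b"))
}

test_that("networks mirror the interaction table", {
  net <- build_network(star_table(3))
  expect_length(net$mirna_nodes, 1)
  expect_length(net$mrna_nodes, 3)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$support == 1))

  tab4 <- interaction_table(
    tibble::tibble(mirna_id = "m", mrna_id = "g",
                   a = TRUE, b = TRUE, c = TRUE, d = TRUE),
    c("a", "b", "c", "d"))
  expect_equal(build_network(tab4)$edges$support, 4)

  dup <- tibble::tibble(mirna_id = c("m", "m"), mrna_id = c("g", "g"),
                        a = TRUE)
  expect_error(interaction_table(dup, "a"), class = "mirtarget_format_error")
  empty <- interaction_table(
    tibble::tibble(mirna_id = character(), mrna_id = character(),
                   alg_a = logical()), "alg_a")
  expect_error(build_network(empty), class = "mirtarget_design_error")
})

test_that("common targets intersect neighbour sets", {
  tab <- interaction_table(
    tibble::tibble(mirna_id = c("m1", "m1", "m2", "m2"),
                   mrna_id = c("g1", "g2", "g2", "g3"), a = TRUE), "a")
  net <- build_network(tab)
  expect_identical(common_targets(net, c("m1", "m2")), "g2")
  expect_identical(common_targets(net, "m1"), c("g1", "g2"))
  tab2 <- interaction_table(
    tibble::tibble(mirna_id = c("m1", "m2"), mrna_id = c("g1", "g2"),
                   a = TRUE), "a")
  expect_length(common_targets(build_network(tab2), c("m1", "m2")), 0)
  expect_error(common_targets(net, "m9"), class = "mirtarget_lookup_error")
})

test_that("fold-change colours saturate red/blue away from white", {
  expect_identical(fold_change_color(1), "#FFFFFF")
  expect_identical(fold_change_color(4, cap = 4), "#FF0000")
  expect_identical(fold_change_color(-4, cap = 4), "#0000FF")
  expect_identical(fold_change_color(9, cap = 4), "#FF0000")  # clamped

  sat <- function(fc) {
    rgbv <- grDevices::col2rgb(fold_change_color(fc, cap = 4)) / 255
    1 - min(rgbv)
  }
  expect_gt(sat(3), sat(1.5))
  expect_error(fold_change_color(2, cap = 1), class = "mirtarget_parameter_error")
})

test_that("exports carry node types and support weights", {
  net <- build_network(star_table(2))
  g <- as_igraph(net)
  expect_setequal(igraph::V(g)$type, c("miRNA", "mRNA"))
  expect_equal(sort(igraph::E(g)$support), c(1, 1))

  tf <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, tf)
  back <- igraph::read_graph(tf, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::ecount(back), 2)

  nf <- withr::local_tempfile(fileext = ".tsv")
  ef <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, nf, ef)
  edges <- readr::read_tsv(ef, show_col_types = FALSE)
  expect_named(edges, c("mirna_id", "mrna_id", "support", "algorithms"))
})
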