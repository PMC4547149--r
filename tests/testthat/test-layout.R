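leaf_geometry <- function(layout, hub, leaves) {
  pos <- as.data.frame(layout)
  rownames(pos) <- pos$node
  ctr <- unlist(pos[hub, c("x", "y")])
  rel <- t(vapply(leaves, function(l) {
    unlist(pos[l, c("x", "y")]) - ctr
  }, numeric(2)))
  list(radii = sqrt(rowSums(rel^2)),
       angles = sort(atan2(rel[, 2], rel[, 1])))
}

test_that("circular layout spaces all nodes evenly", {
  net <- build_network(random_interaction_table(3, 8, 12))
  lay <- layout_network(net, "circular", seed = 4)
  n <- nrow(lay)
  # equally spaced points on a full circle have their centroid at the centre
  ctr <- c(mean(lay$x), mean(lay$y))
  r <- sqrt((lay$x - ctr[1])^2 + (lay$y - ctr[2])^2)
  expect_equal(max(r) - min(r), 0, tolerance = 1e-9)
  ang <- sort(atan2(lay$y - ctr[2], lay$x - ctr[1]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  expect_equal(unname(gaps), rep(2 * pi / n, n), tolerance = 1e-9)
})

test_that("the modified ISOM scatters degree-1 targets around their miRNA", {
  tab <- interaction_table(
    tibble::tibble(mirna_id = "hub", mrna_id = paste0("g", 1:6), a = TRUE), "a")
  net <- build_network(tab)
  lay <- layout_network(net, "isom_modified", seed = 7)
  geo <- leaf_geometry(lay, "hub", paste0("g", 1:6))
  expect_equal(max(geo$radii) - min(geo$radii), 0, tolerance = 1e-9)
  gaps <- diff(c(geo$angles, geo$angles[1] + 2 * pi))
  expect_equal(unname(gaps), rep(pi / 3, 6), tolerance = 1e-9)
  # no coincident positions anywhere
  expect_equal(nrow(dplyr::distinct(lay[, c("x", "y")])), nrow(lay))
})

test_that("multi-star networks keep every star circular and distinct", {
  tab <- interaction_table(
    tibble::tibble(
      mirna_id = rep(c("mA", "mB", "mC"), times = c(5, 4, 3)),
      mrna_id = paste0("g", 1:12), a = TRUE), "a")
  net <- build_network(tab)
  lay <- layout_network(net, "isom_modified", seed = 2)
  for (hub in c("mA", "mB", "mC")) {
    leaves <- net$edges$mrna_id[net$edges$mirna_id == hub]
    geo <- leaf_geometry(lay, hub, leaves)
    expect_equal(max(geo$radii) - min(geo$radii), 0, tolerance = 1e-9)
    gaps <- diff(c(geo$angles, geo$angles[1] + 2 * pi))
    expect_equal(unname(gaps), rep(2 * pi / length(leaves), length(leaves)),
                 tolerance = 1e-9)
  }
  expect_equal(nrow(dplyr::distinct(lay[, c("x", "y")])), nrow(lay))
})

test_that("layouts are deterministic and stay in the unit square", {
  net <- build_network(random_interaction_table(4, 10, 14))
  for (m in c("circular", "force_directed", "kk", "isom_modified")) {
    l1 <- layout_network(net, m, seed = 5)
    l2 <- layout_network(net, m, seed = 5)
    expect_identical(l1, l2)
    expect_true(all(l1$x >= -1e-9 & l1$x <= 1 + 1e-9))
    expect_true(all(l1$y >= -1e-9 & l1$y <= 1 + 1e-9))
    expect_true(all(is.finite(l1$x) & is.finite(l1$y)))
  }
  expect_error(layout_network(net, "spring"))
})
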