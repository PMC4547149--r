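mk_stats <- function(ids, fc) {
  tibble::tibble(entity_id = ids, mean_g1 = 1, mean_g2 = 1, t = 0, p = 0.01,
                 fc = fc)
}

test_that("direction options follow the fold-change signs", {
  ms <- mk_stats("mir", 2.31)
  gs <- mk_stats("ACVR2B", -1.18)
  pair <- tibble::tibble(mirna_id = "mir", mrna_id = "ACVR2B")
  expect_equal(nrow(direction_filter(pair, ms, gs, "up_mir_down_mrna")), 1)
  expect_equal(nrow(direction_filter(pair, ms, gs, "down_mir_up_mrna")), 0)
  expect_equal(nrow(direction_filter(pair, ms, gs, "opposite")), 1)
  expect_equal(nrow(direction_filter(pair, option = "all")), 1)
  expect_error(direction_filter(pair, ms, mk_stats("other", 2), "opposite"),
               class = "mirtarget_design_error")
  # unchanged entities (fc = +1) match no directional option
  expect_equal(nrow(direction_filter(pair, mk_stats("mir", 1), gs,
                                     "up_mir_down_mrna")), 0)
})

test_that("'opposite' equals the union of the one-sided options", {
  set.seed(55)
  for (i in 1:100) {
    ms <- random_stats_table(8, "m")
    gs <- random_stats_table(8, "g")
    pairs <- tidyr::expand_grid(mirna_id = ms$entity_id,
                                mrna_id = gs$entity_id)
    up <- direction_filter(pairs, ms, gs, "up_mir_down_mrna")
    dn <- direction_filter(pairs, ms, gs, "down_mir_up_mrna")
    op <- direction_filter(pairs, ms, gs, "opposite")
    expect_setequal(paste(op$mirna_id, op$mrna_id),
                    union(paste(up$mirna_id, up$mrna_id),
                          paste(dn$mirna_id, dn$mrna_id)))
  }
})

test_that("selection honours ordering, thresholds and saturation", {
  sc <- mirtarget:::new_score_table(
    tibble::tibble(mirna_id = c("a", "b", "c"), mrna_id = "g",
                   score = c(-0.9, -0.2, 0.5)),
    "pearson", list())
  top1 <- select_interactions(sc, top_n = 1)
  expect_identical(top1$mirna_id, "a")  # most negative first

  mic_sc <- mirtarget:::new_score_table(
    tibble::tibble(mirna_id = c("p", "q"), mrna_id = "g",
                   score = c(0.7, 0.5)), "mic", list())
  thr <- select_interactions(mic_sc, threshold = 0.6)
  expect_identical(thr$mirna_id, "p")

  all3 <- select_interactions(sc, top_n = 10)
  expect_equal(nrow(all3), 3)
  expect_error(select_interactions(sc, top_n = 1, threshold = 0),
               class = "mirtarget_parameter_error")

  # deterministic tie-break by pair id
  tied <- mirtarget:::new_score_table(
    tibble::tibble(mirna_id = c("z", "a"), mrna_id = c("g", "g"),
                   score = c(0.5, 0.5)), "mic", list())
  expect_identical(select_interactions(tied, top_n = 1)$mirna_id, "a")

  # threshold mode is monotone in the threshold
  set.seed(6)
  sc2 <- mirtarget:::new_score_table(
    tibble::tibble(mirna_id = paste0("m", 1:50), mrna_id = "g",
                   score = runif(50)), "mic", list())
  n1 <- nrow(select_interactions(sc2, threshold = 0.7))
  n2 <- nrow(select_interactions(sc2, threshold = 0.3))
  expect_lte(n1, n2)
})

test_that("combining keeps flags for all algorithms", {
  pr <- function(alg, mirs, genes) {
    mirtarget:::new_prediction_result(
      tibble::tibble(mirna_id = mirs, mrna_id = genes, score = NA_real_), alg)
  }
  res <- list(
    correlation = pr("correlation", "hp_hsa-mir-3118-5_x_st", "ACVR2B"),
    genmir = pr("genmir", "hp_hsa-mir-3118-5_x_st", "ACVR2B"),
    mine = pr("mine", "other", "OTHER"),
    targetscan = pr("targetscan", "hp_hsa-mir-3118-5_x_st", "ACVR2B"),
    microrna_org = pr("microrna_org", "other", "OTHER"))

  tab <- combine_results(res, "intersection",
                         selected = c("correlation", "genmir", "targetscan"))
  expect_equal(nrow(tab), 1)
  expect_identical(
    unlist(tab[1, c("correlation", "genmir", "mine", "targetscan",
                    "microrna_org")], use.names = FALSE),
    c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(tab$support, 3)

  none <- combine_results(res, "intersection")
  expect_equal(nrow(none), 0)

  un <- combine_results(res[c("mine", "correlation")], "union")
  expect_equal(nrow(un), 2)
  expect_true(all(un$support == 1))

  # intersection is contained in union; both idempotent on one result
  set.seed(8)
  r1 <- pr("a", paste0("m", sample(5, 8, TRUE)), paste0("g", 1:8))
  r2 <- pr("b", paste0("m", sample(5, 8, TRUE)), paste0("g", sample(8)))
  both <- list(a = r1, b = r2)
  ti <- combine_results(both, "intersection")
  tu <- combine_results(both, "union")
  expect_true(all(paste(ti$mirna_id, ti$mrna_id) %in%
                    paste(tu$mirna_id, tu$mrna_id)))
  expect_equal(nrow(combine_results(list(a = r1), "intersection")), nrow(r1))
  expect_error(combine_results(both, "intersection", selected = character(0)),
               class = "mirtarget_design_error")
})
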