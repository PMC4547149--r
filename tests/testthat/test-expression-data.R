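test_that("canonical TSV parses to an identical matrix", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  m <- matrix(c(1.5, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), 3, 4,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  writeLines(c(paste(c("id", paste0("s", 1:4)), collapse = "\t"),
               vapply(rownames(m), function(r) {
                 paste(c(r, m[r, ]), collapse = "\t")
               }, "")), tf)
  ds <- suppressMessages(read_expression_dataset(tf, "multisample", "mRNA"))
  expect_identical(ds$entity_ids, c("a", "b", "c"))
  expect_identical(ds$sample_ids, paste0("s", 1:4))
  expect_equal(unname(ds$values), unname(m))
  expect_identical(dim(ds), c(3L, 4L))
})

test_that("stats-only files load p and fold change without a matrix", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tp\tfc", "g1\t0.01\t2.5", "g2\t0.8\t-1.3"), tf)
  ds <- suppressMessages(read_expression_dataset(tf, "stats_only", "mRNA"))
  expect_null(ds$values)
  expect_equal(ds$stats$p, c(0.01, 0.8))
  expect_equal(ds$stats$fc, c(2.5, -1.3))
  expect_identical(diff_stats(ds), ds$stats)
})

test_that("format violations are rejected with informative errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "a\t1\t2", "a\t3\t4"), tf)
  expect_error(suppressMessages(read_expression_dataset(tf, "multisample", "mRNA")),
               class = "mirtarget_format_error")

  m <- matrix(c(1, NA, 3, 4), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_dataset(m, "mRNA", "multisample"),
               class = "mirtarget_format_error")
})

test_that("paired designs demand a bijection with equal group sizes", {
  m <- matrix(1:12, 2, 6, dimnames = list(c("a", "b"), paste0("s", 1:6)))
  groups_bad <- setNames(c("G1", "G1", "G1", "G1", "G2", "G2"), paste0("s", 1:6))
  expect_error(expression_dataset(m, "miRNA", "paired2", groups = groups_bad,
                                  pairs = c(s1 = "s5", s2 = "s6")),
               class = "mirtarget_design_error")
  groups <- setNames(rep(c("G1", "G2"), each = 3), paste0("s", 1:6))
  expect_error(expression_dataset(m, "miRNA", "paired2", groups = groups,
                                  pairs = c(s1 = "s4", s2 = "s4", s3 = "s6")),
               class = "mirtarget_design_error")
  ok <- expression_dataset(m, "miRNA", "paired2", groups = groups,
                           pairs = c(s1 = "s4", s2 = "s5", s3 = "s6"))
  expect_s3_class(ok, "expression_dataset")
})

test_that("write/read round trip preserves ids, kind and values exactly", {
  b <- generate_synthetic(synthetic_config(n_mirna = 6, n_mrna = 9,
                                           n_samples = 5, n_true_pairs = 4,
                                           seed = 99))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_expression_dataset(b$mrna_ds, tf)
  back <- suppressMessages(read_expression_dataset(tf, "multisample", "mRNA"))
  expect_identical(back$entity_ids, b$mrna_ds$entity_ids)
  expect_identical(back$sample_ids, b$mrna_ds$sample_ids)
  expect_identical(back$values, b$mrna_ds$values)
})

test_that("TCGA barcodes match across assays by configurable prefix", {
  mk <- function(cols, kind) {
    m <- matrix(seq_len(2 * length(cols)), 2, length(cols),
                dimnames = list(c("e1", "e2"), cols))
    expression_dataset(m, kind, "tcga")
  }
  mir <- mk(c("TCGA-AB-0001-01A-x", "TCGA-AB-0002-01A-x"), "miRNA")
  rna <- mk(c("TCGA-AB-0002-01B-y", "TCGA-AB-0003-01A-z"), "mRNA")
  res <- match_tcga_samples(mir, rna, prefix_len = 12)
  expect_identical(res$mirna$sample_ids, "TCGA-AB-0002")
  expect_identical(res$mrna$sample_ids, "TCGA-AB-0002")
  expect_error(match_tcga_samples(mir, rna, prefix_len = 7),
               class = "mirtarget_design_error")
})
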