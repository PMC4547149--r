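test_that("signed fold change follows the +r/-r convention", {
  expect_equal(signed_fold_change(4, 8), 2)
  expect_equal(signed_fold_change(8, 4), -2)
  expect_equal(signed_fold_change(5, 5), 1)
  expect_error(signed_fold_change(0, 1), class = "mirtarget_domain_error")

  # antisymmetry and |fc| >= 1 on random positive means
  set.seed(41)
  a <- runif(200, 0.1, 20); b <- runif(200, 0.1, 20)
  fab <- signed_fold_change(a, b)
  expect_true(all(abs(fab) >= 1))
  uneq <- a != b
  expect_equal(fab[uneq], -signed_fold_change(b, a)[uneq])
})

test_that("paired statistics match the t distribution", {
  ds0 <- make_two_sample_ds(rbind(e = c(1, 2, 3, 1, 2, 3)), "paired2")
  st0 <- diff_stats(ds0)
  expect_equal(st0$t, 0)
  expect_equal(st0$p, 1)
  expect_equal(st0$fc, 1)

  g1 <- c(1, 2, 3, 4); g2 <- c(2.1, 3.0, 4.2, 5.1)
  ds <- make_two_sample_ds(rbind(e = c(g1, g2)), "paired2")
  st <- diff_stats(ds)
  oracle <- t.test(g2, g1, paired = TRUE)
  expect_equal(st$t, unname(oracle$statistic))
  expect_equal(st$p, oracle$p.value)
  expect_equal(st$p, 2 * pt(-abs(st$t), df = 3))
})

test_that("unpaired statistics agree with Welch's t-test on random data", {
  ds1 <- make_two_sample_ds(rbind(e = c(10, 10, 10, 20, 20, 20)), "unpaired2")
  expect_warning(st1 <- diff_stats(ds1), "zero-variance")
  expect_equal(nrow(st1), 0)  # zero variance, unequal means: excluded

  set.seed(7)
  m <- matrix(rlnorm(5 * 10, 1, 0.4), 5, 10,
              dimnames = list(paste0("e", 1:5), NULL))
  ds <- make_two_sample_ds(m, "unpaired2")
  st <- diff_stats(ds)
  for (i in 1:5) {
    o <- t.test(m[i, 6:10], m[i, 1:5], var.equal = FALSE)
    expect_equal(st$t[i], unname(o$statistic))
    expect_equal(st$p[i], o$p.value)
  }
  expect_equal(st$fc,
               unname(signed_fold_change(rowMeans(m[, 1:5]), rowMeans(m[, 6:10]))))
})

test_that("fold change uses group means (and log2 mode exponentiates)", {
  m <- rbind(e = c(10, 12, 8, 21, 19, 20))
  st <- diff_stats(make_two_sample_ds(m, "unpaired2"))
  expect_equal(st$fc, 2)
  stl <- diff_stats(make_two_sample_ds(m, "unpaired2"), values_are_log2 = TRUE)
  expect_equal(stl$fc, 2^(20 - 10))
})

test_that("two-sample filtering is a conjunction and is monotone", {
  stats <- tibble::tibble(entity_id = c("A", "B"),
                          mean_g1 = 1, mean_g2 = 1, t = 0,
                          p = c(0.01, 0.2), fc = c(2, 3))
  expect_identical(filter_two_sample(stats, 0.05, 1), "A")
  expect_identical(filter_two_sample(stats, 0.05, 2.5), character(0))
  expect_identical(filter_two_sample(stats, 1, 1), c("A", "B"))

  set.seed(11)
  for (i in 1:20) {
    st <- random_stats_table(30)
    p1 <- runif(1); p2 <- min(1, p1 + runif(1))
    f2 <- runif(1, 1, 4); f1 <- runif(1, 1, f2)
    expect_true(all(filter_two_sample(st, p1, f2) %in%
                      filter_two_sample(st, p2, f1)))
  }
})

test_that("multisample filtering keeps rows by mean expression", {
  m <- rbind(a = rep(0, 4), b = c(0.1, 0.1, 0.1, 0.1), c = rep(5, 4))
  colnames(m) <- paste0("s", 1:4)
  ds <- expression_dataset(m, "mRNA", "multisample")
  expect_identical(filter_multisample(ds, 1), "c")
  expect_identical(filter_multisample(ds, 0), c("a", "b", "c"))
  z <- expression_dataset(matrix(0, 2, 3,
        dimnames = list(c("a", "b"), paste0("s", 1:3))), "mRNA", "multisample")
  expect_identical(filter_multisample(z, 0.5), character(0))
})
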