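elbo_nondecreasing <- function(fit) {
  d <- diff(fit$elbo_trace)
  length(d) == 0 || all(d >= -1e-8 * pmax(abs(fit$elbo_trace[-1]), 1))
}

test_that("an empty candidate map yields an empty fit without iterations", {
  b <- generate_synthetic(synthetic_config(n_mirna = 2, n_mrna = 2,
                                           n_samples = 5, n_true_pairs = 1,
                                           seed = 1))
  fit <- genmir_fit(b$mirna_ds, b$mrna_ds,
                    tibble::tibble(mirna_id = character(),
                                   mrna_id = character()))
  expect_equal(nrow(fit$beta), 0)
  expect_length(fit$elbo_trace, 0)
  expect_true(fit$converged)

  expect_error(
    genmir_fit(b$mirna_ds, b$mrna_ds,
               tibble::tibble(mirna_id = "nope", mrna_id = "gene0001")),
    class = "mirtarget_design_error")
})

test_that("a strongly planted single pair gets posterior near one", {
  cfg <- synthetic_config(n_mirna = 1, n_mrna = 1, n_samples = 30,
                          n_true_pairs = 1, gamma_true = 1, noise_sd = 0.1,
                          seed = 11)
  b <- generate_synthetic(cfg)
  fit <- genmir_fit(b$mirna_ds, b$mrna_ds, b$true_pairs)
  expect_gt(fit$beta$beta, 0.95)
  expect_true(elbo_nondecreasing(fit))
})

test_that("beta ranking separates planted pairs from decoys", {
  cfg <- synthetic_config(n_mirna = 10, n_mrna = 60, n_samples = 30,
                          n_true_pairs = 10, decoy_candidates_per_true = 9,
                          gamma_true = 1, noise_sd = 0.3, seed = 5)
  b <- generate_synthetic(cfg)
  cand <- tibble::tibble(mirna_id = b$candidate_db$mirna_id,
                         mrna_id = b$candidate_db$gene_symbol)
  fit <- genmir_fit(b$mirna_ds, b$mrna_ds, cand)
  expect_true(elbo_nondecreasing(fit))
  expect_true(fit$converged)

  td <- tidy(fit)
  lab <- paste(td$mirna_id, td$mrna_id) %in%
    paste(b$true_pairs$mirna_id, b$true_pairs$mrna_id)
  a <- mirtarget:::auroc(td$beta, lab)
  expect_gte(a, 0.9)
  # cross-check the rank AUROC against an independent implementation
  expect_equal(a, as.numeric(suppressMessages(
    pROC::auc(pROC::roc(lab, td$beta, quiet = TRUE)))))

  g <- glance(fit)
  expect_equal(g$n_pairs, 100)
  expect_true(g$converged)
})

test_that("a vanishing prior shrinks all posteriors on pure-noise profiles", {
  set.seed(19)
  samp <- paste0("s", 1:20)
  Z <- matrix(rlnorm(5 * 20, 1, 0.5), 5, 20,
              dimnames = list(paste0("m", 1:5), samp))
  X <- matrix(rlnorm(8 * 20, 2, 0.5), 8, 20,
              dimnames = list(paste0("g", 1:8), samp))
  mir <- expression_dataset(Z, "miRNA", "multisample")
  rna <- expression_dataset(X, "mRNA", "multisample")
  cand <- tidyr::expand_grid(mirna_id = rownames(Z), mrna_id = rownames(X))
  fit <- genmir_fit(mir, rna, cand,
                    config = genmir_config(pi = 1e-5, init_gamma = 0))
  expect_lt(max(fit$beta$beta), 0.01)
  expect_true(elbo_nondecreasing(fit))
})

test_that("relabelling miRNAs permutes the posteriors identically", {
  cfg <- synthetic_config(n_mirna = 6, n_mrna = 15, n_samples = 12,
                          n_true_pairs = 6, seed = 33)
  b <- generate_synthetic(cfg)
  cand <- tibble::tibble(mirna_id = b$candidate_db$mirna_id,
                         mrna_id = b$candidate_db$gene_symbol)
  fit1 <- genmir_fit(b$mirna_ds, b$mrna_ds, cand)

  relab <- setNames(paste0("XX_", rev(b$mirna_ds$entity_ids)),
                    b$mirna_ds$entity_ids)
  mir2 <- b$mirna_ds
  rownames(mir2$values) <- relab[rownames(mir2$values)]
  mir2$entity_ids <- unname(relab[mir2$entity_ids])
  cand2 <- dplyr::mutate(cand, mirna_id = unname(relab[mirna_id]))
  fit2 <- genmir_fit(mir2, b$mrna_ds, cand2)

  expect_identical(unname(relab[fit1$beta$mirna_id]), fit2$beta$mirna_id)
  expect_equal(fit1$beta$beta, fit2$beta$beta)
})

test_that("regulatory weights are recovered on model-generated data", {
  set.seed(77)
  K <- 8; J <- 40; Tn <- 25
  samp <- paste0("s", 1:Tn)
  gamma_true <- runif(K, 0.5, 2)
  Z <- matrix(rlnorm(K * Tn, 1, 0.5), K, Tn,
              dimnames = list(paste0("m", 1:K), samp))
  X <- matrix(0, J, Tn, dimnames = list(paste0("g", 1:J), samp))
  reg <- sample(K, J, replace = TRUE)  # one true regulator per mRNA
  for (j in 1:J) {
    X[j, ] <- 12 - gamma_true[reg[j]] * Z[reg[j], ] + rnorm(Tn, 0, 0.3)
  }
  X[X < 1e-3] <- 1e-3
  mir <- expression_dataset(Z, "miRNA", "multisample")
  rna <- expression_dataset(X, "mRNA", "multisample")
  cand <- tibble::tibble(mirna_id = paste0("m", reg), mrna_id = paste0("g", 1:J))
  fit <- genmir_fit(mir, rna, cand,
                    config = genmir_config(standardize = FALSE))
  got <- fit$gamma$gamma[match(paste0("m", 1:K), fit$gamma$mirna_id)]
  expect_gt(cor(got, gamma_true, method = "spearman"), 0.7)
})
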