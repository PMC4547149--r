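#' Configuration for the synthetic expression-bundle generator
#'
#' The generator emulates the down-regulation model the pipeline is built to
#' recover: miRNA profiles are drawn i.i.d. lognormal, and each mRNA with
#' planted regulators is repressed additively by them plus Gaussian noise.
#' Defaults describe a mid-sized microarray-style experiment: 50 miRNAs, 500
#' mRNAs, 20 samples, 50 planted regulations of unit effect size with noise
#' standard deviation 0.3, and 9 decoy candidate pairs per true pair.
#'
#' @param n_mirna,n_mrna,n_samples Dimensions (for `mode = "paired2"`,
#'   `n_samples` is the number of sample *pairs*).
#' @param n_true_pairs Number of planted (miRNA, mRNA) regulations; at most
#'   `n_mirna * n_mrna`.
#' @param gamma_true Repression effect size per planted pair (default 1).
#' @param noise_sd Gaussian noise standard deviation (default 0.3).
#' @param mode `"multisample"` or `"paired2"`.
#' @param decoy_candidates_per_true Decoy candidate pairs per true pair in
#'   the generated candidate database (default 9).
#' @param planted_fc Fold change planted on regulated entities in `paired2`
#'   mode: group-2 values of planted miRNAs are multiplied by `planted_fc`
#'   and of their targets divided by it (default 2).
#' @param seed Integer seed; all randomness derives from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_mirna = 50, n_mrna = 500, n_samples = 20,
                             n_true_pairs = 50, gamma_true = 1,
                             noise_sd = 0.3, mode = c("multisample", "paired2"),
                             decoy_candidates_per_true = 9, planted_fc = 2,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (n_true_pairs > n_mirna * n_mrna) {
    stop_param("n_true_pairs cannot exceed n_mirna * n_mrna")
  }
  if (any(c(n_mirna, n_mrna, n_samples, n_true_pairs) < 1) ||
      gamma_true <= 0 || noise_sd <= 0 || decoy_candidates_per_true < 0 ||
      planted_fc <= 1) {
    stop_param("invalid synthetic configuration")
  }
  structure(list(n_mirna = n_mirna, n_mrna = n_mrna, n_samples = n_samples,
                 n_true_pairs = n_true_pairs, gamma_true = gamma_true,
                 noise_sd = noise_sd, mode = mode,
                 decoy_candidates_per_true = decoy_candidates_per_true,
                 planted_fc = planted_fc, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic miRNA-mRNA bundle with planted regulation
#'
#' Draws miRNA profiles `z_k` i.i.d. lognormal; each mRNA `j` gets
#' `x_j = baseline_j - sum(gamma_true * z_k)` over its planted regulators
#' plus `N(0, noise_sd^2)` noise, floored at `1e-3` so fold-change ratios
#' stay defined. Planted pairs therefore show negative expression
#' association by construction. In `paired2` mode each planted miRNA is
#' additionally up-regulated in group 2 by `planted_fc` and each planted
#' target down-regulated by the same factor, so directional filters can be
#' exercised end to end. The candidate database contains every true pair
#' plus the configured number of decoys, in TargetScan-style form.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_bundle` list: `mirna_ds`, `mrna_ds`
#'   ([expression_dataset()]s sharing sample ids), `true_pairs` (tibble
#'   `mirna_id`, `mrna_id`), `candidate_db` (a `sequence_target_db`-shaped
#'   tibble covering true pairs and decoys), and `config`.
#' @examples
#' b <- generate_synthetic(synthetic_config(n_mirna = 5, n_mrna = 20,
#'   n_samples = 10, n_true_pairs = 5, seed = 42))
#' b$mirna_ds
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    K <- config$n_mirna; J <- config$n_mrna
    paired <- config$mode == "paired2"
    Tn <- if (paired) 2L * config$n_samples else config$n_samples

    mir_ids <- sprintf("mir%03d", seq_len(K))
    gene_ids <- sprintf("gene%04d", seq_len(J))
    samp_ids <- if (paired) {
      c(sprintf("G1_s%02d", seq_len(config$n_samples)),
        sprintf("G2_s%02d", seq_len(config$n_samples)))
    } else sprintf("s%02d", seq_len(Tn))

    Z <- matrix(rlnorm(K * Tn, meanlog = 1, sdlog = 0.5), K, Tn,
                dimnames = list(mir_ids, samp_ids))

    # planted pairs: sample cells of the K x J grid without replacement
    cells <- sample.int(K * J, config$n_true_pairs)
    tp_k <- ((cells - 1L) %% K) + 1L
    tp_j <- ((cells - 1L) %/% K) + 1L
    true_pairs <- tibble(mirna_id = mir_ids[tp_k], mrna_id = gene_ids[tp_j])

    baseline <- rlnorm(J, meanlog = 2.3, sdlog = 0.3)
    X <- matrix(rnorm(J * Tn, 0, config$noise_sd), J, Tn,
                dimnames = list(gene_ids, samp_ids)) + baseline
    for (i in seq_len(config$n_true_pairs)) {
      X[tp_j[i], ] <- X[tp_j[i], ] - config$gamma_true * Z[tp_k[i], ]
    }

    groups <- NULL; pairs <- NULL
    if (paired) {
      g2 <- (config$n_samples + 1L):Tn
      Z[unique(tp_k), g2] <- Z[unique(tp_k), g2] * config$planted_fc
      X[unique(tp_j), g2] <- X[unique(tp_j), g2] / config$planted_fc
      groups <- setNames(rep(c("G1", "G2"), each = config$n_samples), samp_ids)
      pairs <- setNames(samp_ids[g2], samp_ids[seq_len(config$n_samples)])
    }
    X[X < 1e-3] <- 1e-3
    Z[Z < 1e-3] <- 1e-3

    kind <- if (paired) "paired2" else "multisample"
    mirna_ds <- expression_dataset(Z, "miRNA", kind, groups = groups, pairs = pairs)
    mrna_ds <- expression_dataset(X, "mRNA", kind, groups = groups, pairs = pairs)

    # candidate database: true pairs plus decoys drawn from the complement
    n_decoy <- config$n_true_pairs * config$decoy_candidates_per_true
    pool <- setdiff(seq_len(K * J), cells)
    dec <- if (n_decoy > 0) sample(pool, min(n_decoy, length(pool))) else integer()
    cand_cells <- c(cells, dec)
    candidate_db <- tibble(
      mirna_id = mir_ids[((cand_cells - 1L) %% K) + 1L],
      gene_symbol = gene_ids[((cand_cells - 1L) %/% K) + 1L],
      species = "human", source = "targetscan", score = NA_real_,
      is_true = c(rep(TRUE, length(cells)), rep(FALSE, length(dec))))

    structure(list(mirna_ds = mirna_ds, mrna_ds = mrna_ds,
                   true_pairs = true_pairs, candidate_db = candidate_db,
                   config = config),
              class = "synthetic_bundle")
  })
}

#' Write a synthetic bundle to TSV files
#'
#' Emits the canonical expression TSVs, the candidate database and the
#' ground-truth pair list into a directory.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mirna = file.path(dir, "mirna_expression.tsv"),
    mrna = file.path(dir, "mrna_expression.tsv"),
    candidates = file.path(dir, "candidate_db.tsv"),
    truth = file.path(dir, "true_pairs.tsv"))
  write_expression_dataset(bundle$mirna_ds, paths["mirna"])
  write_expression_dataset(bundle$mrna_ds, paths["mrna"])
  readr::write_tsv(bundle$candidate_db, paths["candidates"], progress = FALSE)
  readr::write_tsv(bundle$true_pairs, paths["truth"], progress = FALSE)
  invisible(paths)
}
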