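# Independent oracles and small data builders used across the suite.

# exhaustive MIC: enumerate every axis-aligned grid of shape p x q with
# p * q <= ceiling(n^alpha), p, q >= 2 (cuts on ranks, all positions), and
# maximise grid mutual information / log2(min(p, q)). Independent of the
# package's clump/DP machinery.
brute_force_mic <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- ceiling(n^alpha)
  rx <- rank(x, ties.method = "first")
  ry <- rank(y, ties.method = "first")
  binnings <- function(r, p) {
    cuts <- combn(n - 1, p - 1, simplify = FALSE)
    lapply(cuts, function(ct) findInterval(r, ct + 0.5) + 1L)
  }
  grid_i <- function(xb, yb, p, q) {
    joint <- tabulate((xb - 1L) * q + yb, p * q) / n
    px <- tapply(joint, rep(seq_len(p), each = q), sum)
    py <- tapply(joint, rep(seq_len(q), times = p), sum)
    ind <- px[rep(seq_len(p), each = q)] * py[rep(seq_len(q), times = p)]
    nz <- joint > 0
    sum(joint[nz] * log2(joint[nz] / ind[nz]))
  }
  best <- 0
  for (p in 2:floor(B / 2)) {
    for (q in 2:floor(B / p)) {
      xbs <- binnings(rx, p)
      ybs <- binnings(ry, q)
      nrm <- log2(min(p, q))
      for (xb in xbs) {
        for (yb in ybs) {
          v <- grid_i(xb, yb, p, q) / nrm
          if (v > best) best <- v
        }
      }
    }
  }
  best
}

# direct-counting KSG estimator (method 1): naive double loop, no shortcuts
brute_force_ksg <- function(x, y, k) {
  n <- length(x)
  out <- numeric(n)
  nx <- integer(n); ny <- integer(n)
  for (i in seq_len(n)) {
    dj <- pmax(abs(x - x[i]), abs(y - y[i]))[-i]
    eps <- sort(dj)[k]
    nx[i] <- sum(abs(x - x[i])[-i] < eps)
    ny[i] <- sum(abs(y - y[i])[-i] < eps)
  }
  digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
}

# random differential-statistics table with mixed up/down/unchanged entities
random_stats_table <- function(n, prefix = "e") {
  fc <- sample(c(runif(n, 1, 4), -runif(n, 1, 4), rep(1, ceiling(n / 5))), n)
  tibble::tibble(
    entity_id = paste0(prefix, seq_len(n)),
    mean_g1 = runif(n, 1, 10), mean_g2 = runif(n, 1, 10),
    t = rnorm(n), p = runif(n), fc = fc)
}

# random bipartite interaction table / network
random_interaction_table <- function(n_mir, n_mrna, n_edges) {
  grid <- tidyr::expand_grid(
    mirna_id = paste0("m", seq_len(n_mir)),
    mrna_id = paste0("g", seq_len(n_mrna)))
  rows <- grid[sample(nrow(grid), min(n_edges, nrow(grid))), ]
  rows$alg_a <- TRUE
  rows$alg_b <- runif(nrow(rows)) < 0.5
  interaction_table(rows, c("alg_a", "alg_b"))
}

make_two_sample_ds <- function(mat, kind = "unpaired2", entity_kind = "mRNA") {
  n <- ncol(mat) / 2
  samp <- paste0("s", seq_len(ncol(mat)))
  colnames(mat) <- samp
  groups <- setNames(rep(c("G1", "G2"), each = n), samp)
  pairs <- if (kind == "paired2") setNames(samp[(n + 1):(2 * n)], samp[1:n])
           else NULL
  expression_dataset(mat, entity_kind, kind, groups = groups, pairs = pairs)
}

expect_id_set_equal <- function(a, b) expect_setequal(a, b)
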