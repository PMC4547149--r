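# internal helpers shared across modules

# run `code` under a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# deterministic integer seed derived from numeric data (for tie-breaking jitter)
data_hash_seed <- function(...) {
  v <- unlist(list(...), use.names = FALSE)
  v <- v[is.finite(v)]
  if (!length(v)) return(1L)
  r <- rank(v, ties.method = "average")
  s <- sum(r * (seq_along(r) %% 97 + 1)) + length(v) * 131
  as.integer(abs(s) %% 2147483587) + 1L
}

stop_format <- function(msg, ...) abort(sprintf(msg, ...), class = "mirtarget_format_error")
stop_design <- function(msg, ...) abort(sprintf(msg, ...), class = "mirtarget_design_error")
stop_domain <- function(msg, ...) abort(sprintf(msg, ...), class = "mirtarget_domain_error")
stop_param  <- function(msg, ...) abort(sprintf(msg, ...), class = "mirtarget_parameter_error")
stop_capability <- function(msg, ...) abort(sprintf(msg, ...), class = "mirtarget_capability_error")

# rank-based AUROC of `score` for binary labels (TRUE = positive).
# Equivalent to the Mann-Whitney U statistic scaled to [0, 1].
auroc <- function(score, label) {
  stopifnot(length(score) == length(label))
  pos <- as.logical(label)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
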