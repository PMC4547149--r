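#' Maximal information coefficient (MIC)
#'
#' Computes the MIC of a paired sample: the maximum, over axis-aligned grids
#' whose shape p x q satisfies `p * q <= B(n) = ceiling(n^alpha)` and
#' `p, q >= 2`, of the grid mutual information normalised by
#' `log2(min(p, q))` (logs base 2 throughout). MIC lies in \[0, 1\], reaches 1
#' for noiseless functional relationships and 0 when either variable is
#' constant.
#'
#' For every grid shape the best grid is sought in two ways and the larger
#' value kept:
#' \itemize{
#'   \item \emph{exact}: when the number of cut-point sets on the axis with
#'     fewer bins is small (`choose(n - 1, s - 1) <= exact_limit`), all
#'     partitions of that axis are enumerated and the other axis is optimised
#'     by dynamic programming over clump boundaries, which is provably optimal
#'     for a fixed partition of the first axis. This finds the true best grid
#'     of the shape.
#'   \item \emph{equipartition heuristic}: one axis is equipartitioned (ties
#'     assigned to the lower bin) and the other optimised by the same dynamic
#'     programme over at most `c * p` candidate clump boundaries; both axis
#'     orientations are tried. This is the standard approximation used for
#'     large grids.
#' }
#'
#' @param x,y Numeric vectors of equal length `n >= 8`.
#' @param alpha Grid-size exponent in (0, 1], default 0.6.
#' @param c Candidate-clump factor (>= 1, default 15) for the heuristic path.
#' @param exact_limit Maximum number of enumerated cut sets per shape before
#'   falling back to the heuristic (default 2000).
#' @return MIC in \[0, 1\].
#' @examples
#' x <- seq_len(100)
#' mic(x, x^3)        # noiseless monotone: 1
#' mic(x, rep(1, 100))  # constant: 0
#' @export
mic <- function(x, y, alpha = 0.6, c = 15, exact_limit = 2000) {
  if (length(x) != length(y)) stop_param("x and y must have equal length")
  n <- length(x)
  if (n < 8) stop_param("MIC needs at least 8 points (got %d)", n)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) stop_param("alpha must lie in (0, 1]")
  if (!is.numeric(c) || c < 1) stop_param("c must be >= 1")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(0)

  B <- ceiling(n^alpha)
  if (B < 4) return(0)
  rx <- rank(x, ties.method = "first")
  ry <- rank(y, ties.method = "first")

  best <- 0
  for (p in 2:floor(B / 2)) {
    qmax <- floor(B / p)
    if (qmax < p) break
    for (q in p:qmax) {
      norm <- log2(p)
      iv <- if (choose(n - 1, p - 1) <= exact_limit) {
        max(mic_exact_shape(rx, ry, p, q),
            mic_exact_shape(ry, rx, p, q))
      } else {
        max(mic_heuristic_shape(x, y, rx, ry, p, q, c),
            mic_heuristic_shape(y, x, ry, rx, p, q, c))
      }
      best <- max(best, iv / norm)
    }
  }
  min(best, 1)
}

# exact optimum over grids with exactly s bins on the u axis (enumerated)
# and up to f bins on the v axis (dynamic programme); ru, rv are the
# tie-broken ranks of the two variables
mic_exact_shape <- function(ru, rv, s, f) {
  n <- length(ru)
  ord <- order(rv)
  ruo <- ru[ord]  # u ranks in v order
  cuts <- combn(n - 1, s - 1, simplify = FALSE)
  bestI <- 0
  for (ct in cuts) {
    ub <- findInterval(ruo, c(ct + 0.5)) + 1L  # u bin of each point, v-sorted
    bestI <- max(bestI, mic_dp(ub, s, f, max_clumps = Inf))
  }
  bestI
}

# ApproxMaxMI-style: equipartition u into q bins, optimise v into <= p bins;
# both (q, p) role assignments of the unordered shape are tried
mic_heuristic_shape <- function(u, v, ru, rv, p, q, c) {
  ordv <- order(rv)
  out <- 0
  for (cfg in list(c(q, p), c(p, q))) {
    nb <- cfg[1]; maxl <- cfg[2]
    ub <- mic_equipartition(u, nb)
    if (length(unique(ub)) < 2) next
    out <- max(out, mic_dp(ub[ordv], nb, maxl, max_clumps = c * maxl))
  }
  out
}

# equal-count bins on one axis; tied values all fall in the lower bin
mic_equipartition <- function(v, q) {
  n <- length(v)
  ord <- order(v)
  vals <- v[ord]
  bins <- integer(n)
  b <- 1L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && vals[j + 1L] == vals[i]) j <- j + 1L
    bins[ord[i:j]] <- b
    if (j >= ceiling(b * n / q) && b < q) b <- b + 1L
    i <- j + 1L
  }
  bins
}

# Optimal partition of the free axis given fixed bins on the other axis.
# `ub`: fixed-axis bin label of every point, listed in free-axis order.
# Returns max I (bits) over partitions of the free axis into <= maxl bins
# with boundaries restricted to clump edges (lossless for the optimum).
mic_dp <- function(ub, q, maxl, max_clumps = Inf) {
  cpp_mic_dp(as.integer(ub), as.integer(q), as.integer(maxl),
             if (is.finite(max_clumps)) as.integer(max_clumps) else 0L)
}
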