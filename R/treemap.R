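#' Two-level treemap layout of a miRNA-target network
#'
#' Converts the bipartite network into a two-level hierarchy — each miRNA is
#' the parent of its target mRNAs — and tiles it with the squarified
#' algorithm. The area of a miRNA tile is proportional to its number of
#' targets; within a parent, all mRNA leaves have equal area. An mRNA
#' targeted by several miRNAs appears once under each parent, so the leaf
#' count equals the edge count of the network.
#'
#' @param network A `mirtar_network`.
#' @param width,height Positive canvas dimensions.
#' @return A `treemap_layout` tibble with columns `id`, `parent` (`NA` for
#'   miRNA tiles), `x`, `y`, `w`, `h`, `depth` (0 = miRNA, 1 = mRNA leaf);
#'   origin top-left, y downward. Attribute `canvas = c(width, height)`.
#' @examples
#' tbl <- tibble::tibble(mirna_id = c("m1", "m1", "m2"),
#'                       mrna_id = c("g1", "g2", "g1"), alg = TRUE)
#' net <- build_network(interaction_table(tbl, "alg"))
#' treemap_layout(net, 400, 300)
#' @export
treemap_layout <- function(network, width, height) {
  stopifnot(is_mirtar_network(network))
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0) {
    stop_param("canvas dimensions must be positive")
  }
  counts <- table(network$edges$mirna_id)
  mirnas <- names(sort(counts, decreasing = TRUE))
  areas <- as.numeric(counts[mirnas]) / sum(counts) * width * height

  parents <- squarify(areas, 0, 0, width, height)
  parents$id <- mirnas

  leaves <- purrr::map_dfr(seq_along(mirnas), function(i) {
    kids <- sort(network$edges$mrna_id[network$edges$mirna_id == mirnas[i]])
    pr <- parents[i, ]
    la <- rep(pr$w * pr$h / length(kids), length(kids))
    lf <- squarify(la, pr$x, pr$y, pr$w, pr$h)
    lf$id <- kids
    lf$parent <- mirnas[i]
    lf
  })

  out <- bind_rows(
    tibble(id = parents$id, parent = NA_character_, x = parents$x,
           y = parents$y, w = parents$w, h = parents$h, depth = 0L),
    tibble(id = leaves$id, parent = leaves$parent, x = leaves$x,
           y = leaves$y, w = leaves$w, h = leaves$h, depth = 1L))
  attr(out, "canvas") <- c(width = width, height = height)
  class(out) <- c("treemap_layout", class(out))
  out
}

# squarified treemap: lay rectangles of the given areas (any order) into the
# box (x, y, w, h), greedily extending a row along the shorter side while the
# worst aspect ratio improves. Returns a data frame x, y, w, h per area.
squarify <- function(areas, x, y, w, h) {
  n <- length(areas)
  out <- matrix(0, n, 4)
  i <- 1L
  while (i <= n) {
    short <- min(w, h)
    row <- areas[i]
    j <- i
    worst <- squarify_worst(row, short)
    while (j < n) {
      cand <- c(row, areas[j + 1L])
      cw <- squarify_worst(cand, short)
      if (cw <= worst) {
        row <- cand; j <- j + 1L; worst <- cw
      } else break
    }
    thick <- sum(row) / short
    off <- 0
    for (t in seq_along(row)) {
      len <- row[t] / thick
      if (w >= h) {
        out[i + t - 1L, ] <- c(x, y + off, thick, len)
      } else {
        out[i + t - 1L, ] <- c(x + off, y, len, thick)
      }
      off <- off + len
    }
    if (w >= h) {
      x <- x + thick; w <- w - thick
    } else {
      y <- y + thick; h <- h - thick
    }
    i <- j + 1L
  }
  data.frame(x = out[, 1], y = out[, 2], w = out[, 3], h = out[, 4])
}

# worst aspect ratio of a candidate row laid along a side of length `short`
squarify_worst <- function(row, short) {
  s <- sum(row)
  thick <- s / short
  lens <- row / thick
  max(pmax(lens / thick, thick / lens))
}

#' Write a treemap layout as TSV
#'
#' @param layout A `treemap_layout`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_treemap_tsv <- function(layout, path) {
  readr::write_tsv(as_tibble(layout), path, progress = FALSE)
  invisible(path)
}
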