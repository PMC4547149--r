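#' Node-link layout of a bipartite network
#'
#' Computes 2-D coordinates for every node under one of four layouts:
#' \describe{
#'   \item{`circular`}{all nodes equally spaced on one circle.}
#'   \item{`force_directed`}{Fruchterman-Reingold force simulation.}
#'   \item{`kk`}{Kamada-Kawai stress minimisation on graph distances.}
#'   \item{`isom_modified`}{an inverted self-organizing-map embedding
#'     followed by a radial post-pass: for every miRNA, its degree-1 mRNA
#'     neighbours — which a topology-only embedding would pile onto one
#'     point — are re-placed at equal angular spacing on a circle around the
#'     miRNA. The scatter radius is 0.35 times the distance to the nearest
#'     other miRNA (floor 0.02 in unit coordinates; a lone miRNA uses 0.25).}
#' }
#' Disconnected components are laid out separately and packed on a grid.
#' Coordinates are normalised (aspect-preserving) to the unit square with the
#' screen convention: origin top-left, y growing downward.
#'
#' @param network A `mirtar_network`.
#' @param method One of `"isom_modified"`, `"kk"`, `"force_directed"`,
#'   `"circular"`.
#' @param seed Integer seed; the layout is deterministic given
#'   `(network, method, seed)`.
#' @return A `node_layout` tibble (`node`, `type`, `x`, `y`) with attributes
#'   `method` and `seed`.
#' @export
layout_network <- function(network,
                           method = c("isom_modified", "kk",
                                      "force_directed", "circular"),
                           seed = 1L) {
  method <- match.arg(method)
  stopifnot(is_mirtar_network(network))
  g <- as_igraph(network)
  n <- igraph::vcount(g)

  if (method == "circular") {
    nm <- igraph::V(g)$name
    ang <- 2 * pi * (seq_len(n) - 1) / n
    xy <- cbind(0.5 + 0.5 * cos(ang), 0.5 + 0.5 * sin(ang))
    rownames(xy) <- nm
  } else {
    comps <- igraph::components(g)
    mats <- lapply(seq_len(comps$no), function(ci) {
      sub <- igraph::induced_subgraph(g, which(comps$membership == ci))
      xy <- component_layout(sub, method, seed + ci - 1L)
      if (method == "isom_modified") {
        xy <- isom_post_pass(sub, normalize_unit(xy))
      }
      normalize_unit(xy)
    })
    xy <- pack_components(mats)
  }

  xy <- normalize_unit(xy)
  xy <- deoverlap(xy)
  out <- tibble(node = rownames(xy),
                type = igraph::V(g)$type[match(rownames(xy), igraph::V(g)$name)],
                x = xy[, 1], y = xy[, 2])
  attr(out, "method") <- method
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("node_layout", class(out))
  out
}

component_layout <- function(sub, method, seed) {
  nm <- igraph::V(sub)$name
  nv <- length(nm)
  if (nv == 1L) {
    xy <- matrix(0.5, 1, 2)
  } else if (method == "force_directed") {
    xy <- with_local_seed(seed, igraph::layout_with_fr(sub))
  } else if (method == "kk") {
    xy <- with_local_seed(seed, igraph::layout_with_kk(sub))
  } else {
    xy <- isom_embed(sub, seed)
  }
  rownames(xy) <- nm
  xy
}

# inverted self-organizing-map embedding: nodes start at random positions;
# repeatedly, a random point in the plane attracts its closest node and that
# node's graph neighbourhood, with radius and learning rate cooling over
# epochs. Topology-aware but prone to collapsing degree-1 leaves onto their
# hub, which the post-pass corrects.
isom_embed <- function(g, seed, epochs = 60L) {
  nv <- igraph::vcount(g)
  dist_g <- igraph::distances(g)
  with_local_seed(seed, {
    pos <- matrix(runif(2 * nv), nv, 2)
    iters_per_epoch <- max(10L, nv)
    for (ep in seq_len(epochs)) {
      frac <- ep / epochs
      radius <- max(0, round(3 * (1 - frac)))
      rate <- 0.8 * (1 - frac) + 0.05
      for (i in seq_len(iters_per_epoch)) {
        target <- runif(2)
        d2 <- (pos[, 1] - target[1])^2 + (pos[, 2] - target[2])^2
        w <- which.min(d2)
        nbh <- which(dist_g[w, ] <= radius)
        adapt <- rate * 2^(-dist_g[w, nbh])
        pos[nbh, ] <- pos[nbh, , drop = FALSE] +
          adapt * (matrix(target, length(nbh), 2, byrow = TRUE) -
                     pos[nbh, , drop = FALSE])
      }
    }
    pos
  })
}

# re-place every miRNA's degree-1 mRNA neighbours on a circle around it
isom_post_pass <- function(g, xy) {
  type <- igraph::V(g)$type
  nm <- igraph::V(g)$name
  deg <- igraph::degree(g)
  mir_idx <- which(type == "miRNA")
  mir_pos <- xy[mir_idx, , drop = FALSE]
  for (mi in mir_idx) {
    nb <- as.integer(igraph::neighbors(g, mi))
    leaves <- nb[type[nb] == "mRNA" & deg[nb] == 1L]
    if (!length(leaves)) next
    if (length(mir_idx) > 1L) {
      others <- mir_pos[mir_idx != mi, , drop = FALSE]
      dmin <- min(sqrt((others[, 1] - xy[mi, 1])^2 +
                         (others[, 2] - xy[mi, 2])^2))
      r <- max(0.35 * dmin, 0.02)
    } else {
      r <- 0.25
    }
    leaves <- leaves[order(nm[leaves])]
    ang <- 2 * pi * (seq_along(leaves) - 1) / length(leaves)
    xy[leaves, 1] <- xy[mi, 1] + r * cos(ang)
    xy[leaves, 2] <- xy[mi, 2] + r * sin(ang)
  }
  xy
}

# aspect-preserving rescale into the unit square
normalize_unit <- function(xy) {
  rng_x <- range(xy[, 1]); rng_y <- range(xy[, 2])
  span <- max(rng_x[2] - rng_x[1], rng_y[2] - rng_y[1])
  if (span == 0) {
    xy[, 1] <- 0.5; xy[, 2] <- 0.5
    return(xy)
  }
  xy[, 1] <- (xy[, 1] - mean(rng_x)) / span + 0.5
  xy[, 2] <- (xy[, 2] - mean(rng_y)) / span + 0.5
  xy
}

# place each component's unit-square layout into a grid cell; a single
# uniform scale for both axes keeps the post-pass circles circular
pack_components <- function(mats) {
  k <- length(mats)
  if (k == 1L) return(mats[[1]])
  ncol_g <- ceiling(sqrt(k))
  nrow_g <- ceiling(k / ncol_g)
  s <- 1 / max(ncol_g, nrow_g)
  out <- do.call(rbind, lapply(seq_len(k), function(i) {
    cell_x <- (i - 1) %% ncol_g
    cell_y <- (i - 1) %/% ncol_g
    m <- mats[[i]]
    m[, 1] <- (m[, 1] * 0.9 + 0.05 + cell_x) * s
    m[, 2] <- (m[, 2] * 0.9 + 0.05 + cell_y) * s
    m
  }))
  out
}

# guarantee distinct positions: spread exact duplicates on a tiny circle
deoverlap <- function(xy, eps = 1e-6) {
  key <- paste(round(xy[, 1] / eps), round(xy[, 2] / eps))
  dup_groups <- split(seq_len(nrow(xy)), key)
  for (gset in dup_groups) {
    if (length(gset) > 1L) {
      ang <- 2 * pi * (seq_along(gset) - 1) / length(gset)
      xy[gset, 1] <- xy[gset, 1] + 5 * eps * cos(ang)
      xy[gset, 2] <- xy[gset, 2] + 5 * eps * sin(ang)
    }
  }
  xy
}
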