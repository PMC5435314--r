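#' Fruchterman-Reingold force-directed layout
#'
#' Places nodes in a rectangular frame by simulating spring-like forces:
#' adjacent nodes attract with magnitude d^2/k, all pairs repel with
#' magnitude k^2/d, where d is the current distance and k = C *
#' sqrt(area / n) is the ideal edge length. Displacements are capped by a
#' temperature that cools linearly from `width / 10` to zero, and positions
#' are clipped to the frame after every step. Because adjacent nodes are
#' drawn near each other, densely connected modules emerge as spatially
#' proximate clusters — on sparse anatomical graphs the drawing itself
#' reveals the modular, proximal-distal organization.
#'
#' @param net an [anat_network] with at least one node.
#' @param width,height frame dimensions (default unit square).
#' @param iterations number of cooling steps (default 500).
#' @param C scaling constant for the ideal distance (default 1).
#' @param seed integer seed for the initial random placement.
#' @return Object of class `anat_layout`: a data frame with columns `id`,
#'   `x`, `y`; coordinates lie inside the frame and are fully determined by
#'   the arguments.
#' @examples
#' coords <- fruchterman_reingold(frog_hindlimb(), seed = 1)
#' head(coords, 3)
#' @export
fruchterman_reingold <- function(net, width = 1, height = 1,
                                 iterations = 500L, C = 1, seed = 1L) {
  stopifnot(net$n >= 1, width > 0, height > 0, iterations >= 1)
  n <- net$n
  rng <- local_rng(seed)
  pos <- cbind(rng$unif(n, 0, width), rng$unif(n, 0, height))
  k <- C * sqrt(width * height / n)
  ei <- node_index(net, net$edges[, 1])
  ej <- node_index(net, net$edges[, 2])
  temp <- width / 10
  cool <- temp / iterations
  eps <- 1e-9
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, 2)
    # repulsion: all pairs
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    d <- sqrt(dx^2 + dy^2)
    coincident <- d < eps & upper.tri(d)
    if (any(coincident)) {
      jit <- rng$unif(2 * sum(coincident), -eps, eps)
      idx <- which(coincident, arr.ind = TRUE)
      pos[idx[, 1], ] <- pos[idx[, 1], , drop = FALSE] +
        matrix(jit, ncol = 2)
      dx <- outer(pos[, 1], pos[, 1], "-")
      dy <- outer(pos[, 2], pos[, 2], "-")
      d <- sqrt(dx^2 + dy^2)
    }
    d[d < eps] <- eps
    f <- k^2 / d^2   # (k^2 / d) / d: force over distance, applied to (dx, dy)
    diag(f) <- 0
    disp[, 1] <- rowSums(f * dx)
    disp[, 2] <- rowSums(f * dy)
    # attraction: adjacent pairs
    if (net$m > 0) {
      ddx <- pos[ei, 1] - pos[ej, 1]
      ddy <- pos[ei, 2] - pos[ej, 2]
      dd <- pmax(sqrt(ddx^2 + ddy^2), eps)
      fa <- dd / k     # (d^2 / k) / d
      ax <- fa * ddx; ay <- fa * ddy
      for (e in seq_along(ei)) {
        disp[ei[e], ] <- disp[ei[e], ] - c(ax[e], ay[e])
        disp[ej[e], ] <- disp[ej[e], ] + c(ax[e], ay[e])
      }
    }
    len <- pmax(sqrt(rowSums(disp^2)), eps)
    step <- pmin(len, temp) / len
    pos <- pos + disp * step
    pos[, 1] <- pmin(pmax(pos[, 1], 0), width)
    pos[, 2] <- pmin(pmax(pos[, 2], 0), height)
    temp <- max(temp - cool, 0)
  }
  out <- data.frame(id = net$nodes$id, x = pos[, 1], y = pos[, 2])
  class(out) <- c("anat_layout", "data.frame")
  out
}

#' Spatial module-separation score of a layout
#'
#' Ratio of the mean within-module pairwise Euclidean distance to the mean
#' between-module pairwise distance. Values below 1 mean the partition's
#' modules occupy segregated regions of the drawing; about 1 is expected for
#' random coordinates or an unrelated partition.
#'
#' @param net an [anat_network] (defines the node set).
#' @param layout an `anat_layout` (or `id,x,y` data frame) on the same nodes.
#' @param partition a partition of the same nodes with at least two modules.
#' @return The ratio, a positive real.
#' @export
layout_separation_score <- function(net, layout, partition) {
  p <- as_partition(partition, net)
  if (length(unique(p)) < 2) {
    stop("separation score needs at least two modules", call. = FALSE)
  }
  xy <- as.matrix(layout[match(net$nodes$id, layout$id), c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  same <- outer(p, p, "==") & upper.tri(d)
  diff <- (!outer(p, p, "==")) & upper.tri(d)
  mean(d[same]) / mean(d[diff])
}

#' Plot an anatomical network layout
#'
#' Draws the network with node color by module and plotting symbol by
#' anatomical type (circle = bone, triangle = muscle, square = knot).
#'
#' @param net an [anat_network].
#' @param layout an `anat_layout` for `net` (computed with seed 1 if omitted).
#' @param partition optional partition used for coloring (defaults to the
#'   published labels when present).
#' @param ... passed to [graphics::plot()].
#' @return The layout, invisibly.
#' @export
plot_network <- function(net, layout = NULL, partition = NULL, ...) {
  if (is.null(layout)) layout <- fruchterman_reingold(net, seed = 1L)
  labels <- if (!is.null(partition)) {
    as_partition(partition, net)
  } else if (!anyNA(net$nodes$module)) {
    published_partition(net)
  } else {
    stats::setNames(rep("1", net$n), net$nodes$id)
  }
  xy <- as.matrix(layout[match(net$nodes$id, layout$id), c("x", "y")])
  col <- as.integer(factor(labels[as.character(net$nodes$id)])) + 1L
  pch <- c(bone = 21, muscle = 24, connective_knot = 22)[net$nodes$type]
  graphics::plot(xy, type = "n", xlab = "", ylab = "", axes = FALSE, ...)
  graphics::segments(xy[node_index(net, net$edges[, 1]), 1],
                     xy[node_index(net, net$edges[, 1]), 2],
                     xy[node_index(net, net$edges[, 2]), 1],
                     xy[node_index(net, net$edges[, 2]), 2],
                     col = "grey70")
  graphics::points(xy, pch = pch, bg = col, cex = 1.4)
  graphics::text(xy, labels = net$nodes$id, cex = 0.5, pos = 3)
  invisible(layout)
}
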