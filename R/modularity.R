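#' Build a null model for modularity
#'
#' A null model is the matrix P of expected edge probabilities against which
#' the observed adjacency is contrasted in the modularity coefficient
#' Q = (1/2m) * sum_ij (A_ij - P_ij) * delta(g_i, g_j).
#'
#' Three kinds are available:
#' \describe{
#'   \item{`standard`}{the configuration model, `p_ij = k_i k_j / (2m)` for
#'     every ordered pair including the diagonal (`p_ii = k_i^2 / 2m`). With
#'     this diagonal convention the total expected ordered-pair mass equals
#'     2m exactly, so a single-module partition always scores Q = 0.}
#'   \item{`constrained`}{a quasi-bipartite configuration model for networks
#'     in which one node type forms a (near-)independent set — e.g. muscles,
#'     which attach only to bones and fibrous knots. P assigns probability
#'     zero to every pair of `forbidden_type` nodes, and `p_ij = c k_i k_j`
#'     to allowed pairs, with the constant c chosen so the total expected
#'     edge mass is preserved (ordered sum, diagonal included, equals 2m).
#'     Pairs from the naturally disjoint set thus receive no modularity
#'     penalty. The functional form is this package's interpretation of the
#'     constraint; it keeps degree propensity and edge mass of the standard
#'     null.}
#'   \item{`strict_bipartite`}{a Barber-style alternative: only pairs that
#'     straddle the bipartition (`forbidden_type` vs the rest) get mass,
#'     `p_ij = k_i k_j / m`; all within-side pairs, not just within
#'     `forbidden_type`, get zero.}
#' }
#'
#' @param net an [anat_network] with at least one edge.
#' @param kind `"standard"`, `"constrained"` or `"strict_bipartite"`.
#' @param forbidden_type node type whose pairs are forbidden (constrained) or
#'   that defines one side of the bipartition (strict); required for the
#'   non-standard kinds.
#' @return An object of class `null_model`: list with `kind`,
#'   `forbidden_type`, the dense symmetric matrix `P` (node-id dimnames), and
#'   for the constrained kind the normalizing constant `c`.
#' @examples
#' net <- frog_hindlimb()
#' null <- build_null(net, "constrained", forbidden_type = "muscle")
#' null$c
#' @export
build_null <- function(net,
                       kind = c("standard", "constrained", "strict_bipartite"),
                       forbidden_type = NULL) {
  kind <- match.arg(kind)
  if (net$m == 0) stop("Q is undefined on an edgeless network (m = 0)",
                       call. = FALSE)
  k <- as.numeric(degrees(net))
  two_m <- 2 * net$m
  KK <- outer(k, k)
  cnorm <- NULL
  if (kind == "standard") {
    P <- KK / two_m
  } else {
    if (is.null(forbidden_type) || !forbidden_type %in% NODE_TYPES) {
      stop("kind '", kind, "' requires a valid forbidden_type", call. = FALSE)
    }
    forb <- net$nodes$type == forbidden_type
    if (kind == "constrained") {
      allowed <- !(outer(forb, forb) )
      if (!any(allowed)) stop("all node pairs are forbidden", call. = FALSE)
      mass <- sum(KK[allowed])
      if (mass == 0) stop("no allowed pair has positive degree product",
                          call. = FALSE)
      cnorm <- two_m / mass
      P <- ifelse(allowed, cnorm * KK, 0)
    } else {
      across <- outer(forb, !forb) | outer(!forb, forb)
      if (!any(across)) stop("bipartition has an empty side", call. = FALSE)
      P <- ifelse(across, KK / net$m, 0)
    }
  }
  dimnames(P) <- list(net$nodes$id, net$nodes$id)
  structure(list(kind = kind, forbidden_type = forbidden_type, P = P,
                 c = cnorm, n = net$n, m = net$m),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("<null_model: %s%s, %d nodes, m = %d>\n", x$kind,
              if (!is.null(x$forbidden_type))
                paste0(" (forbidden: ", x$forbidden_type, ")") else "",
              x$n, x$m))
  invisible(x)
}

# coerce a partition to a character vector named by node id, covering net
as_partition <- function(partition, net) {
  if (is.data.frame(partition)) {
    partition <- stats::setNames(as.character(partition[[2]]),
                                 partition[[1]])
  }
  if (is.null(names(partition))) {
    stop("partition must be named by node id (or be an id,module data frame)",
         call. = FALSE)
  }
  p <- partition[as.character(net$nodes$id)]
  if (anyNA(p)) {
    stop("partition is missing node(s): ",
         paste(net$nodes$id[is.na(p)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.character(p), net$nodes$id)
}

# integer membership vector in node-table order
membership_vector <- function(partition, net) {
  p <- as_partition(partition, net)
  as.integer(factor(p, levels = unique(p)))
}

#' Modularity matrix B = A - P
#'
#' @param net an [anat_network].
#' @param null a [build_null()] result built on `net`.
#' @return Dense symmetric matrix; under the standard null every row sums to
#'   zero (the diagonal carries `-k_i^2 / 2m`).
#' @export
modularity_matrix <- function(net, null) {
  stopifnot(inherits(null, "null_model"), null$n == net$n, null$m == net$m)
  adjacency_matrix(net) - null$P
}

#' Modularity Q of a partition
#'
#' Q = (1/2m) * sum over ordered node pairs of (A_ij - P_ij) for pairs in the
#' same module. Q is the excess of within-module edge mass over its
#' expectation under the null; the partition maximizing Q is preferred.
#'
#' @param net an [anat_network].
#' @param partition character vector of module labels named by node id, or a
#'   two-column `id,module` data frame, covering every node of `net`.
#' @param null a [build_null()] result built on `net`.
#' @return Q, a real number in \[-1, 1\]. Zero for the single-module
#'   partition under either mass-preserving null.
#' @examples
#' net <- frog_hindlimb()
#' compute_Q(net, published_partition(net), build_null(net, "standard"))
#' @export
compute_Q <- function(net, partition, null) {
  g <- membership_vector(partition, net)
  B <- modularity_matrix(net, null)
  same <- outer(g, g, "==")
  sum(B[same]) / (2 * net$m)
}

# Q from a membership integer vector and a precomputed B matrix (search core)
q_from_membership <- function(g, B, two_m) {
  sum(B[outer(g, g, "==")]) / two_m
}
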