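#' Generate a limb-like quasi-bipartite musculoskeletal network
#'
#' Emulates the typed degree structure of published musculoskeletal networks:
#' bones form a connected joint scaffold (a chain or a random tree), each
#' fibrous knot branches to at least `knot_min_degree` non-muscle elements
#' (a knot is a connective hub from which more than two aligned fiber sets
#' branch out), and each muscle attaches to 2-4 distinct non-muscle elements
#' (degree drawn from `muscle_degree_dist`, whose default puts most mass on
#' degree 2: origin plus insertion). Muscles therefore form an exactly
#' independent set unless `n_muscle_exceptions > 0` injects that many
#' muscle-muscle contacts, mimicking rare direct muscular links. Every knot
#' and muscle anchors to the scaffold, so the result is always simple and
#' connected.
#'
#' @param n_bones number of bones (>= 2).
#' @param n_muscles,n_knots numbers of muscles and fibrous knots.
#' @param backbone `"chain"` or `"tree"`: shape of the bone-bone scaffold.
#' @param muscle_degree_dist probabilities for muscle degrees 2, 3, 4.
#' @param knot_min_degree minimum knot degree (>= 3).
#' @param locality in \[0, 1\]: probability that each further attachment of a
#'   muscle is drawn from the scaffold neighborhood of its first bone rather
#'   than uniformly (anatomical contacts are local).
#' @param n_muscle_exceptions number of muscle-muscle edges to add.
#' @param seed integer seed.
#' @return An [anat_network] with typed nodes (bones first, then knots, then
#'   muscles, ids consecutive from 1).
#' @examples
#' net <- generate_limb_like(n_bones = 20, n_muscles = 27, n_knots = 7,
#'                           seed = 7)
#' nrow(find_within_type_edges(net, "muscle"))
#' @export
generate_limb_like <- function(n_bones, n_muscles, n_knots,
                               backbone = c("chain", "tree"),
                               muscle_degree_dist = c(`2` = 0.8, `3` = 0.15,
                                                      `4` = 0.05),
                               knot_min_degree = 3L, locality = 0.5,
                               n_muscle_exceptions = 0L, seed = 1L) {
  backbone <- match.arg(backbone)
  stopifnot(n_bones >= 2, n_muscles >= 0, n_knots >= 0,
            locality >= 0, locality <= 1)
  if (knot_min_degree < 3) {
    stop("knot_min_degree must be >= 3: a fibrous knot branches to more ",
         "than two fiber sets", call. = FALSE)
  }
  if (n_knots > 0 && n_bones < knot_min_degree) {
    stop(sprintf(paste0("infeasible parameters: the first knot needs ",
                        "%d distinct non-muscle attachments but only %d ",
                        "bones exist"), knot_min_degree, n_bones),
         call. = FALSE)
  }
  if (n_muscle_exceptions > choose(n_muscles, 2)) {
    stop("more muscle-muscle exception edges requested than muscle pairs",
         call. = FALSE)
  }
  rng <- local_rng(seed)
  bone_ids <- seq_len(n_bones)
  knot_ids <- n_bones + seq_len(n_knots)
  muscle_ids <- n_bones + n_knots + seq_len(n_muscles)
  edges <- NULL
  # bone scaffold: chain 1-2-...-B, or random recursive tree
  if (backbone == "chain") {
    edges <- cbind(bone_ids[-n_bones], bone_ids[-1])
  } else {
    parent <- vapply(2:n_bones, function(b) rng$sample(seq_len(b - 1L), 1), 0L)
    edges <- cbind(parent, 2:n_bones)
  }
  scaffold_adj <- lapply(bone_ids, function(b) {
    unique(c(edges[edges[, 1] == b, 2], edges[edges[, 2] == b, 1]))
  })
  # knots attach to >= knot_min_degree distinct earlier non-muscle elements
  for (kk in seq_len(n_knots)) {
    targets <- c(bone_ids, knot_ids[seq_len(kk - 1L)])
    picked <- rng$sample(targets, knot_min_degree)
    edges <- rbind(edges, cbind(picked, knot_ids[kk]))
  }
  # muscles: degree from the distribution, distinct non-muscle attachments
  deg_values <- as.integer(names(muscle_degree_dist))
  non_muscle <- c(bone_ids, knot_ids)
  for (mm in seq_len(n_muscles)) {
    d <- rng$sample(deg_values, 1, prob = muscle_degree_dist)
    d <- min(d, length(non_muscle))
    home <- rng$sample(bone_ids, 1)
    picked <- home
    while (length(picked) < d) {
      local_pool <- setdiff(c(scaffold_adj[[home]], knot_ids), picked)
      use_local <- length(local_pool) > 0 && rng$unif(1) < locality
      pool <- if (use_local) local_pool else setdiff(non_muscle, picked)
      picked <- c(picked, rng$sample(pool, 1))
    }
    edges <- rbind(edges, cbind(picked, muscle_ids[mm]))
  }
  if (n_muscle_exceptions > 0) {
    all_pairs <- t(utils::combn(muscle_ids, 2))
    pick <- rng$sample(seq_len(nrow(all_pairs)), n_muscle_exceptions)
    edges <- rbind(edges, all_pairs[pick, , drop = FALSE])
  }
  n_total <- n_bones + n_knots + n_muscles
  nodes <- data.frame(
    id = seq_len(n_total),
    name = c(sprintf("bone_%02d", seq_len(n_bones)),
             sprintf("knot_%02d", seq_len(n_knots)),
             sprintf("muscle_%02d", seq_len(n_muscles))),
    type = rep(c("bone", "connective_knot", "muscle"),
               c(n_bones, n_knots, n_muscles)),
    stringsAsFactors = FALSE)
  anat_network(nodes, edges)
}

#' Generate a planted-partition benchmark network
#'
#' Stochastic block model with equal within/between probabilities per block:
#' node pairs inside a module are joined independently with probability
#' `p_in`, pairs in different modules with `p_out`. The ground-truth
#' partition is returned alongside the network, making this the benchmark
#' surface for community-recovery tests. Isolated nodes can occur at small
#' probabilities and are kept.
#'
#' @param module_sizes integer vector of module sizes.
#' @param p_in,p_out edge probabilities, `0 <= p_out` and `p_in <= 1`
#'   (recovery tests additionally need `p_out < p_in`).
#' @param seed integer seed.
#' @return List with `network` (an [anat_network]; all nodes typed `bone`
#'   since the benchmark has no anatomy) and `partition` (the planted
#'   labels, named by node id).
#' @export
generate_planted <- function(module_sizes, p_in, p_out, seed = 1L) {
  stopifnot(length(module_sizes) >= 1, all(module_sizes >= 1),
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  rng <- local_rng(seed)
  n <- sum(module_sizes)
  labels <- rep(sprintf("M%d", seq_along(module_sizes)), module_sizes)
  pairs <- t(utils::combn(seq_len(n), 2))
  p <- ifelse(labels[pairs[, 1]] == labels[pairs[, 2]], p_in, p_out)
  keep <- rng$bernoulli(nrow(pairs), p)
  nodes <- data.frame(id = seq_len(n), name = sprintf("node_%03d", seq_len(n)),
                      type = "bone", stringsAsFactors = FALSE)
  list(network = anat_network(nodes, pairs[keep, , drop = FALSE]),
       partition = stats::setNames(labels, seq_len(n)))
}

#' Degree-preserving edge rewiring
#'
#' Randomizes a network by accepted double-edge swaps: two edges (a,b) and
#' (c,d) are replaced by (a,d) and (c,b). Swaps creating self-loops,
#' duplicate edges, or — when `respect_forbidden` is set — new edges inside
#' the forbidden node type are rejected, so the degree sequence (and
#' optionally the quasi-bipartite character) is exactly preserved.
#'
#' @param net an [anat_network] with at least two edges.
#' @param n_swaps number of accepted swaps to perform.
#' @param seed integer seed.
#' @param respect_forbidden optional node type; swaps may not create new
#'   within-type edges of this type.
#' @param max_tries attempt budget before giving up with a warning.
#' @return A rewired [anat_network] with identical node table and degree
#'   sequence; the acceptance rate is attached as attribute
#'   `acceptance_rate`.
#' @export
degree_preserving_rewire <- function(net, n_swaps, seed = 1L,
                                     respect_forbidden = NULL,
                                     max_tries = 100 * n_swaps) {
  stopifnot(net$m >= 2, n_swaps >= 0)
  rng <- local_rng(seed)
  edges <- net$edges
  type <- stats::setNames(net$nodes$type, net$nodes$id)
  edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  present <- new.env(hash = TRUE, size = 4 * net$m)
  for (r in seq_len(nrow(edges))) {
    assign(edge_key(edges[r, 1], edges[r, 2]), TRUE, envir = present)
  }
  accepted <- 0L; tries <- 0L
  while (accepted < n_swaps && tries < max_tries) {
    tries <- tries + 1L
    rows <- rng$sample(seq_len(nrow(edges)), 2)
    a <- edges[rows[1], 1]; b <- edges[rows[1], 2]
    cc <- edges[rows[2], 1]; dd <- edges[rows[2], 2]
    if (rng$unif(1) < 0.5) { tmp <- cc; cc <- dd; dd <- tmp }
    # proposed: (a, dd), (cc, b)
    if (a == dd || cc == b) next
    k1 <- edge_key(a, dd); k2 <- edge_key(cc, b)
    if (k1 == k2 || exists(k1, envir = present) ||
        exists(k2, envir = present)) next
    if (!is.null(respect_forbidden)) {
      tf <- respect_forbidden
      if ((type[as.character(a)] == tf && type[as.character(dd)] == tf) ||
          (type[as.character(cc)] == tf && type[as.character(b)] == tf)) next
    }
    rm(list = c(edge_key(a, b), edge_key(cc, dd)), envir = present)
    assign(k1, TRUE, envir = present)
    assign(k2, TRUE, envir = present)
    edges[rows[1], ] <- c(min(a, dd), max(a, dd))
    edges[rows[2], ] <- c(min(cc, b), max(cc, b))
    accepted <- accepted + 1L
  }
  if (accepted < n_swaps) {
    warning(sprintf("only %d of %d swaps accepted within the attempt budget",
                    accepted, n_swaps))
  }
  out <- anat_network(net$nodes, edges)
  attr(out, "acceptance_rate") <- if (tries > 0) accepted / tries else NA_real_
  out
}

#' Empirical null distribution of optimal modularity
#'
#' Rewires the network `n_replicates` times with [degree_preserving_rewire()]
#' and maximizes modularity on each replicate, giving an empirical
#' distribution of the best Q attainable at the observed degree sequence.
#' This is an empirical companion to the analytic configuration-model null:
#' the analytic null enters Q itself, while this procedure asks how unusual
#' the observed optimal Q is among degree-matched random networks.
#'
#' @param net an [anat_network].
#' @param n_replicates number of rewired replicates.
#' @param swaps_per_replicate accepted swaps per replicate (default `10 * m`).
#' @param seed integer master seed.
#' @param null a [build_null()] kind understood by [build_null()]; each
#'   replicate gets its own null built on its own rewired degrees (degrees
#'   are preserved, so P is unchanged, but the graph is not).
#' @param restarts restarts for the per-replicate search (default 5).
#' @param respect_forbidden passed to [degree_preserving_rewire()].
#' @return List with `q_values` (length `n_replicates`), `observed_q` (best Q
#'   of `net` itself), and `percentile` (empirical percentile of the observed
#'   Q among the replicates; `NA` when `n_replicates` is 0).
#' @export
q_null_distribution <- function(net, n_replicates, swaps_per_replicate = NULL,
                                seed = 1L, null = "standard", restarts = 5L,
                                respect_forbidden = NULL) {
  if (is.null(swaps_per_replicate)) swaps_per_replicate <- 10 * net$m
  rng <- local_rng(seed)
  observed <- best_partition(net, build_null(net, null), restarts = restarts,
                             seed = rng$int())
  qs <- numeric(0)
  for (r in seq_len(n_replicates)) {
    rep_net <- degree_preserving_rewire(net, swaps_per_replicate,
                                        seed = rng$int(),
                                        respect_forbidden = respect_forbidden)
    res <- best_partition(rep_net, build_null(rep_net, null),
                          restarts = restarts, seed = rng$int())
    qs <- c(qs, res$q)
  }
  percentile <- if (n_replicates > 0) {
    100 * mean(qs <= observed$q)
  } else NA_real_
  list(q_values = qs, observed_q = observed$q, percentile = percentile)
}
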