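Q_TOL <- 1e-12  # double-precision floor for Q improvements and ties

search_result <- function(net, g, B, two_m, method, restarts_used = 0L,
                          seed = NA_integer_) {
  g <- as.integer(factor(g, levels = unique(g)))  # consecutive labels
  partition <- stats::setNames(as.character(g), net$nodes$id)
  structure(list(partition = partition,
                 q = q_from_membership(g, B, two_m),
                 n_modules = length(unique(g)),
                 method = method, restarts_used = restarts_used,
                 seed = seed),
            class = "module_search")
}

#' @export
print.module_search <- function(x, ...) {
  cat(sprintf("<module_search [%s]: Q = %.6f, %d modules>\n",
              x$method, x$q, x$n_modules))
  invisible(x)
}

#' Globally optimal partition by exhaustive enumeration
#'
#' Iterates every set partition of the nodes (in restricted-growth-string
#' order) with incremental Q bookkeeping and returns the global maximum of
#' modularity. Bell(12) is about 4.2 million, so the search is restricted to
#' n <= 12; it exists as the exact oracle against which the heuristic search
#' is validated.
#'
#' @param net an [anat_network] with at most 12 nodes.
#' @param null a [build_null()] result built on `net`.
#' @return A `module_search` result. Ties are broken toward fewer modules,
#'   then toward the lexicographically smallest canonical labeling.
#' @export
exhaustive_best <- function(net, null) {
  if (net$n > 12) {
    stop("exhaustive search is restricted to n <= 12; use best_partition()",
         call. = FALSE)
  }
  B <- modularity_matrix(net, null)
  two_m <- 2 * net$m
  n <- net$n
  g <- integer(n)
  best_q <- -Inf; best_g <- NULL; best_k <- Inf

  recurse <- function(i, kmax, qacc) {
    if (i > n) {
      if (qacc > best_q + Q_TOL ||
          (qacc >= best_q - Q_TOL && kmax < best_k)) {
        best_q <<- qacc; best_g <<- g[seq_len(n)]; best_k <<- kmax
      }
      return(invisible())
    }
    for (cc in seq_len(kmax + 1L)) {
      members <- which(g[seq_len(i - 1L)] == cc)
      dq <- (2 * sum(B[i, members]) + B[i, i]) / two_m
      g[i] <<- cc
      recurse(i + 1L, max(kmax, cc), qacc + dq)
    }
    g[i] <<- 0L
  }
  recurse(1L, 0L, 0)
  search_result(net, best_g, B, two_m, method = "exhaustive")
}

#' Greedy agglomerative modularity maximization
#'
#' Deterministic CNM-style baseline: starts from singleton modules and
#' repeatedly merges the module pair with the largest positive modularity
#' gain (ties broken by the lexicographically smallest pair of smallest
#' member ids), stopping when no merge improves Q.
#'
#' @param net an [anat_network] with at least one edge.
#' @param null a [build_null()] result built on `net`.
#' @return A `module_search` result.
#' @export
greedy_agglomerative <- function(net, null) {
  B <- modularity_matrix(net, null)
  g <- merge_modules(seq_len(net$n), B, 2 * net$m)
  search_result(net, g, B, 2 * net$m, method = "greedy")
}

# agglomerative core: merge modules of membership g while any merge gains Q
merge_modules <- function(g, B, two_m) {
  n <- nrow(B)
  g <- as.integer(factor(g, levels = unique(g)))
  k <- max(g)
  # module-aggregated modularity matrix
  agg <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) agg[a, b] <- sum(B[g == a, g == b])
  }
  M <- agg
  members <- lapply(seq_len(k), function(a) which(g == a))
  live <- seq_len(k)
  repeat {
    if (length(live) < 2) break
    sub <- M[live, live, drop = FALSE]
    diag(sub) <- -Inf
    if (2 * max(sub) / two_m <= Q_TOL) break
    hits <- which(sub == max(sub), arr.ind = TRUE)
    # tie-break: smallest (min-member, min-member) pair, a < b
    reps <- vapply(members[live], min, 0L)
    pa <- pmin(reps[hits[, 1]], reps[hits[, 2]])
    pb <- pmax(reps[hits[, 1]], reps[hits[, 2]])
    pick <- order(pa, pb)[1]
    a <- live[min(hits[pick, ])]; b <- live[max(hits[pick, ])]
    if (min(members[[b]]) < min(members[[a]])) { tmp <- a; a <- b; b <- tmp }
    M[a, ] <- M[a, ] + M[b, ]
    M[, a] <- M[, a] + M[, b]
    members[[a]] <- sort(c(members[[a]], members[[b]]))
    members[[b]] <- integer(0)
    live <- setdiff(live, b)
  }
  out <- integer(n)
  for (idx in seq_along(live)) out[members[[live[idx]]]] <- idx
  out
}

#' Local-moving refinement of a partition
#'
#' Louvain-style node moves: repeatedly relocates single nodes to the
#' neighboring (or a fresh empty) module with the largest modularity gain
#' until a full sweep makes no move that improves Q by more than 1e-12.
#' Node visit order is reshuffled by the seed before every sweep; Q never
#' decreases.
#'
#' @param net an [anat_network].
#' @param null a [build_null()] result built on `net`.
#' @param start starting partition (named label vector or `id,module` data
#'   frame) covering every node.
#' @param seed integer seed for the sweep order.
#' @return A `module_search` result with `q >=` the starting Q.
#' @export
refine_local_moving <- function(net, null, start, seed = 1L) {
  B <- modularity_matrix(net, null)
  two_m <- 2 * net$m
  g <- membership_vector(start, net)
  g <- local_move_core(B, adjacency_positions(net), g, two_m,
                       local_rng(seed))
  search_result(net, g, B, two_m, method = "local_moving", seed = seed)
}

# single-node move sweeps until a full sweep yields no gain > Q_TOL
local_move_core <- function(B, adj, g, two_m, rng) {
  n <- nrow(B)
  repeat {
    improved <- FALSE
    for (v in rng$shuffle(seq_len(n))) {
      cur <- g[v]
      # moving to a module none of v's neighbors inhabit is dominated by
      # moving to a fresh empty module, so neighbors + empty suffice
      cand <- unique(c(g[adj[[v]]], max(g) + 1L))
      cand <- cand[cand != cur]
      if (!length(cand)) next
      stay <- sum(B[v, g == cur]) - B[v, v]
      att <- vapply(cand, function(cc) sum(B[v, g == cc]), 0)
      dq <- 2 * (att - stay) / two_m
      best <- which(dq == max(dq))[1]
      if (dq[best] > Q_TOL) {
        g[v] <- cand[best]
        g <- as.integer(factor(g, levels = unique(g)))
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  g
}

# try to split each module by re-optimizing the partition of its induced
# B-submatrix from singletons; a split is kept only when it raises total Q
split_modules <- function(g, B, adj, two_m, rng) {
  for (lab in unique(g)) {
    S <- which(g == lab)
    if (length(S) < 2) next
    subB <- B[S, S, drop = FALSE]
    pos <- match(seq_len(nrow(B)), S)
    subadj <- lapply(S, function(v) pos[adj[[v]]][!is.na(pos[adj[[v]]])])
    gs <- local_move_core(subB, subadj, seq_along(S), two_m, rng)
    gs <- merge_modules(gs, subB, two_m)
    if (length(unique(gs)) < 2) next
    gain <- sum(subB[outer(gs, gs, "==")]) - sum(subB)
    if (gain / two_m > Q_TOL) {
      g[S] <- max(g) + gs
    }
  }
  as.integer(factor(g, levels = unique(g)))
}

#' Best partition by multi-restart heuristic search
#'
#' Runs the deterministic greedy agglomeration once, then `restarts` seeded
#' refinement passes alternating between the greedy partition and random
#' starting partitions, and returns the highest-Q result. Each refinement
#' pass interleaves local-moving sweeps ([refine_local_moving()]) with
#' whole-module merges (the agglomerative core) until neither improves Q —
#' single-node moves escape bad assignments while merges collapse
#' over-split modules, the two failure modes of either step alone. Fully
#' reproducible given `seed`; Q never decreases along any pass.
#'
#' @param net an [anat_network] with at least one edge.
#' @param null a [build_null()] result built on `net`.
#' @param restarts number of refinement passes (>= 1).
#' @param seed integer master seed; per-pass seeds are derived from it.
#' @return A `module_search` result.
#' @examples
#' net <- frog_hindlimb()
#' res <- best_partition(net, build_null(net, "standard"),
#'                       restarts = 20, seed = 1)
#' round(res$q, 2)
#' @export
best_partition <- function(net, null, restarts = 20L, seed = 1L) {
  stopifnot(restarts >= 1)
  greedy <- greedy_agglomerative(net, null)
  best <- greedy
  rng <- local_rng(seed)
  B <- modularity_matrix(net, null)
  two_m <- 2 * net$m
  for (r in seq_len(restarts)) {
    sub_seed <- rng$int()
    if (r == 1L) {
      start <- greedy$partition
    } else if (r %% 2L == 0L) {
      # shake the incumbent: reassign a random fifth of the nodes to a
      # random neighbor's module, then let refinement repair it
      start <- perturb_partition(net, best$partition, frac = 0.2, rng = rng)
    } else {
      k <- rng$sample(2:max(2L, ceiling(net$n / 3)), 1)
      start <- stats::setNames(as.character(rng$sample(seq_len(k), net$n,
                                                       replace = TRUE)),
                               net$nodes$id)
    }
    # alternate node moves, module splits and module merges to a fixed point
    pass_rng <- local_rng(sub_seed)
    adj <- adjacency_positions(net)
    g <- membership_vector(as_partition(start, net), net)
    q <- q_from_membership(g, B, two_m)
    repeat {
      g <- local_move_core(B, adj, g, two_m, pass_rng)
      g <- split_modules(g, B, adj, two_m, pass_rng)
      g <- merge_modules(g, B, two_m)
      qn <- q_from_membership(g, B, two_m)
      if (qn <= q + Q_TOL) break
      q <- qn
    }
    res <- search_result(net, g, B, two_m, method = "best_partition",
                         seed = sub_seed)
    if (res$q > best$q + Q_TOL) best <- res
  }
  best$method <- "best_partition"
  best$restarts_used <- as.integer(restarts)
  best$seed <- as.integer(seed)
  best
}

#' Compare two partitions
#'
#' Adjusted Rand index (chance-corrected pair-counting agreement; 1 iff the
#' partitions are identical up to relabeling, 0 in expectation for unrelated
#' partitions) and variation of information (an information-theoretic
#' distance; 0 iff identical). By the usual convention the degenerate
#' all-singletons vs all-in-one comparison scores ARI 0; when the ARI
#' denominator vanishes the partitions are necessarily identical and 1 is
#' returned.
#'
#' @param a,b partitions (named label vectors or `id,module` data frames)
#'   over the same node set.
#' @return List with `ari`, `vi`, and `label_map` — for every label of `a`,
#'   the label of `b` with the largest member overlap.
#' @export
compare_partitions <- function(a, b) {
  a <- normalize_partition(a)
  b <- normalize_partition(b)
  if (!setequal(names(a), names(b))) {
    stop("partitions cover different node sets", call. = FALSE)
  }
  b <- b[names(a)]
  n <- length(a)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  denom <- (ai + bj) / 2 - expected
  ari <- if (denom == 0) 1 else (nij - expected) / denom

  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  h <- function(x) -sum(x[x > 0] * log(x[x > 0]))
  mi <- sum(p[p > 0] * log(p[p > 0] /
                           (outer(pa, pb))[p > 0]))
  vi <- max(0, h(pa) + h(pb) - 2 * mi)

  label_map <- apply(tab, 1, function(row) colnames(tab)[which.max(row)])
  list(ari = ari, vi = vi, label_map = label_map)
}

# reassign a random fraction of nodes to the module of a random neighbor
perturb_partition <- function(net, partition, frac, rng) {
  g <- membership_vector(partition, net)
  adj <- adjacency_positions(net)
  n_move <- max(1L, round(frac * net$n))
  for (v in rng$sample(seq_len(net$n), n_move)) {
    if (length(adj[[v]])) {
      g[v] <- g[rng$sample(adj[[v]], 1)]
    }
  }
  stats::setNames(as.character(g), net$nodes$id)
}

normalize_partition <- function(p) {
  if (inherits(p, "module_search")) p <- p$partition
  if (is.data.frame(p)) p <- stats::setNames(as.character(p[[2]]), p[[1]])
  if (is.null(names(p))) stop("partition must be named by node id",
                              call. = FALSE)
  stats::setNames(as.character(p), names(p))
}
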