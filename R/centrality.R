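#' Exact geodesic betweenness centrality
#'
#' Betweenness of a node v is the sum, over unordered pairs of other nodes
#' \{s, t\}, of the fraction of shortest s-t paths that pass through v
#' (endpoints excluded, unit edge lengths). Scores are unnormalized, the
#' convention under which a 54-node musculoskeletal hub can score well above
#' 100. Computed with Brandes' single-source accumulation, O(nm).
#'
#' In a muscle-skeletal network high betweenness flags elements most exposed
#' to the propagation of force: removing them tends to disconnect the system.
#'
#' @param net an [anat_network]; it need not be connected (pairs in different
#'   components contribute nothing).
#' @return An object of class `centrality_table`: a data frame with columns
#'   `id`, `name`, `type`, `degree`, `betweenness` and `rank`, ordered by
#'   decreasing betweenness with ties broken by ascending id.
#' @examples
#' tab <- betweenness_centrality(frog_hindlimb())
#' head(tab, 3)
#' @export
betweenness_centrality <- function(net) {
  adj <- adjacency_positions(net)
  n <- net$n
  cb <- numeric(n)
  for (s in seq_len(n)) {
    order_visited <- integer(0)
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    queue <- c(s); head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  cb <- cb / 2  # every unordered {s, t} pair was accumulated from both ends
  centrality_table(net, cb)
}

centrality_table <- function(net, scores) {
  ord <- order(-scores, net$nodes$id)
  out <- data.frame(id = net$nodes$id, name = net$nodes$name,
                    type = net$nodes$type, degree = unname(degrees(net)),
                    betweenness = scores, stringsAsFactors = FALSE)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Brute-force betweenness by shortest-path enumeration
#'
#' Test oracle: enumerates every geodesic between every node pair explicitly
#' and tallies interior vertices. Identical contract to
#' [betweenness_centrality()], affordable only for tiny graphs.
#'
#' @param net an [anat_network] with at most 10 nodes.
#' @return A `centrality_table` (see [betweenness_centrality()]).
#' @export
brute_force_betweenness <- function(net) {
  if (net$n > 10) {
    stop("brute-force enumeration is restricted to n <= 10; use ",
         "betweenness_centrality()", call. = FALSE)
  }
  adj <- adjacency_positions(net)
  n <- net$n
  dist <- matrix(-1L, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0L
    queue <- c(s); head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (dist[s, w] < 0L) {
          dist[s, w] <- dist[s, v] + 1L
          queue <- c(queue, w)
        }
      }
    }
  }
  cb <- numeric(n)
  enumerate_paths <- function(s, t) {
    # all geodesics s -> t, as a list of vertex sequences
    if (dist[s, t] < 0L) return(list())
    extend <- function(v) {
      if (v == t) return(list(t))
      nxt <- adj[[v]][dist[s, adj[[v]]] == dist[s, v] + 1L &
                      dist[adj[[v]], t] == dist[v, t] - 1L]
      out <- list()
      for (u in nxt) {
        for (tail in extend(u)) out <- c(out, list(c(v, tail)))
      }
      out
    }
    extend(s)
  }
  for (s in seq_len(n - 1L)) {
    for (t in seq(s + 1L, n)) {
      paths <- enumerate_paths(s, t)
      if (length(paths) == 0) next
      interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(interior)) {
        counts <- tabulate(interior, nbins = n)
        cb <- cb + counts / length(paths)
      }
    }
  }
  centrality_table(net, cb)
}

#' Count nodes above a betweenness threshold
#'
#' @param table a `centrality_table`.
#' @param threshold real; nodes with betweenness strictly greater are counted.
#' @return Integer count; non-increasing in `threshold`.
#' @export
count_above_threshold <- function(table, threshold) {
  sum(table$betweenness > threshold)
}
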