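# small builders used across the suite

make_net <- function(n, edges, type = "bone") {
  nodes <- data.frame(id = seq_len(n), name = paste0("v", seq_len(n)),
                      type = type, stringsAsFactors = FALSE)
  anat_network(nodes, edges)
}

path_net <- function(n) make_net(n, cbind(seq_len(n - 1), 2:n))

star_net <- function(leaves) make_net(leaves + 1, cbind(1, 1 + seq_len(leaves)))

cycle_net <- function(n) make_net(n, rbind(cbind(seq_len(n - 1), 2:n), c(n, 1)))

complete_net <- function(n) make_net(n, t(utils::combn(n, 2)))

two_triangles <- function(bridge = FALSE) {
  e <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  if (bridge) e <- rbind(e, c(3, 4))
  make_net(6, e)
}

# G(n, p) conditioned on >= 1 edge; optionally conditioned on connectivity
random_net <- function(n, p = 0.35, connected = FALSE) {
  pairs <- t(utils::combn(n, 2))
  repeat {
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) next
    net <- make_net(n, pairs[keep, , drop = FALSE])
    if (!connected || is_connected_net(net)) return(net)
  }
}

is_connected_net <- function(net) {
  adj <- anatnet:::adjacency_positions(net)
  seen <- logical(net$n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}
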