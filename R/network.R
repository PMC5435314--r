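NODE_TYPES <- c("bone", "muscle", "connective_knot")

#' Construct an anatomical network
#'
#' An anatomical network is an undirected simple graph whose nodes are typed
#' anatomical elements (bones, muscles, connective-tissue knots) and whose
#' edges encode physical contacts: joints, ligaments and monoaxial tendinous
#' connections. This is the substrate for all centrality, modularity and
#' layout computations in the package.
#'
#' @param nodes data frame with columns `id` (positive integers, unique),
#'   `name` (character), `type` (one of `"bone"`, `"muscle"`,
#'   `"connective_knot"`), and optionally `module` (a published module label,
#'   `NA` allowed) and `synonyms` (free-text metadata, never used in any
#'   computation).
#' @param edges two-column matrix or data frame of node id pairs, one row per
#'   undirected edge. Self-loops and duplicate edges (in either orientation)
#'   are rejected.
#' @return An object of class `anat_network`: a list with elements `nodes`
#'   (the node table, ordered by id), `edges` (integer matrix with the smaller
#'   id first, rows sorted), `n` (node count) and `m` (edge count).
#' @examples
#' nodes <- data.frame(id = 1:2, name = c("femur", "cruralis"),
#'                     type = c("bone", "muscle"))
#' net <- anat_network(nodes, cbind(1, 2))
#' net$m
#' @export
anat_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name", "type") %in% names(nodes)))
  nodes$id <- as.integer(nodes$id)
  if (anyNA(nodes$id) || any(nodes$id <= 0)) {
    stop("node ids must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(nodes$type), NODE_TYPES)
  if (length(bad)) {
    stop("unknown node type(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(NODE_TYPES, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(nodes$module)) nodes$module <- NA_character_
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(integer(0), ncol = 2)
  }
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2) stop("edges must have two columns", call. = FALSE)
  unknown <- !(edges %in% nodes$id)
  if (any(unknown)) {
    bad_row <- which(matrix(unknown, ncol = 2), arr.ind = TRUE)[1, 1]
    stop(sprintf("edge (%d, %d) references an undeclared node id",
                 edges[bad_row, 1], edges[bad_row, 2]), call. = FALSE)
  }
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    stop("self-loop on node ", edges[which(loops)[1], 1], call. = FALSE)
  }
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dup <- duplicated(edges)
  if (any(dup)) {
    stop(sprintf("duplicate edge (%d, %d)",
                 edges[which(dup)[1], 1], edges[which(dup)[1], 2]),
         call. = FALSE)
  }
  dimnames(edges) <- NULL

  structure(list(nodes = nodes, edges = edges,
                 n = nrow(nodes), m = nrow(edges)),
            class = "anat_network")
}

#' @export
print.anat_network <- function(x, ...) {
  cat(sprintf("<anat_network: %d nodes, %d edges>\n", x$n, x$m))
  tt <- table(x$nodes$type)
  cat("  types:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  if (any(!is.na(x$nodes$module))) {
    mt <- table(x$nodes$module)
    cat("  published modules:",
        paste(sprintf("%s=%d", names(mt), mt), collapse = ", "), "\n")
  }
  invisible(x)
}

# index of node id in the (id-ordered) node table
node_index <- function(net, ids) match(ids, net$nodes$id)

#' Node degrees
#'
#' @param net an [anat_network].
#' @return Integer vector of degrees named by node id. The handshake identity
#'   `sum(degrees(net)) == 2 * net$m` holds for every valid network.
#' @export
degrees <- function(net) {
  d <- integer(net$n)
  idx <- node_index(net, as.vector(net$edges))
  tb <- tabulate(idx, nbins = net$n)
  d <- d + tb
  names(d) <- net$nodes$id
  d
}

# adjacency structure: list over node positions, entries are node positions
adjacency_positions <- function(net) {
  adj <- vector("list", net$n)
  if (net$m > 0) {
    i <- node_index(net, net$edges[, 1])
    j <- node_index(net, net$edges[, 2])
    adj <- split(c(j, i), factor(c(i, j), levels = seq_len(net$n)))
    adj <- lapply(adj, function(v) sort(unname(v)))
  } else {
    adj <- rep(list(integer(0)), net$n)
  }
  unname(adj)
}

# dense 0/1 adjacency matrix in node-table order
adjacency_matrix <- function(net) {
  A <- matrix(0, net$n, net$n)
  if (net$m > 0) {
    i <- node_index(net, net$edges[, 1])
    j <- node_index(net, net$edges[, 2])
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  dimnames(A) <- list(net$nodes$id, net$nodes$id)
  A
}

#' Load an anatomical network from tabular files
#'
#' Two input layouts are supported. With both `node_file` and `edge_file`, the
#' node table has columns `id,name,type` (optional `module`) and the edge
#' table columns `source,target`. With `node_file` alone, the node table must
#' carry an `adjacency` column listing every neighbor of each node
#' (space-separated ids), mirroring how anatomical adjacency lists are
#' published. In adjacency-list form each contact must be listed from both
#' sides: if node i lists j but j omits i the data are rejected, which catches
#' transcription errors in anatomical data entry.
#'
#' @param node_file path to the node CSV (or a data frame).
#' @param edge_file optional path to the edge CSV (or a data frame) with
#'   columns `source,target`.
#' @return A validated [anat_network].
#' @export
load_network <- function(node_file, edge_file = NULL) {
  nodes <- if (is.data.frame(node_file)) node_file else
    utils::read.csv(node_file, stringsAsFactors = FALSE)
  if (is.null(edge_file)) {
    if (is.null(nodes$adjacency)) {
      stop("no edge table given and node table has no 'adjacency' column",
           call. = FALSE)
    }
    edges <- edges_from_adjacency_lists(nodes$id, nodes$adjacency)
  } else {
    et <- if (is.data.frame(edge_file)) edge_file else
      utils::read.csv(edge_file, stringsAsFactors = FALSE)
    edges <- as.matrix(et[, 1:2])
  }
  nodes$adjacency <- NULL
  anat_network(nodes, edges)
}

# parse published-style adjacency lists; every (i, j) must also appear (j, i)
edges_from_adjacency_lists <- function(ids, adjacency) {
  ids <- as.integer(ids)
  nbrs <- lapply(strsplit(as.character(adjacency), "[,; ]+"), function(x) {
    as.integer(x[nzchar(x)])
  })
  pairs <- do.call(rbind, c(list(matrix(integer(0), ncol = 2)),
    lapply(seq_along(ids), function(k) {
      if (length(nbrs[[k]])) cbind(ids[k], nbrs[[k]]) else NULL
    })))
  if (nrow(pairs)) {
    key <- paste(pairs[, 1], pairs[, 2])
    rev_key <- paste(pairs[, 2], pairs[, 1])
    missing <- !(rev_key %in% key)
    if (any(missing)) {
      k <- which(missing)[1]
      stop(sprintf(
        "asymmetric adjacency list: node %d lists %d but node %d omits %d",
        pairs[k, 1], pairs[k, 2], pairs[k, 2], pairs[k, 1]), call. = FALSE)
    }
  }
  unique(cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2])))
}

#' Degree census
#'
#' Tabulates how many nodes (optionally restricted to one anatomical type)
#' have each degree. In published musculoskeletal networks most muscles are of
#' degree 2, reflecting one origin and one insertion on skeletal elements.
#'
#' @param net an [anat_network].
#' @param type_filter optional node type; count only nodes of this type.
#' @return Named integer vector: names are degrees, values are node counts.
#'   The counts total the number of (filtered) nodes.
#' @export
degree_census <- function(net, type_filter = NULL) {
  d <- degrees(net)
  if (!is.null(type_filter)) {
    stopifnot(type_filter %in% NODE_TYPES)
    d <- d[net$nodes$type == type_filter]
  }
  tb <- table(d)
  out <- as.integer(tb)
  names(out) <- names(tb)
  out
}

#' Edges whose endpoints share an anatomical type
#'
#' For a quasi-bipartite musculoskeletal network the muscle set is (nearly) an
#' independent set; this returns the deviation set, i.e. all within-type
#' contacts.
#'
#' @param net an [anat_network].
#' @param type node type shared by both endpoints.
#' @return Integer matrix with two columns (smaller id first), zero rows if no
#'   within-type edge exists.
#' @export
find_within_type_edges <- function(net, type) {
  stopifnot(type %in% NODE_TYPES)
  ntype <- net$nodes$type[node_index(net, as.vector(net$edges))]
  ntype <- matrix(ntype, ncol = 2)
  keep <- ntype[, 1] == type & ntype[, 2] == type
  net$edges[keep, , drop = FALSE]
}

#' Export and import helpers
#'
#' `export_edge_csv()` writes one row per undirected edge (`source,target`,
#' smaller id first); `export_node_csv()` writes `id,name,type,module`;
#' `export_graphml()` writes GraphML with `name`, `type` and `module` node
#' attributes; `load_graphml()` reads such a file back. A round trip through
#' either format reproduces an identical network.
#'
#' @param net an [anat_network].
#' @param path output (or input) file path.
#' @param partition optional partition (see [compute_Q()]) written to the
#'   GraphML `module` attribute in place of the published labels.
#' @return The file path, invisibly (`load_graphml()` returns an
#'   [anat_network]).
#' @name anatnet-io
NULL

#' @rdname anatnet-io
#' @export
export_edge_csv <- function(net, path) {
  utils::write.csv(
    data.frame(source = net$edges[, 1], target = net$edges[, 2]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname anatnet-io
#' @export
export_node_csv <- function(net, path) {
  utils::write.csv(
    net$nodes[, c("id", "name", "type", "module")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname anatnet-io
#' @export
export_graphml <- function(net, path, partition = NULL) {
  module <- net$nodes$module
  if (!is.null(partition)) {
    partition <- as_partition(partition, net)
    module <- unname(partition[as.character(net$nodes$id)])
  }
  module[is.na(module)] <- ""
  g <- igraph::make_empty_graph(n = net$n, directed = FALSE)
  igraph::V(g)$node_id <- net$nodes$id
  igraph::V(g)$label <- as.character(net$nodes$id)
  igraph::V(g)$name <- net$nodes$name
  igraph::V(g)$type <- net$nodes$type
  igraph::V(g)$module <- module
  if (net$m > 0) {
    g <- igraph::add_edges(g, t(matrix(node_index(net, net$edges), ncol = 2)))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname anatnet-io
#' @export
load_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ids <- as.integer(igraph::V(g)$node_id)
  module <- igraph::V(g)$module
  module[!nzchar(module)] <- NA_character_
  nodes <- data.frame(id = ids, name = igraph::V(g)$name,
                      type = igraph::V(g)$type, module = module,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- cbind(ids[el[, 1]], ids[el[, 2]])
  anat_network(nodes, edges)
}
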