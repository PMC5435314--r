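test_that("minimal networks validate and degenerate inputs are rejected", {
  nodes <- data.frame(id = 1:2, name = c("femur", "cruralis"),
                      type = c("bone", "muscle"))
  net <- anat_network(nodes, cbind(1, 2))
  expect_equal(net$n, 2)
  expect_equal(net$m, 1)

  expect_error(anat_network(nodes, cbind(1, 3)), "undeclared node id")
  expect_error(anat_network(nodes, cbind(1, 1)), "self-loop")
  expect_error(anat_network(nodes, rbind(c(1, 2), c(2, 1))), "duplicate edge")
  expect_error(anat_network(rbind(nodes, nodes[1, ]), cbind(1, 2)),
               "duplicate node id")
  bad <- nodes; bad$type[1] <- "tendon"
  expect_error(anat_network(bad, cbind(1, 2)), "unknown node type")
})

test_that("adjacency-list input requires mutual symmetry and names the pair", {
  nodes <- data.frame(id = c(48, 49), name = c("a", "b"), type = "bone",
                      adjacency = c("49", ""))
  expect_error(load_network(nodes), "node 48 lists 49 but node 49 omits 48")
  nodes$adjacency <- c("49", "48")
  net <- load_network(nodes)
  expect_equal(net$m, 1)
})

test_that("frog hindlimb fixture matches the published census", {
  net <- frog_hindlimb()
  expect_equal(net$n, 54)
  expect_equal(net$m, 102)
  expect_equal(sum(net$nodes$type == "muscle"), 27)
  expect_equal(sum(net$nodes$type == "bone"), 20)
  expect_equal(sum(net$nodes$type == "connective_knot"), 7)

  deg <- degrees(net)
  expect_equal(unname(deg["22"]), 17)         # femur
  expect_equal(sum(deg), 2 * net$m)           # handshake lemma

  part <- published_partition(net)
  sizes <- table(part)
  expect_equal(sizes[["Hip"]], 9)
  expect_equal(sizes[["Thigh"]], 14)
  expect_equal(sizes[["Shank"]], 12)
  expect_equal(sizes[["Calf"]], 3)
  expect_equal(sizes[["Foot"]], 16)
})

test_that("degree census counts filtered nodes at each degree", {
  net <- frog_hindlimb()
  muscle_census <- degree_census(net, "muscle")
  expect_equal(unname(muscle_census["2"]), 22)
  expect_equal(sum(muscle_census), 27)

  star <- star_net(4)
  expect_equal(degree_census(star), c(`1` = 4L, `4` = 1L))

  isolated <- make_net(3, matrix(integer(0), ncol = 2))
  expect_equal(degree_census(isolated), c(`0` = 3L))
})

test_that("within-type edges isolate the quasi-bipartite deviation set", {
  net <- frog_hindlimb()
  mm <- find_within_type_edges(net, "muscle")
  expect_equal(nrow(mm), 1)
  expect_equal(as.vector(mm), c(8L, 20L))    # cruralis - extensor iliotib. B

  # removing that single edge leaves the muscle set fully independent
  keep <- !(net$edges[, 1] == 8 & net$edges[, 2] == 20)
  reduced <- anat_network(net$nodes, net$edges[keep, ])
  expect_equal(nrow(find_within_type_edges(reduced, "muscle")), 0)

  bb <- find_within_type_edges(net, "bone")
  expect_gt(nrow(bb), 0)
  expect_true(any(bb[, 1] == 1 & bb[, 2] == 22))  # acetabulum - femur joint
})

test_that("CSV and GraphML exports round-trip exactly", {
  net <- frog_hindlimb()
  edge_csv <- tempfile(fileext = ".csv")
  node_csv <- tempfile(fileext = ".csv")
  export_edge_csv(net, edge_csv)
  export_node_csv(net, node_csv)
  back <- load_network(node_csv, edge_csv)
  expect_equal(back$nodes[, c("id", "name", "type", "module")],
               net$nodes[, c("id", "name", "type", "module")])
  expect_equal(back$edges, net$edges)

  gml <- tempfile(fileext = ".graphml")
  export_graphml(net, gml)
  back2 <- load_graphml(gml)
  expect_equal(back2$nodes[, c("id", "name", "type", "module")],
               net$nodes[, c("id", "name", "type", "module")])
  expect_equal(back2$edges, net$edges)
  expect_equal(back2$n, 54)
  expect_equal(back2$m, 102)

  k2 <- make_net(2, cbind(1, 2))
  f <- tempfile(fileext = ".csv")
  export_edge_csv(k2, f)
  expect_equal(readLines(f), c("source,target", "1,2"))
})

test_that("round-trip identity holds across random synthetic networks", {
  set.seed(11)
  edge_csv <- tempfile(fileext = ".csv")
  node_csv <- tempfile(fileext = ".csv")
  gml <- tempfile(fileext = ".graphml")
  for (i in 1:100) {
    net <- random_net(sample(3:12, 1), p = stats::runif(1, 0.2, 0.6))
    export_edge_csv(net, edge_csv)
    export_node_csv(net, node_csv)
    back <- load_network(node_csv, edge_csv)
    expect_equal(back$edges, net$edges)
    expect_equal(sum(degrees(back)), 2 * back$m)
    if (i <= 20) {
      export_graphml(net, gml)
      expect_equal(load_graphml(gml)$edges, net$edges)
    }
  }
})
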