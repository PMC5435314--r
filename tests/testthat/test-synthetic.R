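test_that("limb-like generator produces valid quasi-bipartite anatomy", {
  net <- generate_limb_like(n_bones = 20, n_muscles = 27, n_knots = 7,
                            seed = 7)
  expect_equal(net$n, 54)
  expect_equal(sum(degrees(net)), 2 * net$m)
  expect_equal(nrow(find_within_type_edges(net, "muscle")), 0)
  expect_true(is_connected_net(net))

  # knots branch to at least knot_min_degree elements
  deg <- degrees(net)
  knots <- as.character(net$nodes$id[net$nodes$type == "connective_knot"])
  expect_true(all(deg[knots] >= 3))

  # all mass on degree 2 forces every muscle to degree exactly 2
  net2 <- generate_limb_like(10, 12, 3, muscle_degree_dist = c(`2` = 1),
                             seed = 2)
  muscles <- as.character(net2$nodes$id[net2$nodes$type == "muscle"])
  expect_true(all(degrees(net2)[muscles] == 2))

  # exception edges mimic the single published muscle-muscle contact
  net3 <- generate_limb_like(20, 27, 7, n_muscle_exceptions = 1, seed = 9)
  expect_equal(nrow(find_within_type_edges(net3, "muscle")), 1)

  expect_error(generate_limb_like(2, 5, 3, seed = 1), "infeasible")
  expect_error(generate_limb_like(10, 5, 2, knot_min_degree = 2, seed = 1),
               "knot_min_degree")
})

test_that("limb-like generation is seed-reproducible across varied parameters", {
  set.seed(71)
  for (i in 1:20) {
    nb <- sample(5:20, 1); nm <- sample(0:20, 1); nk <- sample(0:5, 1)
    if (nk > 0 && nb < 3) nb <- 3
    bk <- sample(c("chain", "tree"), 1)
    net <- generate_limb_like(nb, nm, nk, backbone = bk, seed = i)
    net_again <- generate_limb_like(nb, nm, nk, backbone = bk, seed = i)
    expect_identical(net$edges, net_again$edges)
    expect_equal(sum(degrees(net)), 2 * net$m)
    expect_equal(nrow(find_within_type_edges(net, "muscle")), 0)
    expect_true(is_connected_net(net))
  }
})

test_that("planted-partition generator honors its edge probabilities", {
  pl <- generate_planted(c(3, 3), p_in = 1, p_out = 0, seed = 1)
  expect_equal(pl$network$m, 6)
  expect_equal(unname(table(pl$partition)), c(3L, 3L), ignore_attr = TRUE)
  comp <- stats::setNames(rep(c("L", "R"), each = 3), 1:6)
  expect_equal(compare_partitions(pl$partition, comp)$ari, 1)

  # p_in = p_out: planted labels carry no signal, Q centers on zero
  # (Q of a fixed partition has a negative O(1/n) finite-size bias, so the
  # check runs at n = 40 where it sits well inside the band)
  qs <- vapply(1:100, function(s) {
    pl <- generate_planted(c(20, 20), p_in = 0.3, p_out = 0.3, seed = s)
    compute_Q(pl$network, pl$partition, build_null(pl$network, "standard"))
  }, 0)
  expect_lt(abs(mean(qs)), 0.02)
})

test_that("strong planted signal is recovered by the search pipeline", {
  aris <- vapply(1:20, function(s) {
    pl <- generate_planted(rep(10, 4), p_in = 0.5, p_out = 0.02, seed = s)
    null <- build_null(pl$network, "standard")
    res <- best_partition(pl$network, null, restarts = 10, seed = s)
    compare_partitions(res, pl$partition)$ari
  }, 0)
  expect_gte(mean(aris), 0.9)
})

test_that("rewiring preserves degrees and respects forbidden types", {
  net <- frog_hindlimb()
  rw <- degree_preserving_rewire(net, 500, seed = 2)
  expect_identical(degrees(rw), degrees(net))
  expect_identical(rw$nodes, net$nodes)
  expect_false(identical(rw$edges, net$edges))
  expect_true(attr(rw, "acceptance_rate") > 0)

  rw2 <- degree_preserving_rewire(net, 10 * net$m, seed = 5,
                                  respect_forbidden = "muscle")
  expect_lte(nrow(find_within_type_edges(rw2, "muscle")), 1)
  expect_identical(degrees(rw2), degrees(net))

  # determinism
  expect_identical(degree_preserving_rewire(net, 100, seed = 3)$edges,
                   degree_preserving_rewire(net, 100, seed = 3)$edges)
})

test_that("empirical Q null distribution behaves and is reproducible", {
  tri2 <- two_triangles()
  res <- q_null_distribution(tri2, n_replicates = 15, seed = 4)
  expect_equal(res$observed_q, 0.5)
  # no degree-preserving rewiring of two triangles can beat two clean cliques
  expect_equal(res$percentile, 100)

  empty <- q_null_distribution(tri2, n_replicates = 0, seed = 4)
  expect_length(empty$q_values, 0)
  expect_true(is.na(empty$percentile))

  a <- q_null_distribution(tri2, n_replicates = 5, seed = 9)
  b <- q_null_distribution(tri2, n_replicates = 5, seed = 9)
  expect_identical(a$q_values, b$q_values)
})

test_that("observed fixture modularity exceeds its rewired null mean", {
  net <- frog_hindlimb()
  res <- q_null_distribution(net, n_replicates = 8,
                             swaps_per_replicate = 5 * net$m, seed = 3,
                             restarts = 5)
  expect_gt(res$observed_q, mean(res$q_values))
})
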