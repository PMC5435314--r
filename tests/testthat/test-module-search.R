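test_that("exhaustive search finds known optima on tiny graphs", {
  bridged <- two_triangles(bridge = TRUE)
  res <- exhaustive_best(bridged, build_null(bridged, "standard"))
  expect_equal(unname(res$partition), rep(c("1", "2"), each = 3))

  k2 <- make_net(2, cbind(1, 2))
  res_k2 <- exhaustive_best(k2, build_null(k2, "standard"))
  expect_equal(res_k2$n_modules, 1)
  expect_equal(res_k2$q, 0)

  # 4-cycle: optimum over all 15 set partitions, found by direct scan
  c4 <- cycle_net(4)
  null4 <- build_null(c4, "standard")
  # direct scan over all 15 set partitions (RGS form, node 1 in module 1)
  best_q <- -Inf
  for (g2 in 1:2) for (g3 in 1:3) for (g4 in 1:4) {
    g <- c(1, g2, g3, g4)
    if (g3 > max(g[1:2]) + 1 || g4 > max(g[1:3]) + 1) next
    q <- compute_Q(c4, stats::setNames(as.character(g), 1:4), null4)
    best_q <- max(best_q, q)
  }
  res4 <- exhaustive_best(c4, null4)
  expect_equal(res4$q, best_q, tolerance = 1e-12)
  expect_error(exhaustive_best(path_net(13), build_null(path_net(13))),
               "n <= 12")
})

test_that("greedy agglomeration recovers clean components and a strong fixture baseline", {
  tri2 <- two_triangles()
  res <- greedy_agglomerative(tri2, build_null(tri2, "standard"))
  expect_equal(res$q, 0.5)
  expect_equal(res$n_modules, 2)

  net <- frog_hindlimb()
  res_f <- greedy_agglomerative(net, build_null(net, "standard"))
  expect_gte(res_f$q, 0.45)   # >= 90% of the published optimum
})

test_that("local moving is monotone and respects local optimality", {
  tri2 <- two_triangles()
  null <- build_null(tri2, "standard")
  singletons <- stats::setNames(as.character(1:6), 1:6)
  res <- refine_local_moving(tri2, null, singletons, seed = 5)
  expect_equal(res$q, 0.5)

  net <- random_net(10, 0.4)
  nullr <- build_null(net, "standard")
  opt <- exhaustive_best(net, nullr)
  refined <- refine_local_moving(net, nullr, opt$partition, seed = 2)
  expect_equal(refined$q, opt$q, tolerance = 1e-12)
  expect_equal(refined$partition, opt$partition)

  fr <- frog_hindlimb()
  nullf <- build_null(fr, "standard")
  greedy <- greedy_agglomerative(fr, nullf)
  for (s in c(1, 9)) {
    expect_gte(refine_local_moving(fr, nullf, greedy$partition, s)$q, greedy$q)
  }
})

test_that("best_partition is reproducible and its Q is recomputable", {
  net <- frog_hindlimb()
  null <- build_null(net, "standard")
  a <- best_partition(net, null, restarts = 8, seed = 4)
  b <- best_partition(net, null, restarts = 8, seed = 4)
  expect_identical(a$partition, b$partition)
  expect_identical(a$q, b$q)
  # no drift between incremental bookkeeping and from-scratch Q
  expect_equal(a$q, compute_Q(net, a$partition, null), tolerance = 1e-12)
})

test_that("fixture search attains the published modularity and partition", {
  net <- frog_hindlimb()
  null <- build_null(net, "standard")
  res <- best_partition(net, null, restarts = 20, seed = 1)
  q_pub <- compute_Q(net, published_partition(net), null)
  expect_gte(res$q, q_pub)
  expect_equal(round(res$q, 2), 0.49)
  expect_equal(res$n_modules, 5)
  cmp <- compare_partitions(res, published_partition(net))
  expect_equal(cmp$ari, 1)
})

test_that("partition comparison behaves at the boundaries", {
  p1 <- stats::setNames(rep(c("a", "b"), each = 5), 1:10)
  p2 <- stats::setNames(rep(c("Y", "X"), each = 5), 1:10)
  cmp <- compare_partitions(p1, p2)
  expect_equal(cmp$ari, 1)
  expect_equal(cmp$vi, 0)
  expect_equal(unname(cmp$label_map), c(a = "Y", b = "X"), ignore_attr = TRUE)

  singletons <- stats::setNames(as.character(1:10), 1:10)
  lumped <- stats::setNames(rep("m", 10), 1:10)
  expect_equal(compare_partitions(singletons, lumped)$ari, 0)

  net <- frog_hindlimb()
  pub <- published_partition(net)
  expect_equal(compare_partitions(pub, pub)$ari, 1)
  expect_error(compare_partitions(p1, stats::setNames("a", 99)),
               "different node sets")

  # cross-check ARI against mclust on random label vectors
  skip_if_not_installed("mclust")
  set.seed(41)
  for (i in 1:20) {
    x <- stats::setNames(sample(letters[1:4], 30, TRUE), 1:30)
    y <- stats::setNames(sample(letters[1:3], 30, TRUE), 1:30)
    expect_equal(compare_partitions(x, y)$ari,
                 mclust::adjustedRandIndex(x[as.character(1:30)],
                                           y[as.character(1:30)]),
                 tolerance = 1e-12)
  }
})

test_that("heuristic search matches the exhaustive optimum on small graphs", {
  set.seed(51)
  hits <- 0
  n_cases <- 30
  for (i in seq_len(n_cases)) {
    net <- random_net(sample(5:9, 1), p = stats::runif(1, 0.3, 0.6))
    null <- build_null(net, "standard")
    opt <- exhaustive_best(net, null)
    heur <- best_partition(net, null, restarts = 20, seed = i)
    expect_lte(heur$q, opt$q + 1e-9)   # the oracle is an upper bound
    if (heur$q >= opt$q - 1e-9) hits <- hits + 1
  }
  expect_gte(hits / n_cases, 0.95)
})
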