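test_that("primary inputs qualify by occupancy or containment routes", {
  d <- c(6, 6, 6)
  sub <- cube_mask(d, c(1, 1, 1), c(3, 3, 3))   # 27 voxels
  filling <- sub
  tiny_inside <- cube_mask(d, c(1, 1, 1), c(1, 1, 2))  # 2 voxels, all inside
  outside <- cube_mask(d, c(5, 5, 5), c(6, 6, 6))
  pi_df <- primary_inputs(sub, list(fill = filling, tiny = tiny_inside,
                                    out = outside))
  expect_true(pi_df$route1[pi_df$subregion == "fill"])
  expect_true(pi_df$route2[pi_df$subregion == "fill"])
  expect_false(pi_df$route1[pi_df$subregion == "tiny"])  # 2/27 < 20%
  expect_true(pi_df$route2[pi_df$subregion == "tiny"])   # 100% inside
  expect_false(pi_df$primary[pi_df$subregion == "out"])
  expect_error(primary_inputs(binary_mask(array(FALSE, dim = d), 100),
                              list(a = filling)), "empty")
})

test_that("a broad source is a primary input to every subdivision", {
  sc <- make_scene(scene_config(seed = 25, noise_sd = 0))
  broad <- binary_mask(sc$striatum_ipsi$values, 100)
  for (l in 1:4) {
    sub <- binary_mask(sc$truth$labels == l, 100)
    pi_df <- primary_inputs(sub, list(broad = broad))
    expect_true(pi_df$primary[1])
  }
})

test_that("corticocortical edges use a strict density cutoff", {
  dens <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  dens["a", "b"] <- 0.16
  dens["b", "c"] <- 0.15
  dens["c", "a"] <- 0.35
  e <- corticocortical_edges(dens, 0.15)
  expect_setequal(paste(e$source, e$target),
                  c("a b", "c a"))
  expect_equal(nrow(corticocortical_edges(matrix(0, 2, 2,
    dimnames = list(c("x", "y"), c("x", "y"))))), 0)
})

test_that("tier-averaged convergence qualifies primary convergent inputs", {
  d <- c(5, 5, 5)
  a <- cube_mask(d, c(1, 1, 1), c(3, 3, 3))
  same <- list(dense = list(a = a, b = a),
               moderate = list(a = a, b = a),
               diffuse = list(a = a, b = a))
  conv <- primary_convergent(same)
  expect_true(all(conv$convergence == 1))
  expect_true(all(conv$qualifies))

  disjoint <- cube_mask(d, c(4, 4, 4), c(5, 5, 5))
  apart <- list(dense = list(a = a, b = disjoint),
                moderate = list(a = a, b = disjoint),
                diffuse = list(a = a, b = disjoint))
  conv2 <- primary_convergent(apart)
  expect_true(all(conv2$convergence == 0))
  expect_false(any(conv2$qualifies))

  # empty tiers drop out of the mean
  empty <- binary_mask(array(FALSE, dim = d), 100)
  mixed <- list(dense = list(a = a, b = a),
                moderate = list(a = empty, b = a),
                diffuse = list(a = a, b = a))
  conv3 <- primary_convergent(mixed)
  expect_equal(conv3$n_tiers[conv3$target == "a"], 2)
})

test_that("thalamic edges apply the strict 20% rule by relation", {
  cov <- data.frame(nucleus = c("MD", "Pf", "VM"),
                    target = "M1",
                    fraction = c(0.25, 0.2, 0.05))
  e <- thalamic_edges(cov, "thalamostriatal", 0.2)
  expect_equal(e$source, "MD")
  e2 <- thalamic_edges(cov, "corticothalamic", 0.2)
  expect_equal(e2$source, "M1")  # direction reversed for feedback
  expect_equal(e2$target, "MD")
})

test_that("edge sets are anti-monotone in every cutoff", {
  set.seed(51)
  dens <- matrix(stats::runif(64), 8, 8,
                 dimnames = list(paste0("s", 1:8), paste0("s", 1:8)))
  prev <- Inf
  for (cut in c(0.1, 0.2, 0.4, 0.6)) {
    n <- nrow(corticocortical_edges(dens, cut))
    expect_lte(n, prev)
    prev <- n
  }
  cov <- data.frame(nucleus = paste0("n", 1:20), target = "t",
                    fraction = stats::runif(20))
  prev <- Inf
  for (cut in c(0.1, 0.3, 0.5)) {
    n <- nrow(thalamic_edges(cov, "thalamocortical", cut))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("circuit graphs round-trip through CSV and GraphML", {
  nodes <- data.frame(name = c("M1", "S1", "MD", "subdivA"),
                      class = c("cortical", "cortical", "thalamic",
                                "striatal_subdivision"))
  edges <- data.frame(
    source = c("M1", "MD", "M1"),
    target = c("S1", "subdivA", "MD"),
    type = c("corticocortical", "thalamostriatal", "corticothalamic"),
    weight = c(0.3, 0.6, 0.25)
  )
  g <- circuit_graph(nodes, edges)
  for (fmt in c("csv", "graphml")) {
    path <- tempfile(fileext = paste0(".", fmt))
    export_graph(g, path, fmt)
    back <- import_graph(path, fmt)
    expect_setequal(back$nodes$name, g$nodes$name)
    expect_equal(nrow(back$edges), nrow(g$edges))
    ord <- order(back$edges$source, back$edges$target)
    ord0 <- order(g$edges$source, g$edges$target)
    expect_equal(back$edges$weight[ord], g$edges$weight[ord0])
    expect_equal(back$edges$type[ord], g$edges$type[ord0])
  }
  # empty graph still round-trips
  g0 <- circuit_graph(nodes, edges[0, ])
  p0 <- tempfile(fileext = ".csv")
  export_graph(g0, p0, "csv")
  expect_equal(nrow(import_graph(p0, "csv")$edges), 0)
  # illegal class pairing is rejected
  bad <- data.frame(source = "MD", target = "S1",
                    type = "corticocortical", weight = 0.5)
  expect_error(circuit_graph(nodes, bad), "illegal")
})
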