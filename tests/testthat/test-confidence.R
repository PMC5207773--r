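perfect_setup <- function() {
  d <- c(8, 8, 8)
  thal <- binary_mask(array(TRUE, dim = d), 100)
  full <- cube_mask(d, c(2, 2, 2), c(6, 6, 6))
  core <- erode_mask(full, 100)
  stri <- c(6, 6, 6)
  proj <- binary_mask(array(TRUE, dim = stri), 100)
  target <- classify_density(
    projection_volume(array(0.5, dim = stri), 100),
    binary_mask(array(TRUE, dim = stri), 100)
  )
  inj <- injection("perfect", "thalamic", full, core, proj)
  list(thalamus = thal, injection = inj, target = target, d = d)
}

test_that("criteria evaluation measures coverage and containment", {
  d <- c(6, 6, 6)
  target <- binary_mask(array(TRUE, dim = d), 100)  # 216 voxels
  mk_inj <- function(proj) {
    full <- cube_mask(c(4, 4, 4), c(1, 1, 1), c(3, 3, 3))
    injection("i", "thalamic", full, erode_mask(full, 100), proj)
  }
  frac_mask <- function(n) {
    v <- array(FALSE, dim = d)
    v[seq_len(n)] <- TRUE
    binary_mask(v, 100)
  }
  crit <- criteria_set("covered", "target", 0.10)
  # 7% coverage fails the 10% criterion, 12% passes
  expect_false(evaluate_criteria(list(mk_inj(frac_mask(15))),
                                 list(target = target), crit)[1, 1])
  expect_true(evaluate_criteria(list(mk_inj(frac_mask(26))),
                                list(target = target), crit)[1, 1])
  # containment inside the target vs coverage of it
  small_target <- frac_mask(11)  # 5% of grid
  inj <- mk_inj(binary_mask(small_target$values, 100))
  res <- evaluate_criteria(list(inj), list(target = small_target),
                           criteria_binary())
  # projection == target: fully covers it and lies fully within it
  expect_true(all(res[1, ]))
  empty_proj <- mk_inj(frac_mask(0))
  res0 <- evaluate_criteria(list(empty_proj), list(target = target),
                            criteria_binary())
  expect_false(any(res0))
  expect_error(evaluate_criteria(list(inj), list(target = frac_mask(0)),
                                 crit), "empty target")
})

test_that("a perfect injection reaches the maximum confidence level", {
  px <- perfect_setup()
  cm <- confidence_map_graded(list(px$injection),
                              px$target, px$thalamus)
  expect_equal(cm$max_level, 6)
  expect_equal(max(cm$values), 6)
  core <- px$injection$core$values
  fullshell <- px$injection$full$values & !core
  expect_true(all(cm$values[core] == 6))
  expect_true(all(cm$values[fullshell] == 3))
  expect_true(all(cm$values[!px$injection$full$values] == 0))

  cm8 <- confidence_map_binary_target(
    list(px$injection),
    binary_mask(array(TRUE, dim = c(6, 6, 6)), 100),
    px$thalamus
  )
  expect_equal(cm8$max_level, 8)
  expect_equal(max(cm8$values), 8)
  expect_true(all(cm8$values[core] == 8))
})

test_that("cores of never-satisfying injections are zeroed", {
  px <- perfect_setup()
  bad_proj <- binary_mask(array(FALSE, dim = c(6, 6, 6)), 100)
  bad <- injection("bad", "thalamic", px$injection$full, px$injection$core,
                   bad_proj)
  cm <- confidence_map_graded(list(bad), px$target, px$thalamus)
  expect_true(all(cm$values[bad$core$values] == 0))
  expect_true(all(cm$values >= 0))
})

test_that("confidence maps equal the per-voxel oracle on random scenes", {
  for (seed in 1:50) {
    sc <- random_injection_scene(seed)
    res <- matrix(stats::runif(length(sc$injections) * 3) < 0.5,
                  nrow = length(sc$injections))
    crit <- criteria_graded()
    cm <- build_confidence_map(sc$injections, res, crit, sc$thalamus)
    oracle <- confidence_oracle(sc$injections, res, sc$thalamus)
    expect_identical(cm$values, oracle)
  }
})

test_that("confidence support shrinks as cutoffs tighten", {
  set.seed(99)
  sc <- random_injection_scene(7, d = c(10, 10, 10), n_inj = 8)
  target <- random_mask(c(6, 6, 6), 0.5)
  support <- function(cutoffs) {
    crit <- criteria_set(rep("covered", 3), rep("target", 3), cutoffs)
    res <- evaluate_criteria(sc$injections, list(target = target), crit)
    cm <- build_confidence_map(sc$injections, res, crit, sc$thalamus)
    cm$values > 0
  }
  loose <- support(c(0.05, 0.1, 0.2))
  tight <- support(c(0.1, 0.2, 0.4))
  expect_true(all(!tight | loose))  # tight support is a subset
})

test_that("criteria are ranked easiest first with declared-order ties", {
  res <- cbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE),
               c(FALSE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_identical(rank_criteria(res), c(2L, 1L, 4L, 3L))
})

test_that("nuclear coverage is nested across levels and averaged", {
  px <- perfect_setup()
  cm <- confidence_map_graded(list(px$injection), px$target, px$thalamus)
  labels <- array(0L, dim = px$d)
  labels[1:4, , ] <- 1L
  labels[5:8, , ] <- 2L
  atlas <- atlas_partition(labels, c("1" = "nucA", "2" = "nucB"), 100)
  cov <- nuclear_coverage(cm, atlas, levels = c(1, 3, 5))
  expect_true(all(cov$level_1 >= cov$level_3))
  expect_true(all(cov$level_3 >= cov$level_5))
  expect_equal(cov$average,
               rowMeans(cov[, c("level_1", "level_3", "level_5")]))
  # all-zero map: zero coverage everywhere
  zero <- cm
  zero$values[] <- 0L
  cov0 <- nuclear_coverage(zero, atlas)
  expect_true(all(cov0$level_1 == 0))
})

test_that("overlaying two maps tallies the four categories correctly", {
  d <- c(4, 4, 4)
  mk <- function(vals) {
    structure(list(values = vals, max_level = 6L,
                   voxel_size_um = c(100, 100, 100)),
              class = "confidence_map")
  }
  a <- array(0L, dim = d); a[1:2, , ] <- 3L
  b <- array(0L, dim = d); b[2:3, , ] <- 3L
  ov <- overlay_confidence(mk(a), mk(b), 1, 1)
  expect_equal(unname(ov$counts["both"]), 16)
  expect_equal(unname(ov$counts["ts_only"]), 16)
  expect_equal(unname(ov$counts["tc_only"]), 16)
  expect_equal(unname(ov$counts["neither"]), 16)
  same <- overlay_confidence(mk(a), mk(a), 1, 1)
  expect_equal(unname(same$counts["both"]), sum(a >= 1))
  expect_equal(unname(same$counts["ts_only"]) +
                 unname(same$counts["tc_only"]), 0)
  # brute-force tally
  set.seed(5)
  x <- array(sample(0:6, 64, TRUE), dim = d)
  y <- array(sample(0:6, 64, TRUE), dim = d)
  ov2 <- overlay_confidence(mk(x), mk(y), 2, 3)
  expect_equal(unname(ov2$counts["both"]), sum(x >= 2 & y >= 3))
  expect_equal(unname(ov2$counts["ts_only"]), sum(x >= 2 & y < 3))
})
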