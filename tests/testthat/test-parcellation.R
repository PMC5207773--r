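test_that("feature matrix categories follow plurality with ties upward", {
  d <- c(3, 3, 3)
  stri <- binary_mask(array(TRUE, dim = d), 100)
  mk_map <- function(x) {
    classify_density(projection_volume(array(x, dim = d), 100), stri)
  }
  fm_dense <- build_feature_matrix(list(a = mk_map(0.5)), stri,
                                   voxel_um = 300)
  expect_true(all(fm_dense$features == 3L))
  fm_none <- build_feature_matrix(list(a = mk_map(0)), stri, voxel_um = 300)
  expect_true(all(fm_none$features == 0L))

  # perfect half/half split inside one coarse voxel: tie goes up
  v <- array(0, dim = c(2, 1, 1))
  v[1, 1, 1] <- 0.5
  cm <- classify_density(projection_volume(v, 100),
                         binary_mask(array(TRUE, dim = c(2, 1, 1)), 100))
  fm_tie <- build_feature_matrix(list(a = cm),
                                 binary_mask(array(TRUE, dim = c(2, 1, 1)),
                                             100), voxel_um = 200)
  expect_equal(unname(fm_tie$features[1, 1]), 3L)
  expect_error(build_feature_matrix(list(a = cm),
                                    binary_mask(array(FALSE,
                                                      dim = c(2, 1, 1)),
                                                100)),
               "empty")
})

test_that("spearman feature distances handle constant rows", {
  f <- rbind(c(0, 1, 2, 3), c(0, 1, 2, 3), c(3, 2, 1, 0), c(1, 1, 1, 1),
             c(1, 1, 1, 1))
  D <- as.matrix(feature_distance(f, "spearman"))
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 2)   # anti-correlated: 1 - (-1)
  expect_equal(D[4, 5], 0)   # identical constant rows
  expect_equal(D[1, 4], 1)   # constant vs varying: maximal rank distance
})

test_that("average-linkage dendrograms match a naive O(n^3) oracle", {
  set.seed(31)
  for (rep in 1:3) {
    n <- sample(20:50, 1)
    f <- matrix(stats::rnorm(n * 6), n)
    D <- feature_distance(f, "euclidean")
    hc <- stats::hclust(D, method = "average")
    coph_pkg <- as.matrix(stats::cophenetic(hc))
    coph_oracle <- average_linkage_oracle(D)
    expect_equal(unname(coph_pkg), coph_oracle, tolerance = 1e-10)
  }
  # two identical rows merge at height zero
  f2 <- rbind(c(1, 2, 3), c(1, 2, 3), c(9, 8, 7))
  hc2 <- cluster_voxels(f2)
  expect_equal(min(hc2$height), 0)
})

test_that("metric selection maximizes the cophenetic coefficient", {
  # ultrametric toy data: every metric fits its own dendrogram perfectly
  f <- rbind(c(0, 0, 0, 0), c(0, 0, 0, 0), c(5, 5, 5, 5), c(5, 5, 5, 5))
  f <- f + matrix(rep(c(0, 0.001, 0, 0.001), 4), 4)
  sel <- select_distance_metric(f, c("euclidean", "manhattan"))
  expect_true(all(sel$coefficients > 0.99))

  set.seed(17)
  sc <- make_scene(scene_config(seed = 12, shape = c(24, 20, 30)))
  sp <- scene_parcellation(sc)
  sub <- sp$fm$features[seq(1, nrow(sp$fm$features), by = 6), ]
  sel2 <- select_distance_metric(sub)
  expect_true(sel2$metric %in% names(sel2$coefficients))
  expect_equal(unname(sel2$coefficients[sel2$metric]),
               max(sel2$coefficients))
  # coefficients agree with a direct cophenetic recomputation
  for (m in c("euclidean", "spearman")) {
    D <- feature_distance(sub, m)
    hc <- stats::hclust(D, method = "average")
    expect_equal(unname(sel2$coefficients[m]),
                 suppressWarnings(stats::cor(D, stats::cophenetic(hc))),
                 tolerance = 1e-12)
  }
})

test_that("dendrogram cuts drop singletons and renumber clusters", {
  f <- rbind(
    matrix(rep(c(3, 0, 0), each = 5), 5, byrow = FALSE),
    matrix(rep(c(0, 3, 0), each = 5), 5, byrow = FALSE)
  )
  f <- f + matrix(stats::rnorm(30, 0, 0.01), 10)
  outlier <- c(-50, 80, -20)
  hc <- cluster_voxels(rbind(f, outlier), metric = "euclidean")
  p <- cut_dendrogram(hc, k = 3)
  expect_equal(p$n_clusters, 2)       # the singleton outlier is dropped
  expect_equal(sum(p$dropped), 1)
  expect_equal(sort(unique(p$labels[p$labels > 0])), 1:2)

  p1 <- cut_dendrogram(hc, k = 1)
  expect_equal(p1$n_clusters, 1)
  expect_error(cut_dendrogram(hc, k = 99), "exceeds")
})

test_that("planted subdivisions are recovered exactly at zero noise", {
  sc <- make_scene(scene_config(seed = 20, noise_sd = 0))
  sp <- scene_parcellation(sc, k = 4)
  ok <- sp$parcellation$labels > 0 & sp$truth > 0
  expect_equal(adjusted_rand_index(sp$parcellation$labels[ok],
                                   sp$truth[ok]), 1)
})

test_that("voxel parcellation is invariant to subregion column order", {
  sc <- make_scene(scene_config(seed = 21, shape = c(24, 20, 30)))
  sp <- scene_parcellation(sc, k = 4)
  perm <- sample(ncol(sp$fm$features))
  fm2 <- sp$fm
  fm2$features <- fm2$features[, perm]
  p2 <- cut_dendrogram(cluster_voxels(fm2), k = 4)
  expect_equal(adjusted_rand_index(sp$parcellation$labels, p2$labels), 1)
})

test_that("source clustering groups subregions with shared targets", {
  sc <- make_scene(scene_config(seed = 22, noise_sd = 0))
  sp <- scene_parcellation(sc)
  hc <- cluster_sources(sp$fm)
  # subregions assigned to the same subdivision have identical fields at
  # zero noise, so they merge at height 0
  truth_groups <- sc$truth$assignment$subdivision
  cut <- stats::cutree(hc, k = sc$config$n_planted_subdivisions)
  expect_equal(adjusted_rand_index(cut, truth_groups), 1)
})

test_that("contiguity reporting counts components per cluster", {
  sc <- make_scene(scene_config(seed = 23, noise_sd = 0))
  sp <- scene_parcellation(sc, k = 4)
  rep <- report_contiguity(sp$parcellation, sp$fm)
  expect_equal(nrow(rep), 4)
  expect_true(all(rep$n_components == 1))
  # deliberately split labels in two spatial halves
  p2 <- sp$parcellation
  half <- sp$fm$coords[, 1] <= stats::median(sp$fm$coords[, 1])
  p2$labels <- ifelse(half, 1L, 2L)
  # relabel one cluster into two far-apart blocks along A-P
  p2$labels[sp$fm$coords[, 1] == min(sp$fm$coords[, 1])] <- 2L
  p2$n_clusters <- 2L
  rep2 <- report_contiguity(p2, sp$fm)
  expect_gte(rep2$n_components[rep2$cluster == 2], 2)
})

test_that("the in-package ARI agrees with mclust", {
  skip_if_not_installed("mclust")
  set.seed(40)
  for (i in 1:10) {
    a <- sample(1:4, 60, TRUE)
    b <- sample(1:3, 60, TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(rep(1, 5), rep(2, 5)), 1)
})

test_that("linkage matrices export losslessly enough to rebuild sizes", {
  f <- matrix(stats::rnorm(40), 10)
  hc <- cluster_voxels(f, "euclidean")
  path <- tempfile(fileext = ".csv")
  write_linkage_csv(hc, path)
  lk <- utils::read.csv(path)
  expect_equal(nrow(lk), 9)
  expect_equal(lk$height, hc$height)
  expect_equal(lk$size[nrow(lk)], 10)
})
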