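# Voxel parcellation: cluster striatal voxels by their per-subregion input
# density signatures (ordinal categories none/diffuse/moderate/dense) with a
# rank-correlation distance and average linkage; sources are clustered the
# same way on the transposed matrix.

#' Build the voxel x subregion feature matrix
#'
#' The striatum is regridded to `voxel_um` voxels; each coarse voxel's
#' category for a subregion is the category covering the plurality of its
#' fine sub-voxels (ties go to the higher category, preserving dense cores at
#' boundaries). Fine voxels are assigned to the coarse voxel containing their
#' center, so a non-integral size ratio (100 um to 150 um) is supported. Rows
#' are restricted to coarse voxels whose plurality fine voxel is striatal.
#'
#' @param classmaps named list of `density_class_map` objects, one per
#'   subregion, on the fine grid.
#' @param striatum `binary_mask` on the fine grid.
#' @param voxel_um coarse voxel size (default 150).
#' @return An object of class `feature_matrix`: `features` (integer matrix
#'   voxels x subregions), `coords` (coarse voxel indices per row),
#'   `coarse_dim`, `voxel_um`.
#' @export
build_feature_matrix <- function(classmaps, striatum, voxel_um = 150) {
  stopifnot(length(classmaps) > 0, inherits(striatum, "binary_mask"))
  if (!sum(striatum$values)) stop("build_feature_matrix: empty striatum")
  d <- dim(striatum$values)
  vs <- striatum$voxel_size_um
  cdim <- pmax(1L, as.integer(ceiling(d * vs / voxel_um)))
  # coarse voxel containing each fine voxel's center
  cidx <- function(i, ax) pmin(cdim[ax], 1L + as.integer(
    floor((i - 0.5) * vs[ax] / voxel_um)))
  fi <- which(array(TRUE, dim = d), arr.ind = TRUE)
  coarse <- cbind(cidx(fi[, 1], 1), cidx(fi[, 2], 2), cidx(fi[, 3], 3))
  key <- (coarse[, 1] - 1L) + cdim[1] * ((coarse[, 2] - 1L) +
                                           cdim[2] * (coarse[, 3] - 1L))
  # striatal coarse voxels: plurality of fine voxels striatal (ties -> in)
  in_frac <- tapply(as.vector(striatum$values), key, mean)
  keep_keys <- as.numeric(names(in_frac))[in_frac >= 0.5]
  plurality <- function(cls_vec) {
    # plurality category per coarse voxel, ties to the higher category,
    # counted over striatal fine voxels only
    sel <- as.vector(striatum$values)
    ktab <- tapply(cls_vec[sel], key[sel], function(x) {
      tb <- tabulate(x + 1L, nbins = 4L)
      max(which(tb == max(tb))) - 1L
    })
    ktab
  }
  feat <- matrix(0L, length(keep_keys), length(classmaps))
  colnames(feat) <- names(classmaps) %||%
    sprintf("src%02d", seq_along(classmaps))
  for (j in seq_along(classmaps)) {
    check_same_grid(striatum, list(values = classmaps[[j]]$classes,
                                   voxel_size_um = vs))
    pj <- plurality(as.vector(classmaps[[j]]$classes))
    feat[, j] <- as.integer(pj[as.character(keep_keys)])
  }
  kk <- keep_keys
  coords <- cbind(
    ap = kk %% cdim[1] + 1L,
    dv = (kk %/% cdim[1]) %% cdim[2] + 1L,
    ml = kk %/% (cdim[1] * cdim[2]) + 1L
  )
  structure(
    list(features = feat, coords = coords, coarse_dim = cdim,
         voxel_um = voxel_um),
    class = "feature_matrix"
  )
}

#' Pairwise distances between feature rows
#'
#' `"spearman"` is 1 minus Spearman's rank correlation. Constant rows (zero
#' variance, e.g. all-zero border voxels) have an undefined rank correlation;
#' they are assigned distance 0 to identical rows and the maximal
#' rank-correlation distance 1 to all other rows, so they remain clusterable.
#'
#' @param features numeric matrix (rows are observations).
#' @param metric one of `"spearman"`, `"correlation"`, `"cosine"`,
#'   `"euclidean"`, `"manhattan"`.
#' @return A `dist` object.
#' @export
feature_distance <- function(features,
                             metric = c("spearman", "correlation", "cosine",
                                        "euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (metric %in% c("euclidean", "manhattan")) {
    return(stats::dist(features, method = metric))
  }
  x <- t(features)
  if (metric == "spearman") x <- apply(x, 2, rank)
  n <- ncol(x)
  if (metric == "cosine") {
    nrm <- sqrt(colSums(x^2))
    S <- crossprod(x) / outer(nrm, nrm)
    S[!is.finite(S)] <- 0
  } else {
    sds <- apply(x, 2, stats::sd)
    ok <- sds > 0
    S <- matrix(NA_real_, n, n)
    if (any(ok)) S[ok, ok] <- stats::cor(x[, ok, drop = FALSE])
  }
  D <- 1 - S
  if (metric %in% c("spearman", "correlation")) {
    # undefined correlations: distance 1, except identical rows at 0
    und <- which(is.na(D), arr.ind = TRUE)
    if (nrow(und)) {
      for (r in seq_len(nrow(und))) {
        i <- und[r, 1]; j <- und[r, 2]
        D[i, j] <- if (all(features[i, ] == features[j, ])) 0 else 1
      }
    }
  }
  diag(D) <- 0
  stats::as.dist(D)
}

#' Select the clustering distance metric by cophenetic correlation
#'
#' Computes an average-linkage dendrogram per candidate metric and its
#' cophenetic correlation coefficient (agreement between the original
#' pairwise distances and the dendrogram-implied distances); returns the
#' argmax.
#'
#' @param features numeric matrix with at least 2 rows.
#' @param candidates metrics to compare (see [feature_distance()]).
#' @return A list with `metric` (the best), and `coefficients` (named vector
#'   of cophenetic correlations).
#' @export
select_distance_metric <- function(features,
                                   candidates = c("spearman", "correlation",
                                                  "cosine", "euclidean",
                                                  "manhattan")) {
  stopifnot(nrow(features) >= 2)
  coefs <- vapply(candidates, function(m) {
    d <- feature_distance(features, m)
    hc <- stats::hclust(d, method = "average")
    if (stats::sd(d) == 0) return(1)  # ultrametric/degenerate: perfect fit
    suppressWarnings(stats::cor(d, stats::cophenetic(hc)))
  }, numeric(1))
  list(metric = candidates[which.max(coefs)], coefficients = coefs)
}

#' Cluster striatal voxels by input signature
#'
#' Agglomerative clustering with average linkage on the chosen distance
#' (default: 1 minus Spearman rank correlation between the voxels' feature
#' vectors). Deterministic: hclust's tie handling is reproducible for a fixed
#' input ordering.
#'
#' @param features a `feature_matrix` or plain numeric matrix.
#' @param metric distance metric (see [feature_distance()]).
#' @return An `hclust` dendrogram.
#' @export
cluster_voxels <- function(features, metric = "spearman") {
  m <- if (inherits(features, "feature_matrix")) features$features else
    features
  stopifnot(nrow(m) >= 2)
  stats::hclust(feature_distance(m, metric), method = "average")
}

#' Cluster input sources by their striatal targets
#'
#' The transpose analysis: sources are points in voxel space, clustered with
#' the same metric and linkage.
#'
#' @inheritParams cluster_voxels
#' @return An `hclust` dendrogram over sources.
#' @export
cluster_sources <- function(features, metric = "spearman") {
  m <- if (inherits(features, "feature_matrix")) features$features else
    features
  stopifnot(ncol(m) >= 2)
  stats::hclust(feature_distance(t(m), metric), method = "average")
}

#' Cut a dendrogram into a parcellation
#'
#' Cuts at a cluster count `k` or a `height`; clusters containing only one
#' voxel are dropped and their voxels flagged unassigned (label 0).
#'
#' @param dendrogram an `hclust` object.
#' @param k desired number of clusters (before singleton dropping).
#' @param height alternative: cut height.
#' @param drop_singletons drop one-voxel clusters (default TRUE).
#' @return An object of class `parcellation`: `labels` (0 = unassigned),
#'   `n_clusters` (surviving), `k_requested`, `dropped` (logical per row).
#' @export
cut_dendrogram <- function(dendrogram, k = NULL, height = NULL,
                           drop_singletons = TRUE) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$order)
  if (!is.null(k) && k > n) stop("cut_dendrogram: k exceeds the row count")
  raw <- if (!is.null(k)) stats::cutree(dendrogram, k = k) else
    stats::cutree(dendrogram, h = height)
  labels <- as.integer(raw)
  dropped <- rep(FALSE, n)
  if (drop_singletons) {
    sizes <- table(labels)
    single <- as.integer(names(sizes)[sizes == 1])
    dropped <- labels %in% single
    labels[dropped] <- 0L
  }
  # renumber surviving clusters consecutively by first appearance
  surv <- unique(labels[labels > 0])
  labels[labels > 0] <- match(labels[labels > 0], surv)
  structure(
    list(labels = labels, n_clusters = length(surv),
         k_requested = k %||% NA_integer_, height = height %||% NA_real_,
         dropped = dropped),
    class = "parcellation"
  )
}

#' Per-cluster contiguity report
#'
#' Counts 6-connected components of each surviving cluster when mapped back
#' onto the coarse voxel grid. Largely contiguous clusters (one component
#' each) indicate spatially coherent subdivisions even though no positional
#' information entered the clustering.
#'
#' @param parcellation a `parcellation`.
#' @param feature_matrix the `feature_matrix` the dendrogram was built from
#'   (provides voxel coordinates).
#' @return A data frame: cluster, n_voxels, n_components.
#' @export
report_contiguity <- function(parcellation, feature_matrix) {
  stopifnot(inherits(parcellation, "parcellation"),
            inherits(feature_matrix, "feature_matrix"))
  cdim <- feature_matrix$coarse_dim
  out <- NULL
  for (cl in seq_len(parcellation$n_clusters)) {
    sel <- parcellation$labels == cl
    if (!any(sel)) next
    v <- array(FALSE, dim = cdim)
    v[feature_matrix$coords[sel, , drop = FALSE]] <- TRUE
    cc <- connected_components(
      binary_mask(v, rep(feature_matrix$voxel_um, 3)))
    out <- rbind(out, data.frame(cluster = cl, n_voxels = sum(sel),
                                 n_components = cc$n_components))
  }
  out %||% data.frame(cluster = integer(), n_voxels = integer(),
                      n_components = integer())
}

#' Parcellation labels on the coarse grid
#'
#' @param parcellation a `parcellation`.
#' @param feature_matrix the matching `feature_matrix`.
#' @return Integer array over the coarse grid (0 outside / unassigned).
#' @export
parcellation_volume <- function(parcellation, feature_matrix) {
  v <- array(0L, dim = feature_matrix$coarse_dim)
  sel <- parcellation$labels > 0
  v[feature_matrix$coords[sel, , drop = FALSE]] <- parcellation$labels[sel]
  v
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two flat clusterings, used to compare a
#' parcellation with planted ground-truth labels.
#'
#' @param a,b integer label vectors of equal length.
#' @return The adjusted Rand index (1 = identical up to permutation).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Export a dendrogram as a linkage-matrix CSV
#'
#' Columns left, right (negative values are leaf indices, positive values
#' earlier merge rows), height, size.
#'
#' @param dendrogram an `hclust`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_linkage_csv <- function(dendrogram, path) {
  m <- dendrogram$merge
  sizes <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    sz <- function(x) if (x < 0) 1 else sizes[x]
    sizes[i] <- sz(m[i, 1]) + sz(m[i, 2])
  }
  utils::write.csv(
    data.frame(left = m[, 1], right = m[, 2],
               height = dendrogram$height, size = sizes),
    path, row.names = FALSE
  )
  invisible(path)
}
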