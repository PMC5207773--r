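# Independent oracles and small fixture builders. Every oracle here is a
# deliberately naive reimplementation (per-voxel loops, flood fill, O(n^3)
# agglomeration) kept separate from the package's vectorized code paths.

mask_from <- function(values, voxel = 100) binary_mask(values, voxel)

cube_mask <- function(dim3, from, to, voxel = 100) {
  v <- array(FALSE, dim = dim3)
  v[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  binary_mask(v, voxel)
}

random_mask <- function(dim3, p = 0.3, voxel = 100) {
  binary_mask(array(stats::runif(prod(dim3)) < p, dim = dim3), voxel)
}

# per-voxel erosion with an explicit structuring-element loop
erode_oracle <- function(mask, distance_um) {
  v <- mask$values
  d <- dim(v)
  vs <- mask$voxel_size_um
  r <- floor(distance_um / vs + 1e-9)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!v[i, j, k]) next
    keep <- TRUE
    for (a in -r[1]:r[1]) for (b in -r[2]:r[2]) for (c in -r[3]:r[3]) {
      if (abs(a) * vs[1] + abs(b) * vs[2] + abs(c) * vs[3] >
            distance_um + 1e-9) next
      ii <- i + a; jj <- j + b; kk <- k + c
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
            kk < 1 || kk > d[3] || !v[ii, jj, kk]) {
        keep <- FALSE
        break
      }
    }
    out[i, j, k] <- keep
  }
  binary_mask(out, vs)
}

# connected components via igraph on the voxel adjacency graph
components_oracle <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(0L)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  lookup <- stats::setNames(seq_len(n), key)
  edges <- c()
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (o in 1:3) {
    nb <- sweep(idx, 2, offs[o, ], `+`)
    nbkey <- paste(nb[, 1], nb[, 2], nb[, 3])
    hit <- nbkey %in% key
    edges <- c(edges, rbind(which(hit), lookup[nbkey[hit]]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$no
}

# per-voxel confidence accumulation with explicit loops over injections
confidence_oracle <- function(injections, criteria_results, thalamus,
                              n_full_subtract = 2) {
  counts <- colSums(criteria_results)
  ord <- order(-counts, seq_along(counts))
  rnk <- integer(length(counts))
  rnk[ord] <- seq_along(counts)
  d <- dim(thalamus$values)
  out <- array(0L, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    total <- 0L
    for (cr in seq_len(ncol(criteria_results))) {
      in_sat_full <- in_sat_core <- in_fail_core <- in_fail_full <- FALSE
      for (q in seq_along(injections)) {
        fullv <- injections[[q]]$full$values[i, j, k]
        corev <- injections[[q]]$core$values[i, j, k]
        if (criteria_results[q, cr]) {
          if (fullv) in_sat_full <- TRUE
          if (corev) in_sat_core <- TRUE
        } else {
          if (corev) in_fail_core <- TRUE
          if (fullv) in_fail_full <- TRUE
        }
      }
      total <- total + in_sat_full + in_sat_core - in_fail_core
      if (rnk[cr] <= n_full_subtract && in_fail_full) total <- total - 1L
    }
    for (q in seq_along(injections)) {
      if (sum(criteria_results[q, ]) == 0 &&
            injections[[q]]$core$values[i, j, k]) {
        total <- 0L
      }
    }
    if (total < 0L) total <- 0L
    if (!thalamus$values[i, j, k]) total <- 0L
    out[i, j, k] <- total
  }
  out
}

# a tiny random injection set on a small thalamic grid (cores are true
# erosions of the fulls so the injection() invariant holds)
random_injection_scene <- function(seed, d = c(8, 8, 8), n_inj = 5) {
  set.seed(seed)
  thal <- binary_mask(array(stats::runif(prod(d)) < 0.9, dim = d), 100)
  injections <- lapply(seq_len(n_inj), function(i) {
    ctr <- sapply(d, function(x) sample(2:(x - 1), 1))
    v <- array(FALSE, dim = d)
    idx <- which(array(TRUE, dim = d), arr.ind = TRUE)
    r <- stats::runif(1, 1.5, 3)
    v[idx[rowSums(sweep(idx, 2, ctr)^2) <= r^2, , drop = FALSE]] <- TRUE
    full <- binary_mask(v, 100)
    injection(id = paste0("inj", i), source = "thalamic", full = full,
              core = erode_mask(full, 100),
              projection = random_mask(c(6, 6, 6), p = 0.4))
  })
  list(thalamus = thal, injections = injections)
}

# naive O(n^3) average-linkage agglomeration returning the full cophenetic
# distance matrix
average_linkage_oracle <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  coph <- matrix(0, n, n)
  dmat <- D
  diag(dmat) <- Inf
  for (step in seq_len(n - 1)) {
    cur <- which(active)
    best <- c(NA, NA)
    bestd <- Inf
    for (a in cur) for (b in cur) {
      if (a < b && dmat[a, b] < bestd) {
        bestd <- dmat[a, b]
        best <- c(a, b)
      }
    }
    a <- best[1]; b <- best[2]
    for (x in members[[a]]) for (y in members[[b]]) {
      coph[x, y] <- coph[y, x] <- bestd
    }
    na <- length(members[[a]]); nb <- length(members[[b]])
    for (c in cur) {
      if (c == a || c == b) next
      dmat[a, c] <- dmat[c, a] <- (na * dmat[a, c] + nb * dmat[b, c]) /
        (na + nb)
    }
    members[[a]] <- c(members[[a]], members[[b]])
    active[b] <- FALSE
    dmat[b, ] <- dmat[, b] <- Inf
  }
  coph
}

# regrid scene truth labels + build the clustering inputs in one step
scene_parcellation <- function(scene, voxel_um = 150, k = 4) {
  maps <- lapply(scene$cortical_fields, classify_density,
                 striatum = scene$striatum)
  fm <- build_feature_matrix(maps, scene$striatum_ipsi, voxel_um)
  hc <- cluster_voxels(fm)
  p <- cut_dendrogram(hc, k = k)
  truth <- truth_labels_coarse(scene, fm)
  list(maps = maps, fm = fm, hc = hc, parcellation = p, truth = truth)
}
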