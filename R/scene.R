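# Synthetic tracing "experiments" with planted ground truth. The generator
# emulates the structure of real mesoscale tracing data -- a bilateral
# striatum section stack, ~15 cortical subregions each with a dense core and
# a wider diffuse halo, highly overlapping thalamic injections with eroded
# cores, planted striatal subdivisions with distinct input signatures, and a
# known sectioning misalignment -- so every downstream stage can be tested
# against known truth.

#' Scene configuration
#'
#' Defaults describe the study conditions the pipeline is designed for:
#' 100 um voxels, 15 cortical subregions, injections overlapping densely
#' enough to cover >93% of the thalamus, four planted striatal subdivisions,
#' and a few-degree sectioning misalignment.
#'
#' @param seed integer RNG seed; identical configs give identical scenes.
#' @param shape striatal grid dimensions (A-P, D-V, M-L).
#' @param voxel_size_um voxel edge length, micrometers.
#' @param n_cortical_subregions number of cortical input sources.
#' @param n_planted_subdivisions number of planted striatal subdivisions.
#' @param dense_level,moderate_level,diffuse_level fluorescence fractions
#'   painted into dense cores, moderate rings and diffuse halos.
#' @param noise_sd SD of i.i.d. Gaussian noise added to painted fractions
#'   (truncated to \[0, 1\]).
#' @param thalamus_shape thalamic grid dimensions.
#' @param n_thalamic_nuclei number of synthetic atlas nuclei.
#' @param injection_radius_um thalamic injection radius.
#' @param injection_spacing_um lattice spacing between injection centers;
#'   smaller than twice the radius so injections overlap heavily.
#' @param core_erosion_um erosion distance deriving injection cores.
#' @param projection_radius_um radius of the striatal spot innervated by each
#'   thalamic voxel under the planted thalamus-to-striatum map.
#' @param subdivision_voxel_um resolution at which subdivisions are planted
#'   (their boundaries align to this grid; default matches the 150 um
#'   clustering voxel size).
#' @param misalignment a [section_transform()] (angles/scales; per-section
#'   jitter is drawn at scene time from `jitter_sd_voxels`).
#' @param jitter_sd_voxels SD of the random per-section in-plane shifts.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(seed = 1,
                         shape = c(32, 26, 40),
                         voxel_size_um = 100,
                         n_cortical_subregions = 15,
                         n_planted_subdivisions = 4,
                         dense_level = 0.30,
                         moderate_level = 0.10,
                         diffuse_level = 0.015,
                         noise_sd = 0.02,
                         thalamus_shape = c(16, 12, 14),
                         n_thalamic_nuclei = 6,
                         injection_radius_um = 300,
                         injection_spacing_um = 200,
                         core_erosion_um = 100,
                         projection_radius_um = 200,
                         subdivision_voxel_um = 150,
                         misalignment = section_transform(
                           roll_deg = 3, pitch_deg = 2, yaw_deg = -2,
                           scale_ap = 1.05, scale_dv = 0.95, scale_ml = 1.08
                         ),
                         jitter_sd_voxels = 1) {
  stopifnot(inherits(misalignment, "section_transform"))
  if (n_planted_subdivisions > 2^n_cortical_subregions - 1) {
    stop("scene_config: more planted subdivisions than distinct subregion sets")
  }
  structure(as.list(environment()), class = "scene_config")
}

ellipsoid_mask <- function(d, center, radii, ml_taper = 0) {
  i <- slice.index(array(0, dim = d), 1)
  j <- slice.index(array(0, dim = d), 2)
  k <- slice.index(array(0, dim = d), 3)
  # dorsal (small D-V index) side is widened by ml_taper, giving the stack a
  # mild dorso-ventral asymmetry like the real dorsal striatum
  rml <- radii[3] * (1 + ml_taper * (center[2] - j) / radii[2])
  ((i - center[1]) / radii[1])^2 + ((j - center[2]) / radii[2])^2 +
    ((k - center[3]) / rml)^2 <= 1
}

ball_voxels <- function(radius_vox) {
  r <- ceiling(radius_vox)
  g <- as.matrix(expand.grid(a = -r:r, b = -r:r, c = -r:r,
                             KEEP.OUT.ATTRS = FALSE))
  g[rowSums(g^2) <= radius_vox^2 + 1e-9, , drop = FALSE]
}

paint_balls <- function(d, centers, radius_vox) {
  out <- array(FALSE, dim = d)
  off <- ball_voxels(radius_vox)
  for (i in seq_len(nrow(centers))) {
    p <- sweep(off, 2, centers[i, ], `+`)
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    out[p[ok, , drop = FALSE]] <- TRUE
  }
  out
}

#' Generate a synthetic tracing scene
#'
#' Builds, deterministically from the config seed: a bilateral striatum mask
#' with an anterior-commissure surrogate landmark; contiguous planted
#' subdivisions of the ipsilateral striatum (Voronoi cells of k-means
#' centers); per-subregion cortical projection volumes with a dense core over
#' the assigned subdivision and moderate/diffuse halos around it; a thalamus
#' with a nucleus partition; overlapping thalamic injections (full + eroded
#' core) whose striatal projection fields follow a planted linear
#' thalamus-to-striatum map; and the ground-truth labels/transform.
#'
#' @param config a [scene_config()].
#' @return An object of class `scene`.
#' @export
make_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  d <- config$shape
  vs <- check_voxel_size(config$voxel_size_um)

  ## bilateral striatum ------------------------------------------------------
  ctr_ap <- d[1] / 2 + 0.5
  ctr_dv <- d[2] / 2
  radii <- c(0.40 * d[1], 0.36 * d[2], 0.22 * d[3] / 2)
  ml_left <- 0.27 * d[3]
  ml_right <- 0.73 * d[3]
  left <- ellipsoid_mask(d, c(ctr_ap, ctr_dv, ml_left), radii, ml_taper = 0.2)
  right <- ellipsoid_mask(d, c(ctr_ap, ctr_dv, ml_right), radii, ml_taper = 0.2)
  striatum <- binary_mask(left | right, vs)
  hemi <- array(FALSE, dim = d)
  hemi[, , seq_len(d[3]) > d[3] / 2] <- TRUE
  striatum_ipsi <- binary_mask(striatum$values & hemi, vs)

  ## anterior-commissure surrogate landmark ---------------------------------
  lm_centers <- rbind(
    c(round(ctr_ap - 0.55 * radii[1]), round(ctr_dv + 0.75 * radii[2]),
      round(ml_left + 0.55 * radii[3])),
    c(round(ctr_ap - 0.55 * radii[1]), round(ctr_dv + 0.75 * radii[2]),
      round(ml_right - 0.55 * radii[3]))
  )
  landmark <- binary_mask(paint_balls(d, lm_centers, 1.6), vs)

  ## planted subdivisions (ipsilateral) --------------------------------------
  # subdivisions are Voronoi cells of k-means centers, planted at the
  # parcellation working resolution (subdivision_voxel_um) so that their
  # boundaries coincide with the coarse clustering grid and the planted
  # labels are exactly representable there
  S <- config$n_planted_subdivisions
  coords <- which(striatum_ipsi$values, arr.ind = TRUE)
  cell <- floor(sweep(coords - 0.5, 2, vs, `*`) / config$subdivision_voxel_um)
  cell_id <- interaction(cell[, 1], cell[, 2], cell[, 3], drop = TRUE)
  cell_centers <- do.call(rbind, lapply(split(seq_len(nrow(coords)), cell_id),
                                        function(ix) colMeans(coords[ix, ,
                                                                     drop = FALSE])))
  km <- stats::kmeans(cell_centers, centers = S, nstart = 5, iter.max = 50)
  # stable label order: by A-P, then D-V, then M-L of the cluster centers
  ord <- order(km$centers[, 1], km$centers[, 2], km$centers[, 3])
  relab <- match(seq_len(S), ord)
  truth_labels <- array(0L, dim = d)
  truth_labels[coords] <- relab[km$cluster[as.integer(cell_id)]]

  ## cortical fields ----------------------------------------------------------
  # each subregion projects densely to one assigned subdivision (its compact
  # core projection field), at moderate strength to a second subdivision, and
  # diffusely across the rest of the ipsilateral striatum (the wide sparse
  # halo); every subdivision therefore carries a distinct input signature
  N <- config$n_cortical_subregions
  assignment <- ((seq_len(N) - 1L) %% S) + 1L
  secondary <- (assignment %% S) + 1L
  subregion_names <- sprintf("ctx%02d", seq_len(N))
  fields <- vector("list", N)
  names(fields) <- subregion_names
  for (j in seq_len(N)) {
    v <- array(0, dim = d)
    v[striatum_ipsi$values] <- config$diffuse_level
    v[truth_labels == secondary[j]] <- config$moderate_level
    v[truth_labels == assignment[j]] <- config$dense_level
    if (config$noise_sd > 0) {
      inside <- striatum_ipsi$values
      v[inside] <- v[inside] + stats::rnorm(sum(inside), 0, config$noise_sd)
    }
    v[!striatum$values] <- 0
    fields[[j]] <- projection_volume(pmin(pmax(v, 0), 1), vs,
                                     origin_label = subregion_names[j])
  }

  ## thalamus + atlas ---------------------------------------------------------
  td <- config$thalamus_shape
  thal <- ellipsoid_mask(td, c(td[1] / 2 + 0.5, td[2] / 2 + 0.5,
                               td[3] / 2 + 0.5),
                         0.42 * td)
  thalamus <- binary_mask(thal, vs)
  tcoords <- which(thal, arr.ind = TRUE)
  tkm <- stats::kmeans(tcoords, centers = config$n_thalamic_nuclei,
                       nstart = 5, iter.max = 50)
  tord <- order(tkm$centers[, 1], tkm$centers[, 2], tkm$centers[, 3])
  trelab <- match(seq_len(config$n_thalamic_nuclei), tord)
  atlas_labels <- array(0L, dim = td)
  atlas_labels[tcoords] <- trelab[tkm$cluster]
  atlas <- atlas_partition(
    atlas_labels,
    stats::setNames(sprintf("nuc%02d", seq_len(config$n_thalamic_nuclei)),
                    seq_len(config$n_thalamic_nuclei)),
    vs
  )

  ## planted thalamus -> striatum map ----------------------------------------
  # linear map from the thalamic bounding box onto the ipsilateral striatal
  # bounding box; each thalamic voxel innervates a small striatal ball there
  tbb <- apply(tcoords, 2, range)
  sbb <- apply(coords, 2, range)
  map_fun <- function(tc) {
    sc <- matrix(0, nrow(tc), 3)
    for (k in 1:3) {
      f <- (tc[, k] - tbb[1, k]) / max(1, tbb[2, k] - tbb[1, k])
      sc[, k] <- round(sbb[1, k] + f * (sbb[2, k] - sbb[1, k]))
    }
    sc
  }

  ## overlapping thalamic injections -----------------------------------------
  r_inj <- config$injection_radius_um / vs[1]
  sp <- max(1L, as.integer(round(config$injection_spacing_um / vs[1])))
  grid <- as.matrix(expand.grid(
    a = seq(tbb[1, 1], tbb[2, 1], by = sp),
    b = seq(tbb[1, 2], tbb[2, 2], by = sp),
    c = seq(tbb[1, 3], tbb[2, 3], by = sp)
  ))
  jit <- matrix(sample(-1:1, length(grid), replace = TRUE), ncol = 3)
  centers <- grid + jit
  keep <- centers[, 1] >= 1 & centers[, 1] <= td[1] &
    centers[, 2] >= 1 & centers[, 2] <= td[2] &
    centers[, 3] >= 1 & centers[, 3] <= td[3]
  centers <- centers[keep, , drop = FALSE]
  centers <- centers[thal[centers], , drop = FALSE]
  r_proj <- config$projection_radius_um / vs[1]
  injections <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    full_v <- paint_balls(td, centers[i, , drop = FALSE], r_inj)
    full <- binary_mask(full_v, vs)
    core <- erode_mask(full, config$core_erosion_um)
    src <- which(full_v & thal, arr.ind = TRUE)
    proj_v <- paint_balls(d, map_fun(src), r_proj) & striatum_ipsi$values
    injections[[i]] <- injection(
      id = sprintf("thal_inj%03d", i), source = "thalamic",
      full = full, core = core,
      projection = binary_mask(proj_v, vs),
      core_erosion_um = config$core_erosion_um
    )
  }

  ## fabricated connectivity tables ------------------------------------------
  # corticocortical and corticothalamic densities arrive preprocessed in the
  # real workflow; here they carry planted block structure: subregions
  # assigned to the same subdivision are strongly interconnected, and each
  # nucleus projects to / receives from the subregions of "its" subdivision
  same_block <- outer(assignment, assignment, `==`)
  cortical_density <- matrix(stats::runif(N * N, 0, 0.08), N, N,
                             dimnames = list(subregion_names,
                                             subregion_names))
  cortical_density[same_block] <- stats::runif(sum(same_block), 0.2, 0.5)
  diag(cortical_density) <- 0
  nuc_names <- sprintf("nuc%02d", seq_len(config$n_thalamic_nuclei))
  nuc_block <- ((seq_len(config$n_thalamic_nuclei) - 1L) %% S) + 1L
  tc_rows <- expand.grid(nucleus = nuc_names, target = subregion_names,
                         stringsAsFactors = FALSE)
  tc_match <- nuc_block[match(tc_rows$nucleus, nuc_names)] ==
    assignment[match(tc_rows$target, subregion_names)]
  thalamocortical_coverage <- data.frame(
    tc_rows,
    fraction = ifelse(tc_match, stats::runif(nrow(tc_rows), 0.3, 0.7),
                      stats::runif(nrow(tc_rows), 0, 0.1))
  )
  corticothalamic_coverage <- data.frame(
    tc_rows,
    fraction = ifelse(tc_match, stats::runif(nrow(tc_rows), 0.25, 0.6),
                      stats::runif(nrow(tc_rows), 0, 0.1))
  )

  ## realized misalignment transform -----------------------------------------
  mis <- config$misalignment
  if (is.null(mis$per_section_shifts) && config$jitter_sd_voxels > 0) {
    shifts <- random_section_jitter(
      d[1], config$jitter_sd_voxels,
      weights = apply(striatum$values, 1, sum)
    )
    mis <- section_transform(mis$roll_deg, mis$pitch_deg, mis$yaw_deg,
                             mis$scale_ap, mis$scale_dv, mis$scale_ml,
                             per_section_shifts = shifts)
  }

  structure(
    list(
      striatum = striatum,
      striatum_ipsi = striatum_ipsi,
      landmark = landmark,
      thalamus = thalamus,
      atlas = atlas,
      cortical_fields = fields,
      thalamic_injections = injections,
      cortical_density = cortical_density,
      thalamocortical_coverage = thalamocortical_coverage,
      corticothalamic_coverage = corticothalamic_coverage,
      truth = list(
        labels = truth_labels,
        assignment = data.frame(subregion = subregion_names,
                                subdivision = assignment),
        transform = mis,
        thalamus_map = map_fun
      ),
      config = config
    ),
    class = "scene"
  )
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(
    "<scene> striatum %s (%d voxels ipsi), %d cortical fields, %d thalamic injections, %d planted subdivisions\n",
    paste(dim(x$striatum$values), collapse = "x"),
    sum(x$striatum_ipsi$values),
    length(x$cortical_fields), length(x$thalamic_injections),
    x$config$n_planted_subdivisions
  ))
  invisible(x)
}

#' Planted subdivision labels on a feature-matrix grid
#'
#' Regrids the scene's fine-resolution ground-truth labels to the coarse
#' voxels of a [build_feature_matrix()] result by plurality over the striatal
#' fine voxels of each coarse voxel (ties to the lower label; with the
#' default generator settings subdivision boundaries align with the coarse
#' grid, so no ties occur).
#'
#' @param scene a `scene`.
#' @param feature_matrix a `feature_matrix` built on the scene's striatum.
#' @return Integer labels, one per feature-matrix row.
#' @export
truth_labels_coarse <- function(scene, feature_matrix) {
  stopifnot(inherits(scene, "scene"),
            inherits(feature_matrix, "feature_matrix"))
  tv <- scene$truth$labels
  d <- dim(tv)
  vs <- scene$striatum$voxel_size_um
  cdim <- feature_matrix$coarse_dim
  voxel_um <- feature_matrix$voxel_um
  cidx <- function(i, ax) pmin(cdim[ax], 1L + as.integer(
    floor((i - 0.5) * vs[ax] / voxel_um)))
  fi <- which(tv > 0, arr.ind = TRUE)
  key <- (cidx(fi[, 1], 1) - 1L) + cdim[1] * ((cidx(fi[, 2], 2) - 1L) +
                                                cdim[2] * (cidx(fi[, 3], 3) - 1L))
  agg <- tapply(tv[fi], key, function(x) {
    tb <- tabulate(x)
    which.max(tb)
  })
  keys <- (feature_matrix$coords[, 1] - 1L) +
    cdim[1] * ((feature_matrix$coords[, 2] - 1L) +
                 cdim[2] * (feature_matrix$coords[, 3] - 1L))
  out <- as.integer(agg[as.character(keys)])
  out[is.na(out)] <- 0L
  out
}

#' Write a scene to disk
#'
#' Writes all volumes as NIfTI, truth tables as CSV, and the configuration as
#' JSON for provenance.
#'
#' @param scene a `scene`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume_nifti(scene$striatum, file.path(dir, "striatum.nii.gz"))
  write_volume_nifti(scene$striatum_ipsi,
                     file.path(dir, "striatum_ipsi.nii.gz"))
  write_volume_nifti(scene$landmark, file.path(dir, "landmark.nii.gz"))
  write_volume_nifti(scene$thalamus, file.path(dir, "thalamus.nii.gz"))
  write_volume_nifti(scene$atlas, file.path(dir, "atlas.nii.gz"))
  for (nm in names(scene$cortical_fields)) {
    write_volume_nifti(scene$cortical_fields[[nm]],
                       file.path(dir, paste0("field_", nm, ".nii.gz")))
  }
  truth_vol <- scene$truth$labels
  utils::write.csv(
    data.frame(which(truth_vol > 0, arr.ind = TRUE),
               label = truth_vol[truth_vol > 0]),
    file.path(dir, "truth_labels.csv"), row.names = FALSE
  )
  utils::write.csv(scene$truth$assignment,
                   file.path(dir, "truth_assignment.csv"), row.names = FALSE)
  cfg <- scene$config
  cfg$misalignment <- unclass(cfg$misalignment)
  jsonlite::write_json(cfg[!vapply(cfg, is.function, logical(1))],
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
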