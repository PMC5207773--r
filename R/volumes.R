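# Axis convention used throughout: axis 1 = anterior->posterior section index,
# axis 2 = dorsal->ventral, axis 3 = medial->lateral. Voxel centers sit at
# (i - 0.5) * voxel_size_um in physical coordinates, 1-based indexing.

#' Projection volume
#'
#' A 3D grid of per-voxel fluorescence fractions. Each value is the fraction of
#' the original imaging voxels inside a coarse voxel that contained positive
#' fluorescence, so all values lie in \[0, 1\].
#'
#' @param values numeric 3D array with values in \[0, 1\].
#' @param voxel_size_um positive voxel edge length(s) in micrometers; a scalar
#'   is recycled to all three axes.
#' @param origin_label free-text provenance label.
#' @return An object of class `projection_volume` with fields `values`,
#'   `voxel_size_um` (length 3) and `origin_label`.
#' @export
projection_volume <- function(values, voxel_size_um, origin_label = "") {
  values <- as_array3d(values)
  vs <- check_voxel_size(voxel_size_um)
  rng <- range(values, finite = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("projection_volume values must lie in [0, 1]")
  }
  structure(
    list(values = values, voxel_size_um = vs, origin_label = origin_label),
    class = "projection_volume"
  )
}

#' Binary mask
#'
#' @param values logical (or 0/1 numeric) 3D array.
#' @param voxel_size_um positive voxel edge length(s) in micrometers.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, voxel_size_um) {
  values <- as_array3d(values)
  storage.mode(values) <- "logical"
  vs <- check_voxel_size(voxel_size_um)
  structure(list(values = values, voxel_size_um = vs), class = "binary_mask")
}

#' Atlas partition
#'
#' Integer labels over a voxel grid: 0 is background, each positive label is a
#' named nucleus or subregion.
#'
#' @param labels integer 3D array (0 = background).
#' @param names named character vector or `data.frame(id, name)` mapping every
#'   nonzero label present in `labels` to a name.
#' @param voxel_size_um positive voxel edge length(s) in micrometers.
#' @return An object of class `atlas_partition`.
#' @export
atlas_partition <- function(labels, names, voxel_size_um) {
  labels <- as_array3d(labels)
  storage.mode(labels) <- "integer"
  vs <- check_voxel_size(voxel_size_um)
  if (is.data.frame(names)) {
    tab <- stats::setNames(as.character(names$name), names$id)
  } else {
    tab <- stats::setNames(as.character(names), base::names(names))
  }
  present <- sort(unique(labels[labels > 0L]))
  ids <- sort(as.integer(base::names(tab)))
  if (!identical(present, ids)) {
    stop("atlas_partition: name table ids must exactly match nonzero labels present")
  }
  structure(
    list(labels = labels, names = tab, voxel_size_um = vs),
    class = "atlas_partition"
  )
}

#' Labeled injection
#'
#' Pairs the full injection mask with its eroded core and the striatal
#' projection field it produced (traveling axons already excluded). The core
#' must be contained in the full mask; by construction it is the erosion of the
#' full mask by `core_erosion_um`.
#'
#' @param id injection identifier.
#' @param source `"thalamic"` or `"cortical"`.
#' @param full,core `binary_mask` objects on the injection-site grid.
#' @param projection `binary_mask` of the striatal projection field.
#' @param core_erosion_um erosion distance used to derive `core` (default 100).
#' @return An object of class `injection`.
#' @export
injection <- function(id, source = c("thalamic", "cortical"), full, core,
                      projection, core_erosion_um = 100) {
  source <- match.arg(source)
  stopifnot(inherits(full, "binary_mask"), inherits(core, "binary_mask"))
  check_same_grid(full, core)
  if (any(core$values & !full$values)) {
    stop("injection: core must be a subset of the full injection mask")
  }
  structure(
    list(id = as.character(id), source = source, full = full, core = core,
         projection = projection, core_erosion_um = core_erosion_um),
    class = "injection"
  )
}

#' @export
print.projection_volume <- function(x, ...) {
  cat(sprintf(
    "<projection_volume> %s voxels @ %s um, values in [%.3g, %.3g]\n",
    paste(dim(x$values), collapse = "x"),
    paste(x$voxel_size_um, collapse = "x"),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %s voxels @ %s um, %d foreground\n",
    paste(dim(x$values), collapse = "x"),
    paste(x$voxel_size_um, collapse = "x"), sum(x$values)
  ))
  invisible(x)
}

as_array3d <- function(values) {
  if (is.null(dim(values)) || length(dim(values)) != 3L) {
    stop("expected a 3D array")
  }
  values
}

check_voxel_size <- function(voxel_size_um) {
  vs <- as.numeric(voxel_size_um)
  if (length(vs) == 1L) vs <- rep(vs, 3L)
  if (length(vs) != 3L || any(!is.finite(vs)) || any(vs <= 0)) {
    stop("voxel_size_um must be positive on every axis")
  }
  vs
}

check_same_grid <- function(a, b) {
  av <- if (is.list(a)) a$values %||% a$labels else a
  bv <- if (is.list(b)) b$values %||% b$labels else b
  if (!identical(dim(av), dim(bv))) {
    stop("grids do not match: ", paste(dim(av), collapse = "x"), " vs ",
         paste(dim(bv), collapse = "x"))
  }
  if (is.list(a) && is.list(b) &&
      !is.null(a$voxel_size_um) && !is.null(b$voxel_size_um) &&
      !isTRUE(all.equal(a$voxel_size_um, b$voxel_size_um))) {
    stop("voxel sizes do not match")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shift array content by `by` voxels (positive = toward higher indices),
# filling vacated voxels with `fill`.
shift_array <- function(a, by, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    b <- by[k]
    if (abs(b) >= d[k]) return(out)
    if (b >= 0) {
      src[[k]] <- seq_len(d[k] - b)
      dst[[k]] <- seq_len(d[k] - b) + b
    } else {
      src[[k]] <- seq_len(d[k] + b) - b
      dst[[k]] <- seq_len(d[k] + b)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Offsets of the discrete ball {o : sum_k |o_k| * voxel_k <= distance}, the
# anisotropic generalization of the 6-connected unit ball (one voxel shell per
# voxel size of distance on an isotropic grid).
ball_offsets <- function(distance_um, voxel_size_um) {
  r <- floor(distance_um / voxel_size_um + 1e-9)
  g <- expand.grid(
    a = -r[1]:r[1], b = -r[2]:r[2], c = -r[3]:r[3],
    KEEP.OUT.ATTRS = FALSE
  )
  keep <- abs(g$a) * voxel_size_um[1] + abs(g$b) * voxel_size_um[2] +
    abs(g$c) * voxel_size_um[3] <= distance_um + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

#' Erode a binary mask
#'
#' Morphological erosion with a discrete ball structuring element whose radius
#' corresponds to `distance_um` at the mask's voxel size (6-connected unit ball
#' per voxel of distance on an isotropic grid; anisotropic voxel sizes are
#' honored per axis). Used to derive injection "cores" from full injection
#' masks, which absorbs the ~100 um alignment variability across brains.
#'
#' @param mask a `binary_mask`.
#' @param distance_um nonnegative erosion distance in micrometers.
#' @return The eroded `binary_mask` (always a subset of the input).
#' @export
erode_mask <- function(mask, distance_um) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.finite(distance_um) || distance_um < 0) {
    stop("erode_mask: distance_um must be nonnegative")
  }
  off <- ball_offsets(distance_um, mask$voxel_size_um)
  out <- mask$values
  for (i in seq_len(nrow(off))) {
    o <- off[i, ]
    if (all(o == 0)) next
    out <- out & shift_array(mask$values, -o, fill = FALSE)
  }
  binary_mask(out, mask$voxel_size_um)
}

#' Dilate a binary mask
#'
#' Morphological dilation with the same structuring element as [erode_mask()].
#'
#' @inheritParams erode_mask
#' @return The dilated `binary_mask`.
#' @export
dilate_mask <- function(mask, distance_um) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.finite(distance_um) || distance_um < 0) {
    stop("dilate_mask: distance_um must be nonnegative")
  }
  off <- ball_offsets(distance_um, mask$voxel_size_um)
  out <- mask$values
  for (i in seq_len(nrow(off))) {
    o <- off[i, ]
    if (all(o == 0)) next
    out <- out | shift_array(mask$values, o, fill = FALSE)
  }
  binary_mask(out, mask$voxel_size_um)
}

#' Fraction of a target mask covered by a probe mask
#'
#' The shared primitive behind every "X% of the volume covered" criterion:
#' `|target n probe| / |target|`.
#'
#' @param target,probe `binary_mask` objects on the same grid.
#' @return A fraction in \[0, 1\].
#' @export
coverage_fraction <- function(target, probe) {
  stopifnot(inherits(target, "binary_mask"), inherits(probe, "binary_mask"))
  check_same_grid(target, probe)
  n_target <- sum(target$values)
  if (n_target == 0L) {
    stop("coverage_fraction: empty target mask gives an undefined fraction")
  }
  sum(target$values & probe$values) / n_target
}

#' Zero a projection volume inside an exclusion mask
#'
#' Used to subtract manually masked regions such as fluorescence from
#' fasciculated traveling axons that do not synapse in the striatum.
#'
#' @param volume a `projection_volume`.
#' @param exclusion a `binary_mask` on the same grid.
#' @return The `projection_volume` with values inside `exclusion` set to 0.
#' @export
subtract_mask <- function(volume, exclusion) {
  stopifnot(inherits(volume, "projection_volume"),
            inherits(exclusion, "binary_mask"))
  check_same_grid(volume, exclusion)
  v <- volume$values
  v[exclusion$values] <- 0
  projection_volume(v, volume$voxel_size_um, volume$origin_label)
}

#' Downsample a fine binary mask to fractional coarse voxels
#'
#' Each coarse voxel holds the fraction of its fine sub-voxels that are true,
#' mirroring how full-resolution segmentation masks are binned into coarse
#' fluorescence-fraction voxels. The target voxel size must be an integer
#' multiple of the source voxel size on every axis; edges are padded with
#' background so mass is conserved exactly.
#'
#' @param mask a `binary_mask` at fine resolution.
#' @param target_voxel_um coarse voxel edge length in micrometers (scalar or
#'   per-axis).
#' @return A `projection_volume` at the coarse resolution.
#' @export
downsample_fraction <- function(mask, target_voxel_um) {
  stopifnot(inherits(mask, "binary_mask"))
  tv <- check_voxel_size(target_voxel_um)
  f <- tv / mask$voxel_size_um
  if (any(abs(f - round(f)) > 1e-8)) {
    stop("downsample_fraction: target voxel size must be an integer multiple ",
         "of the source voxel size on each axis")
  }
  f <- as.integer(round(f))
  d <- dim(mask$values)
  dc <- ceiling(d / f)
  padded <- array(FALSE, dim = dc * f)
  padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- mask$values
  # reshape to (f1, n1, f2, n2, f3, n3) and average over the block axes
  dim(padded) <- c(f[1], dc[1], f[2], dc[2], f[3], dc[3])
  coarse <- apply(padded, c(2, 4, 6), mean)
  projection_volume(coarse, tv)
}

#' Upsample a binary mask by an integer factor
#'
#' Block replication: each voxel becomes a `factor^3` block of voxels at
#' `voxel_size_um / factor`. Used to move masks to the finer resolution at
#' which section alignment operates.
#'
#' @param mask a `binary_mask`.
#' @param factor positive integer replication factor (scalar or per axis).
#' @return The upsampled `binary_mask`.
#' @export
upsample_mask <- function(mask, factor = 2) {
  stopifnot(inherits(mask, "binary_mask"))
  f <- as.integer(factor)
  if (length(f) == 1L) f <- rep(f, 3L)
  if (any(f < 1L)) stop("upsample_mask: factor must be a positive integer")
  d <- dim(mask$values)
  v <- mask$values[
    ceiling(seq_len(d[1] * f[1]) / f[1]),
    ceiling(seq_len(d[2] * f[2]) / f[2]),
    ceiling(seq_len(d[3] * f[3]) / f[3])
  ]
  binary_mask(v, mask$voxel_size_um / f)
}

#' Connected components of a binary mask
#'
#' Deterministic labeling under face (6-) adjacency by default. Labels are
#' assigned in increasing order of each component's smallest linear voxel
#' index.
#'
#' @param mask a `binary_mask`.
#' @param connectivity 6 (face), 18 (face+edge) or 26 (full) neighborhood.
#' @return A list with `labels` (an `atlas_partition` whose components are
#'   named `"cc<k>"`) and `n_components`.
#' @export
connected_components <- function(mask, connectivity = 6) {
  stopifnot(inherits(mask, "binary_mask"))
  stopifnot(connectivity %in% c(6, 18, 26))
  d <- dim(mask$values)
  lab <- array(0, dim = d)
  n <- sum(mask$values)
  if (n > 0L) {
    # seed each foreground voxel with its own id, then propagate the minimum
    # over the neighborhood until a fixed point: components end up labeled by
    # their smallest linear index
    lab[mask$values] <- which(mask$values)
    off <- neighbor_offsets(connectivity)
    repeat {
      nxt <- lab
      for (i in seq_len(nrow(off))) {
        sh <- shift_array(lab, off[i, ], fill = 0)
        upd <- mask$values & sh > 0 & (nxt == 0 | sh < nxt)
        nxt[upd] <- sh[upd]
      }
      if (identical(nxt, lab)) break
      lab <- nxt
    }
  }
  ids <- sort(unique(lab[lab > 0]))
  relab <- array(0L, dim = d)
  for (k in seq_along(ids)) relab[lab == ids[k]] <- k
  nm <- if (length(ids)) {
    stats::setNames(paste0("cc", seq_along(ids)), seq_along(ids))
  } else {
    stats::setNames(character(0), character(0))
  }
  list(
    labels = atlas_partition(relab, nm, mask$voxel_size_um),
    n_components = length(ids)
  )
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(a = -1:1, b = -1:1, c = -1:1,
                             KEEP.OUT.ATTRS = FALSE))
  l1 <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6" = l1 == 1,
    "18" = l1 >= 1 & l1 <= 2,
    "26" = l1 >= 1
  )
  g[keep, , drop = FALSE]
}
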