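# Graded projection-density classification and axis coverage profiles.
# Density tiers follow the fluorescence-fraction thresholds: a voxel is
# "dense" when over 20% of its original imaging sub-voxels contained
# fluorescent axons, "moderate" over 5%, "diffuse" over 0.5%.

DENSITY_LEVELS <- c(none = 0L, diffuse = 1L, moderate = 2L, dense = 3L)

#' Classify projection densities into graded tiers
#'
#' Voxel value v maps to dense if `v > thresholds[1]`, moderate if
#' `thresholds[2] < v <= thresholds[1]`, diffuse if
#' `thresholds[3] < v <= thresholds[2]`, else none. Comparisons are strictly
#' greater-than ("over 20%, 5%, and 0.5%"). Voxels outside the striatum are
#' none.
#'
#' @param volume a `projection_volume`.
#' @param striatum a `binary_mask` on the same grid.
#' @param thresholds strictly decreasing dense/moderate/diffuse cutoffs in
#'   (0, 1); default `c(0.2, 0.05, 0.005)`.
#' @return An object of class `density_class_map` with integer `classes`
#'   (0 = none, 1 = diffuse, 2 = moderate, 3 = dense) and the thresholds
#'   used.
#' @export
classify_density <- function(volume, striatum,
                             thresholds = c(0.2, 0.05, 0.005)) {
  stopifnot(inherits(volume, "projection_volume"),
            inherits(striatum, "binary_mask"))
  check_same_grid(volume, striatum)
  if (length(thresholds) != 3L || any(diff(thresholds) >= 0) ||
      any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("classify_density: thresholds must be strictly decreasing in (0,1)")
  }
  v <- volume$values
  cls <- array(0L, dim = dim(v))
  cls[v > thresholds[3]] <- 1L
  cls[v > thresholds[2]] <- 2L
  cls[v > thresholds[1]] <- 3L
  cls[!striatum$values] <- 0L
  structure(
    list(classes = cls, thresholds = thresholds,
         voxel_size_um = volume$voxel_size_um),
    class = "density_class_map"
  )
}

#' Voxelwise maximum over density class maps
#'
#' The cumulative projection map of a subregion: the ordinal maximum of the
#' class at each voxel across all individual injections.
#'
#' @param maps a nonempty list of `density_class_map` objects on one grid.
#' @return A `density_class_map`.
#' @export
max_density_map <- function(maps) {
  if (!length(maps)) stop("max_density_map: empty map list")
  stopifnot(all(vapply(maps, inherits, logical(1), "density_class_map")))
  out <- maps[[1]]$classes
  for (m in maps[-1]) {
    check_same_grid(list(values = out), list(values = m$classes))
    out <- pmax(out, m$classes)
  }
  structure(
    list(classes = out, thresholds = maps[[1]]$thresholds,
         voxel_size_um = maps[[1]]$voxel_size_um),
    class = "density_class_map"
  )
}

#' Mask of voxels at or above a density tier
#'
#' Tiers are cumulative by default, so the "diffuse projection field" is the
#' outer envelope including moderate and dense voxels; set
#' `cumulative = FALSE` for exclusive tiers.
#'
#' @param map a `density_class_map`.
#' @param tier `"dense"`, `"moderate"` or `"diffuse"`.
#' @param cumulative include higher tiers (default TRUE).
#' @return A `binary_mask`.
#' @export
tier_mask <- function(map, tier = c("dense", "moderate", "diffuse"),
                      cumulative = TRUE) {
  tier <- match.arg(tier)
  lv <- DENSITY_LEVELS[[tier]]
  v <- if (cumulative) map$classes >= lv else map$classes == lv
  binary_mask(v, map$voxel_size_um)
}

#' Axis coverage profile of a density tier
#'
#' For each slab of width `step_um` along an anatomical axis, the fraction of
#' striatal voxels in the slab covered by the tier ("striatal volumes
#' normalized in each step"). Slabs without striatal voxels are `NA`.
#'
#' @param map a `density_class_map`.
#' @param striatum a `binary_mask` on the same grid.
#' @param axis `"A-P"`, `"D-V"` or `"M-L"`.
#' @param step_um slab width, at least one voxel.
#' @param tier density tier (cumulative).
#' @return A data frame with `slab_position_um` (slab start) and `fraction`.
#' @export
axis_distribution <- function(map, striatum, axis = c("A-P", "D-V", "M-L"),
                              step_um = 100, tier = c("dense", "diffuse",
                                                      "moderate")) {
  axis <- match.arg(axis)
  tier <- match.arg(tier)
  ax <- match(axis, c("A-P", "D-V", "M-L"))
  vs <- map$voxel_size_um[ax]
  if (step_um < vs) {
    stop("axis_distribution: step smaller than the voxel size")
  }
  check_same_grid(list(values = map$classes), striatum)
  tm <- tier_mask(map, tier)$values & striatum$values
  n <- dim(map$classes)[ax]
  pos_um <- (seq_len(n) - 0.5) * vs
  slab <- floor(pos_um / step_um)
  cov_by <- tapply(apply(tm, ax, sum), slab, sum)
  str_by <- tapply(apply(striatum$values, ax, sum), slab, sum)
  data.frame(
    slab_position_um = as.numeric(names(str_by)) * step_um,
    fraction = ifelse(str_by > 0, as.numeric(cov_by) / as.numeric(str_by),
                      NA_real_)
  )
}
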