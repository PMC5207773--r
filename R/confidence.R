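# Confidence maps: localizing the thalamic origin of projections to a target
# striatal field at sub-injection resolution. Each overlapping injection is
# scored against graded inclusion criteria; injection masks are then added or
# subtracted voxelwise so that thalamic locations covered by many satisfying
# injection cores reach high confidence levels.

#' Criteria set for confidence mapping
#'
#' An ordered list of inclusion criteria. Each criterion has a measure
#' (`"covered"`: fraction of the target volume covered by the projection;
#' `"within"`: fraction of the projection volume inside the target), a target
#' name (resolved against the supplied target masks, e.g. `"diffuse"` /
#' `"dense"` tier fields or a single binary `"target"`), and a cutoff in
#' (0, 1]. The declared order is kept explicit and used to break ties when
#' ranking criteria by difficulty.
#'
#' @param measure character vector of `"covered"` / `"within"`.
#' @param target character vector of target names.
#' @param cutoff numeric cutoffs in (0, 1].
#' @return An object of class `criteria_set` (a data frame).
#' @export
criteria_set <- function(measure, target, cutoff) {
  stopifnot(all(measure %in% c("covered", "within")))
  if (any(cutoff <= 0) || any(cutoff > 1)) {
    stop("criteria_set: cutoffs must lie in (0, 1]")
  }
  structure(
    data.frame(measure = measure, target = target, cutoff = cutoff,
               order = seq_along(measure)),
    class = c("criteria_set", "data.frame")
  )
}

#' The six-level criteria set for graded-density targets
#'
#' 10% of the diffuse target volume covered, 5% of the dense target volume
#' covered, and 50% of the dense target volume covered.
#' @return A `criteria_set` with 3 criteria (confidence levels 0..6).
#' @export
criteria_graded <- function() {
  criteria_set(
    measure = c("covered", "covered", "covered"),
    target = c("diffuse", "dense", "dense"),
    cutoff = c(0.10, 0.05, 0.50)
  )
}

#' The eight-level criteria set for binary targets
#'
#' 10% of the target covered, 10% of the projection within the target, 25% of
#' the target covered, 25% of the projection within the target.
#' @return A `criteria_set` with 4 criteria (confidence levels 0..8).
#' @export
criteria_binary <- function() {
  criteria_set(
    measure = c("covered", "within", "covered", "within"),
    target = c("target", "target", "target", "target"),
    cutoff = c(0.10, 0.10, 0.25, 0.25)
  )
}

#' Evaluate inclusion criteria for every injection
#'
#' An entry is `TRUE` when the injection's striatal projection meets the
#' criterion's cutoff (at or above) for the named target field.
#'
#' @param injections list of `injection` objects whose `projection` masks
#'   share a grid with the targets.
#' @param targets named list of `binary_mask` target fields; every target
#'   named by `criteria` must be present and nonempty.
#' @param criteria a [criteria_set()].
#' @return A logical matrix, injections x criteria.
#' @export
evaluate_criteria <- function(injections, targets, criteria) {
  stopifnot(inherits(criteria, "criteria_set"))
  for (tn in unique(criteria$target)) {
    if (is.null(targets[[tn]])) {
      stop("evaluate_criteria: missing target field '", tn, "'")
    }
    if (!sum(targets[[tn]]$values)) {
      stop("evaluate_criteria: empty target field '", tn, "'")
    }
  }
  out <- matrix(FALSE, length(injections), nrow(criteria),
                dimnames = list(vapply(injections, `[[`, "", "id"), NULL))
  for (i in seq_along(injections)) {
    proj <- injections[[i]]$projection
    n_proj <- sum(proj$values)
    for (j in seq_len(nrow(criteria))) {
      tg <- targets[[criteria$target[j]]]
      frac <- if (criteria$measure[j] == "covered") {
        coverage_fraction(tg, proj)
      } else {
        if (n_proj == 0) 0 else sum(tg$values & proj$values) / n_proj
      }
      out[i, j] <- frac >= criteria$cutoff[j]
    }
  }
  out
}

#' Rank criteria from easiest to hardest
#'
#' "Easiest to meet" is determined empirically as descending count of
#' satisfying injections, ties broken by the declared criteria order.
#'
#' @param criteria_results logical injection x criterion matrix.
#' @return Integer ranks (1 = easiest) per criterion column.
#' @export
rank_criteria <- function(criteria_results) {
  counts <- colSums(criteria_results)
  ord <- order(-counts, seq_along(counts))
  rank <- integer(length(counts))
  rank[ord] <- seq_along(counts)
  rank
}

#' Build a confidence map from criteria results
#'
#' For each criterion, four binary union masks are formed across injections:
#' the area covered by satisfying full injections, by satisfying injection
#' cores, by non-satisfying cores, and by non-satisfying full injections.
#' The map adds one for each positive mask (full and core, so a location
#' inside satisfying cores gains two per criterion) and subtracts one for
#' the negative core mask; the negative full mask is subtracted only for the
#' two easiest-to-meet criteria. The layers are summed across criteria;
#' thalamic volumes occupied by cores of injections that satisfied no
#' criterion are set to zero; remaining negative values are clipped to zero;
#' and the map is restricted to the thalamus. The maximum attainable level
#' is twice the number of criteria (6 for the graded set, 8 for the binary
#' set).
#'
#' @param injections list of `injection` objects (full/core masks on the
#'   thalamic grid).
#' @param criteria_results logical matrix from [evaluate_criteria()].
#' @param criteria the [criteria_set()] used.
#' @param thalamus a `binary_mask` on the injection grid.
#' @param n_full_subtract how many of the easiest criteria also subtract full
#'   masks of non-satisfying injections (default 2; requires at least 2
#'   criteria).
#' @return An object of class `confidence_map` with integer `values`,
#'   `max_level`, and the criterion ranking used.
#' @export
build_confidence_map <- function(injections, criteria_results, criteria,
                                 thalamus, n_full_subtract = 2) {
  stopifnot(inherits(criteria, "criteria_set"),
            inherits(thalamus, "binary_mask"))
  n_crit <- nrow(criteria)
  if (n_full_subtract > 0 && n_crit < 2) {
    stop("build_confidence_map: the full-mask subtraction exception needs ",
         "at least 2 criteria")
  }
  rank <- rank_criteria(criteria_results)
  d <- dim(thalamus$values)
  acc <- array(0L, dim = d)
  union_mask <- function(idx, what) {
    out <- array(FALSE, dim = d)
    for (i in idx) out <- out | injections[[i]][[what]]$values
    out
  }
  for (j in seq_len(n_crit)) {
    sat <- which(criteria_results[, j])
    fail <- which(!criteria_results[, j])
    acc <- acc + union_mask(sat, "full") + union_mask(sat, "core") -
      union_mask(fail, "core")
    if (rank[j] <= n_full_subtract) {
      acc <- acc - union_mask(fail, "full")
    }
  }
  never <- rowSums(criteria_results) == 0
  for (i in which(never)) {
    acc[injections[[i]]$core$values] <- 0L
  }
  acc[acc < 0L] <- 0L
  acc[!thalamus$values] <- 0L
  structure(
    list(values = acc, max_level = 2L * n_crit,
         voxel_size_um = thalamus$voxel_size_um,
         criteria = criteria, rank = rank),
    class = "confidence_map"
  )
}

#' Confidence map for a graded-density target field
#'
#' Convenience wrapper: evaluates [criteria_graded()] against the diffuse and
#' dense tier fields of a target density map and builds the six-level map.
#'
#' @param injections list of `injection` objects.
#' @param target_map `density_class_map` of the target corticostriatal field.
#' @param thalamus `binary_mask` of the thalamus.
#' @return A `confidence_map` with `max_level` 6.
#' @export
confidence_map_graded <- function(injections, target_map, thalamus) {
  targets <- list(
    diffuse = tier_mask(target_map, "diffuse"),
    dense = tier_mask(target_map, "dense")
  )
  crit <- criteria_graded()
  res <- evaluate_criteria(injections, targets, crit)
  build_confidence_map(injections, res, crit, thalamus)
}

#' Confidence map for a binary target volume
#'
#' The eight-level variant used when the target is a binary striatal volume
#' (e.g. a clustered subdivision or a high/low-convergence compartment)
#' rather than a graded projection field.
#'
#' @param injections list of `injection` objects.
#' @param target `binary_mask` target volume in the striatum.
#' @param thalamus `binary_mask` of the thalamus.
#' @return A `confidence_map` with `max_level` 8.
#' @export
confidence_map_binary_target <- function(injections, target, thalamus) {
  crit <- criteria_binary()
  res <- evaluate_criteria(injections, list(target = target), crit)
  build_confidence_map(injections, res, crit, thalamus)
}

#' @export
print.confidence_map <- function(x, ...) {
  cat(sprintf("<confidence_map> levels 0..%d, %d voxels above zero\n",
              x$max_level, sum(x$values > 0)))
  invisible(x)
}

#' Per-nucleus coverage by confidence levels
#'
#' For each atlas nucleus and each requested level l, the fraction of nucleus
#' voxels with confidence at or above l ("covered by confidence level l"),
#' plus the across-levels average. Nuclei absent from the grid are `NA`.
#'
#' @param confmap a `confidence_map`.
#' @param atlas an `atlas_partition` on the same grid.
#' @param levels confidence levels to report (default `c(1, 3, 5)`).
#' @return A data frame: nucleus, one column per level, and `average`.
#' @export
nuclear_coverage <- function(confmap, atlas, levels = c(1, 3, 5)) {
  check_same_grid(list(values = confmap$values,
                       voxel_size_um = confmap$voxel_size_um),
                  list(values = atlas$labels,
                       voxel_size_um = atlas$voxel_size_um))
  ids <- as.integer(names(atlas$names))
  rows <- lapply(ids, function(id) {
    sel <- atlas$labels == id
    n <- sum(sel)
    fr <- if (n == 0) rep(NA_real_, length(levels)) else {
      vapply(levels, function(l) sum(confmap$values[sel] >= l) / n,
             numeric(1))
    }
    c(fr, mean(fr))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(paste0("level_", levels), "average")
  cbind(data.frame(nucleus = unname(atlas$names[as.character(ids)])), out)
}

#' Overlay two confidence maps
#'
#' Categorizes each voxel by threshold exceedance in a thalamostriatal and a
#' thalamocortical confidence map: neither, first only, second only, or both.
#'
#' @param ts,tc `confidence_map` objects on one grid.
#' @param cutoff_ts,cutoff_tc per-map level cutoffs (voxel counts when
#'   `value >= cutoff`).
#' @return A list with `category` (integer array: 0 neither, 1 ts only,
#'   2 tc only, 3 both) and the category `counts`.
#' @export
overlay_confidence <- function(ts, tc, cutoff_ts = 1, cutoff_tc = 1) {
  check_same_grid(list(values = ts$values), list(values = tc$values))
  a <- ts$values >= cutoff_ts
  b <- tc$values >= cutoff_tc
  cat_arr <- array(0L, dim = dim(ts$values))
  cat_arr[a & !b] <- 1L
  cat_arr[!a & b] <- 2L
  cat_arr[a & b] <- 3L
  counts <- c(neither = sum(cat_arr == 0L), ts_only = sum(cat_arr == 1L),
              tc_only = sum(cat_arr == 2L), both = sum(cat_arr == 3L))
  list(category = cat_arr, counts = counts,
       voxel_size_um = ts$voxel_size_um)
}
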