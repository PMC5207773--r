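# Input convergence: pairwise overlap of subregion projection fields and
# per-voxel convergence counts, with a mean-split into high/low compartments.

#' Pairwise projection-field convergence matrix
#'
#' `M[r, c]` is the fraction of subregion r's projection field covered by
#' subregion c's field. The matrix is not symmetric: a small field inside a
#' large one is fully covered while covering only part of it. Rows with empty
#' fields are `NA`, never silently 0.
#'
#' @param fields named list of `binary_mask` projection fields on one grid.
#' @return A square numeric matrix with subregion names.
#' @export
pairwise_convergence <- function(fields) {
  n <- length(fields)
  nm <- names(fields) %||% sprintf("field%02d", seq_len(n))
  M <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (r in seq_len(n)) {
    if (!sum(fields[[r]]$values)) next
    for (c in seq_len(n)) {
      M[r, c] <- coverage_fraction(fields[[r]], fields[[c]])
    }
  }
  M
}

#' Per-voxel input-convergence count
#'
#' The number of projection fields containing each voxel.
#'
#' @param fields nonempty list of `binary_mask` fields on one grid.
#' @return A `projection_volume`-shaped integer array wrapped as a list with
#'   `counts` and `voxel_size_um`.
#' @export
convergence_count <- function(fields) {
  if (!length(fields)) stop("convergence_count: need at least one field")
  acc <- array(0L, dim = dim(fields[[1]]$values))
  for (f in fields) {
    check_same_grid(fields[[1]], f)
    acc <- acc + f$values
  }
  list(counts = acc, voxel_size_um = fields[[1]]$voxel_size_um,
       n_fields = length(fields))
}

#' Split the striatum into high- and low-convergence compartments
#'
#' The threshold defaults to the mean convergence count over striatal voxels;
#' voxels strictly above it are "high", voxels at or below it "low" (a voxel
#' exactly at the mean goes to low).
#'
#' @param count result of [convergence_count()].
#' @param striatum a nonempty `binary_mask`.
#' @param threshold numeric threshold; default the striatal mean.
#' @return A list with `high`/`low` masks (a partition of the striatum), the
#'   `threshold` used, and per-compartment `mean` and `sd` of the counts.
#' @export
split_high_low <- function(count, striatum, threshold = NULL) {
  stopifnot(inherits(striatum, "binary_mask"))
  check_same_grid(list(values = count$counts,
                       voxel_size_um = count$voxel_size_um), striatum)
  if (!sum(striatum$values)) stop("split_high_low: empty striatum")
  vals <- count$counts[striatum$values]
  if (is.null(threshold)) threshold <- mean(vals)
  high <- count$counts > threshold & striatum$values
  low <- striatum$values & !high
  stat <- function(sel) {
    x <- count$counts[sel]
    c(mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  }
  list(
    high = binary_mask(high, striatum$voxel_size_um),
    low = binary_mask(low, striatum$voxel_size_um),
    threshold = threshold,
    high_stats = stat(high),
    low_stats = stat(low)
  )
}
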