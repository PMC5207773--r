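# Rigid + scale transforms of section stacks. Physical coordinates use the
# package axis convention (1 = A-P, 2 = D-V, 3 = M-L), voxel centers at
# (i - 0.5) * voxel_size_um, rotations about the grid center.

#' Section-stack transform
#'
#' Describes a sectioning misalignment: roll (rotation about the A-P axis),
#' pitch (about the M-L axis), yaw (about the D-V axis), per-axis scale
#' factors, and per-section in-plane (D-V, M-L) shifts in voxels.
#'
#' @param roll_deg,pitch_deg,yaw_deg rotation angles in degrees (|angle| <= 15).
#' @param scale_ap,scale_dv,scale_ml positive per-axis scale factors.
#' @param per_section_shifts `NULL` or an n_sections x 2 matrix of (D-V, M-L)
#'   voxel offsets.
#' @return An object of class `section_transform`.
#' @export
section_transform <- function(roll_deg = 0, pitch_deg = 0, yaw_deg = 0,
                              scale_ap = 1, scale_dv = 1, scale_ml = 1,
                              per_section_shifts = NULL) {
  ang <- c(roll_deg, pitch_deg, yaw_deg)
  if (any(!is.finite(ang)) || any(abs(ang) > 15)) {
    stop("section_transform: angles must be finite and within +/-15 degrees")
  }
  sc <- c(scale_ap, scale_dv, scale_ml)
  if (any(!is.finite(sc)) || any(sc <= 0)) {
    stop("section_transform: scales must be positive")
  }
  if (!is.null(per_section_shifts)) {
    per_section_shifts <- as.matrix(per_section_shifts)
    stopifnot(ncol(per_section_shifts) == 2L)
  }
  structure(
    list(roll_deg = roll_deg, pitch_deg = pitch_deg, yaw_deg = yaw_deg,
         scale_ap = scale_ap, scale_dv = scale_dv, scale_ml = scale_ml,
         per_section_shifts = per_section_shifts),
    class = "section_transform"
  )
}

rotation_matrix <- function(roll_deg, pitch_deg, yaw_deg) {
  a <- roll_deg * pi / 180   # about axis 1 (A-P): mixes D-V and M-L
  p <- pitch_deg * pi / 180  # about axis 3 (M-L): mixes A-P and D-V
  y <- yaw_deg * pi / 180    # about axis 2 (D-V): mixes A-P and M-L
  Rroll <- matrix(c(1, 0, 0,
                    0, cos(a), -sin(a),
                    0, sin(a), cos(a)), 3, byrow = TRUE)
  Rpitch <- matrix(c(cos(p), -sin(p), 0,
                     sin(p), cos(p), 0,
                     0, 0, 1), 3, byrow = TRUE)
  Ryaw <- matrix(c(cos(y), 0, sin(y),
                   0, 1, 0,
                   -sin(y), 0, cos(y)), 3, byrow = TRUE)
  Rroll %*% Rpitch %*% Ryaw
}

voxel_centers <- function(d, voxel_size_um) {
  i <- slice.index(array(0, dim = d), 1)
  j <- slice.index(array(0, dim = d), 2)
  k <- slice.index(array(0, dim = d), 3)
  cbind((as.vector(i) - 0.5) * voxel_size_um[1],
        (as.vector(j) - 0.5) * voxel_size_um[2],
        (as.vector(k) - 0.5) * voxel_size_um[3])
}

# Resample `values` under the *forward* physical map p' = M (p - c) + c:
# each output voxel looks up M^-1 (p' - c) + c in the input.
resample_affine <- function(values, M, voxel_size_um,
                            interp = c("nearest", "linear")) {
  interp <- match.arg(interp)
  d <- dim(values)
  ctr <- d * voxel_size_um / 2
  pts <- voxel_centers(d, voxel_size_um)
  src <- sweep(sweep(pts, 2, ctr) %*% t(solve(M)), 2, ctr, `+`)
  idx <- sweep(src, 2, voxel_size_um, `/`) + 0.5  # fractional 1-based index
  if (interp == "nearest") {
    ri <- round(idx)
    ok <- ri[, 1] >= 1 & ri[, 1] <= d[1] &
      ri[, 2] >= 1 & ri[, 2] <= d[2] &
      ri[, 3] >= 1 & ri[, 3] <= d[3]
    out <- array(if (is.logical(values)) FALSE else 0, dim = d)
    out[ok] <- values[cbind(ri[ok, 1], ri[ok, 2], ri[ok, 3])]
    out
  } else {
    lo <- floor(idx)
    fr <- idx - lo
    acc <- numeric(nrow(idx))
    vv <- values
    storage.mode(vv) <- "double"
    for (da in 0:1) for (db in 0:1) for (dc in 0:1) {
      ci <- cbind(lo[, 1] + da, lo[, 2] + db, lo[, 3] + dc)
      w <- (if (da) fr[, 1] else 1 - fr[, 1]) *
        (if (db) fr[, 2] else 1 - fr[, 2]) *
        (if (dc) fr[, 3] else 1 - fr[, 3])
      ok <- ci[, 1] >= 1 & ci[, 1] <= d[1] &
        ci[, 2] >= 1 & ci[, 2] <= d[2] &
        ci[, 3] >= 1 & ci[, 3] <= d[3]
      acc[ok] <- acc[ok] + w[ok] * vv[ci[ok, , drop = FALSE]]
    }
    array(acc, dim = d)
  }
}

apply_section_shifts <- function(values, shifts, inverse = FALSE) {
  if (is.null(shifts)) return(values)
  out <- values
  sgn <- if (inverse) -1L else 1L
  for (i in seq_len(dim(values)[1])) {
    s <- sgn * as.integer(round(shifts[i, ]))
    if (all(s == 0L)) next
    sec <- values[i, , ]
    d2 <- dim(sec)
    new <- array(if (is.logical(values)) FALSE else 0, dim = d2)
    r <- s[1]; c <- s[2]
    rs <- max(1, 1 - r):min(d2[1], d2[1] - r)
    cs <- max(1, 1 - c):min(d2[2], d2[2] - c)
    if (length(rs) && length(cs)) new[rs + r, cs + c] <- sec[rs, cs]
    out[i, , ] <- new
  }
  out
}

#' Random trend-free per-section jitter
#'
#' Integer (D-V, M-L) per-section offsets drawn as Gaussian white noise and
#' then detrended by a weighted linear fit along the section index. The
#' detrending is part of the jitter's definition: a linear shift profile
#' along A-P is, to first order, exactly a pitch (D-V) or yaw (M-L)
#' sectioning rotation, so leaving it in the "random" jitter would silently
#' change the planted angles.
#'
#' @param n_sections number of sections.
#' @param sd_voxels jitter standard deviation in voxels.
#' @param weights optional per-section weights for the detrending fit
#'   (typically the mask's per-section voxel counts).
#' @return An `n_sections` x 2 integer matrix of (D-V, M-L) offsets.
#' @export
random_section_jitter <- function(n_sections, sd_voxels = 1,
                                  weights = NULL) {
  raw <- matrix(stats::rnorm(2 * n_sections, 0, sd_voxels), ncol = 2)
  if (is.null(weights)) weights <- rep(1, n_sections)
  sec <- seq_len(n_sections)
  for (k in 1:2) {
    fit <- stats::lm(raw[, k] ~ sec, weights = weights)
    raw[, k] <- raw[, k] - stats::fitted(fit)
  }
  matrix(as.integer(round(raw)), ncol = 2)
}

#' Rescale a section transform to an upsampled grid
#'
#' Angles and scales are resolution-independent; per-section shifts are
#' replicated `factor` times along A-P and multiplied by `factor` (the same
#' physical offset in smaller voxels).
#'
#' @param transform a [section_transform()].
#' @param factor integer upsampling factor.
#' @return A [section_transform()] for the upsampled stack.
#' @export
upsample_transform <- function(transform, factor) {
  sh <- transform$per_section_shifts
  if (!is.null(sh)) {
    sh <- sh[rep(seq_len(nrow(sh)), each = factor), , drop = FALSE] * factor
  }
  section_transform(transform$roll_deg, transform$pitch_deg,
                    transform$yaw_deg, transform$scale_ap,
                    transform$scale_dv, transform$scale_ml,
                    per_section_shifts = sh)
}

#' Apply a sectioning misalignment to a section stack
#'
#' Applies the scale, then the roll/pitch/yaw rotation, then the per-section
#' in-plane shifts of a [section_transform()] to a mask or graded volume.
#' Nearest-neighbor resampling is used for masks (preserving binarity) and
#' trilinear interpolation for graded volumes.
#'
#' @param stack a `binary_mask` or `projection_volume` section stack.
#' @param transform a `section_transform`.
#' @return The transformed stack, same class as the input.
#' @export
apply_misalignment <- function(stack, transform) {
  stopifnot(inherits(transform, "section_transform"))
  R <- rotation_matrix(transform$roll_deg, transform$pitch_deg,
                       transform$yaw_deg)
  S <- diag(c(transform$scale_ap, transform$scale_dv, transform$scale_ml))
  M <- R %*% S
  if (inherits(stack, "binary_mask")) {
    v <- resample_affine(stack$values, M, stack$voxel_size_um, "nearest")
    v <- apply_section_shifts(v, transform$per_section_shifts)
    binary_mask(v, stack$voxel_size_um)
  } else if (inherits(stack, "projection_volume")) {
    v <- resample_affine(stack$values, M, stack$voxel_size_um, "linear")
    v <- apply_section_shifts(v, transform$per_section_shifts)
    projection_volume(pmin(pmax(v, 0), 1), stack$voxel_size_um,
                      stack$origin_label)
  } else {
    stop("apply_misalignment: expected a binary_mask or projection_volume")
  }
}
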