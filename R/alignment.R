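# Recovery of sectioning misalignment by center-of-mass registration of a
# striatum section stack against a template. Mirrors the histology workflow:
# verticalize each section (roll), estimate the aberrant sectioning angles
# (pitch, yaw) from hemisphere / dorso-ventral centers of mass, scale to the
# template, then iteratively align each section in D-V and M-L.

section_counts <- function(values) {
  apply(values, 1, sum)
}

com3 <- function(values, voxel_size_um, subset = NULL) {
  idx <- which(if (is.null(subset)) values else values & subset,
               arr.ind = TRUE)
  if (nrow(idx) == 0) return(rep(NA_real_, 3))
  (colMeans(idx) - 0.5) * voxel_size_um
}

#' Per-section midline points
#'
#' For each section with enough mask voxels in all four quadrants, two points
#' on the brain midline: the midpoint between the left and right hemisphere
#' centers of mass of the dorsal half, and the same for the ventral half. On
#' a bilaterally symmetric mask both midpoints lie on the midline, so the
#' vector between them tracks the roll of each section regardless of
#' per-section translations.
#'
#' @param stack a `binary_mask` section stack containing both hemispheres.
#' @param min_voxels minimum mask voxels per quadrant for a section to
#'   contribute.
#' @return A matrix with columns `section, dv_d, ml_d, dv_v, ml_v` (voxel
#'   units).
#' @export
midline_points <- function(stack, min_voxels = 10) {
  v <- stack$values
  out <- NULL
  for (i in seq_len(dim(v)[1])) {
    idx <- which(v[i, , ], arr.ind = TRUE)
    if (nrow(idx) < 2 * min_voxels) next
    mid_ml <- mean(idx[, 2])
    l <- idx[idx[, 2] <= mid_ml, , drop = FALSE]
    r <- idx[idx[, 2] > mid_ml, , drop = FALSE]
    if (nrow(l) < min_voxels || nrow(r) < min_voxels) next
    cl <- colMeans(l)
    cr <- colMeans(r)
    # the midline is the perpendicular bisector of the segment joining the
    # two hemisphere centers of mass; emit one point either side of the
    # midpoint along that bisector (dorsal first)
    mid <- (cl + cr) / 2
    perp <- c(cr[2] - cl[2], -(cr[1] - cl[1])) / 2
    out <- rbind(out, c(i, mid - perp, mid + perp))
  }
  if (is.null(out)) stop("midline_points: no usable sections")
  colnames(out) <- c("section", "dv_d", "ml_d", "dv_v", "ml_v")
  out
}

#' Estimate the roll angle of a section stack
#'
#' The angle that verticalizes the per-section midline, averaged over
#' sections. Midpoints default to [midline_points()] of the stack.
#'
#' @param stack a `binary_mask` section stack.
#' @param midpoints optional midline point matrix as from [midline_points()].
#' @return Roll angle in degrees (positive tilts the ventral midline toward
#'   increasing M-L).
#' @export
estimate_roll <- function(stack, midpoints = NULL) {
  if (is.null(midpoints)) midpoints <- midline_points(stack)
  vs <- stack$voxel_size_um
  ddv <- (midpoints[, "dv_v"] - midpoints[, "dv_d"]) * vs[2]
  dml <- (midpoints[, "ml_v"] - midpoints[, "ml_d"]) * vs[3]
  if (any(abs(ddv) < 1e-9 & abs(dml) < 1e-9)) {
    stop("estimate_roll: degenerate (coincident) midline points")
  }
  mean(atan2(dml, ddv)) * 180 / pi
}

hemi_stats <- function(stack) {
  v <- stack$values
  vs <- stack$voxel_size_um
  idx <- which(v, arr.ind = TRUE)
  mid_ml <- mean(idx[, 3])
  right <- idx[, 3] > mid_ml
  near_mid <- abs(idx[, 3] - mid_ml) < 0.05 * dim(v)[3]
  if (sum(right) < 0.05 * nrow(idx) || sum(!right) < 0.05 * nrow(idx) ||
        mean(near_mid) > 0.2) {
    stop("both hemispheres must be present in the stack")
  }
  mid_dv <- mean(idx[, 2])
  dorsal <- idx[, 2] <= mid_dv
  com <- function(sel) (colMeans(idx[sel, , drop = FALSE]) - 0.5) * vs
  list(
    right = com(right), left = com(!right),
    dorsal = com(dorsal), ventral = com(!dorsal)
  )
}

#' Estimate pitch and yaw sectioning angles
#'
#' Yaw (rotation about the D-V axis) is recovered from the anterior-posterior
#' offset between the two hemispheres' centers of mass (immune to in-plane
#' per-section jitter, which never moves content between sections); pitch
#' (about the M-L axis) from the principal-axis angle of the A-P/D-V
#' second-moment tensor, which rotates exactly with the mass distribution
#' for any shape. Both statistics are measured relative to the template, so
#' intrinsic shape asymmetry cancels. A realized linear trend in per-section
#' jitter is fundamentally confounded with pitch (a linear D-V shift profile
#' *is* a pitch, to first order); the synthetic generator therefore defines
#' jitter as trend-free (see [random_section_jitter()]).
#'
#' @param stack a `binary_mask` section stack containing both hemispheres.
#' @param template the reference `binary_mask` stack.
#' @return A list with `pitch_deg` and `yaw_deg`.
#' @export
estimate_pitch_yaw <- function(stack, template) {
  s <- hemi_stats(stack)
  t <- hemi_stats(template)
  solve_angle <- function(dap_obs, dap0, dother0) {
    f <- function(deg) {
      th <- deg * pi / 180
      cos(th) * dap0 + sin(th) * dother0 - dap_obs
    }
    stats::uniroot(f, c(-15, 15), tol = 1e-6)$root
  }
  yaw <- solve_angle(
    s$right[1] - s$left[1],
    t$right[1] - t$left[1],
    t$right[3] - t$left[3]
  )
  pitch <- (principal_angle_ap_dv(stack) - principal_angle_ap_dv(template)) *
    180 / pi
  list(pitch_deg = pitch, yaw_deg = yaw)
}

# principal-axis angle of the A-P/D-V second-moment tensor; rotates exactly
# with the mass distribution, for any shape
principal_angle_ap_dv <- function(stack) {
  idx <- which(stack$values, arr.ind = TRUE)
  vs <- stack$voxel_size_um
  x <- (idx[, 1] - 0.5) * vs[1]
  y <- (idx[, 2] - 0.5) * vs[2]
  0.5 * atan2(2 * stats::cov(x, y), stats::var(x) - stats::var(y))
}

scale_stats <- function(stack) {
  idx <- which(stack$values, arr.ind = TRUE)
  if (!nrow(idx)) stop("scale_stats: empty stack")
  c(ap = stats::sd(idx[, 1]), dv = stats::sd(idx[, 2]),
    ml = stats::sd(idx[, 3]))
}

#' Estimate per-axis scales against a template and undo them
#'
#' Each axis scale is the ratio of the mask's per-axis spatial standard
#' deviation to the template's. These moment-based extents respond linearly
#' to the planted scale, are insensitive to the ragged edges produced by
#' repeated nearest-neighbor resampling (unlike first/last-section spans or
#' top-of-mask widths), and are unchanged by zero-mean per-section jitter.
#' The returned stack is resampled by the inverse scales.
#'
#' @param stack a `binary_mask` section stack (rotation already corrected).
#' @param template the reference `binary_mask` stack.
#' @return A list with `stack` (scaled to the template) and `scales`
#'   (`c(ap, dv, ml)` — the estimated scale of the input relative to the
#'   template).
#' @export
scale_to_template <- function(stack, template) {
  s <- scale_stats(stack)
  t <- scale_stats(template)
  scales <- as.numeric(s / t)
  v <- resample_affine(stack$values, diag(1 / scales),
                       stack$voxel_size_um, "nearest")
  list(stack = binary_mask(v, stack$voxel_size_um), scales = scales)
}

#' Iterative per-section center-of-mass alignment
#'
#' For each section, the D-V shift comes from the center-of-mass difference
#' against the template (using the anterior-commissure surrogate landmark for
#' sections where the template landmark is present, since the anterior
#' striatal sections are too variable to align on the striatum itself), and
#' the M-L shift from the center of mass of the top (dorsal) half of the
#' mask. Shifts are rounded to whole voxels, applied, and the procedure is
#' repeated `n_rounds` times.
#'
#' @param stack a `binary_mask` section stack.
#' @param template the reference `binary_mask` stack (same grid).
#' @param n_rounds number of alignment rounds (default 2).
#' @param landmark,landmark_template optional landmark masks carried with the
#'   stack and template.
#' @param min_voxels sections need at least this many mask voxels in both
#'   stack and template for a shift to be estimated (slivers at the
#'   anterior/posterior ends otherwise produce unstable centers of mass).
#' @param min_fraction sections additionally need at least this fraction of
#'   the largest section's voxel count, in both stack and template.
#' @return A list with `stack` (aligned), `shifts` (n_sections x 2 total
#'   (D-V, M-L) voxel shifts applied) and `dice` per round.
#' @export
iterative_com_align <- function(stack, template, n_rounds = 2,
                                landmark = NULL, landmark_template = NULL,
                                min_voxels = 20, min_fraction = 0.1) {
  check_same_grid(stack, template)
  d <- dim(stack$values)
  total <- matrix(0, d[1], 2)
  cur <- stack$values
  floor_s <- max(min_voxels, min_fraction * max(section_counts(cur)))
  floor_t <- max(min_voxels,
                 min_fraction * max(section_counts(template$values)))
  lm_cur <- if (!is.null(landmark)) landmark$values else NULL
  dice <- numeric(n_rounds)
  active <- rep(FALSE, d[1])
  raw_total <- matrix(0, d[1], 2)
  for (r in seq_len(n_rounds)) {
    shifts <- matrix(0, d[1], 2)
    raw <- matrix(0, d[1], 2)
    for (i in seq_len(d[1])) {
      sec <- cur[i, , ]
      tsec <- template$values[i, , ]
      si <- which(sec, arr.ind = TRUE)
      ti <- which(tsec, arr.ind = TRUE)
      if (nrow(si) < floor_s || nrow(ti) < floor_t) next
      active[i] <- TRUE
      use_lm <- !is.null(lm_cur) && !is.null(landmark_template) &&
        any(landmark_template$values[i, , ]) && any(lm_cur[i, , ])
      if (use_lm) {
        li <- which(lm_cur[i, , ], arr.ind = TRUE)
        lt <- which(landmark_template$values[i, , ], arr.ind = TRUE)
        ddv <- mean(lt[, 1]) - mean(li[, 1])
      } else {
        ddv <- mean(ti[, 1]) - mean(si[, 1])
      }
      # M-L from the top half only: the ventral mask is the variable part
      s_top <- si[si[, 1] <= mean(si[, 1]), , drop = FALSE]
      t_top <- ti[ti[, 1] <= mean(ti[, 1]), , drop = FALSE]
      dml <- mean(t_top[, 2]) - mean(s_top[, 2])
      raw[i, ] <- c(ddv, dml)
      shifts[i, ] <- round(c(ddv, dml))
    }
    cur <- apply_section_shifts(cur, shifts)
    if (!is.null(lm_cur)) lm_cur <- apply_section_shifts(lm_cur, shifts)
    total <- total + shifts
    raw_total <- raw_total + raw
    dice[r] <- dice_coefficient(binary_mask(cur, stack$voxel_size_um),
                                template)
  }
  list(stack = binary_mask(cur, stack$voxel_size_um), shifts = total,
       raw_shifts = raw_total, dice = dice, active = active,
       landmark = if (!is.null(lm_cur))
         binary_mask(lm_cur, stack$voxel_size_um))
}

#' Dice overlap coefficient of two masks
#'
#' @param a,b `binary_mask` objects on the same grid.
#' @return `2|a n b| / (|a| + |b|)`.
#' @export
dice_coefficient <- function(a, b) {
  check_same_grid(a, b)
  2 * sum(a$values & b$values) / (sum(a$values) + sum(b$values))
}

#' Replace a damaged section by its neighbors' average
#'
#' The section is replaced by the voxelwise mean of the flanking sections;
#' masks are re-binarized at strictly greater than 0.5 (so a voxel must be
#' present in both neighbors to survive).
#'
#' @param stack a `binary_mask` or `projection_volume` section stack.
#' @param section_index index of the damaged section (not first or last).
#' @return The repaired stack.
#' @export
repair_damaged_section <- function(stack, section_index) {
  v <- stack$values
  n <- dim(v)[1]
  if (section_index <= 1 || section_index >= n) {
    stop("repair_damaged_section: section must have flanking sections")
  }
  mean_sec <- (v[section_index - 1, , ] + v[section_index + 1, , ]) / 2
  if (inherits(stack, "binary_mask")) {
    v[section_index, , ] <- mean_sec > 0.5
    binary_mask(v, stack$voxel_size_um)
  } else {
    v[section_index, , ] <- mean_sec
    projection_volume(v, stack$voxel_size_um, stack$origin_label)
  }
}

#' Full misalignment correction
#'
#' Follows the section-registration recipe: (1) verticalize every section by
#' undoing the estimated roll (an in-plane rotation, so per-section jitter is
#' untouched); (2) estimate the aberrant pitch and yaw sectioning angles and
#' rotate the *template* by them, mimicking the stack's sectioning frame;
#' (3) estimate per-axis scales against the rotated template (moment-based,
#' so jitter-insensitive) and undo them; (4) iteratively align each section
#' to the rotated template in D-V and M-L — jitter really is a per-section
#' shift in this frame, so this removes it cleanly; any linear-in-A-P trend
#' left in the shift profile is a residual rotation in disguise and is
#' folded back into the pitch/yaw estimates; (5) resample the aligned stack
#' back into template coordinates; (6) run one more round of iterative
#' per-section alignment against the unrotated template.
#'
#' @param stack misaligned `binary_mask` section stack.
#' @param template reference `binary_mask` stack.
#' @param landmark,landmark_template optional anterior-commissure surrogate
#'   masks (the landmark is corrected alongside the stack and anchors the
#'   D-V alignment of anterior sections).
#' @param n_rounds per-section alignment rounds in each alignment stage.
#' @return A list with the aligned `stack` (and `landmark`), the estimated
#'   `transform` ([section_transform()] whose `per_section_shifts` are the
#'   detrended jitter *corrections* applied), and `dice` against the template
#'   after the in-frame alignment and after the final alignment.
#' @export
correct_misalignment <- function(stack, template, landmark = NULL,
                                 landmark_template = NULL, n_rounds = 2) {
  vs <- stack$voxel_size_um
  n_sec <- dim(stack$values)[1]

  ## 1. verticalize sections (roll is in-plane: jitter-safe)
  roll <- estimate_roll(stack)
  Rr <- rotation_matrix(roll, 0, 0)
  cur <- binary_mask(resample_affine(stack$values, solve(Rr), vs, "nearest"),
                     vs)
  lm_cur <- if (!is.null(landmark)) {
    binary_mask(resample_affine(landmark$values, solve(Rr), vs, "nearest"),
                vs)
  }

  ## 2. sectioning angles; rotate the template into the stack's frame
  py <- estimate_pitch_yaw(cur, template)
  pitch <- py$pitch_deg
  yaw <- py$yaw_deg
  Rpy <- rotation_matrix(0, pitch, yaw)
  template_rot <- binary_mask(
    resample_affine(template$values, Rpy, vs, "nearest"), vs)
  lm_template_rot <- if (!is.null(landmark_template)) {
    binary_mask(resample_affine(landmark_template$values, Rpy, vs,
                                "nearest"), vs)
  }

  ## 3. scales (moment-based, so insensitive to jitter), undone before the
  ## per-section alignment so that scale mismatch cannot masquerade as a
  ## shift profile
  scales <- as.numeric(scale_stats(cur) / scale_stats(template_rot))
  S <- diag(scales)
  cur <- binary_mask(resample_affine(cur$values, solve(S), vs, "nearest"),
                     vs)
  if (!is.null(lm_cur)) {
    lm_cur <- binary_mask(
      resample_affine(lm_cur$values, solve(S), vs, "nearest"), vs)
  }

  ## 4. per-section jitter removal in the sectioning frame
  al <- iterative_com_align(cur, template_rot, n_rounds = n_rounds,
                            landmark = lm_cur,
                            landmark_template = lm_template_rot)
  shifts <- al$shifts
  dice_in_frame <- dice_coefficient(al$stack, template_rot)

  ## 5. back into template coordinates (undo the sectioning rotation)
  cur <- binary_mask(
    resample_affine(al$stack$values, solve(Rpy), vs, "nearest"), vs)
  lm_cur <- if (!is.null(al$landmark)) {
    binary_mask(resample_affine(al$landmark$values, solve(Rpy), vs,
                                "nearest"), vs)
  }

  ## 6. one more round against the unrotated template
  final <- iterative_com_align(cur, template, n_rounds = n_rounds,
                               landmark = lm_cur,
                               landmark_template = landmark_template)
  list(
    stack = final$stack,
    landmark = final$landmark,
    transform = section_transform(
      roll_deg = roll, pitch_deg = pitch, yaw_deg = yaw,
      scale_ap = scales[1], scale_dv = scales[2], scale_ml = scales[3],
      per_section_shifts = shifts
    ),
    dice = c(in_frame = dice_in_frame,
             final = dice_coefficient(final$stack, template))
  )
}
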