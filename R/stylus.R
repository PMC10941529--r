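#' Stylus model
#'
#' Describes a marker-instrumented stylus body: the fixed pose of each
#' fiducial marker in the body frame and the calibrated tip offset. At least
#' two markers are required so the body pose stays observable when some
#' markers face away from the camera.
#'
#' @param markers Named list of [rigid_frame()] objects: pose of each marker
#'   in the stylus body frame, names are marker IDs.
#' @param tip_offset Length-3 vector: tip position in the body frame, mm.
#' @param probe_radius_mm Radius of the spherical contact probe (default
#'   1 mm). Stored for optional surface-offset correction; no correction is
#'   applied by default.
#' @return An object of class `stylus_model`.
#' @export
stylus_model <- function(markers, tip_offset, probe_radius_mm = 1) {
  if (!is.list(markers) || length(markers) < 2 || is.null(names(markers))) {
    abort_contract("`markers` must be a named list of at least two marker poses.")
  }
  lapply(markers, function(f) check_rotation(f$axes))
  tip_offset <- as.numeric(tip_offset)
  if (length(tip_offset) != 3 || any(!is.finite(tip_offset))) {
    abort_contract("`tip_offset` must be three finite numbers (mm).")
  }
  structure(
    list(markers = markers, tip_offset = tip_offset,
         probe_radius_mm = probe_radius_mm),
    class = "stylus_model"
  )
}

# One marker observation row set -> list of rigid_frame (camera <- marker).
obs_to_frames <- function(obs) {
  lapply(seq_len(nrow(obs)), function(i) {
    q <- c(obs$qw[i], obs$qx[i], obs$qy[i], obs$qz[i])
    rigid_frame(c(obs$tx[i], obs$ty[i], obs$tz[i]), quat_to_rotation(q / vnorm(q)))
  })
}

#' Fuse marker observations into a body pose
#'
#' Each visible marker yields a candidate body pose (observed marker pose
#' composed with the inverse of its marker-to-body transform); candidates are
#' averaged with equal weights — translations arithmetically, rotations by
#' the quaternion outer-product eigenvector mean — and the spread across
#' candidates is reported as a quality measure.
#'
#' @param observations Data frame of simultaneous observations with columns
#'   `marker_id`, `tx`, `ty`, `tz` (mm) and `qw`, `qx`, `qy`, `qz`
#'   (camera-frame marker pose quaternion).
#' @param model A [stylus_model()].
#' @return An object of class `body_pose`: `frame` (body in camera frame),
#'   `n_markers` used, `spread_trans_mm` and `spread_rot_deg` (rms deviation
#'   of candidates from the fused pose).
#' @export
fuse_body_pose <- function(observations, model) {
  keep <- observations$marker_id %in% names(model$markers)
  obs <- observations[keep, , drop = FALSE]
  if (nrow(obs) == 0) {
    rlang::abort("No usable marker observations (none match the stylus model).",
                 class = "contourfit_error_no_pose")
  }
  cam_marker <- obs_to_frames(obs)
  candidates <- lapply(seq_along(cam_marker), function(i) {
    frame_compose(cam_marker[[i]],
                  frame_inverse(model$markers[[obs$marker_id[i]]]))
  })
  origins <- t(vapply(candidates, function(f) f$origin, numeric(3)))
  origin <- colMeans(origins)
  R <- mean_rotation(lapply(candidates, function(f) f$axes))
  spread_t <- sqrt(mean(rowSums(sweep(origins, 2, origin)^2)))
  spread_r <- sqrt(mean(vapply(candidates, function(f)
    rotation_angle_deg(f$axes, R)^2, 0)))
  structure(
    list(frame = rigid_frame(origin, R), n_markers = nrow(obs),
         spread_trans_mm = spread_t, spread_rot_deg = spread_r),
    class = "body_pose"
  )
}

#' Pivot calibration of the stylus tip offset
#'
#' While the stylus pivots about a fixed contact point, the tip offset `t`
#' (body frame) and the pivot point `p` (camera frame) satisfy
#' `R_i t + t_i = p` for every body pose `(R_i, t_i)`. Stacking all poses
#' gives a linear least-squares system in `(t, p)`; the per-component rms
#' scatter of the reconstructed tip about the pivot is reported (on the
#' scale of the per-axis measurement noise).
#'
#' @param poses List of [rigid_frame()] body poses (camera frame), at least 3
#'   with sufficient rotational diversity.
#' @return An object of class `pivot_calibration`: `tip_offset` (body frame,
#'   mm), `pivot_point` (camera frame, mm), `rms` (mm), `n_poses`.
#' @export
pivot_calibrate <- function(poses) {
  if (length(poses) < 3) {
    abort_contract("Pivot calibration needs at least 3 poses.")
  }
  n <- length(poses)
  A <- matrix(0, 3 * n, 6)
  b <- numeric(3 * n)
  for (i in seq_len(n)) {
    rows <- (3 * i - 2):(3 * i)
    A[rows, 1:3] <- poses[[i]]$axes
    A[rows, 4:6] <- -diag(3)
    b[rows] <- -poses[[i]]$origin
  }
  sv <- svd(A)
  if (sv$d[6] / sv$d[1] < 1e-8) {
    rlang::abort(
      "Degenerate pivoting motion (no rotational diversity); the tip offset is unobservable.",
      class = "contourfit_error_degenerate_motion"
    )
  }
  sol <- sv$v %*% ((crossprod(sv$u, b)[1:6] / sv$d))
  tip <- as.numeric(sol[1:3])
  pivot <- as.numeric(sol[4:6])
  resid <- A %*% sol - b
  # per-component rms of the reconstructed-tip scatter, so the value is on
  # the scale of the per-axis measurement noise
  rms <- sqrt(mean(resid^2))
  structure(
    list(tip_offset = tip, pivot_point = pivot, rms = rms, n_poses = n),
    class = "pivot_calibration"
  )
}

#' @export
print.pivot_calibration <- function(x, ...) {
  cat(sprintf(
    "<pivot_calibration> tip offset (%.3f, %.3f, %.3f) mm, rms %.4g mm (n = %d poses)\n",
    x$tip_offset[1], x$tip_offset[2], x$tip_offset[3], x$rms, x$n_poses
  ))
  invisible(x)
}

#' Stylus tip trajectory from a marker stream
#'
#' Fuses the marker observations of each frame into a body pose and composes
#' it with the calibrated tip offset. Frames without any usable marker yield
#' gaps (`NA` coordinates) — dropouts are data, never interpolated.
#'
#' @param stream Data frame with columns `time` (s), `marker_id`, `tx`, `ty`,
#'   `tz`, `qw`, `qx`, `qy`, `qz`; timestamps need not be equally spaced but
#'   must be non-decreasing.
#' @param model A [stylus_model()] with a calibrated `tip_offset`.
#' @return A tibble with one row per frame: `time`, tip `x`, `y`, `z`
#'   (camera frame, mm; `NA` on dropout) and `n_markers`.
#' @export
tip_trajectory <- function(stream, model) {
  required <- c("time", "marker_id", "tx", "ty", "tz", "qw", "qx", "qy", "qz")
  missing <- setdiff(required, names(stream))
  if (length(missing) > 0) {
    abort_contract(sprintf("Marker stream is missing column(s): %s.",
                           paste(missing, collapse = ", ")))
  }
  if (is.unsorted(stream$time)) {
    abort_contract("Marker stream timestamps must be non-decreasing.")
  }
  times <- unique(stream$time)
  rows <- lapply(times, function(tt) {
    frame_obs <- stream[stream$time == tt, , drop = FALSE]
    pose <- tryCatch(fuse_body_pose(frame_obs, model),
                     contourfit_error_no_pose = function(e) NULL)
    if (is.null(pose)) {
      tibble::tibble(time = tt, x = NA_real_, y = NA_real_, z = NA_real_,
                     n_markers = 0L)
    } else {
      tip <- pose$frame$origin + pose$frame$axes %*% model$tip_offset
      tibble::tibble(time = tt, x = tip[1], y = tip[2], z = tip[3],
                     n_markers = pose$n_markers)
    }
  })
  dplyr::bind_rows(rows)
}
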