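#' Anatomical landmark vocabulary
#'
#' Landmark identifiers accepted by the bone-frame constructors: three on the
#' scapula (SIA: inferior angle, SRS: root of the scapular spine, SAA:
#' acromial angle) and four on the clavicle (CAJ: superior edge centre of the
#' acromioclavicular joint, CSJ: superior edge centre of the sternoclavicular
#' joint, CAS: anterior border apex of the sternoclavicular joint, CSC:
#' centre of the sternoclavicular cartilage).
#'
#' @return Character vector of valid landmark IDs.
#' @export
landmark_vocabulary <- function() {
  c("SIA", "SRS", "SAA", "CAJ", "CSJ", "CAS", "CSC")
}

#' Build a landmark set
#'
#' Validates a table of anatomical landmarks (mm) against the landmark
#' vocabulary and tags it with the specimen laterality.
#'
#' @param landmarks Data frame with columns `id`, `x`, `y`, `z` (mm), or a
#'   named list of length-3 coordinates.
#' @param laterality `"left"` or `"right"`.
#' @return A tibble of class `landmark_set` with attribute `laterality`.
#' @export
landmark_set <- function(landmarks, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  if (!is.data.frame(landmarks)) {
    if (is.null(names(landmarks))) {
      abort_contract("`landmarks` must be a data frame or a named list.")
    }
    landmarks <- tibble::tibble(
      id = names(landmarks),
      x = vapply(landmarks, function(p) p[[1]], 0),
      y = vapply(landmarks, function(p) p[[2]], 0),
      z = vapply(landmarks, function(p) p[[3]], 0)
    )
  }
  missing <- setdiff(c("id", "x", "y", "z"), names(landmarks))
  if (length(missing) > 0) {
    abort_contract(sprintf("Landmark table is missing column(s): %s.",
                           paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(landmarks$id, landmark_vocabulary())
  if (length(unknown) > 0) {
    rlang::abort(
      sprintf("Unknown landmark ID(s): %s. Valid IDs are: %s.",
              paste(unknown, collapse = ", "),
              paste(landmark_vocabulary(), collapse = ", ")),
      class = "contourfit_error_vocabulary"
    )
  }
  if (anyDuplicated(landmarks$id)) {
    abort_contract("Duplicate landmark IDs in the set.")
  }
  m <- as_xyz_matrix(landmarks, arg = "landmarks")
  if (nrow(m) > 1) {
    d <- as.matrix(stats::dist(m))
    diag(d) <- Inf
    if (min(d) <= 1) {
      abort_contract("Landmarks must be pairwise distinct (> 1 mm apart).")
    }
  }
  out <- tibble::tibble(id = landmarks$id, x = m[, 1], y = m[, 2], z = m[, 3])
  attr(out, "laterality") <- laterality
  class(out) <- c("landmark_set", class(out))
  out
}

landmark_point <- function(lms, id) {
  i <- match(id, lms$id)
  if (is.na(i)) {
    abort_contract(sprintf("Landmark '%s' is required but absent.", id))
  }
  c(lms$x[i], lms$y[i], lms$z[i])
}

new_bone_frame <- function(origin, X, Y, Z, bone, laterality) {
  f <- rigid_frame(origin, cbind(X, Y, Z))
  f$bone <- bone
  f$laterality <- laterality
  class(f) <- c("bone_frame", class(f))
  f
}

# Resolve an axis sign so it points along the anatomical hint direction.
resolve_sign <- function(axis, hint, what) {
  d <- sum(axis * hint)
  if (abs(d) < 1e-9) {
    abort_contract(sprintf(
      "The %s hint is orthogonal to the candidate axis; cannot resolve its sign.", what))
  }
  if (d < 0) -axis else axis
}

#' Scapula bone coordinate system
#'
#' Builds the scapula frame from the SIA, SRS and SAA landmarks: origin at
#' SAA; Z along the line SRS to SAA (pointing to SAA, i.e. laterally in a
#' right scapula); X perpendicular to the SIA-SAA-SRS plane pointing
#' anteriorly; Y = Z x X pointing superiorly. Because landmark coordinates
#' alone cannot disambiguate "anterior", the sign of X is resolved against a
#' caller-supplied anterior direction hint in the digitiser world frame.
#'
#' @param landmarks A [landmark_set()] (or data frame accepted by it)
#'   containing SIA, SRS and SAA.
#' @param anterior_hint Approximate anterior direction in the world frame
#'   (default `c(1, 0, 0)`).
#' @param laterality Specimen side, taken from the landmark set when present.
#' @return A `bone_frame` (a [rigid_frame()] tagged with bone and laterality).
#' @export
build_scapula_frame <- function(landmarks, anterior_hint = c(1, 0, 0),
                                laterality = NULL) {
  lms <- if (inherits(landmarks, "landmark_set")) landmarks else
    landmark_set(landmarks, laterality %||% "right")
  laterality <- laterality %||% attr(lms, "laterality")
  saa <- landmark_point(lms, "SAA")
  srs <- landmark_point(lms, "SRS")
  sia <- landmark_point(lms, "SIA")
  Z <- normalize(saa - srs)
  n <- cross3(saa - sia, srs - sia)
  if (vnorm(n) < 1e-9 * max(vnorm(saa - sia), 1)) {
    abort_degenerate("SIA, SRS and SAA are collinear; the scapular plane is undefined.")
  }
  X <- resolve_sign(normalize(n), anterior_hint, "anterior")
  Y <- cross3(Z, X)
  new_bone_frame(saa, X, Y, Z, "scapula", laterality)
}

#' Clavicle bone coordinate system
#'
#' Builds the clavicle frame from the CSJ, CAJ, CAS and CSC landmarks:
#' origin at CSJ; Z along the line CSJ to CAJ (pointing to CAJ, i.e.
#' laterally in a right clavicle); X from the CAS-CSC line orthogonalised
#' against Z (Gram-Schmidt) and pointing anteriorly; Y = Z x X pointing
#' superiorly. This thorax-free anteroposterior axis follows the
#' sternoclavicular-cartilage construction used when no thorax landmarks are
#' available.
#'
#' @inheritParams build_scapula_frame
#' @return A `bone_frame`.
#' @export
build_clavicle_frame <- function(landmarks, anterior_hint = c(1, 0, 0),
                                 laterality = NULL) {
  lms <- if (inherits(landmarks, "landmark_set")) landmarks else
    landmark_set(landmarks, laterality %||% "right")
  laterality <- laterality %||% attr(lms, "laterality")
  csj <- landmark_point(lms, "CSJ")
  caj <- landmark_point(lms, "CAJ")
  cas <- landmark_point(lms, "CAS")
  csc <- landmark_point(lms, "CSC")
  Z <- normalize(caj - csj)
  d <- cas - csc
  x0 <- d - sum(d * Z) * Z
  if (vnorm(x0) < 1e-9 * max(vnorm(d), 1)) {
    abort_degenerate("The CAS-CSC line is parallel to the clavicle long axis.")
  }
  X <- resolve_sign(normalize(x0), anterior_hint, "anterior")
  Y <- cross3(Z, X)
  new_bone_frame(csj, X, Y, Z, "clavicle", laterality)
}

#' Express points in a bone frame
#'
#' Rigid change of coordinates from the world (digitiser) frame into a bone
#' frame; pairwise distances are preserved.
#'
#' @param points Data frame/matrix with `x`, `y`, `z` (mm, world frame).
#' @param frame A `bone_frame` or [rigid_frame()].
#' @return A tibble with `x`, `y`, `z` in the frame's coordinates.
#' @export
express_in_frame <- function(points, frame) {
  m <- as_xyz_matrix(points)
  check_rotation(frame$axes)
  local <- sweep(m, 2, frame$origin) %*% frame$axes
  xyz_tibble(local)
}

#' Homogenise laterality by mirroring left-sided geometry
#'
#' Right-sided inputs are returned unchanged. Left-sided inputs, expressed in
#' a bone frame, are reflected across the frame's X-Y plane (the
#' medio-lateral third coordinate is negated) so that mirrored left bones
#' superpose on right bones. Mirroring twice is the identity.
#'
#' @param points Data frame/matrix with `x`, `y`, `z` in a bone frame, or a
#'   [landmark_set()].
#' @param laterality `"left"` or `"right"`; taken from a landmark set when
#'   not supplied.
#' @return Same type as the input (landmark sets come back tagged `"right"`).
#' @export
mirror_to_right <- function(points, laterality = NULL) {
  if (inherits(points, "landmark_set")) {
    laterality <- laterality %||% attr(points, "laterality")
    if (!laterality %in% c("left", "right")) {
      abort_contract("`laterality` must be \"left\" or \"right\".")
    }
    if (identical(laterality, "left")) points$z <- -points$z
    attr(points, "laterality") <- "right"
    return(points)
  }
  if (is.null(laterality) || !laterality %in% c("left", "right")) {
    abort_contract("`laterality` must be \"left\" or \"right\".")
  }
  m <- as_xyz_matrix(points)
  if (identical(laterality, "left")) m[, 3] <- -m[, 3]
  if (is.data.frame(points)) xyz_tibble(m) else m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
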