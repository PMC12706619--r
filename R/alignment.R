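#' Rigid transform acting on world coordinates
#'
#' The action on a point p is `R (p - pivot) + pivot + translation`: a
#' rotation about a pivot point followed by an optional translation.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (within 1e-10).
#' @param pivot World-mm pivot of the rotation (default origin).
#' @param translation World-mm translation (default zero).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), pivot = c(0, 0, 0),
                            translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("rotation must be a 3x3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10)
    stop("rotation is not orthonormal (R'R differs from I by more than 1e-10)")
  if (abs(det(rotation) - 1) > 1e-10)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, pivot = as.numeric(pivot),
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat("<rigid_transform> angle ", sprintf("%.3f", ang), " deg, pivot (",
      paste(sprintf("%.2f", x$pivot), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# rotation matrix about a unit axis by angle (radians), Rodrigues form
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

rotation_angle_deg <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_))) * 180 / pi
}

#' Rotation spec for orthogonal-axis perturbations
#'
#' Axis convention in RAS world space: `pitch` rotates about the x
#' (left-right) axis, `yaw` about the z (inferior-superior) axis and `roll`
#' about the y (posterior-anterior) axis.
#'
#' @param axis One of `"pitch"`, `"yaw"`, `"roll"`.
#' @param angle_deg Finite rotation angle in degrees.
#' @return An object of class `rotation_spec`.
#' @export
rotation_spec <- function(axis = c("pitch", "yaw", "roll"), angle_deg) {
  axis <- match.arg(axis)
  if (!is.finite(angle_deg)) stop("angle must be finite")
  structure(list(axis = axis, angle_deg = as.numeric(angle_deg)),
            class = "rotation_spec")
}

rotation_axis_vector <- function(axis) {
  switch(axis,
         pitch = c(1, 0, 0),
         yaw   = c(0, 0, 1),
         roll  = c(0, 1, 0),
         stop("unknown rotation axis '", axis, "'"))
}

#' Apply a rigid transform to points
#'
#' @param t A [rigid_transform].
#' @param pts Length-3 vector or n x 3 matrix of world-mm points.
#' @return Transformed points, same shape as the input.
#' @export
transform_points <- function(t, pts) {
  if (is.null(dim(pts))) {
    as.numeric(t$rotation %*% (as.numeric(pts) - t$pivot)) + t$pivot + t$translation
  } else {
    sweep(sweep(pts, 2, t$pivot) %*% t(t$rotation), 2,
          t$pivot + t$translation, "+")
  }
}

inverse_transform <- function(t) {
  rigid_transform(t(t$rotation), t$pivot,
                  as.numeric(-t(t$rotation) %*% t$translation))
}

#' AC-PC realignment rotation
#'
#' Computes the minimal-angle rotation that takes the AC-PC direction
#' `v = (ac - pc)/|ac - pc|` onto the world anterior axis (0, 1, 0), pivoted
#' at the AC-PC midpoint. After applying it, the AC-PC line is horizontal in
#' the sagittal view and runs along the image y-axis in the axial view.
#' Two collinear landmarks cannot constrain rotation about their own axis,
#' so roll about the A-P axis is left unchanged; an explicit `roll_deg` may
#' be supplied if roll is known from elsewhere.
#'
#' @param landmarks A [landmark_set] with AC anterior to PC.
#' @param roll_deg Optional additional roll (about the anterior axis, in
#'   degrees) composed after the alignment rotation. Default 0.
#' @return A [rigid_transform] with zero translation.
#' @export
acpc_rotation <- function(landmarks, roll_deg = 0) {
  stopifnot(inherits(landmarks, "landmark_set"))
  d <- landmarks$ac - landmarks$pc
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) stop("AC and PC coincide")
  v <- d / nd
  if (v[2] <= 0) stop("landmarks reversed or implausible (AC not anterior to PC)")
  yhat <- c(0, 1, 0)
  cosang <- sum(v * yhat)
  angle <- acos(min(1, max(-1, cosang)))
  pivot <- (landmarks$ac + landmarks$pc) / 2
  if (angle < 1e-9) {
    R <- diag(3)
  } else {
    axis <- c(v[2] * yhat[3] - v[3] * yhat[2],
              v[3] * yhat[1] - v[1] * yhat[3],
              v[1] * yhat[2] - v[2] * yhat[1])  # v x yhat
    R <- rotation_about(axis, angle)
  }
  if (roll_deg != 0)
    R <- rotation_about(yhat, roll_deg * pi / 180) %*% R
  rigid_transform(R, pivot)
}

#' Resample a label volume under a rigid transform
#'
#' The output grid and affine equal the input's; each output voxel takes the
#' label of the input voxel nearest to the inverse-mapped world point
#' (nearest-neighbour, preserving label integers exactly). Points mapping
#' outside the input grid become background. The volume must be in
#' canonical RAS orientation.
#'
#' @param vol A [label_volume] in canonical RAS orientation.
#' @param t A [rigid_transform].
#' @return A [label_volume] on the same grid.
#' @export
apply_rigid <- function(vol, t) {
  stopifnot(inherits(vol, "label_volume"), inherits(t, "rigid_transform"))
  if (max(abs(t$rotation - diag(3))) < 1e-12 &&
      max(abs(t$translation)) < 1e-12)
    return(vol)
  d <- dim(vol$grid)
  A <- vol$affine
  origin <- A[1:3, 4]
  sp <- diag(A[1:3, 1:3])
  if (max(abs(A[1:3, 1:3] - diag(sp))) > 1e-9)
    stop("apply_rigid requires a canonical RAS volume; run reorient_to_ras first")

  bb <- fg_bbox(vol$grid)
  if (is.null(bb)) return(vol)

  # restrict output computation to the forward-mapped bounding box of the
  # input foreground (plus margin); everything else is background anyway
  rng <- cbind(bb$x, bb$y, bb$z) - 1L  # 0-based
  corners <- as.matrix(expand.grid(rng[, 1], rng[, 2], rng[, 3]))
  wc <- sweep(corners %*% diag(sp), 2, origin, "+")
  fwd <- transform_points(t, wc)
  lo <- pmax(floor((apply(fwd, 2, min) - origin) / sp) - 2, 0)
  hi <- pmin(ceiling((apply(fwd, 2, max) - origin) / sp) + 2, d - 1)
  if (any(lo > hi)) {
    empty <- label_volume(array(0L, d), A)
    class(empty) <- class(vol)
    return(empty)
  }

  ti <- inverse_transform(t)
  out <- .nn_resample_cpp(vol$grid, dim(vol$grid),
                          as.integer(lo), as.integer(hi),
                          as.numeric(origin), as.numeric(sp),
                          ti$rotation, as.numeric(ti$pivot),
                          as.numeric(ti$pivot + ti$translation))
  dim(out) <- d
  out <- label_volume(out, A)
  if (inherits(vol, "binary_mask")) class(out) <- class(vol)
  out
}

#' Transform a landmark set
#'
#' Maps each landmark by the forward transform and re-validates the result
#' (the AC must remain anterior to the PC).
#'
#' @param landmarks A [landmark_set].
#' @param t A [rigid_transform].
#' @return A transformed [landmark_set].
#' @export
rotate_landmarks <- function(landmarks, t) {
  stopifnot(inherits(landmarks, "landmark_set"), inherits(t, "rigid_transform"))
  landmark_set(transform_points(t, landmarks$ac),
               transform_points(t, landmarks$pc),
               transform_points(t, landmarks$ivf))
}

#' Apply a controlled rotational perturbation
#'
#' Rotates a volume and its landmarks together about the AC-PC midpoint by
#' a named pitch/yaw/roll angle, emulating acquisition with the head off
#' the reference orientation. An angle of 0 returns the inputs unchanged.
#'
#' @param vol A [label_volume] in canonical RAS orientation.
#' @param landmarks A [landmark_set].
#' @param spec A [rotation_spec].
#' @return A list with elements `vol` and `landmarks`.
#' @export
perturb <- function(vol, landmarks, spec) {
  stopifnot(inherits(spec, "rotation_spec"))
  if (spec$angle_deg == 0) return(list(vol = vol, landmarks = landmarks))
  pivot <- (landmarks$ac + landmarks$pc) / 2
  R <- rotation_about(rotation_axis_vector(spec$axis), spec$angle_deg * pi / 180)
  t <- rigid_transform(R, pivot)
  list(vol = apply_rigid(vol, t), landmarks = rotate_landmarks(landmarks, t))
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' The JSON object holds the rotation as 9 floats in row-major order, plus
#' `pivot` and `translation` as 3-vectors.
#'
#' @param t A [rigid_transform].
#' @param path Output (or input) JSON path.
#' @return `path` invisibly for the writer; a [rigid_transform] for the reader.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::write_json(
    list(rotation = as.numeric(t(t$rotation)), pivot = t$pivot,
         translation = t$translation),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::fromJSON(path)
  rigid_transform(matrix(obj$rotation, 3, 3, byrow = TRUE),
                  obj$pivot, obj$translation)
}
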