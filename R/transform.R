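#' Rigid transform in world coordinates
#'
#' A rigid transform acts on world points (mm) as
#' \code{p -> R (p - center) + center + translation}: rotation about an
#' explicit pivot followed by a translation. The pivot is bookkeeping only --
#' two transforms with different centers can describe the same map -- but
#' keeping it explicit lets registration rotate about the mask centroid while
#' migration is reported about the implant centre of gravity.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation numeric length-3, in mm.
#' @param center rotation pivot, world point in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)),
            length(translation) == 3, length(center) == 3,
            all(is.finite(rotation)), all(is.finite(translation)),
            all(is.finite(center)))
  orth <- max(abs(crossprod(rotation) - diag(3)))
  if (orth > 1e-9)
    stop("rotation matrix is not orthogonal (residual ", format(orth), ")")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation matrix is not proper (det != +1)")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rt_angles_deg(x)
  cat("<rigid_transform>\n")
  cat(sprintf("  rotation (deg, x/y/z Cardan): %.4f %.4f %.4f\n",
              ang[1], ang[2], ang[3]))
  cat(sprintf("  translation (mm): %.4f %.4f %.4f\n",
              x$translation[1], x$translation[2], x$translation[3]))
  cat(sprintf("  center (mm): %.3f %.3f %.3f\n",
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Rotation matrix from Cardan angles (degrees)
#'
#' Fixed-axes sequence x then y then z, i.e. \code{R = Rz \%*\% Ry \%*\% Rx}.
#' This is the sequence used for all reported rotations.
#'
#' @param rx,ry,rz rotations about the x, y and z axes in degrees.
#' @return 3x3 rotation matrix.
#' @export
cardan_matrix <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; c <- rz * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Cardan angles (degrees) of a rotation matrix
#'
#' Inverse of [cardan_matrix()]. At the gimbal-lock singularity
#' (|ry| = 90 deg) rz is set to 0; migration rotations are far below that
#' regime.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric length-3: rx, ry, rz in degrees.
#' @export
cardan_angles <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ry <- asin(sy)
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rz <- 0
    rx <- atan2(-R[2, 3], R[2, 2])
  }
  c(rx, ry, rz) * 180 / pi
}

#' @rdname cardan_angles
#' @param tf a `rigid_transform`.
#' @export
rt_angles_deg <- function(tf) cardan_angles(tf$rotation)

#' Build a rigid transform from Cardan angles and a translation
#'
#' @inheritParams cardan_matrix
#' @param t translation, mm.
#' @param center rotation pivot, mm.
#' @export
rt_from_params <- function(rx = 0, ry = 0, rz = 0, t = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  rigid_transform(cardan_matrix(rx, ry, rz), t, center)
}

#' Apply a rigid transform to points
#'
#' @param tf a `rigid_transform`.
#' @param pts n x 3 matrix of world points (mm); a length-3 vector is treated
#'   as one point.
#' @return n x 3 matrix of transformed points.
#' @export
rt_apply <- function(tf, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  ctr <- tf$center
  shifted <- sweep(pts, 2, ctr)
  out <- shifted %*% t(tf$rotation)
  sweep(out, 2, ctr + tf$translation, `+`)
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param tf a `rigid_transform`.
#' @export
rt_matrix <- function(tf) {
  H <- diag(4)
  H[1:3, 1:3] <- tf$rotation
  H[1:3, 4] <- tf$translation + tf$center - tf$rotation %*% tf$center
  H
}

#' Rigid transform from a homogeneous 4x4 matrix
#' @param H 4x4 homogeneous rigid matrix.
#' @param center pivot to express the result about.
#' @export
rt_from_matrix <- function(H, center = c(0, 0, 0)) {
  tf <- rigid_transform(H[1:3, 1:3], H[1:3, 4], c(0, 0, 0))
  rt_with_center(tf, center)
}

#' Re-express a rigid transform about a different pivot
#'
#' The underlying map is unchanged; only the (rotation, translation, center)
#' bookkeeping moves.
#' @param tf a `rigid_transform`.
#' @param center new pivot, mm.
#' @export
rt_with_center <- function(tf, center) {
  H <- rt_matrix(tf)
  b <- H[1:3, 4]
  t2 <- b - center + H[1:3, 1:3] %*% center
  rigid_transform(H[1:3, 1:3], t2, center)
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the map `p -> a(b(p))`.
#' @param a,b `rigid_transform` objects.
#' @export
rt_compose <- function(a, b) {
  rt_from_matrix(rt_matrix(a) %*% rt_matrix(b))
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @export
rt_invert <- function(tf) {
  R <- t(tf$rotation)
  H <- rt_matrix(tf)
  b <- H[1:3, 4]
  rigid_transform(R, as.numeric(-R %*% b), c(0, 0, 0))
}

#' Mirror a rigid transform about a sagittal plane
#'
#' Conjugates the transform with a reflection about the plane x = `x0`
#' (the sagittal plane in the anatomical frame used here, +x medial). Used to
#' report left-knee migration in the right-knee sign convention: the result
#' negates Tx, Ry and Rz while leaving MTPM, TT and TR unchanged.
#'
#' @param tf a `rigid_transform`.
#' @param x0 x-coordinate of the mirror plane, mm.
#' @export
rt_mirror_sagittal <- function(tf, x0 = 0) {
  FH <- diag(4)
  FH[1, 1] <- -1
  FH[1, 4] <- 2 * x0
  rt_from_matrix(FH %*% rt_matrix(tf) %*% FH)
}
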