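# Migration parameters in the implant-centred anatomical frame.
# Translations are the displacement of the implant centre of gravity,
# rotations are Cardan angles (fixed axes x -> y -> z) of the relative
# rigid motion, MTPM is the maximum displacement over the implant point set.

new_migration_result <- function(Tx, Ty, Tz, Rx, Ry, Rz, MTPM,
                                 laterality = "right", point_count = 0L) {
  TT <- sqrt(Tx^2 + Ty^2 + Tz^2)
  TR <- sqrt(Rx^2 + Ry^2 + Rz^2)
  structure(list(Tx = Tx, Ty = Ty, Tz = Tz, Rx = Rx, Ry = Ry, Rz = Rz,
                 TT = TT, TR = TR, MTPM = MTPM,
                 laterality = laterality,
                 point_count = as.integer(point_count),
                 cardan_sequence = "x-y-z (fixed axes, R = Rz Ry Rx)"),
            class = "migration_result")
}

#' @export
print.migration_result <- function(x, ...) {
  cat("<migration_result> (reported for a right-sided knee)\n")
  cat(sprintf("  MTPM %.4f mm | TT %.4f mm | TR %.4f deg\n",
              x$MTPM, x$TT, x$TR))
  cat(sprintf("  T (mm):  x %+.4f  y %+.4f  z %+.4f\n", x$Tx, x$Ty, x$Tz))
  cat(sprintf("  R (deg): x %+.4f  y %+.4f  z %+.4f\n", x$Rx, x$Ry, x$Rz))
  invisible(x)
}

#' @export
as.data.frame.migration_result <- function(x, ...) {
  data.frame(MTPM = x$MTPM, TT = x$TT, TR = x$TR,
             Tx = x$Tx, Ty = x$Ty, Tz = x$Tz,
             Rx = x$Rx, Ry = x$Ry, Rz = x$Rz,
             laterality = x$laterality, point_count = x$point_count)
}

#' Implant motion relative to the bone
#'
#' Both structures are registered independently from baseline to follow-up;
#' the migration of the implant with respect to the bone, expressed in the
#' baseline bone frame, is `bone_t^-1` composed with `implant_t`. A stable
#' implant (moving exactly with the bone) gives the identity.
#'
#' @param bone_t,implant_t `rigid_transform`s mapping baseline world points
#'   to follow-up world points for each structure.
#' @return A `rigid_transform`.
#' @export
relative_motion <- function(bone_t, implant_t) {
  rt_compose(rt_invert(bone_t), implant_t)
}

#' Implant model derived from the implant mask
#'
#' Surface points are the world centres of the mask's 6-connectivity boundary
#' voxels; the centre of gravity is the unweighted centroid of all mask voxel
#' centres (metal HU values are scanner-saturated, so intensity weighting
#' would add noise, not information).
#'
#' @param mask implant `voxel_mask`.
#' @return list(`surface_points` n x 3 mm, `cog` length-3 mm,
#'   `point_count`).
#' @export
implant_model <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!any(mask$grid)) stop("implant mask is empty")
  bnd <- cpp_boundary6(mask$grid, dim(mask$grid))
  surface <- voxel_world_coords(mask, which(bnd))
  cog <- colMeans(voxel_world_coords(mask, which(mask$grid)))
  list(surface_points = surface, cog = as.numeric(cog),
       point_count = nrow(surface))
}

#' Maximum total point motion
#'
#' The largest Euclidean displacement of any point of the set under the
#' motion, in mm -- the main outcome parameter of migration analysis. It
#' depends only on the transform as a map (not on its rotation pivot) and is
#' monotone non-decreasing under point-set union.
#'
#' @param motion a `rigid_transform`.
#' @param points n x 3 matrix of world points, mm.
#' @export
mtpm <- function(motion, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  if (nrow(points) == 0) stop("point set is empty")
  disp <- rt_apply(motion, points) - points
  max(sqrt(rowSums(disp^2)))
}

#' Decompose a relative motion into migration parameters
#'
#' Translations are the displacement of the implant centre of gravity
#' projected on the anatomical axes; rotations are Cardan angles of the
#' rotation part (fixed-axes sequence x -> y -> z, recorded in the result);
#' MTPM is the maximum displacement over the implant surface points. Left
#' knees are mirrored about the sagittal plane through the implant CoG and
#' re-decomposed, so that all results are reported in the right-knee sign
#' convention (this negates Tx, Ry, Rz and leaves MTPM, TT, TR unchanged).
#'
#' @param motion a `rigid_transform` (implant motion relative to bone).
#' @param model an [implant_model()].
#' @param laterality `"right"` or `"left"`.
#' @param axes 3x3 orthonormal matrix whose columns are the anatomical
#'   (medial, proximal, anterior) directions in the world frame.
#' @return A `migration_result`.
#' @export
decompose_motion <- function(motion, model, laterality = c("right", "left"),
                             axes = diag(3)) {
  laterality <- match.arg(laterality)
  if (is.null(model$surface_points) || nrow(model$surface_points) == 0)
    stop("implant model has no surface points")
  # work in the anatomical frame
  if (max(abs(axes - diag(3))) > 0) {
    A <- rt_matrix(rigid_transform(t(axes)))
    motion <- rt_from_matrix(A %*% rt_matrix(motion) %*% t(A))
    model <- list(surface_points = model$surface_points %*% axes,
                  cog = as.numeric(model$cog %*% axes),
                  point_count = model$point_count)
  }
  d_cog <- as.numeric(rt_apply(motion, model$cog)) - model$cog
  ang <- cardan_angles(motion$rotation)
  mtpm_val <- mtpm(motion, model$surface_points)
  if (laterality == "left") {
    # reflection about the sagittal plane followed by re-decomposition;
    # for this Cardan sequence that is exactly a sign flip of Tx, Ry, Rz
    # (conjugating R = Rz(c) Ry(b) Rx(a) by diag(-1,1,1) yields angles
    # (a, -b, -c)), and it leaves MTPM, TT and TR unchanged
    d_cog[1] <- -d_cog[1]
    ang[2] <- -ang[2]
    ang[3] <- -ang[3]
  }
  new_migration_result(Tx = d_cog[1], Ty = d_cog[2], Tz = d_cog[3],
                       Rx = ang[1], Ry = ang[2], Rz = ang[3],
                       MTPM = mtpm_val,
                       laterality = laterality,
                       point_count = model$point_count)
}
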