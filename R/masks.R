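# Mask construction from the baseline CT volume: thresholding, seeded region
# growing, binary morphology, the proximal bone cut under the tray, implant
# subtraction, bone length, and the segmentation report.

#' Threshold a CT volume into a mask
#'
#' Selects voxels with `lo <= HU` (and `HU < hi` when `hi` is finite). An
#' empty result is legal (it is flagged in the segmentation report), since
#' threshold choice is an observer decision.
#'
#' @param volume a `ct_volume`.
#' @param lo lower HU bound (inclusive).
#' @param hi upper HU bound (exclusive); `Inf` for unbounded.
#' @param role mask role, `"bone"` or `"implant"`.
#' @return A `voxel_mask`.
#' @export
threshold_mask <- function(volume, lo, hi = Inf, role = "bone") {
  stopifnot(inherits(volume, "ct_volume"))
  if (!(lo < hi)) stop("lower threshold must be below the upper threshold")
  grid <- volume$voxels >= lo & volume$voxels < hi
  voxel_mask(grid, volume, role)
}

#' Seeded region growing (26-connectivity)
#'
#' Retains only the 26-connected components of the mask that contain at least
#' one seed point. Seeds outside the grid are an error; seeds on background
#' voxels are ignored with a warning.
#'
#' @param mask a `voxel_mask`.
#' @param seeds n x 3 matrix of world points (mm), or a length-3 vector.
#' @return A `voxel_mask`.
#' @export
region_grow <- function(mask, seeds) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (is.null(dim(seeds))) seeds <- matrix(seeds, nrow = 1)
  d <- dim(mask$grid)
  idx <- round(world_to_index(mask, seeds))
  inside <- idx[, 1] >= 0 & idx[, 1] < d[1] &
            idx[, 2] >= 0 & idx[, 2] < d[2] &
            idx[, 3] >= 0 & idx[, 3] < d[3]
  if (!all(inside))
    stop(sprintf("%d seed point(s) fall outside the volume grid",
                 sum(!inside)))
  on_fg <- mask$grid[idx + 1L]
  if (!all(on_fg)) {
    warning(sprintf("%d seed point(s) fall on background voxels and are ignored",
                    sum(!on_fg)))
    idx <- idx[on_fg, , drop = FALSE]
  }
  grown <- cpp_flood26(mask$grid, d, matrix(as.integer(idx), ncol = 3))
  voxel_mask(array(grown, d), mask, mask$role)
}

# Integer offsets of a discrete Euclidean ball of the given voxel radius.
ball_offsets <- function(radius_vox) {
  r <- as.integer(radius_vox)
  g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  g <- g[g$i^2 + g$j^2 + g$k^2 <= radius_vox^2, , drop = FALSE]
  matrix(as.integer(as.matrix(g)), ncol = 3)
}

#' Binary morphology with a ball structuring element
#'
#' Erosion or dilation with a discrete Euclidean ball of `radius_vox` voxels.
#' The ball is defined in voxel units; anisotropic spacing is deliberately
#' ignored, matching how interactive segmentation tools apply these
#' operators. Radius 0 is the identity.
#'
#' @param mask a `voxel_mask`.
#' @param op `"erode"` or `"dilate"`.
#' @param radius_vox non-negative integer radius in voxels.
#' @return A `voxel_mask`.
#' @export
morph_mask <- function(mask, op = c("erode", "dilate"), radius_vox = 1) {
  op <- match.arg(op)
  stopifnot(inherits(mask, "voxel_mask"), radius_vox >= 0)
  if (radius_vox == 0) return(mask)
  off <- ball_offsets(radius_vox)
  d <- dim(mask$grid)
  out <- cpp_morph(mask$grid, d, off, op == "erode")
  voxel_mask(array(out, d), mask, mask$role)
}

#' Plane of the most distal tray face, derived from the implant mask
#'
#' Identifies the tray slab as the contiguous run of axial (y) slices whose
#' in-slice voxel count is at least half the maximum (the plate is much wider
#' than the stem), and returns the plane through the most distal face of that
#' slab with the normal pointing proximally (+y).
#'
#' @param implant implant `voxel_mask`.
#' @return list(`point` world mm, `normal` unit vector).
#' @export
tray_plane <- function(implant) {
  stopifnot(inherits(implant, "voxel_mask"))
  if (!any(implant$grid)) stop("implant mask is empty")
  counts <- apply(implant$grid, 2, sum)
  big <- which(counts >= 0.5 * max(counts))
  # contiguous run containing the widest slice
  peak <- which.max(counts)
  lo <- peak
  while (lo - 1 >= 1 && (lo - 1) %in% big) lo <- lo - 1
  j0 <- lo - 1  # 0-based index of the most distal tray slice
  y_face <- index_to_world(implant, c(0, j0, 0))[2] - implant$spacing[2] / 2
  list(point = c(0, y_face, 0), normal = c(0, 1, 0))
}

#' Remove the proximal, scatter-degraded part of the bone mask
#'
#' Removes all bone voxels proximal to the tray plane and those within
#' `cut_mm` distal of it -- the region directly under the tibial baseplate is
#' degraded by metal scatter and would corrupt the bone registration.
#'
#' @param bone bone `voxel_mask`.
#' @param plane list(`point`, `normal`) as returned by [tray_plane()]; the
#'   normal must point proximally.
#' @param cut_mm thickness of the distal band to remove below the plane, mm.
#' @return A `voxel_mask`.
#' @export
proximal_cut <- function(bone, plane, cut_mm = 5) {
  stopifnot(inherits(bone, "voxel_mask"), cut_mm >= 0)
  n <- plane$normal / sqrt(sum(plane$normal^2))
  d <- dim(bone$grid)
  # signed distance to the plane is linear in the voxel indices, so build it
  # separably instead of materializing all voxel coordinates
  ax <- (0:(d[1] - 1)) * bone$spacing[1]
  ay <- (0:(d[2] - 1)) * bone$spacing[2]
  az <- (0:(d[3] - 1)) * bone$spacing[3]
  dn <- as.numeric(n %*% bone$direction)  # n projected on voxel axes
  const <- sum((bone$origin - plane$point) * n)
  dist <- const +
    outer(outer(ax * dn[1], ay * dn[2], `+`), az * dn[3], `+`)
  keep <- bone$grid & (dist < -cut_mm)
  if (!any(keep))
    stop("proximal cut removed the entire bone mask (cut too aggressive)")
  voxel_mask(keep, bone, bone$role)
}

#' Subtract the implant mask from the bone mask
#'
#' Guarantees the two registration masks are disjoint, so no voxel intensity
#' contributes to both structure registrations.
#'
#' @param bone,implant `voxel_mask`s on the same grid.
#' @return A `voxel_mask` (bone AND NOT implant).
#' @export
subtract_implant <- function(bone, implant) {
  stopifnot(inherits(bone, "voxel_mask"), inherits(implant, "voxel_mask"))
  if (!same_geometry(bone, implant))
    stop("bone and implant masks have different geometry")
  voxel_mask(bone$grid & !implant$grid, bone, bone$role)
}

#' Bone length along the proximal axis
#'
#' Physical extent of the mask projected on the given (unit) axis, in mm:
#' the span of the voxel-centre projections plus the projection of one voxel
#' footprint. A quality warning is emitted below 70 mm, the recommended
#' minimum amount of tibial bone for a reliable registration.
#'
#' @param bone bone `voxel_mask`.
#' @param proximal_axis unit vector, world frame.
#' @return Length in mm.
#' @export
bone_length <- function(bone, proximal_axis = c(0, 1, 0)) {
  stopifnot(inherits(bone, "voxel_mask"))
  if (!any(bone$grid)) stop("bone mask is empty")
  ax <- proximal_axis / sqrt(sum(proximal_axis^2))
  proj <- voxel_world_coords(bone, which(bone$grid)) %*% ax
  footprint <- sum(abs(as.numeric(ax %*% bone$direction)) * bone$spacing)
  len <- (max(proj) - min(proj)) + footprint
  if (len < 70)
    warning(sprintf(paste("bone length %.1f mm is below the recommended 70 mm",
                          "of tibial bone for registration"), len))
  len
}

#' Segmentation report in the style of a per-observer summary table
#'
#' Records the HU thresholds used and the resulting mask volumes in cubic
#' centimetres for one observer.
#'
#' @param params list with `threshold_bone` and `threshold_implant` (HU).
#' @param bone,implant the final `voxel_mask`s.
#' @param observer label for the observer/run.
#' @return A one-row data.frame.
#' @export
segmentation_report <- function(params, bone, implant, observer = "OBS1") {
  data.frame(observer = observer,
             threshold_bone_hu = params$threshold_bone,
             threshold_implant_hu = params$threshold_implant,
             volume_bone_cm3 = mask_volume_cm3(bone),
             volume_implant_cm3 = mask_volume_cm3(implant),
             bone_empty = !any(bone$grid),
             implant_empty = !any(implant$grid))
}

#' Compare two observers' segmentation reports
#'
#' Absolute differences of thresholds and mask volumes between two
#' [segmentation_report()] rows, the layout used to summarize interobserver
#' segmentation variability.
#'
#' @param report_a,report_b one-row data.frames from [segmentation_report()].
#' @return A data.frame with one row per quantity and columns for each
#'   observer and their absolute difference.
#' @export
compare_segmentations <- function(report_a, report_b) {
  fields <- c("threshold_bone_hu", "threshold_implant_hu",
              "volume_bone_cm3", "volume_implant_cm3")
  data.frame(quantity = fields,
             obs_a = as.numeric(report_a[1, fields]),
             obs_b = as.numeric(report_b[1, fields]),
             abs_dif = abs(as.numeric(report_a[1, fields]) -
                           as.numeric(report_b[1, fields])))
}
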