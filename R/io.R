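# Volume, mask and transform I/O plus eligibility checks. Volumes travel as
# NIfTI with the world geometry in the sform; transforms as JSON.

#' Read / write CT volumes as NIfTI
#'
#' The world geometry (spacing, origin, direction) is carried in the NIfTI
#' sform; a write/read round trip preserves voxels bit-exactly and geometry
#' to well below 1e-6 mm. The axial axis (for the slice-thickness metadata)
#' defaults to the third voxel axis, the NIfTI convention; producers that
#' know better (e.g. the phantom, whose axial direction is +y) can override.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param axial_axis which voxel axis is the scan's axial direction (1-3).
#' @return A `ct_volume`.
#' @export
read_volume <- function(path, axial_axis = 3) {
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  if (length(dim(arr)) != 3)
    stop("expected a 3-D volume, got ", length(dim(arr)), " dimensions")
  arr <- array(as.vector(arr), dim(arr))  # drop NIfTI attributes
  aff <- RNifti::xform(im)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume has missing or invalid voxel spacing metadata")
  direction <- sweep(aff[1:3, 1:3], 2, spacing, `/`)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-4)
    stop("volume direction matrix is not orthonormal")
  # re-orthonormalize exactly (headers carry float32 precision)
  sv <- svd(direction)
  direction <- sv$u %*% t(sv$v)
  ct_volume(arr, spacing, aff[1:3, 4], direction,
            slice_thickness = spacing[axial_axis],
            pixel_spacing = max(spacing[-axial_axis]))
}

#' @rdname read_volume
#' @param vol a `ct_volume` (or `voxel_mask` for `write_mask`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  im <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(im) <- vol$spacing
  aff <- diag(4)
  aff[1:3, 1:3] <- vol$direction %*% diag(vol$spacing)
  aff[1:3, 4] <- vol$origin
  im <- RNifti::`sform<-`(im, structure(aff, code = 2L))
  im <- RNifti::`qform<-`(im, structure(aff, code = 2L))
  RNifti::writeNifti(im, path, datatype = "double")
  invisible(path)
}

#' Read / write voxel masks as 0/1 NIfTI volumes
#' @param mask a `voxel_mask`.
#' @param path file path.
#' @param role role for the mask read back.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  vol <- ct_volume(array(as.numeric(mask$grid), dim(mask$grid)),
                   mask$spacing, mask$origin, mask$direction)
  write_volume(vol, path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, role = "bone") {
  vol <- read_volume(path)
  voxel_mask(vol$voxels > 0.5, vol, role)
}

#' Serialize rigid transforms as JSON
#'
#' Layout: `matrix` (rotation, row-major), `translation_mm`, `center_mm`.
#' @param tf a `rigid_transform`.
#' @param path file path.
#' @export
write_transform <- function(tf, path) {
  stopifnot(inherits(tf, "rigid_transform"))
  obj <- list(matrix = as.numeric(t(tf$rotation)),
              translation_mm = tf$translation,
              center_mm = tf$center,
              cardan_sequence = "x-y-z (fixed axes, R = Rz Ry Rx)")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(obj$matrix, 3, 3, byrow = TRUE),
                  obj$translation_mm, obj$center_mm)
}

#' Study configuration
#'
#' Bundles the segmentation parameters, registration options, anatomical
#' axis information and eligibility rule for one analysis run.
#'
#' @param laterality `"right"` or `"left"` knee.
#' @param threshold_bone,threshold_implant lower HU thresholds for the bone
#'   and implant masks; the implant threshold also caps the bone mask so the
#'   two never share metal voxels.
#' @param erosion_radius,dilation_radius ball radii (voxels) for the mask
#'   cleanup opening.
#' @param implant_dilate_radius ball radius (voxels) by which the implant
#'   mask is dilated before subtraction from the bone mask: the metal's
#'   partial-volume halo falls inside the bone HU window but moves with the
#'   implant, so leaving it in the bone mask would bias the bone
#'   registration toward the implant's motion.
#' @param proximal_cut_mm bone removed distal to the tray plane, mm.
#' @param bone_seeds,implant_seeds optional world seed points for region
#'   growing; `NULL` derives seeds automatically (bone: mask voxel nearest
#'   the mask centroid; implant: brightest voxel).
#' @param max_slice_thickness eligibility cap, mm (strict inequality).
#' @param reg registration options from [reg_opts()].
#' @param axes 3x3 matrix of anatomical axis directions (columns = medial,
#'   proximal, anterior in the volume world frame).
#' @export
study_config <- function(laterality = c("right", "left"),
                         threshold_bone = 430, threshold_implant = 2200,
                         erosion_radius = 1, dilation_radius = 1,
                         implant_dilate_radius = 4,
                         proximal_cut_mm = 8,
                         bone_seeds = NULL, implant_seeds = NULL,
                         max_slice_thickness = 1.0,
                         reg = reg_opts(),
                         axes = diag(3)) {
  laterality <- match.arg(laterality)
  stopifnot(threshold_implant > threshold_bone)
  structure(list(laterality = laterality, threshold_bone = threshold_bone,
                 threshold_implant = threshold_implant,
                 erosion_radius = erosion_radius,
                 dilation_radius = dilation_radius,
                 implant_dilate_radius = implant_dilate_radius,
                 proximal_cut_mm = proximal_cut_mm,
                 bone_seeds = bone_seeds, implant_seeds = implant_seeds,
                 max_slice_thickness = max_slice_thickness,
                 reg = reg, axes = axes),
            class = "study_config")
}

#' Scan-pair eligibility check
#'
#' A pair is eligible when both scans have a slice thickness strictly below
#' the configured maximum (default 1.0 mm). Report-only: thin-slice
#' reconstructions are required for sub-voxel migration measurement.
#'
#' @param baseline,followup `ct_volume`s.
#' @param cfg a [study_config()].
#' @return list(`eligible`, `slice_thickness` (both scans, mm), `max_allowed`).
#' @export
check_eligibility <- function(baseline, followup, cfg = study_config()) {
  st <- c(baseline = baseline$meta$slice_thickness,
          followup = followup$meta$slice_thickness)
  if (anyNA(st)) stop("slice thickness metadata is missing")
  list(eligible = all(st < cfg$max_slice_thickness),
       slice_thickness = st,
       max_allowed = cfg$max_slice_thickness)
}
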