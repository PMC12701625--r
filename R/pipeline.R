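# End-to-end orchestration: segment the baseline, clean the masks, register
# bone and implant to the follow-up, convert to migration parameters.

# Automatic seed points when the config supplies none. The bone seed sits in
# the largest connected component of the thresholded mask (the cortical
# shell) -- centroid-based seeds can land in thin partial-volume halos around
# the metal. The implant seed is the brightest voxel.
auto_bone_seed <- function(mask) {
  biggest <- cpp_largest_component(mask$grid, dim(mask$grid))
  sel <- which(biggest)
  pts <- voxel_world_coords(mask, sel)
  ctr <- colMeans(pts)
  pts[which.min(rowSums(sweep(pts, 2, ctr)^2)), , drop = FALSE]
}

auto_implant_seed <- function(volume, mask) {
  sel <- which(mask$grid)
  vals <- volume$voxels[sel]
  voxel_world_coords(mask, sel[which.max(vals)])
}

#' Segment bone and implant masks from the baseline volume
#'
#' Thresholding (the bone mask is capped above by the implant threshold so
#' metal voxels never enter it), seeded region growing, a morphological
#' opening (erode then dilate), the proximal cut below the tray plane, and
#' implant subtraction.
#'
#' @param baseline a `ct_volume`.
#' @param cfg a [study_config()].
#' @return list(`bone`, `implant` (`voxel_mask`s), `tray_plane`,
#'   `bone_length_mm`, `report` ([segmentation_report()])).
#' @export
segment_pair_masks <- function(baseline, cfg = study_config()) {
  implant_raw <- threshold_mask(baseline, cfg$threshold_implant, Inf,
                                role = "implant")
  if (!any(implant_raw$grid)) stop("segmentation: implant threshold selects no voxels")
  iseed <- if (is.null(cfg$implant_seeds)) auto_implant_seed(baseline, implant_raw)
           else cfg$implant_seeds
  implant <- region_grow(implant_raw, iseed)

  bone_raw <- threshold_mask(baseline, cfg$threshold_bone,
                             cfg$threshold_implant, role = "bone")
  if (!any(bone_raw$grid)) stop("segmentation: bone threshold selects no voxels")
  bseed <- if (is.null(cfg$bone_seeds)) auto_bone_seed(bone_raw)
           else cfg$bone_seeds
  bone <- region_grow(bone_raw, bseed)
  if (cfg$erosion_radius > 0)
    bone <- morph_mask(bone, "erode", cfg$erosion_radius)
  if (cfg$dilation_radius > 0)
    bone <- morph_mask(bone, "dilate", cfg$dilation_radius)

  plane <- tray_plane(implant)
  bone <- proximal_cut(bone, plane, cfg$proximal_cut_mm)
  # subtract the implant with a safety margin: the metal partial-volume halo
  # lies inside the bone HU window but moves with the implant
  impl_grown <- if (cfg$implant_dilate_radius > 0)
    morph_mask(implant, "dilate", cfg$implant_dilate_radius) else implant
  bone <- subtract_implant(bone, impl_grown)
  blen <- bone_length(bone, cfg$axes[, 2])

  list(bone = bone, implant = implant, tray_plane = plane,
       bone_length_mm = blen,
       report = segmentation_report(
         list(threshold_bone = cfg$threshold_bone,
              threshold_implant = cfg$threshold_implant),
         bone, implant))
}

#' Run the full migration measurement pipeline on a scan pair
#'
#' Executes segmentation, bone and implant registration, the relative-motion
#' composition and the migration decomposition, returning the migration
#' result together with all diagnostics. Fully deterministic: repeated runs
#' on the same inputs give identical results.
#'
#' @param baseline,followup `ct_volume`s (same day-0 and follow-up scan).
#' @param cfg a [study_config()].
#' @param force proceed even when a registration did not converge or the
#'   pair fails the eligibility check.
#' @return list(`result` (`migration_result`), `diagnostics`: segmentation
#'   report, bone length, eligibility, per-structure registration results,
#'   relative transform).
#' @export
run_pipeline <- function(baseline, followup, cfg = study_config(),
                         force = FALSE) {
  elig <- check_eligibility(baseline, followup, cfg)
  if (!elig$eligible && !force)
    stop(sprintf("eligibility: slice thickness %.2f/%.2f mm not below %.2f mm",
                 elig$slice_thickness[1], elig$slice_thickness[2],
                 elig$max_allowed))

  seg <- segment_pair_masks(baseline, cfg)

  reg_bone <- register_rigid(baseline, followup, seg$bone, cfg$reg)
  if (!reg_bone$converged && !force)
    stop("bone registration did not converge")
  reg_impl <- register_rigid(baseline, followup, seg$implant, cfg$reg)
  if (!reg_impl$converged && !force)
    stop("implant registration did not converge")

  rel <- relative_motion(reg_bone$transform, reg_impl$transform)
  model <- implant_model(seg$implant)
  res <- decompose_motion(rel, model, laterality = cfg$laterality,
                          axes = cfg$axes)
  list(result = res,
       diagnostics = list(eligibility = elig,
                          segmentation = seg$report,
                          bone_length_mm = seg$bone_length_mm,
                          tray_plane = seg$tray_plane,
                          registration_bone = reg_bone,
                          registration_implant = reg_impl,
                          relative_transform = rel,
                          implant_cog = model$cog))
}

#' Write a migration result as a single-row CSV
#'
#' Columns MTPM, TT, TR, Tx, Ty, Tz, Rx, Ry, Rz (mm / degrees) plus
#' laterality and the point count, matching the parameter set reported in
#' migration studies.
#'
#' @param result a `migration_result` (or list of them, one row each).
#' @param path file path.
#' @param subjects optional subject labels.
#' @export
write_migration_csv <- function(result, path, subjects = NULL) {
  if (inherits(result, "migration_result")) result <- list(result)
  df <- do.call(rbind, lapply(result, as.data.frame))
  if (!is.null(subjects)) df <- cbind(subject = subjects, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
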