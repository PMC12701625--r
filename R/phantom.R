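#' Digital tibia + tibial-tray phantom specification
#'
#' Describes an analytically defined proximal tibia (tapered cylinder with a
#' cortical shell) carrying a metal tibial tray (plate + stem + fins), used to
#' generate baseline/follow-up CT pairs with a known rigid implant micromotion.
#' Intensities default to values that the clinically used Hounsfield
#' thresholds (bone around 220-770 HU, implant 1900 HU and above) segment
#' cleanly: trabecular 300 HU, cortical 600 HU, implant 2500 HU, background
#' -50 HU, with 20 HU additive Gaussian noise. Default spacing is 0.5 mm
#' in-plane and 0.4 mm between slices, matching clinically typical knee
#' protocols for this kind of analysis.
#'
#' The phantom is emitted directly in the anatomical reporting frame
#' (+x medial, +y proximal, +z anterior, right knee); the bone axis is +y with
#' the resection plane at `y = bone$length` and the tray sitting on it.
#'
#' @param bone list: `outer_radius` (mm, at the proximal end),
#'   `shell_thickness` (mm), `length` (mm), `taper_ratio` (distal outer radius
#'   as a fraction of the proximal one), plus a lobed angular modulation of
#'   the outer radius (`lobe_amplitude`, `lobe_freq`, `lobe_phase`) giving
#'   the tibia-like, rotationally asymmetric cross-section that makes axial
#'   rotation observable -- a plain cylinder would leave rotation about the
#'   bone axis undetermined.
#' @param implant list: `tray_radius_ml` and `tray_radius_ap` (semi-axes of
#'   the elliptical tray plate -- tibial trays are wider medial-lateral than
#'   anterior-posterior, which also makes axial rotation observable),
#'   `tray_thickness`, `stem_radius`, `stem_length`, `fin_count`,
#'   `fin_length`, `fin_extent` (radial reach of the fins beyond the stem),
#'   `fin_half_thickness` (all mm except counts).
#' @param hu_trabecular,hu_cortical,hu_implant,hu_background HU plateaus; must
#'   satisfy implant > cortical > trabecular > background.
#' @param noise_sd additive Gaussian noise, HU.
#' @param edge_width 10-90% width of the smooth edge profile, mm, emulating
#'   the scanner's finite spatial resolution (about 1 lp/mm clinically).
#'   Edges are attached to each structure's local frame, so partial-volume
#'   intensities carry consistent sub-voxel position information at any pose.
#' @param scatter_band_mm width of the scatter-degraded band directly distal
#'   to the tray plate, mm.
#' @param scatter_amp_frac amplitude of the multiplicative radial streak
#'   pattern as a fraction of local HU (0.25 of 600 HU cortical = 150 HU).
#' @param spacing voxel spacing (dx, dy, dz), mm.
#' @param volume_shape voxel counts; `NULL` derives a shape that encloses the
#'   geometry with a 6 mm margin.
#' @param repositioning `rigid_transform` applied to the whole limb at
#'   follow-up (patient repositioning in the scanner).
#' @param implant_motion `rigid_transform`: ground-truth implant migration in
#'   the (baseline) bone frame.
#' @param remodeling_sd optional HU perturbation of bone intensities at
#'   follow-up, emulating interval bone remodeling.
#' @param seed integer; the only source of randomness (noise fields).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(bone = list(outer_radius = 28, shell_thickness = 4,
                                     length = 80, taper_ratio = 0.75,
                                     lobe_amplitude = 0.12, lobe_freq = 3,
                                     lobe_phase = 0.6),
                         implant = list(tray_radius_ml = 32,
                                        tray_radius_ap = 22,
                                        tray_thickness = 4,
                                        stem_radius = 6, stem_length = 40,
                                        fin_count = 4, fin_length = 24,
                                        fin_extent = 8,
                                        fin_half_thickness = 1.5),
                         hu_trabecular = 300, hu_cortical = 600,
                         hu_implant = 2500, hu_background = -50,
                         noise_sd = 20, edge_width = 0.8,
                         scatter_band_mm = 5,
                         scatter_amp_frac = 0.25,
                         spacing = c(0.5, 0.4, 0.5),
                         volume_shape = NULL,
                         repositioning = rt_identity(),
                         implant_motion = rt_identity(),
                         remodeling_sd = 0,
                         seed = 42L) {
  if (!(hu_implant > hu_cortical && hu_cortical > hu_trabecular &&
        hu_trabecular > hu_background))
    stop("HU plateaus must satisfy implant > cortical > trabecular > background")
  if (noise_sd < 0 || remodeling_sd < 0) stop("noise sd must be >= 0")
  if (any(spacing <= 0)) stop("spacing components must be > 0")
  if (scatter_band_mm < 0) stop("scatter_band_mm must be >= 0")
  if (edge_width <= 0) stop("edge_width must be > 0")
  stopifnot(inherits(repositioning, "rigid_transform"),
            inherits(implant_motion, "rigid_transform"))
  spec <- structure(list(bone = bone, implant = implant,
                         hu_trabecular = hu_trabecular,
                         hu_cortical = hu_cortical, hu_implant = hu_implant,
                         hu_background = hu_background, noise_sd = noise_sd,
                         edge_width = edge_width,
                         scatter_band_mm = scatter_band_mm,
                         scatter_amp_frac = scatter_amp_frac,
                         scatter_freq = 7, scatter_phase = 1,
                         spacing = as.numeric(spacing),
                         volume_shape = volume_shape,
                         repositioning = repositioning,
                         implant_motion = implant_motion,
                         remodeling_sd = remodeling_sd,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  if (is.null(spec$volume_shape)) spec$volume_shape <- phantom_grid(spec)$dims
  spec
}

# Grid (dims + origin) enclosing the phantom with a fixed margin. The bone
# spans y in [0, length]; x and z are centred on the bone axis.
phantom_grid <- function(spec, margin = 6) {
  sp <- spec$spacing
  r_bone <- spec$bone$outer_radius * (1 + spec$bone$lobe_amplitude)
  half_xz <- max(spec$implant$tray_radius_ml, spec$implant$tray_radius_ap,
                 r_bone) + margin
  y_lo <- -margin
  y_hi <- spec$bone$length + spec$implant$tray_thickness + margin
  if (!is.null(spec$volume_shape)) {
    dims <- as.integer(spec$volume_shape)
  } else {
    dims <- c(ceiling(2 * half_xz / sp[1]) + 1L,
              ceiling((y_hi - y_lo) / sp[2]) + 1L,
              ceiling(2 * half_xz / sp[3]) + 1L)
    dims <- as.integer(dims)
  }
  origin <- c(-(dims[1] - 1) / 2 * sp[1], y_lo, -(dims[3] - 1) / 2 * sp[3])
  list(dims = dims, origin = origin)
}

# World-frame transform placing the implant local frame (tray bottom at the
# local origin, +y proximal) onto the resected bone surface.
phantom_implant_pose <- function(spec) {
  rigid_transform(diag(3), c(0, spec$bone$length, 0))
}

#' Analytic surface points of the phantom implant (baseline pose)
#'
#' Points on the tray rim and faces and the stem tip, in world mm. For any
#' rigid motion the maximum point displacement is attained on the convex hull,
#' which these points cover; they serve as the ground-truth point set for the
#' analytic migration oracle.
#'
#' @param spec a `phantom_spec`.
#' @param n_angles angular sampling density.
#' @return n x 3 matrix of world points.
#' @export
phantom_implant_points <- function(spec, n_angles = 360) {
  im <- spec$implant
  th <- seq(0, 2 * pi, length.out = n_angles + 1)[-1]
  ell <- function(a, b, y) cbind(a * cos(th), y, b * sin(th))
  pts <- rbind(ell(im$tray_radius_ml, im$tray_radius_ap, 0),  # tray bottom rim
               ell(im$tray_radius_ml, im$tray_radius_ap,
                   im$tray_thickness),                        # tray top rim
               ell(im$stem_radius, im$stem_radius,
                   -im$stem_length),                          # stem tip rim
               c(0, -im$stem_length, 0),
               c(0, im$tray_thickness, 0))
  rt_apply(phantom_implant_pose(spec), pts)
}

#' Analytic centre of gravity of the phantom implant (baseline pose)
#'
#' Volume-weighted centroid of plate, stem and fins, world mm.
#' @param spec a `phantom_spec`.
#' @export
phantom_implant_cog <- function(spec) {
  im <- spec$implant
  v_plate <- pi * im$tray_radius_ml * im$tray_radius_ap * im$tray_thickness
  v_stem <- pi * im$stem_radius^2 * im$stem_length
  v_fin1 <- im$fin_extent * 2 * im$fin_half_thickness * im$fin_length
  v_fins <- im$fin_count * v_fin1
  y <- (v_plate * im$tray_thickness / 2 +
        v_stem * (-im$stem_length / 2) +
        v_fins * (-im$fin_length / 2)) / (v_plate + v_stem + v_fins)
  as.numeric(rt_apply(phantom_implant_pose(spec), c(0, y, 0)))
}

#' Migration parameters computed directly from a rigid transform
#'
#' The imaging-free oracle for the migration module: given the ground-truth
#' motion, an implant point set and the implant centre of gravity, computes
#' translations (displacement of the CoG), Cardan rotations, their 3-D vector
#' norms TT and TR, and MTPM as the exhaustive per-point maximum displacement.
#'
#' @param motion a `rigid_transform` (implant motion in the bone frame).
#' @param points n x 3 matrix of implant points, world mm.
#' @param cog implant centre of gravity, world mm.
#' @return A `migration_result` (see [decompose_motion()]).
#' @export
analytic_migration <- function(motion, points, cog) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  if (nrow(points) == 0) stop("implant point set is empty")
  d_cog <- as.numeric(rt_apply(motion, cog)) - as.numeric(cog)
  ang <- cardan_angles(motion$rotation)
  disp <- rt_apply(motion, points) - points
  mtpm_val <- max(sqrt(rowSums(disp^2)))
  new_migration_result(Tx = d_cog[1], Ty = d_cog[2], Tz = d_cog[3],
                       Rx = ang[1], Ry = ang[2], Rz = ang[3],
                       MTPM = mtpm_val, laterality = "right",
                       point_count = nrow(points))
}

#' Generate a baseline/follow-up phantom CT pair with known micromotion
#'
#' Both volumes are voxelized by supersampled analytic evaluation of the
#' geometry in its own pose (follow-up = repositioning applied to the limb,
#' with the implant additionally moved by the ground-truth migration in the
#' bone frame) -- never by resampling the baseline grid, so sub-voxel motion
#' is represented exactly up to the partial-volume model. Gaussian noise is
#' drawn independently for the two volumes from the spec seed. A structured
#' zero-mean streak band directly distal to the tray plate emulates the
#' scatter degradation that motivates the proximal bone cut.
#'
#' @param spec a `phantom_spec`.
#' @param baseline_voxels optional noise-free baseline voxel array from a
#'   previous call with the same spec apart from the motions (the baseline
#'   does not depend on them); reusing it halves the cost of motion sweeps.
#' @return list with elements `baseline` and `followup` (`ct_volume`),
#'   `ground_truth`: list(`migration` = the spec's implant motion,
#'   `reference` = [analytic_migration()] of it over the analytic implant
#'   surface points), and `baseline_clean` (the noise-free baseline array,
#'   reusable as `baseline_voxels`).
#' @export
generate_pair <- function(spec, baseline_voxels = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_grid(spec)
  dims <- g$dims
  sp <- spec$spacing

  T_impl <- phantom_implant_pose(spec)
  S <- spec$repositioning
  M <- spec$implant_motion

  # world -> structure-local maps for each time point
  inv_bone_base <- rt_matrix(rt_identity())
  inv_impl_base <- rt_matrix(rt_invert(T_impl))
  inv_bone_fu <- rt_matrix(rt_invert(S))
  inv_impl_fu <- rt_matrix(rt_invert(rt_compose(S, rt_compose(M, T_impl))))

  check_inside <- function(limb_tf, when) {
    ext_lo <- g$origin - sp / 2
    ext_hi <- g$origin + (dims - 1) * sp + sp / 2
    impl_pts <- rt_apply(limb_tf$implant, phantom_implant_points(spec, 90))
    bone_pts <- rt_apply(limb_tf$bone, phantom_bone_points(spec))
    for (nm in c("implant", "bone")) {
      pts <- if (nm == "implant") impl_pts else bone_pts
      ok <- pts >= matrix(ext_lo, nrow(pts), 3, byrow = TRUE) &
            pts <= matrix(ext_hi, nrow(pts), 3, byrow = TRUE)
      if (!all(ok))
        stop(sprintf("%s geometry extends outside the volume at %s", nm, when))
    }
  }
  check_inside(list(implant = rt_identity(), bone = rt_identity()), "baseline")
  check_inside(list(implant = rt_compose(S, M), bone = S), "follow-up")

  bone_par <- with(spec$bone, c(outer_radius, shell_thickness, length,
                                taper_ratio, lobe_amplitude, lobe_freq,
                                lobe_phase))
  impl_par <- with(spec$implant, c(tray_radius_ml, tray_radius_ap,
                                   tray_thickness, stem_radius,
                                   stem_length, fin_count, fin_length,
                                   fin_extent, fin_half_thickness))
  hu <- c(spec$hu_background, spec$hu_trabecular, spec$hu_cortical,
          spec$hu_implant)
  scat <- c(as.numeric(spec$scatter_band_mm > 0), spec$scatter_band_mm,
            spec$scatter_amp_frac, spec$scatter_freq, spec$scatter_phase,
            spec$implant$tray_radius_ml, spec$implant$tray_radius_ap)
  vox <- function(inv_bone, inv_impl) {
    cpp_voxelize_phantom(dims, sp, g$origin, 3L, bone_par, impl_par, hu,
                         inv_bone, inv_impl, scat, spec$edge_width)
  }
  base_clean <- if (is.null(baseline_voxels)) vox(inv_bone_base, inv_impl_base)
  else baseline_voxels
  fu_clean <- vox(inv_bone_fu, inv_impl_fu)

  n <- prod(dims)
  set.seed(spec$seed)
  base_noise <- if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0
  fu_noise <- if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0
  if (spec$remodeling_sd > 0) {
    bone_like <- fu_clean > (spec$hu_background + spec$hu_trabecular) / 2 &
      fu_clean < (spec$hu_cortical + spec$hu_implant) / 2
    remod <- rnorm(n, 0, spec$remodeling_sd) * bone_like
    fu_clean <- fu_clean + remod
  }

  mk <- function(clean, noise) {
    ct_volume(array(clean + noise, dims), sp, g$origin,
              slice_thickness = sp[2], pixel_spacing = max(sp[c(1, 3)]))
  }
  gt_pts <- phantom_implant_points(spec)
  list(baseline = mk(base_clean, base_noise),
       followup = mk(fu_clean, fu_noise),
       ground_truth = list(
         migration = M,
         reference = analytic_migration(M, gt_pts, phantom_implant_cog(spec))),
       baseline_clean = base_clean)
}

# Extreme bone surface points for the bounds check.
phantom_bone_points <- function(spec, n_angles = 90) {
  b <- spec$bone
  r_max <- b$outer_radius * (1 + b$lobe_amplitude)
  th <- seq(0, 2 * pi, length.out = n_angles + 1)[-1]
  rbind(cbind(r_max * cos(th), b$length, r_max * sin(th)),
        cbind(r_max * b$taper_ratio * cos(th), 0,
              r_max * b$taper_ratio * sin(th)))
}
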