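#' CT volume container
#'
#' A 3-D scalar field in Hounsfield units with world geometry. Voxel (i,j,k)
#' (1-based) has world position
#' \code{origin + direction \%*\% (spacing * (c(i,j,k) - 1))}. The anatomical
#' reporting frame used throughout is +x medial, +y proximal, +z anterior for
#' a right knee; the phantom emits this frame natively and
#' [remap_axes()] brings scanner-frame volumes into it.
#'
#' @param voxels 3-D numeric array, HU.
#' @param spacing voxel spacing (dx, dy, dz), mm; all > 0.
#' @param origin world position of the first voxel centre, mm.
#' @param direction 3x3 orthonormal axis-cosine matrix (columns = world
#'   directions of the voxel axes).
#' @param slice_thickness reconstructed slice thickness, mm. Defaults to the
#'   spacing along the axial (third) voxel axis.
#' @param pixel_spacing in-plane pixel spacing, mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      direction = diag(3),
                      slice_thickness = spacing[3],
                      pixel_spacing = max(spacing[1:2])) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)")
  direction <- as.matrix(direction)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction matrix is not orthonormal")
  if (any(!is.finite(voxels)))
    stop("voxel intensities must be finite HU values")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), direction = direction,
                 meta = list(slice_thickness = as.numeric(slice_thickness),
                             pixel_spacing = as.numeric(pixel_spacing))),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.0f, %.0f]; slice thickness %.3g mm\n",
              min(x$voxels), max(x$voxels), x$meta$slice_thickness))
  invisible(x)
}

#' @rdname ct_volume
#' @param vol a `ct_volume`.
#' @export
vol_dims <- function(vol) dim(vol$voxels)

#' Convert between world coordinates and continuous voxel indices
#'
#' Indices are 0-based and continuous (0 = centre of the first voxel), the
#' convention used by the trilinear interpolator.
#'
#' @param vol a `ct_volume` (or `voxel_mask`).
#' @param pts n x 3 matrix of world points (mm) or 0-based indices.
#' @return n x 3 matrix.
#' @export
world_to_index <- function(vol, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  local <- sweep(pts, 2, vol$origin) %*% vol$direction  # = t(D) %*% (p - o)
  sweep(local, 2, vol$spacing, `/`)
}

#' @rdname world_to_index
#' @export
index_to_world <- function(vol, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  local <- sweep(pts, 2, vol$spacing, `*`)
  sweep(local %*% t(vol$direction), 2, vol$origin, `+`)
}

#' World coordinates of a set of voxels
#' @param vol a `ct_volume` or `voxel_mask`.
#' @param lin_idx linear indices into the voxel array (1-based); defaults to
#'   all voxels of a mask's foreground when `vol` is a mask.
#' @return n x 3 matrix of world points, mm.
#' @export
voxel_world_coords <- function(vol, lin_idx) {
  d <- if (inherits(vol, "voxel_mask")) dim(vol$grid) else dim(vol$voxels)
  ijk <- arrayInd(lin_idx, d) - 1L
  index_to_world(vol, ijk)
}

#' Boolean voxel mask sharing a CT volume's geometry
#'
#' @param grid 3-D logical array.
#' @param geometry a `ct_volume` (geometry donor) or another `voxel_mask`.
#' @param role `"bone"` or `"implant"`.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(grid, geometry, role = c("bone", "implant")) {
  role <- match.arg(role)
  ref_dims <- if (inherits(geometry, "voxel_mask")) dim(geometry$grid)
              else dim(geometry$voxels)
  stopifnot(is.logical(grid), all(dim(grid) == ref_dims))
  structure(list(grid = grid, spacing = geometry$spacing,
                 origin = geometry$origin, direction = geometry$direction,
                 role = role),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask role=%s> %s voxels set, %.2f cm^3\n", x$role,
              format(sum(x$grid)), mask_volume_cm3(x)))
  invisible(x)
}

#' Mask volume in cubic centimetres
#'
#' Voxel count times voxel volume, the quantity reported in segmentation
#' summaries.
#' @param mask a `voxel_mask`.
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$grid) * prod(mask$spacing) / 1000
}

same_geometry <- function(a, b, tol = 1e-9) {
  da <- if (inherits(a, "voxel_mask")) dim(a$grid) else dim(a$voxels)
  db <- if (inherits(b, "voxel_mask")) dim(b$grid) else dim(b$voxels)
  all(da == db) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

#' Remap a volume into a different axis convention
#'
#' Applies a signed permutation of the voxel axes, e.g. to bring a
#' scanner-frame volume into the anatomical reporting frame (+x medial,
#' +y proximal, +z anterior). The world frame is rotated/reflected with the
#' voxels: new world coordinates are `P %*% old` where `P` is the signed
#' permutation matrix.
#'
#' @param vol a `ct_volume`.
#' @param perm integer length-3: which old axis supplies each new axis.
#' @param flip logical length-3: whether each new axis is the reverse of the
#'   old one.
#' @return A `ct_volume` in the new frame.
#' @export
remap_axes <- function(vol, perm = c(1, 2, 3), flip = c(FALSE, FALSE, FALSE)) {
  stopifnot(sort(perm) == 1:3, length(flip) == 3)
  v <- aperm(vol$voxels, perm)
  sp <- vol$spacing[perm]
  d <- dim(v)
  idx <- lapply(1:3, function(a) if (flip[a]) d[a]:1 else 1:d[a])
  v <- v[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  # signed permutation matrix: new world = P %*% old world
  P <- matrix(0, 3, 3)
  for (a in 1:3) P[a, perm[a]] <- if (flip[a]) -1 else 1
  # old-world position of the new first voxel centre
  first_old_idx <- vapply(1:3, function(a) if (flip[a]) d[a] - 1 else 0,
                          numeric(1))
  ijk_old <- numeric(3)
  ijk_old[perm] <- first_old_idx
  o_old <- as.numeric(index_to_world(vol, ijk_old))
  dir_new <- P %*% vol$direction[, perm, drop = FALSE] %*%
    diag(ifelse(flip, -1, 1), 3)
  ct_volume(v, sp, as.numeric(P %*% o_old), dir_new,
            slice_thickness = vol$meta$slice_thickness,
            pixel_spacing = vol$meta$pixel_spacing)
}
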