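# Toy geometry helpers: unit-spacing volumes where voxel (i,j,k) sits at
# world (i-1, j-1, k-1).
toy_volume <- function(arr, spacing = c(1, 1, 1)) {
  ct_volume(arr, spacing)
}

toy_mask <- function(grid, spacing = c(1, 1, 1), role = "bone") {
  voxel_mask(grid, toy_volume(array(0, dim(grid)), spacing), role)
}

test_that("thresholding selects exactly the configured HU window", {
  arr <- array(0, c(3, 1, 1))
  arr[1, 1, 1] <- 100; arr[2, 1, 1] <- 600; arr[3, 1, 1] <- 2500
  vol <- toy_volume(arr)
  # clinical median bone window picks only the 600 HU voxel
  expect_equal(which(threshold_mask(vol, 430, 1900)$grid), 2L)
  # unbounded implant threshold picks only the metal voxel
  expect_equal(which(threshold_mask(vol, 2200)$grid), 3L)
  # threshold above the global maximum: empty mask is legal
  expect_equal(sum(threshold_mask(vol, 5000)$grid), 0)
  expect_error(threshold_mask(vol, 500, 400), "below")
})

test_that("raising the lower threshold never adds voxels", {
  set.seed(31)
  vol <- toy_volume(array(rnorm(8 * 8 * 8, 500, 400), c(8, 8, 8)))
  prev <- threshold_mask(vol, 0)
  for (lo in c(200, 400, 600, 800)) {
    cur <- threshold_mask(vol, lo)
    expect_true(all(prev$grid[cur$grid]))
    prev <- cur
  }
})

test_that("region growing keeps only seeded 26-connected components", {
  grid <- array(FALSE, c(20, 20, 20))
  grid[3:6, 3:6, 3:6] <- TRUE     # blob A
  grid[12:15, 12:15, 12:15] <- TRUE  # blob B
  mask <- toy_mask(grid)
  grown <- region_grow(mask, c(3, 3, 3))  # world point inside blob A
  expect_equal(sum(grown$grid), 4^3)
  expect_true(all(which(grown$grid) %in% which(grid)))
  # seeds covering both components reproduce the input
  both <- region_grow(mask, rbind(c(3, 3, 3), c(12, 12, 12)))
  expect_identical(both$grid, grid)
  # background seed: warning and empty result
  expect_warning(empty <- region_grow(mask, c(9, 9, 9)), "background")
  expect_equal(sum(empty$grid), 0)
  expect_error(region_grow(mask, c(100, 0, 0)), "outside")
})

test_that("diagonally touching voxels are one 26-connected component", {
  grid <- array(FALSE, c(4, 4, 4))
  grid[1, 1, 1] <- TRUE
  grid[2, 2, 2] <- TRUE  # touches only at a corner
  grown <- region_grow(toy_mask(grid), c(0, 0, 0))
  expect_equal(sum(grown$grid), 2)
})

test_that("ball morphology matches the brute-force cube result", {
  grid <- array(FALSE, c(9, 9, 9))
  grid[3:7, 3:7, 3:7] <- TRUE
  mask <- toy_mask(grid)
  # radius 0 is the identity
  expect_identical(morph_mask(mask, "erode", 0)$grid, grid)
  # radius-1 ball = 6-neighbourhood: eroding a 5-cube leaves its 3-cube core
  er <- morph_mask(mask, "erode", 1)
  expected <- array(FALSE, c(9, 9, 9))
  expected[4:6, 4:6, 4:6] <- TRUE
  expect_identical(er$grid, expected)
  # closing a convex mask contains the original
  cl <- morph_mask(morph_mask(mask, "dilate", 1), "erode", 1)
  expect_true(all(cl$grid[grid]))
})

test_that("the proximal cut removes the scatter band and everything above", {
  grid <- array(FALSE, c(5, 100, 5))
  grid[3, , 3] <- TRUE  # 100 mm column of bone along +y
  bone <- toy_mask(grid)
  plane <- list(point = c(0, 100, 0), normal = c(0, 1, 0))
  cut <- proximal_cut(bone, plane, cut_mm = 5)
  expect_equal(sum(cut$grid), 95)
  expect_equal(suppressWarnings(bone_length(cut)), 95)
  # cut 0 removes only voxels at/above the plane
  expect_equal(sum(proximal_cut(bone, list(point = c(0, 99, 0),
                                           normal = c(0, 1, 0)), 0)$grid), 99)
  # plane below all bone: nothing survives
  expect_error(proximal_cut(bone, list(point = c(0, -10, 0),
                                       normal = c(0, 1, 0)), 5),
               "entire bone mask")
})

test_that("implant subtraction leaves masks disjoint and counts voxels", {
  ga <- array(FALSE, c(10, 10, 10)); ga[2:7, 2:7, 2:7] <- TRUE
  gb <- array(FALSE, c(10, 10, 10)); gb[6:9, 6:9, 6:9] <- TRUE
  bone <- toy_mask(ga); implant <- toy_mask(gb, role = "implant")
  overlap <- sum(ga & gb)
  out <- subtract_implant(bone, implant)
  expect_equal(sum(out$grid), sum(ga) - overlap)
  expect_equal(sum(out$grid & implant$grid), 0)
  # implant covering all bone: empty result
  gc <- array(TRUE, c(10, 10, 10))
  expect_equal(sum(subtract_implant(bone, toy_mask(gc, role = "implant"))$grid), 0)
  # geometry mismatch is an error
  other <- voxel_mask(gb, ct_volume(array(0, c(10, 10, 10)), c(2, 1, 1)),
                      "implant")
  expect_error(subtract_implant(bone, other), "geometry")
})

test_that("bone length is the projected extent with a 7 cm quality warning", {
  grid <- array(FALSE, c(3, 70, 3)); grid[2, , 2] <- TRUE
  expect_silent(len <- bone_length(toy_mask(grid)))
  expect_equal(len, 70)
  grid50 <- array(FALSE, c(3, 50, 3)); grid50[2, , 2] <- TRUE
  expect_warning(len50 <- bone_length(toy_mask(grid50)), "70 mm")
  expect_equal(len50, 50)
  # a single voxel spans one voxel footprint along the axis
  g1 <- array(FALSE, c(3, 3, 3)); g1[2, 2, 2] <- TRUE
  expect_warning(l1 <- bone_length(toy_mask(g1, spacing = c(1, 0.4, 1))))
  expect_equal(l1, 0.4)
  expect_error(bone_length(toy_mask(array(FALSE, c(2, 2, 2)))), "empty")
})

test_that("segmentation reports record thresholds and cm3 volumes", {
  grid <- array(FALSE, c(10, 10, 10)); grid[1:5, 1:5, 1:5] <- TRUE
  sp <- c(0.5, 0.4, 0.5)
  mask <- voxel_mask(grid, ct_volume(array(0, c(10, 10, 10)), sp), "bone")
  expect_equal(mask_volume_cm3(mask), 125 * prod(sp) / 1000)
  params <- list(threshold_bone = 430, threshold_implant = 2200)
  rep1 <- segmentation_report(params, mask, mask)
  expect_equal(rep1$volume_bone_cm3, 125 * prod(sp) / 1000)
  cmp <- compare_segmentations(rep1, rep1)
  expect_true(all(cmp$abs_dif == 0))
  params2 <- list(threshold_bone = 360, threshold_implant = 2300)
  cmp2 <- compare_segmentations(rep1, segmentation_report(params2, mask, mask))
  expect_equal(cmp2$abs_dif[cmp2$quantity == "threshold_bone_hu"], 70)
})

test_that("clinical median thresholds recover the true phantom interiors", {
  an <- default_translation_analysis()
  spec <- an$spec
  clean <- an$pair$baseline_clean
  # voxels entirely inside a structure have exact plateau HU (no partial
  # volume): use them as the geometric truth. At a 430 HU threshold the
  # segmentable bone compartment is the cortical shell (600 HU); trabecular
  # bone (300 HU) is below every observer's threshold.
  true_cortical <- abs(clean - spec$hu_cortical) < 1
  true_impl <- abs(clean - spec$hu_implant) < 1
  vol <- an$pair$baseline
  # seed in the middle of the cortical shell at mid-shaft, angle 0
  b <- spec$bone
  y_seed <- 20
  r_out <- b$outer_radius * (b$taper_ratio +
                             (1 - b$taper_ratio) * y_seed / b$length) *
    (1 + b$lobe_amplitude * cos(b$lobe_phase))
  seed <- c(r_out - b$shell_thickness / 2, y_seed, 0)
  bone_m <- region_grow(threshold_mask(vol, 430, 2200), seed)
  impl_m <- threshold_mask(vol, 2200)
  expect_gt(sum(bone_m$grid & true_cortical) / sum(true_cortical), 0.99)
  expect_gt(sum(impl_m$grid & true_impl) / sum(true_impl), 0.99)
})
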