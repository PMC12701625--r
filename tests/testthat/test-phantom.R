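test_that("analytic migration matches closed forms and the brute-force maximum", {
  spec <- small_spec()
  pts <- phantom_implant_points(spec, n_angles = 120)
  cog <- phantom_implant_cog(spec)

  # identity motion: everything zero
  res0 <- analytic_migration(rt_identity(), pts, cog)
  expect_equal(res0$MTPM, 0)
  expect_equal(res0$TT, 0)
  expect_equal(res0$TR, 0)

  # 3-4-5 translation: TT = MTPM = 5
  res_t <- analytic_migration(rt_from_params(t = c(3, 4, 0)), pts, cog)
  expect_equal(res_t$TT, 5, tolerance = 1e-12)
  expect_equal(res_t$MTPM, 5, tolerance = 1e-12)

  # rotation about an axis through the CoG: MTPM = 2 d_max sin(theta/2)
  theta <- 1.4
  rot <- rt_from_params(ry = theta, center = cog)
  d_perp <- sqrt((pts[, 1] - cog[1])^2 + (pts[, 3] - cog[3])^2)
  expect_equal(analytic_migration(rot, pts, cog)$MTPM,
               2 * max(d_perp) * sin(theta / 2 * pi / 180),
               tolerance = 1e-9)

  # exhaustive per-point oracle agreement on random motions
  set.seed(21)
  for (i in 1:10) {
    tf <- random_rigid()
    expect_equal(analytic_migration(tf, pts, cog)$MTPM,
                 mtpm_bruteforce(tf, pts), tolerance = 1e-12)
  }
  expect_error(analytic_migration(rt_identity(), pts[0, , drop = FALSE], cog),
               "empty")
})

test_that("known pure translation gives the derived TT and MTPM", {
  spec <- small_spec(implant_motion = rt_from_params(t = c(0.5, -0.3, 0.2)),
                     noise_sd = 0)
  pair <- generate_pair(spec)
  expect_equal(pair$ground_truth$reference$TT, sqrt(0.38), tolerance = 1e-9)
  expect_equal(pair$ground_truth$reference$MTPM, sqrt(0.38), tolerance = 1e-9)
  expect_equal(round(pair$ground_truth$reference$MTPM, 3), 0.616)
})

test_that("identity motions and zero noise give bit-identical volumes", {
  spec <- small_spec(noise_sd = 0)
  pair <- generate_pair(spec)
  expect_identical(pair$baseline$voxels, pair$followup$voxels)
  expect_equal(pair$ground_truth$reference$MTPM, 0)
})

test_that("the seed controls noise only, reproducibly", {
  spec_a <- small_spec(seed = 7)
  spec_b <- small_spec(seed = 7)
  spec_c <- small_spec(seed = 8)
  pa <- generate_pair(spec_a)
  pb <- generate_pair(spec_b)
  pc <- generate_pair(spec_c)
  expect_identical(pa$baseline$voxels, pb$baseline$voxels)
  expect_identical(pa$followup$voxels, pb$followup$voxels)
  expect_false(identical(pa$baseline$voxels, pc$baseline$voxels))
  # geometry (noise-free field) unchanged by the seed
  expect_identical(pa$baseline_clean, pc$baseline_clean)
})

test_that("default intensities sit inside the clinical segmentation windows", {
  sm <- small_pair_translation()
  clean <- sm$pair$baseline_clean
  expect_gte(max(clean), 1900)            # implant segmentable at 1900+
  expect_equal(max(clean), 2500)
  # cortical plateau lies inside the clinical bone threshold window
  expect_true(any(clean >= 220 & clean <= 770))
  spec <- sm$spec
  expect_true(spec$hu_cortical >= 220 && spec$hu_cortical <= 770)
  expect_true(spec$hu_implant >= 1900)
})

test_that("geometry escaping the volume is reported with the structure name", {
  expect_error(
    generate_pair(small_spec(
      implant_motion = rt_from_params(t = c(0, 40, 0)))),
    "implant")
  expect_error(
    generate_pair(small_spec(
      repositioning = rt_from_params(t = c(60, 0, 0)))),
    "bone|implant")
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(hu_implant = 100), "implant > cortical")
  expect_error(phantom_spec(noise_sd = -1), ">= 0")
  expect_error(phantom_spec(spacing = c(0.5, 0, 0.5)), "> 0")
})
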