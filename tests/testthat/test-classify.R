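mat <- cartilage_material()

test_that("out-of-plane fraction separates membrane, bending and mixed vectors", {
  sys <- coarse_system("spring")
  bend <- solve_bending_modes(sys, NULL, 2)
  memb <- solve_membrane_modes(sys, 2)
  expect_equal(out_of_plane_fraction(shape_membrane = memb$shapes[[1]], Mm = sys$Mm), 0)
  fb <- out_of_plane_fraction(shape_bending = bend$shapes[[1]], Mb = sys$Mb)
  expect_gt(fb, 0.9); expect_lte(fb, 1)
  # synthetic mixed vector with equal partitioned modal masses -> 1/2 exactly
  # (transverse mass of the w-only bending part vs equal membrane mass)
  wonly <- bend$shapes[[1]]
  wonly[-seq(1, length(wonly), 3)] <- 0
  mb_mass <- as.numeric(wonly %*% (sys$Mb %*% wonly))
  phim <- memb$shapes[[1]]
  mm_mass <- as.numeric(phim %*% (sys$Mm %*% phim))
  phim <- phim * sqrt(mb_mass / mm_mass)
  expect_equal(out_of_plane_fraction(wonly, phim, sys$Mb, sys$Mm), 0.5, tolerance = 1e-10)
  expect_error(out_of_plane_fraction(0 * wonly, Mb = sys$Mb), "zero total modal mass")
})

test_that("sign-region counting matches constructed lobe patterns and orientations", {
  msh <- coarse_mesh()
  y <- msh$nodes[, 2]; x <- msh$nodes[, 1]
  H <- max(y); W <- max(x)
  expect_error(count_sign_regions(msh, numeric(nrow(msh$nodes))), "all-zero")
  expect_error(count_sign_regions(msh, y, eps = 0.5), "eps")
  # single positive lobe = tilt pattern
  expect_equal(count_sign_regions(msh, rep(1, length(y)))$count, 1)
  # one sign flip along y: nodal line along x => anteroposterior orientation
  two <- sin(pi * y / H - pi / 2)
  r2 <- count_sign_regions(msh, two)
  expect_equal(r2$count, 2)
  expect_equal(r2$orientation, "anteroposterior")
  # one sign flip along x: nodal line along y => cephalocaudal
  two_x <- sin(pi * x / W - pi / 2)
  r2x <- count_sign_regions(msh, two_x)
  expect_equal(r2x$count, 2)
  expect_equal(r2x$orientation, "cephalocaudal")
  # three lobes from two x-running nodal lines
  three <- sin(3 * pi * y / H)
  r3 <- count_sign_regions(msh, three)
  expect_equal(r3$count, 3)
  expect_equal(r3$orientation, "anteroposterior")
})

test_that("sign-region counts equal a brute-force flood fill on random smooth fields", {
  msh <- mesh_outline(build_idealized_outline(), 3.5e-3)
  for (seed in 1:8) {
    f <- random_smooth_field(msh, seed)
    got <- count_sign_regions(msh, f, eps = 0.02)$count
    expect_equal(got, brute_force_sign_components(msh, f, 0.02),
                 info = paste("seed", seed))
  }
})

test_that("classification maps lobe counts to types and is sign/scale invariant", {
  msh <- coarse_mesh()
  sys <- coarse_system("spring")
  reg <- landmark_regions(msh)
  bend <- solve_bending_modes(sys, NULL, 3)
  memb <- solve_membrane_modes(sys, 1)
  # membrane mode is a dash
  cm <- classify_mode(memb$shapes[[1]], "membrane", msh, reg, mat, Mm = sys$Mm)
  expect_equal(cm$type, "-")
  expect_equal(cm$type_numeric, 0L)
  # fundamental bending mode is a single-lobe tilt
  c1 <- classify_mode(bend$shapes[[1]], "bending", msh, reg, mat, Mb = sys$Mb)
  expect_equal(c1$type, "I")
  expect_equal(c1$sign_region_count, 1)
  # constructed three-lobe bending field -> III, anteroposterior
  y <- msh$nodes[, 2]; H <- max(y)
  w3 <- sin(3 * pi * y / H)
  fixed <- unlist(msh$node_sets[c("nasal_bone", "ethmoid", "vomer", "hard_palate")])
  w3[fixed] <- 0
  shape3 <- numeric(3 * nrow(msh$nodes)); shape3[seq(1, length(shape3), 3)] <- w3
  c3 <- classify_mode(shape3, "bending", msh, reg, mat, Mb = sys$Mb)
  expect_equal(c3$type, "III")
  expect_equal(c3$orientation, "anteroposterior")
  # invariance under sign flip and amplitude rescaling
  for (tf in list(function(s) -s, function(s) 0.37 * s, function(s) -5 * s)) {
    ci <- classify_mode(tf(bend$shapes[[2]]), "bending", msh, reg, mat, Mb = sys$Mb)
    cr <- classify_mode(bend$shapes[[2]], "bending", msh, reg, mat, Mb = sys$Mb)
    expect_equal(ci$type, cr$type)
    expect_equal(ci$sign_region_count, cr$sign_region_count)
    expect_equal(ci$orientation, cr$orientation)
    expect_equal(ci$hotspots$landmark, cr$hotspots$landmark)
  }
})

test_that("classify_modeset aligns one row per mode and is deterministic", {
  msh <- coarse_mesh()
  sys <- coarse_system("spring")
  reg <- landmark_regions(msh)
  memb <- solve_membrane_modes(sys, 4)
  all_dash <- classify_modeset(memb, msh, reg, mat, sys$Mb, sys$Mm)
  expect_equal(all_dash$type, rep("-", 4))
  expect_equal(unname(attr(all_dash, "summary")["-"]), 4L)

  bend <- solve_bending_modes(sys, NULL, 4)
  merged <- merge_and_sort(bend, memb, 6)
  c1 <- classify_modeset(merged, msh, reg, mat, sys$Mb, sys$Mm)
  expect_equal(nrow(c1), 6)
  expect_equal(c1$mode, 1:6)
  # re-merging (stable, deterministic) reproduces the identical table
  c2 <- classify_modeset(merge_and_sort(bend, memb, 6), msh, reg, mat, sys$Mb, sys$Mm)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("modal hotspots rank the landmark containing the global stress maximum first", {
  run <- default_run()
  hs <- attr(run$classification, "hotspots")
  for (k in seq_along(hs)) {
    h <- hs[[k]]
    expect_equal(nrow(h), 4)
    expect_true(all(h$peak_von_mises >= 0))
    expect_true(all(diff(h$peak_von_mises) <= 0))      # ranked descending
    if (any(h$contains_global_max))
      expect_true(h$contains_global_max[1])            # containing region first
  }
  # the documented fatigue landmarks actually host the peaks somewhere
  expect_true(all(run$classification$top_landmark %in%
                    c("ANS", "BC_junction", "VEJ", "vomerine_groove")))
})

test_that("deviation-type reference text covers every type", {
  for (ty in c("I", "II", "III")) {
    info <- deviation_type_info(ty)
    expect_true(nzchar(info$pattern))
    expect_gt(length(info$procedures), 0)
  }
  expect_length(deviation_type_info("-")$procedures, 0)
})
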