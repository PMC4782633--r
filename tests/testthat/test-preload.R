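mat <- cartilage_material()

test_that("edge-pressure load integrates to p * t * L inward on straight free edges", {
  msh <- mesh_outline(rect_outline(30, 20), 5e-3)   # caudal edge x=30 mm, dorsal y=20 mm
  f <- build_load_vector(msh, load_case("dorsal_caudal_pressure"))
  fx <- f[seq(1, length(f), 2)]; fy <- f[seq(2, length(f), 2)]
  p <- 2000; t0 <- 2e-3
  # right (caudal) edge, length 20 mm: total force p t L pointing -x
  expect_equal(sum(fx), -p * t0 * 0.020, tolerance = 1e-12)
  # top (dorsal) edge, length 30 mm: total force p t L pointing -y
  expect_equal(sum(fy), -p * t0 * 0.030, tolerance = 1e-12)
  # zero magnitude gives a zero vector
  f0 <- build_load_vector(msh, load_case("dorsal_caudal_pressure", pressure_magnitude = 0))
  expect_equal(max(abs(f0)), 0)
})

test_that("tip couple applies 1 N per axis at each flanking node with zero net force", {
  msh <- coarse_mesh()
  f <- build_load_vector(msh, load_case("anteroposterior_couple"))
  loaded <- which(f != 0)
  expect_length(loaded, 4)                       # two nodes x two axes
  expect_equal(sum(abs(f[loaded])), 4)           # per-axis sum 2 x 1 N per axis
  fx <- f[seq(1, length(f), 2)]; fy <- f[seq(2, length(f), 2)]
  expect_equal(sum(fx), 0); expect_equal(sum(fy), 0)
  # non-zero net moment about the origin
  mom <- sum(msh$nodes[, 1] * fy - msh$nodes[, 2] * fx)
  expect_gt(abs(mom), 1e-4)
})

test_that("membrane static solve is linear, accurate, and recovers patch stresses", {
  sys <- coarse_system("spring")
  f <- build_load_vector(sys$mesh, load_case("anteroposterior_couple"))
  st <- solve_membrane_static(sys, f)
  expect_lt(st$residual, 1e-10)
  st2 <- solve_membrane_static(sys, 2 * f)
  expect_equal(st2$u, 2 * st$u, tolerance = 1e-9)
  expect_equal(st2$stress, 2 * st$stress, tolerance = 1e-9)
  st0 <- solve_membrane_static(sys, numeric(length(f)))
  expect_equal(max(abs(st0$u)), 0)
  expect_equal(max(st0$von_mises), 0)

  # uniaxial plane-stress patch (nu = 0): end traction sigma0 reproduced
  mat0 <- cartilage_material(E = 5e6, nu = 0, rho = 2000)
  pm <- septamodal:::rect_mesh(0.03, 0.01, 6L, 2L, 2e-3)
  pm$node_sets$left <- which(abs(pm$nodes[, 1]) < 1e-12)
  psys <- assemble_system(pm, mat0, NULL, fixed_labels = "left")
  sigma0 <- 1e4; t0 <- 2e-3
  right <- which(abs(pm$nodes[, 1] - 0.03) < 1e-12)
  fr <- numeric(2 * nrow(pm$nodes))
  seg <- 0.01 / 2                                  # 2 elements across height
  for (nd in right) {
    wgt <- if (min(abs(pm$nodes[nd, 2] - c(0, 0.01))) < 1e-9) 0.5 else 1
    fr[2 * nd - 1] <- sigma0 * t0 * seg * wgt
  }
  stp <- solve_membrane_static(psys, fr)
  expect_equal(unname(stp$stress[, 1]), rep(sigma0, nrow(pm$triangles)), tolerance = 1e-8)
  expect_lt(max(abs(stp$stress[, 2:3])), 1e-6 * sigma0)
  expect_equal(unname(stp$von_mises), rep(sigma0, nrow(pm$triangles)), tolerance = 1e-8)
})

test_that("geometric stiffness is zero without stress, linear, and matches the hand integral", {
  msh <- coarse_mesh()
  zero <- matrix(0, nrow(msh$triangles), 3)
  expect_equal(max(abs(assemble_geometric_stiffness(msh, zero))), 0)
  sys <- coarse_system("spring")
  st <- solve_membrane_static(sys, build_load_vector(msh, load_case("anteroposterior_couple")))
  Kg <- assemble_geometric_stiffness(msh, st)
  Kg3 <- assemble_geometric_stiffness(msh, st$stress * 3)
  expect_equal(as.matrix(Kg3), 3 * as.matrix(Kg), tolerance = 1e-12)
  expect_lt(max(abs(Kg - Matrix::t(Kg))), 1e-12 * max(abs(Kg)))

  # single element, uniform uniaxial stress: Kg = t A G' S G by hand
  xy <- rbind(c(0, 0), c(2e-2, 0), c(0, 1e-2))
  s <- c(1234, 0, 0)
  Kge <- element_geometric_stiffness(xy, 2e-3, s)
  A <- septamodal:::tri_area(xy)
  G <- rbind(c(xy[2, 2] - xy[3, 2], xy[3, 2] - xy[1, 2], xy[1, 2] - xy[2, 2]),
             c(xy[3, 1] - xy[2, 1], xy[1, 1] - xy[3, 1], xy[2, 1] - xy[1, 1])) / (2 * A)
  expect_equal(Kge, 2e-3 * A * t(G) %*% diag(c(1234, 0)) %*% G, tolerance = 1e-12)
})

test_that("compressive preload lowers and tension raises every bending frequency", {
  fx <- rectangular_plate_fixture(0.03, 0.03, mat, 2e-3, target_edge_length = 0.03 / 10)
  sys <- assemble_system(fx$mesh, mat, NULL, fixed_labels = character(),
                         ss_labels = "ss_edge")
  ne <- nrow(fx$mesh$triangles)
  # biaxial SS critical stress is ~2 pi^2 D/(b^2 t) ~ 41 kPa here; stay below
  comp <- matrix(c(rep(-2e4, ne), rep(-2e4, ne), rep(0, ne)), ncol = 3)
  f0 <- solve_bending_modes(sys, NULL, 4)$frequency
  fc <- solve_bending_modes(sys, assemble_geometric_stiffness(fx$mesh, comp), 4)$frequency
  ft <- solve_bending_modes(sys, assemble_geometric_stiffness(fx$mesh, -comp), 4)$frequency
  expect_true(all(fc < f0))
  expect_true(all(ft > f0))
})

test_that("a strong enough compressive preload is reported as buckling", {
  fx <- rectangular_plate_fixture(0.03, 0.03, mat, 2e-3, target_edge_length = 0.03 / 8)
  sys <- assemble_system(fx$mesh, mat, NULL, fixed_labels = character(),
                         ss_labels = "ss_edge")
  ne <- nrow(fx$mesh$triangles)
  crush <- matrix(c(rep(-5e6, ne), rep(-5e6, ne), rep(0, ne)), ncol = 3)
  expect_error(solve_bending_modes(sys, assemble_geometric_stiffness(fx$mesh, crush), 3),
               "buckled under preload")
})
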