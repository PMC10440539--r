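mats <- default_materials()

test_that("structured meshing yields the expected element layout", {
  s <- concentric_slice()
  mesh <- build_mesh(s, n_rays = 100, n_radial_per_layer = 3, n_slabs = 2)
  expect_equal(nrow(mesh$elems), 100 * 9 * 2)   # rays x radial x slabs
  q <- vesselfem:::fem_mesh_quality(mesh$nodes, mesh$elems - 1L)
  expect_gt(min(q$min_detJ), 0)
  # region volumes sum to the slab volume
  slab <- (contour_area(s$adv) - contour_area(s$lumen)) * mesh$thickness
  expect_equal(sum(q$volume), slab, tolerance = 5e-3)
  expect_error(build_mesh(s, n_rays = 16), ">= 32")
})

test_that("component elements capture the lipid pool volume", {
  # centroid containment resolves the pool to element granularity, so the
  # pool must span whole element bands for a tight volume check
  lip <- sector_lipid(1.58, 1.78, 0.3, 1.6)
  s <- concentric_slice(components = list(lip))
  mesh <- build_mesh(s, n_rays = 64, n_radial_per_layer = 3)
  vol_lip <- sum(mesh$volume[mesh$region == "lipid"])
  expect_equal(vol_lip, contour_area(lip) * mesh$thickness, tolerance = 0.1)
  expect_gt(sum(mesh$region == "lipid"), 0)
})

test_that("the unloaded reference state is in equilibrium", {
  mesh <- build_mesh(concentric_slice(), n_rays = 32,
                     n_radial_per_layer = 2)
  sol <- solve_inflation(mesh, mats, 0, axial_stretch = 1)
  expect_lt(max(abs(sol$U)), 1e-8)
  expect_lt(max(abs(sol$sigma_max)), 1e-8)
  expect_error(solve_inflation(mesh, mats, -1), ">= 0")
})

test_that("a thin-walled pressurised cylinder recovers the Laplace law", {
  r0 <- 2; t0 <- 0.1   # r/t = 20
  sl <- merge_to_single_layer(
    concentric_slice(c(r0, r0 + t0 / 3, r0 + 2 * t0 / 3, r0 + t0)))
  reg <- stiff_wall_registry(200)   # stiff so strain stays small
  mesh <- build_mesh(sl, n_rays = 48, n_radial_per_layer = 1)
  p <- 0.5
  sol <- solve_inflation(mesh, reg, p, axial_stretch = 1)
  hoop <- vapply(c(mesh$inner_ring, mesh$outer_ring), function(id)
    hoop_stress_at(sol, mesh, id), 0)
  expect_equal(mean(hoop), p * (r0 + t0 / 2) / t0, tolerance = 0.05)
})

test_that("layered inflation matches the semi-analytic cylinder oracle", {
  sl <- concentric_slice()
  mesh <- build_mesh(sl)
  layers <- mats[c("intima", "media", "adventitia")]
  for (p_mmHg in c(60, 100, 140)) {
    p <- mmHg_to_kPa(p_mmHg)
    sol <- solve_inflation(mesh, mats, p, axial_stretch = 1.05)
    orc <- axisym_cylinder_oracle(c(1.5, 1.8, 2.0, 2.3), layers, p, 1.05)
    # deformed inner radius
    rin_fem <- mean(sqrt(rowSums(
      (mesh$nodes[mesh$inner_ring, 1:2] + sol$U[mesh$inner_ring, 1:2])^2)))
    expect_equal(rin_fem, orc$r_in, tolerance = 1e-3)
    # peak hoop stress (at the lumen surface)
    expect_equal(max(sol$sigma_max[mesh$inner_ring]),
                 max(orc$profile$sigma_theta), tolerance = 0.05)
    # hoop profile at interior wall nodes (layer-interface nodes excluded:
    # there the nodal average straddles the inter-layer stress jump)
    Nr <- 3 * mesh$n_radial_per_layer
    ray1 <- mesh$inner_ring[1] + mesh$n_rays * (1:(Nr - 1))
    for (id in ray1) {
      R <- sqrt(sum(mesh$nodes[id, 1:2]^2))
      if (min(abs(R - c(1.8, 2.0))) < 1e-9) next
      ora <- approx(orc$profile$R, orc$profile$sigma_theta, xout = R,
                    ties = "ordered")$y
      expect_lt(abs(hoop_stress_at(sol, mesh, id) - ora),
                0.05 * max(orc$profile$sigma_theta))
    }
  }
})

test_that("reactions balance the applied load", {
  mesh <- build_mesh(concentric_slice(), n_rays = 40,
                     n_radial_per_layer = 2)
  sol <- solve_inflation(mesh, mats, mmHg_to_kPa(100), 1.05)
  fext <- matrix(sol$f_ext, ncol = 3, byrow = TRUE)
  rea <- matrix(sol$reactions, ncol = 3, byrow = TRUE)
  scale <- sqrt(sum(sol$f_ext^2))
  # follower pressure on the closed lumen ring has no net force; the
  # reactions must absorb exactly the (zero) total in every direction
  for (k in 1:3)
    expect_lt(abs(sum(rea[, k]) + sum(fext[, k])), 1e-6 * scale)
})

test_that("rotating the geometry and frames rotates the solution", {
  th0 <- 30 * pi / 180
  R2 <- matrix(c(cos(th0), -sin(th0), sin(th0), cos(th0)), 2, 2,
               byrow = TRUE)
  sl <- generate_synthetic_slice(cohort_spec(seed = 60), 1, 1)
  p <- mmHg_to_kPa(90)
  m1 <- build_mesh(sl, n_rays = 40, n_radial_per_layer = 2)
  # rigidly rotate the mesh (nodes, local frames, centroid, ray angles)
  m2 <- m1
  m2$nodes[, 1:2] <- m1$nodes[, 1:2] %*% t(R2)
  m2$ecirc[, 1:2] <- m1$ecirc[, 1:2] %*% t(R2)
  m2$centroid <- as.numeric(R2 %*% m1$centroid)
  m2$theta <- (m1$theta + th0) %% (2 * pi)
  s1 <- solve_inflation(m1, mats, p, 1.05)
  s2 <- solve_inflation(m2, mats, p, 1.05)
  # principal stresses are rotation invariants; displacements are compared
  # through the deformed radii because the in-plane rigid rotation is a
  # neutral mode whose pinning differs between the two meshes
  scale <- max(abs(s1$sigma_max))
  expect_lt(max(abs(s2$sigma_max - s1$sigma_max)) / scale, 1e-6)
  rad_about_lumen <- function(m, s) {
    x <- m$nodes[, 1:2] + s$U[, 1:2]
    ctr <- contour_centroid(x[m$inner_ring, ])
    sqrt((x[, 1] - ctr[1])^2 + (x[, 2] - ctr[2])^2)
  }
  expect_lt(max(abs(rad_about_lumen(m2, s2) - rad_about_lumen(m1, s1))),
            1e-6)
})

test_that("identical layer materials make multilayer and single-layer agree", {
  reg <- uniform_registry()
  sl <- generate_synthetic_slice(cohort_spec(seed = 77,
                                             calcification_prob = 0), 1, 1)
  p <- mmHg_to_kPa(100)
  m_multi <- build_mesh(sl, n_rays = 40, n_radial_per_layer = 2)
  m_single <- build_mesh(merge_to_single_layer(sl), n_rays = 40,
                         n_radial_per_layer = 2)
  s1 <- solve_inflation(m_multi, reg, p, 1.05)
  s2 <- solve_inflation(m_single, reg, p, 1.05)
  expect_lt(max(abs(s1$U - s2$U)), 1e-8)
  expect_lt(max(abs(s1$sigma_max - s2$sigma_max)), 1e-8)
  expect_lt(max(abs(s1$eps_max - s2$eps_max)), 1e-8)
})

test_that("near-incompressibility holds in solved states", {
  mesh <- build_mesh(concentric_slice(), n_rays = 40,
                     n_radial_per_layer = 2)
  sol <- solve_inflation(mesh, mats, mmHg_to_kPa(140), 1.05)
  expect_lt(max(abs(sol$J_range - 1)), 1e-2)
})

test_that("a media-walled single-layer model also solves", {
  # sensitivity companion to the intima-as-wall default
  reg <- default_materials(single_layer_material = "media")
  sl <- merge_to_single_layer(concentric_slice())
  mesh <- build_mesh(sl, n_rays = 32, n_radial_per_layer = 2)
  sol <- solve_inflation(mesh, reg, mmHg_to_kPa(100), 1.05)
  expect_true(all(is.finite(sol$sigma_max)))
  expect_gt(max(sol$sigma_max[mesh$inner_ring]), 0)
})

test_that("the mesh-convergence rule terminates under the 2% criterion", {
  sl <- concentric_slice()
  st <- mesh_convergence_study(sl, mats, mmHg_to_kPa(100),
                               axial_stretch = 1.05, n_rays = 36,
                               n_radial_per_layer = 2)
  hist <- st$history
  expect_lt(hist$diff_rel[nrow(hist)], 0.02)
  # the accepted solution agrees with the oracle
  orc <- axisym_cylinder_oracle(c(1.5, 1.8, 2.0, 2.3),
                                mats[c("intima", "media", "adventitia")],
                                mmHg_to_kPa(100), 1.05)
  expect_equal(max(st$solution$sigma_max[st$mesh$inner_ring]),
               max(orc$profile$sigma_theta), tolerance = 0.05)
  # an already-fine start terminates after a single comparison
  st2 <- mesh_convergence_study(sl, mats, mmHg_to_kPa(100),
                                n_rays = st$n_rays,
                                n_radial_per_layer = st$n_radial_per_layer)
  expect_lte(nrow(st2$history), nrow(hist))
})
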