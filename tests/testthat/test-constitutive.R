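mats <- default_materials()
five <- mats[c("intima", "media", "adventitia", "lipid", "calcification")]

# energy in principal stretches for an isochoric diagonal state, used as the
# finite-difference oracle against the tensor stress routine
energy_at <- function(lt, lz, p) {
  lr <- 1 / (lt * lz)
  FF <- diag(c(lt, lr, lz))
  st <- deformation_state(FF, ecirc = c(1, 0, 0), eax = c(0, 0, 1))
  if (p$isotropic || p$K1 == 0) strain_energy_iso(st, p)
  else strain_energy_aniso(st, p)
}

test_that("strain energies vanish in the reference state", {
  ref <- list(I1 = 3, I2 = 3, lambda_theta = 1, lambda_z = 1)
  for (p in five) {
    expect_equal(strain_energy_iso(ref, p), 0)
    if (!p$isotropic) expect_equal(strain_energy_aniso(ref, p), 0)
  }
})

test_that("scalar energy values match independent evaluation", {
  # lipid at I1 = 3.2: c2 = 0 so only the c1 and exponential terms act
  w <- strain_energy_iso(list(I1 = 3.2, I2 = 3.4), mats$lipid)
  expect_equal(w, 0.5 * 0.2 + 0.5 * (exp(1.5 * 0.2) - 1), tolerance = 1e-12)
  # calcification with only I2 leaving 3: c2 = 0 kills the active term
  expect_equal(strain_energy_iso(list(I1 = 3, I2 = 3.05),
                                 mats$calcification), 0)
  # media fiber term at I4 = 1.05 on an undistorted isotropic base
  w2 <- strain_energy_aniso(list(I1 = 3, I2 = 3), mats$media, I4 = 1.05)
  expect_equal(w2, 7 / 4 * (exp(4 * 0.05^2) - 1), tolerance = 1e-12)
})

test_that("fiber invariant follows the stretch-angle formula", {
  expect_equal(fiber_invariant(1.2, 0.8, 0), 1.44)
  expect_equal(fiber_invariant(0.9, 1.05, 90), 1.1025)
  # oblique angle against direct trig evaluation
  a <- 24.9 * pi / 180
  expect_equal(fiber_invariant(1.1, 1.05, 24.9),
               1.1^2 * cos(a)^2 + 1.05^2 * sin(a)^2, tolerance = 1e-12)
  # the fiber energy term is nonnegative for any I4
  for (I4 in c(0.8, 1, 1.002, 1.1)) {
    w <- strain_energy_aniso(list(I1 = 3, I2 = 3), mats$media, I4 = I4)
    expect_gte(w, 0)
  }
})

test_that("overflow guards reject unphysical deformation", {
  expect_error(strain_energy_iso(list(I1 = 8, I2 = 9), mats$intima),
               "overflow")
  expect_error(strain_energy_aniso(list(I1 = 3, I2 = 3), mats$intima,
                                   I4 = 3), "overflow")
  expect_error(deformation_state(diag(c(-1, 1, 1))), "det")
})

test_that("Cauchy stress is zero at identity and symmetric everywhere", {
  for (p in five) {
    sig <- cauchy_stress(diag(3), p)
    expect_lt(max(abs(sig)), 1e-10)
  }
  set.seed(4)
  for (i in 1:20) {
    FF <- diag(3) + 0.1 * matrix(rnorm(9), 3, 3)
    if (det(FF) <= 0) next
    p <- five[[i %% 5 + 1]]
    sig <- cauchy_stress(FF, p)
    expect_lt(max(abs(sig - t(sig))), 1e-10)
  }
})

test_that("stress matches the finite-difference energy derivative", {
  # along isochoric diagonal paths sigma_tt - sigma_rr = lt * dW/dlt
  set.seed(11)
  h <- 1e-5
  for (p in five) {
    for (i in 1:10) {
      lt <- runif(1, 0.95, 1.2)
      lz <- runif(1, 0.98, 1.1)
      FF <- diag(c(lt, 1 / (lt * lz), lz))
      sig <- cauchy_stress(deformation_state(FF), p)
      lhs <- sig[1, 1] - sig[2, 2]
      rhs <- lt * (energy_at(lt + h, lz, p) - energy_at(lt - h, lz, p)) /
        (2 * h)
      if (abs(rhs) > 1e-8)
        expect_equal(lhs, rhs, tolerance = 1e-3)
      # and the axial component against d/dlz
      lhs_z <- sig[3, 3] - sig[2, 2]
      rhs_z <- lz * (energy_at(lt, lz + h, p) - energy_at(lt, lz - h, p)) /
        (2 * h)
      if (abs(rhs_z) > 1e-8)
        expect_equal(lhs_z, rhs_z, tolerance = 1e-3)
    }
  }
})

test_that("component materials are isotropic under material rotations", {
  set.seed(7)
  FF <- diag(c(1.1, 1 / 1.1 / 1.03, 1.03))
  for (p in mats[c("lipid", "calcification")]) {
    s0 <- cauchy_stress(FF, p)
    for (i in 1:5) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      th <- runif(1, 0, pi)
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
      # material (right) rotation leaves an isotropic response unchanged
      expect_lt(max(abs(cauchy_stress(FF %*% R, p) - s0)), 1e-8)
      # spatial (left) rotation rotates the stress
      expect_lt(max(abs(cauchy_stress(R %*% FF, p) - R %*% s0 %*% t(R))),
                1e-8)
    }
  }
})

test_that("uniaxial curves are zero at unit stretch and strictly rising", {
  grid <- seq(1, 1.3, by = 0.02)
  for (nm in names(five)) {
    for (dir in c("circumferential", "axial")) {
      tab <- stress_stretch_curve(nm, dir, grid)
      expect_equal(tab$stress_kPa[1], 0)
      expect_true(all(diff(tab$stress_kPa) > 0))
    }
  }
  expect_error(stress_stretch_curve("intima", stretch = c(0.9, 1.1)),
               "within")
})

test_that("curves agree with an energy-minimisation oracle", {
  # plane-stress uniaxial: the lateral stretch minimises the incompressible
  # energy at fixed primary stretch; the stress is the energy slope there
  h <- 1e-6
  for (nm in c("media", "adventitia", "lipid")) {
    p <- mats[[nm]]
    for (l in c(1.08, 1.2)) {
      lo <- optimize(function(x) energy_at(l, x, p), c(0.5, 1.2),
                     tol = 1e-10)$minimum
      sig_oracle <- l * (energy_at(l + h, lo, p) -
                           energy_at(l - h, lo, p)) / (2 * h)
      got <- stress_stretch_curve(nm, "circumferential", l)$stress_kPa
      expect_equal(got, sig_oracle, tolerance = 1e-3)
    }
  }
})

test_that("relative layer stiffness matches the material curves", {
  # calcification is the stiffest tissue at moderate stretch; by 1.2 the
  # intima's exponential fiber term overtakes it, so the three-way
  # ordering is asserted at 1.1 and the robust pairs again at 1.2
  at <- function(nm, l = 1.2) stress_stretch_curve(nm, "circumferential",
                                                   l)$stress_kPa
  expect_gt(at("calcification", 1.1), at("intima", 1.1))
  expect_gt(at("intima", 1.1), at("lipid", 1.1))
  expect_gt(at("calcification"), at("lipid"))
  expect_gt(at("intima"), at("lipid"))
  # adventitia fibers at 75.3 degrees lie near-axial: the axial curve is
  # stiffer than the circumferential one at moderate stretch
  adv_ax <- stress_stretch_curve("adventitia", "axial", 1.15)$stress_kPa
  adv_ci <- stress_stretch_curve("adventitia", "circumferential",
                                 1.15)$stress_kPa
  expect_gt(adv_ax, adv_ci)
})

test_that("the material registry serializes losslessly to JSON", {
  path <- file.path(tempdir(), "mats.json")
  write_materials(mats, path)
  back <- read_materials(path)
  expect_equal(lapply(back, unclass), lapply(mats, unclass))
})
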