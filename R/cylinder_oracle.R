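#' Semi-analytic inflation of a layered incompressible cylinder
#'
#' Independent verification solution for concentric geometries: exact
#' incompressible kinematics `r(R) = sqrt(r_in^2 + (R^2 - R_in^2)/lambda_z)`
#' and quadrature of the radial equilibrium equation
#' `d(sigma_r)/dr = (sigma_theta - sigma_r)/r` through the layered wall,
#' using the same strain-energy functions as the finite-element material
#' model but evaluated directly in principal stretches (numerical
#' differentiation of the energy, an implementation path fully independent
#' of the element stress routine). The deformed inner radius is found by a
#' root solve on the outer traction-free condition; by construction
#' `sigma_r(inner) = -p` and `sigma_r(outer) = 0`.
#'
#' @param radii reference layer boundary radii (mm), length L+1 increasing.
#' @param materials list of L `material_params`, inner to outer.
#' @param pressure_kPa lumen pressure (kPa).
#' @param axial_stretch axial stretch (default 1.05).
#' @param n_grid quadrature points per layer.
#' @return list with `r_in` (deformed inner radius, mm) and `profile`, a
#'   data frame of `R`, `r`, `lambda_theta`, `sigma_r`, `sigma_theta`,
#'   `sigma_z` (kPa) and `layer`.
#' @export
axisym_cylinder_oracle <- function(radii, materials, pressure_kPa,
                                   axial_stretch = 1.05, n_grid = 200) {
  L <- length(materials)
  stopifnot(length(radii) == L + 1, all(diff(radii) > 0))
  lz <- axial_stretch
  Rin <- radii[1]

  grid <- do.call(rbind, lapply(seq_len(L), function(l)
    data.frame(R = seq(radii[l], radii[l + 1], length.out = n_grid),
               layer = l)))

  profile_for <- function(r_in) {
    r <- sqrt(r_in^2 + (grid$R^2 - Rin^2) / lz)
    lt <- r / grid$R
    h <- numeric(nrow(grid))
    for (l in seq_len(L)) {
      sel <- grid$layer == l
      h[sel] <- vapply(lt[sel], dWdlt_times_lt, 0, lz = lz,
                       p = materials[[l]])
    }
    integrand <- h * grid$R / (lz * r^2)   # (s_t - s_r)/r * dr/dR
    cumint <- cumtrapz_by_layer(grid$R, integrand, grid$layer)
    sigr <- -pressure_kPa + cumint
    list(r = r, lt = lt, h = h, sigr = sigr)
  }

  gfun <- function(r_in) {
    # outside the physical stretch range the wall tension is enormous;
    # treat the overflow guard as "far too inflated" so the root-find
    # (g is increasing in r_in) steps back inside
    tryCatch(profile_for(r_in)$sigr[nrow(grid)],
             error = function(e) 1e12)
  }
  r_in <- stats::uniroot(gfun, c(0.7 * Rin, 1.6 * Rin), tol = 1e-10,
                         extendInt = "yes")$root
  pf <- profile_for(r_in)

  sigz <- numeric(nrow(grid))
  for (l in seq_len(L)) {
    sel <- grid$layer == l
    sigz[sel] <- pf$sigr[sel] +
      vapply(pf$lt[sel], dWdlz_times_lz, 0, lz = lz, p = materials[[l]])
  }
  list(r_in = r_in,
       profile = data.frame(R = grid$R, r = pf$r, lambda_theta = pf$lt,
                            sigma_r = pf$sigr,
                            sigma_theta = pf$sigr + pf$h,
                            sigma_z = sigz, layer = grid$layer))
}

# incompressible energy in stretches; fiber tension-only as in the FEM model
W_hat <- function(lt, lz, p) {
  lr <- 1 / (lt * lz)
  I1 <- lr^2 + lt^2 + lz^2
  I2 <- lr^2 * lt^2 + lt^2 * lz^2 + lz^2 * lr^2
  w <- p$c1 * (I1 - 3) + p$c2 * (I2 - 3) +
    p$D1 * (exp(guard_exp(p$D2 * (I1 - 3), "D2*(I1-3)")) - 1)
  if (!p$isotropic && p$K1 > 0) {
    a <- p$phi * pi / 180
    I4 <- lt^2 * cos(a)^2 + lz^2 * sin(a)^2
    if (I4 > 1)
      w <- w + p$K1 / p$K2 *
        (exp(guard_exp(p$K2 * (I4 - 1)^2, "K2*(I4-1)^2")) - 1)
  }
  w
}

dWdlt_times_lt <- function(lt, lz, p, h = 1e-6) {
  lt * (W_hat(lt + h, lz, p) - W_hat(lt - h, lz, p)) / (2 * h)
}

dWdlz_times_lz <- function(lt, lz, p, h = 1e-6) {
  lz * (W_hat(lt, lz + h, p) - W_hat(lt, lz - h, p)) / (2 * h)
}

# cumulative trapezoid, continuous across the duplicated layer-boundary
# abscissae (the integrand may jump between layers)
cumtrapz_by_layer <- function(x, y, layer) {
  out <- numeric(length(x))
  acc <- 0
  for (l in unique(layer)) {
    sel <- which(layer == l)
    ct <- c(0, cumsum(diff(x[sel]) * (y[sel][-1] + y[sel][-length(sel)]) / 2))
    out[sel] <- acc + ct
    acc <- out[sel[length(sel)]]
  }
  out
}
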