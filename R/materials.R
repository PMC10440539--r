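#' Constitutive parameters for one tissue
#'
#' Modified Mooney-Rivlin model with an exponential isotropic term and, for
#' the vessel layers, an exponential fiber reinforcement term:
#' \deqn{W_{iso} = c_1(I_1-3) + c_2(I_2-3) + D_1[\exp(D_2(I_1-3)) - 1]}
#' \deqn{W_{aniso} = W_{iso} + (K_1/K_2)[\exp(K_2(I_4-1)^2) - 1]}
#' with \eqn{I_4 = \lambda_\theta^2\cos^2\varphi + \lambda_z^2\sin^2\varphi}
#' the squared stretch along fibers at angle \eqn{\varphi} from the
#' circumferential direction. Plaque components (lipid, calcification) are
#' isotropic (no fiber term).
#'
#' @param c1,c2,D1 stress-like constants (kPa).
#' @param D2 dimensionless exponent.
#' @param K1 fiber stiffness (kPa); 0 disables the fiber term.
#' @param K2 dimensionless fiber exponent (> 0 when the fiber term is active).
#' @param phi fiber angle from the circumferential direction (degrees,
#'   in `[0, 90]`).
#' @param isotropic `TRUE` for component tissues without fibers.
#' @param name optional tissue name.
#' @return an object of class `material_params`.
#' @export
material_params <- function(c1, c2, D1, D2, K1 = 0, K2 = 0, phi = 0,
                            isotropic = (K1 == 0), name = "") {
  if (D2 < 0) stop("material_params: D2 must be >= 0", call. = FALSE)
  if (!isotropic && K1 != 0 && K2 <= 0)
    stop("material_params: K2 must be > 0 when the fiber term is active",
         call. = FALSE)
  if (phi < 0 || phi > 90)
    stop("material_params: phi must lie in [0, 90] degrees", call. = FALSE)
  structure(list(c1 = c1, c2 = c2, D1 = D1, D2 = D2,
                 K1 = if (isotropic) 0 else K1,
                 K2 = if (isotropic) 0 else K2,
                 phi = if (isotropic) 0 else phi,
                 isotropic = isotropic, name = name),
            class = "material_params")
}

#' Default material registry
#'
#' Layer-specific parameter sets for intima, media and adventitia, isotropic
#' lipid and calcification, and the single-layer `wall` material. The intima
#' fiber angle is not reported with the layer curves this set reproduces;
#' circumferential fibers (`phi = 0`) are used, the convention of the source
#' material curves. The single-layer wall uses the intima parameter set by
#' default (`single_layer_material` switches it).
#'
#' @param single_layer_material which layer's parameters the merged
#'   single-layer wall uses (`"intima"`, the default, or `"media"`,
#'   `"adventitia"`).
#' @return named list of `material_params` of class `material_registry`,
#'   with entries intima, media, adventitia, lipid, calcification, wall.
#' @export
default_materials <- function(single_layer_material = "intima") {
  reg <- list(
    intima       = material_params(-169.23, 177.40, 2.4, 13, 32, 36, 0,
                                   isotropic = FALSE, name = "intima"),
    media        = material_params(-67.25, 35.01, 17, 2, 7, 4, 24.9,
                                   isotropic = FALSE, name = "media"),
    adventitia   = material_params(-94.44, 102.42, 0.8, 10, 10, 40, 75.3,
                                   isotropic = FALSE, name = "adventitia"),
    lipid        = material_params(0.5, 0, 0.5, 1.5, name = "lipid"),
    calcification = material_params(920, 0, 360, 2.0, name = "calcification"))
  single_layer_material <- match.arg(single_layer_material,
                                     c("intima", "media", "adventitia"))
  reg$wall <- reg[[single_layer_material]]
  reg$wall$name <- "wall"
  structure(reg, class = "material_registry")
}

#' Serialize / restore a material registry
#'
#' @param reg a `material_registry`.
#' @param path file path.
#' @return `write_materials` returns `path` invisibly; `read_materials`
#'   returns a `material_registry`.
#' @export
write_materials <- function(reg, path) {
  jsonlite::write_json(lapply(reg, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_materials
#' @export
read_materials <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  reg <- lapply(raw, function(m)
    material_params(m$c1, m$c2, m$D1, m$D2, m$K1, m$K2, m$phi,
                    isotropic = m$isotropic, name = m$name))
  structure(reg, class = "material_registry")
}

#' Kinematic state from a deformation gradient
#'
#' Computes the right Cauchy-Green tensor `C = t(F) %*% F`, `J = det(F)`,
#' the invariants I1, I2, and (in the given local frame) the circumferential
#' and axial stretches used by the fiber invariant.
#'
#' @param F 3x3 deformation gradient.
#' @param ecirc,eax local circumferential and axial unit vectors in the
#'   reference configuration.
#' @return an object of class `deformation_state` with fields `F`, `C`, `J`,
#'   `I1`, `I2`, `lambda_theta`, `lambda_z`, `ecirc`, `eax`.
#' @export
deformation_state <- function(F, ecirc = c(1, 0, 0), eax = c(0, 0, 1)) {
  F <- matrix(as.numeric(F), 3, 3)
  J <- det(F)
  if (J <= 0) stop("deformation_state: det(F) must be > 0 (inverted state)",
                   call. = FALSE)
  C <- crossprod(F)
  I1 <- sum(diag(C))
  I2 <- 0.5 * (I1^2 - sum(C * C))
  structure(list(F = F, C = C, J = J, I1 = I1, I2 = I2,
                 lambda_theta = sqrt(drop(ecirc %*% C %*% ecirc)),
                 lambda_z = sqrt(drop(eax %*% C %*% eax)),
                 ecirc = ecirc, eax = eax),
            class = "deformation_state")
}

guard_exp <- function(x, what) {
  if (any(x > 50))
    stop("constitutive overflow guard: ", what,
         " > 50 (deformation outside the physical range)", call. = FALSE)
  x
}

#' Isotropic strain-energy density
#'
#' `c1*(I1-3) + c2*(I2-3) + D1*(exp(D2*(I1-3)) - 1)` in kPa, evaluated on the
#' invariants carried by `state` (any list with `I1` and `I2` works).
#'
#' @param state a `deformation_state` (or list with `I1`, `I2`).
#' @param p a `material_params`.
#' @return energy density (kPa).
#' @export
strain_energy_iso <- function(state, p) {
  x <- guard_exp(p$D2 * (state$I1 - 3), "D2*(I1-3)")
  p$c1 * (state$I1 - 3) + p$c2 * (state$I2 - 3) + p$D1 * (exp(x) - 1)
}

#' Fiber invariant
#'
#' Squared stretch along a fiber at angle `phi` (degrees) from the
#' circumferential direction:
#' `lambda_theta^2 * cos(phi)^2 + lambda_z^2 * sin(phi)^2`.
#'
#' @param lambda_theta,lambda_z circumferential and axial stretches (> 0).
#' @param phi fiber angle in degrees.
#' @return the invariant I4.
#' @export
fiber_invariant <- function(lambda_theta, lambda_z, phi) {
  stopifnot(all(lambda_theta > 0), all(lambda_z > 0))
  a <- phi * pi / 180
  lambda_theta^2 * cos(a)^2 + lambda_z^2 * sin(a)^2
}

#' Anisotropic strain-energy density
#'
#' Adds the exponential fiber term `(K1/K2)*(exp(K2*(I4-1)^2) - 1)` to
#' [strain_energy_iso()]. Fibers support tension only: for `I4 <= 1` the
#' term is zero.
#'
#' @param state a `deformation_state` (needs `lambda_theta`, `lambda_z`
#'   unless `I4` is supplied).
#' @param p a `material_params` with an active fiber term.
#' @param I4 optional fiber invariant override.
#' @return energy density (kPa).
#' @export
strain_energy_aniso <- function(state, p, I4 = NULL) {
  if (p$isotropic || p$K1 == 0)
    stop("strain_energy_aniso: material has no active fiber term",
         call. = FALSE)
  if (is.null(I4))
    I4 <- fiber_invariant(state$lambda_theta, state$lambda_z, p$phi)
  w <- strain_energy_iso(state, p)
  if (I4 > 1) {
    x <- guard_exp(p$K2 * (I4 - 1)^2, "K2*(I4-1)^2")
    w <- w + p$K1 / p$K2 * (exp(x) - 1)
  }
  w
}

#' Volumetric penalty stiffness for a material
#'
#' `1000 * max(|c1|, |c2|, D1)` kPa; keeps `|J - 1|` below about 1e-3 in
#' inflation problems without ill-conditioning the tangent.
#'
#' @param p a `material_params`.
#' @return penalty modulus kappa (kPa).
#' @export
penalty_kappa <- function(p) 1000 * max(abs(p$c1), abs(p$c2), p$D1)

#' Cauchy stress of the nearly-incompressible material
#'
#' Evaluates `sigma = (2/J) * F %*% dWbar/dC %*% t(F) + kappa*(J-1)*I`, where
#' `Wbar` is the strain energy on distortional (isochoric) invariants
#' `J^(-2/3) I1`, `J^(-4/3) I2`, `J^(-2/3) I4`, and the volumetric penalty
#' `kappa/2 (J-1)^2` enforces near-incompressibility. Fibers act as one
#' symmetric pair at `+phi` and `-phi` in the circumferential-axial plane
#' (each with weight 1/2, tension-only), which reduces to the single-I4 form
#' in shear-free states.
#'
#' @param state a `deformation_state` (or a 3x3 deformation gradient).
#' @param p a `material_params`.
#' @param kappa volumetric penalty (kPa); default [penalty_kappa()].
#' @return symmetric 3x3 Cauchy stress (kPa).
#' @export
cauchy_stress <- function(state, p, kappa = penalty_kappa(p)) {
  if (is.matrix(state)) state <- deformation_state(state)
  F <- state$F; C <- state$C; J <- state$J
  I1 <- state$I1; I2 <- state$I2
  Ci <- solve(C)
  Jm23 <- J^(-2 / 3)
  I1b <- Jm23 * I1
  I2b <- Jm23^2 * I2
  x <- guard_exp(p$D2 * (I1b - 3), "D2*(I1-3)")
  psi1 <- p$c1 + p$D1 * p$D2 * exp(x)
  psi2 <- p$c2
  Id <- diag(3)
  S <- 2 * (psi1 * Jm23 * (Id - (I1 / 3) * Ci) +
              psi2 * Jm23^2 * (I1 * Id - C - (2 * I2 / 3) * Ci))
  if (!p$isotropic && p$K1 > 0) {
    a <- p$phi * pi / 180
    for (sgn in c(1, -1)) {
      v <- cos(a) * state$ecirc + sgn * sin(a) * state$eax
      I4 <- drop(v %*% C %*% v)
      I4b <- Jm23 * I4
      if (I4b > 1) {
        xf <- guard_exp(p$K2 * (I4b - 1)^2, "K2*(I4-1)^2")
        psi4 <- 0.5 * 2 * p$K1 * (I4b - 1) * exp(xf)
        S <- S + 2 * psi4 * Jm23 * (outer(v, v) - (I4 / 3) * Ci)
      }
    }
  }
  sig <- (F %*% S %*% t(F)) / J + kappa * (J - 1) * Id
  (sig + t(sig)) / 2
}
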