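#' Uniaxial stress-stretch curve for a registry material
#'
#' Exactly incompressible plane-stress uniaxial protocol: the stretch in the
#' requested direction is prescribed, the radial (thickness) stress is zero,
#' and the lateral in-plane stretch is solved so its stress vanishes too.
#' The fiber angle enters through the fiber invariant, so circumferential and
#' axial curves differ for the anisotropic layers.
#'
#' @param layer registry entry name (`"intima"`, `"media"`, `"adventitia"`,
#'   `"lipid"`, `"calcification"`, `"wall"`).
#' @param direction `"circumferential"` or `"axial"`.
#' @param stretch numeric vector of stretches in `[1, 1.5]`.
#' @param materials a `material_registry`.
#' @return data frame with columns `stretch` and `stress_kPa` (Cauchy).
#' @export
stress_stretch_curve <- function(layer,
                                 direction = c("circumferential", "axial"),
                                 stretch = seq(1, 1.3, by = 0.01),
                                 materials = default_materials()) {
  direction <- match.arg(direction)
  if (!layer %in% names(materials))
    stop("stress_stretch_curve: unknown layer '", layer, "'", call. = FALSE)
  if (any(stretch < 1 - 1e-12) || any(stretch > 1.5 + 1e-12))
    stop("stress_stretch_curve: stretch grid must lie within [1.0, 1.5]",
         call. = FALSE)
  p <- materials[[layer]]
  sig <- vapply(stretch, function(l) uniaxial_stress(l, direction, p), 0)
  data.frame(stretch = stretch, stress_kPa = sig)
}

# principal Cauchy stress differences for the incompressible material at
# stretches (lt = circumferential, lz = axial, lr = 1/(lt*lz)):
# sigma_i - sigma_r = lambda_i * dW*/dlambda_i, with W* the substituted
# incompressible energy. Analytic chain rule on I1, I2, I4.
incompressible_sigma <- function(lt, lz, p) {
  lr <- 1 / (lt * lz)
  I1 <- lr^2 + lt^2 + lz^2
  I2 <- lr^2 * lt^2 + lt^2 * lz^2 + lz^2 * lr^2
  x <- guard_exp(p$D2 * (I1 - 3), "D2*(I1-3)")
  W1 <- p$c1 + p$D1 * p$D2 * exp(x)
  W2 <- p$c2
  W4 <- 0
  cs2 <- sn2 <- 0
  if (!p$isotropic && p$K1 > 0) {
    a <- p$phi * pi / 180
    cs2 <- cos(a)^2; sn2 <- sin(a)^2
    I4 <- lt^2 * cs2 + lz^2 * sn2
    if (I4 > 1) {
      xf <- guard_exp(p$K2 * (I4 - 1)^2, "K2*(I4-1)^2")
      W4 <- 2 * p$K1 * (I4 - 1) * exp(xf)
    }
  }
  dlr2_dlt <- -2 * lr^2 / lt
  dlr2_dlz <- -2 * lr^2 / lz
  dI1t <- 2 * lt + dlr2_dlt
  dI1z <- 2 * lz + dlr2_dlz
  dI2t <- 2 * lt * (lr^2 + lz^2) + dlr2_dlt * (lt^2 + lz^2)
  dI2z <- 2 * lz * (lr^2 + lt^2) + dlr2_dlz * (lt^2 + lz^2)
  st <- lt * (W1 * dI1t + W2 * dI2t + W4 * 2 * lt * cs2)
  sz <- lz * (W1 * dI1z + W2 * dI2z + W4 * 2 * lz * sn2)
  c(circumferential = st, axial = sz)
}

uniaxial_stress <- function(l, direction, p) {
  if (abs(l - 1) < 1e-12) return(0)
  other <- if (direction == "circumferential") "axial" else "circumferential"
  g <- function(lo) {
    s <- if (direction == "circumferential")
      incompressible_sigma(l, lo, p) else incompressible_sigma(lo, l, p)
    s[[other]]
  }
  # the lateral stretch stays near 1 under uniaxial load; a wide bracket
  # would push the stiff exponential terms past their overflow guard
  lo <- stats::uniroot(g, c(0.7, 1.3), tol = 1e-12, extendInt = "yes")$root
  s <- if (direction == "circumferential")
    incompressible_sigma(l, lo, p) else incompressible_sigma(lo, l, p)
  s[[direction]]
}
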