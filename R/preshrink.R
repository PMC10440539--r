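#' Axial pre-stretch factor
#'
#' The imaged vessel is axially stretched in vivo; the slab is therefore
#' first shrunk axially by `1/(1 + fraction)` (geometry scale along z before
#' solving) and then stretched back by `1 + fraction` as a prescribed
#' boundary displacement during the solve, so the loaded slab recovers its
#' imaged 0.5 mm thickness.
#'
#' @param fraction axial shrink-stretch fraction (default 0.05, i.e. 5%).
#' @return the axial stretch ratio `1 + fraction`.
#' @export
axial_prestretch_factor <- function(fraction = 0.05) 1 + fraction

#' Circumferential pre-shrink of an imaged slice
#'
#' Recovers the computational start shape: a uniform in-plane scale factor
#' `s` (about the lumen centroid) is applied to all contours such that
#' inflating the shrunk geometry to the imaging pressure and axial stretch
#' reproduces the imaged lumen circumference. The match is a scalar
#' root-find on `s` (bracketed secant/bisection hybrid on [0.85, 1]); the
#' shrunk configuration is stress-free by construction, and downstream
#' stresses/strains are measured relative to it.
#'
#' @param slice a valid `vessel_slice` (imaged, in vivo geometry).
#' @param materials a `material_registry`.
#' @param pressure_kPa imaging pressure (kPa, >= 0).
#' @param axial_stretch axial stretch ratio (default 1.05).
#' @param tol relative lumen-circumference tolerance (default 0.005).
#' @param max_iter iteration cap (default 25).
#' @param bracket search interval for the shrink factor (default
#'   `c(0.75, 1)`; compliant walls at high pressure can need factors below
#'   0.85).
#' @param n_rays,n_radial_per_layer,n_slabs mesh resolution used for the
#'   embedded inflation solves.
#' @return a list of class `preshrink_result`: `shrink_factor`, `shrunk`
#'   (the scaled slice), `residual` (relative circumference mismatch),
#'   `iterations`, plus the final `mesh` and `solution` at the converged
#'   factor.
#' @export
circumferential_preshrink <- function(slice, materials, pressure_kPa,
                                      axial_stretch = 1.05, tol = 0.005,
                                      max_iter = 25, bracket = c(0.75, 1),
                                      n_rays = 48, n_radial_per_layer = 2,
                                      n_slabs = 1) {
  validate_slice(slice)
  if (pressure_kPa < 0) stop("pressure must be >= 0", call. = FALSE)
  target <- contour_perimeter(slice$lumen)
  thick <- 0.5 / axial_stretch

  if (pressure_kPa == 0) {
    mesh <- build_mesh(slice, thickness = thick, n_rays = n_rays,
                       n_radial_per_layer = n_radial_per_layer,
                       n_slabs = n_slabs)
    sol <- solve_inflation(mesh, materials, 0, axial_stretch)
    return(structure(list(shrink_factor = 1, shrunk = slice, residual = 0,
                          iterations = 1L, mesh = mesh, solution = sol),
                     class = "preshrink_result"))
  }

  warm <- NULL
  last <- NULL
  evals <- 0L
  g <- function(s) {
    sl <- scale_slice(slice, s)
    mesh <- build_mesh(sl, thickness = thick, n_rays = n_rays,
                       n_radial_per_layer = n_radial_per_layer,
                       n_slabs = n_slabs)
    sol <- solve_inflation(mesh, materials, pressure_kPa, axial_stretch,
                           init_U = warm)
    warm <<- sol$U
    evals <<- evals + 1L
    ring <- mesh$nodes[mesh$inner_ring, 1:2] + sol$U[mesh$inner_ring, 1:2]
    last <<- list(mesh = mesh, solution = sol, shrunk = sl)
    contour_perimeter(ring) / target - 1
  }

  lo <- bracket[1]; hi <- bracket[2]
  g_hi <- g(hi)
  if (abs(g_hi) <= tol)
    return(structure(list(shrink_factor = hi, shrunk = last$shrunk,
                          residual = g_hi, iterations = evals,
                          mesh = last$mesh, solution = last$solution),
                     class = "preshrink_result"))
  if (g_hi < 0)
    stop("preshrink bracket: inflated geometry is smaller than imaged ",
         "(no shrink factor in [", lo, ", ", hi, "] can match)",
         call. = FALSE)
  g_lo <- NA   # sign at the lower end, evaluated lazily
  s1 <- hi; g1 <- g_hi
  s2 <- max(lo, hi / (1 + g_hi))   # secant-style first guess
  repeat {
    g2 <- g(s2)
    if (abs(g2) <= tol)
      return(structure(list(shrink_factor = s2, shrunk = last$shrunk,
                            residual = g2, iterations = evals,
                            mesh = last$mesh, solution = last$solution),
                       class = "preshrink_result"))
    if (evals >= max_iter)
      stop("circumferential_preshrink: no convergence in ", max_iter,
           " iterations (|residual| = ", signif(abs(g2), 3), ")",
           call. = FALSE)
    if (g2 > 0) hi <- s2 else { lo <- s2; g_lo <- g2 }
    s_new <- s2 - g2 * (s2 - s1) / (g2 - g1)
    if (!is.finite(s_new)) s_new <- (lo + hi) / 2
    if (s_new <= bracket[1] + 1e-12 && is.na(g_lo)) {
      # secant points below the bracket: check there is a sign change
      g_lo <- g(bracket[1])
      if (abs(g_lo) <= tol)
        return(structure(list(shrink_factor = bracket[1],
                              shrunk = last$shrunk, residual = g_lo,
                              iterations = evals, mesh = last$mesh,
                              solution = last$solution),
                         class = "preshrink_result"))
      if (g_lo > 0)
        stop("preshrink bracket: no sign change in [", bracket[1], ", ",
             bracket[2], "]", call. = FALSE)
    }
    if (s_new <= lo || s_new >= hi) s_new <- (lo + hi) / 2
    s1 <- s2; g1 <- g2; s2 <- s_new
  }
}

#' Uniformly scale a slice in-plane about its lumen centroid
#'
#' @param slice a `vessel_slice`.
#' @param s scale factor.
#' @return the scaled `vessel_slice` (wall mode preserved).
#' @export
scale_slice <- function(slice, s) {
  ctr <- contour_centroid(slice$lumen)
  sc <- function(cc) {
    cc$points <- sweep(sweep(cc$points, 2, ctr, "-") * s, 2, ctr, "+")
    cc
  }
  out <- slice
  out$lumen <- sc(slice$lumen); out$iem <- sc(slice$iem)
  out$eem <- sc(slice$eem); out$adv <- sc(slice$adv)
  out$components <- lapply(slice$components, sc)
  out
}
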