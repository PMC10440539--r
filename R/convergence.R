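#' Mesh-convergence study
#'
#' Repeatedly refines the characteristic element size by 10% in each
#' dimension (angular and radial counts scaled by 1/0.9), re-solves the
#' inflation problem, and compares the maximum principal stress on the
#' inner (lumen) wall between successive resolutions. The loop stops when
#' the successive relative difference drops below `tol` (2% by default) and
#' returns the accepted resolution together with the difference trace.
#'
#' @param slice a valid `vessel_slice`.
#' @param materials a `material_registry`.
#' @param pressure_kPa lumen pressure (kPa).
#' @param axial_stretch axial stretch ratio.
#' @param n_rays,n_radial_per_layer base (coarsest) resolution.
#' @param tol relative stopping tolerance on the monitored stress.
#' @param max_refine refinement cap; exceeding it is an error carrying the
#'   difference trace.
#' @return list with `n_rays`, `n_radial_per_layer` (accepted resolution),
#'   `solution` (accepted solve), `mesh`, and `history` (data frame of
#'   resolution, monitored max inner-wall stress, successive difference).
#' @export
mesh_convergence_study <- function(slice, materials, pressure_kPa,
                                   axial_stretch = 1.05, n_rays = 36,
                                   n_radial_per_layer = 2, tol = 0.02,
                                   max_refine = 10) {
  validate_slice(slice)
  grow <- 1 / 0.9
  hist <- NULL
  prev <- NULL
  nr <- n_rays; nl <- n_radial_per_layer
  for (lev in 0:max_refine) {
    mesh <- build_mesh(slice, thickness = 0.5 / axial_stretch,
                       n_rays = nr, n_radial_per_layer = nl)
    sol <- solve_inflation(mesh, materials, pressure_kPa, axial_stretch)
    metric <- max(sol$sigma_max[mesh$inner_ring])
    diff_rel <- if (is.null(prev)) NA_real_ else
      abs(metric - prev$metric) / abs(prev$metric)
    hist <- rbind(hist, data.frame(level = lev, n_rays = nr,
                                   n_radial_per_layer = nl,
                                   max_inner_stress_kPa = metric,
                                   diff_rel = diff_rel))
    if (!is.null(prev) && diff_rel < tol)
      return(list(n_rays = prev$nr, n_radial_per_layer = prev$nl,
                  solution = prev$sol, mesh = prev$mesh, history = hist))
    prev <- list(metric = metric, sol = sol, mesh = mesh, nr = nr, nl = nl)
    nr <- as.integer(ceiling(nr * grow))
    nl <- as.integer(ceiling(nl * grow))
  }
  stop("mesh_convergence_study: no convergence after ", max_refine,
       " refinements; difference trace: ",
       paste(signif(hist$diff_rel[-1], 3), collapse = ", "), call. = FALSE)
}
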