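#' Solve quasi-static inflation of a thin-slice mesh
#'
#' Incremental Newton solution of the nearly-incompressible anisotropic
#' hyperelastic equilibrium under a follower pressure on the lumen surface
#' and a prescribed axial stretch. The pressure and the axial stretch are
#' ramped together in `n_steps` equal increments with automatic step halving
#' (floor 1/128 of an increment, regrown after successes) on Newton failure
#' and a backtracking line search. Boundary conditions: the
#' z- face is fixed axially, the z+ face gets the prescribed uniform axial
#' displacement (plane sections), and three in-plane point constraints on
#' the outer ring remove the rigid translations and rotation.
#'
#' @param mesh a `thin_slice_mesh`.
#' @param materials a `material_registry` covering every region label in
#'   the mesh.
#' @param pressure_kPa lumen pressure in kPa (>= 0).
#' @param axial_stretch axial stretch applied across the slab (default 1.05).
#' @param n_steps number of equal load increments (>= 1; 5 by default).
#' @param tol relative residual tolerance (default 1e-8, w.r.t. the load
#'   norm).
#' @param max_iter Newton iteration cap per increment.
#' @param init_U optional displacement warm start (n_nodes x 3).
#' @return an object of class `solution_field`: nodal displacements `U`
#'   (mm), nodal Cauchy stress and Green-Lagrange strain (n x 6, averaged
#'   from adjacent element Gauss values), nodal `sigma_max` (kPa) and
#'   `eps_max` principal values, reaction forces, `J` range and convergence
#'   metadata.
#' @export
solve_inflation <- function(mesh, materials, pressure_kPa,
                            axial_stretch = 1.05, n_steps = 5,
                            tol = 1e-8, max_iter = 30, init_U = NULL) {
  stopifnot(inherits(mesh, "thin_slice_mesh"))
  if (pressure_kPa < 0) stop("solve_inflation: pressure must be >= 0",
                             call. = FALSE)
  nn <- nrow(mesh$nodes)
  mats <- material_table(mesh, materials)
  elems0 <- mesh$elems - 1L
  faces0 <- mesh$lumen_faces - 1L

  zmax <- max(mesh$nodes[, 3])
  uz_top <- (axial_stretch - 1) * zmax
  bot <- which(abs(mesh$nodes[, 3]) < 1e-12)
  top <- which(abs(mesh$nodes[, 3] - zmax) < 1e-12)
  fix <- rbind(cbind(3 * (bot - 1L) + 3L, 0),
               cbind(3 * (top - 1L) + 3L, uz_top))
  # in-plane rigid-body constraints: tangential dofs on three outer-ring
  # nodes near 0, 90 and 180 degrees (radial motion stays free)
  ring <- mesh$outer_ring
  pick <- function(ang) ring[which.min(abs(angdiff(mesh$theta, ang)))]
  fix <- rbind(fix,
               cbind(3 * (pick(0) - 1L) + 2L, 0),        # uy at 0 deg
               cbind(3 * (pick(pi) - 1L) + 2L, 0),       # uy at 180 deg
               cbind(3 * (pick(pi / 2) - 1L) + 1L, 0))   # ux at 90 deg
  cdof <- as.integer(fix[, 1])
  cval <- fix[, 2]
  free <- setdiff(seq_len(3L * nn), cdof)

  U <- matrix(0, nn, 3)
  lam <- 0
  dlam <- 1 / n_steps
  dlam_floor <- dlam / 128
  steps <- list()
  dU_pred <- NULL
  dlam_pred <- 1
  total_newton <- 0L

  residual_at <- function(U, lam) {
    fint <- fem_internal_force(mesh$nodes, U, elems0, mats$mat,
                               mats$ecirc, mats$eax)
    fext <- fem_pressure_force(mesh$nodes, U, faces0, lam * pressure_kPa)
    list(R = fint - fext, fext = fext, fint = fint)
  }

  # a warm start from a nearby solved state usually converges at full load
  # in a few iterations; fall back to the incremental ramp if it does not
  if (!is.null(init_U)) {
    U_try <- init_U
    U_try[cbind(((cdof - 1L) %/% 3L) + 1L, ((cdof - 1L) %% 3L) + 1L)] <- cval
    res <- step_newton(mesh, mats, U_try, 1, pressure_kPa, elems0, faces0,
                       free, tol, max_iter, residual_at)
    if (res$ok) {
      U <- res$U
      lam <- 1
      total_newton <- res$iters
      steps[[1L]] <- data.frame(lambda = 1, iters = res$iters,
                                resid = res$resid)
    }
  }

  while (lam < 1 - 1e-12) {
    dlam_try <- min(dlam, 1 - lam)
    lam_t <- lam + dlam_try
    U_try <- U
    if (!is.null(dU_pred)) U_try <- U_try + dU_pred * (dlam_try / dlam_pred)
    U_try[cbind(((cdof - 1L) %/% 3L) + 1L, ((cdof - 1L) %% 3L) + 1L)] <-
      cval * lam_t
    res <- step_newton(mesh, mats, U_try, lam_t, pressure_kPa, elems0,
                       faces0, free, tol, max_iter, residual_at)
    if (res$ok) {
      dU_pred <- res$U - U
      dlam_pred <- dlam_try
      U <- res$U
      lam <- lam_t
      total_newton <- total_newton + res$iters
      steps[[length(steps) + 1L]] <-
        data.frame(lambda = lam, iters = res$iters, resid = res$resid)
      # grow a previously halved increment back toward the nominal size
      dlam <- min(2 * dlam, 1 / n_steps)
    } else {
      dU_pred <- NULL
      dlam <- dlam_try / 2
      if (dlam < dlam_floor)
        stop("solve_inflation: Newton divergence after step halving to ",
             "floor (reached load fraction ", signif(lam, 4), "); trace: ",
             paste(vapply(steps, function(s)
               sprintf("%.3f:%d", s$lambda, s$iters), ""), collapse = " "),
             call. = FALSE)
    }
  }

  fields <- fem_element_fields(mesh$nodes, U, elems0, mats$mat,
                               mats$ecirc, mats$eax)
  nod <- nodal_average(mesh, fields)
  nod <- boundary_ring_recovery(mesh, fields, nod, mats$mat)
  fin <- residual_at(U, 1)
  reactions <- fin$R
  reactions[free] <- 0
  structure(list(
    U = U, stress = nod$stress, strain = nod$strain,
    sigma_max = nod$sigma_max, eps_max = nod$eps_max,
    J_range = range(fields$J_centroid),
    reactions = reactions, f_ext = fin$fext,
    constrained_dofs = cdof,
    pressure_kPa = pressure_kPa, axial_stretch = axial_stretch,
    steps = do.call(rbind, steps), newton_iterations = total_newton),
    class = "solution_field")
}

material_table <- function(mesh, materials) {
  need <- unique(mesh$region)
  miss <- setdiff(need, names(materials))
  if (length(miss))
    stop("solve_inflation: registry lacks material(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  mat <- matrix(0, nrow(mesh$elems), 8)
  for (rg in need) {
    p <- materials[[rg]]
    sel <- mesh$region == rg
    mat[sel, ] <- matrix(c(p$c1, p$c2, p$D1, p$D2, p$K1, p$K2,
                           p$phi * pi / 180, penalty_kappa(p)),
                         sum(sel), 8, byrow = TRUE)
  }
  list(mat = mat, ecirc = mesh$ecirc, eax = mesh$eax)
}

step_newton <- function(mesh, mats, U, lam, pressure_kPa, elems0, faces0,
                        free, tol, max_iter, residual_at) {
  uvec <- function(U) as.numeric(t(U))
  res <- residual_at(U, lam)
  # force scale: the applied load, or (for displacement-driven states such
  # as a pure axial stretch) the internal force level
  ref_at <- function(res) max(sqrt(sum(res$fext^2)),
                              sqrt(sum(res$fint^2)), 1e-6)
  ref <- ref_at(res)
  rn <- sqrt(sum(res$R[free]^2))
  best <- rn
  iters <- 0L
  while (rn > tol * ref) {
    # the residual may spike transiently when the tension-only fiber terms
    # switch between iterations, so only persistent blow-up is divergence
    if (iters >= max_iter || !is.finite(rn) ||
        (iters > 6L && rn > 1e3 * best))
      return(list(ok = FALSE))
    kk <- try({
      ti <- fem_tangent(mesh$nodes, U, elems0, mats$mat,
                        mats$ecirc, mats$eax)
      tp <- fem_pressure_tangent(mesh$nodes, U, faces0,
                                 lam * pressure_kPa)
      Matrix::sparseMatrix(i = c(ti$i, tp$i), j = c(ti$j, tp$j),
                           x = c(ti$x, -tp$x),
                           dims = c(3 * nrow(U), 3 * nrow(U)))
    }, silent = TRUE)
    if (inherits(kk, "try-error")) return(list(ok = FALSE))
    du <- try(as.numeric(Matrix::solve(kk[free, free, drop = FALSE],
                                       -res$R[free])), silent = TRUE)
    if (inherits(du, "try-error") || any(!is.finite(du)))
      return(list(ok = FALSE))
    # backtracking line search: keeps the iteration stable when the
    # tension-only fiber terms switch on/off between iterations
    u0 <- uvec(U)
    alpha <- 1
    repeat {
      u <- u0
      u[free] <- u[free] + alpha * du
      U_new <- matrix(u, ncol = 3, byrow = TRUE)
      res_new <- try(residual_at(U_new, lam), silent = TRUE)
      ok_eval <- !inherits(res_new, "try-error")
      rn_new <- if (ok_eval) sqrt(sum(res_new$R[free]^2)) else Inf
      if ((ok_eval && (rn_new < rn || alpha <= 0.26)) ||
          (!ok_eval && alpha <= 0.06))
        break
      alpha <- alpha / 2
    }
    if (!ok_eval) return(list(ok = FALSE))
    U <- U_new
    res <- res_new
    rn <- rn_new
    ref <- ref_at(res)
    best <- min(best, rn)
    iters <- iters + 1L
  }
  list(ok = TRUE, U = U, iters = iters, resid = rn)
}

# nodal stress/strain: Gauss values extrapolated to element nodes (done in
# the element routine), then averaged over all elements sharing each node;
# principal values as the largest eigenvalue of the symmetric tensors
nodal_average <- function(mesh, fields) {
  nn <- nrow(mesh$nodes)
  cnt <- numeric(nn)
  sacc <- matrix(0, nn, 6)
  eacc <- matrix(0, nn, 6)
  for (a in 1:8) {
    ids <- mesh$elems[, a]
    cnt <- cnt + tabulate(ids, nn)
    cols <- (a - 1L) * 6L + 1:6
    sacc <- sacc + rows_add(fields$stress[, cols, drop = FALSE], ids, nn)
    eacc <- eacc + rows_add(fields$strain[, cols, drop = FALSE], ids, nn)
  }
  sacc <- sacc / cnt
  eacc <- eacc / cnt
  list(stress = sacc, strain = eacc,
       sigma_max = principal_max(sacc),
       eps_max = principal_max(eacc))
}

rows_add <- function(m, ids, n) {
  out <- matrix(0, n, ncol(m))
  agg <- rowsum(m, ids)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# Patch recovery at the lumen and outer surfaces: along each structured
# radial element column, fit a polynomial in the reference radius through
# the element-mean Gauss stresses at the element mid-radii (element means
# are markedly more accurate than individual Gauss values in steep
# near-wall gradients), stopping at the first material change to avoid
# fitting across a stress discontinuity, and evaluate it at the surface
# radius. This restores the surface accuracy that plain
# node-extrapolation averaging loses.
boundary_ring_recovery <- function(mesh, fields, nod, matrows) {
  Nr <- 3L * mesh$n_radial_per_layer
  nray <- mesh$n_rays
  eid <- function(iz, ir, k) ((iz - 1L) * Nr + (ir - 1L)) * nray +
    ((k - 1L) %% nray) + 1L
  ctr <- mesh$centroid
  nrad <- function(ids) {
    pm <- mesh$nodes[ids, 1:2, drop = FALSE]
    sqrt((pm[, 1] - ctr[1])^2 + (pm[, 2] - ctr[2])^2)
  }
  gp_mean <- function(e) {
    sv <- colMeans(matrix(fields$stress_gp[e, ], 8, 6, byrow = TRUE))
    ev <- colMeans(matrix(fields$strain_gp[e, ], 8, 6, byrow = TRUE))
    c(sv, ev)
  }
  recover <- function(side) {
    irs <- if (side == "inner") seq_len(Nr) else rev(seq_len(Nr))
    ring <- if (side == "inner") mesh$inner_ring else mesh$outer_ring
    out <- list()
    for (k in seq_len(nray)) {
      node <- ring[k]
      Rs <- nrad(node)
      # fit each adjacent column independently (their radii nearly
      # coincide, so a joint fit would be ill-conditioned on eccentric
      # slices), then average the two surface predictions
      preds <- NULL
      for (col in c(k - 1L, k)) {
        m0 <- matrows[eid(1L, irs[1], col), ]
        samples <- NULL
        for (ir in irs) {
          e <- eid(1L, ir, col)
          # stop at a material change (stress is discontinuous there)
          if (any(matrows[e, ] != m0) || (!is.null(samples) &&
                                          nrow(samples) >= 3L)) break
          rin <- mean(nrad(mesh$elems[e, c(1, 4, 5, 8)]))
          rout <- mean(nrad(mesh$elems[e, c(2, 3, 6, 7)]))
          samples <- rbind(samples, c((rin + rout) / 2, gp_mean(e)))
        }
        x <- samples[, 1]
        deg <- min(2L, length(unique(round(x, 9))) - 1L)
        if (deg == 0L) {
          preds <- rbind(preds, samples[1, -1])
        } else {
          Xd <- stats::poly(c(x, Rs), degree = deg, raw = TRUE)
          Xfit <- cbind(1, Xd[seq_along(x), , drop = FALSE])
          Xev <- c(1, Xd[length(x) + 1L, ])
          coef <- solve(crossprod(Xfit), crossprod(Xfit, samples[, -1]))
          preds <- rbind(preds, drop(Xev %*% coef))
        }
      }
      val <- colMeans(preds)
      # all z-levels of this surface column share the recovery (prismatic)
      stride <- (Nr + 1L) * nray
      ids <- node + stride * (0:mesh$n_slabs)
      out[[length(out) + 1L]] <- list(ids = ids, val = val)
    }
    out
  }
  for (upd in c(recover("inner"), recover("outer"))) {
    nod$stress[upd$ids, ] <- rep(upd$val[1:6], each = length(upd$ids))
    nod$strain[upd$ids, ] <- rep(upd$val[7:12], each = length(upd$ids))
  }
  nod$sigma_max <- principal_max(nod$stress)
  nod$eps_max <- principal_max(nod$strain)
  nod
}

# largest eigenvalue of symmetric tensors stored as (xx,yy,zz,xy,yz,xz)
# rows; vectorized closed form (Cardano) for symmetric 3x3 matrices
principal_max <- function(m) {
  a11 <- m[, 1]; a22 <- m[, 2]; a33 <- m[, 3]
  a12 <- m[, 4]; a23 <- m[, 5]; a13 <- m[, 6]
  p1 <- a12^2 + a23^2 + a13^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  out <- q
  nz <- p > 1e-300
  b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
  b12 <- a12 / p; b23 <- a23 / p; b13 <- a13 / p
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(1, pmax(-1, detB / 2))
  out[nz] <- (q + 2 * p * cos(acos(r) / 3))[nz]
  out
}
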