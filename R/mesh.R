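#' Build a structured thin-slice mesh from a segmented slice
#'
#' Rays from the lumen centroid through the four boundary contours partition
#' each layer annulus into quadrilateral columns, which are extruded along z
#' into `n_slabs` layers of trilinear hexahedra. Elements whose centroid
#' falls inside a component contour are relabeled lipid/calcification. For
#' single-layer slices (see [merge_to_single_layer()]) the same radial node
#' positions are used (the IEM/EEM markers still guide node placement) so
#' multilayer and single-layer meshes of one slice are geometrically
#' identical; only the region labels differ.
#'
#' @param slice a valid `vessel_slice`.
#' @param thickness slab thickness in mm (default 0.5; pass the axially
#'   pre-shrunk thickness when an axial stretch will be applied).
#' @param n_rays number of angular rays (>= 32).
#' @param n_radial_per_layer radial element count per wall layer.
#' @param n_slabs element count through the slab thickness.
#' @return an object of class `thin_slice_mesh` with fields `nodes` (n x 3,
#'   mm), `elems` (ne x 8, 1-based), `region` (per element), `ecirc`/`eax`
#'   (per-element local frame), `lumen_faces`/`outer_faces` (quad node ids),
#'   `inner_ring`/`outer_ring` (node ids on the z = 0 lumen/outer rings,
#'   ordered by ray), `theta` (ray angles) and the build parameters.
#' @export
build_mesh <- function(slice, thickness = 0.5, n_rays = 48,
                       n_radial_per_layer = 3, n_slabs = 1) {
  stopifnot(inherits(slice, "vessel_slice"))
  if (n_rays < 32) stop("build_mesh: n_rays must be >= 32", call. = FALSE)
  single <- identical(wall_mode(slice), "single")
  ctr <- contour_centroid(slice$lumen)
  theta <- 2 * pi * (seq_len(n_rays) - 1) / n_rays

  rad <- sapply(list(slice$lumen, slice$iem, slice$eem, slice$adv),
                function(cc) ray_radii(cc$points, ctr, theta))
  # rad: n_rays x 4 of boundary radii per ray
  nr <- n_radial_per_layer
  Nr <- 3L * nr
  frac <- seq(0, 1, length.out = nr + 1L)
  radial <- matrix(0, n_rays, Nr + 1L)
  for (k in seq_len(n_rays)) {
    r <- rad[k, ]
    radial[k, ] <- c(r[1] + frac * (r[2] - r[1]),
                     (r[2] + frac * (r[3] - r[2]))[-1],
                     (r[3] + frac * (r[4] - r[3]))[-1])
  }
  band_region <- if (single) rep("wall", Nr) else
    rep(c("intima", "media", "adventitia"), each = nr)

  nz <- n_slabs + 1L
  nid <- function(iz, ir, k) ((iz * (Nr + 1L) + ir) * n_rays +
                                (k - 1L) %% n_rays) + 1L
  n_nodes <- nz * (Nr + 1L) * n_rays
  nodes <- matrix(0, n_nodes, 3)
  zlev <- thickness * (0:n_slabs) / n_slabs
  for (iz in 0:n_slabs) for (ir in 0:Nr) {
    ids <- nid(iz, ir, seq_len(n_rays))
    nodes[ids, 1] <- ctr[1] + radial[, ir + 1L] * cos(theta)
    nodes[ids, 2] <- ctr[2] + radial[, ir + 1L] * sin(theta)
    nodes[ids, 3] <- zlev[iz + 1L]
  }

  ne <- n_slabs * Nr * n_rays
  elems <- matrix(0L, ne, 8)
  region <- character(ne)
  ecirc <- matrix(0, ne, 3); eax <- matrix(0, ne, 3)
  cen <- matrix(0, ne, 2)
  e <- 0L
  for (iz in seq_len(n_slabs)) for (ir in seq_len(Nr)) {
    for (k in seq_len(n_rays)) {
      e <- e + 1L
      elems[e, ] <- c(nid(iz - 1L, ir - 1L, k), nid(iz - 1L, ir, k),
                      nid(iz - 1L, ir, k + 1L), nid(iz - 1L, ir - 1L, k + 1L),
                      nid(iz, ir - 1L, k), nid(iz, ir, k),
                      nid(iz, ir, k + 1L), nid(iz, ir - 1L, k + 1L))
      region[e] <- band_region[ir]
    }
  }
  cen <- cbind(rowMeans(matrix(nodes[t(elems), 1], ncol = 8, byrow = TRUE)),
               rowMeans(matrix(nodes[t(elems), 2], ncol = 8, byrow = TRUE)))
  the <- atan2(cen[, 2] - ctr[2], cen[, 1] - ctr[1])
  ecirc <- cbind(-sin(the), cos(the), rep(0, ne))
  eax <- matrix(rep(c(0, 0, 1), each = ne), ne, 3)

  for (cc in slice$components) {
    inside <- point_in_contour(cen, cc)
    region[inside] <- cc$label
  }

  lumen_faces <- outer_faces <- matrix(0L, n_slabs * n_rays, 4)
  f <- 0L
  for (iz in seq_len(n_slabs)) for (k in seq_len(n_rays)) {
    f <- f + 1L
    lumen_faces[f, ] <- c(nid(iz - 1L, 0L, k), nid(iz - 1L, 0L, k + 1L),
                          nid(iz, 0L, k + 1L), nid(iz, 0L, k))
    # outer surface normal must point away from the wall: reverse order
    outer_faces[f, ] <- c(nid(iz - 1L, Nr, k + 1L), nid(iz - 1L, Nr, k),
                          nid(iz, Nr, k), nid(iz, Nr, k + 1L))
  }

  mesh <- structure(list(
    nodes = nodes, elems = elems, region = region,
    ecirc = ecirc, eax = eax,
    lumen_faces = lumen_faces, outer_faces = outer_faces,
    inner_ring = nid(0L, 0L, seq_len(n_rays)),
    outer_ring = nid(0L, Nr, seq_len(n_rays)),
    theta = theta, centroid = ctr, thickness = thickness,
    n_rays = n_rays, n_radial_per_layer = n_radial_per_layer,
    n_slabs = n_slabs, wall_mode = if (single) "single" else "multi",
    slice_id = slice$slice_id), class = "thin_slice_mesh")
  q <- fem_mesh_quality(mesh$nodes, mesh$elems - 1L)
  if (any(q$min_detJ <= 0))
    stop("build_mesh: mesh contains non-positive Jacobians", call. = FALSE)
  mesh$volume <- q$volume
  mesh
}

# radius at which a ray from ctr at each angle hits the polyline; errors if
# a ray does not cross exactly once (severely non-star-shaped contour).
ray_radii <- function(p, ctr, theta) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  qx <- a[, 1] - ctr[1]; qy <- a[, 2] - ctr[2]
  out <- numeric(length(theta))
  for (k in seq_along(theta)) {
    dx <- cos(theta[k]); dy <- sin(theta[k])
    den <- dx * ey - dy * ex
    ok <- abs(den) > 1e-14
    t <- (qx * ey - qy * ex) / den
    u <- (qx * dy - qy * dx) / den
    # half-open segment with a tolerance so a ray through a shared vertex
    # is counted once (u ~ 1 on one segment, u ~ 0 on the next)
    hit <- ok & t > 0 & u >= -1e-9 & u < 1 - 1e-9
    nh <- sum(hit)
    if (nh != 1L) {
      if (nh == 0L)
        stop("build_mesh: ray misses a contour (geometry not star-shaped ",
             "about the lumen centroid)", call. = FALSE)
      # multiple crossings of a wiggly but star-shaped polyline are tolerated
      # only if the crossing radii agree closely; otherwise fail loudly
      tr <- t[hit]
      if (diff(range(tr)) > 1e-6 * max(tr))
        stop("build_mesh: ray crosses a contour ", nh, " times ",
             "(severely non-star-shaped slice)", call. = FALSE)
    }
    out[k] <- t[hit][1]
  }
  out
}
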