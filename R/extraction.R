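#' Quarter-dividing lumen/out-wall pairing
#'
#' Splits the lumen and out-wall contours into four quarters by angular
#' position about the lumen centroid (boundaries at `anchor_deg`, +90, +180,
#' +270 degrees from the +x axis) and places `n_per_quarter` equal arc-step
#' nodes on each contour within each quarter independently (the piecewise
#' equal-step rule: a longer out-wall quarter gets proportionally wider
#' steps, which avoids pairing distortion where the wall is thick). Nodes
#' are paired by (quarter, within-quarter index).
#'
#' @param lumen,outwall `vessel_contour`s (lumen and ADV of one slice).
#' @param n_per_quarter nodes per quarter per contour (default 25, i.e. 100
#'   nodes per contour).
#' @param anchor_deg angular anchor of the first quarter boundary (default
#'   0, the +x axis; the split is anchor-convention dependent and
#'   configurable).
#' @return list of class `region_node_sets`: `lumen_points` and
#'   `outwall_points` (n x 2, paired row-wise), `quarter` (1-4 per node),
#'   `index` (within-quarter), `angles` (lumen node angles, radians).
#' @export
quarter_divide <- function(lumen, outwall, n_per_quarter = 25,
                           anchor_deg = 0) {
  ctr <- contour_centroid(lumen)
  lp <- quarter_points(lumen, ctr, n_per_quarter, anchor_deg)
  op <- quarter_points(outwall, ctr, n_per_quarter, anchor_deg)
  structure(list(lumen_points = lp$pts, outwall_points = op$pts,
                 quarter = lp$quarter, index = lp$index,
                 angles = atan2(lp$pts[, 2] - ctr[2], lp$pts[, 1] - ctr[1]),
                 centroid = ctr, n_per_quarter = n_per_quarter,
                 anchor_deg = anchor_deg),
            class = "region_node_sets")
}

# equal arc-length steps within each angular quarter of a closed contour
quarter_points <- function(cont, ctr, n_per_quarter, anchor_deg) {
  M <- 2000L
  p <- resample_contour(cont, M)$points
  ang <- atan2(p[, 2] - ctr[2], p[, 1] - ctr[1])
  dang <- diff(c(ang, ang[1]))
  dang <- ifelse(dang > pi, dang - 2 * pi, ifelse(dang < -pi,
                                                  dang + 2 * pi, dang))
  if (any(dang <= 0))
    stop("quarter_divide: contour is not star-shaped about the lumen ",
         "centroid", call. = FALSE)
  aw <- ang[1] + cumsum(c(0, dang[-M]))        # unwrapped, increasing
  seg <- sqrt(rowSums((p[c(2:M, 1L), ] - p)^2))
  s <- cumsum(c(0, seg[-M]))                   # arc length at each vertex
  L <- sum(seg)
  a0 <- anchor_deg * pi / 180
  # first quarter boundary mapped into the contour's unwrapped angle range
  b1 <- aw[1] + ((a0 - aw[1]) %% (2 * pi))
  bnd <- b1 + (0:4) * pi / 2
  # arc positions where the unwrapped angle crosses the quarter boundaries
  # (angle-arc relation extended over two turns so all boundaries resolve)
  aw_ext <- c(aw, aw + 2 * pi, aw[1] + 4 * pi)
  s_ext <- c(s, s + L, 2 * L)
  sb <- stats::approx(aw_ext, s_ext, xout = bnd, ties = "ordered")$y
  pts <- matrix(0, 4L * n_per_quarter, 2)
  quarter <- integer(4L * n_per_quarter)
  index <- integer(4L * n_per_quarter)
  xfun <- stats::approxfun(c(s, L), c(p[, 1], p[1, 1]), ties = "ordered")
  yfun <- stats::approxfun(c(s, L), c(p[, 2], p[1, 2]), ties = "ordered")
  for (q in 1:4) {
    sq <- sb[q] + (sb[q + 1] - sb[q]) * (seq_len(n_per_quarter) - 1L) /
      n_per_quarter
    sq <- sq %% L
    rows <- (q - 1L) * n_per_quarter + seq_len(n_per_quarter)
    pts[rows, ] <- cbind(xfun(sq), yfun(sq))
    quarter[rows] <- q
    index[rows] <- seq_len(n_per_quarter)
  }
  list(pts = pts, quarter = quarter, index = index)
}

#' Identify cap nodes
#'
#' Cap nodes are the lumen nodes whose pairing segment (lumen node to its
#' paired out-wall node) crosses a lipid contour: the tissue between the
#' lumen and the pool at these angles is the fibrous cap. Calcifications do
#' not define a cap. Returns an empty set when the slice has no lipid pool.
#'
#' @param sets a `region_node_sets` from [quarter_divide()].
#' @param slice the `vessel_slice` the sets were built from.
#' @return integer vector of cap node indices (subset of `1:nrow(lumen_points)`).
#' @export
identify_cap_nodes <- function(sets, slice) {
  lipids <- Filter(function(cc) cc$label == "lipid", slice$components)
  if (!length(lipids)) return(integer(0))
  n <- nrow(sets$lumen_points)
  hit <- rep(FALSE, n)
  for (lp in lipids) {
    poly <- lp$points
    for (i in seq_len(n)) {
      if (hit[i]) next
      hit[i] <- segment_hits_polygon(sets$lumen_points[i, ],
                                     sets$outwall_points[i, ], poly)
    }
  }
  which(hit)
}

segment_hits_polygon <- function(a, b, poly) {
  mid <- (a + b) / 2
  if (point_in_contour(rbind(mid), poly)) return(TRUE)
  n <- nrow(poly)
  p3 <- poly
  p4 <- poly[c(2:n, 1L), , drop = FALSE]
  d1 <- (p4[, 1] - p3[, 1]) * (a[2] - p3[, 2]) -
    (p4[, 2] - p3[, 2]) * (a[1] - p3[, 1])
  d2 <- (p4[, 1] - p3[, 1]) * (b[2] - p3[, 2]) -
    (p4[, 2] - p3[, 2]) * (b[1] - p3[, 1])
  d3 <- (b[1] - a[1]) * (p3[, 2] - a[2]) - (b[2] - a[2]) * (p3[, 1] - a[1])
  d4 <- (b[1] - a[1]) * (p4[, 2] - a[2]) - (b[2] - a[2]) * (p4[, 1] - a[1])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Per-patient scalar summaries
#'
#' `patient_max()` and `patient_mean()` reduce the pooled nodal values of
#' one patient (all slices, typically 10 x 100 nodes) to the patient
#' maximum and mean. `relative_difference()` is the multilayer-vs-single
#' percent difference with the single-layer value as base.
#' `cohort_average()` is the across-patient mean and sample standard
#' deviation (n - 1 denominator).
#'
#' @param values numeric vector of nodal values (non-empty).
#' @return a scalar; `cohort_average` returns `c(mean, sd)`.
#' @export
patient_max <- function(values) {
  if (!length(values)) stop("patient_max: empty value set", call. = FALSE)
  max(values)
}

#' @rdname patient_max
#' @export
patient_mean <- function(values) {
  if (!length(values)) stop("patient_mean: empty value set", call. = FALSE)
  mean(values)
}

#' @rdname patient_max
#' @param multi,single paired scalars (multilayer and single-layer model);
#'   `single` must be nonzero.
#' @export
relative_difference <- function(multi, single) {
  if (any(single == 0))
    stop("relative_difference: zero base value", call. = FALSE)
  100 * (multi - single) / single
}

#' @rdname patient_max
#' @param x per-patient scalars, length >= 2.
#' @export
cohort_average <- function(x) {
  if (length(x) < 2L)
    stop("cohort_average: need >= 2 patients for mean and SD", call. = FALSE)
  c(mean = mean(x), sd = stats::sd(x))
}

#' Extract the per-slice nodal stress/strain summaries
#'
#' Samples the solved nodal maximum principal stress and strain at the 100
#' quarter-divide lumen nodes (plaque inner wall) and their 100 paired
#' out-wall nodes, by periodic linear interpolation in angle along the mesh
#' boundary rings, and flags the cap subset.
#'
#' @param solution a `solution_field`.
#' @param mesh the `thin_slice_mesh` it was solved on.
#' @param slice the (pre-shrunk) `vessel_slice` the mesh was built from.
#' @param n_per_quarter nodes per quarter (default 25).
#' @param anchor_deg quarter anchor (default 0).
#' @return list with `plaque_stress`, `plaque_strain`, `outwall_stress`,
#'   `outwall_strain` (length 4*n_per_quarter each), `cap_idx` (indices
#'   into the plaque vectors) and the `region_node_sets` used.
#' @export
extract_slice_values <- function(solution, mesh, slice, n_per_quarter = 25,
                                 anchor_deg = 0) {
  sets <- quarter_divide(slice$lumen, slice$adv, n_per_quarter, anchor_deg)
  cap <- identify_cap_nodes(sets, slice)
  ctr <- mesh$centroid
  qang <- function(pts) atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
  samp <- function(ring, values, pts) {
    interp_periodic(mesh$theta, values[ring], qang(pts))
  }
  list(plaque_stress = samp(mesh$inner_ring, solution$sigma_max,
                            sets$lumen_points),
       plaque_strain = samp(mesh$inner_ring, solution$eps_max,
                            sets$lumen_points),
       outwall_stress = samp(mesh$outer_ring, solution$sigma_max,
                             sets$outwall_points),
       outwall_strain = samp(mesh$outer_ring, solution$eps_max,
                             sets$outwall_points),
       cap_idx = cap, sets = sets)
}

# periodic linear interpolation of ring values given at angles th (uniform,
# increasing from 0) onto arbitrary query angles
interp_periodic <- function(th, v, q) {
  n <- length(th)
  q <- q %% (2 * pi)
  stats::approx(c(th, th[1] + 2 * pi), c(v, v[1]), xout = q,
                ties = "ordered")$y
}
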