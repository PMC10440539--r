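#' Specification for a synthetic segmented-OCT cohort
#'
#' Defines the geometric and sampling ranges used by the synthetic slice
#' generator, which emulates the output of multilayer intravascular OCT
#' segmentation: nested lumen/IEM/EEM/ADV contours with eccentric intimal
#' (plaque) thickening, a lipid pool with a fibrous cap, and optional
#' calcification. Defaults reflect typical coronary dimensions at this
#' imaging scale.
#'
#' @param n_patients number of patients.
#' @param slices_per_patient slices per patient (default 10).
#' @param lumen_radius lumen radius range (mm).
#' @param intima_thickness intima thickness range (mm); the upper end is
#'   reached on the plaque sector, the lower end off-plaque.
#' @param media_thickness media thickness range (mm).
#' @param adventitia_thickness adventitia thickness range (mm).
#' @param eccentricity plaque eccentricity range in `[0, 1]`; 0 gives
#'   concentric circles, 1 the thickest allowed plaque sector.
#' @param lipid_arc_deg lipid pool angular extent range (degrees).
#' @param cap_thickness fibrous cap thickness range (mm); the generator
#'   guarantees lumen-to-lipid distance of at least the range minimum.
#' @param calcification_prob per-slice probability of a calcification.
#' @param pressure_mmHg systolic pressure sampling range (mmHg), or the
#'   string `"reference"` to cycle through the bundled 20-patient systolic
#'   pressures.
#' @param n_points points per generated contour (default 100).
#' @param seed base random seed; generation is deterministic given
#'   `(seed, patient_index, slice_index)`.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20, slices_per_patient = 10,
                        lumen_radius = c(1.0, 2.0),
                        intima_thickness = c(0.05, 0.6),
                        media_thickness = c(0.10, 0.25),
                        adventitia_thickness = c(0.15, 0.35),
                        eccentricity = c(0.45, 1.0),
                        lipid_arc_deg = c(30, 120),
                        cap_thickness = c(0.05, 0.3),
                        calcification_prob = 0.25,
                        pressure_mmHg = c(101, 175),
                        n_points = 100, seed = 1) {
  chk_range <- function(r, nm) {
    if (length(r) != 2L || any(!is.finite(r)) || any(r < 0) || r[1] > r[2])
      stop("cohort_spec: '", nm, "' must be a nonnegative range c(lo, hi)",
           call. = FALSE)
  }
  for (nm in c("lumen_radius", "intima_thickness", "media_thickness",
               "adventitia_thickness", "eccentricity", "lipid_arc_deg",
               "cap_thickness"))
    chk_range(get(nm), nm)
  if (slices_per_patient < 1L) stop("slices_per_patient must be >= 1",
                                    call. = FALSE)
  if (n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 slices_per_patient = as.integer(slices_per_patient),
                 lumen_radius = lumen_radius,
                 intima_thickness = intima_thickness,
                 media_thickness = media_thickness,
                 adventitia_thickness = adventitia_thickness,
                 eccentricity = eccentricity,
                 lipid_arc_deg = lipid_arc_deg,
                 cap_thickness = cap_thickness,
                 calcification_prob = calcification_prob,
                 pressure_mmHg = pressure_mmHg,
                 n_points = as.integer(n_points),
                 seed = seed),
            class = "cohort_spec")
}

# Systolic pressures (mmHg) of the bundled 20-patient reference cohort.
.reference_systolic_mmHg <- c(138, 155, 149, 150, 112, 150, 151, 117, 128,
                              143, 115, 130, 159, 124, 175, 130, 113, 136,
                              141, 101)

# Deterministic per-(patient, slice) seed below 2^31.
slice_seed <- function(seed, patient_index, slice_index) {
  (as.numeric(seed) * 7919 + patient_index * 104729 +
     slice_index * 1299709) %% 2147483647
}

#' Generate one synthetic segmented slice
#'
#' Builds a nested four-contour cross-section with eccentric intimal
#' thickening on a random angular sector, a crescent-shaped lipid pool under
#' a fibrous cap on that sector, and (with configured probability) a small
#' calcification in the media. All `vessel_slice` invariants hold on return;
#' degenerate random draws are retried up to 100 times before erroring.
#'
#' @param spec a [cohort_spec()].
#' @param patient_index,slice_index 1-based indices; together with
#'   `spec$seed` they determine the slice exactly.
#' @return a validated `vessel_slice`.
#' @export
generate_synthetic_slice <- function(spec, patient_index = 1L,
                                     slice_index = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(slice_seed(spec$seed, patient_index, slice_index))
  for (attempt in seq_len(100L)) {
    s <- try(synth_slice_once(spec, patient_index, slice_index),
             silent = TRUE)
    if (!inherits(s, "try-error")) return(s)
  }
  stop("generate_synthetic_slice: no valid geometry after 100 attempts ",
       "(spec ranges cannot produce nested contours): ",
       attr(s, "condition")$message, call. = FALSE)
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

synth_slice_once <- function(spec, patient_index, slice_index) {
  n <- spec$n_points
  th <- 2 * pi * (seq_len(n) - 1) / n
  ecc <- runif1(spec$eccentricity)

  r0 <- runif1(spec$lumen_radius)
  oval <- 0.05 * ecc * stats::runif(1)
  ph <- stats::runif(1, 0, 2 * pi)
  r_lum <- r0 * (1 + oval * cos(2 * (th - ph)))

  # eccentric intimal thickening on a random plaque sector
  t_base <- stats::runif(1, spec$intima_thickness[1],
                         min(spec$intima_thickness[2],
                             spec$intima_thickness[1] + 0.07))
  th0 <- stats::runif(1, 0, 2 * pi)
  arc_pl <- stats::runif(1, 100, 170) * pi / 180   # plaque sector width
  dth <- angdiff(th, th0)
  bump <- ifelse(abs(dth) < arc_pl / 2, cos(pi * dth / arc_pl)^2, 0)
  t_pl <- ecc * (spec$intima_thickness[2] - t_base)
  t_int <- t_base + t_pl * bump

  wob <- function() 1 + 0.08 * ecc * stats::runif(1) *
    cos(th - stats::runif(1, 0, 2 * pi))
  t_med <- runif1(spec$media_thickness) * wob()
  t_adv <- runif1(spec$adventitia_thickness) * wob()

  r_iem <- r_lum + t_int
  r_eem <- r_iem + t_med
  r_adv <- r_eem + t_adv

  ring <- function(r, lb) contour(cbind(r * cos(th), r * sin(th)), lb,
                                  validate = FALSE)
  lumen <- ring(r_lum, "lumen")
  comps <- list()

  # lipid pool with fibrous cap, centered on the plaque sector
  cap_min <- spec$cap_thickness[1]
  cap <- runif1(spec$cap_thickness)
  arc_lip <- min(runif1(spec$lipid_arc_deg) * pi / 180, 0.8 * arc_pl)
  margin <- 0.02
  lip_ok <- function(a) {
    d <- angdiff(th, th0)
    sel <- abs(d) <= a / 2
    all((r_iem - margin - (r_lum + cap))[sel] > 0.02)
  }
  while (arc_lip > 10 * pi / 180 && !lip_ok(arc_lip)) arc_lip <- 0.9 * arc_lip
  if (arc_lip > 5 * pi / 180 && lip_ok(arc_lip)) {
    m <- 40L
    a_lip <- th0 + seq(-arc_lip / 2, arc_lip / 2, length.out = m)
    rl_in <- stats::approx(c(th - 2 * pi, th, th + 2 * pi),
                           rep(r_lum, 3), xout = a_lip)$y + cap
    rl_out <- stats::approx(c(th - 2 * pi, th, th + 2 * pi),
                            rep(r_iem, 3), xout = a_lip)$y - margin
    # taper the pool thickness to zero at both ends for a crescent shape
    taper <- sin(seq(0, pi, length.out = m))^0.75
    rl_out <- rl_in + pmax(rl_out - rl_in, 0) * pmax(taper, 0.02)
    pts <- rbind(cbind(rl_in * cos(a_lip), rl_in * sin(a_lip)),
                 cbind(rl_out * cos(rev(a_lip)), rl_out * sin(rev(a_lip))))
    comps <- c(comps, list(contour(pts, "lipid", validate = FALSE)))
  }

  # optional calcification: small ellipse inside the media, off the pool
  if (stats::runif(1) < spec$calcification_prob) {
    a_c <- th0 + sample(c(-1, 1), 1) * (arc_pl / 2 + stats::runif(1, 0.3, 0.9))
    r_mid <- stats::approx(c(th - 2 * pi, th, th + 2 * pi),
                           rep((r_iem + r_eem) / 2, 3), xout = a_c)$y
    t_here <- stats::approx(c(th - 2 * pi, th, th + 2 * pi),
                            rep(t_med, 3), xout = a_c)$y
    sa <- stats::runif(1, 0.06, 0.12)          # tangential semi-axis (rad)
    sb <- 0.30 * t_here                        # radial semi-axis (mm)
    tt <- seq(0, 2 * pi, length.out = 25L)[-25L]
    rr <- r_mid + sb * sin(tt)
    aa <- a_c + sa * cos(tt)
    comps <- c(comps, list(contour(cbind(rr * cos(aa), rr * sin(aa)),
                                   "calcification", validate = FALSE)))
  }

  s <- vessel_slice(lumen, ring(r_iem, "IEM"), ring(r_eem, "EEM"),
                    ring(r_adv, "ADV"), components = comps,
                    slice_id = sprintf("P%02d_S%02d", patient_index,
                                       slice_index))
  # recenter on the lumen centroid
  ctr <- contour_centroid(s$lumen)
  s <- shift_slice(s, -ctr)
  # enforce the configured minimum cap thickness geometrically
  lip <- Filter(function(cc) cc$label == "lipid", s$components)
  if (length(lip) &&
      polyline_min_dist(s$lumen$points, lip[[1]]$points) < cap_min)
    stop("cap thinner than configured minimum")
  validate_slice(s)
  s
}

angdiff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

shift_slice <- function(s, dxy) {
  mv <- function(cc) { cc$points <- sweep(cc$points, 2, -dxy, "-"); cc }
  s$lumen <- mv(s$lumen); s$iem <- mv(s$iem)
  s$eem <- mv(s$eem); s$adv <- mv(s$adv)
  s$components <- lapply(s$components, mv)
  s
}

# min distance between two closed polylines (vertex-to-segment, both ways)
polyline_min_dist <- function(p, q) {
  min(pts_to_polyline(p, q), pts_to_polyline(q, p))
}

pts_to_polyline <- function(pts, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1L), , drop = FALSE]
  dmin <- Inf
  for (i in seq_len(n)) {
    ab <- b[i, ] - a[i, ]
    L2 <- sum(ab^2)
    t <- if (L2 == 0) rep(0, nrow(pts)) else
      pmin(1, pmax(0, ((pts[, 1] - a[i, 1]) * ab[1] +
                         (pts[, 2] - a[i, 2]) * ab[2]) / L2))
    dx <- pts[, 1] - (a[i, 1] + t * ab[1])
    dy <- pts[, 2] - (a[i, 2] + t * ab[2])
    dmin <- min(dmin, min(dx^2 + dy^2))
  }
  sqrt(dmin)
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `vessel_cohort`; one element per patient with
#'   `patient_id`, `pressure_mmHg` and `slices` (a list of `vessel_slice`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  patients <- vector("list", spec$n_patients)
  for (p in seq_len(spec$n_patients)) {
    if (identical(spec$pressure_mmHg, "reference")) {
      pr <- .reference_systolic_mmHg[(p - 1L) %%
                                       length(.reference_systolic_mmHg) + 1L]
    } else {
      set.seed(slice_seed(spec$seed, p, 0L))
      pr <- round(runif1(spec$pressure_mmHg))
    }
    slices <- lapply(seq_len(spec$slices_per_patient), function(k)
      generate_synthetic_slice(spec, p, k))
    patients[[p]] <- list(patient_id = sprintf("P%02d", p),
                          pressure_mmHg = pr, slices = slices)
  }
  structure(patients, class = "vessel_cohort", seed = spec$seed)
}

#' Cohort manifest
#'
#' @param cohort a `vessel_cohort`.
#' @return data frame with one row per slice: patient, slice, pressure (mmHg).
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p)
    data.frame(patient = p$patient_id,
               slice = vapply(p$slices, function(s) s$slice_id, ""),
               pressure_mmHg = p$pressure_mmHg)))
}
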