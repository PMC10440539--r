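# geometry and registry helpers shared across test files

circle_contour <- function(r, label, n = 100, phase = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n + phase
  contour(cbind(r * cos(th), r * sin(th)), label)
}

# four concentric rings; the standard well-behaved test slice
concentric_slice <- function(radii = c(1.5, 1.8, 2.0, 2.3), n = 100,
                             components = list()) {
  vessel_slice(circle_contour(radii[1], "lumen", n),
               circle_contour(radii[2], "IEM", n),
               circle_contour(radii[3], "EEM", n),
               circle_contour(radii[4], "ADV", n),
               components = components, slice_id = "concentric")
}

# annular-sector lipid pool between radii r1 < r2 over [a0, a1] (radians)
sector_lipid <- function(r1, r2, a0, a1, m = 30) {
  a <- seq(a0, a1, length.out = m)
  pts <- rbind(cbind(r1 * cos(a), r1 * sin(a)),
               cbind(r2 * cos(rev(a)), r2 * sin(rev(a))))
  contour(pts, "lipid")
}

# registry with one material copied to every region (layer degeneracy)
uniform_registry <- function(base = default_materials()$media) {
  reg <- default_materials()
  for (nm in names(reg)) {
    reg[[nm]] <- base
    reg[[nm]]$name <- nm
  }
  reg
}

# stiff isotropic single-material wall for small-strain checks
stiff_wall_registry <- function(c1 = 200) {
  reg <- default_materials()
  reg$wall <- material_params(c1, 0, c1 / 2, 2, name = "wall")
  reg
}

# winding-number point-in-polygon oracle (independent of pracma)
winding_inside <- function(pts, poly) {
  n <- nrow(poly)
  apply(pts, 1, function(p) {
    v <- sweep(poly, 2, p)
    a <- atan2(v[, 2], v[, 1])
    d <- diff(c(a, a[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi   # |winding| ~ 2*pi inside, ~0 outside
  })
}

hoop_stress_at <- function(solution, mesh, node) {
  v <- solution$stress[node, ]
  S <- matrix(c(v[1], v[4], v[6], v[4], v[2], v[5], v[6], v[5], v[3]), 3, 3)
  xy <- mesh$nodes[node, 1:2] - mesh$centroid
  r <- sqrt(sum(xy^2))
  e <- c(-xy[2], xy[1], 0) / r
  drop(e %*% S %*% e)
}
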