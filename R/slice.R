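#' Assemble a segmented vessel cross-section
#'
#' Bundles the four boundary contours of a multilayer segmentation (lumen,
#' internal elastic membrane, external elastic membrane,
#' adventitia-periadventitia interface) plus any plaque component contours
#' (lipid pools, calcifications) into one validated slice object.
#'
#' @param lumen,iem,eem,adv `vessel_contour` objects with matching labels.
#' @param components list of component `vessel_contour`s (may be empty).
#' @param slice_id identifier string.
#' @param frame_spacing slice spacing context in mm (informational).
#' @param validate run [validate_slice()] (default `TRUE`).
#' @return an object of class `vessel_slice`.
#' @export
vessel_slice <- function(lumen, iem, eem, adv, components = list(),
                         slice_id = "slice", frame_spacing = 0.5,
                         validate = TRUE) {
  for (nm in c("lumen", "iem", "eem", "adv")) {
    obj <- get(nm)
    if (!inherits(obj, "vessel_contour"))
      stop("'", nm, "' must be a vessel_contour", call. = FALSE)
  }
  if (lumen$label != "lumen" || iem$label != "IEM" ||
      eem$label != "EEM" || adv$label != "ADV")
    stop("boundary contour labels must be lumen/IEM/EEM/ADV in order",
         call. = FALSE)
  if (!all(vapply(components, inherits, TRUE, "vessel_contour")))
    stop("'components' must be a list of vessel_contour objects", call. = FALSE)
  bad <- vapply(components, function(cc)
    !(cc$label %in% .vesselfem_component_labels), TRUE)
  if (any(bad))
    stop("component labels must be lipid or calcification", call. = FALSE)
  s <- structure(list(lumen = lumen, iem = iem, eem = eem, adv = adv,
                      components = components,
                      slice_id = as.character(slice_id),
                      frame_spacing = frame_spacing),
                 class = "vessel_slice")
  if (validate) validate_slice(s)
  s
}

#' Validate a vessel slice
#'
#' Checks each contour's own invariants plus the slice-level invariants:
#' strict nesting lumen < IEM < EEM < ADV (every vertex of the inner contour
#' inside the outer one), each component between lumen and ADV, and pairwise
#' non-overlap of components. Validation is idempotent: it never modifies the
#' slice.
#'
#' @param s a `vessel_slice`.
#' @return the slice, invisibly.
#' @export
validate_slice <- function(s) {
  stopifnot(inherits(s, "vessel_slice"))
  ring <- list(s$lumen, s$iem, s$eem, s$adv)
  for (cc in c(ring, s$components)) validate_contour(cc)
  nm <- c("lumen", "IEM", "EEM", "ADV")
  for (k in 1:3) {
    inner <- ring[[k]]; outer <- ring[[k + 1]]
    if (!all(point_in_contour(inner$points, outer)))
      stop("nesting violation: contour '", nm[k],
           "' is not strictly inside '", nm[k + 1], "'", call. = FALSE)
  }
  for (cc in s$components) {
    if (!all(point_in_contour(cc$points, s$adv)))
      stop("nesting violation: component '", cc$label,
           "' extends outside 'ADV'", call. = FALSE)
    if (any(point_in_contour(cc$points, s$lumen)))
      stop("nesting violation: component '", cc$label,
           "' overlaps the lumen", call. = FALSE)
  }
  nc <- length(s$components)
  if (nc > 1L) {
    for (a in seq_len(nc - 1L)) for (b in (a + 1L):nc) {
      ca <- s$components[[a]]; cb <- s$components[[b]]
      if (any(point_in_contour(ca$points, cb)) ||
          any(point_in_contour(cb$points, ca)))
        stop("components ", a, " and ", b, " overlap", call. = FALSE)
    }
  }
  invisible(s)
}

#' Collapse a multilayer slice to a single-layer wall
#'
#' Returns a slice whose wall spans lumen to ADV as one material region
#' ("three layers combined"). The IEM and EEM contours are retained as
#' passive geometric markers by default (so that meshes built from the merged
#' slice and the multilayer slice share node positions), or dropped when
#' `keep_markers = FALSE`, in which case they are replaced by interpolated
#' placeholders at 1/3 and 2/3 wall depth. Component contours pass through
#' unchanged.
#'
#' @param s a valid multilayer `vessel_slice`.
#' @param keep_markers keep the original IEM/EEM contours as markers.
#' @return a `vessel_slice` with attribute `wall_mode = "single"`.
#' @export
merge_to_single_layer <- function(s, keep_markers = TRUE) {
  validate_slice(s)
  out <- s
  if (!keep_markers) {
    # placeholders at fractional wall depth along matched ray directions
    ctr <- contour_centroid(s$lumen)
    n <- nrow(s$lumen$points)
    lum <- resample_contour(s$lumen, n)$points
    adv <- resample_contour(s$adv, n)$points
    out$iem <- contour(lum + (adv - lum) / 3, "IEM", validate = FALSE)
    out$eem <- contour(lum + 2 * (adv - lum) / 3, "EEM", validate = FALSE)
  }
  attr(out, "wall_mode") <- "single"
  out
}

#' Wall mode of a slice
#'
#' @param s a `vessel_slice`.
#' @return `"single"` for slices produced by [merge_to_single_layer()],
#'   otherwise `"multi"`.
#' @export
wall_mode <- function(s) {
  wm <- attr(s, "wall_mode")
  if (is.null(wm)) "multi" else wm
}
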