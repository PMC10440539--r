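#' Read a segmented slice from a contour file
#'
#' JSON schema: an object `{slice_id, units:"mm", contours:[{label,
#' points:[[x,y],...]}]}` with exactly one contour for each of lumen, IEM,
#' EEM, ADV and any number of lipid/calcification contours. A CSV variant is
#' accepted when `path` ends in `.csv`: one row per point with columns
#' `slice_id,label,idx,x,y`.
#'
#' @param path path to a `.json` or `.csv` contour file.
#' @return a validated `vessel_slice`.
#' @export
read_contours <- function(path) {
  if (!file.exists(path))
    stop("read_contours: file not found: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    return(read_contours_csv(path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyMatrix = TRUE),
                  error = function(e)
                    stop("read_contours: malformed JSON in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  for (field in c("slice_id", "contours"))
    if (is.null(doc[[field]]))
      stop("read_contours: missing field '", field, "'", call. = FALSE)
  if (!is.null(doc$units) && !identical(doc$units, "mm"))
    stop("read_contours: field 'units' must be \"mm\"", call. = FALSE)
  cts <- doc$contours
  if (is.data.frame(cts)) {
    cts <- lapply(seq_len(nrow(cts)), function(i)
      list(label = cts$label[i], points = cts$points[[i]]))
  }
  labs <- vapply(cts, function(cc) {
    if (is.null(cc$label)) stop("read_contours: contour missing field 'label'",
                                call. = FALSE)
    cc$label
  }, "")
  parsed <- lapply(cts, function(cc) {
    if (is.null(cc$points))
      stop("read_contours: contour '", cc$label,
           "' missing field 'points'", call. = FALSE)
    contour(cc$points, cc$label, validate = FALSE)
  })
  build_slice_from_contours(parsed, labs, doc$slice_id,
                            frame_spacing = doc$frame_spacing %||% 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_contours_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slice_id", "label", "idx", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_contours: CSV missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  sid <- unique(df$slice_id)
  if (length(sid) != 1L)
    stop("read_contours: CSV must contain exactly one slice_id", call. = FALSE)
  keys <- unique(df$label)
  parsed <- lapply(keys, function(lb) {
    sub <- df[df$label == lb, , drop = FALSE]
    sub <- sub[order(sub$idx), , drop = FALSE]
    contour(cbind(sub$x, sub$y), lb, validate = FALSE)
  })
  build_slice_from_contours(parsed, keys, sid)
}

build_slice_from_contours <- function(parsed, labs, slice_id,
                                      frame_spacing = 0.5) {
  pick1 <- function(lb) {
    hit <- which(labs == lb)
    if (length(hit) != 1L)
      stop("read_contours: need exactly one '", lb, "' contour, found ",
           length(hit), call. = FALSE)
    parsed[[hit]]
  }
  comps <- parsed[labs %in% .vesselfem_component_labels]
  vessel_slice(pick1("lumen"), pick1("IEM"), pick1("EEM"), pick1("ADV"),
               components = comps, slice_id = slice_id,
               frame_spacing = frame_spacing)
}

#' Write a segmented slice to a contour file
#'
#' Deterministic serialization (fixed contour order, 12 significant digits)
#' so that write/read round-trips are stable to 1e-9 mm and identical inputs
#' produce byte-identical files. Format chosen by extension as in
#' [read_contours()].
#'
#' @param s a valid `vessel_slice`.
#' @param path output path (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_contours <- function(s, path) {
  validate_slice(s)
  cts <- c(list(s$lumen, s$iem, s$eem, s$adv), s$components)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- do.call(rbind, lapply(cts, function(cc)
      data.frame(slice_id = s$slice_id, label = cc$label,
                 idx = seq_len(nrow(cc$points)),
                 x = cc$points[, 1], y = cc$points[, 2])))
    utils::write.csv(format(rows, digits = 12, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  doc <- list(
    slice_id = jsonlite::unbox(s$slice_id),
    units = jsonlite::unbox("mm"),
    frame_spacing = jsonlite::unbox(s$frame_spacing),
    contours = lapply(cts, function(cc)
      list(label = jsonlite::unbox(cc$label), points = cc$points)))
  txt <- jsonlite::toJSON(doc, digits = I(12), pretty = FALSE)
  writeLines(txt, path)
  invisible(path)
}
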