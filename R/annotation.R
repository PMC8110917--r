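#' Vessel polyline annotation
#'
#' An ordered chain of 2D points (pixel units, sub-pixel precision allowed)
#' with a class label. Polylines are both the manual annotation primitive
#' (an expert traces each vessel's linear extent) and the output of the
#' reconstruction pipeline. Labels distinguish true vessels from
#' out-of-plane objects (too blurry to classify confidently, mostly in
#' phase contrast) and debris (undigested tissue pieces that resemble
#' vessels).
#'
#' @param points numeric matrix with 2 columns `(x, y)` and at least 2
#'   rows; no two consecutive points may coincide.
#' @param label one of `"vessel"`, `"out_of_plane"`, `"debris"`.
#' @return An object of class `polyline`.
#' @export
polyline <- function(points, label = "vessel") {
  assert_label(label)
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L || nrow(points) < 2L)
    stop_validation("points must be a numeric matrix with 2 columns and >= 2 rows")
  if (!all(is.finite(points)))
    stop_validation("polyline points must be finite")
  d <- diff(points)
  if (any(rowSums(d^2) == 0))
    stop_validation("no two consecutive polyline points may be identical")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, label = label), class = "polyline")
}

#' @export
print.polyline <- function(x, ...) {
  cat(sprintf("<polyline %s> %d points, length %.2f px\n",
              x$label, nrow(x$points), polyline_length(x)))
  invisible(x)
}

#' Set of polyline annotations for one image
#'
#' @param image_id non-empty image identifier the polylines belong to.
#' @param polylines list of [polyline] objects; may be empty (an image with
#'   no vessels).
#' @param scale_um_per_px pixel size carried for serialization.
#' @param author free-text author tag.
#' @param created creation timestamp string.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, polylines = list(), scale_um_per_px = 1,
                           author = "synthetic",
                           created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  if (!is.character(image_id) || length(image_id) != 1L || !nzchar(image_id))
    stop_validation("image_id must be a non-empty string")
  if (!is.list(polylines) ||
      !all(vapply(polylines, inherits, TRUE, what = "polyline")))
    stop_validation("polylines must be a list of polyline objects")
  assert_scalar_number(scale_um_per_px, "scale_um_per_px", lower = 0,
                       strict_lower = TRUE)
  structure(
    list(image_id = image_id, polylines = polylines,
         scale_um_per_px = scale_um_per_px, author = author, created = created),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  labs <- vapply(x$polylines, `[[`, "", "label")
  cat(sprintf("<annotation_set '%s'> %d polylines (%s)\n", x$image_id,
              length(x$polylines),
              paste(names(table(labs)), table(labs), sep = ":", collapse = ", ")))
  invisible(x)
}

#' Arc length of a polyline in pixels
#'
#' Sum of the Euclidean lengths of consecutive segments; invariant under
#' translation and under reversal of point order.
#'
#' @param p a [polyline].
#' @return Non-negative length in pixel units.
#' @export
polyline_length <- function(p) {
  stopifnot(inherits(p, "polyline"))
  d <- diff(p$points)
  sum(sqrt(rowSums(d^2)))
}

# Points at given arc-length positions along a polyline (linear
# interpolation within segments). Positions are clamped to [0, L].
arc_point <- function(p, s) {
  pts <- p$points
  seg <- diff(pts)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  L <- cum[length(cum)]
  s <- pmin(pmax(s, 0), L)
  out <- matrix(NA_real_, length(s), 2)
  for (k in seq_along(s)) {
    i <- findInterval(s[k], cum, rightmost.closed = TRUE)
    i <- min(i, length(seg_len))
    t <- if (seg_len[i] > 0) (s[k] - cum[i]) / seg_len[i] else 0
    out[k, ] <- pts[i, ] + t * seg[i, ]
  }
  out
}

#' Overlapping square training regions along a polyline
#'
#' Samples box centers along the arc length of the polyline at a fixed
#' stride, always including both endpoints, and emits one axis-aligned
#' square detection box per sample carrying the polyline's label. This is
#' how a single traced vessel is turned into the many overlapping
#' rectangular input regions an object detector trains on: a stride
#' smaller than the box side guarantees consecutive regions overlap, so
#' the union of boxes covers the whole trace. Boxes near the image border
#' keep their nominal center (clipping, when needed, is a rendering
#' concern), preserving the regular arc sampling at edges.
#'
#' @param p a [polyline].
#' @param box_size side of the square boxes in pixels (>= 2).
#' @param stride arc-length sampling interval in pixels; must be smaller
#'   than `box_size` so consecutive boxes overlap.
#' @param confidence confidence assigned to every generated box.
#' @param image_id image identifier for the resulting [detection_set].
#' @return A [detection_set] with `floor(L / stride) + 1` boxes when the
#'   stride divides the arc length `L` evenly, else `floor(L / stride) + 2`
#'   (the regular samples plus the final endpoint).
#' @export
boxes_from_polyline <- function(p, box_size = 32, stride = box_size / 2,
                                confidence = 1, image_id = "image") {
  stopifnot(inherits(p, "polyline"))
  assert_scalar_number(box_size, "box_size", lower = 2)
  assert_scalar_number(stride, "stride", lower = 0, strict_lower = TRUE)
  if (stride >= box_size)
    stop_validation("stride (", stride, ") must be < box_size (", box_size,
                    "): regions would not overlap")
  L <- polyline_length(p)
  s <- seq(0, L, by = stride)
  if (s[length(s)] < L) s <- c(s, L)
  centers <- arc_point(p, s)
  detection_set(
    image_id = image_id,
    boxes = data.frame(
      cx = centers[, 1], cy = centers[, 2],
      w = box_size, h = box_size,
      confidence = confidence, label = p$label,
      stringsAsFactors = FALSE
    )
  )
}

polyline_to_list <- function(p) {
  list(label = p$label,
       points = lapply(seq_len(nrow(p$points)),
                       function(i) unname(p$points[i, ])))
}

#' Write annotations to JSON
#'
#' The interchange schema is
#' `{"image_id", "scale_um_per_px", "author", "created", "polylines":
#' [{"label", "points": [[x, y], ...]}]}` and is used for ground truth,
#' manual annotations, and reconstruction output alike. Coordinates are
#' written at full double precision so a write/read round trip reproduces
#' points exactly.
#'
#' @param set an [annotation_set].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  obj <- list(
    image_id = set$image_id,
    scale_um_per_px = set$scale_um_per_px,
    author = set$author,
    created = set$created,
    polylines = lapply(set$polylines, polyline_to_list)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read annotations from JSON
#'
#' @param path JSON file in the schema written by [write_annotations()].
#' @return An [annotation_set].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    stop_io("cannot read annotations: no such file: ", path)
  obj <- jsonlite::read_json(path)
  if (is.null(obj$image_id))
    stop_validation("annotation file ", path, " lacks image_id")
  polys <- lapply(obj$polylines, function(pl) {
    lab <- pl$label
    if (is.null(lab) || !(lab %in% VESSEL_LABELS))
      stop_validation("unknown polyline label '", lab, "'; allowed labels: ",
                      paste(VESSEL_LABELS, collapse = ", "))
    pts <- do.call(rbind, lapply(pl$points, function(q) as.numeric(unlist(q))))
    polyline(pts, lab)
  })
  annotation_set(
    image_id = obj$image_id,
    polylines = polys,
    scale_um_per_px = if (is.null(obj$scale_um_per_px)) 1 else obj$scale_um_per_px,
    author = if (is.null(obj$author)) "" else obj$author,
    created = if (is.null(obj$created)) "" else obj$created
  )
}
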