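#' Set of detection boxes for one image
#'
#' Axis-aligned rectangular detections with confidence and class label —
#' the interface between any object-detection backend and the polyline
#' reconstruction stage. Boxes are stored as a data frame with columns
#' `cx, cy` (real pixel center), `w, h` (positive extents), `confidence`
#' in `[0, 1]` and `label`.
#'
#' @param image_id identifier of the image the boxes belong to.
#' @param boxes data frame with columns `cx, cy, w, h, confidence, label`;
#'   may have zero rows.
#' @return An object of class `detection_set`.
#' @export
detection_set <- function(image_id, boxes = empty_boxes()) {
  if (!is.character(image_id) || length(image_id) != 1L || !nzchar(image_id))
    stop_validation("image_id must be a non-empty string")
  boxes <- as.data.frame(boxes)
  need <- c("cx", "cy", "w", "h", "confidence", "label")
  if (!all(need %in% names(boxes)))
    stop_validation("boxes must have columns: ", paste(need, collapse = ", "))
  boxes <- boxes[, need]
  if (nrow(boxes) > 0) {
    bad <- which(!(boxes$w > 0 & boxes$h > 0))
    if (length(bad))
      stop_validation("box ", bad[1], " has non-positive extent (w=",
                      boxes$w[bad[1]], ", h=", boxes$h[bad[1]], ")")
    bad <- which(boxes$confidence < 0 | boxes$confidence > 1)
    if (length(bad))
      stop_validation("box ", bad[1], " has confidence outside [0, 1]: ",
                      boxes$confidence[bad[1]])
    if (!all(boxes$label %in% VESSEL_LABELS))
      stop_validation("box labels must be one of: ",
                      paste(VESSEL_LABELS, collapse = ", "))
    if (!all(is.finite(boxes$cx)) || !all(is.finite(boxes$cy)))
      stop_validation("box centers must be finite")
  }
  rownames(boxes) <- NULL
  structure(list(image_id = image_id, boxes = boxes), class = "detection_set")
}

empty_boxes <- function() {
  data.frame(cx = numeric(0), cy = numeric(0), w = numeric(0), h = numeric(0),
             confidence = numeric(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set '%s'> %d boxes\n", x$image_id, nrow(x$boxes)))
  invisible(x)
}

# Concatenate detection sets for the same image.
bind_detections <- function(sets) {
  sets <- Filter(Negate(is.null), sets)
  if (length(sets) == 0L) stop_validation("no detection sets to bind")
  ids <- unique(vapply(sets, `[[`, "", "image_id"))
  if (length(ids) != 1L)
    stop_validation("cannot bind detections from different images: ",
                    paste(ids, collapse = ", "))
  detection_set(ids, do.call(rbind, lapply(sets, `[[`, "boxes")))
}

#' Ground-truth-driven oracle detector
#'
#' Stands in for a trained object detector in tests and synthetic
#' experiments: it emits the training regions of every vessel polyline in
#' `truth`, then corrupts them with controllable detector-like noise —
#' isotropic Gaussian jitter of box centers, independent box drop-out
#' (missed detections), and uniformly placed spurious boxes (false
#' positives, labeled `vessel` with low confidence). Deterministic given
#' `seed`.
#'
#' @param truth an [annotation_set]; only polylines labeled `vessel`
#'   generate boxes.
#' @param box_size,stride region geometry passed to [boxes_from_polyline()].
#' @param jitter_sd standard deviation (px) of center perturbation.
#' @param miss_rate probability in `[0, 1)` that each box is dropped.
#' @param false_positive_count number of spurious boxes to add.
#' @param field_px `(width, height)` extent in which false positives are
#'   placed; required when `false_positive_count > 0`.
#' @param seed RNG seed.
#' @return A [detection_set].
#' @export
oracle_detect <- function(truth, box_size = 32, stride = box_size / 2,
                          jitter_sd = 0, miss_rate = 0,
                          false_positive_count = 0, field_px = NULL,
                          seed = 1) {
  stopifnot(inherits(truth, "annotation_set"))
  assert_scalar_number(jitter_sd, "jitter_sd", lower = 0)
  assert_scalar_number(miss_rate, "miss_rate", lower = 0, upper = 1,
                       strict_upper = TRUE)
  assert_scalar_number(false_positive_count, "false_positive_count", lower = 0)
  vessels <- Filter(function(p) p$label == "vessel", truth$polylines)
  base <- lapply(vessels, boxes_from_polyline, box_size = box_size,
                 stride = stride, image_id = truth$image_id)
  boxes <- if (length(base)) do.call(rbind, lapply(base, `[[`, "boxes"))
  else empty_boxes()
  with_seed(seed, {
    n <- nrow(boxes)
    if (n > 0 && jitter_sd > 0) {
      boxes$cx <- boxes$cx + stats::rnorm(n, 0, jitter_sd)
      boxes$cy <- boxes$cy + stats::rnorm(n, 0, jitter_sd)
    }
    if (n > 0 && miss_rate > 0)
      boxes <- boxes[stats::runif(n) >= miss_rate, , drop = FALSE]
    if (false_positive_count > 0) {
      if (is.null(field_px))
        stop_validation("field_px is required when false_positive_count > 0")
      fp <- data.frame(
        cx = stats::runif(false_positive_count, 0, field_px[1] - 1),
        cy = stats::runif(false_positive_count, 0, field_px[2] - 1),
        w = box_size, h = box_size, confidence = 0.5, label = "vessel",
        stringsAsFactors = FALSE
      )
      boxes <- rbind(boxes, fp)
    }
  })
  detection_set(truth$image_id, boxes)
}

#' Classical intensity-based detector
#'
#' A trained-weight-free detection backend: thresholds the (equalized)
#' image at an intensity quantile, discards connected components outside a
#' size window, skeletonizes each surviving component, and samples square
#' boxes along the skeleton paths at a fixed stride. Box confidence is the
#' mean normalized intensity inside the box. Useful as a fully
#' deterministic backend on bright-on-dark images.
#'
#' @param image an [image2d] (preprocessed; equalization is applied here).
#' @param threshold_quantile foreground intensity quantile in (0, 1).
#' @param min_component_px,max_component_px component area window in pixels.
#' @param box_size,stride region geometry.
#' @return A [detection_set] (empty when no foreground survives).
#' @export
classical_detect <- function(image, threshold_quantile = 0.9,
                             min_component_px = 50, max_component_px = 50000,
                             box_size = 32, stride = box_size / 2) {
  stopifnot(inherits(image, "image2d"))
  assert_scalar_number(threshold_quantile, "threshold_quantile", lower = 0,
                       upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  mask <- foreground_mask(image, threshold_quantile)
  mask <- filter_components(mask, min_component_px, max_component_px)
  if (!any(mask)) {
    message("classical_detect: empty foreground, returning no boxes")
    return(detection_set(image$id))
  }
  skel <- skeletonize(mask)
  paths <- skeleton_paths(skel)
  if (length(paths) == 0L) return(detection_set(image$id))
  sets <- lapply(paths, function(p)
    boxes_from_polyline(p, box_size = box_size, stride = stride,
                        image_id = image$id))
  out <- bind_detections(sets)
  out$boxes$confidence <- box_mean_intensity(image, out$boxes)
  out
}

# Foreground mask: pixels strictly above the given intensity quantile of
# the equalized image.
foreground_mask <- function(image, quantile) {
  eq <- suppressWarnings(equalize_histogram(image))
  thr <- stats::quantile(eq$pixels, quantile, names = FALSE)
  eq$pixels > thr
}

# Drop connected components (4-connectivity) with area outside [lo, hi].
filter_components <- function(mask, lo, hi) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= lo & sizes <= hi)
  matrix(lab %in% keep, nrow = nrow(mask))
}

# Decompose a skeleton mask into polylines: skeleton pixels become graph
# nodes, 8-adjacent pixels are linked, cycles are removed by minimum
# spanning tree, and the forest is split into maximal paths.
skeleton_paths <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(list())
  nodes <- data.frame(id = seq_len(nrow(idx)),
                      x = idx[, 2] - 1, y = idx[, 1] - 1)
  key <- matrix(0L, nrow(skel), ncol(skel))
  key[idx] <- nodes$id
  offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    r2 <- idx[, 1] + offs[k, 1]; c2 <- idx[, 2] + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nrow(skel) & c2 >= 1 & c2 <= ncol(skel)
    j <- integer(nrow(idx)); j[ok] <- key[cbind(r2[ok], c2[ok])]
    hit <- which(j > 0)
    if (length(hit))
      edges[[length(edges) + 1L]] <- data.frame(
        i = nodes$id[hit], j = j[hit],
        weight = sqrt(sum(offs[k, ]^2)))
  }
  if (length(edges) == 0L) return(list())
  g <- vessel_graph(nodes, do.call(rbind, edges))
  graph_to_polylines(remove_cycles(g))
}

box_mean_intensity <- function(image, boxes) {
  px <- image$pixels
  rng <- range(px)
  norm <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1]) else px * 0
  vapply(seq_len(nrow(boxes)), function(i) {
    c0 <- max(1, round(boxes$cx[i] - boxes$w[i] / 2) + 1)
    c1 <- min(ncol(px), round(boxes$cx[i] + boxes$w[i] / 2) + 1)
    r0 <- max(1, round(boxes$cy[i] - boxes$h[i] / 2) + 1)
    r1 <- min(nrow(px), round(boxes$cy[i] + boxes$h[i] / 2) + 1)
    if (r0 > r1 || c0 > c1) return(0)
    mean(norm[r0:r1, c0:c1])
  }, numeric(1))
}

#' Pixel-based vessel length measurement
#'
#' The classical comparison protocol: improve contrast by histogram
#' equalization, threshold at an intensity quantile, filter out connected
#' components that are too small (isolated cells) or too large (tissue
#' clumps), skeletonize the remaining foreground, and report total
#' skeleton length with the diagonal step weighted sqrt(2). Because the
#' method is purely morphological it cannot distinguish vessels from other
#' elongated objects of similar width, and so tends to overestimate vessel
#' length on noisy scenes.
#'
#' @param image an [image2d].
#' @param threshold_quantile foreground intensity quantile in (0, 1).
#' @param min_object_px,max_object_px component area window in pixels.
#' @return Total skeleton length in pixels (0 for a blank image).
#' @export
pixel_based_length <- function(image, threshold_quantile = 0.9,
                               min_object_px = 50, max_object_px = 50000) {
  stopifnot(inherits(image, "image2d"))
  assert_scalar_number(threshold_quantile, "threshold_quantile", lower = 0,
                       upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  mask <- foreground_mask(image, threshold_quantile)
  mask <- filter_components(mask, min_object_px, max_object_px)
  if (!any(mask)) return(0)
  skeleton_length(skeletonize(mask))
}

#' Run a detection backend with contract validation
#'
#' Dispatches to any function implementing the detector contract
#' `image -> detection_set` and validates the result against the
#' [detection_set] type invariants, so a misbehaving backend (zero-width
#' box, confidence outside `[0, 1]`, wrong image id) fails loudly at the
#' interface rather than deep inside reconstruction.
#'
#' @param image an [image2d].
#' @param backend a function taking the image as first argument, or one of
#'   the backend names `"classical"`.
#' @param ... parameters forwarded to the backend.
#' @return The backend's [detection_set].
#' @export
detect <- function(image, backend = "classical", ...) {
  stopifnot(inherits(image, "image2d"))
  fn <- if (is.function(backend)) backend
  else switch(backend,
              classical = classical_detect,
              stop_validation("unknown backend '", backend, "'"))
  out <- fn(image, ...)
  if (!inherits(out, "detection_set")) {
    # re-validate plain list output through the constructor
    out <- tryCatch(detection_set(out$image_id, out$boxes),
                    error = function(e)
                      stop_validation("backend violated the detector contract: ",
                                      conditionMessage(e)))
  } else {
    # constructor re-check catches backends that mutated fields in place
    out <- detection_set(out$image_id, out$boxes)
  }
  if (out$image_id != image$id)
    stop_validation("backend returned detections for image '", out$image_id,
                    "' but was given image '", image$id, "'")
  out
}

#' Write detections to JSON
#'
#' Schema: `{"image_id": str, "boxes": [{"cx","cy","w","h","confidence",
#' "label"}]}` — the on-disk handoff that lets external detectors plug
#' into reconstruction.
#'
#' @param set a [detection_set].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(set, path) {
  stopifnot(inherits(set, "detection_set"))
  boxes <- lapply(seq_len(nrow(set$boxes)), function(i)
    as.list(set$boxes[i, ]))
  jsonlite::write_json(list(image_id = set$image_id, boxes = boxes), path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read detections from JSON
#'
#' @param path JSON file in the schema written by [write_detections()].
#' @return A [detection_set].
#' @export
read_detections <- function(path) {
  if (!file.exists(path))
    stop_io("cannot read detections: no such file: ", path)
  obj <- jsonlite::read_json(path)
  if (length(obj$boxes) == 0L) return(detection_set(obj$image_id))
  boxes <- do.call(rbind, lapply(obj$boxes, function(b)
    data.frame(cx = b$cx, cy = b$cy, w = b$w, h = b$h,
               confidence = b$confidence, label = b$label,
               stringsAsFactors = FALSE)))
  detection_set(obj$image_id, boxes)
}
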