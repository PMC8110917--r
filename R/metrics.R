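#' Total vessel length in micrometres
#'
#' Sums the arc lengths of polylines labeled `vessel` and converts to
#' micrometres; `out_of_plane` and `debris` polylines are excluded — they
#' are annotated precisely so that they do not contribute to vessel
#' length.
#'
#' @param polylines list of [polyline] objects.
#' @param scale_um_per_px positive micrometres per pixel.
#' @return Total vessel length in micrometres (0 for an empty list).
#' @export
total_vessel_length <- function(polylines, scale_um_per_px) {
  assert_scalar_number(scale_um_per_px, "scale_um_per_px", lower = 0,
                       strict_lower = TRUE)
  if (length(polylines) == 0L) return(0)
  stopifnot(all(vapply(polylines, inherits, TRUE, what = "polyline")))
  vessels <- Filter(function(p) p$label == "vessel", polylines)
  if (length(vessels) == 0L) return(0)
  sum(vapply(vessels, polyline_length, numeric(1))) * scale_um_per_px
}

#' Vessel length density of one image
#'
#' Divides total vessel length by the physical image area. Density is
#' reported in micrometres of vessel per square millimetre of field — the
#' primary readout of an angiogenesis assay.
#'
#' @param total_length_um non-negative total vessel length in micrometres.
#' @param image the measured [image2d] (provides field area via its pixel
#'   dimensions and scale).
#' @param method which measurement produced the length: `"annotated"`
#'   (manual tracing), `"reconstructed"` (detection-box reconstruction), or
#'   `"pixel_based"` (threshold/skeletonize).
#' @return A `length_density_result`: list with `image_id`,
#'   `total_length_um`, `area_mm2`, `density_um_per_mm2`, `method`.
#' @export
length_density <- function(total_length_um, image,
                           method = c("annotated", "reconstructed", "pixel_based")) {
  method <- match.arg(method)
  stopifnot(inherits(image, "image2d"))
  assert_scalar_number(total_length_um, "total_length_um", lower = 0)
  area_um2 <- image_width(image) * image_height(image) * image$scale_um_per_px^2
  if (area_um2 <= 0) stop_validation("image area must be positive")
  area_mm2 <- area_um2 / 1e6
  structure(
    list(image_id = image$id, total_length_um = total_length_um,
         area_mm2 = area_mm2,
         density_um_per_mm2 = total_length_um / area_mm2,
         method = method),
    class = "length_density_result"
  )
}

#' Average image densities into a sample density
#'
#' One biological sample is imaged several times (conventionally 4 fields)
#' and the per-image densities are averaged to the sample value. A warning
#' is emitted when the image count differs from 4; mixing measurement
#' methods within one sample is an error.
#'
#' @param image_results list of `length_density_result` objects for one
#'   sample, all with the same `method`.
#' @return Mean density in micrometres per square millimetre.
#' @export
sample_density <- function(image_results) {
  if (length(image_results) < 1L)
    stop_validation("at least one image result is required")
  stopifnot(all(vapply(image_results, inherits, TRUE,
                       what = "length_density_result")))
  methods <- unique(vapply(image_results, `[[`, "", "method"))
  if (length(methods) != 1L)
    stop_validation("all image results must share one method; got: ",
                    paste(methods, collapse = ", "))
  if (length(image_results) != 4L)
    warning("sample averaged over ", length(image_results),
            " images (convention is 4 images per sample)")
  mean(vapply(image_results, `[[`, numeric(1), "density_um_per_mm2"))
}

#' Summarize sample densities within an experimental group
#'
#' @param group_id group identifier.
#' @param sample_means numeric vector of per-sample densities.
#' @return A `group_result`: list with `group_id`, `sample_means`, `mean`
#'   and the sample standard deviation `sd` (denominator n - 1; `NA` for a
#'   single sample).
#' @export
group_summary <- function(group_id, sample_means) {
  if (!is.numeric(sample_means) || length(sample_means) < 1L)
    stop_validation("sample_means must be a non-empty numeric vector")
  structure(
    list(group_id = as.character(group_id), sample_means = sample_means,
         mean = mean(sample_means), sd = stats::sd(sample_means)),
    class = "group_result"
  )
}

#' Percent error of a measured length against a reference
#'
#' `|reference - measured| / reference * 100`, with the manually annotated
#' length as reference. Scale-invariant: rescaling both lengths by any
#' positive factor leaves it unchanged.
#'
#' @param reference_length positive reference (manually annotated) length
#'   or density.
#' @param measured_length non-negative measured length or density.
#' @return Non-negative percent error.
#' @export
percent_error <- function(reference_length, measured_length) {
  assert_scalar_number(reference_length, "reference_length", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(measured_length, "measured_length", lower = 0)
  abs(reference_length - measured_length) / reference_length * 100
}

#' Percent accuracy from percent error
#'
#' `100 - percent_error` when the error does not exceed 100; a percent
#' error above 100 means the measurement is off by more than the reference
#' itself and accuracy is reported as `NA` rather than a negative number.
#'
#' @param pe non-negative percent error.
#' @return Accuracy in `[0, 100]`, or `NA` when `pe > 100`.
#' @export
percent_accuracy <- function(pe) {
  assert_scalar_number(pe, "pe", lower = 0)
  if (pe > 100) NA_real_ else 100 - pe
}

#' Group-level accuracy report
#'
#' Compares group-mean densities of a measurement method against the
#' group-mean reference (annotated) densities. The comparison is made on
#' group means — not per image — matching how assay accuracy is reported
#' per experimental group.
#'
#' @param group_id group identifier.
#' @param reference_mean positive group-mean reference density.
#' @param measured_mean non-negative group-mean measured density.
#' @return An `accuracy_report`: list with `group_id`, `percent_error`,
#'   `percent_accuracy` (NA when error exceeds 100).
#' @export
accuracy_report <- function(group_id, reference_mean, measured_mean) {
  pe <- percent_error(reference_mean, measured_mean)
  structure(
    list(group_id = as.character(group_id), percent_error = pe,
         percent_accuracy = percent_accuracy(pe)),
    class = "accuracy_report"
  )
}

#' Aggregate accuracy reports
#'
#' Mean accuracy over groups. `NA` accuracies (groups whose percent error
#' exceeded 100) propagate: the aggregate is `NA` whenever any group is
#' `NA`, and the number of such excluded groups is reported alongside.
#'
#' @param reports list of `accuracy_report` objects.
#' @return List with `mean_accuracy` (possibly `NA`) and `n_na` (count of
#'   NA groups).
#' @export
aggregate_accuracy <- function(reports) {
  if (length(reports) == 0L)
    stop_validation("at least one accuracy report is required")
  stopifnot(all(vapply(reports, inherits, TRUE, what = "accuracy_report")))
  acc <- vapply(reports, `[[`, numeric(1), "percent_accuracy")
  list(mean_accuracy = if (anyNA(acc)) NA_real_ else mean(acc),
       n_na = sum(is.na(acc)))
}

#' Per-image percent error (diagnostic)
#'
#' Convenience diagnostic comparing a single image's measured density to
#' its annotated reference. Note that reported assay accuracy is defined
#' on group-mean densities (see [accuracy_report()]); this per-image
#' variant exists for debugging reconstruction quality only.
#'
#' @param reference_density positive per-image reference density.
#' @param measured_density non-negative per-image measured density.
#' @return Non-negative percent error.
#' @export
image_percent_error <- function(reference_density, measured_density) {
  percent_error(reference_density, measured_density)
}
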