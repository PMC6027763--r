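#' Threshold specification
#'
#' The measurement procedure relies on "adequate thresholding" whose exact
#' values are an analyst choice; a threshold is therefore specified either
#' as a fixed intensity or as Otsu's method computed on the image at hand.
#'
#' For `"otsu"`, an optional `floor` guards against the known failure of
#' Otsu's criterion on marker-negative images: when no signal class
#' exists the between-class optimum lands inside the noise, so a batch
#' pipeline that must process negative control sections with the same
#' parameters as diseased sections takes `max(otsu, floor)`.
#'
#' @param method `"otsu"` or `"fixed"`.
#' @param value Fixed intensity threshold; required iff `method = "fixed"`.
#' @param floor Minimum threshold applied under `"otsu"` (default 0, i.e.
#'   plain Otsu).
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(method = c("otsu", "fixed"), value = NULL,
                           floor = 0) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value) || !is.numeric(value) || length(value) != 1L)
      stop("a fixed threshold_spec requires a single numeric `value`")
  } else if (!is.null(value)) {
    stop("`value` is only meaningful for method = \"fixed\"")
  }
  if (!is.numeric(floor) || length(floor) != 1L || floor < 0)
    stop("`floor` must be a single non-negative number")
  structure(list(method = method, value = value, floor = floor),
            class = "threshold_spec")
}

#' Resolve a threshold spec against an image
#'
#' Otsu's threshold is computed with [EBImage::otsu()] on a 256-bin
#' histogram over the full bit range.
#'
#' @param spec A [threshold_spec].
#' @param img A [channel_image].
#' @return A single numeric intensity threshold.
#' @export
resolve_threshold <- function(spec, img) {
  stopifnot(inherits(spec, "threshold_spec"), is_channel_image(img))
  maxval <- 2^img$bit_depth - 1
  if (spec$method == "fixed") {
    if (spec$value < 0 || spec$value > maxval)
      stop("fixed threshold ", spec$value, " outside the ", img$bit_depth,
           "-bit range [0, ", maxval, "]")
    return(spec$value)
  }
  max(EBImage::otsu(EBImage::Image(img$pixels / maxval),
                    range = c(0, 1), levels = 256) * maxval,
      spec$floor)
}

#' Segmentation parameters for one marker
#'
#' Bundles every tunable of the measurement procedure for a single marker:
#' background correction scale, autofluorescence masking, edge enhancement,
#' detection threshold, and the size and shape restrictions applied to
#' candidate objects. All numeric values are configuration, not constants:
#' the procedure they parameterise is fixed, the values are calibrated per
#' marker and logged with every run.
#'
#' @param marker_name Marker label carried into measurement records.
#' @param background_sigma_um Gaussian lowpass scale (um) for background
#'   estimation. Should be well above the largest expected object diameter
#'   (>= 5x is a good rule) so that objects are not flattened.
#' @param af_threshold [threshold_spec] applied to the autofluorescence
#'   channel to build the exclusion mask.
#' @param af_dilation_px Number of 3x3 dilation passes applied to the
#'   autofluorescence mask; suppresses sub-threshold halo rims around
#'   lipofuscin granules.
#' @param edge_strength High-boost edge-enhancement gain; 0 disables
#'   enhancement (identity).
#' @param edge_sigma_um Scale (um) of the small lowpass inside the edge
#'   enhancement.
#' @param signal_threshold [threshold_spec] for object detection on the
#'   enhanced image.
#' @param min_area_um2,max_area_um2 Retained-object area bounds in um^2.
#' @param roundness_range Closed interval within `[0, 1]` of admissible
#'   roundness `4*pi*area/perimeter^2` (1 = disc, small = elongated).
#'   The default `[0, 1]` keeps thin neuropil threads.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(marker_name = "ptau",
                       background_sigma_um = 50,
                       af_threshold = threshold_spec("fixed", 15000),
                       af_dilation_px = 1L,
                       edge_strength = 1,
                       edge_sigma_um = 1,
                       signal_threshold = threshold_spec("otsu",
                                                         floor = 8000),
                       min_area_um2 = 5,
                       max_area_um2 = 1e4,
                       roundness_range = c(0, 1)) {
  if (background_sigma_um <= 0) stop("`background_sigma_um` must be > 0")
  if (edge_strength < 0) stop("`edge_strength` must be >= 0")
  if (edge_sigma_um <= 0) stop("`edge_sigma_um` must be > 0")
  if (af_dilation_px < 0) stop("`af_dilation_px` must be >= 0")
  if (min_area_um2 <= 0 || max_area_um2 <= 0 || min_area_um2 >= max_area_um2)
    stop("need 0 < min_area_um2 < max_area_um2")
  if (length(roundness_range) != 2L || roundness_range[1] > roundness_range[2] ||
      roundness_range[1] < 0 || roundness_range[2] > 1)
    stop("`roundness_range` must be an interval within [0, 1]")
  stopifnot(inherits(af_threshold, "threshold_spec"),
            inherits(signal_threshold, "threshold_spec"))
  structure(
    list(marker_name = marker_name,
         background_sigma_um = background_sigma_um,
         af_threshold = af_threshold,
         af_dilation_px = as.integer(af_dilation_px),
         edge_strength = edge_strength,
         edge_sigma_um = edge_sigma_um,
         signal_threshold = signal_threshold,
         min_area_um2 = min_area_um2,
         max_area_um2 = max_area_um2,
         roundness_range = roundness_range),
    class = "seg_params"
  )
}

#' Default plaque-core segmentation parameters
#'
#' Plaque cores are detected on the ThioflavinS channel by thresholding
#' plus a size restriction only (no edge enhancement): cores are large and
#' intensely labeled, tangles only weakly, so a fixed threshold combined
#' with a generous minimum area separates the two classes.
#'
#' @param min_area_um2 Minimum plaque-core area (um^2); the size cutoff
#'   that excludes tangles.
#' @param threshold [threshold_spec] on the ThioS channel.
#' @return A [seg_params] object for the `"ThioS"` marker.
#' @export
plaque_params <- function(min_area_um2 = 200,
                          threshold = threshold_spec("fixed", 15000)) {
  seg_params(marker_name = "ThioS",
             signal_threshold = threshold,
             edge_strength = 0,
             min_area_um2 = min_area_um2,
             max_area_um2 = 1e5 - 1,  # effectively unbounded above
             roundness_range = c(0, 1))
}
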