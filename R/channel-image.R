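#' Single-channel intensity image
#'
#' The atomic unit every filter in the pipeline operates on: one 2D
#' grayscale raster with its channel role and physical pixel size attached.
#'
#' @param pixels Numeric matrix of non-negative intensities. Rows run down
#'   the image (y), columns run rightward (x).
#' @param role One of `"signal"` (the immunofluorescent marker),
#'   `"autofluorescence"` (unlabeled channel capturing lipofuscin and other
#'   autofluorescent material), `"nuclear"` (counterstain) or `"thios"`
#'   (ThioflavinS).
#' @param pixel_size_um Physical edge length of one pixel in micrometres.
#' @param bit_depth Sensor bit depth, 8 or 16. Intensities must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, role, pixel_size_um, bit_depth = 16L) {
  role <- match.arg(role, c("signal", "autofluorescence", "nuclear", "thios"))
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  maxval <- 2^bit_depth - 1
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > maxval)
    stop("intensities must lie within [0, ", maxval, "] for ", bit_depth,
         "-bit images")
  structure(
    list(pixels = pixels, role = role,
         pixel_size_um = as.numeric(pixel_size_um),
         bit_depth = as.integer(bit_depth)),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> role=%s  %d x %d px  %.3g um/px  %d-bit\n",
              x$role, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$bit_depth))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_channel_image <- function(x) inherits(x, "channel_image")

#' Replace the pixel raster of a channel image, keeping its metadata
#' @noRd
with_pixels <- function(img, pixels) {
  img$pixels <- pixels
  img
}

#' Maximum-intensity projection of a z-stack
#'
#' Sections are captured at several z-levels and reduced to a single 2D
#' image by per-pixel maximum before any quantification.
#'
#' @param stack A list of [channel_image] objects at distinct z-levels,
#'   all with the same dimensions, role and pixel size.
#' @return A single [channel_image]: the per-pixel maximum across planes.
#' @export
project_stack <- function(stack) {
  if (is_channel_image(stack)) return(stack)
  if (!is.list(stack) || length(stack) == 0L)
    stop("empty image stack: no z-planes to project")
  if (!all(vapply(stack, is_channel_image, logical(1))))
    stop("`stack` must be a list of channel_image objects")
  dims <- vapply(stack, function(p) dim(p$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all z-planes must share the same dimensions")
  if (length(unique(vapply(stack, `[[`, character(1), "role"))) != 1L)
    stop("all z-planes must share the same channel role")
  out <- stack[[1L]]
  if (length(stack) > 1L)
    out$pixels <- Reduce(pmax, lapply(stack, `[[`, "pixels"))
  out
}
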