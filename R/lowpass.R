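# Separable Gaussian lowpass as two dense matrix products.
#
# For background estimation the kernel scale (e.g. sigma = 100 px for a
# 50 um scale at 0.5 um/px) is comparable to the image itself, so the
# filter is applied exactly as K_row %*% X %*% t(K_col) with truncated,
# row-renormalized 1-D Gaussian kernels. Renormalization at the borders is
# equivalent to normalized convolution (weights that fall off the image
# are dropped and the remainder rescaled), which keeps a constant image
# exactly constant -- the property the background-correction contract
# relies on.

.kernel_cache <- new.env(parent = emptyenv())

gauss_weight_matrix <- function(n, sigma_px) {
  key <- paste0(n, "_", signif(sigma_px, 10))
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  d2 <- outer(seq_len(n), seq_len(n), function(i, j) (i - j)^2)
  K <- exp(-d2 / (2 * sigma_px^2))
  K <- K / rowSums(K)
  if (length(ls(.kernel_cache)) < 32L) .kernel_cache[[key]] <- K
  K
}

#' Gaussian lowpass of an intensity matrix
#' @param pixels Numeric matrix.
#' @param sigma_px Gaussian standard deviation in pixels.
#' @return Matrix of the same shape.
#' @noRd
gaussian_lowpass <- function(pixels, sigma_px) {
  if (sigma_px <= 0) stop("`sigma_px` must be > 0")
  Kr <- gauss_weight_matrix(nrow(pixels), sigma_px)
  Kc <- gauss_weight_matrix(ncol(pixels), sigma_px)
  Kr %*% pixels %*% t(Kc)
}

#' Lowpass background correction
#'
#' Estimates the smooth background (uneven illumination, diffuse
#' out-of-focus light) as a large-scale Gaussian lowpass of the image and
#' subtracts it, clipping at zero. A constant image maps to the zero
#' image; the mean of the output never exceeds the mean of the input.
#'
#' @param img A [channel_image].
#' @param background_sigma_um Lowpass scale in micrometres. Recommended to
#'   be at least 5x the largest expected object diameter so that real
#'   objects survive with their prominence nearly intact.
#' @return The background-corrected [channel_image].
#' @export
correct_background <- function(img, background_sigma_um = 50) {
  stopifnot(is_channel_image(img))
  if (!is.numeric(background_sigma_um) || background_sigma_um <= 0)
    stop("`background_sigma_um` must be > 0")
  sigma_px <- background_sigma_um / img$pixel_size_um
  bg <- gaussian_lowpass(img$pixels, sigma_px)
  with_pixels(img, pmax(img$pixels - bg, 0))
}

#' High-boost edge enhancement
#'
#' Sharpens object boundaries to facilitate threshold-based detection:
#' `img + strength * (img - lowpass(img, edge_sigma_um))`, clipped to the
#' bit range. Strength 0 is the identity; a constant image is unchanged
#' for any strength.
#'
#' @param img A [channel_image].
#' @param edge_strength Gain `>= 0` on the highpass residual.
#' @param edge_sigma_um Scale (um) of the small lowpass; defaults to 1 um.
#' @return The enhanced [channel_image].
#' @export
edge_enhance <- function(img, edge_strength, edge_sigma_um = 1) {
  stopifnot(is_channel_image(img))
  if (!is.numeric(edge_strength) || edge_strength < 0)
    stop("`edge_strength` must be >= 0")
  if (edge_strength == 0) return(img)
  low <- gaussian_lowpass(img$pixels, edge_sigma_um / img$pixel_size_um)
  maxval <- 2^img$bit_depth - 1
  out <- img$pixels + edge_strength * (img$pixels - low)
  with_pixels(img, pmin(pmax(out, 0), maxval))
}

#' Autofluorescence exclusion mask
#'
#' Objects in the unlabeled autofluorescence channel (mostly lipofuscin
#' and erythrocytes) are detected by thresholding, and the resulting mask
#' -- optionally dilated to swallow sub-threshold halo rims -- is later
#' subtracted from the marker channel.
#'
#' @param af_img A [channel_image] with role `"autofluorescence"`.
#' @param spec A [threshold_spec]; pixels `>=` the resolved threshold are
#'   masked.
#' @param dilation_px Number of 3x3 (8-neighbourhood) dilation passes.
#' @return A logical matrix, `TRUE` where autofluorescent.
#' @export
autofluorescence_mask <- function(af_img, spec = threshold_spec("fixed", 15000),
                                  dilation_px = 1L) {
  stopifnot(is_channel_image(af_img))
  if (af_img$role != "autofluorescence")
    stop("`af_img` must have role \"autofluorescence\", got \"",
         af_img$role, "\"")
  if (dilation_px < 0) stop("`dilation_px` must be >= 0")
  thr <- resolve_threshold(spec, af_img)
  mask <- af_img$pixels >= thr
  if (dilation_px > 0 && any(mask)) {
    m <- mask * 1
    brush <- EBImage::makeBrush(3L, shape = "box")
    for (i in seq_len(dilation_px)) m <- EBImage::dilate(m, brush)
    mask <- m > 0
  }
  mask
}

#' Subtract a binary mask from an image
#'
#' Pixels under the mask are set to zero; all others are untouched. The
#' masked pixels remain part of the measured region of interest (the
#' denominator of percent immunoreactive area is the full image).
#'
#' @param img A [channel_image].
#' @param mask Logical matrix of the same shape.
#' @return The masked [channel_image].
#' @export
subtract_mask <- function(img, mask) {
  stopifnot(is_channel_image(img))
  if (!identical(dim(mask), dim(img$pixels)))
    stop("mask dimensions ", paste(dim(mask), collapse = "x"),
         " do not match image dimensions ",
         paste(dim(img$pixels), collapse = "x"))
  px <- img$pixels
  px[mask] <- 0
  with_pixels(img, px)
}
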