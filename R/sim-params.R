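#' Parameters of the synthetic section generator
#'
#' Describes one simulated multi-channel fluorescence section: field size,
#' pixel size, per-class object counts and size ranges, channel
#' intensities, illumination gradient and the sensor noise model. Object
#' size defaults are implementer choices consistent with cortical tau
#' pathology (flame-shaped tangles tens of um across, thin neuropil
#' threads, large plaque cores, small lipofuscin granules); they are
#' configuration, not facts, and can be overridden per study.
#'
#' @param image_size_px Integer pair (rows, cols).
#' @param pixel_size_um Pixel edge in micrometres.
#' @param n_tangles,n_threads,n_plaques,n_lipofuscin,n_nuclei Object
#'   counts used for any class whose burden target is `NA` in the
#'   [stage_burden_profile()].
#' @param tangle_diameter_um Range of tangle major-axis diameters.
#' @param plaque_diameter_um Range of plaque-core diameters.
#' @param lipofuscin_diameter_um Range of granule diameters.
#' @param thread_length_um,thread_width_um Neuropil-thread geometry ranges.
#' @param nucleus_diameter_um Range of nuclear diameters.
#' @param signal_intensity Peak intensity of marker-positive objects
#'   (16-bit scale).
#' @param af_intensity Intensity of autofluorescent (lipofuscin) granules;
#'   granules carry this intensity in every channel, which is their
#'   defining property.
#' @param background_level Diffuse background intensity.
#' @param gradient_amplitude Illumination gradient amplitude as a fraction
#'   of `background_level`.
#' @param poisson_scale Photons per intensity unit for shot noise
#'   (`0` disables); smaller values mean noisier images.
#' @param gaussian_sd Additive read-noise standard deviation.
#' @param tangle_thios_brightness_factor Tangle brightness in the ThioS
#'   channel relative to plaque cores, in (0, 1): tangles bind ThioS only
#'   weakly.
#' @return An object of class `section_sim_params`.
#' @export
section_sim_params <- function(image_size_px = c(256L, 256L),
                               pixel_size_um = 0.5,
                               n_tangles = 8L, n_threads = 12L,
                               n_plaques = 2L, n_lipofuscin = 40L,
                               n_nuclei = 30L,
                               tangle_diameter_um = c(15, 30),
                               plaque_diameter_um = c(30, 80),
                               lipofuscin_diameter_um = c(1, 5),
                               thread_length_um = c(10, 40),
                               thread_width_um = c(1, 2),
                               nucleus_diameter_um = c(6, 10),
                               signal_intensity = 30000,
                               af_intensity = 30000,
                               background_level = 2000,
                               gradient_amplitude = 0.3,
                               poisson_scale = 0.05,
                               gaussian_sd = 100,
                               tangle_thios_brightness_factor = 0.3) {
  image_size_px <- as.integer(image_size_px)
  if (length(image_size_px) != 2L || any(image_size_px <= 0))
    stop("`image_size_px` must be two positive integers")
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0")
  counts <- c(n_tangles, n_threads, n_plaques, n_lipofuscin, n_nuclei)
  if (any(counts < 0)) stop("object counts must be >= 0")
  for (rng in list(tangle_diameter_um, plaque_diameter_um,
                   lipofuscin_diameter_um, thread_length_um,
                   thread_width_um, nucleus_diameter_um)) {
    if (length(rng) != 2L || any(rng <= 0) || rng[1] > rng[2])
      stop("size ranges must be positive with min <= max")
  }
  if (poisson_scale < 0 || gaussian_sd < 0)
    stop("noise parameters must be >= 0")
  if (tangle_thios_brightness_factor <= 0 ||
      tangle_thios_brightness_factor >= 1)
    stop("`tangle_thios_brightness_factor` must be in (0, 1)")
  structure(
    list(image_size_px = image_size_px, pixel_size_um = pixel_size_um,
         n_tangles = as.integer(n_tangles), n_threads = as.integer(n_threads),
         n_plaques = as.integer(n_plaques),
         n_lipofuscin = as.integer(n_lipofuscin),
         n_nuclei = as.integer(n_nuclei),
         tangle_diameter_um = tangle_diameter_um,
         plaque_diameter_um = plaque_diameter_um,
         lipofuscin_diameter_um = lipofuscin_diameter_um,
         thread_length_um = thread_length_um,
         thread_width_um = thread_width_um,
         nucleus_diameter_um = nucleus_diameter_um,
         signal_intensity = signal_intensity, af_intensity = af_intensity,
         background_level = background_level,
         gradient_amplitude = gradient_amplitude,
         poisson_scale = poisson_scale, gaussian_sd = gaussian_sd,
         tangle_thios_brightness_factor = tangle_thios_brightness_factor),
    class = "section_sim_params"
  )
}

#' Per-class burden targets for one disease-stage group
#'
#' Target area fractions per object class. A target of `NA` means "place
#' the fixed count from the [section_sim_params()]"; a numeric target
#' makes the generator place objects until the realized ground-truth
#' fraction approaches the target. Summed numeric targets must not exceed
#' 0.5 -- objects must not tile the section.
#'
#' @param group Group label, conventionally one of `"control"`, `"I_II"`,
#'   `"III_IV"`, `"V_VI"`.
#' @param tangle,thread,plaque,lipofuscin,nucleus Target area fractions in
#'   `[0, 1]` or `NA`.
#' @return An object of class `stage_burden_profile`.
#' @export
stage_burden_profile <- function(group = "control", tangle = 0, thread = 0,
                                 plaque = 0, lipofuscin = 0, nucleus = NA) {
  fr <- c(tangle = tangle, thread = thread, plaque = plaque,
          lipofuscin = lipofuscin, nucleus = nucleus)
  num <- fr[!is.na(fr)]
  if (any(num < 0 | num > 1))
    stop("burden fractions must lie in [0, 1]")
  if (sum(num) > 0.5)
    stop("summed burden fraction ", round(sum(num), 3),
         " exceeds 0.5: objects cannot pack the section")
  structure(list(group = group, fractions = fr),
            class = "stage_burden_profile")
}
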