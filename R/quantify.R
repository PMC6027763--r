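#' Quantify one marker on one section
#'
#' Runs the full measurement procedure in its canonical order:
#' z-projection, lowpass background correction of the marker channel,
#' thresholding of the autofluorescence channel into an exclusion mask,
#' mask subtraction, edge enhancement, object detection with size and
#' shape restrictions, and reduction to percent immunoreactive area over
#' the full imaged field. Fully deterministic for fixed inputs and
#' parameters.
#'
#' @param section A `simulated_section` (see [generate_section()]) or a
#'   named list of channels by role; each channel may be a
#'   [channel_image] or a list of them (a z-stack, projected first).
#'   Roles `signal` and `autofluorescence` are required.
#' @param params A [seg_params].
#' @param case_id,region Tags carried into the measurement record.
#' @return A one-row measurement record (see [measure_ir_area()]) with the
#'   retained objects attached as `attr(, "objects")` and their label
#'   mask as `attr(, "labels")`.
#' @export
quantify_marker <- function(section, params = seg_params(),
                            case_id = "case", region = NA_character_) {
  channels <- if (inherits(section, "simulated_section")) section$channels
              else section
  for (role in c("signal", "autofluorescence")) {
    if (is.null(channels[[role]]))
      stop("section is missing the required channel role \"", role, "\"")
  }
  signal_raw <- project_stack(channels$signal)
  af <- project_stack(channels$autofluorescence)
  corrected <- correct_background(signal_raw, params$background_sigma_um)
  af_mask <- autofluorescence_mask(af, params$af_threshold,
                                   params$af_dilation_px)
  cleaned <- subtract_mask(corrected, af_mask)
  enhanced <- edge_enhance(cleaned, params$edge_strength,
                           params$edge_sigma_um)
  det <- detect_objects(enhanced, params, raw = signal_raw)
  roi <- prod(dim(signal_raw$pixels)) * signal_raw$pixel_size_um^2
  rec <- measure_ir_area(det$objects, roi, case_id = case_id,
                         region = region, marker = params$marker_name)
  attr(rec, "objects") <- det$objects
  attr(rec, "labels") <- det$labels
  rec
}

#' Simulate, quantify and analyse one complete staged study
#'
#' The whole pipeline in one call: simulate a study of
#' `n_cases_per_group` cases per Braak group with two mosaic fields per
#' (case, region), quantify every section, average mosaic replicates,
#' then run the factorial ANOVA with Bonferroni contrasts and the fold
#' change versus controls.
#'
#' @param seed Master seed.
#' @param n_cases_per_group,n_mosaics Study dimensions.
#' @param params Simulator settings shared by all sections.
#' @param design Burden design table; defaults to the stage-increasing
#'   [default_study_design()].
#' @param seg Segmentation parameters for the marker channel.
#' @return List with `measurements` (per-section records), `averaged`
#'   (one row per case, region), `anova` (an `anova_result`) and
#'   `fold_change`.
#' @export
simulate_and_analyze_study <- function(seed, n_cases_per_group = 5L,
                                       n_mosaics = 2L,
                                       params = section_sim_params(),
                                       design = default_study_design(),
                                       seg = seg_params()) {
  study <- generate_study(design, n_cases_per_group, seed = seed,
                          n_mosaics = n_mosaics, params = params)
  m <- quantify_study(study, seg)
  av <- average_mosaics(m)
  list(measurements = m, averaged = av,
       anova = two_way_anova(av),
       fold_change = fold_change(av))
}

#' Quantify every section of a simulated study
#'
#' Applies [quantify_marker()] to each section in a study collection and
#' binds the records (one per section; mosaic replicates are averaged
#' later with [average_mosaics()]).
#'
#' @param study A study as returned by [generate_study()].
#' @param params A [seg_params].
#' @return A data frame of measurement records joined to the study's case
#'   table columns (braak_group, mosaic).
#' @export
quantify_study <- function(study, params = seg_params()) {
  stopifnot(inherits(study, "simulated_study"))
  recs <- vector("list", length(study$sections))
  for (i in seq_along(study$sections)) {
    meta <- study$case_table[i, ]
    rec <- quantify_marker(study$sections[[i]], params,
                           case_id = meta$case_id, region = meta$region)
    rec$braak_group <- meta$braak_group
    rec$mosaic <- meta$mosaic
    attr(rec, "objects") <- NULL
    attr(rec, "labels") <- NULL
    recs[[i]] <- rec
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
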