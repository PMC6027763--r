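SECTION_PAGE_ORDER <- c("signal", "autofluorescence", "nuclear", "thios")

#' Write a section as a multi-page 16-bit TIFF
#'
#' Pages are stored in the fixed order signal, autofluorescence, nuclear,
#' thios.
#'
#' @param section A `simulated_section` or named list of [channel_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_section_tiff <- function(section, path) {
  channels <- if (inherits(section, "simulated_section")) section$channels
              else section
  roles <- intersect(SECTION_PAGE_ORDER, names(channels))
  pages <- lapply(roles, function(r) channels[[r]]$pixels / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page section TIFF
#'
#' @param path TIFF path.
#' @param role_map Character vector assigning a channel role to each page
#'   in order; its length must match the page count.
#' @param pixel_size_um Physical pixel size to attach.
#' @return Named list of [channel_image] by role, with bit depth detected
#'   from the file.
#' @export
read_section_tiff <- function(path, role_map = SECTION_PAGE_ORDER,
                              pixel_size_um = 0.5) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (length(pages) != length(role_map))
    stop("page/role mismatch for ", path, ": expected ", length(role_map),
         " page(s) [", paste(role_map, collapse = ", "), "], found ",
         length(pages))
  out <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    bits <- attr(p, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(p) > 255) 16L else 8L
    channel_image(matrix(as.numeric(p), nrow(p), ncol(p)),
                  role = role_map[i], pixel_size_um = pixel_size_um,
                  bit_depth = as.integer(bits))
  })
  names(out) <- role_map
  out
}

#' Write ground-truth masks and area fractions of a section
#'
#' One binary PNG per class (`<prefix>_gt_<class>.png`) plus a
#' `ground_truth.csv` row set (section_id, class, true_area_fraction),
#' appended to an existing file or created with a header.
#'
#' @param section A `simulated_section`.
#' @param dir Output directory.
#' @param section_id Identifier used in filenames and the CSV.
#' @return Path of the ground-truth CSV, invisibly.
#' @export
write_ground_truth <- function(section, dir, section_id = "section") {
  stopifnot(inherits(section, "simulated_section"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (class in names(section$ground_truth$masks)) {
    png::writePNG(section$ground_truth$masks[[class]] * 1,
                  file.path(dir, sprintf("%s_gt_%s.png", section_id, class)))
  }
  csv <- file.path(dir, "ground_truth.csv")
  df <- data.frame(section_id = section_id,
                   class = names(section$ground_truth$true_area_fraction),
                   true_area_fraction =
                     as.numeric(section$ground_truth$true_area_fraction))
  utils::write.table(df, csv, sep = ",", row.names = FALSE,
                     col.names = !file.exists(csv), append = file.exists(csv))
  invisible(csv)
}

#' Write / read measurement tables
#'
#' Schema-stable CSV (UTF-8, comma separated, `.` decimal) holding one
#' measurement record per row; an empty record set yields a header-only
#' file. Round-trips preserve every field at full precision.
#'
#' @param records Measurement table.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_measurements <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

CONFIG_KEYS <- c("pixel_size_um", "channels", "seed", "alpha", "posthoc",
                 "exclusions", "markers")

#' Load and validate a run configuration
#'
#' YAML configuration with fail-closed validation: unknown keys are an
#' error, `pixel_size_um` is required, defaults are filled for the rest,
#' and each marker block is turned into a [seg_params()]. The validated
#' configuration should be snapshotted next to every output directory so
#' a run can be replayed.
#'
#' @param path YAML file. Recognised keys: `pixel_size_um` (required),
#'   `channels` (page-role list for TIFF input), `seed`, `alpha`,
#'   `posthoc` (`bonferroni`, `tukey` or `newman_keuls`; no default --
#'   the choice must be explicit where it matters), `exclusions` (path),
#'   `markers` (map of marker name to seg_params fields; `*_threshold`
#'   entries are either a number, meaning fixed, or the string "otsu").
#' @return A `run_config` list with `markers` as [seg_params()] objects.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$pixel_size_um))
    stop("config is missing required key: pixel_size_um")
  if (!is.null(cfg$alpha) && (cfg$alpha <= 0 || cfg$alpha >= 1))
    stop("alpha must be in (0, 1)")
  cfg$channels <- cfg$channels %||% SECTION_PAGE_ORDER
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$seed <- cfg$seed %||% 1L
  as_thr <- function(x, default) {
    if (is.null(x)) default
    else if (identical(x, "otsu")) threshold_spec("otsu")
    else if (is.list(x)) do.call(threshold_spec, x)
    else threshold_spec("fixed", as.numeric(x))
  }
  cfg$markers <- lapply(
    stats::setNames(names(cfg$markers %||% list()),
                    names(cfg$markers %||% list())),
    function(m) {
      blk <- cfg$markers[[m]]
      known <- c("background_sigma_um", "af_threshold", "af_dilation_px",
                 "edge_strength", "edge_sigma_um", "signal_threshold",
                 "min_area_um2", "max_area_um2", "roundness_range")
      bad <- setdiff(names(blk), known)
      if (length(bad))
        stop("unknown key(s) in marker block \"", m, "\": ",
             paste(bad, collapse = ", "))
      defaults <- seg_params(marker_name = m)
      seg_params(
        marker_name = m,
        background_sigma_um = blk$background_sigma_um %||%
          defaults$background_sigma_um,
        af_threshold = as_thr(blk$af_threshold, defaults$af_threshold),
        af_dilation_px = blk$af_dilation_px %||% defaults$af_dilation_px,
        edge_strength = blk$edge_strength %||% defaults$edge_strength,
        edge_sigma_um = blk$edge_sigma_um %||% defaults$edge_sigma_um,
        signal_threshold = as_thr(blk$signal_threshold,
                                  defaults$signal_threshold),
        min_area_um2 = blk$min_area_um2 %||% defaults$min_area_um2,
        max_area_um2 = blk$max_area_um2 %||% defaults$max_area_um2,
        roundness_range = unlist(blk$roundness_range) %||%
          defaults$roundness_range)
    })
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
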