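# Connected-component labeling and object measurement.
#
# EBImage::bwlabel is 4-connected; the measurement procedure specifies
# 8-connectivity, so components are built here from the 8-neighbour
# adjacency graph of the foreground pixels (igraph). Labels are
# renumbered in raster order (column-major, as R stores matrices) so the
# result is deterministic.

label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(out)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  from <- integer(0); to <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1L]; c2 <- cc + d[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[j]
    from <- c(from, pos[idx[ok][keep]])
    to <- c(to, pos[j[keep]])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  # renumber components by first occurrence in raster order
  relab <- integer(max(memb))
  nxt <- 0L
  for (m in memb) if (relab[m] == 0L) { nxt <- nxt + 1L; relab[m] <- nxt }
  out[idx] <- relab[memb]
  out
}

measure_labeled <- function(labels, raw_pixels, pixel_size_um) {
  n <- max(labels)
  if (n == 0L)
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), roundness = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      mean_raw_intensity = numeric(0)))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  nr <- nrow(labels)
  row0 <- (idx - 1L) %% nr          # 0-based y (downward)
  col0 <- (idx - 1L) %/% nr         # 0-based x (rightward)
  npx <- tabulate(lab, n)
  area <- npx * pixel_size_um^2
  shp <- EBImage::computeFeatures.shape(labels)
  perim <- shp[, "s.perimeter"] * pixel_size_um
  # discretized perimeters make 4*pi*A/P^2 overshoot 1 for compact
  # objects; clamp at 1 (documented epsilon) so discs score 1 exactly
  roundness <- pmin(1, 4 * pi * area / pmax(perim, .Machine$double.eps)^2)
  data.frame(
    label = seq_len(n),
    area_um2 = area,
    perimeter_um = as.numeric(perim),
    roundness = as.numeric(roundness),
    centroid_x = as.numeric(tapply(col0, lab, mean)),
    centroid_y = as.numeric(tapply(row0, lab, mean)),
    mean_raw_intensity = as.numeric(tapply(raw_pixels[idx], lab, mean))
  )
}

#' Detect marker-positive objects
#'
#' Thresholds the (background-corrected, autofluorescence-subtracted,
#' edge-enhanced) image, labels 8-connected components, measures each, and
#' retains components passing the size and shape restrictions. Mean raw
#' intensity is measured on the raw (pre-enhancement) image supplied in
#' `raw`: detection outlines are loaded back onto the original data so
#' reported intensities are unaffected by the enhancement.
#'
#' @param img The [channel_image] to threshold (typically the enhanced
#'   image produced by the earlier pipeline stages).
#' @param params A [seg_params]; uses `signal_threshold`, `min_area_um2`,
#'   `max_area_um2` and `roundness_range`.
#' @param raw Optional [channel_image] of the unprocessed data for raw
#'   intensity measurement; defaults to `img`.
#' @return A list with `objects` (data frame: label, area_um2,
#'   perimeter_um, roundness, centroid_x/centroid_y in 0-based pixel
#'   coordinates with origin top-left, mean_raw_intensity) and `labels`
#'   (integer label matrix of the retained objects).
#' @export
detect_objects <- function(img, params, raw = img) {
  stopifnot(is_channel_image(img), inherits(params, "seg_params"))
  thr <- resolve_threshold(params$signal_threshold, img)
  labels <- label_components_8(img$pixels >= thr)
  obj <- measure_labeled(labels, raw$pixels, img$pixel_size_um)
  keep <- obj$area_um2 >= params$min_area_um2 &
    obj$area_um2 <= params$max_area_um2 &
    obj$roundness >= params$roundness_range[1] &
    obj$roundness <= params$roundness_range[2]
  dropped <- obj$label[!keep]
  if (length(dropped)) labels[labels %in% dropped] <- 0L
  obj <- obj[keep, , drop = FALSE]
  # relabel retained objects 1..k in the mask and the table
  if (nrow(obj)) {
    relab <- integer(max(obj$label))
    relab[obj$label] <- seq_len(nrow(obj))
    labels[labels > 0L] <- relab[labels[labels > 0L]]
    obj$label <- seq_len(nrow(obj))
  }
  rownames(obj) <- NULL
  list(objects = obj, labels = labels, threshold = thr)
}

#' Detect plaque cores on the ThioflavinS channel
#'
#' Plaque cores bind ThioflavinS intensely while tangles are only weakly
#' labeled, so thresholding (no edge enhancement) followed by a minimum
#' size restriction retains the cores and excludes tangles.
#'
#' @param thios_img A [channel_image] with role `"thios"`.
#' @param params A [seg_params], typically [plaque_params()]; only the
#'   threshold and the minimum area restriction are applied.
#' @return A data frame of plaque-core candidates (see [detect_objects()]).
#' @export
detect_plaque_cores <- function(thios_img, params = plaque_params()) {
  stopifnot(is_channel_image(thios_img))
  if (thios_img$role != "thios")
    stop("`thios_img` must have role \"thios\", got \"", thios_img$role, "\"")
  thr <- resolve_threshold(params$signal_threshold, thios_img)
  labels <- label_components_8(thios_img$pixels >= thr)
  obj <- measure_labeled(labels, thios_img$pixels, thios_img$pixel_size_um)
  obj <- obj[obj$area_um2 >= params$min_area_um2, , drop = FALSE]
  rownames(obj) <- NULL
  obj
}

#' Summarise detected objects into a measurement record
#'
#' The atom of all downstream statistics: percent immunoreactive area for
#' one (case, region, marker).
#'
#' @param objects Data frame of retained objects (needs `area_um2`).
#' @param roi_area_um2 Area of the measured region of interest in um^2
#'   (the full imaged field).
#' @param case_id,region,marker Identifying tags.
#' @return A one-row data frame: case_id, region, marker, ir_area_percent,
#'   n_objects, roi_area_um2.
#' @export
measure_ir_area <- function(objects, roi_area_um2, case_id = "case",
                            region = NA_character_, marker = "marker") {
  if (!is.numeric(roi_area_um2) || length(roi_area_um2) != 1L ||
      roi_area_um2 <= 0)
    stop("`roi_area_um2` must be a single positive number")
  total <- if (nrow(objects)) sum(objects$area_um2) else 0
  data.frame(case_id = as.character(case_id), region = as.character(region),
             marker = as.character(marker),
             ir_area_percent = 100 * total / roi_area_um2,
             n_objects = nrow(objects),
             roi_area_um2 = roi_area_um2,
             stringsAsFactors = FALSE)
}
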