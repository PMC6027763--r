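ISO_REGIONS <- c("TeCtx", "FrCtx", "CiCtx", "OcCtx")

#' Average mosaic replicates
#'
#' Two mosaic fields are captured per (case, region); their measurements
#' are combined by the arithmetic mean so that every (case, region,
#' marker) contributes exactly one row downstream. Singletons pass
#' through; more than two replicates signal a misconfigured pipeline and
#' raise an error.
#'
#' @param records Measurement table with columns case_id, region, marker,
#'   ir_area_percent, n_objects, roi_area_um2 (extra columns such as
#'   braak_group are kept, taking the first value per group).
#' @return Averaged measurement table, one row per (case, region, marker).
#' @export
average_mosaics <- function(records) {
  key <- interaction(records$case_id, records$region, records$marker,
                     drop = TRUE)
  counts <- table(key)
  if (any(counts > 2L))
    stop("more than 2 mosaic replicates for ",
         names(counts)[which.max(counts)],
         ": pipeline misconfiguration")
  idx <- split(seq_len(nrow(records)), key)
  out <- lapply(idx, function(ii) {
    row <- records[ii[1L], , drop = FALSE]
    row$ir_area_percent <- mean(records$ir_area_percent[ii])
    row$n_objects <- mean(records$n_objects[ii])
    row$roi_area_um2 <- mean(records$roi_area_um2[ii])
    row$mosaic <- NULL
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Add the isocortex mean as a synthetic region
#'
#' Per case and marker, the isocortex value is the mean of the four
#' isocortical regions (temporal, frontal, cingulate, occipital); the
#' transentorhinal region is never included. Cases missing any of the
#' four regions are flagged with a warning and excluded from the
#' isocortex rows (their regional rows are untouched).
#'
#' @param table Averaged measurement table (one row per case, region,
#'   marker).
#' @return The table with additional rows for region `"Isocortex"`.
#' @export
isocortex_mean <- function(table) {
  iso <- table[table$region %in% ISO_REGIONS, , drop = FALSE]
  key <- interaction(iso$case_id, iso$marker, drop = TRUE)
  idx <- split(seq_len(nrow(iso)), key)
  rows <- lapply(idx, function(ii) {
    if (length(unique(iso$region[ii])) < 4L) {
      warning("case ", iso$case_id[ii[1]], " marker ", iso$marker[ii[1]],
              " is missing isocortical regions; excluded from Isocortex")
      return(NULL)
    }
    row <- iso[ii[1L], , drop = FALSE]
    row$region <- "Isocortex"
    row$ir_area_percent <- mean(iso$ir_area_percent[ii])
    row$n_objects <- mean(iso$n_objects[ii])
    row$roi_area_um2 <- mean(iso$roi_area_um2[ii])
    row
  })
  out <- rbind(table, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Fold change of group means relative to the control group
#'
#' Per (region, marker), the ratio of each group's mean percent
#' immunoreactive area to the reference (control) group's mean. The
#' reference row is exactly 1 by construction. A zero reference mean
#' makes the ratio undefined: such rows carry `NA` with
#' `reference_zero = TRUE` rather than an infinity.
#'
#' @param table Measurement table with braak_group, region, marker and
#'   ir_area_percent columns.
#' @param reference_group Name of the reference group.
#' @return Data frame: region, marker, braak_group, group_mean,
#'   fold_change, reference_zero.
#' @export
fold_change <- function(table, reference_group = "control") {
  strata <- unique(table[, c("region", "marker")])
  out <- list()
  for (i in seq_len(nrow(strata))) {
    sub <- table[table$region == strata$region[i] &
                 table$marker == strata$marker[i], , drop = FALSE]
    if (!reference_group %in% sub$braak_group)
      stop("reference group \"", reference_group, "\" missing for region ",
           strata$region[i], ", marker ", strata$marker[i])
    gm <- tapply(sub$ir_area_percent, sub$braak_group, mean)
    ref <- gm[[reference_group]]
    fc <- if (ref == 0) rep(NA_real_, length(gm)) else as.numeric(gm) / ref
    if (ref != 0) fc[names(gm) == reference_group] <- 1
    out[[i]] <- data.frame(region = strata$region[i],
                           marker = strata$marker[i],
                           braak_group = names(gm),
                           group_mean = as.numeric(gm),
                           fold_change = fc,
                           reference_zero = ref == 0,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Standard error of the mean
#' @param x Numeric vector (after exclusions).
#' @return `sd(x) / sqrt(n)`.
#' @export
sem <- function(x) stats::sd(x) / sqrt(length(x))
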