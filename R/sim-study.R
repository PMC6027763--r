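#' Default study design: stage-increasing pathology burdens
#'
#' A per-group, per-region burden table emulating the canonical
#' progression of cortical tau pathology: tangle and thread burdens rise
#' monotonically across Braak stage groups and are higher in the
#' transentorhinal region (where pathology begins) than in the four
#' isocortical regions; lipofuscin is age pigment and held constant. The
#' numeric fractions are simulator settings chosen to give a realistic
#' dynamic range at desk-scale field sizes, not measured tissue values.
#'
#' @return Data frame with columns group, region, tangle, thread, plaque,
#'   lipofuscin, nucleus (burden fractions; `NA` = count-driven).
#' @export
default_study_design <- function() {
  groups <- c("control", "I_II", "III_IV", "V_VI")
  regions <- c("TeCtx", "FrCtx", "CiCtx", "OcCtx", "TEntR")
  iso_tangle <- c(control = 0.004, I_II = 0.006, III_IV = 0.012,
                  V_VI = 0.035)
  tentr_tangle <- c(control = 0.004, I_II = 0.010, III_IV = 0.022,
                    V_VI = 0.050)
  g <- rep(groups, each = length(regions))
  r <- rep(regions, times = length(groups))
  tangle <- ifelse(r == "TEntR", tentr_tangle[g], iso_tangle[g])
  data.frame(group = g, region = r,
             tangle = tangle, thread = tangle / 2,
             plaque = 0, lipofuscin = 0.01, nucleus = NA,
             stringsAsFactors = FALSE)
}

#' Generate a complete simulated study
#'
#' Emits one section per (case, region, mosaic) according to a burden
#' design table, plus a case table describing each section. Per-case
#' biological variability is modelled as a lognormal multiplier applied
#' to the tangle and thread burden targets of all sections of that case.
#' Section seeds are derived from the master seed by a fixed counter
#' scheme (`(seed + 9973 * counter) mod (2^31 - 1)`), so the whole study
#' is reproducible from `(design, seed)`.
#'
#' @param design Burden table as from [default_study_design()]: one row
#'   per (group, region) with per-class fraction columns.
#' @param n_cases_per_group Cases per group.
#' @param seed Master integer seed.
#' @param n_mosaics Fields captured per (case, region); measurements of
#'   mosaic replicates are averaged downstream with [average_mosaics()].
#' @param params A [section_sim_params()] shared by all sections.
#' @param case_scale_sd Standard deviation (log scale) of the per-case
#'   burden multiplier; 0 disables inter-individual variability.
#' @return A `simulated_study`: list with `sections` (list of
#'   `simulated_section`) and `case_table` (data frame: section_id,
#'   case_id, braak_group, region, mosaic, seed).
#' @export
generate_study <- function(design = default_study_design(),
                           n_cases_per_group = 5L, seed = 1L,
                           n_mosaics = 1L,
                           params = section_sim_params(),
                           case_scale_sd = 0.25) {
  groups <- unique(design$group)
  regions <- unique(design$region)
  if (length(groups) != 4L || length(regions) != 5L)
    stop("`design` must cover 4 groups x 5 regions")
  classes <- c("tangle", "thread", "plaque", "lipofuscin", "nucleus")
  if (!all(classes %in% names(design)))
    stop("`design` must have burden columns: ",
         paste(classes, collapse = ", "))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  n_cases <- n_cases_per_group * length(groups)
  case_scale <- if (case_scale_sd > 0 && n_cases > 0)
    exp(rnorm(n_cases, -case_scale_sd^2 / 2, case_scale_sd))
  else rep(1, max(n_cases, 1L))

  sections <- list()
  rows <- list()
  counter <- 0L
  case_no <- 0L
  for (g in groups) for (i in seq_len(n_cases_per_group)) {
    case_no <- case_no + 1L
    case_id <- sprintf("%s_case%02d", g, i)
    for (r in regions) {
      drow <- design[design$group == g & design$region == r, ]
      for (m in seq_len(n_mosaics)) {
        counter <- counter + 1L
        sub_seed <- as.integer((seed + 9973 * counter) %% 2147483647)
        burden <- stage_burden_profile(
          group = g,
          tangle = min(drow$tangle * case_scale[case_no], 0.2),
          thread = min(drow$thread * case_scale[case_no], 0.1),
          plaque = drow$plaque, lipofuscin = drow$lipofuscin,
          nucleus = drow$nucleus)
        sections[[counter]] <- generate_section(params, burden, sub_seed)
        rows[[counter]] <- data.frame(
          section_id = sprintf("sec%04d", counter), case_id = case_id,
          braak_group = g, region = r, mosaic = m, seed = sub_seed,
          stringsAsFactors = FALSE)
      }
    }
  }
  case_table <- if (length(rows)) do.call(rbind, rows)
  else data.frame(section_id = character(0), case_id = character(0),
                  braak_group = character(0), region = character(0),
                  mosaic = integer(0), seed = integer(0))
  structure(list(sections = sections, case_table = case_table,
                 seed = as.integer(seed)),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study> %d sections, %d cases, master seed %d\n",
              length(x$sections), length(unique(x$case_table$case_id)),
              x$seed))
  invisible(x)
}
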