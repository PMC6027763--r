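#' Read a case-metadata table
#'
#' @param path CSV with columns case_id, age, sex, braak_group,
#'   braak_stage, pmd_hours, fixation_weeks, clinical_note.
#' @return Data frame with `braak_group` as a factor ordered
#'   control < I_II < III_IV < V_VI (levels present in the data).
#' @export
read_cases <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("case_id", "age", "sex", "braak_group", "braak_stage",
              "pmd_hours", "fixation_weeks")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("case table is missing columns: ", paste(missing, collapse = ", "))
  df$braak_group <- factor(df$braak_group,
                           levels = intersect(c("control", "I_II", "III_IV",
                                                "V_VI"),
                                              unique(df$braak_group)))
  df
}

#' Demographic case table of the 20-case Braak-staged cohort
#'
#' Five autopsy cases per Braak stage group (controls at stage 0, then
#' I/II, III/IV, V/VI) with age, sex, Braak stage, post-mortem delay to
#' fixation and fixation time, as used by the worked examples and the
#' summary checks.
#'
#' @return Data frame, one row per case.
#' @export
example_case_table <- function() {
  read_cases(system.file("extdata", "case_info.csv", package = "tauquant",
                         mustWork = TRUE))
}

# round half away from zero, the convention of printed summary tables
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Per-group demographic summaries
#'
#' Arithmetic group means of age, Braak stage, post-mortem delay and
#' fixation time, reported at the 1-decimal printed precision (rounding
#' half away from zero). Groups present as factor levels but empty in the
#' data are omitted with a warning.
#'
#' @param cases Case table as from [read_cases()].
#' @return Data frame: braak_group, n, age, braak_stage, pmd_hours,
#'   fixation_weeks (group means, 1 decimal).
#' @export
summarize_cases <- function(cases) {
  if (!nrow(cases)) stop("empty case table")
  groups <- if (is.factor(cases$braak_group)) levels(cases$braak_group)
            else unique(cases$braak_group)
  cols <- c("age", "braak_stage", "pmd_hours", "fixation_weeks")
  out <- list()
  for (g in groups) {
    sub <- cases[cases$braak_group == g, , drop = FALSE]
    if (!nrow(sub)) {
      warning("group ", g, " has no cases; omitted from summary")
      next
    }
    means <- vapply(cols, function(cl) round_half_up(mean(sub[[cl]]), 1),
                    numeric(1))
    out[[g]] <- data.frame(braak_group = g, n = nrow(sub),
                           as.list(means), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exclusion rules
#'
#' @param case_id Case identifier.
#' @param scope Marker name the exclusion applies to, or `"all"`.
#' @param reason Free-text justification (logged, not interpreted).
#' @return One-row data frame; rbind several to build a rule set.
#' @export
exclusion_rule <- function(case_id, scope = "all", reason = "") {
  data.frame(case_id = as.character(case_id), scope = as.character(scope),
             reason = as.character(reason), stringsAsFactors = FALSE)
}

#' Apply exclusion rules to a measurement table
#'
#' Removes rows matching each rule's (case, scope); scope `"all"` removes
#' every row of the case, a marker name only that marker's rows. The
#' input table is not modified; the number of removed rows is reported as
#' a message and attached as `attr(, "n_removed")`.
#'
#' @param table Measurement table with `case_id` and `marker` columns.
#' @param rules Data frame of rules (see [exclusion_rule()]); may be
#'   empty.
#' @return The filtered table.
#' @export
apply_exclusions <- function(table, rules) {
  if (is.null(rules) || !nrow(rules)) {
    attr(table, "n_removed") <- 0L
    return(table)
  }
  unknown <- setdiff(rules$case_id, table$case_id)
  if (length(unknown))
    stop("exclusion rule references unknown case(s): ",
         paste(unknown, collapse = ", "))
  drop <- rep(FALSE, nrow(table))
  for (i in seq_len(nrow(rules))) {
    hit <- table$case_id == rules$case_id[i]
    if (rules$scope[i] != "all") hit <- hit & table$marker == rules$scope[i]
    drop <- drop | hit
  }
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  message(sum(drop), " row(s) removed by ", nrow(rules),
          " exclusion rule(s)")
  attr(out, "n_removed") <- sum(drop)
  out
}
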