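# order Braak-group labels by disease stage rather than alphabetically
braak_ordered_factor <- function(x) {
  canon <- c("control", "I_II", "III_IV", "V_VI")
  u <- unique(as.character(x))
  if (all(u %in% canon)) factor(x, levels = intersect(canon, u))
  else factor(x)
}

#' Two-way factorial ANOVA with Bonferroni cell-mean contrasts
#'
#' The study design crosses Braak stage group with brain region, with
#' cases as replicates. Balanced designs use the classical (type-I,
#' order-independent) sums of squares; unbalanced designs -- which arise
#' whenever exclusions remove cases -- use type-II sums of squares via
#' [car::Anova()]. If the omnibus ANOVA finds any significant term
#' (interaction or main effect) at `alpha`,
#' Bonferroni-adjusted pairwise comparisons of cell means are computed in
#' the two families of the figure-legend convention: stage groups
#' compared within each region ("solid lines") and regions compared
#' within each stage group ("dotted lines"). Each family's multiplier m
#' is its total number of comparisons; adjusted p is `min(1, m * p_raw)`
#' with t statistics built on the pooled residual mean square.
#'
#' @param table Data frame of measurements.
#' @param factor_a,factor_b,response Column names; defaults braak_group,
#'   region, ir_area_percent.
#' @param alpha Significance level for the post-hoc gate and the
#'   post-hoc flags.
#' @param posthoc `"bonferroni"` (the only family-wise method used at
#'   this design) or `"none"`.
#' @return An `anova_result`: list with `table` (term, df, sum_sq,
#'   mean_sq, statistic, p), `post_hoc` (data frame or NULL), `type`
#'   (`"I"` or `"II"`), `alpha`, `balanced`.
#' @export
two_way_anova <- function(table, factor_a = "braak_group",
                          factor_b = "region",
                          response = "ir_area_percent", alpha = 0.05,
                          posthoc = c("bonferroni", "none")) {
  posthoc <- match.arg(posthoc)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  A <- braak_ordered_factor(table[[factor_a]])
  B <- braak_ordered_factor(table[[factor_b]])
  y <- table[[response]]
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stop("both factors need at least 2 levels")
  cell_n <- table(A, B)
  if (any(cell_n == 0L)) {
    empty <- which(cell_n == 0L, arr.ind = TRUE)[1L, ]
    stop("empty design cell: ", levels(A)[empty[1]], " x ",
         levels(B)[empty[2]])
  }
  if (any(cell_n < 2L))
    stop("every cell needs >= 2 replicates for the interaction term")
  balanced <- length(unique(as.vector(cell_n))) == 1L
  dat <- data.frame(y = y, A = A, B = B)
  fit <- stats::aov(y ~ A * B, data = dat)
  if (balanced) {
    sm <- summary(fit)[[1L]]
    tab <- data.frame(term = trimws(rownames(sm)), df = sm$Df,
                      sum_sq = sm$`Sum Sq`, mean_sq = sm$`Mean Sq`,
                      statistic = sm$`F value`, p = sm$`Pr(>F)`,
                      stringsAsFactors = FALSE)
    type <- "I"
  } else {
    ca <- car::Anova(stats::lm(y ~ A * B, data = dat), type = 2)
    tab <- data.frame(term = rownames(ca), df = ca$Df, sum_sq = ca$`Sum Sq`,
                      mean_sq = ca$`Sum Sq` / ca$Df,
                      statistic = ca$`F value`, p = ca$`Pr(>F)`,
                      stringsAsFactors = FALSE)
    type <- "II"
  }
  tab$term <- sub("^A:B$", paste0(factor_a, ":", factor_b), tab$term)
  tab$term <- sub("^A$", factor_a, tab$term)
  tab$term <- sub("^B$", factor_b, tab$term)
  tab$term <- sub("^\\(?Residuals?\\)?$", "residual", tab$term)
  rownames(tab) <- NULL

  res_row <- tab$term == "residual"
  mse <- tab$sum_sq[res_row] / tab$df[res_row]
  df_res <- tab$df[res_row]
  # cell-mean contrasts follow a significant omnibus result; a strong
  # main effect with parallel region profiles (no interaction) still
  # licenses the stage-within-region comparisons
  term_p <- tab$p[!res_row]
  ph <- NULL
  if (posthoc == "bonferroni" && any(term_p < alpha, na.rm = TRUE)) {
    ph <- rbind(
      bonferroni_cells(y, A, B, mse, df_res,
                       family = paste0(factor_a, "_within_", factor_b)),
      bonferroni_cells(y, B, A, mse, df_res,
                       family = paste0(factor_b, "_within_", factor_a))
    )
    ph$significant <- ph$p_adj < alpha
  }
  structure(list(table = tab, post_hoc = ph, type = type, alpha = alpha,
                 balanced = balanced,
                 total_ss = sum((y - mean(y))^2)),
            class = "anova_result")
}

# pairwise comparisons of `comp` levels within each level of `within`,
# one Bonferroni family across all of them
bonferroni_cells <- function(y, comp, within, mse, df_res, family) {
  out <- list()
  for (w in levels(within)) {
    lv <- levels(comp)
    for (i in seq_len(length(lv) - 1L)) for (j in (i + 1L):length(lv)) {
      yi <- y[comp == lv[i] & within == w]
      yj <- y[comp == lv[j] & within == w]
      se <- sqrt(mse * (1 / length(yi) + 1 / length(yj)))
      tval <- (mean(yi) - mean(yj)) / se
      out[[length(out) + 1L]] <- data.frame(
        family = family, stratum = w,
        comparison = paste(lv[i], "vs", lv[j]),
        estimate = mean(yi) - mean(yj), statistic = tval,
        p_raw = 2 * stats::pt(-abs(tval), df_res),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$m <- nrow(res)
  res$p_adj <- pmin(1, res$m * res$p_raw)
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat("ANOVA (type ", x$type, if (!is.null(x$balanced))
      if (x$balanced) ", balanced" else ", unbalanced", ")\n", sep = "")
  print(x$table, digits = 4)
  if (!is.null(x$post_hoc)) {
    cat("\nPost-hoc (", sum(x$post_hoc$significant), " of ",
        nrow(x$post_hoc), " comparisons significant at alpha = ",
        x$alpha, ")\n", sep = "")
  }
  invisible(x)
}

#' One-way ANOVA with Tukey and Newman-Keuls post-hoc families
#'
#' Omnibus F test across groups followed by both multiple-comparison
#' procedures based on the studentized range: Tukey's HSD (every pairwise
#' comparison at the full-range critical value, Tukey-Kramer for unequal
#' n) and the Newman-Keuls stepwise procedure, where the critical value
#' depends on the number of ordered means spanned by each comparison and
#' a non-significant span seals every comparison nested inside it. When
#' all residual variation is zero the F statistic is undefined and
#' returned as `NA` with no significant comparisons.
#'
#' @param values Numeric response vector.
#' @param group Group labels (coerced to factor); every group needs at
#'   least 2 values.
#' @param alpha Significance level for post-hoc flags.
#' @return An `anova_result` with `table`, `tukey` and `newman_keuls`
#'   post-hoc data frames.
#' @export
one_way_anova <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  n_g <- table(group)
  if (any(n_g < 2L))
    stop("group(s) with fewer than 2 values: ",
         paste(names(n_g)[n_g < 2L], collapse = ", "))
  dat <- data.frame(y = values, g = group)
  fit <- stats::aov(y ~ g, data = dat)
  sm <- summary(fit)[[1L]]
  tab <- data.frame(term = trimws(rownames(sm)), df = sm$Df,
                    sum_sq = sm$`Sum Sq`, mean_sq = sm$`Mean Sq`,
                    statistic = sm$`F value`, p = sm$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  tab$term <- sub("^g$", "group", tab$term)
  tab$term <- sub("^\\(?Residuals?\\)?$", "residual", tab$term)
  rownames(tab) <- NULL
  mse <- tab$mean_sq[tab$term == "residual"]
  df_res <- tab$df[tab$term == "residual"]
  # residual variance that is zero up to floating-point noise makes the
  # F statistic meaningless; guard rather than report astronomic F values
  degenerate <- !is.finite(mse) ||
    mse <= 1e-10 * (abs(mean(values)) + 1)^2

  if (degenerate) {
    tab$statistic[tab$term == "group"] <- NA_real_
    tab$p[tab$term == "group"] <- NA_real_
    tk <- nk <- NULL
  } else {
    th <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    tk <- data.frame(comparison = sub("-", " vs ", rownames(th),
                                      fixed = TRUE),
                     estimate = th[, "diff"], p_adj = th[, "p adj"],
                     significant = th[, "p adj"] < alpha,
                     stringsAsFactors = FALSE)
    rownames(tk) <- NULL
    nk <- newman_keuls(values, group, mse, df_res, alpha)
  }
  structure(list(table = tab, tukey = tk, newman_keuls = nk,
                 alpha = alpha, type = "I", degenerate = degenerate),
            class = "anova_result")
}

#' Newman-Keuls stepwise studentized-range procedure
#'
#' Group means are ranked; a comparison of means `r` ranks apart is
#' tested against the studentized-range distribution with parameter `r`
#' (so the largest span uses the same critical value as Tukey's HSD and
#' narrower spans use smaller ones). Testing proceeds from the widest
#' span inward; a non-significant span seals all comparisons nested
#' within it, which keeps the procedure coherent.
#'
#' @param values,group Response and group labels.
#' @param mse,df_res Residual mean square and degrees of freedom from the
#'   omnibus fit.
#' @param alpha Significance level.
#' @return Data frame: comparison, span, statistic (q), p, significant.
#' @export
newman_keuls <- function(values, group, mse, df_res, alpha = 0.05) {
  group <- factor(group)
  means <- tapply(values, group, mean)
  ns <- tapply(values, group, length)
  ord <- order(means)
  means <- means[ord]; ns <- ns[ord]
  k <- length(means)
  sealed <- matrix(FALSE, k, k)
  out <- list()
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      q <- abs(means[j] - means[i]) / se
      p <- stats::ptukey(q, span, df_res, lower.tail = FALSE)
      sig <- !sealed[i, j] && p < alpha
      if (!sig) {
        # seal every nested comparison
        for (a in i:j) for (b in i:j) sealed[a, b] <- TRUE
      }
      out[[length(out) + 1L]] <- data.frame(
        comparison = paste(names(means)[j], "vs", names(means)[i]),
        span = span, statistic = q, p = p, significant = sig,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the data against a normal distribution
#' with the sample mean and standard deviation. Because the parameters
#' are estimated from the same data, the honest null distribution is
#' Lilliefors' (the default flavour, via [nortest::lillie.test()], n >= 5);
#' the `"asymptotic"` flavour uses the classical KS null (anti-conservative
#' with estimated parameters, kept as a switch for parity with software
#' that reports it, n >= 3).
#'
#' @param values Numeric sample.
#' @param flavor `"lilliefors"` or `"asymptotic"`.
#' @return List with `statistic` (the max ECDF deviation) and `p`.
#' @export
ks_normality <- function(values, flavor = c("lilliefors", "asymptotic")) {
  flavor <- match.arg(flavor)
  n <- length(values)
  min_n <- if (flavor == "lilliefors") 5L else 3L
  if (n < min_n)
    stop("need at least ", min_n, " values for the ", flavor, " flavour")
  s <- stats::sd(values)
  if (s == 0)
    stop("sample is constant: normality statistic is undefined")
  x <- sort(values)
  p_i <- stats::pnorm(x, mean(values), s)
  D <- max(seq_len(n) / n - p_i, p_i - (seq_len(n) - 1) / n)
  p <- if (flavor == "lilliefors") nortest::lillie.test(values)$p.value
       else suppressWarnings(stats::ks.test(values, "pnorm", mean(values),
                                            s)$p.value)
  list(statistic = D, p = p)
}
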