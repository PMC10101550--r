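#' Compare behavior scores across groups
#'
#' Runs the assay's group-comparison workflow on a table of centered
#' behavior scores: a one-way ANOVA on `group`, or a two-way factorial
#' ANOVA on `group` and `time` (type-II sums of squares, appropriate for
#' unbalanced factorial behavior data), each followed by Tukey's HSD for
#' pairwise comparisons. Differences are flagged significant when the
#' Tukey-adjusted p-value falls below `alpha` (default 0.05).
#'
#' @param table data frame with columns `score` (centered behavior score)
#'   and `group`; two-way designs also need `time` (or any second factor
#'   named by `factor2`).
#' @param design `"one_way"` or `"two_way"`.
#' @param alpha significance level.
#' @param factor2 name of the second factor column for two-way designs.
#' @return a `group_comparison` object: list with `anova` (data frame
#'   `term, df, F, p`), `tukey` (data frame `term, pair, diff, p_adj,
#'   significant`), `design`, `alpha`.
#' @examples
#' tab <- data.frame(score = c(-0.3, -0.25, -0.2, 0.05, 0.0, 0.1),
#'                   group = rep(c("WT", "KO"), each = 3))
#' compare_groups(tab, "one_way")
#' @export
compare_groups <- function(table, design = c("one_way", "two_way"),
                           alpha = 0.05, factor2 = "time") {
  design <- match.arg(design)
  table <- as.data.frame(table)
  stopifnot(all(c("score", "group") %in% names(table)))
  table$group <- factor(table$group)
  if (nlevels(table$group) < 2L)
    stop("degenerate design: need at least 2 groups", call. = FALSE)
  if (any(tabulate(table$group) < 2L))
    stop("degenerate design: need at least 2 observations per group",
         call. = FALSE)

  if (design == "one_way") {
    wvar <- tapply(table$score, table$group, stats::var)
    if (all(wvar == 0))
      stop("degenerate design: zero within-group variance everywhere",
           call. = FALSE)
    fit <- stats::aov(score ~ group, data = table)
    an <- summary(fit)[[1L]]
    terms_keep <- trimws(rownames(an)) != "Residuals"
    anova_df <- data.frame(term = trimws(rownames(an))[terms_keep],
                           df = an$Df[terms_keep],
                           F = an$`F value`[terms_keep],
                           p = an$`Pr(>F)`[terms_keep],
                           stringsAsFactors = FALSE)
  } else {
    if (!factor2 %in% names(table))
      stop("two-way design needs a '", factor2, "' column", call. = FALSE)
    table$.f2 <- factor(table[[factor2]])
    if (nlevels(table$.f2) < 2L)
      stop("degenerate design: second factor needs >= 2 levels",
           call. = FALSE)
    cvar <- tapply(table$score, interaction(table$group, table$.f2),
                   stats::var)
    if (all(is.na(cvar) | cvar == 0))
      stop("degenerate design: zero within-cell variance everywhere",
           call. = FALSE)
    fit <- stats::aov(score ~ group * .f2, data = table)
    an <- car::Anova(fit, type = 2)
    terms_keep <- trimws(rownames(an)) != "Residuals"
    term_names <- gsub("\\.f2", factor2, trimws(rownames(an))[terms_keep])
    anova_df <- data.frame(term = term_names,
                           df = an$Df[terms_keep],
                           F = an$`F value`[terms_keep],
                           p = an$`Pr(>F)`[terms_keep],
                           stringsAsFactors = FALSE)
  }

  tk <- stats::TukeyHSD(fit)
  tukey_df <- do.call(rbind, lapply(names(tk), function(term) {
    tt <- tk[[term]]
    data.frame(term = gsub("\\.f2", factor2, term),
               pair = rownames(tt), diff = tt[, "diff"],
               p_adj = tt[, "p adj"],
               significant = tt[, "p adj"] < alpha,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(anova = anova_df, tukey = tukey_df, design = design,
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s ANOVA with Tukey HSD (alpha = %g)\n",
              gsub("_", "-", x$design), x$alpha))
  cat("\nANOVA table:\n")
  print(transform(x$anova, F = signif(F, 5), p = signif(p, 4)),
        row.names = FALSE)
  cat("\nTukey pairwise comparisons:\n")
  print(transform(x$tukey, diff = signif(diff, 4), p_adj = signif(p_adj, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Write comparison results to CSV
#'
#' Writes the ANOVA table and the Tukey pairwise table as two CSV files.
#'
#' @param comparison a `group_comparison`.
#' @param anova_path,tukey_path output paths.
#' @export
write_comparison <- function(comparison, anova_path, tukey_path) {
  utils::write.csv(comparison$anova, anova_path, row.names = FALSE)
  utils::write.csv(comparison$tukey, tukey_path, row.names = FALSE)
  invisible(c(anova_path, tukey_path))
}
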