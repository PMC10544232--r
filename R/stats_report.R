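# Group-comparison statistics and relative qPCR quantification.

#' Relative gene expression by the delta-delta-Ct method
#'
#' Fold change `2^-ddCt` with
#' `ddCt = (ct_target_sample - ct_ref_sample) - (ct_target_control - ct_ref_control)`.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the sample of interest (cycles, > 0).
#' @param ct_target_control,ct_ref_control Ct of target and reference gene
#'   in the control/calibrator.
#' @return Fold change relative to the control (vectorised).
#' @export
delta_delta_ct <- function(ct_target_sample, ct_ref_sample,
                           ct_target_control, ct_ref_control) {
  stopifnot(all(ct_target_sample > 0), all(ct_ref_sample > 0),
            all(ct_target_control > 0), all(ct_ref_control > 0))
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

# Holm-Sidak step-down adjustment of p-values.
#' @noRd
p_adjust_holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Compare measurement groups by t test or one-way ANOVA with post hoc tests
#'
#' Two groups: two-sided unpaired t test (pooled variance by default;
#' `var_equal = FALSE` gives the Welch variant). More than two groups:
#' one-way ANOVA, followed by all pairwise post hoc comparisons adjusted by
#' Tukey's HSD or the Holm-Šídák step-down procedure (pairwise pooled-variance
#' t tests with step-down Šídák adjustment). Group means are reported with
#' both SD and SEM. Comparisons with adjusted p below `alpha` are flagged
#' significant.
#'
#' @param table long-format data frame with columns `sample_id`, `group`,
#'   `metric`, `value`.
#' @param metric which metric to analyse (defaults to the only one present).
#' @param method `"auto"` (t test for 2 groups, ANOVA otherwise), `"ttest"`
#'   or `"anova"`.
#' @param posthoc `"tukey"` or `"holm_sidak"` (ANOVA only).
#' @param var_equal pooled-variance t test (`TRUE`) or Welch (`FALSE`).
#' @param alpha significance threshold for flagging (default 0.05).
#' @return A `group_comparison` list: `test` (data frame: method, statistic,
#'   df, p_value, significant), `posthoc` (data frame of pairwise adjusted
#'   comparisons, or `NULL`), `group_stats` (n, mean, sd, sem per group).
#' @export
compare_groups <- function(table, metric = NULL,
                           method = c("auto", "ttest", "anova"),
                           posthoc = c("tukey", "holm_sidak"),
                           var_equal = TRUE, alpha = 0.05) {
  method <- match.arg(method)
  posthoc <- match.arg(posthoc)
  stopifnot(all(c("group", "value") %in% names(table)))
  if (!is.null(metric) && "metric" %in% names(table))
    table <- table[table$metric == metric, ]
  if (!nrow(table)) stop("no rows for requested metric")
  stopifnot(all(is.finite(table$value)))
  table$group <- factor(table$group)
  groups <- split(table$value, table$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least 2 values")

  gs <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))

  if (method == "auto") method <- if (length(groups) == 2) "ttest" else "anova"
  if (method == "ttest" && length(groups) != 2)
    stop("t test requires exactly 2 groups")

  if (method == "ttest") {
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = var_equal)
    test <- data.frame(method = if (var_equal) "t (pooled)" else "t (Welch)",
                       statistic = unname(tt$statistic), df = unname(tt$parameter),
                       p_value = tt$p.value,
                       significant = tt$p.value < alpha)
    ph <- NULL
  } else {
    fit <- stats::aov(value ~ group, data = table)
    an <- summary(fit)[[1]]
    test <- data.frame(method = "one-way ANOVA",
                       statistic = an[["F value"]][1],
                       df = paste0(an[["Df"]][1], ",", an[["Df"]][2]),
                       p_value = an[["Pr(>F)"]][1],
                       significant = isTRUE(an[["Pr(>F)"]][1] < alpha))
    ph <- if (posthoc == "tukey") posthoc_tukey(fit, alpha) else
      posthoc_holm_sidak(groups, alpha)
  }
  structure(list(test = test, posthoc = ph, group_stats = gs),
            class = "group_comparison")
}

#' @noRd
posthoc_tukey <- function(fit, alpha) {
  tk <- stats::TukeyHSD(fit)$group
  data.frame(comparison = rownames(tk),
             diff = tk[, "diff"],
             p_adjusted = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha,
             row.names = NULL)
}

#' @noRd
posthoc_holm_sidak <- function(groups, alpha) {
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  raw <- apply(pairs, 2, function(pr) {
    stats::t.test(groups[[pr[1]]], groups[[pr[2]]], var.equal = TRUE)$p.value
  })
  diffs <- apply(pairs, 2, function(pr) mean(groups[[pr[2]]]) - mean(groups[[pr[1]]]))
  adj <- p_adjust_holm_sidak(raw)
  data.frame(comparison = paste(pairs[2, ], pairs[1, ], sep = "-"),
             diff = diffs, p_raw = raw, p_adjusted = adj,
             significant = adj < alpha, row.names = NULL)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(x$test, row.names = FALSE)
  cat("group summaries:\n")
  print(x$group_stats, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
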