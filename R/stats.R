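#' One-way ANOVA with Tukey HSD post hoc comparison
#'
#' Group comparison as reported for the per-spectrum metrics: a one-way
#' ANOVA F test across conditions, followed by Tukey's honestly-significant-
#' difference test on all pairwise contrasts (Tukey-Kramer form, so
#' unbalanced cohorts such as 70/80/80 are handled). Adjusted p-values are
#' mapped to star codes at the conventional thresholds 0.05 (`*`), 0.01
#' (`**`), 0.001 (`***`), and 0.0001 (`****`); `ns` otherwise.
#'
#' Group summaries report mean +/- SE with SE = sample SD / sqrt(n). If the
#' response has zero variance overall the F statistic is undefined; it is
#' reported as 0 with p = 1 and `degenerate = TRUE`.
#'
#' @param values numeric vector of per-spectrum metric values.
#' @param groups condition labels, same length (>= 2 groups, >= 2 values per
#'   group).
#' @param metric optional metric name carried into the output.
#' @return An object of class `ftir_stats`: list with `summary` (per-group n,
#'   mean, sd, se), `anova` (F, df, p, degenerate flag, low-n flag), and
#'   `pairwise` (contrast, difference, Tukey-adjusted p, stars).
#' @export
anova_tukey <- function(values, groups, metric = NA_character_) {
  if (length(values) != length(groups)) stop("values and groups differ in length", call. = FALSE)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(as.character(groups)[keep])
  counts <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(counts < 2L)) stop("each group needs at least two values", call. = FALSE)

  summary_tab <- data.frame(
    metric = metric,
    condition = levels(groups),
    n = as.integer(counts),
    mean = as.numeric(tapply(values, groups, mean)),
    sd = as.numeric(tapply(values, groups, sd)),
    stringsAsFactors = FALSE
  )
  summary_tab$se <- summary_tab$sd / sqrt(summary_tab$n)

  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  pairs <- utils::combn(levels(groups), 2L)
  contrast <- paste(pairs[2, ], pairs[1, ], sep = "-")

  if (var(values) == 0) {
    anova_tab <- data.frame(metric = metric, F = 0, df1 = df1, df2 = df2,
                            p = 1, degenerate = TRUE, low_n = any(counts < 3L))
    pw <- data.frame(metric = metric, contrast = contrast,
                     diff = 0, p_adj = 1, stars = "ns", stringsAsFactors = FALSE)
  } else {
    fit <- aov(values ~ groups)
    ss <- summary(fit)[[1]]
    anova_tab <- data.frame(metric = metric,
                            F = ss[["F value"]][1], df1 = df1, df2 = df2,
                            p = ss[["Pr(>F)"]][1],
                            degenerate = FALSE, low_n = any(counts < 3L))
    tk <- TukeyHSD(fit)$groups
    pw <- data.frame(metric = metric,
                     contrast = rownames(tk),
                     diff = tk[, "diff"],
                     p_adj = tk[, "p adj"],
                     stringsAsFactors = FALSE)
    pw$stars <- p_stars(pw$p_adj)
    rownames(pw) <- NULL
  }
  structure(list(summary = summary_tab, anova = anova_tab, pairwise = pw),
            class = "ftir_stats")
}

#' Significance star codes
#'
#' @param p vector of p-values.
#' @return Character vector: `"****"` below 1e-4, `"***"` below 1e-3, `"**"`
#'   below 0.01, `"*"` below 0.05, else `"ns"`.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |> as.character()
}

#' Compare every metric column across conditions
#'
#' Runs [anova_tukey()] on each numeric metric column of a per-spectrum
#' metrics table and stacks the results.
#'
#' @param metrics data.frame with a `condition` column and numeric metric
#'   columns.
#' @param metric_cols columns to test (default: all numeric columns).
#' @return List of stacked `summary`, `anova`, and `pairwise` data.frames.
#' @export
compare_conditions <- function(metrics, metric_cols = NULL) {
  stopifnot(is.data.frame(metrics), "condition" %in% names(metrics))
  if (is.null(metric_cols)) {
    metric_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  }
  res <- lapply(metric_cols, function(mc) {
    ok <- is.finite(metrics[[mc]])
    if (!any(ok)) return(NULL)
    anova_tukey(metrics[[mc]][ok], metrics$condition[ok], metric = mc)
  })
  res <- Filter(Negate(is.null), res)
  list(
    summary = do.call(rbind, lapply(res, `[[`, "summary")),
    anova = do.call(rbind, lapply(res, `[[`, "anova")),
    pairwise = do.call(rbind, lapply(res, `[[`, "pairwise"))
  )
}

#' @export
print.ftir_stats <- function(x, ...) {
  cat(sprintf("<ftir_stats> %s: F(%d, %d) = %.4g, p = %.3g%s\n",
              x$anova$metric, x$anova$df1, x$anova$df2, x$anova$F, x$anova$p,
              if (x$anova$degenerate) " (degenerate: zero variance)" else ""))
  print(x$pairwise, digits = 4)
  invisible(x)
}
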