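#' Statistical comparison of normalized probing experiments
#'
#' Runs the test cascade over 2-5 normalized profiles, each contributing
#' its non-missing normalized values as one sample: a Shapiro-Wilk
#' normality test per sample, a Bartlett test of variance homogeneity
#' across samples, and — if any sample departs from normality
#' (`shapiro_p < alpha`) — a two-sided Mann-Whitney test for two samples
#' or a Kruskal-Wallis rank-sum test for three to five. When every
#' sample passes normality no location test runs and the report says so;
#' Bartlett's result is informational and does not gate the branch.
#'
#' @param profiles List of 2-5 `normalized_profile` objects.
#' @param alpha Significance level for the normality gate (default 0.05).
#' @return A `comparison_report` list: per-experiment `shapiro_p` and
#'   `normality` verdicts, `bartlett_p`, `selected_test`
#'   (`"MANN_WHITNEY"`, `"KRUSKAL_WALLIS"` or `"NONE"`), `test_p`
#'   (`NA` when no test ran), `alpha`, `n_experiments`, `labels`.
#' @export
compare_experiments <- function(profiles, alpha = 0.05) {
  k <- length(profiles)
  if (k < 2L || k > 5L) {
    stop("validation error: comparison requires between 2 and 5 experiments, got ", k)
  }
  labels <- vapply(seq_along(profiles), function(i)
    profiles[[i]]$label %||% paste0("experiment_", i), character(1))
  samples <- lapply(profiles, function(p) p$values$value[!is.na(p$values$value)])
  small <- which(vapply(samples, length, integer(1)) < 3L)
  if (length(small)) {
    stop("validation error: experiment '", labels[small[[1L]]],
         "' has fewer than 3 non-missing values")
  }

  shapiro_p <- vapply(samples, function(s) stats::shapiro.test(s)$p.value, numeric(1))
  names(shapiro_p) <- labels
  normality <- shapiro_p >= alpha
  bartlett_p <- stats::bartlett.test(samples)$p.value

  if (any(!normality)) {
    if (k == 2L) {
      selected <- "MANN_WHITNEY"
      exact <- all(lengths(samples) <= 20L)
      test_p <- suppressWarnings(
        stats::wilcox.test(samples[[1L]], samples[[2L]],
                           alternative = "two.sided",
                           exact = exact, correct = TRUE)$p.value)
    } else {
      selected <- "KRUSKAL_WALLIS"
      test_p <- stats::kruskal.test(samples)$p.value
    }
  } else {
    selected <- "NONE"
    test_p <- NA_real_
  }

  structure(list(shapiro_p = shapiro_p, normality = normality,
                 bartlett_p = bartlett_p, selected_test = selected,
                 test_p = test_p, alpha = alpha, n_experiments = k,
                 labels = labels),
            class = "comparison_report")
}

#' Plain-text summary of a comparison report
#'
#' Deterministic text stating, for each experiment, whether its data are
#' compatible with a normal distribution; whether the variances are
#' homogeneous; which location test (if any) was selected and its
#' p-value, or why none ran.
#'
#' @param report A `comparison_report`.
#' @return A single character string (lines joined by `\n`).
#' @export
report_text <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  lines <- c(
    sprintf("Statistical comparison of %d experiments (alpha = %g)",
            report$n_experiments, report$alpha),
    "",
    "Normality (Shapiro-Wilk):")
  for (i in seq_len(report$n_experiments)) {
    lines <- c(lines, sprintf(
      "  %s: p = %.6g -> %s", report$labels[[i]], report$shapiro_p[[i]],
      if (report$normality[[i]]) "consistent with a normal distribution"
      else "departs from a normal distribution"))
  }
  lines <- c(lines, "", sprintf(
    "Variance homogeneity (Bartlett): p = %.6g -> %s",
    report$bartlett_p,
    if (report$bartlett_p >= report$alpha) "variances homogeneous"
    else "variances not homogeneous"))
  lines <- c(lines, "")
  if (report$selected_test == "NONE") {
    lines <- c(lines,
      "No location test was performed: every sample is consistent with a",
      "normal distribution at the chosen alpha, so the nonparametric branch",
      "was not taken.")
  } else {
    name <- switch(report$selected_test,
                   MANN_WHITNEY = "Mann-Whitney test (two-sided)",
                   KRUSKAL_WALLIS = "Kruskal-Wallis rank-sum test")
    lines <- c(lines, sprintf("Selected test: %s", name),
               sprintf("p-value: %.6g", report$test_p))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(report_text(x), "\n")
  invisible(x)
}
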