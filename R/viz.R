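#' Default bin color map
#'
#' @return Named character vector mapping `LOW`/`MID`/`HIGH` to colors.
#' @export
default_bin_colors <- function() {
  c(LOW = "black", MID = "orange", HIGH = "red")
}

#' Reactivity profile plot (bar or step)
#'
#' Renders one profile. The bar plot draws one bar per position, colored
#' by its reactivity bin (black/orange/red by default), with gaps — not
#' zeros — at missing positions. The step plot draws a piecewise-constant
#' trace broken at runs of missing data. For an averaged profile the bar
#' plot adds per-position SD whiskers where an sd is available.
#'
#' @param profile A `normalized_profile` or `averaged_profile`.
#' @param kind `"bar"` or `"step"`.
#' @param bin_colors Named colors for `LOW`, `MID`, `HIGH`.
#' @param thresholds Bin thresholds used when binning an averaged profile.
#' @param title Plot title.
#' @return A ggplot object; render to file with [save_plot()].
#' @export
plot_profile <- function(profile, kind = c("bar", "step"),
                         bin_colors = default_bin_colors(),
                         thresholds = c(0.4, 0.85),
                         title = NULL) {
  kind <- match.arg(kind)
  if (!all(c("LOW", "MID", "HIGH") %in% names(bin_colors))) {
    stop("validation error: bin_colors must name LOW, MID and HIGH")
  }
  if (inherits(profile, "normalized_profile")) {
    df <- profile$values
    sd <- rep(NA_real_, nrow(df))
    title <- title %||% profile$label
  } else if (inherits(profile, "averaged_profile")) {
    df <- data.frame(position = profile$position, value = profile$mean,
                     bin = bin_label(profile$mean, thresholds))
    sd <- profile$sd
    title <- title %||% "averaged profile"
  } else {
    stop("unsupported profile object")
  }
  if (nrow(df) == 0L || all(is.na(df$value))) {
    stop("validation error: empty profile, nothing to plot")
  }
  df$sd <- sd
  plotted <- df[!is.na(df$value), , drop = FALSE]

  p <- ggplot2::ggplot(plotted,
                       ggplot2::aes(x = .data$position, y = .data$value))
  if (kind == "bar") {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$bin), width = 0.8)
    has_sd <- !is.na(plotted$sd)
    if (any(has_sd)) {
      p <- p + ggplot2::geom_errorbar(
        data = plotted[has_sd, , drop = FALSE],
        ggplot2::aes(ymin = .data$value - .data$sd,
                     ymax = .data$value + .data$sd),
        width = 0.3, linewidth = 0.3)
    }
    p <- p + ggplot2::scale_fill_manual(
      values = bin_colors, breaks = c("LOW", "MID", "HIGH"),
      name = "reactivity", drop = FALSE)
  } else {
    # break the trace at missing runs
    gap <- c(0L, which(diff(plotted$position) > 1L))
    plotted$segment <- rep(seq_along(gap),
                           diff(c(gap, nrow(plotted))))
    p <- ggplot2::ggplot(plotted,
                         ggplot2::aes(x = .data$position, y = .data$value,
                                      group = .data$segment)) +
      ggplot2::geom_step()
  }
  p + ggplot2::labs(x = "nucleotide position", y = "normalized reactivity",
                    title = title) +
    ggplot2::theme_classic(base_size = 10)
}

bin_label <- function(v, thresholds) {
  ifelse(is.na(v), NA_character_,
         ifelse(v < thresholds[[1L]], "LOW",
                ifelse(v < thresholds[[2L]], "MID", "HIGH")))
}

#' Comparison plots for 2-5 experiments
#'
#' `"step"` overlays one piecewise-constant reactivity trace per
#' experiment in a single chart with a legend; `"box"` draws one
#' box-and-whisker per experiment with whiskers at the sample minimum and
#' maximum (position measures: quartiles, minimum, maximum); `"violin"`
#' draws one density shape per experiment.
#'
#' @param profiles List of 2-5 `normalized_profile` objects.
#' @param kind `"step"`, `"box"` or `"violin"`.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_comparison <- function(profiles, kind = c("step", "box", "violin"),
                            title = NULL) {
  kind <- match.arg(kind)
  k <- length(profiles)
  if (k < 2L || k > 5L) {
    stop("validation error: comparison plots take between 2 and 5 profiles, got ", k)
  }
  labels <- vapply(seq_along(profiles), function(i)
    profiles[[i]]$label %||% paste0("experiment_", i), character(1))
  df <- do.call(rbind, lapply(seq_len(k), function(i) {
    v <- profiles[[i]]$values
    data.frame(experiment = labels[[i]], position = v$position,
               value = v$value, stringsAsFactors = FALSE)
  }))
  df <- df[!is.na(df$value), , drop = FALSE]

  p <- switch(kind,
    step = ggplot2::ggplot(df, ggplot2::aes(
        x = .data$position, y = .data$value, color = .data$experiment)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "nucleotide position", y = "normalized reactivity"),
    box = ggplot2::ggplot(df, ggplot2::aes(
        x = .data$experiment, y = .data$value)) +
      ggplot2::stat_boxplot(geom = "errorbar", width = 0.25,
                            coef = 1e9) +                    # min/max whiskers
      ggplot2::geom_boxplot(coef = 1e9) +
      ggplot2::labs(x = NULL, y = "normalized reactivity"),
    violin = ggplot2::ggplot(df, ggplot2::aes(
        x = .data$experiment, y = .data$value)) +
      ggplot2::geom_violin(scale = "width") +
      ggplot2::labs(x = NULL, y = "normalized reactivity"))
  p + ggplot2::labs(title = title) + ggplot2::theme_classic(base_size = 10)
}

#' Save a plot as PNG or EPS
#'
#' Fixed figure geometry (7 x 3.5 in, 150 dpi for PNG) keeps repeated
#' renders of the same plot byte-identical.
#'
#' @param plot A ggplot object.
#' @param path Output path; the format is taken from the extension unless
#'   `format` is given.
#' @param format `"png"` or `"eps"`.
#' @param width,height Figure size in inches.
#' @param dpi Resolution for PNG output.
#' @return The path, invisibly.
#' @export
save_plot <- function(plot, path, format = NULL,
                      width = 7, height = 3.5, dpi = 150) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("png", "eps")) {
    stop("validation error: output format must be png or eps, got '", format, "'")
  }
  if (format == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = dpi, type = "cairo")
  } else {
    grDevices::postscript(path, width = width, height = height,
                          horizontal = FALSE, onefile = FALSE,
                          paper = "special")
  }
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
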