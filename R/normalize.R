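#' Box-plot normalization of absolute reactivities
#'
#' Rescales the reliable absolute reactivities of one experiment onto the
#' uniform SHAPE scale. The procedure:
#'
#' 1. Collect the reactivities `V` at positions the mask calls reliable
#'    (`n = |V|`; at least 10 are required).
#' 2. Compute the first and third quartiles by linear interpolation
#'    between order statistics (the "type 7" convention) and the upper
#'    extreme `UP = Q3 + 1.5 * (Q3 - Q1)`.
#' 3. Values above `UP` are outlier candidates, capped at
#'    `floor(0.10 * n)` when `n > 100` and `floor(0.05 * n)` otherwise;
#'    when candidates exceed the cap, the largest values win (ties broken
#'    by higher value, then lower position).
#' 4. The effective maximum reactivity is the mean of the top
#'    `ceiling(0.08 * n_nonoutlier)` non-outlier values (at least one).
#' 5. Every reliable value — outliers included — is divided by the
#'    effective maximum; masked positions become missing.
#'
#' Outliers are excluded only from the effective-maximum computation;
#' they remain in the output, scaled and flagged in the diagnostics.
#' Negative reactivities surviving a manual keep policy participate in
#' the quartile computation.
#'
#' @param exp A `probing_experiment` (reactivities possibly adjusted by
#'   [apply_manual_policy()]).
#' @param mask A `strongstop_mask` aligned with `exp`.
#' @param thresholds Color-bin thresholds passed to [assign_color_bins()].
#' @return A `normalized_profile`: list with `values` (data frame
#'   `position`, `value`, `bin`) and `diagnostics` (quartiles, `iqr`,
#'   `upper_extreme`, `outlier_positions`, `effective_max`,
#'   `cap_fraction`, `n_included`).
#' @export
normalize_profile <- function(exp, mask, thresholds = c(0.4, 0.85)) {
  stopifnot(inherits(exp, "probing_experiment"),
            inherits(mask, "strongstop_mask"))
  r <- exp$records
  if (!identical(r$position, mask$position)) {
    stop("validation error: mask positions do not match experiment positions")
  }
  reliable <- mask$flag == "RELIABLE"
  v <- r$reactivity[reliable]
  pos <- r$position[reliable]
  n <- length(v)
  if (n < 10L) {
    stop("insufficient data for normalization: ", n,
         " reliable value(s), need at least 10")
  }

  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  q1 <- q[[1L]]; q3 <- q[[2L]]
  iqr <- q3 - q1
  up <- q3 + 1.5 * iqr

  cap_fraction <- if (n > 100L) 0.10 else 0.05
  max_outliers <- floor(cap_fraction * n)
  cand <- which(v > up)
  if (length(cand) > max_outliers) {
    ord <- cand[order(-v[cand], pos[cand])]
    cand <- ord[seq_len(max_outliers)]
  }
  is_outlier <- logical(n)
  is_outlier[cand] <- TRUE

  keep <- v[!is_outlier]
  k <- max(1L, ceiling(0.08 * length(keep)))
  effective_max <- mean(sort(keep, decreasing = TRUE)[seq_len(k)])
  if (!is.finite(effective_max) || effective_max <= 0) {
    stop("non-positive scale: effective maximum reactivity is ",
         format(effective_max))
  }

  value <- rep(NA_real_, nrow(r))
  value[reliable] <- v / effective_max
  diagnostics <- list(q1 = q1, q3 = q3, iqr = iqr, upper_extreme = up,
                      outlier_positions = sort(pos[is_outlier]),
                      effective_max = effective_max,
                      cap_fraction = cap_fraction, n_included = n,
                      top8_count = k)
  profile <- structure(
    list(values = data.frame(position = r$position, value = value,
                             bin = NA_character_, stringsAsFactors = FALSE),
         diagnostics = diagnostics, label = exp$label),
    class = "normalized_profile")
  assign_color_bins(profile, thresholds)
}

#' @export
print.normalized_profile <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<normalized_profile '%s'> %d positions (%d normalized), eff. max %.4g, %d outlier(s)\n",
    x$label %||% "", nrow(x$values), sum(!is.na(x$values$value)),
    d$effective_max, length(d$outlier_positions)))
  invisible(x)
}

#' Assign reactivity color bins
#'
#' Partitions normalized reactivities into the three display bins used
#' for bar plots and spreadsheet rows: `LOW` (black) below `t1`, `MID`
#' (orange) in `[t1, t2)`, and `HIGH` (red) at or above `t2`; defaults
#' `t1 = 0.4`, `t2 = 0.85`, half-open on the left. Negative values fall
#' in `LOW`; missing values stay missing.
#'
#' @param profile A `normalized_profile`.
#' @param thresholds Numeric pair `c(t1, t2)` with `t1 < t2`.
#' @return The profile with its `bin` column (re)assigned.
#' @export
assign_color_bins <- function(profile, thresholds = c(0.4, 0.85)) {
  stopifnot(inherits(profile, "normalized_profile"), length(thresholds) == 2L)
  t1 <- thresholds[[1L]]; t2 <- thresholds[[2L]]
  if (t1 >= t2) stop("validation error: thresholds must satisfy t1 < t2")
  v <- profile$values$value
  bin <- ifelse(is.na(v), NA_character_,
                ifelse(v < t1, "LOW", ifelse(v < t2, "MID", "HIGH")))
  profile$values$bin <- bin
  profile$thresholds <- c(t1, t2)
  profile
}

#' Restrict a DMS experiment to adenosine/cytidine positions
#'
#' DMS methylates the Watson-Crick edge of unpaired A and C residues
#' only, so G/U read-outs carry no structural signal. When enabled, all
#' non-A/C positions are flagged missing before strong-stop detection and
#' normalization, so quartiles and the effective maximum are computed
#' over A/C data only. Disabled, the experiment passes through unchanged.
#'
#' @param exp A `probing_experiment` with `reagent == "DMS"`.
#' @param enabled Apply the restriction? Default `TRUE`.
#' @return The (possibly restricted) experiment.
#' @export
dms_position_filter <- function(exp, enabled = TRUE) {
  stopifnot(inherits(exp, "probing_experiment"))
  if (!enabled) return(exp)
  if (exp$reagent != "DMS") {
    stop("validation error: A/C restriction applies to DMS experiments only")
  }
  drop <- !exp$records$base %in% c("A", "C")
  exp$records$missing[drop] <- TRUE
  exp
}
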