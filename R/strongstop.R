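#' Automated detection of reverse-transcriptase strong-stops
#'
#' Classifies every nucleotide position of an experiment as `RELIABLE` or
#' `EXCLUDED`. A position is excluded when the first of these criteria
#' fires (evaluated in order, the first match recorded as the reason):
#'
#' 1. `NEGATIVE_REACTIVITY` — the absolute reactivity is negative;
#' 2. `HIGH_BACKGROUND` — the background peak area is at least five times
#'    the average background peak area (`bg >= 5 * mean_bg`, inclusive);
#' 3. `LOW_DIFFERENCE` — the reaction-minus-background peak-area
#'    difference is below 35% of the average background peak area *and*
#'    the background peak area is at least that average.
#'
#' `mean_bg` is the arithmetic mean of the background peak areas over all
#' non-missing records, computed once before any exclusion (single pass,
#' no iteration). Records flagged missing on input are excluded with
#' reason `MISSING_INPUT`.
#'
#' @param exp A `probing_experiment`.
#' @return A `strongstop_mask`: data frame with columns `position`,
#'   `flag` (`"RELIABLE"`/`"EXCLUDED"`) and `reason` (`NA` for reliable
#'   positions), with the shared `mean_bg` stored as an attribute.
#' @export
detect_strong_stops_auto <- function(exp) {
  stopifnot(inherits(exp, "probing_experiment"))
  r <- exp$records
  ok <- !r$missing & !is.na(r$bg_area)
  if (!any(ok)) stop("no background data: all records are missing")
  mean_bg <- mean(r$bg_area[ok])

  n <- nrow(r)
  flag <- rep("RELIABLE", n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (r$missing[i]) {
      flag[i] <- "EXCLUDED"; reason[i] <- "MISSING_INPUT"
    } else if (r$reactivity[i] < 0) {
      flag[i] <- "EXCLUDED"; reason[i] <- "NEGATIVE_REACTIVITY"
    } else if (r$bg_area[i] >= 5 * mean_bg) {
      flag[i] <- "EXCLUDED"; reason[i] <- "HIGH_BACKGROUND"
    } else if ((r$rx_area[i] - r$bg_area[i]) < 0.35 * mean_bg &&
               r$bg_area[i] >= mean_bg) {
      flag[i] <- "EXCLUDED"; reason[i] <- "LOW_DIFFERENCE"
    }
  }
  new_strongstop_mask(r$position, flag, reason, mean_bg)
}

new_strongstop_mask <- function(position, flag, reason, mean_bg) {
  structure(data.frame(position = position, flag = flag, reason = reason,
                       stringsAsFactors = FALSE),
            mean_bg = mean_bg, class = c("strongstop_mask", "data.frame"))
}

#' @export
print.strongstop_mask <- function(x, ...) {
  cat(sprintf("<strongstop_mask> %d positions, %d excluded (mean_bg = %.4g)\n",
              nrow(x), sum(x$flag == "EXCLUDED"), attr(x, "mean_bg")))
  tab <- table(x$reason[x$flag == "EXCLUDED"])
  if (length(tab)) print(tab)
  invisible(x)
}

#' Construct a manual strong-stop policy
#'
#' @param negative_threshold Reactivities below this value are treated as
#'   negative (default 0).
#' @param negative_treatment How to treat them: `"keep"` (leave as-is),
#'   `"zero"` (set to 0), or `"nodata"` (exclude as missing data).
#' @param positions Integer positions the user marks as strong-stops.
#' @return A `manual_policy` list.
#' @export
manual_policy <- function(negative_threshold = 0,
                          negative_treatment = c("keep", "zero", "nodata"),
                          positions = integer()) {
  structure(list(negative_threshold = negative_threshold,
                 negative_treatment = match.arg(negative_treatment),
                 positions = as.integer(positions)),
            class = "manual_policy")
}

#' Apply a manual strong-stop policy
#'
#' User-selected positions are excluded with reason `MANUAL`. Reactivities
#' below the policy's negative threshold are then handled per the chosen
#' treatment: kept unchanged, set to zero, or excluded as no-data (reason
#' `NEGATIVE_REACTIVITY`). All other positions stay reliable and
#' unchanged; records missing on input are excluded as `MISSING_INPUT`.
#'
#' @param exp A `probing_experiment`.
#' @param policy A [manual_policy()].
#' @return List with elements `mask` (a `strongstop_mask`) and
#'   `experiment` (the input with adjusted reactivities).
#' @export
apply_manual_policy <- function(exp, policy) {
  stopifnot(inherits(exp, "probing_experiment"), inherits(policy, "manual_policy"))
  r <- exp$records
  absent <- setdiff(policy$positions, r$position)
  if (length(absent)) {
    stop("validation error: selected position(s) absent from experiment: ",
         paste(absent, collapse = ", "))
  }
  ok <- !r$missing & !is.na(r$bg_area)
  mean_bg <- if (any(ok)) mean(r$bg_area[ok]) else NA_real_

  n <- nrow(r)
  flag <- rep("RELIABLE", n)
  reason <- rep(NA_character_, n)
  flag[r$missing] <- "EXCLUDED"; reason[r$missing] <- "MISSING_INPUT"
  sel <- r$position %in% policy$positions
  flag[sel] <- "EXCLUDED"; reason[sel] <- "MANUAL"

  neg <- !r$missing & !sel & r$reactivity < policy$negative_threshold
  if (policy$negative_treatment == "zero") {
    r$reactivity[neg] <- 0
  } else if (policy$negative_treatment == "nodata") {
    flag[neg] <- "EXCLUDED"; reason[neg] <- "NEGATIVE_REACTIVITY"
  }
  exp$records <- r
  list(mask = new_strongstop_mask(r$position, flag, reason, mean_bg),
       experiment = exp)
}

#' Aligned background/reaction peak-area series for the manual view
#'
#' Returns the per-position series backing the histogram a user inspects
#' when selecting strong-stops by hand. Missing records yield `NA` gaps,
#' never zeros.
#'
#' @param exp A `probing_experiment`.
#' @return Data frame with columns `position`, `bg_area`, `rx_area`.
#' @export
histogram_data <- function(exp) {
  stopifnot(inherits(exp, "probing_experiment"))
  r <- exp$records
  data.frame(position = r$position,
             bg_area = ifelse(r$missing, NA_real_, r$bg_area),
             rx_area = ifelse(r$missing, NA_real_, r$rx_area))
}

#' Binary classification quality metrics
#'
#' Computes accuracy, precision, sensitivity and specificity from a
#' confusion matrix of reliable-vs-strong-stop calls:
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `PPV = TP/(TP+FP)`, `TPR = TP/(TP+FN)`,
#' `TNR = TN/(TN+FP)`. A rate whose denominator is zero is reported as
#' `NA` (not applicable), never as 0.
#'
#' @param tp,tn,fp,fn Non-negative integer counts; their total must be
#'   positive.
#' @return A `classification_metrics` list with the counts and the four
#'   rates at full precision. `print()` renders the rates to two decimals.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("validation error: negative count")
  total <- sum(counts)
  if (total == 0) stop("validation error: all counts are zero")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 acc = rate(tp + tn, total),
                 ppv = rate(tp, tp + fp),
                 tpr = rate(tp, tp + fn),
                 tnr = rate(tn, tn + fp)),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n/a" else formatC(round(v, 2), format = "g")
  cat(sprintf("TP %d  TN %d  FP %d  FN %d\nACC %s  PPV %s  TPR %s  TNR %s\n",
              x$tp, x$tn, x$fp, x$fn,
              fmt(x$acc), fmt(x$ppv), fmt(x$tpr), fmt(x$tnr)))
  invisible(x)
}

#' Write an exclusion log as TSV
#'
#' One row per excluded position: position, reason, and the triggering
#' values (reactivity, background and reaction peak areas, mean_bg).
#'
#' @param exp A `probing_experiment`.
#' @param mask The corresponding `strongstop_mask`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_exclusion_log <- function(exp, mask, path) {
  r <- exp$records
  ex <- mask$flag == "EXCLUDED"
  df <- data.frame(position = mask$position[ex], reason = mask$reason[ex],
                   reactivity = r$reactivity[ex], rx_area = r$rx_area[ex],
                   bg_area = r$bg_area[ex],
                   mean_bg = rep(attr(mask, "mean_bg"), sum(ex)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
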