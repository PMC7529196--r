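#' Specification for a synthetic CE probing experiment
#'
#' Describes a deterministic synthetic peak-area table with planted RT
#' strong-stops whose classification is guaranteed by construction: each
#' planted stop satisfies its criterion with at least a 10% margin, and
#' each clean position violates every criterion with at least a 10%
#' margin, so the automated classifier must recover the planted mask
#' exactly. Planting modes:
#'
#' * `NEGATIVE` — reaction area below background (negative reactivity);
#' * `HIGH_BG` — background at 5.5x the average background;
#' * `HIGH_BG_BOUNDARY` — background at exactly 5x the average
#'   (adversarial: pins the inclusive >= 5x decision, margin waived);
#' * `LOW_DIFF` — background at 1.5x the average with a
#'   reaction-background difference of 0.2x the average.
#'
#' Background areas are gamma-distributed (mean `bg_mean`, shape
#' `bg_shape`), truncated to `[0.5, 2] * bg_mean` so that no clean
#' position can stray into strong-stop territory. Reliable positions
#' carry a background-subtracted signal of
#' `(0.45 + intended reactivity) * mean_bg`, i.e. a baseline offset plus
#' the intended profile, which keeps every clean position clear of the
#' low-difference criterion. Planted background levels are solved jointly
#' with the background mean in closed form, so the realized mean equals
#' the design mean exactly.
#'
#' @param length Number of nucleotides (a typical CE read resolves
#'   300-600; default 300).
#' @param seed Integer seed; the same spec and seed reproduce the same
#'   experiment byte for byte.
#' @param bg_mean,bg_shape Gamma parameters of the background peak-area
#'   distribution (arbitrary fluorescence units).
#' @param reactivity_profile Optional numeric vector of intended
#'   normalized reactivities in `[0, 1.5]`, one per position; drawn from
#'   a right-skewed gamma (capped at 1.5) when `NULL`.
#' @param planted_stops Data frame with columns `position` and `mode`,
#'   or `NULL` for none.
#' @param replicate_noise_sd Log-normal noise sd on the signal, applied
#'   per replicate; 0 makes replicates identical.
#' @param reagent `"SHAPE"` or `"DMS"`.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(length = 300L, seed = 1L,
                           bg_mean = 100, bg_shape = 8,
                           reactivity_profile = NULL,
                           planted_stops = NULL,
                           replicate_noise_sd = 0.1,
                           reagent = c("SHAPE", "DMS")) {
  reagent <- match.arg(reagent)
  if (is.null(planted_stops)) {
    planted_stops <- data.frame(position = integer(), mode = character())
  }
  modes <- c("NEGATIVE", "HIGH_BG", "HIGH_BG_BOUNDARY", "LOW_DIFF")
  stopifnot(length >= 1L, bg_mean > 0, bg_shape > 0,
            replicate_noise_sd >= 0,
            all(planted_stops$mode %in% modes),
            all(planted_stops$position >= 1L),
            all(planted_stops$position <= length),
            !anyDuplicated(planted_stops$position))
  if (!is.null(reactivity_profile)) {
    stopifnot(length(reactivity_profile) == length,
              all(reactivity_profile >= 0), all(reactivity_profile <= 1.5))
  }
  structure(list(length = as.integer(length), seed = as.integer(seed),
                 bg_mean = bg_mean, bg_shape = bg_shape,
                 reactivity_profile = reactivity_profile,
                 planted_stops = planted_stops,
                 replicate_noise_sd = replicate_noise_sd,
                 reagent = reagent),
            class = "synthetic_spec")
}

#' Generate a synthetic experiment with its ground-truth mask
#'
#' Deterministic for a fixed spec, seed and replicate index; different
#' replicate indices share the same background and intended reactivity
#' profile and differ only in signal noise.
#'
#' @param spec A [synthetic_spec()].
#' @param replicate Replicate index (1-based).
#' @return List with `experiment` (a `probing_experiment`), `mask` (the
#'   ground-truth `strongstop_mask`), and `intended` (the intended
#'   reactivity profile).
#' @export
generate_experiment <- function(spec, replicate = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), replicate >= 1L)
  L <- spec$length
  st <- spec$planted_stops
  mode <- rep("CLEAN", L)
  mode[st$position] <- st$mode

  set.seed(spec$seed)
  intended <- spec$reactivity_profile %||%
    pmin(stats::rgamma(L, shape = 0.7, scale = 0.5), 1.5)
  bg_draw <- pmin(pmax(stats::rgamma(L, shape = spec$bg_shape,
                                     scale = spec$bg_mean / spec$bg_shape),
                       0.5 * spec$bg_mean), 2 * spec$bg_mean)
  bases <- draw_bases(L, intended)

  # solve the design background mean m jointly with the planted levels:
  # planted HIGH_BG backgrounds are 5.5 m (boundary: 5 m), LOW_DIFF 1.5 m
  factor <- c(HIGH_BG = 5.5, HIGH_BG_BOUNDARY = 5.0, LOW_DIFF = 1.5)
  own_bg <- !mode %in% names(factor)
  denom <- L - sum(factor[mode[!own_bg]])
  if (denom <= 0) {
    stop("margins unachievable: too many high-background stops for length ", L)
  }
  m <- sum(bg_draw[own_bg]) / denom
  bg <- bg_draw
  bg[!own_bg] <- factor[mode[!own_bg]] * m

  set.seed(spec$seed + 97L * as.integer(replicate))
  f <- exp(stats::rnorm(L, 0, spec$replicate_noise_sd))
  f <- pmin(pmax(f, 0.87), 1.15)

  diff <- (0.45 + intended) * m * f
  diff[mode == "LOW_DIFF"] <- 0.2 * m * f[mode == "LOW_DIFF"]
  diff[mode == "NEGATIVE"] <- -0.3 * m * f[mode == "NEGATIVE"]
  rx <- pmax(bg + diff, 0.05 * bg)

  records <- data.frame(
    position = seq_len(L),
    base = bases,
    rx_area = rx, bg_area = bg, reactivity = rx - bg,
    missing = FALSE, stringsAsFactors = FALSE)

  check_margins(records, mode, margin = 0.10)

  flag <- ifelse(mode == "CLEAN", "RELIABLE", "EXCLUDED")
  reason <- rep(NA_character_, L)
  reason[mode == "NEGATIVE"] <- "NEGATIVE_REACTIVITY"
  reason[mode %in% c("HIGH_BG", "HIGH_BG_BOUNDARY")] <- "HIGH_BACKGROUND"
  reason[mode == "LOW_DIFF"] <- "LOW_DIFFERENCE"

  exp <- new_probing_experiment(
    records, reagent = spec$reagent, dialect = "qushape",
    label = sprintf("synthetic_seed%d_rep%d", spec$seed, replicate))
  list(experiment = exp,
       mask = new_strongstop_mask(records$position, flag, reason,
                                  mean(records$bg_area)),
       intended = intended)
}

# Base composition: reactive positions lean A/C-rich so DMS fixtures keep
# signal under the A/C restriction.
draw_bases <- function(L, intended) {
  reactive <- intended > stats::median(intended)
  probs <- ifelse(reactive, 0.7, 0.4)
  ac <- stats::runif(L) < probs
  out <- character(L)
  out[ac] <- sample(c("A", "C"), sum(ac), replace = TRUE)
  out[!ac] <- sample(c("G", "U"), sum(!ac), replace = TRUE)
  out
}

# Verify every planted stop meets its criterion and every clean position
# misses all of them, with the stated relative margin (boundary-mode
# high-background stops sit exactly on the 5x line by design).
check_margins <- function(records, mode, margin = 0.10) {
  mb <- mean(records$bg_area)
  diff <- records$rx_area - records$bg_area
  for (i in seq_len(nrow(records))) {
    ok <- switch(mode[[i]],
      CLEAN = records$reactivity[[i]] > 0 &&
        records$bg_area[[i]] <= (5 - margin * 5) * mb &&
        (diff[[i]] >= (1 + margin) * 0.35 * mb ||
           records$bg_area[[i]] <= (1 - margin) * mb),
      NEGATIVE = records$reactivity[[i]] <= -margin * 0.35 * mb,
      HIGH_BG = records$bg_area[[i]] >= (5 + margin) * mb,
      HIGH_BG_BOUNDARY = records$bg_area[[i]] >= 5 * mb,
      LOW_DIFF = diff[[i]] >= 0 &&
        diff[[i]] <= (1 - margin) * 0.35 * mb &&
        records$bg_area[[i]] >= (1 + margin) * mb)
    if (!ok) {
      stop("margins unachievable at position ", records$position[[i]],
           " (mode ", mode[[i]], ")")
    }
  }
  invisible(TRUE)
}

#' Scatter planted stops across all three modes
#'
#' Convenience constructor: places `n` stops at evenly spread positions
#' cycling through the NEGATIVE, HIGH_BG and LOW_DIFF modes.
#'
#' @param length Experiment length.
#' @param n Number of stops.
#' @return Data frame suitable for [synthetic_spec()]'s `planted_stops`.
#' @export
spread_stops <- function(length, n) {
  stopifnot(n >= 1L, n <= length)
  pos <- unique(round(seq(2, length - 1, length.out = n)))
  data.frame(position = as.integer(pos),
             mode = rep(c("NEGATIVE", "HIGH_BG", "LOW_DIFF"),
                        length.out = length(pos)))
}

#' Write a synthetic experiment as an upstream-dialect fixture file
#'
#' Emits a table that [parse_probing_file()] reads back with round-trip
#' equality of every field, including missing flags (missing records get
#' blank area fields). The generator seed is recorded in a leading
#' comment line.
#'
#' @param exp A `probing_experiment`.
#' @param dialect `"qushape"` (header-bearing) or `"shapefinder"`
#'   (headerless positional).
#' @param path Output path.
#' @param comment Optional comment line (written with a leading `#`).
#' @return The path, invisibly.
#' @export
write_fixture <- function(exp, dialect = c("qushape", "shapefinder"),
                          path, comment = NULL) {
  dialect <- match.arg(dialect)
  r <- exp$records
  num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  lines <- character()
  if (!is.null(comment)) lines <- paste0("# ", comment)
  if (dialect == "qushape") {
    lines <- c(lines, "seqNum\tseqRNA\tareaRX\tareaBG\tareaDiff")
  }
  rx <- r$rx_area; bg <- r$bg_area; re <- r$reactivity
  rx[r$missing] <- NA; bg[r$missing] <- NA; re[r$missing] <- NA
  lines <- c(lines, sprintf("%d\t%s\t%s\t%s\t%s",
                            r$position, r$base, num(rx), num(bg), num(re)))
  writeLines(lines, path)
  invisible(path)
}
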