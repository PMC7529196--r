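# Builders -------------------------------------------------------------

make_experiment <- function(reactivity = NULL, bg = NULL, rx = NULL,
                            base = NULL, missing = NULL,
                            reagent = "SHAPE", label = "test") {
  n <- max(length(reactivity), length(bg), length(rx))
  bg <- bg %||% rep(1, n)
  rx <- rx %||% (bg + (reactivity %||% rep(1, n)))
  reactivity <- reactivity %||% (rx - bg)
  ceprobe:::new_probing_experiment(
    data.frame(position = seq_len(n),
               base = base %||% rep("A", n),
               rx_area = rx, bg_area = bg, reactivity = reactivity,
               missing = missing %||% rep(FALSE, n),
               stringsAsFactors = FALSE),
    reagent = reagent, dialect = "qushape", label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

all_reliable_mask <- function(n, mean_bg = 1) {
  ceprobe:::new_strongstop_mask(seq_len(n), rep("RELIABLE", n),
                                rep(NA_character_, n), mean_bg)
}

make_profile <- function(values, label = "p", positions = seq_along(values)) {
  structure(list(values = data.frame(position = positions, value = values,
                                     bin = NA_character_,
                                     stringsAsFactors = FALSE),
                 diagnostics = list(), label = label),
            class = "normalized_profile")
}

random_experiment <- function(n = sample(5:50, 1)) {
  bg <- stats::runif(n, 0.1, 10)
  rx <- stats::runif(n, 0, 15)
  miss <- stats::runif(n) < 0.05
  make_experiment(reactivity = rx - bg, bg = bg, rx = rx, missing = miss)
}

# Independent oracles ---------------------------------------------------

# Literal transcription of the three exclusion criteria: the average
# background is taken once over non-missing records; a position is
# excluded if its reactivity is negative, OR its background is at least
# five times the average background, OR its reaction-background
# difference is below 35% of the average background while its background
# is at least that average. First matching criterion is the reason.
oracle_strongstop <- function(exp) {
  r <- exp$records
  avg_bg <- mean(r$bg_area[!r$missing & !is.na(r$bg_area)])
  flag <- character(nrow(r)); reason <- rep(NA_character_, nrow(r))
  for (i in seq_len(nrow(r))) {
    if (r$missing[i]) { flag[i] <- "EXCLUDED"; reason[i] <- "MISSING_INPUT"; next }
    c1 <- r$reactivity[i] < 0
    c2 <- r$bg_area[i] >= 5 * avg_bg
    c3 <- (r$rx_area[i] - r$bg_area[i]) < 0.35 * avg_bg && r$bg_area[i] >= avg_bg
    if (c1 || c2 || c3) {
      flag[i] <- "EXCLUDED"
      reason[i] <- if (c1) "NEGATIVE_REACTIVITY" else if (c2) "HIGH_BACKGROUND" else "LOW_DIFFERENCE"
    } else flag[i] <- "RELIABLE"
  }
  list(flag = flag, reason = reason, mean_bg = avg_bg)
}

# Brute-force transcription of the box-plot normalization text: type-7
# quartiles, UP = Q3 + 1.5 IQR, outliers above UP capped at 10% (n > 100)
# or 5% of the data keeping the largest, effective maximum = mean of the
# top 8% (ceiling, min 1) of non-outliers, every value divided by it.
oracle_normalize <- function(v, pos = seq_along(v)) {
  n <- length(v)
  q <- unname(stats::quantile(v, c(0.25, 0.75), type = 7))
  up <- q[2] + 1.5 * (q[2] - q[1])
  cap <- if (n > 100) 0.10 else 0.05
  cand <- which(v > up)
  limit <- floor(cap * n)
  if (length(cand) > limit) {
    cand <- cand[order(-v[cand], pos[cand])][seq_len(limit)]
  }
  keep <- v[setdiff(seq_len(n), cand)]
  k <- max(1, ceiling(0.08 * length(keep)))
  eff <- mean(sort(keep, decreasing = TRUE)[seq_len(k)])
  list(normalized = v / eff, effective_max = eff,
       outlier_positions = sort(pos[cand]), upper_extreme = up,
       cap_fraction = cap)
}

# Deterministic distribution fixtures (no randomness: quantile grids)
normal_sample <- function(n = 50, mean = 0.5, sd = 0.15) {
  mean + sd * stats::qnorm(stats::ppoints(n))
}
skewed_sample <- function(n = 60, rate = 2) {
  stats::qexp(stats::ppoints(n), rate = rate)
}
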