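test_that("no criterion fires on clean uniform data", {
  exp <- make_experiment(reactivity = rep(1, 10), bg = rep(1, 10), rx = rep(2, 10))
  mask <- detect_strong_stops_auto(exp)
  expect_true(all(mask$flag == "RELIABLE"))
  expect_equal(attr(mask, "mean_bg"), 1)
})

test_that("negative reactivity is excluded first", {
  reac <- c(rep(1, 9), -0.1)
  exp <- make_experiment(reactivity = reac, bg = rep(1, 10), rx = 1 + reac)
  mask <- detect_strong_stops_auto(exp)
  expect_identical(mask$flag, c(rep("RELIABLE", 9), "EXCLUDED"))
  expect_identical(mask$reason[10], "NEGATIVE_REACTIVITY")
})

test_that("the five-times-average background criterion is inclusive", {
  # bg (1,...,1,9): mean_bg 1.8, 5*mean_bg = 9.0, so bg = 9 is excluded
  bg <- c(rep(1, 9), 9)
  exp <- make_experiment(bg = bg, rx = rep(3, 10), reactivity = 3 - bg)
  mask <- detect_strong_stops_auto(exp)
  expect_equal(attr(mask, "mean_bg"), 1.8)
  expect_identical(mask$flag, c(rep("RELIABLE", 9), "EXCLUDED"))
  # same geometry with positive reactivity isolates the background reason
  exp2 <- make_experiment(bg = bg, rx = bg + 2, reactivity = rep(2, 10))
  mask2 <- detect_strong_stops_auto(exp2)
  expect_identical(mask2$reason[10], "HIGH_BACKGROUND")
  expect_identical(mask2$flag[10], "EXCLUDED")
})

test_that("the low-difference criterion needs both small diff and high background", {
  # mean_bg 2: diff 0.5 < 0.35*2 = 0.7 with bg >= mean -> excluded;
  # diff 1.0 >= 0.7 -> reliable
  exp <- make_experiment(bg = rep(2, 10),
                         rx = c(2.5, rep(3.0, 9)),
                         reactivity = c(0.5, rep(1.0, 9)))
  mask <- detect_strong_stops_auto(exp)
  expect_identical(mask$flag[1], "EXCLUDED")
  expect_identical(mask$reason[1], "LOW_DIFFERENCE")
  expect_true(all(mask$flag[-1] == "RELIABLE"))
  # small diff but background below the average stays reliable
  exp2 <- make_experiment(bg = c(0.5, rep(2, 9)),
                          rx = c(0.6, rep(3, 9)),
                          reactivity = c(0.1, rep(1, 9)))
  expect_identical(detect_strong_stops_auto(exp2)$flag[1], "RELIABLE")
})

test_that("missing records are excluded as missing input; all-missing errors", {
  exp <- make_experiment(reactivity = rep(1, 5), missing = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  mask <- detect_strong_stops_auto(exp)
  expect_identical(mask$reason[2], "MISSING_INPUT")
  exp_all <- make_experiment(reactivity = rep(1, 3), missing = rep(TRUE, 3))
  expect_error(detect_strong_stops_auto(exp_all), "no background data")
})

test_that("classifier agrees exactly with the literal criteria transcription", {
  set.seed(101)
  for (i in 1:200) {
    exp <- random_experiment()
    if (all(exp$records$missing)) next
    mask <- detect_strong_stops_auto(exp)
    oracle <- oracle_strongstop(exp)
    expect_identical(mask$flag, oracle$flag)
    expect_identical(mask$reason, oracle$reason)
    expect_equal(attr(mask, "mean_bg"), oracle$mean_bg)
  }
})

test_that("the mask is invariant under rescaling all areas", {
  set.seed(7)
  exp <- random_experiment(40)
  base_mask <- detect_strong_stops_auto(exp)
  for (c in c(1e-3, 0.5, 7, 1e4)) {
    scaled <- exp
    scaled$records$rx_area <- c * exp$records$rx_area
    scaled$records$bg_area <- c * exp$records$bg_area
    scaled$records$reactivity <- c * exp$records$reactivity
    m <- detect_strong_stops_auto(scaled)
    expect_identical(m$flag, base_mask$flag)
    expect_identical(m$reason, base_mask$reason)
  }
})

test_that("raising one background (mean held fixed) never rescues a position", {
  set.seed(13)
  for (trial in 1:50) {
    exp <- random_experiment(20)
    exp$records$missing[] <- FALSE
    i <- sample(20, 1)
    j <- sample(setdiff(1:20, i), 1)
    bump <- stats::runif(1, 0.01, min(2, exp$records$bg_area[j] * 0.9))
    before <- oracle_strongstop(exp)$flag[i]
    exp2 <- exp
    exp2$records$bg_area[i] <- exp$records$bg_area[i] + bump
    exp2$records$bg_area[j] <- exp$records$bg_area[j] - bump  # mean_bg unchanged
    exp2$records$reactivity[i] <- exp2$records$rx_area[i] - exp2$records$bg_area[i]
    after <- detect_strong_stops_auto(exp2)$flag[i]
    if (before == "EXCLUDED") expect_identical(after, "EXCLUDED")
  }
})

test_that("manual policy implements the three negative-value treatments", {
  exp <- make_experiment(reactivity = c(0.5, -0.2, 1.0))
  nd <- apply_manual_policy(exp, manual_policy(0, "nodata"))
  expect_identical(nd$mask$flag, c("RELIABLE", "EXCLUDED", "RELIABLE"))
  expect_identical(nd$mask$reason[2], "NEGATIVE_REACTIVITY")

  z <- apply_manual_policy(exp, manual_policy(0, "zero"))
  expect_true(all(z$mask$flag == "RELIABLE"))
  expect_equal(z$experiment$records$reactivity, c(0.5, 0, 1.0))

  k <- apply_manual_policy(exp, manual_policy(0, "keep", positions = 3))
  expect_identical(k$mask$flag, c("RELIABLE", "RELIABLE", "EXCLUDED"))
  expect_identical(k$mask$reason[3], "MANUAL")
  expect_equal(k$experiment$records$reactivity[2], -0.2)  # kept

  expect_error(apply_manual_policy(exp, manual_policy(positions = 9)),
               "absent.*9")
})

test_that("manual policy honors a non-zero negative threshold", {
  exp <- make_experiment(reactivity = c(0.05, 0.5, -0.3))
  out <- apply_manual_policy(exp, manual_policy(0.1, "zero"))
  expect_equal(out$experiment$records$reactivity, c(0, 0.5, 0))
})

test_that("histogram series align with positions and gap at missing records", {
  exp <- make_experiment(reactivity = rep(1, 3), missing = c(FALSE, TRUE, FALSE))
  h <- histogram_data(exp)
  expect_equal(h$position, 1:3)
  expect_true(is.na(h$bg_area[2]) && is.na(h$rx_area[2]))
  expect_false(anyNA(h$bg_area[-2]))
})

test_that("classification metrics reproduce the published confusion-matrix rates", {
  shape <- classification_metrics(2462, 38, 0, 32)
  expect_equal(round(shape$acc, 2), 0.99)
  expect_equal(shape$ppv, 1)
  expect_equal(round(shape$tpr, 2), 0.99)
  expect_equal(shape$tnr, 1)
  dms <- classification_metrics(2431, 35, 0, 25)
  expect_equal(round(dms$acc, 2), 0.99)
  expect_equal(dms$ppv, 1)
  expect_equal(round(dms$tpr, 2), 0.99)
  expect_equal(dms$tnr, 1)
})

test_that("zero-denominator rates are not-applicable, never zero", {
  m <- classification_metrics(1, 0, 0, 0)
  expect_equal(m$acc, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$tpr, 1)
  expect_true(is.na(m$tnr))
  expect_error(classification_metrics(0, 0, 0, 0), "all counts")
})

test_that("the exclusion log lists excluded positions with triggering values", {
  bg <- c(rep(1, 9), 9)
  exp <- make_experiment(bg = bg, rx = bg + c(rep(2, 9), -10),
                         reactivity = c(rep(2, 9), -10))
  mask <- detect_strong_stops_auto(exp)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_exclusion_log(exp, mask, path)
  log <- utils::read.delim(path)
  expect_equal(log$position, 10)
  expect_identical(log$reason, "NEGATIVE_REACTIVITY")
  expect_equal(log$mean_bg, 1.8)
})
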