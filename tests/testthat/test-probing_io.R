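test_that("qushape tables parse with direct column mapping", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("seqNum\tseqRNA\tareaRX\tareaBG\tareaDiff",
               sprintf("%d\t%s\t%g\t%g\t%g", 1:5, c("A", "C", "G", "U", "A"),
                       c(2, 3, 4, 5, 6), c(1, 1, 2, 2, 3), c(1, 2, 2, 3, 3))),
             path)
  exp <- parse_probing_file(path)
  expect_s3_class(exp, "probing_experiment")
  expect_identical(exp$dialect, "qushape")
  expect_equal(nrow(exp$records), 5L)
  expect_equal(exp$records$reactivity, c(1, 2, 2, 3, 3))  # taken from areaDiff
  expect_equal(exp$records$base, c("A", "C", "G", "U", "A"))
})

test_that("rows with blank areas are flagged missing, never dropped", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("seqNum\tseqRNA\tareaRX\tareaBG\tareaDiff",
               "1\tA\t2\t1\t1",
               "2\tC\t\t1\t",            # blank areaRX
               "3\tG\t4\t2\t2"),
             path)
  exp <- parse_probing_file(path)
  expect_equal(nrow(exp$records), 3L)
  expect_equal(exp$records$missing, c(FALSE, TRUE, FALSE))
})

test_that("duplicate positions raise a validation error naming the position", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("seqNum\tseqRNA\tareaRX\tareaBG\tareaDiff",
               "1\tA\t2\t1\t1", "2\tC\t3\t1\t2", "2\tG\t4\t2\t2", "3\tU\t5\t2\t3"),
             path)
  expect_error(parse_probing_file(path), "duplicate position.*2")
})

test_that("shapefinder tables parse positionally, with or without a label row", {
  body <- sprintf("%d\tA\t%g\t%g\t%g", 1:6, 7:12, rep(2, 6), 5:10)
  for (header in list(character(), "Pos\tBase\tRX\tBG\tReact")) {
    path <- withr::local_tempfile(fileext = ".txt")
    writeLines(c(header, body), path)
    exp <- parse_probing_file(path)
    expect_identical(exp$dialect, "shapefinder")
    expect_equal(exp$records$rx_area, as.numeric(7:12))
    expect_equal(exp$records$reactivity, as.numeric(5:10))
  }
})

test_that("reactivity falls back to rx minus bg when the column is absent", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("seqNum\tseqRNA\tareaRX\tareaBG",
               "1\tA\t2.5\t1", "2\tC\t0.5\t1"), path)
  exp <- parse_probing_file(path)
  expect_equal(exp$records$reactivity, c(1.5, -0.5))
})

test_that("empty and unrecognizable files are rejected with clear errors", {
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), empty)
  expect_error(parse_probing_file(empty), "empty file")
  narrow <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1\tA\t2", "2\tC\t3"), narrow)
  expect_error(parse_probing_file(narrow), "position, base, rx_area, bg_area, reactivity")
})

test_that("sequence validation folds case, converts T to U, checks length", {
  exp8 <- make_experiment(reactivity = rep(1, 8),
                          base = strsplit("ACGUACGU", "")[[1]])
  s <- validate_sequence("ACGUacgu", list(exp8))
  expect_identical(s$residues, "ACGUACGU")
  expect_equal(s$length, 8L)
  expect_identical(validate_sequence("ACGT")$residues, "ACGU")
  # identical verdicts for upper and lower case
  expect_identical(validate_sequence("acgt")$residues,
                   validate_sequence("ACGT")$residues)
  exp5 <- make_experiment(reactivity = rep(1, 5))
  expect_error(validate_sequence("ACGU", list(exp5)), "4.*5|5.*4")
  expect_error(validate_sequence("ACGX"), "not RNA.*X")
})

test_that("base mismatches against the sequence warn but do not fail", {
  exp <- make_experiment(reactivity = rep(1, 4), base = c("A", "A", "G", "U"))
  expect_warning(validate_sequence("ACGU", list(exp)), "mismatch")
})

test_that(".shape writer renders the exact two-column contract", {
  path <- withr::local_tempfile(fileext = ".shape")
  prof <- data.frame(position = 1:3, value = c(0.5, NA, 1.2))
  write_shape(prof, path)
  expect_identical(readLines(path), c("1\t0.500", "2\t-999", "3\t1.200"))
})

test_that(".shape writer rejects empty and non-contiguous profiles", {
  path <- withr::local_tempfile(fileext = ".shape")
  expect_error(write_shape(data.frame(position = integer(), value = numeric()),
                           path), "empty profile")
  expect_false(file.exists(path))
  expect_error(write_shape(data.frame(position = c(1L, 3L), value = c(1, 2)),
                           path), "contiguous")
  # pad_profile repairs the gap
  padded <- pad_profile(data.frame(position = c(1L, 3L), value = c(1, 2)))
  write_shape(padded, path)
  expect_identical(readLines(path)[2], "2\t-999")
})

test_that(".shape write -> read is the identity on positions, values, missing set", {
  set.seed(42)
  for (rep in 1:5) {
    vals <- round(stats::runif(30, 0, 2), 3)     # writer precision grid
    vals[sample(30, 4)] <- NA
    path <- withr::local_tempfile(fileext = ".shape")
    write_shape(data.frame(position = 1:30, value = vals), path)
    back <- read_shape(path)
    expect_equal(back$position, 1:30)
    expect_equal(back$value, vals)
    expect_identical(is.na(back$value), is.na(vals))
  }
})

test_that("workbook export writes input, normalized and averaged sheets", {
  n <- 12
  exps <- lapply(1:3, function(i)
    make_experiment(reactivity = stats::runif(n, 0.5, 3), label = paste0("rep", i)))
  profs <- lapply(exps, function(e)
    normalize_profile(e, all_reliable_mask(n)))
  # a position missing in every replicate
  for (i in seq_along(profs)) {
    profs[[i]]$values$value[5] <- NA
    profs[[i]]$values$bin[5] <- NA
  }
  # force one high-reactivity row to pin the bin tag
  profs[[1]]$values$value[2] <- 0.9
  profs[[1]] <- assign_color_bins(profs[[1]])
  avg <- average_profiles(profs)
  dir <- withr::local_tempdir()
  manifest <- export_workbook(exps, profs, avg, dir)
  expect_gte(length(manifest$sheets), 5L)        # 3 input + 3 normalized + averaged
  norm1 <- utils::read.csv(file.path(dir, "normalized_01.csv"))
  expect_identical(norm1$color_bin[2], "HIGH")
  avg_sheet <- utils::read.csv(file.path(dir, "averaged.csv"))
  expect_equal(avg_sheet$mean[5], -999)          # missing code
  expect_true(is.na(avg_sheet$sd[5]))            # SD blank
  expect_error(export_workbook(exps[1:2], profs, avg, dir), "2 experiment")
})
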