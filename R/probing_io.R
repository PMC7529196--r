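#' Parse a ShapeFinder or QuShape peak-area table
#'
#' Reads a tab-delimited per-nucleotide table from one of the two upstream
#' CE signal-processing tools and returns a `probing_experiment`. Two
#' dialects are supported:
#'
#' * **qushape** — a header-bearing table whose columns match
#'   (case-insensitively) `seqNum`/`posSeq`, `seqRNA`, `areaRX`, `areaBG`
#'   and optionally `areaDiff`.
#' * **shapefinder** — a headerless (or label-row-bearing) table of five or
#'   more columns read positionally as
#'   (position, base, rx_area, bg_area, reactivity).
#'
#' When `dialect` is not given, a sniffing pass selects `qushape` if a
#' header row containing `areaRX` is found, else `shapefinder`.
#'
#' Absolute reactivity is taken from the file's reactivity column when
#' present; otherwise it is computed as `rx_area - bg_area`, so that adduct
#' signal above background is positive. Rows whose reaction or background
#' area fails to parse become records flagged missing — they are never
#' dropped, so the record count always equals the data-row count.
#'
#' @param path Path to a tab-delimited text file.
#' @param dialect `"qushape"`, `"shapefinder"`, or `NULL` to sniff.
#' @param reagent Probing reagent: `"SHAPE"`, `"DMS"` or `"OTHER"`.
#' @param label Free-text identifier; defaults to the file name.
#' @return A `probing_experiment`: a list with a `records` data frame
#'   (`position`, `base`, `rx_area`, `bg_area`, `reactivity`, `missing`)
#'   plus `reagent`, `dialect` and `label`.
#' @export
parse_probing_file <- function(path, dialect = NULL,
                               reagent = c("SHAPE", "DMS", "OTHER"),
                               label = NULL) {
  reagent <- match.arg(reagent)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]      # fixture seed comments
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("format error: empty file: ", path)

  if (is.null(dialect)) {
    dialect <- if (grepl("arearx", tolower(lines[[1L]]), fixed = TRUE))
      "qushape" else "shapefinder"
  }
  dialect <- match.arg(dialect, c("qushape", "shapefinder"))

  fields <- strsplit(lines, "\t", fixed = TRUE)

  if (dialect == "qushape") {
    header <- tolower(trimws(fields[[1L]]))
    col_of <- function(names) {
      hit <- which(header %in% tolower(names))
      if (length(hit)) hit[[1L]] else NA_integer_
    }
    pos_col  <- col_of(c("seqnum", "posseq"))
    base_col <- col_of("seqrna")
    rx_col   <- col_of("arearx")
    bg_col   <- col_of("areabg")
    diff_col <- col_of("areadiff")
    if (is.na(pos_col) || is.na(base_col) || is.na(rx_col) || is.na(bg_col)) {
      stop("dialect error: qushape input requires columns ",
           "seqNum|posSeq, seqRNA, areaRX, areaBG (optionally areaDiff); got: ",
           paste(trimws(fields[[1L]]), collapse = ", "))
    }
    rows <- fields[-1L]
    if (length(rows) == 0L) stop("format error: no data rows in ", path)
    get <- function(row, i) if (!is.na(i) && i <= length(row)) trimws(row[[i]]) else ""
    position <- vapply(rows, function(r) suppressWarnings(as.integer(get(r, pos_col))), integer(1))
    base     <- vapply(rows, function(r) get(r, base_col), character(1))
    rx_area  <- vapply(rows, function(r) suppressWarnings(as.numeric(get(r, rx_col))), numeric(1))
    bg_area  <- vapply(rows, function(r) suppressWarnings(as.numeric(get(r, bg_col))), numeric(1))
    reactivity <- vapply(rows, function(r) suppressWarnings(as.numeric(get(r, diff_col))), numeric(1))
  } else {
    # positional; a leading non-numeric row is a label row
    first_num <- suppressWarnings(as.numeric(trimws(fields[[1L]][[1L]])))
    rows <- if (is.na(first_num)) fields[-1L] else fields
    if (length(rows) == 0L) stop("format error: no data rows in ", path)
    if (max(vapply(rows, length, integer(1))) < 5L) {
      stop("dialect error: shapefinder input needs >= 5 tab-separated columns ",
           "(position, base, rx_area, bg_area, reactivity)")
    }
    # blank trailing fields (missing areas) are dropped by strsplit; restore
    rows <- lapply(rows, function(r) c(r, rep("", max(0L, 5L - length(r)))))
    num <- function(i) vapply(rows, function(r)
      suppressWarnings(as.numeric(trimws(r[[i]]))), numeric(1))
    position <- as.integer(num(1L))
    base     <- vapply(rows, function(r) trimws(r[[2L]]), character(1))
    rx_area  <- num(3L)
    bg_area  <- num(4L)
    reactivity <- num(5L)
  }

  if (anyNA(position)) {
    stop("validation error: unparseable position in row(s) ",
         paste(which(is.na(position)), collapse = ", "))
  }
  dup <- unique(position[duplicated(position)])
  if (length(dup)) {
    stop("validation error: duplicate position(s): ", paste(dup, collapse = ", "))
  }
  if (any(position < 1L)) stop("validation error: positions must be >= 1")

  ord <- order(position)
  base <- toupper(base[ord])
  base[base == "T"] <- "U"
  base[!base %in% c("A", "C", "G", "U")] <- "N"

  rx_area <- rx_area[ord]; bg_area <- bg_area[ord]
  reactivity <- reactivity[ord]
  missing <- is.na(rx_area) | is.na(bg_area)
  if (any(!missing & (rx_area < 0 | bg_area < 0))) {
    stop("validation error: negative peak area(s)")
  }
  need <- is.na(reactivity) & !missing
  reactivity[need] <- rx_area[need] - bg_area[need]

  new_probing_experiment(
    data.frame(position = position[ord], base = base, rx_area = rx_area,
               bg_area = bg_area, reactivity = reactivity, missing = missing,
               stringsAsFactors = FALSE),
    reagent = reagent, dialect = dialect,
    label = label %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_probing_experiment <- function(records, reagent, dialect, label) {
  stopifnot(nrow(records) >= 1L)
  structure(list(records = records, reagent = reagent,
                 dialect = dialect, label = label),
            class = "probing_experiment")
}

#' @export
print.probing_experiment <- function(x, ...) {
  cat(sprintf("<probing_experiment '%s'> %d records, reagent %s, dialect %s, %d missing\n",
              x$label, nrow(x$records), x$reagent, x$dialect, sum(x$records$missing)))
  invisible(x)
}

#' Validate an RNA sequence against parsed experiments
#'
#' Checks that `raw` is an RNA sequence (alphabet `{A,C,G,U}` after `T`-to-`U`
#' conversion and case folding) and that it is at least as long as the
#' highest nucleotide position in every supplied experiment. Base identity
#' against the experiments' base column is not enforced; mismatches produce
#' a warning only, since the upstream tables' base calls can disagree with
#' the reference sequence without invalidating positions.
#'
#' @param raw Sequence string (whitespace and FASTA header lines are
#'   stripped, so pasted single-record FASTA text is accepted).
#' @param experiments List of `probing_experiment` objects (may be empty).
#' @return An `rna_sequence`: list with `residues` and `length`.
#' @export
validate_sequence <- function(raw, experiments = list()) {
  if (inherits(experiments, "probing_experiment")) experiments <- list(experiments)
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1L]]
  lines <- lines[!startsWith(trimws(lines), ">")]
  s <- gsub("\\s", "", paste(lines, collapse = ""))
  if (!nzchar(s)) stop("validation error: empty sequence")
  chars <- strsplit(toupper(s), "")[[1L]]
  chars[chars == "T"] <- "U"
  bad <- setdiff(unique(chars), c("A", "C", "G", "U"))
  if (length(bad)) {
    stop("not RNA: sequence contains characters outside {A,C,G,U,T}: ",
         paste(bad, collapse = ", "))
  }
  res <- paste(chars, collapse = "")
  for (exp in experiments) {
    maxpos <- max(exp$records$position)
    if (nchar(res) < maxpos) {
      stop(sprintf(
        "validation error: sequence length %d is shorter than max position %d in experiment '%s'",
        nchar(res), maxpos, exp$label))
    }
    idx <- exp$records$position
    file_base <- exp$records$base
    seq_base <- chars[idx]
    mism <- which(file_base != "N" & file_base != seq_base)
    if (length(mism)) {
      warning(sprintf(
        "experiment '%s': %d base mismatch(es) against the sequence (first at position %d)",
        exp$label, length(mism), exp$records$position[mism[[1L]]]))
    }
  }
  structure(list(residues = res, length = nchar(res)), class = "rna_sequence")
}

#' Read an RNA sequence from a single-record FASTA or plain-text file
#'
#' @param path File path; FASTA header lines are ignored.
#' @param experiments Passed to [validate_sequence()].
#' @return An `rna_sequence`.
#' @export
read_rna_sequence <- function(path, experiments = list()) {
  validate_sequence(paste(readLines(path, warn = FALSE), collapse = "\n"),
                    experiments)
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %d nt\n", x$length))
  invisible(x)
}

#' Write a normalized profile as an RNAstructure .shape restraint file
#'
#' Emits one `position<TAB>value` line per nucleotide from position 1 to L.
#' Values are rendered with three decimal places; missing or excluded
#' positions are written literally as `-999`, the no-data code understood
#' by data-driven folding software.
#'
#' @param profile A `normalized_profile`, `averaged_profile` (means are
#'   written), or a data frame with columns `position` and `value`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_shape <- function(profile, path) {
  df <- profile_values(profile)
  if (nrow(df) == 0L) stop("validation error: empty profile, nothing to write")
  pos <- df$position
  if (pos[[1L]] != 1L || any(diff(pos) != 1L)) {
    stop("validation error: profile positions must be contiguous 1..L; ",
         "pad missing positions first (see pad_profile)")
  }
  val <- df$value
  out <- ifelse(is.na(val), sprintf("%d\t-999", pos),
                sprintf("%d\t%.3f", pos, val))
  writeLines(out, path)
  invisible(path)
}

#' Read a .shape restraint file
#'
#' @param path Path to a two-column (position, value) file; `-999` encodes
#'   missing data and is returned as `NA`.
#' @return Data frame with columns `position` and `value`.
#' @export
read_shape <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("position", "value"),
                          colClasses = c("integer", "numeric"))
  df$value[df$value == -999] <- NA_real_
  df
}

# Extract a (position, value) data frame from any profile-like object.
profile_values <- function(profile) {
  if (inherits(profile, "normalized_profile")) {
    data.frame(position = profile$values$position, value = profile$values$value)
  } else if (inherits(profile, "averaged_profile")) {
    data.frame(position = profile$position, value = profile$mean)
  } else if (is.data.frame(profile)) {
    stopifnot(all(c("position", "value") %in% names(profile)))
    profile[, c("position", "value")]
  } else {
    stop("unsupported profile object of class ", paste(class(profile), collapse = "/"))
  }
}

#' Pad a profile with missing values to cover positions 1..length
#'
#' @param profile Profile-like object (see [write_shape()]).
#' @param length Target length L; defaults to the profile's max position.
#' @return Data frame with contiguous positions `1..L`; positions absent
#'   from the input carry `NA`.
#' @export
pad_profile <- function(profile, length = NULL) {
  df <- profile_values(profile)
  L <- length %||% max(df$position)
  out <- data.frame(position = seq_len(L), value = NA_real_)
  keep <- df$position <= L
  out$value[df$position[keep]] <- df$value[keep]
  out
}

#' Export experiments, normalized profiles and the averaged profile as a
#' plain-text workbook
#'
#' Writes a directory of CSV sheets plus a JSON manifest: one `input_*`
#' sheet per experiment (the raw columns), one `normalized_*` sheet per
#' replicate (position, normalized value, color bin), and one `averaged`
#' sheet (position, mean, SD, n_obs). Missing values are written as the
#' `-999` code in value columns and blank in the SD column. Rows carrying
#' normalized values are tagged with their color bin (`LOW`/`MID`/`HIGH`).
#'
#' @param experiments List of `probing_experiment`s.
#' @param profiles List of `normalized_profile`s, aligned with `experiments`.
#' @param averaged An `averaged_profile`.
#' @param path Output directory (created if absent).
#' @return A `workbook_manifest` list (sheet names and files), invisibly.
#' @export
export_workbook <- function(experiments, profiles, averaged, path) {
  if (length(experiments) != length(profiles)) {
    stop("validation error: ", length(experiments), " experiment(s) but ",
         length(profiles), " normalized profile(s)")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sheets <- list()
  add_sheet <- function(name, df) {
    file <- file.path(path, paste0(name, ".csv"))
    utils::write.csv(df, file, row.names = FALSE, na = "")
    sheets[[name]] <<- basename(file)
  }
  for (i in seq_along(experiments)) {
    exp <- experiments[[i]]
    add_sheet(sprintf("input_%02d", i),
              cbind(label = exp$label, exp$records))
  }
  for (i in seq_along(profiles)) {
    v <- profiles[[i]]$values
    add_sheet(sprintf("normalized_%02d", i),
              data.frame(position = v$position,
                         value = ifelse(is.na(v$value), -999, v$value),
                         color_bin = ifelse(is.na(v$bin), "", v$bin)))
  }
  add_sheet("averaged",
            data.frame(position = averaged$position,
                       mean = ifelse(is.na(averaged$mean), -999, averaged$mean),
                       sd = averaged$sd,   # blank when missing (na = "")
                       n_obs = averaged$n_obs))
  manifest <- list(sheets = sheets, n_experiments = length(experiments))
  jsonlite::write_json(manifest, file.path(path, "workbook.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(manifest, class = "workbook_manifest"))
}
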