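#' Data-driven secondary structure prediction via an external folder
#'
#' Thin bridge to an installed RNAstructure `Fold` executable (or any
#' drop-in with the same command-line contract): writes the sequence as a
#' single-record FASTA and the profile as a `.shape` restraint file
#' (missing positions as `-999`, so no restraint is applied there),
#' invokes the tool, and parses its connectivity-table (CT) output into a
#' pseudoknot-free dot-bracket structure. The folding algorithm itself is
#' deliberately not part of this package; SHAPE pseudo-energy slope and
#' intercept can be passed through via `extra_args`.
#'
#' @param seq An `rna_sequence`.
#' @param profile A profile covering the sequence (see [write_shape()]).
#' @param tool_path Path to the external folding executable.
#' @param extra_args Additional command-line arguments passed through
#'   (e.g. `c("-sm", "1.8", "-si", "-0.6")`).
#' @param workdir Directory for intermediate files (default: a tempdir).
#' @return A `secondary_structure`: list with `sequence`, `pairs`
#'   (two-column matrix, i < j) and `dot_bracket`.
#' @export
predict_structure <- function(seq, profile, tool_path = NULL,
                              extra_args = character(),
                              workdir = tempfile("fold")) {
  stopifnot(inherits(seq, "rna_sequence"))
  if (is.null(tool_path) || !file.exists(tool_path)) {
    stop("external dependency missing: the RNAstructure 'Fold' executable ",
         "was not found", if (!is.null(tool_path)) paste0(" at ", tool_path),
         "; supply tool_path")
  }
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(workdir, "input.fasta")
  shape <- file.path(workdir, "input.shape")
  ct <- file.path(workdir, "output.ct")
  writeLines(c(">input", seq$residues), fasta)
  write_shape(pad_profile(profile, seq$length), shape)

  out <- suppressWarnings(system2(tool_path,
                                  c(fasta, ct, "--SHAPE", shape, extra_args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stop("external folding tool exited with status ", status, ":\n",
         paste(out, collapse = "\n"))
  }
  if (!file.exists(ct)) stop("format error: folding tool produced no CT output")
  ct_to_dotbracket(readLines(ct, warn = FALSE))
}

#' Convert a connectivity table to dot-bracket notation
#'
#' Parses CT text (header line `N title`, then per-nucleotide rows
#' `i base i-1 i+1 j index` where `j = 0` means unpaired) and renders the
#' pair set with matched parentheses. This adapter is pseudoknot-free:
#' crossing pairs are rejected, as are inconsistent pairings and pairs
#' closer than 3 positions.
#'
#' @param ct Character vector of CT lines, or a path to a CT file.
#' @return A `secondary_structure`.
#' @export
ct_to_dotbracket <- function(ct) {
  if (length(ct) == 1L && file.exists(ct)) ct <- readLines(ct, warn = FALSE)
  ct <- ct[nzchar(trimws(ct))]
  if (length(ct) < 1L) stop("format error: empty connectivity table")
  header <- strsplit(trimws(ct[[1L]]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(header[[1L]]))
  if (is.na(n) || n < 1L) stop("format error: bad CT header: ", ct[[1L]])
  if (length(ct) < n + 1L) {
    stop("format error: CT declares ", n, " nucleotides but has ",
         length(ct) - 1L, " rows")
  }
  partner <- integer(n)
  base <- character(n)
  for (row in ct[1L + seq_len(n)]) {
    f <- strsplit(trimws(row), "\\s+")[[1L]]
    if (length(f) < 5L) stop("format error: short CT row: ", row)
    i <- as.integer(f[[1L]])
    if (is.na(i) || i < 1L || i > n) stop("format error: bad CT index in: ", row)
    base[[i]] <- toupper(f[[2L]])
    partner[[i]] <- as.integer(f[[5L]])
  }
  for (i in seq_len(n)) {
    j <- partner[[i]]
    if (j != 0L) {
      if (j < 1L || j > n || partner[[j]] != i) {
        stop("format error: inconsistent pairing ", i, " -> ", j)
      }
      if (abs(j - i) < 3L) {
        stop("format error: paired positions ", min(i, j), " and ", max(i, j),
             " are fewer than 3 apart")
      }
    }
  }
  pairs <- cbind(i = which(partner > seq_len(n)),
                 j = partner[partner > seq_len(n)])

  # crossing check: pairs (a,b) and (c,d) with a < c < b < d
  if (nrow(pairs) > 1L) {
    for (a in seq_len(nrow(pairs) - 1L)) {
      for (b in (a + 1L):nrow(pairs)) {
        i1 <- pairs[a, 1L]; j1 <- pairs[a, 2L]
        i2 <- pairs[b, 1L]; j2 <- pairs[b, 2L]
        if ((i1 < i2 && i2 < j1 && j1 < j2) ||
            (i2 < i1 && i1 < j2 && j2 < j1)) {
          stop("pseudoknot not representable: pairs (", i1, ",", j1,
               ") and (", i2, ",", j2, ") cross")
        }
      }
    }
  }

  db <- rep(".", n)
  db[pairs[, 1L]] <- "("
  db[pairs[, 2L]] <- ")"
  residues <- paste(ifelse(nzchar(base), base, "N"), collapse = "")
  structure(list(
    sequence = structure(list(residues = residues, length = n),
                         class = "rna_sequence"),
    pairs = pairs,
    dot_bracket = paste(db, collapse = "")),
    class = "secondary_structure")
}

#' Recover the pair set from a dot-bracket string
#'
#' @param db Dot-bracket string over `.`, `(`, `)`.
#' @return Two-column integer matrix of pairs (i < j).
#' @export
dotbracket_to_pairs <- function(db) {
  chars <- strsplit(db, "")[[1L]]
  bad <- setdiff(unique(chars), c(".", "(", ")"))
  if (length(bad)) stop("format error: unexpected character(s): ",
                        paste(bad, collapse = ", "))
  stack <- integer()
  pairs <- matrix(integer(), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(chars)) {
    if (chars[[k]] == "(") {
      stack <- c(stack, k)
    } else if (chars[[k]] == ")") {
      if (!length(stack)) stop("format error: unbalanced brackets at ", k)
      pairs <- rbind(pairs, c(stack[[length(stack)]], k))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("format error: unbalanced brackets (", length(stack),
                          " unmatched '(')")
  pairs[order(pairs[, 1L]), , drop = FALSE]
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d pair(s)\n%s\n",
              x$sequence$length, nrow(x$pairs), x$dot_bracket))
  invisible(x)
}
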