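#' Average normalized replicate profiles
#'
#' Combines 1-15 normalized replicate profiles into one averaged profile
#' with a per-nucleotide sample standard deviation. At each position the
#' mean and sd are taken over the replicates where the value is
#' non-missing; missing values are skipped, never imputed as zero.
#' Positions with no observations are missing (written as -999
#' downstream); the sd is missing wherever fewer than two replicates
#' contribute. The number of contributing replicates is reported so
#' downstream users can filter by support.
#'
#' @param profiles List of `normalized_profile` objects sharing one
#'   position range (1 to 15 of them).
#' @return An `averaged_profile`: data frame with columns `position`,
#'   `mean`, `sd`, `n_obs`.
#' @export
average_profiles <- function(profiles) {
  if (inherits(profiles, "normalized_profile")) profiles <- list(profiles)
  k <- length(profiles)
  if (k < 1L || k > 15L) {
    stop("validation error: expected between 1 and 15 replicate profiles, got ", k)
  }
  pos <- profiles[[1L]]$values$position
  mat <- vapply(profiles, function(p) {
    if (!identical(p$values$position, pos)) {
      stop("validation error: replicate profiles have inconsistent position ranges")
    }
    p$values$value
  }, numeric(length(pos)))
  mat <- matrix(mat, nrow = length(pos))

  n_obs <- rowSums(!is.na(mat))
  mean_v <- rowMeans(mat, na.rm = TRUE)
  mean_v[n_obs == 0L] <- NA_real_
  sd_v <- apply(mat, 1L, function(row) stats::sd(row, na.rm = TRUE))
  sd_v[n_obs <= 1L] <- NA_real_

  structure(data.frame(position = pos, mean = mean_v, sd = sd_v,
                       n_obs = as.integer(n_obs)),
            n_replicates = k,
            class = c("averaged_profile", "data.frame"))
}

#' @export
print.averaged_profile <- function(x, ...) {
  cat(sprintf("<averaged_profile> %d positions from %d replicate(s), %d with data\n",
              nrow(x), attr(x, "n_replicates"), sum(x$n_obs > 0L)))
  invisible(x)
}
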