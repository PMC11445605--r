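#' Normalize arm-pair orientation
#'
#' Puts each chromosome's two arm lengths into the conventional orientation
#' `long_arm >= short_arm`. Observers sometimes label the arms inconsistently,
#' so pairs given as short-before-long are swapped rather than rejected; every
#' swap is reported through a single consolidated warning.
#'
#' @param data A data frame with numeric columns `long_arm` and `short_arm`
#'   (one row per chromosome). Any other columns are passed through.
#' @param quiet If `TRUE`, suppress the swap warning (the `swapped` attribute
#'   is still set).
#'
#' @return A tibble with the same columns, `long_arm >= short_arm` on every
#'   row, and an integer attribute `swapped` giving the row indices that were
#'   reordered.
#'
#' @details Arm lengths must be finite and non-negative, and at least one arm
#'   of each pair must be positive; violations are errors, not warnings.
#'   A zero short arm is legitimate (telocentric chromosome).
#'
#' @examples
#' normalize_arms(tibble::tibble(long_arm = c(3, 1), short_arm = c(1, 3)))
#' @export
normalize_arms <- function(data, quiet = FALSE) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.")
  }
  missing_cols <- setdiff(c("long_arm", "short_arm"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  data <- tibble::as_tibble(data)
  l <- data$long_arm
  s <- data$short_arm
  if (!is.numeric(l) || !is.numeric(s)) {
    abort("`long_arm` and `short_arm` must be numeric.")
  }
  bad <- which(!is.finite(l) | !is.finite(s))
  if (length(bad) > 0) {
    abort(paste0("Non-finite arm length in row(s): ",
                 paste(head(bad, 5), collapse = ", "), "."))
  }
  neg <- which(l < 0 | s < 0)
  if (length(neg) > 0) {
    abort(paste0("Negative arm length in row(s): ",
                 paste(head(neg, 5), collapse = ", "), "."))
  }
  zero <- which(l == 0 & s == 0)
  if (length(zero) > 0) {
    abort(paste0("Both arms are zero in row(s): ",
                 paste(head(zero, 5), collapse = ", "), "."))
  }
  swapped <- which(s > l)
  if (length(swapped) > 0) {
    data$long_arm <- pmax(l, s)
    data$short_arm <- pmin(l, s)
    if (!quiet) {
      warn(paste0("Swapped short/long arms in ", length(swapped),
                  " row(s) where short_arm > long_arm."))
    }
  }
  attr(data, "swapped") <- as.integer(swapped)
  data
}

#' Centromeric index
#'
#' The centromeric index CI = S / (L + S): the short arm's share of the
#' chromosome length. Ranges from 0 (telocentric) to 0.5 (metacentric) for
#' arm pairs in conventional orientation (L >= S).
#'
#' @param long_arm,short_arm Numeric vectors of arm lengths (same unit).
#' @return Numeric vector of centromeric indices.
#' @examples
#' centromeric_index(3, 1)   # 0.25
#' centromeric_index(2, 2)   # 0.5
#' @export
centromeric_index <- function(long_arm, short_arm) {
  short_arm / (long_arm + short_arm)
}

#' Centromeric asymmetry of one chromosome
#'
#' CA = 100 * (L - S) / (L + S): the difference between the long-arm and
#' short-arm proportions of the chromosome, as a percentage. 0 for a
#' metacentric chromosome, 100 for a telocentric one. The mean of CA over a
#' complement is the karyotype trait M_CA.
#'
#' @inheritParams centromeric_index
#' @return Numeric vector of per-chromosome asymmetries in `[0, 100]` for
#'   pairs in conventional orientation.
#' @examples
#' centromeric_asymmetry(3, 1)  # 50
#' @export
centromeric_asymmetry <- function(long_arm, short_arm) {
  100 * (long_arm - short_arm) / (long_arm + short_arm)
}
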