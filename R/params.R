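#' Karyomorphometric descriptors of a metaphase plate
#'
#' Computes, for each measured plate (one group per `plate_id` x
#' `observer_id`), the four standard quantitative karyotype descriptors:
#'
#' * `THL`  — total haploid (monoploid) chromosome length: the sum of all
#'   chromosome lengths (L + S) in the plate divided by the ploidy level;
#'   a gross proxy of genome size, in the unit of the input lengths.
#' * `M_CA` — mean centromeric asymmetry: the mean over chromosomes of
#'   100 * (L - S) / (L + S); intrachromosomal asymmetry, in percent.
#' * `CV_CL` — coefficient of variation of chromosome length:
#'   100 * sd(CL) / mean(CL); interchromosomal asymmetry, in percent.
#' * `CV_CI` — coefficient of variation of the centromeric index
#'   S / (L + S): 100 * sd(CI) / mean(CI); heterogeneity of centromere
#'   position, in percent.
#'
#' Statistics are taken over all measured chromosomes (all 2n of them), not
#' over homolog means; homolog pairing is out of scope here. No rounding is
#' applied — round at report time if needed.
#'
#' @param data A data frame of arm measurements with numeric columns
#'   `long_arm` and `short_arm`, one row per chromosome. If `plate_id` /
#'   `observer_id` columns are present the descriptors are computed per
#'   group; otherwise all rows are treated as one plate.
#' @param ploidy Positive integer, the ploidy level of the plate (2 for the
#'   usual diploid case). Used only by THL.
#' @param sd Standard-deviation divisor convention for the two CVs:
#'   `"sample"` (divisor n - 1, the default and the default of most
#'   statistics packages) or `"population"` (divisor n).
#' @param normalize If `TRUE` (default), run [normalize_arms()] first so
#'   reversed pairs are swapped (with a warning) before computing.
#'
#' @return A tibble with one row per plate/observer and columns `plate_id`,
#'   `observer_id`, `n_chromosomes`, `ploidy`, `THL`, `M_CA`, `CV_CL`,
#'   `CV_CI`, `mean_CL`, `mean_CI`.
#'
#' @details A plate needs at least 2 chromosomes (the CVs are undefined
#'   otherwise). A plate whose chromosomes are all telocentric has mean
#'   CI = 0, making CV_CI undefined; this is an explicit error rather than a
#'   silent NaN.
#'
#' @examples
#' plate <- tibble::tibble(
#'   long_arm  = c(3, 3, 2, 2),
#'   short_arm = c(1, 1, 2, 2)
#' )
#' karyotype_params(plate, ploidy = 2)
#' @export
karyotype_params <- function(data, ploidy = 2, sd = c("sample", "population"),
                             normalize = TRUE) {
  sd <- match.arg(sd)
  if (!is.numeric(ploidy) || length(ploidy) != 1 || !is.finite(ploidy) ||
      ploidy < 1 || ploidy != round(ploidy)) {
    abort("`ploidy` must be a single positive integer.")
  }
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of arm measurements.")
  }
  data <- tibble::as_tibble(data)
  if (!"plate_id" %in% names(data))    data$plate_id <- "plate1"
  if (!"observer_id" %in% names(data)) data$observer_id <- "obs1"
  if (normalize) {
    data <- normalize_arms(data)
  }
  out <- data |>
    dplyr::group_by(.data$plate_id, .data$observer_id) |>
    dplyr::group_modify(function(g, key) {
      p <- plate_params(g$long_arm, g$short_arm, ploidy = ploidy, sd = sd)
      tibble::as_tibble(p)
    }) |>
    dplyr::ungroup()
  out
}

# Descriptor core on bare arm-length vectors; assumes normalized orientation.
# Kept free of data-frame machinery so the simulator can call it in tight
# Monte-Carlo loops.
plate_params <- function(long_arm, short_arm, ploidy = 2, sd = "sample") {
  n <- length(long_arm)
  if (n < 2) {
    abort("At least 2 chromosomes are required (CVs are undefined otherwise).")
  }
  cl <- long_arm + short_arm
  ci <- short_arm / cl
  ca <- 100 * (long_arm - short_arm) / cl
  mean_cl <- mean(cl)
  mean_ci <- mean(ci)
  if (mean_ci == 0) {
    abort(paste0("All chromosomes are telocentric (mean centromeric index ",
                 "is 0): CV_CI is undefined."))
  }
  sd_cl <- stats::sd(cl)
  sd_ci <- stats::sd(ci)
  if (sd == "population") {
    f <- sqrt((n - 1) / n)
    sd_cl <- sd_cl * f
    sd_ci <- sd_ci * f
  }
  list(
    n_chromosomes = n,
    ploidy = as.integer(ploidy),
    THL = sum(cl) / ploidy,
    M_CA = mean(ca),
    CV_CL = 100 * sd_cl / mean_cl,
    CV_CI = 100 * sd_ci / mean_ci,
    mean_CL = mean_cl,
    mean_CI = mean_ci
  )
}
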