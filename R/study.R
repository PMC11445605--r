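#' Assemble the per-observer trait table for one plate
#'
#' Takes repeated measurements of a single metaphase plate by several
#' observers and computes each observer's karyomorphometric descriptors
#' ([karyotype_params()]), yielding the observers-by-traits table on which
#' the inter-observer reliability analysis operates.
#'
#' @param measurements Long measurement tibble: one row per chromosome, with
#'   columns `plate_id`, `observer_id`, `long_arm`, `short_arm` (and
#'   optionally `chromosome_index`). All rows must belong to one plate.
#' @inheritParams karyotype_params
#'
#' @return A tibble of class `observer_study`, one row per observer with the
#'   columns of [karyotype_params()]. Attributes: `plate_id`, `ploidy`,
#'   `sd`.
#'
#' @details Observers whose rows fail validation (non-finite or negative
#'   arm lengths, both arms zero) are dropped with a warning rather than
#'   imputed; reversed arm pairs are merely swapped. Mixed plates and
#'   duplicated `(observer, chromosome_index)` keys are errors.
#'
#' @examples
#' truth <- make_true_karyotype(n_pairs = 4, seed = 1)
#' cfg <- simulation_config(truth, n_observers = 5, seed = 1)
#' sim <- simulate_study(cfg)
#' build_study_table(sim$measurements)
#' @export
build_study_table <- function(measurements, ploidy = 2,
                              sd = c("sample", "population")) {
  sd <- match.arg(sd)
  measurements <- as_measurement_tbl(measurements)
  plates <- unique(measurements$plate_id)
  if (length(plates) != 1) {
    abort(paste0("All measurements must refer to one plate; found: ",
                 paste(plates, collapse = ", "), "."))
  }
  if ("chromosome_index" %in% names(measurements)) {
    dup <- measurements |>
      dplyr::count(.data$observer_id, .data$chromosome_index) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort(paste0("Duplicated chromosome_index within observer(s): ",
                   paste(unique(dup$observer_id), collapse = ", "), "."))
    }
  }
  # Drop (with a warning) observers with unusable rows instead of imputing.
  bad_obs <- measurements |>
    dplyr::group_by(.data$observer_id) |>
    dplyr::summarise(bad = any(!is.finite(.data$long_arm) |
                               !is.finite(.data$short_arm) |
                               .data$long_arm < 0 | .data$short_arm < 0 |
                               (.data$long_arm == 0 & .data$short_arm == 0))) |>
    dplyr::filter(.data$bad)
  if (nrow(bad_obs) > 0) {
    warn(paste0("Excluding observer(s) with invalid chromosome rows: ",
                paste(bad_obs$observer_id, collapse = ", "), "."))
    measurements <- dplyr::filter(
      measurements, !.data$observer_id %in% bad_obs$observer_id)
  }
  if (nrow(measurements) == 0) {
    abort("No valid observers remain.")
  }
  tab <- karyotype_params(measurements, ploidy = ploidy, sd = sd)
  new_observer_study(tab, plate_id = plates, ploidy = ploidy, sd = sd)
}

new_observer_study <- function(tab, plate_id, ploidy, sd) {
  structure(
    tab,
    plate_id = plate_id,
    ploidy = ploidy,
    sd = sd,
    class = c("observer_study", class(tibble::as_tibble(tab)))
  )
}

#' @export
glance.observer_study <- function(x, ...) {
  tibble::tibble(
    plate_id = attr(x, "plate_id"),
    n_observers = nrow(x),
    ploidy = attr(x, "ploidy"),
    sd = attr(x, "sd")
  )
}

check_traits <- function(table, traits = karyo_traits) {
  missing_tr <- setdiff(traits, names(table))
  if (length(missing_tr) > 0) {
    abort(paste0("Trait column(s) not found: ",
                 paste(missing_tr, collapse = ", "), "."))
  }
  invisible(traits)
}

#' Per-trait dispersion across observers
#'
#' For each karyomorphometric trait, summarises its spread across the
#' observers who measured the same plate: mean, sample standard deviation,
#' coefficient of variation (100 * sd / mean — the reliability statistic of
#' the inter-observer analysis), the five-number summary for boxplots, and
#' the raw per-observer values for jitter overlays.
#'
#' @param table An `observer_study` table (or any data frame with columns
#'   `THL`, `M_CA`, `CV_CL`, `CV_CI` and `observer_id`).
#' @param traits Character vector of trait columns to summarise.
#'
#' @return A tibble of class `trait_dispersion`: one row per trait with
#'   columns `trait`, `n`, `mean`, `sd`, `cv`, `min`, `q1`, `median`, `q3`,
#'   `max`, and a list-column `values` holding the raw per-observer values.
#'
#' @details Quartiles use linear interpolation between order statistics
#'   (`stats::quantile()` type 7, the common default). A trait whose mean is
#'   0 has an undefined CV and raises an error. At least 2 observers are
#'   required.
#'
#' @examples
#' tab <- tibble::tibble(
#'   observer_id = c("a", "b", "c"),
#'   THL = c(8, 10, 12), M_CA = c(40, 40, 40),
#'   CV_CL = c(20, 22, 24), CV_CI = c(15, 18, 21)
#' )
#' trait_cv(tab)
#' @export
trait_cv <- function(table, traits = karyo_traits) {
  check_traits(table, traits)
  if (nrow(table) < 2) {
    abort("At least 2 observers are required to compute trait CVs.")
  }
  long <- tidyr::pivot_longer(
    tibble::as_tibble(table)[, traits, drop = FALSE],
    cols = dplyr::all_of(traits),
    names_to = "trait", values_to = "value"
  )
  out <- long |>
    dplyr::group_by(trait = factor(.data$trait, levels = traits)) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      min = min(.data$value),
      q1 = stats::quantile(.data$value, 0.25, names = FALSE, type = 7),
      median = stats::median(.data$value),
      q3 = stats::quantile(.data$value, 0.75, names = FALSE, type = 7),
      max = max(.data$value),
      values = list(.data$value)
    ) |>
    dplyr::mutate(trait = as.character(.data$trait)) |>
    dplyr::arrange(match(.data$trait, traits))
  if (any(out$mean == 0)) {
    abort(paste0("Trait(s) with zero mean have undefined CV: ",
                 paste(out$trait[out$mean == 0], collapse = ", "), "."))
  }
  out <- dplyr::mutate(out, cv = 100 * .data$sd / .data$mean,
                       .after = "sd")
  structure(out, class = c("trait_dispersion", class(out)))
}

#' Pearson correlation matrix across observers
#'
#' Correlates the karyomorphometric traits across the observers of one
#' plate: Pearson's product-moment coefficient for every trait pair, with
#' two-sided p values from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom. No
#' multiple-testing correction is applied by default, matching common
#' practice for these small descriptive matrices; set `bonferroni = TRUE`
#' to adjust.
#'
#' @inheritParams trait_cv
#' @param bonferroni If `TRUE`, Bonferroni-adjust the p values over the
#'   `choose(k, 2)` distinct pairs.
#'
#' @return An object of class `karyo_cor`: a list with elements `traits`
#'   (trait names), `r` and `p` (symmetric k x k matrices; `r` has unit
#'   diagonal, `p` has `NA` on the diagonal), and `n` (observer count).
#'   Use [tidy()] for a long pair-per-row tibble and [glance()] for a
#'   one-row summary.
#'
#' @details Requires at least 3 observers (the t test needs n - 2 >= 1) and
#'   nonzero variance in every trait; a constant trait is an error naming
#'   the trait.
#'
#' @examples
#' truth <- make_true_karyotype(seed = 1)
#' sim <- simulate_study(simulation_config(truth, seed = 1))
#' cm <- pearson_matrix(sim$study)
#' tidy(cm)
#' @export
pearson_matrix <- function(table, traits = karyo_traits, bonferroni = FALSE) {
  check_traits(table, traits)
  n <- nrow(table)
  if (n < 3) {
    abort("At least 3 observers are required for correlation p values.")
  }
  x <- as.matrix(tibble::as_tibble(table)[, traits, drop = FALSE])
  constant <- traits[apply(x, 2, function(v) stats::sd(v) == 0)]
  if (length(constant) > 0) {
    abort(paste0("Trait(s) with zero variance across observers: ",
                 paste(constant, collapse = ", "), "."))
  }
  k <- length(traits)
  r <- diag(1, k)
  p <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      rp <- pearson_rp(x[, i], x[, j])
      r[i, j] <- r[j, i] <- rp$r
      p[i, j] <- p[j, i] <- rp$p
    }
  }
  if (bonferroni) {
    m <- k * (k - 1) / 2
    p <- pmin(p * m, 1)
  }
  dimnames(r) <- dimnames(p) <- list(traits, traits)
  structure(
    list(traits = traits, r = r, p = p, n = n,
         plate_id = attr(table, "plate_id") %||% NA_character_),
    class = "karyo_cor"
  )
}

# Product-moment r and two-sided t-based p for one pair of vectors.
pearson_rp <- function(x, y) {
  n <- length(x)
  dx <- x - mean(x)
  dy <- y - mean(y)
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  # Guard against r marginally outside [-1, 1] from rounding.
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p)
}

# Report annotation used in printed/tidied output.
significance_label <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.01 ~ "highly significant",
    p < 0.05 ~ "marginally significant",
    TRUE ~ "not significant"
  )
}

#' @export
print.karyo_cor <- function(x, digits = 5, ...) {
  cat("Pearson correlation of karyomorphometric traits (n = ",
      x$n, " observers)\n\n", sep = "")
  cat("r:\n")
  print(signif(x$r, digits))
  cat("\ntwo-sided p:\n")
  print(signif(x$p, digits))
  invisible(x)
}

#' @export
tidy.karyo_cor <- function(x, ...) {
  k <- length(x$traits)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    trait_x = x$traits[idx[, "row"]],
    trait_y = x$traits[idx[, "col"]],
    r = x$r[idx],
    p = x$p[idx],
    significance = significance_label(x$p[idx])
  )
}

#' @export
glance.karyo_cor <- function(x, ...) {
  td <- tidy(x)
  strongest <- td[which.max(abs(td$r)), ]
  tibble::tibble(
    n_observers = x$n,
    n_pairs = nrow(td),
    n_significant = sum(td$p < 0.05),
    strongest_pair = paste(strongest$trait_x, strongest$trait_y, sep = "-"),
    strongest_r = strongest$r
  )
}

#' Paired trait values for a scatter plot
#'
#' Extracts per-observer (x, y) value pairs for two traits, ready for a
#' scatter plot, together with the Pearson r and p of that pair as
#' attributes. Individual observers can be flagged for highlighting (for
#' example the one measurement that was used in a published karyotype).
#'
#' @inheritParams trait_cv
#' @param trait_x,trait_y Names of the traits on the x and y axes.
#' @param highlight Character vector of `observer_id`s to flag, or `NULL`.
#'
#' @return A tibble with columns `observer_id`, `x`, `y`, `highlighted`,
#'   and attributes `trait_x`, `trait_y`, `r`, `p`.
#' @export
scatter_export <- function(table, trait_x = "THL", trait_y = "M_CA",
                           highlight = NULL) {
  check_traits(table, c(trait_x, trait_y))
  if (!"observer_id" %in% names(table)) {
    abort("`table` must have an `observer_id` column.")
  }
  unknown <- setdiff(highlight, table$observer_id)
  if (length(unknown) > 0) {
    warn(paste0("highlight id(s) not present in table: ",
                paste(unknown, collapse = ", "), "."))
  }
  tab <- tibble::as_tibble(table)
  out <- tibble::tibble(
    observer_id = tab$observer_id,
    x = tab[[trait_x]],
    y = tab[[trait_y]],
    highlighted = tab$observer_id %in% (highlight %||% character())
  )
  rp <- pearson_rp(out$x, out$y)
  attr(out, "trait_x") <- trait_x
  attr(out, "trait_y") <- trait_y
  attr(out, "r") <- rp$r
  attr(out, "p") <- rp$p
  out
}
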