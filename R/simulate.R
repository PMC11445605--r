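#' Generate a true (noise-free) diploid karyotype
#'
#' Draws a ground-truth karyotype for simulation studies: `n_pairs`
#' chromosome types with chromosome length uniform in `length_range` and
#' centromeric index uniform in `ci_range`, each type duplicated so homologs
#' are identical in truth — emulating a diploid metaphase plate with
#' 2n = 2 * n_pairs chromosomes.
#'
#' @param n_pairs Number of homolog pairs (9 gives the common 2n = 18
#'   diploid plate).
#' @param length_range Length-2 numeric, min/max chromosome length (µm or
#'   any consistent unit); both positive.
#' @param ci_range Length-2 numeric, min/max centromeric index, within
#'   `(0, 0.5]`.
#' @param seed Integer seed; the same seed always yields the same karyotype.
#' @param plate_id Identifier stored in the output.
#'
#' @return A measurement tibble (one row per chromosome) with columns
#'   `plate_id`, `observer_id` (`"truth"`), `chromosome_index`, `long_arm`,
#'   `short_arm`.
#' @examples
#' make_true_karyotype(n_pairs = 9, seed = 42)
#' @export
make_true_karyotype <- function(n_pairs = 9, length_range = c(2, 6),
                                ci_range = c(0.25, 0.45), seed = NULL,
                                plate_id = "plate1") {
  if (!is.numeric(n_pairs) || length(n_pairs) != 1 || n_pairs < 1 ||
      n_pairs != round(n_pairs)) {
    abort("`n_pairs` must be a single positive integer.")
  }
  check_range <- function(r, name, lo, hi) {
    if (!is.numeric(r) || length(r) != 2 || !all(is.finite(r)) ||
        r[1] > r[2] || r[1] <= lo || r[2] > hi) {
      abort(paste0("`", name, "` must be (min, max) with ", lo,
                   " < min <= max <= ", hi, "."))
    }
  }
  check_range(length_range, "length_range", 0, Inf)
  check_range(ci_range, "ci_range", 0, 0.5)
  local_rng_seed(seed)
  cl <- runif(n_pairs, length_range[1], length_range[2])
  ci <- runif(n_pairs, ci_range[1], ci_range[2])
  short <- rep(cl * ci, each = 2)
  long <- rep(cl * (1 - ci), each = 2)
  tibble::tibble(
    plate_id = plate_id,
    observer_id = "truth",
    chromosome_index = seq_len(2 * n_pairs),
    long_arm = long,
    short_arm = short
  )
}

#' Configuration of the multi-observer error model
#'
#' Bundles a true karyotype with the parameters of the observer error model
#' used by [simulate_observer()] and [simulate_study()]. Each observer o
#' gets
#' * a calibration factor `c_o = exp(N(0, sigma_calibration^2))` applied to
#'   every arm (overall scale error, e.g. in converting pixels to µm);
#' * independent per-arm multiplicative noise `exp(N(0, sigma_arm^2))`
#'   (delineation jitter on each individual arm); and
#' * a nonnegative short-arm bias `b_o = |N(0, sigma_shortarm_bias^2)|`
#'   in length units, shared across all short arms of that observer's plate
#'   — the systematic short-arm overestimation under study.
#'
#' `bias_mode` controls how `b_o` enters: `"additive"` adds it to every
#' short arm (total chromosome length grows), `"transfer"` moves it from the
#' long arm to the short arm (centromere misplacement: total length is
#' preserved up to noise).
#'
#' @param true_karyotype Measurement tibble of the ground-truth plate, e.g.
#'   from [make_true_karyotype()].
#' @param n_observers Number of simulated observers (default 15).
#' @param sigma_calibration SD of the observer-level log-scale calibration
#'   factor (default 0.05, i.e. ~5% scale error).
#' @param sigma_arm SD of per-arm log-scale noise (default 0.03).
#' @param sigma_shortarm_bias Scale of the half-normal observer short-arm
#'   bias, in the length unit of the karyotype (default 0.15 µm).
#' @param bias_mode `"additive"` or `"transfer"`.
#' @param seed Integer master seed; per-observer substreams are derived from
#'   it by a stable counter scheme, so adding observers never perturbs
#'   earlier ones.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(true_karyotype, n_observers = 15,
                              sigma_calibration = 0.05, sigma_arm = 0.03,
                              sigma_shortarm_bias = 0.15,
                              bias_mode = c("additive", "transfer"),
                              seed = 1L) {
  bias_mode <- match.arg(bias_mode)
  true_karyotype <- as_measurement_tbl(true_karyotype)
  sigmas <- c(sigma_calibration, sigma_arm, sigma_shortarm_bias)
  if (!is.numeric(sigmas) || length(sigmas) != 3 || any(!is.finite(sigmas)) ||
      any(sigmas < 0)) {
    abort("All sigma parameters must be finite and >= 0.")
  }
  if (!is.numeric(n_observers) || length(n_observers) != 1 ||
      n_observers < 1 || n_observers != round(n_observers)) {
    abort("`n_observers` must be a single positive integer.")
  }
  structure(
    list(
      true_karyotype = true_karyotype,
      n_observers = as.integer(n_observers),
      sigma_calibration = sigma_calibration,
      sigma_arm = sigma_arm,
      sigma_shortarm_bias = sigma_shortarm_bias,
      bias_mode = bias_mode,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Observer-error simulation config\n")
  cat("  true karyotype : ", nrow(x$true_karyotype), " chromosomes (plate ",
      x$true_karyotype$plate_id[1], ")\n", sep = "")
  cat("  n_observers    :", x$n_observers, "\n")
  cat("  sigma_calibration:", x$sigma_calibration,
      " sigma_arm:", x$sigma_arm,
      " sigma_shortarm_bias:", x$sigma_shortarm_bias, "\n")
  cat("  bias_mode      :", x$bias_mode, "  seed:", x$seed, "\n")
  invisible(x)
}

#' Apply a fixed observer error to a plate
#'
#' Deterministic core of the observer model: given explicit calibration
#' factor, per-arm noise factors and short-arm bias, transforms the true arm
#' lengths. Exposed separately so the mechanism can be studied (and tested)
#' without randomness.
#'
#' @param long_arm,short_arm True arm-length vectors (normalized
#'   orientation).
#' @param calibration Scalar multiplicative calibration factor.
#' @param noise_long,noise_short Per-arm multiplicative noise factors
#'   (vectors recycled to length of the arms).
#' @param shortarm_bias Scalar additive bias applied to every short arm
#'   (length units, >= 0).
#' @param bias_mode `"additive"` (bias inflates total length) or
#'   `"transfer"` (bias moves length from long to short arm).
#' @param floor_frac In transfer mode, long arms are not allowed below
#'   `floor_frac` times the true long arm (default 1%); clipping is
#'   reported via the `clipped` attribute and a warning.
#'
#' @return A tibble with columns `long_arm`, `short_arm` (re-normalized so
#'   `long_arm >= short_arm`) and attribute `clipped` (row indices floored).
#' @examples
#' apply_observer_bias(c(4, 3), c(2, 1), shortarm_bias = 0.2)
#' @export
apply_observer_bias <- function(long_arm, short_arm, calibration = 1,
                                noise_long = 1, noise_short = 1,
                                shortarm_bias = 0,
                                bias_mode = c("additive", "transfer"),
                                floor_frac = 0.01) {
  bias_mode <- match.arg(bias_mode)
  l <- calibration * long_arm * noise_long
  s <- calibration * short_arm * noise_short + shortarm_bias
  clipped <- integer(0)
  if (bias_mode == "transfer") {
    l <- l - shortarm_bias
    floor_l <- floor_frac * long_arm
    clipped <- which(l < floor_l)
    if (length(clipped) > 0) {
      l[clipped] <- floor_l[clipped]
      warn(paste0("Transfer bias clipped ", length(clipped),
                  " long arm(s) at the ", floor_frac * 100,
                  "% floor."))
    }
  }
  out <- normalize_arms(tibble::tibble(long_arm = l, short_arm = s),
                        quiet = TRUE)
  attr(out, "clipped") <- clipped
  out
}

# Stable per-observer substream seed: a counter scheme on the master seed,
# kept inside the 32-bit integer range.
derive_observer_seed <- function(seed, observer_index) {
  as.integer((as.double(seed) %% 2147483647 +
                as.double(observer_index) * 1000003) %% 2147483647)
}

#' Simulate one observer's measurement of a plate
#'
#' Draws the observer-level calibration factor, per-arm noise and short-arm
#' bias specified by a [simulation_config()] and applies them to the true
#' karyotype via [apply_observer_bias()].
#'
#' @param truth Measurement tibble of the true plate (normalized).
#' @param cfg A [simulation_config()].
#' @param observer_index Positive integer; indexes the observer's random
#'   substream, so the same (config, index) always reproduces the same
#'   measurement.
#'
#' @return A measurement tibble for the simulated observer, with
#'   `observer_id` of the form `"obs03"`.
#' @export
simulate_observer <- function(truth, cfg, observer_index) {
  stopifnot(inherits(cfg, "simulation_config"))
  truth <- as_measurement_tbl(truth)
  nchr <- nrow(truth)
  local_rng_seed(derive_observer_seed(cfg$seed, observer_index))
  calibration <- exp(rnorm(1, 0, cfg$sigma_calibration))
  bias <- abs(rnorm(1, 0, cfg$sigma_shortarm_bias))
  noise_long <- exp(rnorm(nchr, 0, cfg$sigma_arm))
  noise_short <- exp(rnorm(nchr, 0, cfg$sigma_arm))
  arms <- apply_observer_bias(
    truth$long_arm, truth$short_arm,
    calibration = calibration,
    noise_long = noise_long, noise_short = noise_short,
    shortarm_bias = bias, bias_mode = cfg$bias_mode
  )
  tibble::tibble(
    plate_id = truth$plate_id,
    observer_id = sprintf("obs%02d", observer_index),
    chromosome_index = truth$chromosome_index,
    long_arm = arms$long_arm,
    short_arm = arms$short_arm
  )
}

#' Simulate a full multi-observer study of one plate
#'
#' Draws `n_observers` independent simulated measurements of the true
#' karyotype and assembles them into the per-observer trait table, emulating
#' a study in which many evaluators independently measure the same metaphase
#' plate.
#'
#' @param cfg A [simulation_config()].
#'
#' @return A list of class `karyo_simulation` with elements
#'   `measurements` (long tibble of all observers' arm measurements),
#'   `study` (the [build_study_table()] result), `truth` (the true plate),
#'   `true_params` (descriptors of the true plate) and `config`.
#' @examples
#' truth <- make_true_karyotype(seed = 7)
#' sim <- simulate_study(simulation_config(truth, n_observers = 15, seed = 7))
#' pearson_matrix(sim$study)
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  truth <- normalize_arms(cfg$true_karyotype, quiet = TRUE)
  measurements <- purrr::map(
    seq_len(cfg$n_observers),
    function(i) simulate_observer(truth, cfg, i)
  ) |>
    dplyr::bind_rows()
  study <- build_study_table(measurements)
  structure(
    list(
      measurements = measurements,
      study = study,
      truth = truth,
      true_params = karyotype_params(truth, normalize = FALSE),
      config = cfg
    ),
    class = "karyo_simulation"
  )
}

#' @export
print.karyo_simulation <- function(x, ...) {
  cat("Simulated observer study:", x$config$n_observers, "observers,",
      nrow(x$truth), "chromosomes,", x$config$bias_mode, "bias mode\n")
  print(x$study, n = 5)
  invisible(x)
}

#' Replicate the simulated study and track the THL-MCA coupling
#'
#' Runs the full simulate-then-analyse pipeline once per seed and records,
#' for each replicate study, the Pearson correlation between THL and M_CA
#' across observers plus the across-observer CVs of all four traits. This is
#' the Monte-Carlo experiment that probes whether a shared short-arm
#' overestimation simultaneously inflates THL and deflates M_CA (a negative
#' r), and which traits the error model destabilises most.
#'
#' @param cfg A [simulation_config()]; its `seed` field is replaced by each
#'   element of `seeds` in turn.
#' @param seeds Integer vector of replicate seeds.
#'
#' @return A tibble with one row per replicate: `seed`, `r_thl_mca`,
#'   `p_thl_mca`, and `cv_THL`, `cv_M_CA`, `cv_CV_CL`, `cv_CV_CI`.
#' @export
replicate_study_correlation <- function(cfg, seeds = 0:199) {
  stopifnot(inherits(cfg, "simulation_config"))
  purrr::map(seeds, function(s) {
    cfg$seed <- as.integer(s)
    sim <- simulate_study(cfg)
    cm <- pearson_matrix(sim$study)
    cvs <- trait_cv(sim$study)
    tibble::tibble(
      seed = as.integer(s),
      r_thl_mca = cm$r["THL", "M_CA"],
      p_thl_mca = cm$p["THL", "M_CA"],
      cv_THL = cvs$cv[cvs$trait == "THL"],
      cv_M_CA = cvs$cv[cvs$trait == "M_CA"],
      cv_CV_CL = cvs$cv[cvs$trait == "CV_CL"],
      cv_CV_CI = cvs$cv[cvs$trait == "CV_CI"]
    )
  }) |>
    dplyr::bind_rows()
}

# Seed the RNG locally: restores the caller's .Random.seed on exit so
# simulation helpers do not disturb the session's random stream.
local_rng_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  defer_expr <- if (is.null(old)) {
    quote(rm(".Random.seed", envir = globalenv()))
  } else {
    substitute(assign(".Random.seed", old, envir = globalenv()),
               list(old = old))
  }
  do.call(on.exit, list(defer_expr, add = TRUE), envir = envir)
  set.seed(seed)
  invisible(NULL)
}
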