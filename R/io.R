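#' Coerce to the long measurement table
#'
#' Validates that a data frame follows the long measurement schema (one row
#' per chromosome: `plate_id`, `observer_id`, `chromosome_index`,
#' `long_arm`, `short_arm`) and returns it as a tibble. `chromosome_index`
#' is optional and filled sequentially within each observer when absent.
#'
#' @param data A data frame.
#' @return A tibble with the schema columns first.
#' @export
as_measurement_tbl <- function(data) {
  if (!is.data.frame(data)) {
    abort("Measurements must be a data frame.")
  }
  data <- tibble::as_tibble(data)
  required <- c("plate_id", "observer_id", "long_arm", "short_arm")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Measurement table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (!"chromosome_index" %in% names(data)) {
    data <- data |>
      dplyr::group_by(.data$plate_id, .data$observer_id) |>
      dplyr::mutate(chromosome_index = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  dplyr::relocate(data, dplyr::all_of(measurement_cols))
}

#' Read arm measurements from CSV
#'
#' Reads a long-format measurement CSV (comma-separated, decimal point,
#' UTF-8, header required; header matching is case-insensitive) and
#' validates it: required columns present, lengths parseable as finite
#' non-negative decimals, `(plate_id, observer_id, chromosome_index)` unique.
#' Rows whose arms are given short-before-long are swapped with a warning.
#'
#' @param path Path to the CSV file.
#' @param col_map Optional named character vector renaming non-standard
#'   headers to the schema, e.g. `c(long_arm = "L", short_arm = "S")` for a
#'   file whose columns are `L` and `S` (useful when ingesting third-party
#'   exports whose layout differs from the documented schema).
#' @param normalize If `TRUE` (default) apply [normalize_arms()].
#'
#' @return A measurement tibble (see [as_measurement_tbl()]).
#' @export
read_measurements <- function(path, col_map = NULL, normalize = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0) {
    abort(paste0("Empty measurement file: ", path))
  }
  if (!is.null(col_map)) {
    if (is.null(names(col_map)) || any(names(col_map) == "")) {
      abort("`col_map` must be a named vector: c(schema_name = \"file_header\").")
    }
    for (schema_name in names(col_map)) {
      hit <- which(tolower(names(raw)) == tolower(col_map[[schema_name]]))
      if (length(hit) == 1) names(raw)[hit] <- schema_name
    }
  }
  # Case-insensitive header matching against the schema.
  for (col in measurement_cols) {
    hit <- which(tolower(names(raw)) == tolower(col))
    if (length(hit) == 1) names(raw)[hit] <- col
  }
  required <- c("plate_id", "observer_id", "long_arm", "short_arm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  parse_len <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0) {
      abort(paste0("Non-numeric or non-finite `", col, "` in row(s) ",
                   paste(head(bad, 5), collapse = ", "),
                   " of ", path, "."))
    }
    v
  }
  raw$long_arm <- parse_len(raw$long_arm, "long_arm")
  raw$short_arm <- parse_len(raw$short_arm, "short_arm")
  if ("chromosome_index" %in% names(raw)) {
    raw$chromosome_index <- parse_len(raw$chromosome_index, "chromosome_index")
    dup <- which(duplicated(raw[c("plate_id", "observer_id",
                                  "chromosome_index")]))
    if (length(dup) > 0) {
      abort(paste0("Duplicate (plate_id, observer_id, chromosome_index) ",
                   "key in row(s) ", paste(head(dup, 5), collapse = ", "),
                   " of ", path, "."))
    }
  }
  out <- as_measurement_tbl(raw)
  if (normalize) {
    out <- normalize_arms(out)
  }
  out
}

#' Write arm measurements to CSV
#'
#' Writes a measurement tibble in the canonical schema (comma-separated,
#' decimal point, UTF-8, full precision) so that a read/write round trip
#' preserves every value exactly.
#'
#' @param data A measurement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  data <- as_measurement_tbl(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Reads a [simulation_config()] from a YAML file whose keys mirror the
#' constructor arguments. The true karyotype is given either inline under
#' `true_karyotype:` (keys `n_pairs`, `length_range`, `ci_range`, `seed`)
#' or as `true_karyotype_csv:` pointing at a measurement CSV (relative paths
#' resolve against the YAML file's directory).
#'
#' @param path Path to the YAML file.
#' @param seed Optional integer overriding the file's `seed`.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path))
  }
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$true_karyotype_csv)) {
    csv <- cfg$true_karyotype_csv
    if (!file.exists(csv)) {
      csv <- file.path(dirname(path), cfg$true_karyotype_csv)
    }
    truth <- read_measurements(csv)
  } else if (!is.null(cfg$true_karyotype)) {
    tk <- cfg$true_karyotype
    truth <- make_true_karyotype(
      n_pairs = tk$n_pairs %||% 9,
      length_range = unlist(tk$length_range %||% c(2, 6)),
      ci_range = unlist(tk$ci_range %||% c(0.25, 0.45)),
      seed = tk$seed %||% 1L
    )
  } else {
    abort("Config must define `true_karyotype` or `true_karyotype_csv`.")
  }
  simulation_config(
    true_karyotype = truth,
    n_observers = cfg$n_observers %||% 15,
    sigma_calibration = cfg$sigma_calibration %||% 0.05,
    sigma_arm = cfg$sigma_arm %||% 0.03,
    sigma_shortarm_bias = cfg$sigma_shortarm_bias %||% 0.15,
    bias_mode = cfg$bias_mode %||% "additive",
    seed = seed %||% cfg$seed %||% 1L
  )
}

#' Write the observer-study output bundle
#'
#' Writes the full analysis of one observer-study table to a directory:
#' per-observer descriptors (`observer_params.csv`), trait dispersion and
#' CVs (`trait_dispersion.csv`), the correlation matrices
#' (`correlation_r.csv`, `correlation_p.csv`, 5 significant digits, plus
#' the tidy pair table `correlation_pairs.csv` at full precision),
#' boxplot-ready long values (`boxplot_data.csv`) and the THL vs M_CA
#' scatter pairs (`scatter_thl_mca.csv`).
#'
#' @param study An `observer_study` table from [build_study_table()].
#' @param dir Output directory (created if needed).
#' @param highlight Optional `observer_id`(s) to flag in the scatter export.
#' @return The directory path, invisibly.
#' @export
write_study_outputs <- function(study, dir, highlight = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(study),
                   file.path(dir, "observer_params.csv"))
  disp <- trait_cv(study)
  readr::write_csv(dplyr::select(tibble::as_tibble(disp), -"values"),
                   file.path(dir, "trait_dispersion.csv"))
  boxdata <- disp |>
    tibble::as_tibble() |>
    dplyr::select("trait", "values") |>
    tidyr::unnest("values") |>
    dplyr::rename(value = "values")
  readr::write_csv(boxdata, file.path(dir, "boxplot_data.csv"))
  cm <- pearson_matrix(study)
  mat_tbl <- function(m) {
    tibble::as_tibble(signif(m, 5), rownames = "trait")
  }
  readr::write_csv(mat_tbl(cm$r), file.path(dir, "correlation_r.csv"))
  readr::write_csv(mat_tbl(cm$p), file.path(dir, "correlation_p.csv"))
  readr::write_csv(tidy(cm), file.path(dir, "correlation_pairs.csv"))
  sc <- scatter_export(study, "THL", "M_CA", highlight = highlight)
  readr::write_csv(sc, file.path(dir, "scatter_thl_mca.csv"))
  invisible(dir)
}
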