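# Canonical per-cow record layout shared by every stage of the pipeline.

#' Canonical columns of a VFA/methane dataset
#'
#' A valid dataset is an ordinary data frame (returned as a tibble) with one
#' row per cow and the columns below. Volatile fatty acid (VFA) proportions
#' are molar, expressed as mol/100 mol total VFA; `butyrate` is total
#' butyrate (n- plus iso-).
#'
#' Required: `experiment_id`, `treatment_id`, `cow_id`, `acetate`,
#' `propionate`, `butyrate`, `methane_yield` (g CH4/kg dry-matter intake).
#' Optional: `propionate_conc` (mmol/L), `total_vfa_conc` (mmol/L), `dmi`
#' (kg/day), and `n_butyrate`/`iso_butyrate` which, when both are present and
#' `butyrate` is absent, are summed into `butyrate` on read.
#'
#' @return Character vector of canonical column names, required first.
#' @export
vfa_columns <- function() {
  c("experiment_id", "treatment_id", "cow_id",
    "acetate", "propionate", "butyrate", "methane_yield",
    "propionate_conc", "total_vfa_conc", "dmi")
}

.vfa_required <- function() vfa_columns()[1:7]
.vfa_numeric <- function() {
  c("acetate", "propionate", "butyrate", "methane_yield",
    "propionate_conc", "total_vfa_conc", "dmi")
}

#' Validate a VFA/methane dataset
#'
#' Checks the structural and scientific invariants of a per-cow dataset:
#' required columns present and numeric where appropriate; acetate (A),
#' propionate (P) and butyrate (B) strictly positive with A + P + B <= 100
#' (the remainder being minor VFA); methane yield strictly positive (a
#' warning is raised for values outside the plausible 2-50 g/kg DMI range);
#' `propionate_conc` consistent with `P/100 * total_vfa_conc` when both are
#' given; and (experiment, treatment, cow) triples unique. Violations are
#' reported with row numbers. Out-of-range but parseable values are errors,
#' never silently repaired.
#'
#' @param data A data frame with the columns of [vfa_columns()].
#' @param require_methane If `FALSE`, allow `methane_yield` to be absent
#'   (prediction-only inputs).
#' @return `data` as a tibble, invisibly, with `n_butyrate`/`iso_butyrate`
#'   folded into `butyrate` when needed.
#' @export
validate_vfa_data <- function(data, require_methane = TRUE) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  data <- tibble::as_tibble(data)

  if (!"butyrate" %in% names(data) &&
      all(c("n_butyrate", "iso_butyrate") %in% names(data))) {
    data$butyrate <- data$n_butyrate + data$iso_butyrate
  }

  required <- .vfa_required()
  if (!require_methane) required <- setdiff(required, "methane_yield")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0) return(invisible(data))

  for (col in intersect(.vfa_numeric(), names(data))) {
    if (!is.numeric(data[[col]])) {
      coerced <- suppressWarnings(as.numeric(data[[col]]))
      bad <- which(is.na(coerced) & !is.na(data[[col]]))
      if (length(bad) > 0) {
        stop(sprintf("column '%s' is not numeric (e.g. row %d: '%s')",
                     col, bad[1], as.character(data[[col]][bad[1]])),
             call. = FALSE)
      }
      data[[col]] <- coerced
    }
  }

  .fail_rows <- function(bad, msg) {
    if (length(bad) > 0) {
      stop(sprintf("%s (row%s %s)", msg, if (length(bad) > 1) "s" else "",
                   paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  .fail_rows(which(is.na(data$acetate) | data$acetate <= 0),
             "acetate must be > 0")
  .fail_rows(which(is.na(data$propionate) | data$propionate <= 0),
             "propionate must be > 0")
  .fail_rows(which(is.na(data$butyrate) | data$butyrate <= 0),
             "butyrate must be > 0")
  .fail_rows(which(data$acetate + data$propionate + data$butyrate > 100 + 1e-9),
             "acetate + propionate + butyrate must not exceed 100 mol/100 mol")
  if ("methane_yield" %in% names(data)) {
    .fail_rows(which(is.na(data$methane_yield) | data$methane_yield <= 0),
               "methane_yield must be > 0")
    implausible <- which(data$methane_yield < 2 | data$methane_yield > 50)
    if (length(implausible) > 0) {
      warning(sprintf(
        "methane_yield outside the plausible range [2, 50] g/kg DMI (row%s %s)",
        if (length(implausible) > 1) "s" else "",
        paste(utils::head(implausible, 5), collapse = ", ")), call. = FALSE)
    }
  }
  if (all(c("propionate_conc", "total_vfa_conc") %in% names(data))) {
    both <- which(!is.na(data$propionate_conc) & !is.na(data$total_vfa_conc))
    if (length(both) > 0) {
      expected <- data$propionate[both] / 100 * data$total_vfa_conc[both]
      rel <- abs(data$propionate_conc[both] - expected) /
        pmax(abs(expected), .Machine$double.eps)
      .fail_rows(both[rel > 1e-6],
                 "propionate_conc inconsistent with propionate/100 * total_vfa_conc")
    }
  }

  key <- paste(data$experiment_id, data$treatment_id, data$cow_id, sep = "\r")
  .fail_rows(which(duplicated(key)),
             "(experiment_id, treatment_id, cow_id) triples must be unique")

  invisible(data)
}

#' Read a VFA/methane dataset from CSV
#'
#' Reads a comma-separated file (UTF-8, "." decimal, header mandatory) into a
#' validated tibble. Non-canonical headers can be mapped with `column_map`.
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(acetate = "C2_molpct")`.
#' @param require_methane Passed to [validate_vfa_data()].
#' @return A validated tibble with canonical columns, row order preserved.
#' @export
#' @examples
#' d <- make_fixture("tiny_2exp")
#' path <- tempfile(fileext = ".csv")
#' write_vfa_data(d, path)
#' identical(nrow(read_vfa_data(path)), nrow(d))
read_vfa_data <- function(path, column_map = NULL, require_methane = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(names(column_map) == "")) {
      stop("`column_map` must be a named character vector (canonical = file)",
           call. = FALSE)
    }
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src) > 0) {
      stop("column_map refers to absent column(s): ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (canonical in names(column_map)) {
      names(raw)[names(raw) == column_map[[canonical]]] <- canonical
    }
  }
  keep <- intersect(c(vfa_columns(), "n_butyrate", "iso_butyrate"), names(raw))
  data <- validate_vfa_data(raw[keep], require_methane = require_methane)
  data[intersect(vfa_columns(), names(data))]
}

#' Write a VFA/methane dataset to CSV
#'
#' Writes canonical columns (in canonical order, optional ones only when
#' present) so that `read_vfa_data(write_vfa_data(d))` reproduces `d`
#' field-for-field.
#'
#' @param data A valid dataset (see [validate_vfa_data()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vfa_data <- function(data, path) {
  data <- validate_vfa_data(data, require_methane = "methane_yield" %in% names(data))
  cols <- intersect(vfa_columns(), names(data))
  readr::write_csv(data[cols], path, progress = FALSE)
  invisible(path)
}

#' Summarise a VFA/methane dataset
#'
#' Per-variable mean, sample standard deviation (n - 1 divisor), minimum and
#' maximum for methane yield and the three VFA proportions, together with
#' counts of experiments, treatments and cows — the conventional descriptive
#' table for a multi-experiment rumen-fermentation dataset.
#'
#' @param data A valid dataset.
#' @return An object of class `vfa_summary`: a list with `stats` (a tibble,
#'   one row per variable) and the counts `n_experiments`, `n_treatments`,
#'   `n_records`. `tidy()` returns the stats tibble.
#' @export
summarize_vfa_data <- function(data) {
  data <- validate_vfa_data(data)
  if (nrow(data) == 0) stop("cannot summarise an empty dataset", call. = FALSE)
  vars <- c("methane_yield", "acetate", "propionate", "butyrate")
  stats <- purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    tibble::tibble(
      variable = v,
      mean = mean(x),
      sd = if (length(x) > 1) stats::sd(x) else NA_real_,
      min = min(x),
      max = max(x)
    )
  })
  structure(
    list(
      stats = stats,
      n_experiments = dplyr::n_distinct(data$experiment_id),
      n_treatments = dplyr::n_distinct(
        paste(data$experiment_id, data$treatment_id, sep = "\r")),
      n_records = nrow(data)
    ),
    class = "vfa_summary"
  )
}

#' @export
print.vfa_summary <- function(x, ...) {
  cat(sprintf("VFA/methane dataset: %d records, %d experiments, %d treatments\n",
              x$n_records, x$n_experiments, x$n_treatments))
  print(x$stats)
  invisible(x)
}

#' @export
tidy.vfa_summary <- function(x, ...) x$stats

# internal: counts used by fitting preconditions
.vfa_counts <- function(data) {
  list(
    experiments = dplyr::n_distinct(data$experiment_id),
    treatments = dplyr::n_distinct(
      paste(data$experiment_id, data$treatment_id, sep = "\r")),
    records = nrow(data)
  )
}
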