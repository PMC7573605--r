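#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

#' Study phases and hemodynamic variables
#'
#' The three protocol phases of a controlled hemorrhagic-shock experiment,
#' in chronological order, and the four monitored hemodynamic variables.
#' SBP and DBP are in mmHg, HR in beats/min, CO in l/min.
#'
#' @name hv_levels
NULL

#' @rdname hv_levels
#' @export
hv_phases <- c("pre_bleeding", "bleeding", "post_bleeding")

#' @rdname hv_levels
#' @export
hv_variables <- c("SBP", "DBP", "HR", "CO")

#' Blood-pressure variables (mmHg-scaled error bins apply to these)
#' @rdname hv_levels
#' @export
hv_bp_variables <- c("SBP", "DBP")

hv_columns <- c("animal_id", "phase", "time_min", "variable",
                "reference_value", "device_value")

#' Validate a paired-observation dataset
#'
#' A dataset is a long-format tibble of timestamped paired observations:
#' one row per (animal, variable, time) holding the invasive reference
#' value and the device value in the same unit. `validate_dataset()`
#' checks the schema and the row-level invariants and returns the data
#' (invisibly unchanged) or throws an informative error.
#'
#' Invariants checked:
#' * all six columns present (`animal_id`, `phase`, `time_min`,
#'   `variable`, `reference_value`, `device_value`);
#' * `phase` in `r toString(hv_phases)`, `variable` in
#'   `r toString(hv_variables)`;
#' * `time_min` finite and non-negative; both values finite and strictly
#'   positive;
#' * no duplicate (animal_id, variable, time_min) key;
#' * within an animal, phase membership follows time order
#'   (all pre-bleeding times precede bleeding times, which precede
#'   post-bleeding times).
#'
#' @param data A data frame of paired observations.
#' @return `data`, invisibly, as a tibble.
#' @export
validate_dataset <- function(data) {
  if (!is.data.frame(data)) {
    stop("dataset must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(hv_columns, names(data))
  if (length(missing_cols) > 0) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    return(invisible(data))
  }

  bad_phase <- which(!data$phase %in% hv_phases)
  if (length(bad_phase) > 0) {
    stop("invalid phase at row(s) ", paste(utils::head(bad_phase, 5), collapse = ", "),
         "; phases must be one of: ", paste(hv_phases, collapse = ", "),
         call. = FALSE)
  }
  bad_var <- which(!data$variable %in% hv_variables)
  if (length(bad_var) > 0) {
    stop("invalid variable at row(s) ", paste(utils::head(bad_var, 5), collapse = ", "),
         "; variables must be one of: ", paste(hv_variables, collapse = ", "),
         call. = FALSE)
  }
  bad_time <- which(!is.finite(data$time_min) | data$time_min < 0)
  if (length(bad_time) > 0) {
    stop("time_min must be finite and non-negative; offending row(s): ",
         paste(utils::head(bad_time, 5), collapse = ", "), call. = FALSE)
  }
  for (col in c("reference_value", "device_value")) {
    v <- data[[col]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0) {
      stop(col, " must be finite and strictly positive; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }

  key <- paste(data$animal_id, data$variable, data$time_min, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (animal_id, variable, time_min) key at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }

  # phase order must follow time order within each animal
  ord <- data |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      ok = {
        ph <- match(.data$phase, hv_phases)
        tm <- .data$time_min
        o <- order(tm, ph)
        all(diff(ph[o]) >= 0)
      },
      .groups = "drop"
    )
  if (!all(ord$ok)) {
    bad_animals <- ord$animal_id[!ord$ok]
    stop("phase membership does not follow time order for animal(s): ",
         paste(utils::head(bad_animals, 5), collapse = ", "), call. = FALSE)
  }

  invisible(data)
}

#' Read a paired-observation dataset from CSV
#'
#' Reads a long-format CSV with the columns `animal_id`, `phase`,
#' `time_min`, `variable`, `reference_value`, `device_value` (comma
#' separator, `.` decimal, header required) and validates it.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of paired observations with a
#'   `"provenance"` attribute holding the file path.
#' @seealso [write_dataset()], [validate_dataset()]
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(hv_columns, names(data))
  if (length(missing_cols) > 0) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data[hv_columns])
  data$animal_id <- as.character(data$animal_id)
  if (nrow(data) == 0) {
    warning("file ", path, " contains no data rows", call. = FALSE)
  }
  validate_dataset(data)
  attr(data, "provenance") <- path
  data
}

#' Write a paired-observation dataset to CSV
#'
#' Writes the six canonical columns in canonical row order
#' (animal_id, variable, time_min) so repeated writes of the same data
#' are byte-identical. Round-trips through [read_dataset()].
#'
#' @param data A valid paired-observation dataset.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  data <- validate_dataset(data)
  out <- data |>
    dplyr::arrange(.data$animal_id, .data$variable, .data$time_min) |>
    dplyr::select(dplyr::all_of(hv_columns))
  utils::write.csv(as.data.frame(out), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a dataset into per-animal, per-variable measurement series
#'
#' A measurement series is the unit on which outlier screening and
#' successive-change (trending) analysis operate: all observations of one
#' variable in one animal, in strictly increasing time order.
#'
#' @param data A valid paired-observation dataset.
#' @return A list of tibbles, one per (animal_id, variable) combination
#'   present in the data, each sorted by `time_min`. Names are
#'   `"<animal_id>.<variable>"`.
#' @export
split_series <- function(data) {
  data <- validate_dataset(data)
  if (nrow(data) == 0) {
    return(list())
  }
  data <- dplyr::arrange(data, .data$animal_id, .data$variable, .data$time_min)
  f <- paste(data$animal_id, data$variable, sep = ".")
  split(data, factor(f, levels = unique(f)))
}
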