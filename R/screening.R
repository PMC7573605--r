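# Outlier screen for invasively measured series: successive percentage
# differences on the reference channel, a pooled 2*SD cutoff per
# variable, and single-pass conjunctive elimination (a point goes only
# when it differs from BOTH neighbours by more than the cutoff).

#' Successive percentage differences within a measurement series
#'
#' For each interior point i of a series' reference channel, the
#' percentage difference from the preceding value,
#' `100 * (x_i - x_{i-1}) / x_{i-1}`, and from the following value,
#' `100 * (x_i - x_{i+1}) / x_{i+1}`. Endpoints have no pair. A zero
#' neighbour makes a delta undefined; such points are flagged and carry
#' `NA` deltas.
#'
#' @param series One measurement series (a tibble from [split_series()]).
#' @return A tibble with one row per interior point: `animal_id`,
#'   `variable`, `time_min`, `delta_prev`, `delta_next`, `defined`.
#'   Series shorter than 3 yield zero rows.
#' @export
percent_deltas <- function(series) {
  stopifnot(is.data.frame(series))
  n <- nrow(series)
  if (n > 0) {
    if (length(unique(series$animal_id)) != 1 ||
        length(unique(series$variable)) != 1) {
      stop("a series must contain a single animal_id and variable",
           call. = FALSE)
    }
    if (is.unsorted(series$time_min, strictly = TRUE)) {
      stop("series times must be strictly increasing", call. = FALSE)
    }
  }
  if (n < 3) {
    return(tibble::tibble(animal_id = character(0), variable = character(0),
                          time_min = numeric(0), delta_prev = numeric(0),
                          delta_next = numeric(0), defined = logical(0)))
  }
  i <- 2:(n - 1)
  x <- series$reference_value
  prev_ok <- x[i - 1] != 0
  next_ok <- x[i + 1] != 0
  dp <- ifelse(prev_ok, 100 * (x[i] - x[i - 1]) / x[i - 1], NA_real_)
  dn <- ifelse(next_ok, 100 * (x[i] - x[i + 1]) / x[i + 1], NA_real_)
  tibble::tibble(
    animal_id = series$animal_id[i],
    variable = series$variable[i],
    time_min = series$time_min[i],
    delta_prev = dp,
    delta_next = dn,
    defined = prev_ok & next_ok
  )
}

#' Screen a dataset for transient outliers
#'
#' Implements the successive-percentage-difference screen applied to the
#' invasive (reference) channel before any agreement analysis. Per
#' variable, pooling interior points across all animals:
#'
#' 1. compute each point's percentage differences from its preceding and
#'    following values ([percent_deltas()]);
#' 2. take the SD of the pooled set of all absolute deltas (preceding
#'    and following combined) and set the cutoff `T = k * SD`;
#' 3. eliminate a point iff **both** `|delta_prev| > T` and
#'    `|delta_next| > T`.
#'
#' The screen is single-pass (deltas and cutoffs are computed once, on
#' the unscreened data); endpoints are never removed; removing a point
#' drops its reference and device values together so downstream pairs
#' stay aligned; surviving values are never altered.
#'
#' @param data A valid paired-observation dataset.
#' @param k Cutoff multiplier on the pooled SD (default 2).
#' @return A list with `clean` (the screened dataset) and `report`, a
#'   list with `removed` (tibble of animal_id/variable/time_min),
#'   `per_variable_counts` (named integer), `thresholds` (named numeric,
#'   the `k * SD` cutoff per variable), and `total_screened` (number of
#'   interior points evaluated).
#' @export
screen_outliers <- function(data, k = 2) {
  data <- validate_dataset(data)
  stopifnot(is.numeric(k), length(k) == 1, k > 0)
  series_list <- split_series(data)
  deltas <- dplyr::bind_rows(lapply(series_list, percent_deltas))

  empty_report <- function() {
    list(removed = tibble::tibble(animal_id = character(0),
                                  variable = character(0),
                                  time_min = numeric(0)),
         per_variable_counts = stats::setNames(
           integer(length(hv_variables)), hv_variables),
         thresholds = stats::setNames(
           rep(NA_real_, length(hv_variables)), hv_variables),
         total_screened = 0L)
  }
  if (nrow(deltas) == 0) {
    warning("no series long enough to screen (need >= 3 points)",
            call. = FALSE)
    return(list(clean = data, report = empty_report()))
  }

  report <- empty_report()
  report$total_screened <- sum(deltas$defined)
  removed <- list()
  for (v in intersect(hv_variables, unique(deltas$variable))) {
    dv <- deltas[deltas$variable == v & deltas$defined, ]
    if (nrow(dv) == 0) next
    pooled <- c(abs(dv$delta_prev), abs(dv$delta_next))
    cutoff <- k * stats::sd(pooled)
    report$thresholds[v] <- cutoff
    hit <- abs(dv$delta_prev) > cutoff & abs(dv$delta_next) > cutoff
    if (any(hit)) {
      removed[[v]] <- dv[hit, c("animal_id", "variable", "time_min")]
      report$per_variable_counts[v] <- sum(hit)
    }
  }
  if (length(removed) > 0) {
    report$removed <- dplyr::bind_rows(removed)
    drop_key <- paste(report$removed$animal_id, report$removed$variable,
                      report$removed$time_min, sep = "\r")
    keep <- !(paste(data$animal_id, data$variable, data$time_min,
                    sep = "\r") %in% drop_key)
    clean <- data[keep, ]
  } else {
    clean <- data
  }
  attr(clean, "provenance") <- attr(data, "provenance")
  list(clean = clean, report = report)
}
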