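# Trending (successive-change) analysis: four-quadrant concordance with
# a central exclusion zone and Pearson correlation of the changes.

#' Default exclusion-zone half-widths
#'
#' +/- 2 mmHg for blood pressure and 0.5 l/min for cardiac output, the
#' conventional zones used to remove clinically meaningless small
#' changes from four-quadrant analysis. HR trending is not analysed.
#'
#' @export
hv_default_zones <- c(SBP = 2, DBP = 2, CO = 0.5)

#' Successive changes within a measurement series
#'
#' One change pair per consecutive surviving observation of an animal's
#' series: the change on the reference channel and on the device channel
#' over the same interval. Changes chain across phase boundaries;
#' intervals may be unequal after screening.
#'
#' @param series One measurement series (a tibble from [split_series()]).
#' @return A tibble with one row per consecutive pair: `animal_id`,
#'   `variable`, `t_from`, `t_to`, `d_ref`, `d_dev`. Series shorter than
#'   2 yield zero rows.
#' @export
successive_changes <- function(series) {
  stopifnot(is.data.frame(series))
  n <- nrow(series)
  if (n > 0 && is.unsorted(series$time_min, strictly = TRUE)) {
    stop("series times must be strictly increasing", call. = FALSE)
  }
  if (n < 2) {
    return(tibble::tibble(animal_id = character(0), variable = character(0),
                          t_from = numeric(0), t_to = numeric(0),
                          d_ref = numeric(0), d_dev = numeric(0)))
  }
  i <- 2:n
  tibble::tibble(
    animal_id = series$animal_id[i],
    variable = series$variable[i],
    t_from = series$time_min[i - 1],
    t_to = series$time_min[i],
    d_ref = series$reference_value[i] - series$reference_value[i - 1],
    d_dev = series$device_value[i] - series$device_value[i - 1]
  )
}

#' Four-quadrant concordance of successive changes
#'
#' A change pair is excluded iff both `|d_ref| <= zone` and
#' `|d_dev| <= zone` (central exclusion square, inclusive boundary; set
#' `zone_rule = "either"` for the alternative rule excluding a pair when
#' either channel's change is small). Among the surviving pairs, a pair
#' is concordant iff the two changes have the same strict sign — a zero
#' change on either axis belongs to no quadrant and is never concordant.
#' The concordance rate is the percentage of concordant pairs among
#' surviving pairs (set `denominator = "all"` for the literal
#' all-changes denominator).
#'
#' @param changes A tibble of change pairs ([successive_changes()]), all
#'   of one variable.
#' @param zone Exclusion half-width in the variable's units; defaults to
#'   [hv_default_zones] for SBP/DBP/CO.
#' @param zone_rule `"both"` (central square, default) or `"either"`.
#' @param denominator `"surviving"` (default) or `"all"`.
#' @return A list: `variable`, `n_changes_total`, `n_excluded`,
#'   `n_concordant`, `concordance_rate` (%), `change_r`, `p_value`,
#'   `all_excluded` flag. With every pair excluded the rate and
#'   correlation are `NA` and `all_excluded` is `TRUE`.
#' @export
four_quadrant <- function(changes, zone = NULL,
                          zone_rule = c("both", "either"),
                          denominator = c("surviving", "all")) {
  zone_rule <- match.arg(zone_rule)
  denominator <- match.arg(denominator)
  vars <- unique(changes$variable)
  if (length(vars) > 1) {
    stop("all change pairs must share one variable", call. = FALSE)
  }
  if (is.null(zone)) {
    if (length(vars) == 0 || !vars %in% names(hv_default_zones)) {
      stop("no default zone for this variable; supply `zone`", call. = FALSE)
    }
    zone <- hv_default_zones[[vars]]
  }
  stopifnot(zone >= 0)
  n_total <- nrow(changes)
  small_ref <- abs(changes$d_ref) <= zone
  small_dev <- abs(changes$d_dev) <= zone
  excluded <- if (zone_rule == "both") small_ref & small_dev
              else small_ref | small_dev
  keep <- changes[!excluded, ]
  n_kept <- nrow(keep)
  concordant <- sign(keep$d_ref) * sign(keep$d_dev) > 0
  n_conc <- sum(concordant)
  denom <- if (denominator == "surviving") n_kept else n_total

  if (n_kept == 0) {
    return(list(variable = if (length(vars)) vars else NA_character_,
                n_changes_total = n_total, n_excluded = n_total,
                n_concordant = 0L, concordance_rate = NA_real_,
                change_r = NA_real_, p_value = NA_real_,
                all_excluded = TRUE))
  }
  rate <- if (denom > 0) 100 * n_conc / denom else NA_real_
  if (n_kept >= 3 && stats::sd(keep$d_ref) > 0 && stats::sd(keep$d_dev) > 0) {
    ct <- stats::cor.test(keep$d_ref, keep$d_dev)
    change_r <- unname(ct$estimate)
    p_value <- ct$p.value
  } else {
    change_r <- NA_real_
    p_value <- NA_real_
  }
  list(variable = vars,
       n_changes_total = n_total,
       n_excluded = sum(excluded),
       n_concordant = as.integer(n_conc),
       concordance_rate = rate,
       change_r = change_r,
       p_value = p_value,
       all_excluded = FALSE)
}

#' Trending table for SBP, DBP and CO
#'
#' Computes successive changes per animal series and the four-quadrant
#' concordance analysis for the three trended variables (HR trending is
#' not part of the analysis surface).
#'
#' @param data A (screened) paired-observation dataset.
#' @param zones Named numeric of exclusion half-widths (default
#'   [hv_default_zones]).
#' @inheritParams four_quadrant
#' @return A tibble with one row per variable: counts, concordance rate,
#'   and the correlation of changes.
#' @export
trending_table <- function(data, zones = hv_default_zones,
                           zone_rule = c("both", "either"),
                           denominator = c("surviving", "all")) {
  zone_rule <- match.arg(zone_rule)
  denominator <- match.arg(denominator)
  data <- validate_dataset(data)
  out <- list()
  for (v in names(zones)) {
    dv <- data[data$variable == v, ]
    if (nrow(dv) == 0) {
      warning("variable ", v, " absent; skipped", call. = FALSE)
      next
    }
    changes <- dplyr::bind_rows(lapply(split_series(dv), successive_changes))
    fq <- four_quadrant(changes, zone = zones[[v]], zone_rule = zone_rule,
                        denominator = denominator)
    out[[v]] <- tibble::as_tibble(fq[c("variable", "n_changes_total",
                                       "n_excluded", "n_concordant",
                                       "concordance_rate", "change_r",
                                       "p_value", "all_excluded")])
  }
  dplyr::bind_rows(out)
}

#' Collect successive changes for one variable across a dataset
#'
#' Convenience used by plots and the pipeline report.
#'
#' @param data A (screened) paired-observation dataset.
#' @param variable One variable name.
#' @return A tibble of change pairs.
#' @export
dataset_changes <- function(data, variable) {
  data <- validate_dataset(data)
  dv <- data[data$variable == variable, ]
  dplyr::bind_rows(lapply(split_series(dv), successive_changes))
}
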