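# Pipeline orchestration: (simulate | ingest) -> screen -> agreement ->
# trending -> structured validation report.

#' Run the full validation pipeline
#'
#' Sequencing mirrors the analysis order of a device-validation study:
#' the dataset is screened for transient outliers first, then the static
#' agreement table and the trending table are computed on the surviving
#' pairs, and acceptability flags are evaluated.
#'
#' Acceptability flags are conveniences referencing published
#' thresholds (CO percentage error <= 30%; SBP/DBP within +/-15 mmHg for
#' at least `bp_within15_min` percent of pairs), not claims of
#' regulatory compliance.
#'
#' @param input A paired-observation dataset (data frame) or a
#'   [sim_config()] to simulate one.
#' @param k Outlier-screen cutoff multiplier (default 2).
#' @param zones Trending exclusion half-widths (default
#'   [hv_default_zones]).
#' @param pe_max CO percentage-error acceptability bound (default 30).
#' @param bp_within15_min Minimum percentage of BP pairs within
#'   +/-15 mmHg for the BP flag (default 85).
#' @return A `validation_report`: a list with `schema_version`,
#'   `provenance`, `counts` (pairs per variable x stratum after
#'   screening), `outliers` (the screening report), `agreement` (tibble),
#'   `trending` (tibble), and `flags`.
#' @export
run_pipeline <- function(input, k = 2, zones = hv_default_zones,
                         pe_max = 30, bp_within15_min = 85) {
  data <- if (inherits(input, "sim_config")) {
    simulate_experiment(input)
  } else {
    validate_dataset(input)
  }
  provenance <- attr(data, "provenance")
  if (is.null(provenance)) provenance <- "unspecified"

  screened <- screen_outliers(data, k = k)
  agreement <- agreement_table(screened$clean)
  trending <- trending_table(screened$clean, zones = zones)

  counts <- screened$clean |>
    dplyr::count(.data$variable, .data$phase, name = "n_pairs") |>
    dplyr::arrange(match(.data$variable, hv_variables),
                   match(.data$phase, hv_phases))

  co_all <- agreement[agreement$variable == "CO" & agreement$stratum == "all", ]
  bp_all <- agreement[agreement$variable %in% hv_bp_variables &
                        agreement$stratum == "all", ]
  flags <- list(
    co_percentage_error_ok =
      nrow(co_all) == 1 && is.finite(co_all$percentage_error) &&
      co_all$percentage_error <= pe_max,
    bp_within15_ok =
      nrow(bp_all) > 0 && all(bp_all$within_15 >= bp_within15_min)
  )

  structure(list(schema_version = "1.0",
                 provenance = provenance,
                 n_observations = nrow(data),
                 n_after_screening = nrow(screened$clean),
                 counts = counts,
                 outliers = screened$report,
                 agreement = agreement,
                 trending = trending,
                 flags = flags),
            class = "validation_report")
}

#' Write a validation report as versioned JSON
#'
#' @param report A `validation_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  out <- unclass(report)
  out$counts <- as.data.frame(out$counts)
  out$agreement <- as.data.frame(out$agreement)
  out$trending <- as.data.frame(out$trending)
  out$outliers$removed <- as.data.frame(out$outliers$removed)
  out$outliers$per_variable_counts <- as.list(out$outliers$per_variable_counts)
  out$outliers$thresholds <- as.list(out$outliers$thresholds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Hemodynamic monitor validation report (schema ", x$schema_version,
      ")\n", sep = "")
  cat("  provenance: ", x$provenance, "\n", sep = "")
  cat("  observations: ", x$n_observations, " (",
      x$n_after_screening, " after outlier screening; ",
      nrow(x$outliers$removed), " removed)\n", sep = "")
  cat("\nAgreement (all phases combined):\n")
  all_rows <- x$agreement[x$agreement$stratum == "all", ]
  for (i in seq_len(nrow(all_rows))) {
    r <- all_rows[i, ]
    extra <- if (r$variable == "CO") {
      sprintf(", PE %.1f%%", r$percentage_error)
    } else if (r$variable %in% hv_bp_variables) {
      sprintf(", within 15 mmHg %.0f%%", r$within_15)
    } else ""
    cat(sprintf("  %-3s n=%4d  r=%.3f  ICC=%.3f (SEM %.2f)  bias=%+.2f  LOA [%.2f, %.2f]%s\n",
                r$variable, r$n, r$pearson_r, r$icc, r$sem_measurement,
                r$bias, r$loa_lower, r$loa_upper, extra))
  }
  cat("\nTrending (four-quadrant):\n")
  for (i in seq_len(nrow(x$trending))) {
    r <- x$trending[i, ]
    cat(sprintf("  %-3s changes=%4d excluded=%3d concordance=%s change_r=%s\n",
                r$variable, r$n_changes_total, r$n_excluded,
                ifelse(is.na(r$concordance_rate), "NA",
                       sprintf("%.1f%%", r$concordance_rate)),
                ifelse(is.na(r$change_r), "NA",
                       sprintf("%.3f", r$change_r))))
  }
  cat("\nFlags: CO percentage error ok: ", x$flags$co_percentage_error_ok,
      "; BP within-15 ok: ", x$flags$bp_within15_ok, "\n", sep = "")
  invisible(x)
}
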