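# Static (point-wise) method-comparison statistics: Pearson correlation
# and device-on-reference regression, ICC(A,1) with standard error of
# measurement, Bland-Altman bias and 95% limits of agreement, Critchley
# percentage error for cardiac output, and ESH-style error bins for
# blood pressure.

#' Pearson correlation and device-on-reference regression
#'
#' Ordinary least squares of the device value on the reference value,
#' with Pearson's r and two-sided tests that the slope and the intercept
#' equal zero.
#'
#' @param reference,device Numeric vectors of paired measurements.
#' @return A list: `n`, `r`, `p` (correlation test), `slope`,
#'   `intercept`, `p_slope`, `p_intercept`.
#' @export
pearson_regression <- function(reference, device) {
  stopifnot(length(reference) == length(device))
  if (length(reference) < 3) {
    stop("need at least 3 pairs", call. = FALSE)
  }
  if (stats::sd(reference) == 0 || stats::sd(device) == 0) {
    stop("zero variance on a channel; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(reference, device)
  # a perfect fit (e.g. identical channels) is a legitimate degenerate
  # input here; silence summary.lm's reliability warning for that case
  fit <- withCallingHandlers(
    stats::summary.lm(stats::lm(device ~ reference))$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(n = length(reference),
       r = unname(ct$estimate),
       p = ct$p.value,
       slope = fit["reference", "Estimate"],
       intercept = fit["(Intercept)", "Estimate"],
       p_slope = fit["reference", "Pr(>|t|)"],
       p_intercept = fit["(Intercept)", "Pr(>|t|)"])
}

#' Intraclass correlation (absolute agreement) and SEM
#'
#' Two-way random-effects, absolute-agreement, single-measurement
#' intraclass correlation — ICC(2,1) in the Shrout-Fleiss scheme,
#' ICC(A,1) in McGraw-Wong — computed from the two-way ANOVA mean
#' squares with subjects as rows and the two methods as columns:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' The standard error of measurement is the pooled SD of all
#' measurements times `sqrt(1 - ICC)`, in the variable's units.
#'
#' Negative ICC estimates (possible in degenerate samples) are clamped
#' to 0 and flagged via `clamped = TRUE`.
#'
#' @param reference,device Numeric vectors of paired measurements.
#' @return A list: `n`, `icc`, `sem_measurement`, `clamped`,
#'   `degenerate` (zero between-subject variance).
#' @export
icc_sem <- function(reference, device) {
  stopifnot(length(reference) == length(device))
  n <- length(reference)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  x <- cbind(reference, device)
  k <- 2
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  resid <- x - outer(row_means, rep(1, k)) -
    outer(rep(1, n), col_means) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))

  degenerate <- isTRUE(all.equal(msr, 0)) || stats::sd(row_means) == 0
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- if (denom == 0) 1 else (msr - mse) / denom
  clamped <- FALSE
  if (icc < 0) {
    icc <- 0
    clamped <- TRUE
  }
  pooled_sd <- stats::sd(as.vector(x))
  list(n = n,
       icc = icc,
       sem_measurement = pooled_sd * sqrt(max(1 - icc, 0)),
       clamped = clamped,
       degenerate = degenerate)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are taken device minus reference; the limits of agreement
#' are `bias +/- 1.96 * SD` of the differences (sample SD, n-1
#' denominator).
#'
#' @param reference,device Numeric vectors of paired measurements.
#' @return A list: `n`, `bias`, `sd_diff`, `loa_lower`, `loa_upper`.
#' @export
bland_altman <- function(reference, device) {
  stopifnot(length(reference) == length(device))
  if (length(reference) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- device - reference
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  list(n = length(d),
       bias = bias,
       sd_diff = sd_diff,
       loa_lower = bias - 1.96 * sd_diff,
       loa_upper = bias + 1.96 * sd_diff)
}

#' Percentage error for cardiac-output agreement
#'
#' The Critchley criterion: the half-width of the 95% limits of
#' agreement as a percentage of the mean reference cardiac output,
#' `100 * 1.96 * SD(differences) / mean(reference)`. Values at or below
#' 30% are conventionally considered clinically acceptable for CO
#' monitors.
#'
#' @param reference,device Numeric vectors of paired CO measurements
#'   (l/min).
#' @return Percentage error (scalar, %).
#' @export
percentage_error <- function(reference, device) {
  stopifnot(length(reference) == length(device))
  if (length(reference) < 2) stop("need at least 2 pairs", call. = FALSE)
  m <- mean(reference)
  if (m <= 0) stop("mean reference value must be positive", call. = FALSE)
  100 * 1.96 * stats::sd(device - reference) / m
}

#' Blood-pressure error bins
#'
#' Percentage of pairs whose absolute device-minus-reference difference
#' is within 5, 10, and 15 mmHg (inclusive) — the binning used by the
#' ESH International Protocol for BP device validation.
#'
#' @param reference,device Numeric vectors of paired BP measurements
#'   (mmHg).
#' @return A list: `within_5`, `within_10`, `within_15` (percentages).
#' @export
bp_error_bins <- function(reference, device) {
  stopifnot(length(reference) == length(device))
  if (length(reference) == 0) stop("empty input", call. = FALSE)
  ad <- abs(device - reference)
  list(within_5 = 100 * mean(ad <= 5),
       within_10 = 100 * mean(ad <= 10),
       within_15 = 100 * mean(ad <= 15))
}

#' Normality tests on a sample
#'
#' Lilliefors-corrected Kolmogorov-Smirnov and Shapiro-Wilk p-values,
#' reported descriptively (not used as a gate anywhere in the pipeline).
#' Constant input yields a degenerate flag with `NA` p-values.
#'
#' @param values Numeric vector (typically paired differences within a
#'   stratum).
#' @return A list: `ks_p`, `sw_p`, `degenerate`.
#' @export
normality_tests <- function(values) {
  if (length(values) < 4) stop("need at least 4 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    return(list(ks_p = NA_real_, sw_p = NA_real_, degenerate = TRUE))
  }
  sw <- if (length(values) <= 5000) {
    stats::shapiro.test(values)$p.value
  } else {
    stats::shapiro.test(sample(values, 5000))$p.value
  }
  list(ks_p = nortest::lillie.test(values)$p.value,
       sw_p = sw,
       degenerate = FALSE)
}

agreement_one <- function(pairs, variable, stratum) {
  ref <- pairs$reference_value
  dev <- pairs$device_value
  reg <- pearson_regression(ref, dev)
  ic <- icc_sem(ref, dev)
  ba <- bland_altman(ref, dev)
  nt <- if (length(ref) >= 4) normality_tests(dev - ref) else {
    list(ks_p = NA_real_, sw_p = NA_real_, degenerate = NA)
  }
  tibble::tibble(
    variable = variable,
    stratum = stratum,
    n = reg$n,
    pearson_r = reg$r,
    p_value = reg$p,
    slope = reg$slope,
    intercept = reg$intercept,
    p_slope = reg$p_slope,
    p_intercept = reg$p_intercept,
    icc = ic$icc,
    icc_clamped = ic$clamped,
    sem_measurement = ic$sem_measurement,
    bias = ba$bias,
    sd_diff = ba$sd_diff,
    loa_lower = ba$loa_lower,
    loa_upper = ba$loa_upper,
    percentage_error = if (variable == "CO") {
      percentage_error(ref, dev)
    } else NA_real_,
    within_5 = if (variable %in% hv_bp_variables) {
      bp_error_bins(ref, dev)$within_5
    } else NA_real_,
    within_10 = if (variable %in% hv_bp_variables) {
      bp_error_bins(ref, dev)$within_10
    } else NA_real_,
    within_15 = if (variable %in% hv_bp_variables) {
      bp_error_bins(ref, dev)$within_15
    } else NA_real_,
    ks_p = nt$ks_p,
    sw_p = nt$sw_p
  )
}

#' Full agreement table per variable and stratum
#'
#' Computes every static agreement statistic for each variable in each
#' phase and for all phases combined (`stratum = "all"`), pooling pairs
#' across animals within a stratum. Percentage error is reported for CO
#' only; the mmHg error bins for SBP/DBP only.
#'
#' @param data A (screened) paired-observation dataset.
#' @param min_n Minimum pair count for a stratum; smaller strata are
#'   skipped with a warning (default 3).
#' @return A tibble with one row per variable x stratum.
#' @export
agreement_table <- function(data, min_n = 3) {
  data <- validate_dataset(data)
  out <- list()
  for (v in intersect(hv_variables, unique(data$variable))) {
    dv <- data[data$variable == v, ]
    for (s in c(hv_phases, "all")) {
      ds <- if (s == "all") dv else dv[dv$phase == s, ]
      if (nrow(ds) < min_n) {
        warning("stratum ", v, " / ", s, " has fewer than ", min_n,
                " pairs; skipped", call. = FALSE)
        next
      }
      out[[paste(v, s)]] <- agreement_one(ds, v, s)
    }
  }
  dplyr::bind_rows(out)
}
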