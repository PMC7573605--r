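# Independent brute-force oracles. These deliberately avoid the code
# paths of the package: plain-sum arithmetic for correlation/regression,
# anova(lm(...)) mean squares for the ICC, and an explicit double loop
# for the outlier screen.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

oracle_ols <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  se_slope <- sqrt(s2 / sxx)
  se_int <- sqrt(s2 * (1 / n + mx^2 / sxx))
  list(slope = slope, intercept = intercept,
       p_slope = 2 * stats::pt(abs(slope / se_slope), n - 2, lower.tail = FALSE),
       p_intercept = 2 * stats::pt(abs(intercept / se_int), n - 2,
                                   lower.tail = FALSE))
}

# ICC(A,1) via anova(lm()) mean squares -- a different computational
# route from the package's explicit sums of squares
oracle_icc_a1 <- function(x, y) {
  n <- length(x)
  long <- data.frame(value = c(x, y),
                     subject = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(c("ref", "dev"), each = n)))
  # F-test warnings on zero-residual tables are irrelevant: only the
  # mean squares are used
  ms <- suppressWarnings(
    stats::anova(stats::lm(value ~ subject + rater, data = long)))
  msr <- ms["subject", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Brute-force re-computation of the percentage-difference screen with
# explicit loops over series and points.
oracle_screen <- function(data, k = 2) {
  removed <- data.frame(animal_id = character(0), variable = character(0),
                        time_min = numeric(0))
  for (v in unique(data$variable)) {
    deltas <- data.frame(animal_id = character(0), time_min = numeric(0),
                         dp = numeric(0), dn = numeric(0))
    for (a in unique(data$animal_id)) {
      s <- data[data$animal_id == a & data$variable == v, ]
      s <- s[order(s$time_min), ]
      if (nrow(s) < 3) next
      for (i in 2:(nrow(s) - 1)) {
        x <- s$reference_value
        deltas <- rbind(deltas, data.frame(
          animal_id = a, time_min = s$time_min[i],
          dp = 100 * (x[i] - x[i - 1]) / x[i - 1],
          dn = 100 * (x[i] - x[i + 1]) / x[i + 1]))
      }
    }
    if (nrow(deltas) == 0) next
    cutoff <- k * stats::sd(c(abs(deltas$dp), abs(deltas$dn)))
    hit <- abs(deltas$dp) > cutoff & abs(deltas$dn) > cutoff
    if (any(hit)) {
      removed <- rbind(removed, data.frame(
        animal_id = deltas$animal_id[hit], variable = v,
        time_min = deltas$time_min[hit]))
    }
  }
  removed
}

# Random small valid dataset for round-trip/property tests
random_dataset <- function(n_animals = 3, n_times = 5) {
  rows <- list()
  for (a in seq_len(n_animals)) {
    for (v in hv_variables) {
      times <- seq(0, by = 5, length.out = n_times)
      phase <- rep(hv_phases, each = ceiling(n_times / 3))[seq_len(n_times)]
      ref <- stats::runif(n_times, 40, 120)
      rows[[paste(a, v)]] <- tibble::tibble(
        animal_id = paste0("a", a),
        phase = phase,
        time_min = times,
        variable = v,
        reference_value = ref,
        device_value = pmax(ref + stats::rnorm(n_times, 0, 3), 1))
    }
  }
  dplyr::bind_rows(rows)
}

# degenerate (error-free) simulator configuration
degenerate_config <- function(seed = 5) {
  sim_config(
    seed = seed,
    device = device_error_model(
      calibration_offset_sd = c(SBP = 0, DBP = 0, HR = 0, CO = 0),
      proportional_bias = 0,
      noise_sd = c(SBP = 0, DBP = 0, HR = 0, CO = 0),
      ar1_rho = 0),
    spike_prob = 0)
}
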