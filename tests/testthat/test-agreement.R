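test_that("pearson_regression matches hand arithmetic and the brute-force oracle", {
  res <- pearson_regression(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$r, 1)
  expect_equal(res$slope, 1)
  expect_equal(res$intercept, 0)

  expect_equal(pearson_regression(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_equal(pearson_regression(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6)

  set.seed(20)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    x <- rnorm(n, 50, 10)
    y <- 0.9 * x + rnorm(n, 2, 4)
    res <- pearson_regression(x, y)
    ols <- oracle_ols(x, y)
    expect_equal(res$r, oracle_pearson(x, y), tolerance = 1e-12)
    expect_equal(res$slope, ols$slope, tolerance = 1e-12)
    expect_equal(res$intercept, ols$intercept, tolerance = 1e-12)
    expect_equal(res$p_slope, ols$p_slope, tolerance = 1e-10)
    expect_equal(res$p_intercept, ols$p_intercept, tolerance = 1e-10)
  }

  expect_error(pearson_regression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(pearson_regression(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("icc_sem implements ICC(A,1) and the standard error of measurement", {
  x <- c(4, 9, 14, 22)
  ident <- icc_sem(x, x)
  expect_equal(ident$icc, 1)
  expect_equal(ident$sem_measurement, 0)

  # constant offset: absolute agreement penalizes the shift
  off <- icc_sem(c(1, 2, 3), c(2, 3, 4))
  expect_lt(off$icc, 1)
  expect_equal(off$icc, oracle_icc_a1(c(1, 2, 3), c(2, 3, 4)),
               tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    subj <- rnorm(n, 0, 3)
    ref <- 60 + subj + rnorm(n)
    dev <- 60 + subj + rnorm(n) + 1.5
    res <- icc_sem(ref, dev)
    expect_equal(res$icc, max(oracle_icc_a1(ref, dev), 0), tolerance = 1e-10)
    expect_equal(res$sem_measurement,
                 sd(c(ref, dev)) * sqrt(1 - res$icc), tolerance = 1e-12)
  }

  # degenerate: no between-subject variance
  deg <- icc_sem(rep(5, 4), rep(5, 4) + c(0.1, -0.1, 0.1, -0.1))
  expect_true(deg$icc == 0 || deg$clamped)
})

test_that("bland_altman computes bias and 1.96-SD limits", {
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$loa_lower, ident$loa_upper), c(0, 0))

  ba <- bland_altman(c(10, 10, 10), c(11, 12, 13))  # differences 1,2,3
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_lower, 2 - 1.96)
  expect_equal(ba$loa_upper, 2 + 1.96)

  # sign symmetry: flipping all differences negates bias, mirrors LOA
  flip <- bland_altman(c(11, 12, 13), c(10, 10, 10))
  expect_equal(flip$bias, -ba$bias)
  expect_equal(flip$loa_lower, -ba$loa_upper)
  expect_equal(flip$loa_upper, -ba$loa_lower)

  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("percentage_error follows the Critchley formula and is scale invariant", {
  expect_equal(percentage_error(c(4, 4, 4), c(4, 4, 4)), 0)

  ref <- rep(4, 4)
  dev <- 4 + c(0.5, -0.5, 0.5, -0.5)
  pe <- percentage_error(ref, dev)
  expect_equal(pe, 100 * 1.96 * sd(c(0.5, -0.5, 0.5, -0.5)) / 4,
               tolerance = 1e-12)
  expect_equal(round(pe, 1), 28.3)
  expect_equal(percentage_error(10 * ref, 10 * dev), pe, tolerance = 1e-12)
})

test_that("bp_error_bins counts inclusively and nests", {
  ident <- bp_error_bins(c(100, 110), c(100, 110))
  expect_equal(unlist(ident), c(within_5 = 100, within_10 = 100, within_15 = 100))

  b <- bp_error_bins(rep(100, 4), 100 + c(0, 6, 12, 20))
  expect_equal(b$within_5, 25)
  expect_equal(b$within_10, 50)
  expect_equal(b$within_15, 75)

  expect_equal(bp_error_bins(rep(100, 3), rep(115, 3))$within_15, 100)

  set.seed(5)
  for (rep in 1:10) {
    r <- runif(30, 60, 120)
    d <- r + rnorm(30, 0, 8)
    bb <- bp_error_bins(r, d)
    expect_lte(bb$within_5, bb$within_10)
    expect_lte(bb$within_10, bb$within_15)
  }
  expect_error(bp_error_bins(numeric(0), numeric(0)), "empty")
})

test_that("normality tests flag degenerate input and behave sensibly", {
  const <- normality_tests(rep(3, 10))
  expect_true(const$degenerate)
  expect_true(is.na(const$ks_p))

  set.seed(77)
  normal_ok <- replicate(60, {
    nt <- normality_tests(rnorm(300))
    nt$ks_p >= 0.01 && nt$sw_p >= 0.01
  })
  expect_gte(mean(normal_ok), 0.9)

  bimodal_hit <- replicate(40, {
    x <- c(rnorm(100, -4), rnorm(100, 4))
    normality_tests(x)$sw_p < 0.05
  })
  expect_gte(mean(bimodal_hit), 0.95)
})

test_that("agreement_table strata are complete and recover constructed truth", {
  p <- make_fixture("perfect")
  tab <- agreement_table(p)
  expect_equal(nrow(tab), 4 * 4)  # 4 variables x (3 phases + all)
  expect_true(all(abs(tab$pearson_r - 1) < 1e-12))
  expect_true(all(abs(tab$icc - 1) < 1e-12))
  expect_true(all(tab$bias == 0))

  b <- make_fixture("biased")
  sbp_all <- agreement_table(b) |>
    dplyr::filter(variable == "SBP", stratum == "all")
  expect_equal(sbp_all$bias, 4)
  expect_equal(sbp_all$loa_upper - sbp_all$loa_lower, 0)
  expect_lt(sbp_all$icc, 1)

  # LOA invariant and bin nesting on a noisy simulated cohort
  tab_sim <- agreement_table(simulate_experiment(sim_config(seed = 3)))
  expect_true(all(tab_sim$loa_lower <= tab_sim$bias))
  expect_true(all(tab_sim$bias <= tab_sim$loa_upper))
  expect_true(all(tab_sim$pearson_r >= -1 & tab_sim$pearson_r <= 1))
  expect_true(all(tab_sim$icc >= 0 & tab_sim$icc <= 1))
  bp_rows <- tab_sim[tab_sim$variable %in% c("SBP", "DBP"), ]
  expect_true(all(bp_rows$within_5 <= bp_rows$within_10))
  expect_true(all(bp_rows$within_10 <= bp_rows$within_15))
  expect_true(all(is.na(tab_sim$percentage_error[tab_sim$variable != "CO"])))

  # a stratum below the minimum is skipped with a warning
  tiny <- p[p$phase != "bleeding" | p$time_min < 40, ]
  w <- testthat::capture_warnings(agreement_table(tiny))
  expect_length(w, 4)  # one skipped bleeding stratum per variable
  expect_true(all(grepl("skipped", w)))
})

test_that("noise recovery: LOA half-width tracks the configured noise SD", {
  # device = reference + N(0, sigma), no offset/slope: LOA half-width -> 1.96 sigma
  cfg <- sim_config(
    n_animals = 40, seed = 9, spike_prob = 0, dropout_prob = 0,
    device = device_error_model(
      calibration_offset_sd = c(SBP = 0, DBP = 0, HR = 0, CO = 0),
      proportional_bias = 0,
      noise_sd = c(SBP = 6, DBP = 6, HR = 6, CO = 0.5),
      ar1_rho = 0))
  tab <- agreement_table(simulate_experiment(cfg))
  sbp <- tab[tab$variable == "SBP" & tab$stratum == "all", ]
  half_width <- (sbp$loa_upper - sbp$loa_lower) / 2
  expect_lt(abs(half_width - 1.96 * 6) / (1.96 * 6), 0.05)
  expect_lt(abs(sbp$bias), 3 * 6 / sqrt(sbp$n))

  # monotonicity: more noise, lower ICC, wider LOA
  stats_at <- function(noise) {
    cfg <- sim_config(
      n_animals = 40, seed = 9, spike_prob = 0, dropout_prob = 0,
      device = device_error_model(
        calibration_offset_sd = c(SBP = 0, DBP = 0, HR = 0, CO = 0),
        proportional_bias = 0,
        noise_sd = c(SBP = noise, DBP = noise, HR = noise, CO = 0.1),
        ar1_rho = 0))
    tab <- agreement_table(simulate_experiment(cfg))
    tab[tab$variable == "SBP" & tab$stratum == "all", ]
  }
  grid <- lapply(c(2, 8, 20), stats_at)
  iccs <- vapply(grid, function(g) g$icc, numeric(1))
  widths <- vapply(grid, function(g) g$loa_upper - g$loa_lower, numeric(1))
  expect_true(all(diff(iccs) < 0))
  expect_true(all(diff(widths) > 0))
})
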