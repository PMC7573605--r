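test_that("simulation is reproducible from the seed", {
  cfg <- sim_config(seed = 13)
  d1 <- simulate_experiment(cfg)
  d2 <- simulate_experiment(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_experiment(sim_config(seed = 14))
  expect_false(isTRUE(all.equal(as.data.frame(d1), as.data.frame(d3))))
})

test_that("degenerate error model reproduces the reference exactly", {
  d <- simulate_experiment(degenerate_config())
  expect_identical(d$reference_value, d$device_value)
})

test_that("protocol shape: cadences, bleeding duration, phase ordering", {
  d <- simulate_experiment(sim_config(seed = 11))
  for (s in split_series(d[d$variable == "SBP", ])) {
    pre <- s$time_min[s$phase == "pre_bleeding"]
    bl <- s$time_min[s$phase == "bleeding"]
    post <- s$time_min[s$phase == "post_bleeding"]
    expect_true(all(diff(pre) == 5))
    expect_true(all(diff(bl) == 5))
    if (length(post) > 1) expect_true(all(diff(post) == 20))
    expect_true(max(pre) < min(bl) && max(bl) < min(post))
    dur <- max(bl) - max(pre)
    expect_gte(dur, 20)
    expect_lte(dur, 60)
  }
})

test_that("simulated bleeding MAP never drops below the floor", {
  for (seed in c(2, 9, 31)) {
    d <- simulate_experiment(sim_config(seed = seed))
    wide <- tidyr::pivot_wider(
      d[d$variable %in% c("SBP", "DBP"),
        c("animal_id", "phase", "time_min", "variable", "reference_value")],
      names_from = "variable", values_from = "reference_value")
    bleed <- wide[wide$phase == "bleeding", ]
    map <- (bleed$SBP + 2 * bleed$DBP) / 3
    expect_gte(min(map), 30 - 1e-9)
  }
})

test_that("phase levels converge to configured targets as the cohort grows", {
  cfg <- sim_config(n_animals = 120, seed = 8, dropout_prob = 0,
                    spike_prob = 0)
  d <- simulate_experiment(cfg)
  for (v in hv_variables) {
    for (ph in hv_phases) {
      x <- d$reference_value[d$variable == v & d$phase == ph]
      mu <- cfg$phases[[ph]]$level_mean[[v]]
      sd_t <- cfg$phases[[ph]]$level_sd[[v]]
      # cluster-aware SE of the mean: animals carry a stable level
      m <- cfg$n_animals
      se <- sqrt(cfg$between_frac * sd_t^2 / m +
                   (1 - cfg$between_frac) * sd_t^2 / length(x))
      expect_lt(abs(mean(x) - mu), 4 * se + 0.05 * mu)
      # SDs are matched exactly in pre-bleeding, loosely elsewhere
      tol <- if (ph == "pre_bleeding") 0.25 else 1.0
      expect_lt(abs(sd(x) - sd_t), tol * sd_t + 1e-9)
    }
  }
})

test_that("CO observations are thinned in bleeding/post-bleeding", {
  d <- simulate_experiment(sim_config(seed = 21, dropout_prob = 0))
  n_by <- dplyr::count(d, variable, phase)
  n_co_bleed <- n_by$n[n_by$variable == "CO" & n_by$phase == "bleeding"]
  n_bp_bleed <- n_by$n[n_by$variable == "SBP" & n_by$phase == "bleeding"]
  expect_lt(n_co_bleed, n_bp_bleed)
  n_co_pre <- n_by$n[n_by$variable == "CO" & n_by$phase == "pre_bleeding"]
  n_bp_pre <- n_by$n[n_by$variable == "SBP" & n_by$phase == "pre_bleeding"]
  expect_equal(n_co_pre, n_bp_pre)
})

test_that("dropout truncates all of an animal's series at one time", {
  cfg <- sim_config(seed = 4, dropout_prob = 1, co_missing_prob = 0)
  d <- simulate_experiment(cfg)
  ends <- d |>
    dplyr::group_by(animal_id, variable) |>
    dplyr::summarise(end = max(time_min), .groups = "drop") |>
    dplyr::group_by(animal_id) |>
    dplyr::summarise(spread = max(end) - min(end), end = max(end),
                     .groups = "drop")
  # all variables of an animal end within one post-bleeding cadence
  expect_true(all(ends$spread <= 20))
  full_end <- 30 + 5 + 420  # earliest possible full-protocol end
  expect_true(any(ends$end < full_end))
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(sim_config(n_animals = 0), "n_animals")
  expect_error(sim_config(dropout_prob = 1.5), "probabilities")
  expect_error(sim_config(spike_prob = -0.1), "probabilities")
  expect_error(device_error_model(ar1_rho = 1), "ar1_rho")
  expect_error(device_error_model(noise_sd = c(SBP = -1, DBP = 1, HR = 1, CO = 1)),
               "noise_sd")
  expect_error(phase_spec("bleeding", c(0, 10), 5,
                          c(SBP = 1, DBP = 1, HR = 1, CO = 1),
                          c(SBP = 1, DBP = 1, HR = 1, CO = 1)))
  expect_error(simulate_experiment(list(seed = 1)), "sim_config")
})

test_that("fixtures carry their constructed ground truth", {
  p <- make_fixture("perfect")
  expect_identical(p$reference_value, p$device_value)
  expect_lt(nrow(p), 200)

  b <- make_fixture("biased")
  bp <- b$variable %in% c("SBP", "DBP")
  expect_equal(b$device_value[bp] - b$reference_value[bp],
               rep(4, sum(bp)))
  expect_identical(b$device_value[!bp], b$reference_value[!bp])

  nz <- make_fixture("noisy")
  for (v in hv_variables) {
    idx <- nz$variable == v
    expect_equal(unique(abs(nz$device_value[idx] - nz$reference_value[idx])),
                 attr(nz, "noise_sd")[[v]])
  }

  s <- make_fixture("spiky")
  spikes <- attr(s, "spikes")
  expect_equal(nrow(spikes), 4)
  p_key <- paste(p$animal_id, p$variable, p$time_min)
  s_key <- paste(s$animal_id, s$variable, s$time_min)
  changed <- s_key[s$reference_value != p$reference_value[match(s_key, p_key)]]
  expect_setequal(changed,
                  paste(spikes$animal_id, spikes$variable, spikes$time_min))

  expect_error(make_fixture("weird"), "perfect, biased, noisy, spiky")
})
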