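# Synthetic three-phase hemorrhagic-shock cohort.
#
# Reference trajectories are piecewise latent paths per animal: a flat
# baseline around the pre-bleeding mean, a controlled decline during
# bleeding constrained so MAP = (SBP + 2*DBP)/3 never falls below the
# protocol floor, and a slow post-bleeding drift (HR rising, BP/CO
# partially recovering). Phase target means are honoured by construction;
# the device channel adds a one-time per-animal calibration offset,
# an optional proportional bias, and AR(1) observation noise.

#' Phase specification for the synthetic cohort
#'
#' Describes one protocol phase: its duration (a per-animal draw range,
#' in minutes), its sampling cadence, and the target marginal mean/SD of
#' the invasive reference channel for each variable during that phase.
#'
#' @param name One of `r toString(hv_phases)`.
#' @param duration_range Length-2 numeric, minutes; per-animal durations
#'   are drawn uniformly on the cadence grid within this range.
#' @param cadence_min Sampling interval in minutes (> 0).
#' @param level_mean,level_sd Named numeric vectors over
#'   `r toString(hv_variables)`: phase target mean and SD of the
#'   reference channel.
#' @return An object of class `"phase_spec"`.
#' @export
phase_spec <- function(name, duration_range, cadence_min, level_mean, level_sd) {
  name <- match.arg(name, hv_phases)
  stopifnot(length(duration_range) == 2, all(duration_range > 0),
            duration_range[1] <= duration_range[2], cadence_min > 0)
  for (v in hv_variables) {
    if (is.na(level_mean[v]) || is.na(level_sd[v])) {
      stop("level_mean and level_sd must name every variable: ", v,
           call. = FALSE)
    }
    if (level_sd[v] < 0) stop("level_sd must be non-negative", call. = FALSE)
  }
  structure(list(name = name,
                 duration_range = as.numeric(duration_range),
                 cadence_min = cadence_min,
                 level_mean = level_mean[hv_variables],
                 level_sd = level_sd[hv_variables]),
            class = "phase_spec")
}

#' Device measurement-error model
#'
#' The device channel is modelled as
#' `device = reference * (1 + proportional_bias) + offset_a + e_t`
#' where `offset_a` is drawn once per animal from
#' `N(0, calibration_offset_sd^2)` — mimicking the one-time baseline
#' calibration-by-offset of the monitor — and `e_t` is AR(1) noise with
#' lag-1 correlation `ar1_rho` and marginal SD `noise_sd`.
#'
#' @param calibration_offset_sd Named numeric over variables: SD of the
#'   per-animal additive offset fixed at baseline calibration.
#' @param proportional_bias Scalar multiplicative slope error (0 = none).
#' @param noise_sd Named numeric over variables: marginal SD of the
#'   additive AR(1) error.
#' @param ar1_rho Lag-1 autocorrelation of the additive error, in [0, 1).
#' @return An object of class `"device_error_model"`.
#' @export
device_error_model <- function(calibration_offset_sd = c(SBP = 4, DBP = 4, HR = 2, CO = 0.3),
                               proportional_bias = 0,
                               noise_sd = c(SBP = 5, DBP = 4, HR = 4, CO = 0.4),
                               ar1_rho = 0.5) {
  stopifnot(ar1_rho >= 0, ar1_rho < 1)
  for (v in hv_variables) {
    if (is.na(calibration_offset_sd[v]) || calibration_offset_sd[v] < 0) {
      stop("calibration_offset_sd must be >= 0 for every variable", call. = FALSE)
    }
    if (is.na(noise_sd[v]) || noise_sd[v] < 0) {
      stop("noise_sd must be >= 0 for every variable", call. = FALSE)
    }
  }
  structure(list(calibration_offset_sd = calibration_offset_sd[hv_variables],
                 proportional_bias = proportional_bias,
                 noise_sd = noise_sd[hv_variables],
                 ar1_rho = ar1_rho),
            class = "device_error_model")
}

default_phases <- function() {
  list(
    pre_bleeding = phase_spec(
      "pre_bleeding", duration_range = c(30, 30), cadence_min = 5,
      level_mean = c(SBP = 79, DBP = 57, HR = 96, CO = 3.8),
      level_sd   = c(SBP = 14, DBP = 18, HR = 20, CO = 1.0)),
    bleeding = phase_spec(
      "bleeding", duration_range = c(20, 60), cadence_min = 5,
      level_mean = c(SBP = 51, DBP = 32, HR = 99, CO = 2.4),
      level_sd   = c(SBP = 20, DBP = 12, HR = 20, CO = 1.1)),
    post_bleeding = phase_spec(
      "post_bleeding", duration_range = c(420, 420), cadence_min = 20,
      level_mean = c(SBP = 58, DBP = 30, HR = 125, CO = 2.2),
      level_sd   = c(SBP = 12, DBP = 18, HR = 25, CO = 0.5))
  )
}

#' Full parameterization of a synthetic cohort
#'
#' Defaults reproduce the study conditions of an 11-pig controlled
#' hemorrhagic-shock protocol: a ~30-min baseline sampled every 5 min,
#' a 20-60-min bleeding phase sampled every 5 min with MAP held at or
#' above 30 mmHg, and a 7-h untreated follow-up sampled every 20 min,
#' with phase target levels taken from the invasive reference summary
#' statistics of that protocol.
#'
#' @param n_animals Number of animals (default 11).
#' @param phases List of three [phase_spec()] objects (pre_bleeding,
#'   bleeding, post_bleeding).
#' @param device A [device_error_model()].
#' @param between_frac Fraction of each phase's target variance carried
#'   by the stable per-animal level (0-1).
#' @param dropout_prob Per-animal probability of death during
#'   post-bleeding, truncating all series at a uniformly drawn time.
#' @param co_missing_prob Probability a CO observation is absent in the
#'   bleeding and post-bleeding phases (thermodilution readings are
#'   harder to obtain during instability).
#' @param spike_prob Per-observation probability of a transient artifact
#'   multiplying a channel's value by `1 + spike_magnitude`.
#' @param spike_magnitude Relative artifact size (default 0.5, i.e. +50%).
#' @param map_floor Mean-arterial-pressure floor (mmHg) enforced during
#'   bleeding (default 30).
#' @param seed Integer seed driving one root generator; per-animal
#'   substreams are derived from it deterministically.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_animals = 11,
                       phases = default_phases(),
                       device = device_error_model(),
                       between_frac = 0.4,
                       dropout_prob = 2 / 11,
                       co_missing_prob = 0.15,
                       spike_prob = 0.004,
                       spike_magnitude = 0.5,
                       map_floor = 30,
                       seed = 1L) {
  stopifnot(n_animals >= 1)
  probs <- c(dropout_prob, co_missing_prob, spike_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (between_frac < 0 || between_frac > 1) {
    stop("between_frac must lie in [0, 1]", call. = FALSE)
  }
  if (!identical(sort(names(phases)), sort(hv_phases)) ||
      !all(vapply(phases, inherits, logical(1), "phase_spec"))) {
    stop("phases must be a named list of phase_spec objects for: ",
         paste(hv_phases, collapse = ", "), call. = FALSE)
  }
  if (!inherits(device, "device_error_model")) {
    stop("device must be a device_error_model object", call. = FALSE)
  }
  structure(list(n_animals = as.integer(n_animals),
                 phases = phases[hv_phases],
                 device = device,
                 between_frac = between_frac,
                 dropout_prob = dropout_prob,
                 co_missing_prob = co_missing_prob,
                 spike_prob = spike_prob,
                 spike_magnitude = spike_magnitude,
                 map_floor = map_floor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic within-phase target path for one variable.
# Bleeding declines in (at most) two segments from the animal's baseline
# level S0 to a nadir L, holding the phase mean at mu by choosing the
# breakpoint; L is 2*mu - S0 (the linear-decline nadir) raised to l_min
# where a floor applies. Post-bleeding drifts linearly from its start
# level to the mirror point 2*mu - start, preserving the phase mean.
decline_path <- function(u, S0, mu, l_min = -Inf) {
  if (mu >= S0) return(rep(mu, length(u)))
  L <- max(2 * mu - S0, l_min)
  if (L >= S0) return(rep(mu, length(u)))
  f <- 2 * (mu - L) / (S0 - L)   # fraction of the phase spent declining
  f <- min(max(f, 1e-6), 1)
  ifelse(u < f, S0 + (L - S0) * u / f, L)
}

drift_path <- function(u, start, mu) {
  end <- 2 * mu - start
  start + (end - start) * u
}

ar1_series <- function(n, rho, marginal_sd) {
  if (n == 0) return(numeric(0))
  if (marginal_sd == 0) return(rep(0, n))
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, marginal_sd)
  if (n > 1) {
    innov_sd <- marginal_sd * sqrt(1 - rho^2)
    for (t in 2:n) e[t] <- rho * e[t - 1] + stats::rnorm(1, 0, innov_sd)
  }
  e
}

# value floors keeping observations physiological and strictly positive
value_floor <- c(SBP = 20, DBP = 10, HR = 20, CO = 0.3)

# lag-1 autocorrelation of the latent within-animal fluctuation around the
# phase target path; high because physiological variation at 5-20 min
# sampling is dominated by slow drift, not sample-to-sample jitter
path_rho <- 0.9

simulate_animal <- function(id, config, animal_seed) {
  set.seed(animal_seed)
  ph <- config$phases
  dev <- config$device
  bf <- config$between_frac

  draw_duration <- function(spec) {
    grid <- seq(spec$duration_range[1], spec$duration_range[2],
                by = spec$cadence_min)
    if (length(grid) == 1) grid else sample(grid, 1)
  }
  dur <- vapply(ph, draw_duration, numeric(1))

  t_pre <- seq(0, dur["pre_bleeding"], by = ph$pre_bleeding$cadence_min)
  bleed_start <- max(t_pre) + ph$bleeding$cadence_min
  t_bleed <- seq(bleed_start, max(t_pre) + dur["bleeding"],
                 by = ph$bleeding$cadence_min)
  post_start <- max(t_bleed) + ph$post_bleeding$cadence_min
  t_post <- seq(post_start, max(t_bleed) + dur["post_bleeding"],
                by = ph$post_bleeding$cadence_min)
  times <- list(pre_bleeding = t_pre, bleeding = t_bleed,
                post_bleeding = t_post)

  # stable per-animal z-score (one per variable) and calibration offset
  z_animal <- stats::rnorm(length(hv_variables))
  names(z_animal) <- hv_variables
  offset_animal <- stats::rnorm(length(hv_variables)) * dev$calibration_offset_sd
  names(offset_animal) <- hv_variables

  rows <- list()
  for (v in hv_variables) {
    mu <- vapply(ph, function(p) p$level_mean[[v]], numeric(1))
    sdv <- vapply(ph, function(p) p$level_sd[[v]], numeric(1))
    names(mu) <- names(sdv) <- hv_phases

    S0 <- mu["pre_bleeding"] + z_animal[v] * sqrt(bf) * sdv["pre_bleeding"]
    u_bleed <- seq_along(t_bleed) / length(t_bleed)
    bleed_target <- decline_path(u_bleed, S0, mu["bleeding"],
                                 l_min = value_floor[[v]])
    post_start_level <- bleed_target[length(bleed_target)]
    u_post <- if (length(t_post) > 1) {
      (seq_along(t_post) - 1) / (length(t_post) - 1)
    } else rep(0.5, length(t_post))
    post_target <- drift_path(u_post, post_start_level, mu["post_bleeding"])

    target <- c(rep(S0, length(t_pre)), bleed_target, post_target)
    phase_of <- rep(hv_phases, times = lengths(times))

    # residual noise: pre-bleeding carries the full within-animal share;
    # bleeding/post paths already carry spread, so only a residual is added
    wig_sd <- ifelse(phase_of == "pre_bleeding",
                     sqrt(1 - bf) * sdv["pre_bleeding"],
                     0.3 * sdv[phase_of])
    lvl_sd <- ifelse(phase_of == "pre_bleeding", 0, 0.3 * sdv[phase_of])
    wiggle <- ar1_series(length(target), path_rho, 1) * wig_sd
    reference <- target + z_animal[v] * lvl_sd + wiggle
    reference <- pmax(reference, value_floor[[v]])

    noise <- ar1_series(length(target), dev$ar1_rho, dev$noise_sd[[v]])
    rows[[v]] <- tibble::tibble(
      animal_id = id,
      phase = phase_of,
      time_min = unlist(times, use.names = FALSE),
      variable = v,
      reference_value = reference,
      dev_noise = noise
    )
  }
  out <- dplyr::bind_rows(rows)

  # MAP floor during bleeding: protocol pauses bleeding rather than let
  # MAP = (SBP + 2 DBP)/3 fall below the floor; rescale the BP pair up
  wide <- tidyr::pivot_wider(out[c("animal_id", "phase", "time_min",
                                   "variable", "reference_value")],
                             names_from = "variable",
                             values_from = "reference_value")
  map <- (wide$SBP + 2 * wide$DBP) / 3
  viol <- wide$phase == "bleeding" & map < config$map_floor
  if (any(viol)) {
    scale <- config$map_floor / map[viol]
    key <- paste(wide$animal_id[viol], wide$time_min[viol])
    for (v in hv_bp_variables) {
      idx <- out$variable == v & paste(out$animal_id, out$time_min) %in% key
      sc <- scale[match(paste(out$animal_id[idx], out$time_min[idx]), key)]
      out$reference_value[idx] <- out$reference_value[idx] * sc
    }
  }

  out$device_value <- out$reference_value * (1 + dev$proportional_bias) +
    offset_animal[out$variable] + out$dev_noise
  out$dev_noise <- NULL
  out$device_value <- pmax(out$device_value, value_floor[out$variable])

  # spike artifacts: transient +spike_magnitude excursions on either channel
  if (config$spike_prob > 0) {
    sp_ref <- stats::runif(nrow(out)) < config$spike_prob
    sp_dev <- stats::runif(nrow(out)) < config$spike_prob
    out$reference_value[sp_ref] <- out$reference_value[sp_ref] *
      (1 + config$spike_magnitude)
    out$device_value[sp_dev] <- out$device_value[sp_dev] *
      (1 + config$spike_magnitude)
  } else {
    stats::runif(2 * nrow(out))  # keep the stream aligned across configs
  }

  # CO missingness: independent thinning in bleeding/post-bleeding
  co_rows <- out$variable == "CO" & out$phase != "pre_bleeding"
  drop_co <- co_rows & stats::runif(nrow(out)) < config$co_missing_prob
  out <- out[!drop_co, ]

  # dropout: early death truncates every series at the death time
  if (stats::runif(1) < config$dropout_prob) {
    death_time <- stats::runif(1, min(t_post), max(t_post))
    out <- out[out$time_min <= death_time, ]
  }
  out
}

#' Simulate a synthetic validation cohort
#'
#' Generates a full paired-observation dataset with the protocol
#' structure described in [sim_config()]: per-animal latent reference
#' trajectories over the three phases, a device channel with per-animal
#' calibration offset, proportional bias and AR(1) noise, per-phase
#' sampling cadences, CO thinning, animal dropout, and occasional spike
#' artifacts. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A validated paired-observation dataset (tibble) with
#'   provenance attribute `"simulated"`.
#' @examples
#' d <- simulate_experiment(sim_config(seed = 7))
#' dplyr::count(d, phase, variable)
#' @export
simulate_experiment <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    stop("config must be a sim_config object", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  ids <- sprintf("animal%02d", seq_len(config$n_animals))
  animal_seeds <- sample.int(.Machine$integer.max - 1L, config$n_animals)
  out <- dplyr::bind_rows(
    lapply(seq_len(config$n_animals), function(i) {
      simulate_animal(ids[i], config, animal_seeds[i])
    })
  )
  out <- dplyr::arrange(out, .data$animal_id, .data$variable, .data$time_min)
  validate_dataset(out)
  attr(out, "provenance") <- "simulated"
  out
}

#' Small deterministic fixture datasets with known ground truth
#'
#' Four hand-constructed datasets (< 200 rows) used throughout the test
#' suite, each with its ground truth attached as attributes:
#'
#' * `"perfect"` — device identical to reference.
#' * `"biased"` — perfect plus a constant +4 mmHg device offset on SBP
#'   and DBP (attribute `bias_bp`).
#' * `"noisy"` — perfect plus alternating +/- deterministic "noise" of
#'   known per-variable SD (attribute `noise_sd`).
#' * `"spiky"` — perfect plus +50% reference-channel spikes at recorded
#'   rows (attribute `spikes`: a tibble of animal_id/variable/time_min).
#'
#' @param name One of `"perfect"`, `"biased"`, `"noisy"`, `"spiky"`.
#' @return A validated paired-observation dataset.
#' @export
make_fixture <- function(name = c("perfect", "biased", "noisy", "spiky")) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("perfect", "biased", "noisy", "spiky")) {
    stop("unknown fixture name; valid names: perfect, biased, noisy, spiky",
         call. = FALSE)
  }

  # move/hold staircase: every interior point has a zero percentage
  # difference on at least one side, so the outlier screen removes
  # nothing from the spike-free fixtures by construction, while the
  # moves provide genuine successive changes for trending
  base_level <- c(SBP = 80, DBP = 55, HR = 95, CO = 3.8)
  step <- c(SBP = 5, DBP = 4, HR = 6, CO = 0.7)
  times <- c(seq(0, 30, by = 5), seq(35, 60, by = 5), seq(80, 200, by = 20))
  phase <- c(rep("pre_bleeding", 7), rep("bleeding", 6),
             rep("post_bleeding", 7))
  n_t <- length(times)
  rows <- list()
  for (a in c("pigA", "pigB")) {
    lag <- if (a == "pigA") 0 else 2
    for (v in hv_variables) {
      moves <- rep_len(c(1, 0, -1, 0), n_t - 1 + lag)[(lag + 1):(n_t - 1 + lag)]
      ref <- base_level[[v]] + step[[v]] * cumsum(c(0, moves))
      rows[[paste(a, v)]] <- tibble::tibble(
        animal_id = a, phase = phase, time_min = times, variable = v,
        reference_value = ref, device_value = ref)
    }
  }
  d <- dplyr::bind_rows(rows)
  d <- dplyr::arrange(d, .data$animal_id, .data$variable, .data$time_min)

  if (name == "biased") {
    bp <- d$variable %in% hv_bp_variables
    d$device_value[bp] <- d$device_value[bp] + 4
    attr(d, "bias_bp") <- 4
  } else if (name == "noisy") {
    noise_sd <- c(SBP = 3, DBP = 3, HR = 2, CO = 0.25)
    for (v in hv_variables) {
      idx <- which(d$variable == v)
      d$device_value[idx] <- d$device_value[idx] +
        noise_sd[[v]] * rep_len(c(1, -1), length(idx))
    }
    attr(d, "noise_sd") <- noise_sd
  } else if (name == "spiky") {
    spikes <- tibble::tibble(
      animal_id = c("pigA", "pigA", "pigB", "pigB"),
      variable = c("SBP", "CO", "HR", "DBP"),
      time_min = c(45, 120, 15, 160))
    for (i in seq_len(nrow(spikes))) {
      idx <- which(d$animal_id == spikes$animal_id[i] &
                     d$variable == spikes$variable[i] &
                     d$time_min == spikes$time_min[i])
      d$reference_value[idx] <- d$reference_value[idx] * 1.5
    }
    attr(d, "spikes") <- spikes
  }
  validate_dataset(d)
  attr(d, "provenance") <- paste0("fixture:", name)
  d
}
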