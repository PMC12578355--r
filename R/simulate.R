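# Synthetic cohort generator: emulates multi-rate wearable recordings with a
# block-structured affective-state schedule and state-dependent signal
# statistics. Nothing here is fitted to real recordings; the generator exists
# so that every downstream stage is testable without external data.

#' Default per-state generative parameters
#'
#' One row of parameters per affective state (0 baseline, 1 amusement,
#' 2 stress). Units: heart rate bpm, SDNN-scale inter-beat jitter ms, EDA
#' tonic level microsiemens, skin-conductance-response rate events/min,
#' respiration rate breaths/min, temperature drift degrees C per minute,
#' motion intensity g, EMG activity scale mV.
#'
#' @return data.frame with one row per state.
#' @export
default_state_params <- function() {
  data.frame(
    state        = 0:2,
    hr_bpm       = c(70, 80, 95),
    sdnn_ms      = c(50, 40, 25),
    eda_tonic_us = c(2.0, 4.0, 7.0),
    scr_per_min  = c(2, 6, 12),
    resp_bpm     = c(14, 17, 22),
    temp_drift_c_per_min = c(0.0, 0.01, -0.02),
    motion_g     = c(0.10, 0.50, 0.30),
    emg_mv       = c(0.02, 0.05, 0.08)
  )
}

# Channel rate presets mirroring a chest device (one rate for all channels)
# and a wrist device (per-channel rates).
device_rates <- function(device = c("wrist", "chest"), chest_hz = 700) {
  device <- match.arg(device)
  if (device == "chest") {
    rates <- rep(chest_hz, 8)
    names(rates) <- c("ACC_x", "ACC_y", "ACC_z", "ECG", "EDA", "EMG",
                      "TEMP", "RESP")
  } else {
    rates <- c(ACC_x = 32, ACC_y = 32, ACC_z = 32, BVP = 64, EDA = 4, TEMP = 4)
  }
  rates
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_subjects number of participants.
#' @param state_schedule data.frame with columns `state` (0/1/2) and
#'   `duration_s`; the protocol blocks every subject follows, in order.
#' @param device `"wrist"` or `"chest"`; selects the channel set and default
#'   rates (wrist: ACC 32 Hz, BVP 64 Hz, EDA 4 Hz, TEMP 4 Hz; chest: all
#'   channels at `chest_hz`).
#' @param channel_rates optional named Hz vector overriding the device preset.
#' @param state_params per-state generative parameters, see
#'   [default_state_params()].
#' @param subject_effect_sd named list of between-subject random-effect SDs:
#'   `hr_bpm`, `eda_us`, `temp_c`.
#' @param noise_sd named list of additive white-noise SDs per channel family:
#'   `acc`, `bvp`, `eda`, `emg`, `ecg`, `temp`, `resp`.
#' @param label_rate_hz sampling rate of the label stream.
#' @param chest_hz sampling rate used for every chest channel.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 8,
                          state_schedule = data.frame(
                            state = c(0L, 1L, 2L),
                            duration_s = c(600, 300, 600)),
                          device = c("wrist", "chest"),
                          channel_rates = NULL,
                          state_params = default_state_params(),
                          subject_effect_sd = list(hr_bpm = 3, eda_us = 0.3,
                                                   temp_c = 0.3),
                          noise_sd = list(acc = 0.02, bvp = 0.05, eda = 0.05,
                                          emg = 0.005, ecg = 0.02,
                                          temp = 0.02, resp = 0.05),
                          label_rate_hz = 4,
                          chest_hz = 700,
                          seed = 1L) {
  device <- match.arg(device)
  if (n_subjects < 1) stop_config("n_subjects must be >= 1")
  if (!all(c("state", "duration_s") %in% names(state_schedule)))
    stop_config("state_schedule needs columns state, duration_s")
  if (any(state_schedule$duration_s <= 0))
    stop_config("schedule durations must be positive")
  if (!all(state_schedule$state %in% 0:2))
    stop_config("schedule states must be in {0,1,2}")
  if (!all(0:2 %in% state_params$state))
    stop_config("state_params must define all three states")
  rates <- channel_rates %||% device_rates(device, chest_hz)
  if (any(rates <= 0)) stop_config("channel rates must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 state_schedule = state_schedule, device = device,
                 channel_rates = rates, state_params = state_params,
                 subject_effect_sd = subject_effect_sd, noise_sd = noise_sd,
                 label_rate_hz = label_rate_hz, seed = as.integer(seed)),
            class = "cohort_config")
}

# Per-sample state code at a given rate for the whole schedule.
schedule_codes <- function(schedule, rate) {
  unlist(lapply(seq_len(nrow(schedule)), function(i) {
    rep(schedule$state[i], round(schedule$duration_s[i] * rate))
  }), use.names = FALSE)
}

# Per-sample value of a state-dependent parameter at a given rate.
schedule_values <- function(schedule, rate, values_by_state) {
  unlist(lapply(seq_len(nrow(schedule)), function(i) {
    rep(values_by_state[schedule$state[i] + 1L],
        round(schedule$duration_s[i] * rate))
  }), use.names = FALSE)
}

# Beat times over the schedule: piecewise-constant heart rate with Gaussian
# inter-beat jitter of the state's SDNN scale.
simulate_beat_times <- function(schedule, hr_by_state, sdnn_by_state,
                                hr_shift) {
  total <- sum(schedule$duration_s)
  bounds <- cumsum(c(0, schedule$duration_s))
  state_at <- function(t) {
    i <- findInterval(t, bounds, rightmost.closed = TRUE)
    schedule$state[clamp(i, 1, nrow(schedule))]
  }
  beats <- numeric(0)
  t <- 0
  while (t < total) {
    s <- state_at(t)
    ibi <- 60 / (hr_by_state[s + 1L] + hr_shift)
    ibi <- ibi + rnorm(1, 0, sdnn_by_state[s + 1L] / 1000)
    ibi <- max(ibi, 0.25)
    t <- t + ibi
    if (t < total) beats <- c(beats, t)
  }
  beats
}

# Place a pulse waveform at each beat time on a sample grid.
pulse_train <- function(beat_times, n, rate, width_s, sharp = FALSE) {
  x <- numeric(n)
  half <- width_s / 2
  for (bt in beat_times) {
    i0 <- max(1L, floor((bt - half) * rate) + 1L)
    i1 <- min(n, ceiling((bt + half) * rate) + 1L)
    if (i0 > i1) next
    tt <- (seq(i0, i1) - 1) / rate - bt
    w <- if (sharp) pmax(0, 1 - abs(tt) / half)        # narrow triangle (R wave)
         else 0.5 * (1 + cos(pi * clamp(tt / half, -1, 1)))  # raised cosine
    x[i0:i1] <- x[i0:i1] + w
  }
  x
}

# Bi-exponential skin-conductance-response kernel (rise 0.75 s, decay 2 s).
scr_kernel <- function(rate, rise_s = 0.75, decay_s = 2.0, length_s = 10) {
  t <- seq(0, length_s, by = 1 / rate)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k / max(k)
}

# Band-limited Gaussian noise: white noise low-passed at `cutoff` Hz.
bandlimited_noise <- function(n, rate, cutoff) {
  x <- rnorm(n)
  if (cutoff < rate / 2) x <- butterworth_lowpass(x, rate, cutoff, order = 2)
  x / max(sd(x), 1e-12)
}

simulate_subject <- function(config, subject_id, seed) {
  with_local_seed(seed, {
    sp <- config$state_params[order(config$state_params$state), ]
    sched <- config$state_schedule
    total <- sum(sched$duration_s)
    rates <- config$channel_rates
    nz <- config$noise_sd
    es <- config$subject_effect_sd

    attrs <- list(
      age = sample(20:45, 1),
      gender = sample(c("female", "male"), 1),
      height = round(runif(1, 155, 195), 1),
      weight = round(runif(1, 50, 100), 1),
      smoker = runif(1) < 0.3,
      exercised_today = runif(1) < 0.5
    )
    # Older subjects run a slightly lower heart rate (-0.2 bpm per year from 30).
    hr_shift <- rnorm(1, 0, es$hr_bpm) - 0.2 * (attrs$age - 30)
    eda_shift <- rnorm(1, 0, es$eda_us)
    temp_base <- 34 + rnorm(1, 0, es$temp_c)

    channels <- list()
    mk <- function(name, samples, rate) {
      channels[[name]] <<- list(name = name, sampling_rate = rate,
                                samples = as.numeric(samples))
    }
    beat_times <- NULL
    need_beats <- any(c("BVP", "ECG") %in% names(rates))
    if (need_beats)
      beat_times <- simulate_beat_times(sched, sp$hr_bpm, sp$sdnn_ms, hr_shift)

    for (ch in names(rates)) {
      r <- rates[[ch]]
      n <- round(total * r)
      tt <- (seq_len(n) - 1) / r
      samples <- switch(sub("_[xyz]$", "", ch),
        ACC = {
          motion <- schedule_values(sched, r, sp$motion_g)
          g0 <- if (ch == "ACC_z") 1 else 0   # gravity on one axis
          g0 + motion * bandlimited_noise(n, r, min(10, r / 2 * 0.9)) +
            rnorm(n, 0, nz$acc)
        },
        BVP = pulse_train(beat_times, n, r, width_s = 0.45) +
          rnorm(n, 0, nz$bvp),
        ECG = pulse_train(beat_times, n, r, width_s = 0.06, sharp = TRUE) +
          rnorm(n, 0, nz$ecg),
        EDA = {
          tonic <- schedule_values(sched, r, sp$eda_tonic_us) + eda_shift
          rate_per_s <- schedule_values(sched, r, sp$scr_per_min) / 60
          events <- rbinom(n, 1, pmin(rate_per_s / r, 1)) *
            (0.3 + stats::rexp(n, 2))
          phasic <- convolve_causal(events, scr_kernel(r))
          tonic + phasic + rnorm(n, 0, nz$eda)
        },
        EMG = schedule_values(sched, r, sp$emg_mv) * rnorm(n),
        TEMP = {
          drift <- cumsum(schedule_values(sched, r,
                                          sp$temp_drift_c_per_min)) / (60 * r)
          temp_base + drift + rnorm(n, 0, nz$temp)
        },
        RESP = {
          phase <- 2 * pi * cumsum(schedule_values(sched, r,
                                                   sp$resp_bpm) / 60) / r
          sin(phase) + rnorm(n, 0, nz$resp)
        },
        stop_config("unknown channel ", ch))
      mk(ch, samples, r)
    }

    labels <- list(sampling_rate = config$label_rate_hz,
                   codes = as.integer(schedule_codes(sched,
                                                     config$label_rate_hz)))
    structure(list(subject_id = subject_id, attributes = attrs,
                   channels = channels, labels = labels,
                   duration_s = total),
              class = "subject_record")
  })
}

convolve_causal <- function(x, kernel) {
  n <- length(x)
  y <- stats::convolve(x, rev(kernel), type = "open")[seq_len(n)]
  y
}

#' Generate a synthetic cohort
#'
#' Produces `n_subjects` subject records following the configured state
#' schedule. ECG/BVP are pulse trains at the state's heart rate with
#' inter-beat jitter at the state's SDNN scale; EDA is a tonic level plus
#' Poisson-like SCR events convolved with a bi-exponential kernel; RESP is
#' sinusoidal at the state's rate; TEMP drifts linearly; EMG is white noise
#' scaled by state; ACC axes are band-limited noise scaled by motion
#' intensity. Deterministic given the configuration seed.
#'
#' @param config a [cohort_config()].
#' @return list of `subject_record` objects.
#' @examples
#' cfg <- cohort_config(n_subjects = 2, state_schedule = data.frame(
#'   state = c(0L, 2L), duration_s = c(60, 60)), seed = 11)
#' cohort <- generate_cohort(cfg)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_seeds(config$seed, config$n_subjects)
  lapply(seq_len(config$n_subjects), function(i) {
    simulate_subject(config, sprintf("S%02d", i), seeds[i])
  })
}

#' Generate a tabular dataset from a symbolic expression
#'
#' Draws inputs uniformly over per-variable domains and evaluates the
#' expression (plus optional Gaussian noise) as the target column. Used to
#' benchmark the symbolic-regression engine.
#'
#' @param expression an expression tree (see [parse_expression()]) or an infix
#'   string such as `"2*x1 + sin(x2)"`.
#' @param n number of rows.
#' @param domain named list of `c(lower, upper)` intervals, one per variable.
#' @param noise_sd standard deviation of additive Gaussian noise on the target.
#' @param seed integer seed.
#' @return data.frame with one column per variable plus `target`.
#' @export
generate_formula_dataset <- function(expression, n, domain, noise_sd = 0,
                                     seed = 1L) {
  expr <- if (is.character(expression)) parse_expression(expression)
          else expression
  vars <- expression_variables(expr)
  missing <- setdiff(vars, names(domain))
  if (length(missing))
    stop_config("no domain declared for variable(s): ",
                paste(missing, collapse = ", "))
  with_local_seed(seed, {
    inputs <- as.data.frame(lapply(domain, function(d) runif(n, d[1], d[2])))
    target <- evaluate_expression(expr, inputs)
    if (noise_sd > 0) target <- target + rnorm(n, 0, noise_sd)
    cbind(inputs, target = target)
  })
}
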