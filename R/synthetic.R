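#' Cohort generator configuration
#'
#' Defines the study conditions a synthetic free-living cohort emulates:
#' group sizes (default 8 tremor-positive PD-like subjects, 16 PD-like
#' subjects without tremor, 24 control-like subjects), per-subject recording
#' duration, the activity repertoire, tremor signal priors (fundamental
#' frequency uniform on 4--7 Hz, per-subject constant), amplitude and noise
#' scales in g, and the fraction of clean intervals flagged as prototypical
#' examples.
#'
#' @param n_tremor,n_pd_no_tremor,n_control Subjects per group.
#' @param duration_s Recording length per subject in seconds.
#' @param activities Activity repertoire (subset of `N1`..`N7`).
#' @param tremor_freq_range Range of per-subject tremor fundamental (Hz).
#' @param tremor_amp_range Range of per-subject tremor amplitude (g).
#' @param harmonic_range Range of the relative amplitude of the 2f harmonic.
#' @param noise_sd_g Accelerometer noise floor SD (g).
#' @param drift_rate Orientation drift scale (g per knot step).
#' @param n5_freq_range Frequency range of the `N5` "suspicious" periodic
#'   confuser (Hz).
#' @param n5_amp Amplitude of the `N5` confuser (g).
#' @param prototype_fraction Fraction of each sub-class's intervals flagged
#'   as prototypical examples (at least one per present sub-class).
#' @return A `pn_cohort_config` list.
#' @export
cohort_config <- function(n_tremor = 8,
                          n_pd_no_tremor = 16,
                          n_control = 24,
                          duration_s = 600,
                          activities = c("N1", "N2", "N3", "N4", "N6", "N7"),
                          tremor_freq_range = c(4, 7),
                          tremor_amp_range = c(0.10, 0.15),
                          harmonic_range = c(0.1, 0.4),
                          noise_sd_g = 0.01,
                          drift_rate = 0.02,
                          n5_freq_range = c(3, 5),
                          n5_amp = 0.08,
                          prototype_fraction = 0.3) {
  stopifnot(duration_s > 0, all(activities %in% non_tremor_sub_classes()))
  structure(list(n_tremor = n_tremor,
                 n_pd_no_tremor = n_pd_no_tremor,
                 n_control = n_control,
                 duration_s = duration_s,
                 activities = activities,
                 tremor_freq_range = tremor_freq_range,
                 tremor_amp_range = tremor_amp_range,
                 harmonic_range = harmonic_range,
                 noise_sd_g = noise_sd_g,
                 drift_rate = drift_rate,
                 n5_freq_range = n5_freq_range,
                 n5_amp = n5_amp,
                 prototype_fraction = prototype_fraction),
            class = "pn_cohort_config")
}

#' Difficulty presets for the synthetic cohort
#'
#' `"easy"` uses a high tremor amplitude relative to the noise floor and no
#' `N5` "suspicious" confuser activity. `"hard"` lowers the tremor
#' amplitude toward the noise floor and schedules `N5` confusers whose
#' periodic frequency falls inside the 4--7 Hz tremor band.
#'
#' @param name `"easy"` or `"hard"`.
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `pn_cohort_config`.
#' @export
difficulty_presets <- function(name = c("easy", "hard"), ...) {
  name <- match.arg(name)
  base <- if (name == "easy") {
    cohort_config(activities = c("N1", "N2", "N3", "N4", "N6", "N7"),
                  tremor_amp_range = c(0.10, 0.15),
                  noise_sd_g = 0.01)
  } else {
    cohort_config(activities = c("N1", "N2", "N3", "N4", "N5", "N6", "N7"),
                  tremor_amp_range = c(0.03, 0.05),
                  noise_sd_g = 0.02,
                  n5_freq_range = c(4, 5.5),
                  n5_amp = 0.05)
  }
  overrides <- list(...)
  if (length(overrides) > 0L) base[names(overrides)] <- overrides
  base
}

#' Per-subject generator profile
#'
#' @param subject_id Subject identifier.
#' @param has_tremor Whether the subject exhibits tremor episodes.
#' @param tremor_freq_hz Per-subject rest-tremor fundamental in \[4, 7\] Hz.
#' @param tremor_amp_g Tremor amplitude scale (g).
#' @param harmonic_ratio Relative amplitude of the 2f harmonic in \[0, 1\].
#' @param sub_class_mix Probability weights over tremor sub-classes
#'   `T1`..`T7` (normalised internally).
#' @param activity_schedule Optional pre-built schedule tibble with columns
#'   `activity`, `duration_s`; built from `config` when `NULL`.
#' @param drift_rate Orientation drift scale.
#' @param noise_sd_g Noise floor SD (g).
#' @param seed Integer seed making the subject a pure function of the
#'   profile.
#' @param config A [cohort_config()] supplying activity parameters.
#' @return A `pn_subject_profile` list.
#' @export
subject_profile <- function(subject_id,
                            has_tremor,
                            tremor_freq_hz = 5,
                            tremor_amp_g = 0.12,
                            harmonic_ratio = 0.25,
                            sub_class_mix = rep(1 / 7, 7),
                            activity_schedule = NULL,
                            drift_rate = 0.02,
                            noise_sd_g = 0.01,
                            seed = 1L,
                            config = cohort_config()) {
  if (has_tremor && (tremor_freq_hz < 4 || tremor_freq_hz > 7)) {
    abort("`tremor_freq_hz` must lie in [4, 7] Hz.")
  }
  if (tremor_amp_g <= 0) abort("`tremor_amp_g` must be positive.")
  sub_class_mix <- sub_class_mix / sum(sub_class_mix)
  structure(list(subject_id = as.character(subject_id),
                 has_tremor = isTRUE(has_tremor),
                 tremor_freq_hz = tremor_freq_hz,
                 tremor_amp_g = tremor_amp_g,
                 harmonic_ratio = harmonic_ratio,
                 sub_class_mix = sub_class_mix,
                 activity_schedule = activity_schedule,
                 drift_rate = drift_rate,
                 noise_sd_g = noise_sd_g,
                 seed = as.integer(seed),
                 config = config),
            class = "pn_subject_profile")
}

# Typical block durations per activity (seconds); blocks are drawn uniform
# within the range.
activity_duration_ranges <- function() {
  list(N1 = c(20, 40), N2 = c(3, 6), N3 = c(15, 30), N4 = c(20, 40),
       N5 = c(10, 20), N6 = c(10, 20), N7 = c(24, 50))
}

# Build a block schedule with tremor carriers already planted. Blocks
# alternate between ordinary activities (a seeded cycle through the
# repertoire, then weighted draws favouring rest) and -- for tremor
# subjects -- designated carrier blocks: tremor rides on rest (T1..T6 on
# N7 blocks) or on gait (T7 on N1 blocks). The first carriers enumerate
# all seven tremor sub-classes in seeded order so the taxonomy is covered
# whenever the recording is long enough; later carriers draw from the
# subject's sub-class mix. Roughly a third of a tremor subject's time
# carries tremor.
build_schedule <- function(duration_s, activities, has_tremor,
                           sub_class_mix = rep(1 / 7, 7)) {
  if (duration_s <= 0) abort("Schedule duration must be positive.")
  rng <- activity_duration_ranges()
  draw_dur <- function(a) runif(1L, rng[[a]][1L], rng[[a]][2L])
  w <- ifelse(activities == "N7", 3, ifelse(activities == "N2", 0.5, 1))
  act_queue <- sample(activities)
  carrier_queue <- if (has_tremor) {
    q <- sample(c(paste0("T", 1:6), if ("N1" %in% activities) "T7"))
    q
  } else {
    character(0L)
  }
  blocks <- list()
  total <- 0
  i_act <- 0L
  i_car <- 0L
  phase <- 1L   # 1, 2 = activity blocks; 3 = carrier block (tremor subjects)
  while (total < duration_s) {
    if (has_tremor && phase == 3L) {
      i_car <- i_car + 1L
      sc <- if (i_car <= length(carrier_queue)) {
        carrier_queue[i_car]
      } else if (runif(1L) < 1 / 7 && "N1" %in% activities) {
        "T7"
      } else {
        sample(paste0("T", 1:6), 1L, prob = sub_class_mix[1:6])
      }
      a <- if (sc == "T7") "N1" else "N7"
      blocks[[length(blocks) + 1L]] <-
        tibble::tibble(activity = a, duration_s = draw_dur(a),
                       tremor = TRUE, tremor_sub_class = sc)
    } else {
      i_act <- i_act + 1L
      a <- if (i_act <= length(act_queue)) {
        act_queue[i_act]
      } else {
        sample(activities, 1L, prob = w)
      }
      blocks[[length(blocks) + 1L]] <-
        tibble::tibble(activity = a, duration_s = draw_dur(a),
                       tremor = FALSE, tremor_sub_class = "none")
    }
    total <- total + blocks[[length(blocks)]]$duration_s
    phase <- if (phase == 3L) 1L else phase + 1L
    if (!has_tremor && phase == 3L) phase <- 1L
  }
  blocks <- dplyr::bind_rows(blocks)
  excess <- sum(blocks$duration_s) - duration_s
  last <- nrow(blocks)
  blocks$duration_s[last] <- blocks$duration_s[last] - excess
  if (blocks$duration_s[last] < 2) {
    # fold a too-short trailing block into its predecessor so the schedule
    # always covers duration_s exactly
    blocks$duration_s[last - 1L] <- blocks$duration_s[last - 1L] +
      blocks$duration_s[last]
    blocks <- blocks[-last, , drop = FALSE]
  }
  blocks
}

# Piecewise-linear orientation drift around the resting gravity vector
# (0, 0, 1): knots every ~30 s, axis offsets interpolated linearly.
gravity_drift <- function(n, rate_hz, drift_rate) {
  dur <- n / rate_hz
  n_knots <- max(2L, ceiling(dur / 30) + 1L)
  knot_t <- seq(0, dur, length.out = n_knots)
  t <- (seq_len(n) - 1L) / rate_hz
  out <- matrix(0, n, 3L)
  base <- c(0, 0, 1)
  for (j in 1:3) {
    knots <- base[j] + cumsum(c(0, rnorm(n_knots - 1L, 0, drift_rate)))
    out[, j] <- stats::approx(knot_t, knots, xout = t, rule = 2)$y
  }
  out
}

# Slowly varying log-normal amplitude envelope: AR(1) discretisation of an
# Ornstein-Uhlenbeck process on log-amplitude (correlation time tau_s).
ou_envelope <- function(n, rate_hz, tau_s = 5, sd_log = 0.3) {
  phi <- exp(-1 / (rate_hz * tau_s))
  eps <- rnorm(n, 0, sd_log * sqrt(1 - phi^2))
  x <- as.numeric(stats::filter(eps, phi, method = "recursive"))
  exp(x)
}

# Smooth on/off burst envelope used for N6-type intermittent activity.
burst_envelope <- function(n, rate_hz, mean_on_s = 2, mean_off_s = 2) {
  env <- numeric(n)
  i <- 1L
  on <- runif(1L) < 0.5
  while (i <= n) {
    len <- ceiling(rate_hz * stats::rexp(1L, 1 / (if (on) mean_on_s else mean_off_s)))
    j <- min(n, i + len - 1L)
    if (on) env[i:j] <- 1
    i <- j + 1L
    on <- !on
  }
  k <- ceiling(rate_hz * 0.25)
  sm <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- env[is.na(sm)]
  sm
}

# Harmonic oscillation distributed over axes by a mixing vector.
oscillation <- function(n, rate_hz, freq, amp, mix, harmonics = c(1)) {
  t <- (seq_len(n) - 1L) / rate_hz
  sig <- numeric(n)
  for (h in seq_along(harmonics)) {
    if (harmonics[h] <= 0) next
    sig <- sig + harmonics[h] * sin(2 * pi * freq * h * t + runif(1L, 0, 2 * pi))
  }
  outer(amp * sig, mix / sqrt(sum(mix^2)))
}

# Per-activity signal component for one block (n samples at rate_hz).
activity_signal <- function(activity, n, rate_hz, config) {
  switch(activity,
    N1 = oscillation(n, rate_hz, freq = rnorm(1L, 1.8, 0.08), amp = 0.25,
                     mix = c(0.7, 0.3, 0.8), harmonics = c(1, 0.5, 0.25)),
    N2 = {
      env <- exp(-((seq_len(n) - n / 2)^2) / (2 * (n / 6)^2))
      noise <- matrix(rnorm(3L * n, 0, 1), n, 3L)
      k <- max(3L, ceiling(rate_hz / 25))
      for (j in 1:3) {
        sm <- stats::filter(noise[, j], rep(1 / k, k), sides = 2)
        sm[is.na(sm)] <- 0
        noise[, j] <- sm
      }
      0.5 * env * noise
    },
    N3 = oscillation(n, rate_hz, freq = runif(1L, 2.5, 3), amp = 0.7,
                     mix = c(0.8, 0.4, 0.6), harmonics = c(1, 0.6, 0.3)),
    N4 = oscillation(n, rate_hz, freq = runif(1L, 0.8, 1.2), amp = 0.15,
                     mix = c(0.5, 0.5, 0.7), harmonics = c(1, 0.3)) +
      matrix(rnorm(3L * n, 0, 0.02), n, 3L),
    N5 = {
      f <- runif(1L, config$n5_freq_range[1L], config$n5_freq_range[2L])
      env <- ou_envelope(n, rate_hz, tau_s = 4, sd_log = 0.25)
      env * oscillation(n, rate_hz, freq = f, amp = config$n5_amp,
                        mix = c(0.8, 0.5, 0.3), harmonics = c(1))
    },
    N6 = {
      env <- burst_envelope(n, rate_hz)
      noise <- matrix(rnorm(3L * n, 0, 1), n, 3L)
      k <- max(3L, ceiling(rate_hz / 12))
      for (j in 1:3) {
        sm <- stats::filter(noise[, j], rep(1 / k, k), sides = 2)
        sm[is.na(sm)] <- 0
        noise[, j] <- sm
      }
      0.35 * env * noise
    },
    N7 = matrix(0, n, 3L),
    abort(sprintf("Unknown activity token '%s'.", activity))
  )
}

# Axis mixing vectors per tremor sub-class: T1/T2 dominantly one axis,
# T3/T4 another, T5/T6 spread across two axes, T7 superposed on gait.
tremor_mixes <- function() {
  list(T1 = c(1.0, 0.20, 0.10), T2 = c(0.9, 0.35, 0.20),
       T3 = c(0.2, 1.00, 0.20), T4 = c(0.3, 0.90, 0.35),
       T5 = c(0.7, 0.70, 0.15), T6 = c(0.6, 0.60, 0.55),
       T7 = c(0.7, 0.30, 0.60))
}

tremor_signal <- function(n, rate_hz, profile, sub_class) {
  mix <- tremor_mixes()[[sub_class]]
  f <- profile$tremor_freq_hz
  t <- (seq_len(n) - 1L) / rate_hz
  env <- ou_envelope(n, rate_hz, tau_s = 5, sd_log = 0.3)
  base <- sin(2 * pi * f * t + runif(1L, 0, 2 * pi)) +
    profile$harmonic_ratio * sin(2 * pi * 2 * f * t + runif(1L, 0, 2 * pi))
  sig <- profile$tremor_amp_g * env * base
  wob <- if (sub_class %in% c("T2", "T4", "T6")) {
    0.03 * sin(2 * pi * 0.3 * t + runif(1L, 0, 2 * pi))
  } else {
    0
  }
  outer(sig, mix / sqrt(sum(mix^2))) + wob
}

#' Generate one synthetic subject
#'
#' Produces a 200 Hz tri-axial recording as the sum of gravity with
#' piecewise-linear orientation drift, an activity component per scheduled
#' block, a tremor component on tremor-planted blocks (per-subject constant
#' fundamental in 4--7 Hz plus a 2f harmonic, amplitude modulated by a
#' slowly varying log-normal envelope and distributed over axes by a
#' per-sub-class mixing vector), and white accelerometer noise. Every block
#' is annotated; a seeded fraction of intervals per sub-class is flagged as
#' prototypical examples.
#'
#' @param profile A [subject_profile()].
#' @param rate_hz Output sampling rate (200 Hz device rate).
#' @return A list with elements `recording` and `annotations`.
#' @export
generate_subject <- function(profile, rate_hz = 200) {
  config <- profile$config
  with_seed(profile$seed, {
    sched <- profile$activity_schedule
    if (is.null(sched)) {
      sched <- build_schedule(config$duration_s, config$activities,
                              profile$has_tremor, profile$sub_class_mix)
    }
    if (nrow(sched) == 0L || sum(sched$duration_s) <= 0) {
      abort("Activity schedule has zero duration.")
    }
    if (!"tremor" %in% names(sched)) {
      sched$tremor <- FALSE
      sched$tremor_sub_class <- "none"
    }
    if (!profile$has_tremor) {
      sched$tremor <- FALSE
      sched$tremor_sub_class <- "none"
    }
    # cumulative rounding: total sample count depends only on total
    # duration, not on how the schedule is partitioned into blocks
    bounds <- round(cumsum(c(0, sched$duration_s)) * rate_hz)
    n_block <- as.integer(diff(bounds))
    n_block[n_block < 1L] <- 1L
    n <- sum(n_block)
    acc <- gravity_drift(n, rate_hz, profile$drift_rate)
    offs <- cumsum(c(0L, head(n_block, -1L)))
    for (b in seq_len(nrow(sched))) {
      idx <- offs[b] + seq_len(n_block[b])
      acc[idx, ] <- acc[idx, ] +
        activity_signal(sched$activity[b], n_block[b], rate_hz, config)
      if (sched$tremor[b]) {
        acc[idx, ] <- acc[idx, ] +
          tremor_signal(n_block[b], rate_hz, profile, sched$tremor_sub_class[b])
      }
    }
    acc <- acc + matrix(rnorm(3L * n, 0, profile$noise_sd_g), n, 3L)
    df <- tibble::tibble(time_s = (seq_len(n) - 1L) / rate_hz,
                         acc_x = acc[, 1L], acc_y = acc[, 2L],
                         acc_z = acc[, 3L])
    rec <- recording(df, subject_id = profile$subject_id, side = "right",
                     rate_hz = rate_hz)
    starts <- offs / rate_hz
    ends <- (offs + n_block) / rate_hz
    ann <- tibble::tibble(
      start_s = starts,
      end_s = ends,
      label = ifelse(sched$tremor, "tremor", "non_tremor"),
      sub_class = ifelse(sched$tremor, sched$tremor_sub_class,
                         sched$activity),
      prototype = FALSE
    )
    # Flag a seeded fraction of each sub-class's intervals as prototypes
    # (at least one per present sub-class).
    for (sc in unique(ann$sub_class)) {
      idx <- which(ann$sub_class == sc)
      k <- min(length(idx), max(1L, round(config$prototype_fraction * length(idx))))
      ann$prototype[idx[sample.int(length(idx), k)]] <- TRUE
    }
    list(recording = rec,
         annotations = annotation_track(ann, subject_id = profile$subject_id))
  })
}

#' Generate a synthetic free-living cohort
#'
#' A cohort is a pure function of `(config, master_seed)`: per-subject
#' seeds are derived deterministically from the master seed with a
#' counter-based scheme, so subjects are independent and the whole cohort
#' is reproducible bit-for-bit.
#'
#' @param config A [cohort_config()] or [difficulty_presets()] output.
#' @param master_seed Integer master seed.
#' @return A `pn_cohort` tibble with one row per subject and list-columns
#'   `recording` and `annotations`.
#' @export
generate_cohort <- function(config = cohort_config(), master_seed = 1L) {
  groups <- c(rep("tremor", config$n_tremor),
              rep("pd_no_tremor", config$n_pd_no_tremor),
              rep("control", config$n_control))
  if (config$n_tremor == 0L && config$prototype_fraction > 0) {
    warn("Cohort has no tremor subjects: tremor prototypes are unavailable.")
  }
  subjects <- vector("list", length(groups))
  ids <- character(length(groups))
  for (i in seq_along(groups)) {
    seed_i <- derive_seed(master_seed, i)
    ids[i] <- sprintf("S%02d", i)
    prof <- with_seed(derive_seed(master_seed, 100000L + i), {
      subject_profile(
        subject_id = ids[i],
        has_tremor = groups[i] == "tremor",
        tremor_freq_hz = runif(1L, config$tremor_freq_range[1L],
                               config$tremor_freq_range[2L]),
        tremor_amp_g = runif(1L, config$tremor_amp_range[1L],
                             config$tremor_amp_range[2L]),
        harmonic_ratio = runif(1L, config$harmonic_range[1L],
                               config$harmonic_range[2L]),
        sub_class_mix = rep(1 / 7, 7),
        drift_rate = config$drift_rate,
        noise_sd_g = config$noise_sd_g,
        seed = seed_i,
        config = config)
    })
    subjects[[i]] <- generate_subject(prof)
  }
  out <- tibble::tibble(
    subject_id = ids,
    group = groups,
    has_tremor = groups == "tremor",
    recording = lapply(subjects, `[[`, "recording"),
    annotations = lapply(subjects, `[[`, "annotations")
  )
  structure(out,
            class = c("pn_cohort", class(out)),
            config = config,
            master_seed = as.integer(master_seed))
}

#' @export
print.pn_cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d tremor), master seed %d\n",
              nrow(x), sum(x$has_tremor), attr(x, "master_seed")))
  NextMethod()
}
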