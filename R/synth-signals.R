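#' Configuration for simulated calcium trials
#'
#' Emulates the acquisition the scoring assumes: a uniformly sampled
#' fluorescence trace at 6.61 frames/s, a 30 s resting period, a short
#' (100 ms) stimulation event, and a 30 s post-stimulus period. The
#' simulated trace is `F0` plus Gaussian noise plus an exponentially
#' decaying transient of amplitude `A` starting at the first acquired
#' frame after stimulus offset (so the noise-free ground-truth peak is
#' exactly `A / F0`, free of sampling lag).
#'
#' @param n_animals,trials_per_animal cohort shape.
#' @param fps frame rate, frames/s (default 6.61).
#' @param rest_s resting period before and after the stimulus, s.
#' @param stim_s stimulation duration, s (default 0.1).
#' @param f0 baseline fluorescence, a.u.
#' @param noise_sd Gaussian noise SD, a.u.
#' @param amplitude transient amplitude `A`, a.u. (ground-truth peak is
#'   `A / f0`).
#' @param tau_s transient decay time constant, s.
#' @param modality stimulation modality (sets the default rejection band).
#' @return list of class `calcium_sim_config`.
#' @export
calcium_sim_config <- function(n_animals = 6, trials_per_animal = 3,
                               fps = 6.61, rest_s = 30, stim_s = 0.1,
                               f0 = 100, noise_sd = 5, amplitude = 80,
                               tau_s = 2,
                               modality = "mechanosensory") {
  stopifnot(fps > 0, tau_s > 0, noise_sd >= 0, f0 > 0, rest_s >= 3)
  structure(list(n_animals = n_animals,
                 trials_per_animal = trials_per_animal, fps = fps,
                 rest_s = rest_s, stim_s = stim_s, f0 = f0,
                 noise_sd = noise_sd, amplitude = amplitude,
                 tau_s = tau_s, modality = modality),
            class = "calcium_sim_config")
}

#' Simulate stimulus-locked calcium trials
#'
#' Pure function of (config, seed).
#'
#' @param config a [calcium_sim_config()].
#' @param seed integer seed.
#' @return list with `trials` (list of [calcium_trial()]) and
#'   `ground_truth` (`peak = amplitude / f0`, plus the config).
#' @export
simulate_calcium <- function(config = calcium_sim_config(), seed = 1) {
  set.seed(seed)
  dt <- 1 / config$fps
  total_s <- 2 * config$rest_s + config$stim_s
  times <- seq(0, total_s, by = dt)
  onset <- config$rest_s
  offset <- config$rest_s + config$stim_s
  t_first <- times[times > offset][1]
  trials <- list()
  for (a in seq_len(config$n_animals))
    for (tr in seq_len(config$trials_per_animal)) {
      f <- config$f0 + stats::rnorm(length(times), 0, config$noise_sd)
      post <- times >= t_first
      f[post] <- f[post] + config$amplitude *
        exp(-(times[post] - t_first) / config$tau_s)
      trials[[length(trials) + 1]] <-
        calcium_trial(times, f, onset, offset, modality = config$modality,
                      animal_id = paste0("animal", a),
                      trial_id = paste0("animal", a, "_trial", tr))
    }
  list(trials = trials,
       ground_truth = list(peak = config$amplitude / config$f0,
                           config = config))
}

#' Configuration for simulated behavior cohorts
#'
#' Each animal responds with its group's design probability; responding
#' animals get a behavior bout inside the analysis window. Tracking gaps
#' and collisions are injected at design rates so the coverage and
#' collision filters are exercised. Defaults emulate a vibration assay:
#' 30 s pre-stimulus, a 15 s analysis window at stimulus onset, around
#' 300 animals per group.
#'
#' @param groups data.frame with `group`, `n_animals`, `p_response`.
#' @param behavior bout label.
#' @param total_s recording length, s.
#' @param window a [behavior_window()].
#' @param bout_shape,bout_scale gamma bout-duration parameters, s.
#' @param gap_rate probability an animal has a tracking gap overlapping
#'   the window.
#' @param gap_s gap length, s (long enough to break 95% coverage).
#' @param collision_rate probability of a collision inside the window.
#' @return list of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(groups = data.frame(
                                  group = c("experimental", "control"),
                                  n_animals = c(300, 300),
                                  p_response = c(0.5, 0.3)),
                                behavior = "bend", total_s = 75,
                                window = behavior_window(30, 15),
                                bout_shape = 2, bout_scale = 1,
                                gap_rate = 0.1, gap_s = 2,
                                collision_rate = 0.05) {
  stopifnot(all(groups$p_response >= 0 & groups$p_response <= 1),
            gap_rate >= 0 && gap_rate <= 1,
            collision_rate >= 0 && collision_rate <= 1)
  structure(list(groups = groups, behavior = behavior, total_s = total_s,
                 window = window, bout_shape = bout_shape,
                 bout_scale = bout_scale, gap_rate = gap_rate,
                 gap_s = gap_s, collision_rate = collision_rate),
            class = "behavior_sim_config")
}

#' Simulate behavior tracks
#'
#' Pure function of (config, seed).
#'
#' @param config a [behavior_sim_config()].
#' @param seed integer seed.
#' @return list with `tracks` (the track table consumed by
#'   [behavior_probability()] etc.) and `ground_truth` (per-animal
#'   response, gap and collision draws plus the config).
#' @export
simulate_behavior <- function(config = behavior_sim_config(), seed = 1) {
  set.seed(seed)
  w <- config$window
  rows <- list()
  truth <- list()
  for (gi in seq_len(nrow(config$groups))) {
    g <- config$groups[gi, ]
    for (a in seq_len(g$n_animals)) {
      id <- paste0(g$group, "_", a)
      responded <- stats::runif(1) < g$p_response
      has_gap <- stats::runif(1) < config$gap_rate
      has_collision <- stats::runif(1) < config$collision_rate
      if (has_gap) {
        gap_start <- stats::runif(1, w$onset_s,
                                  w$end_s - config$gap_s)
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = id, group = g$group,
          interval_type = "tracked", behavior = NA,
          start_s = c(0, gap_start + config$gap_s),
          end_s = c(gap_start, config$total_s))
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = id, group = g$group, interval_type = "tracked",
          behavior = NA, start_s = 0, end_s = config$total_s)
      }
      if (has_collision)
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = id, group = g$group, interval_type = "collision",
          behavior = NA,
          start_s = stats::runif(1, w$onset_s, w$end_s - 0.5),
          end_s = NA)
      if (responded) {
        dur <- stats::rgamma(1, config$bout_shape, scale = config$bout_scale)
        dur <- min(dur, w$length_s - 0.2)
        start <- stats::runif(1, w$onset_s, w$end_s - dur)
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = id, group = g$group, interval_type = "bout",
          behavior = config$behavior, start_s = start, end_s = start + dur)
      }
      truth[[length(truth) + 1]] <- data.frame(
        animal_id = id, group = g$group, responded = responded,
        has_gap = has_gap, has_collision = has_collision)
    }
  }
  tracks <- do.call(rbind, rows)
  tracks$end_s[is.na(tracks$end_s)] <-
    tracks$start_s[is.na(tracks$end_s)] + 0.5
  list(tracks = tracks, ground_truth = list(
    animals = do.call(rbind, truth), config = config))
}
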