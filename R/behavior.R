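#' Analysis window for behavior scoring
#'
#' @param onset_s window start, s (stimulus onset; for thermogenetic
#'   ramps, the moment the plate reaches the target temperature).
#' @param length_s window length, s (15 for optogenetic or vibration
#'   stimuli, 40 for thermogenetic activation).
#' @return list of class `behavior_window`.
#' @export
behavior_window <- function(onset_s, length_s = 15) {
  stopifnot(length_s > 0)
  structure(list(onset_s = onset_s, length_s = length_s,
                 end_s = onset_s + length_s), class = "behavior_window")
}

check_tracks <- function(tracks) {
  required_cols(tracks, c("animal_id", "interval_type", "start_s", "end_s"),
                "track")
  if (any(tracks$start_s >= tracks$end_s))
    stop("track intervals must have start_s < end_s")
  if (!"behavior" %in% names(tracks)) tracks$behavior <- NA_character_
  if (!"group" %in% names(tracks)) tracks$group <- "all"
  tracks
}

overlap_len <- function(start, end, window) {
  pmax(0, pmin(end, window$end_s) - pmax(start, window$onset_s))
}

#' Animal inclusion under coverage and collision filters
#'
#' An animal is included when it was tracked for at least `min_coverage`
#' of the analysis window and had no collision with another animal
#' intersecting the window (any overlap excludes).
#'
#' @param tracks track table: `animal_id`, `group`, `interval_type`
#'   (`"tracked"`, `"collision"`, `"bout"`), `behavior`, `start_s`,
#'   `end_s`.
#' @param window a [behavior_window()].
#' @param min_coverage minimum tracked fraction of the window (default
#'   0.95).
#' @return list with `included` (animal ids) and `exclusions`
#'   (data.frame: `animal_id`, `reason`).
#' @export
valid_animals <- function(tracks, window, min_coverage = 0.95) {
  tracks <- check_tracks(tracks)
  animals <- unique(tracks$animal_id)
  tr <- tracks[tracks$interval_type == "tracked", ]
  col <- tracks[tracks$interval_type == "collision", ]
  cov <- vapply(animals, function(a) {
    g <- tr[tr$animal_id == a, ]
    sum(overlap_len(g$start_s, g$end_s, window)) / window$length_s
  }, numeric(1))
  hit <- vapply(animals, function(a) {
    g <- col[col$animal_id == a, ]
    any(overlap_len(g$start_s, g$end_s, window) > 0 |
          (g$start_s < window$end_s & g$end_s > window$onset_s))
  }, logical(1))
  reason <- ifelse(cov < min_coverage, "coverage",
                   ifelse(hit, "collision", NA))
  list(included = animals[is.na(reason)],
       exclusions = data.frame(animal_id = animals[!is.na(reason)],
                               reason = reason[!is.na(reason)]))
}

bouts_in_window <- function(tracks, behavior, window, animals) {
  b <- tracks[tracks$interval_type == "bout" &
                tracks$behavior == behavior &
                tracks$animal_id %in% animals, , drop = FALSE]
  b$clipped <- overlap_len(b$start_s, b$end_s, window)
  b[b$clipped > 0, , drop = FALSE]
}

#' Behavior probability in a window
#'
#' The proportion of valid animals that performed the behavior at least
#' once during the window (a bout counts when it intersects the window at
#' all), with a 95% confidence interval.
#'
#' @param tracks track table (see [valid_animals()]).
#' @param behavior behavior label (e.g. `"bend"`, `"hunch"`, `"roll"`).
#' @param window a [behavior_window()].
#' @param min_coverage passed to [valid_animals()].
#' @param ci_method `"wilson"` (default) or `"wald"`.
#' @return list of class `behavior_summary`: `n_valid`, `n_responding`,
#'   `probability`, `ci95`, `responders`, `exclusions`.
#' @export
behavior_probability <- function(tracks, behavior, window,
                                 min_coverage = 0.95,
                                 ci_method = "wilson") {
  tracks <- check_tracks(tracks)
  va <- valid_animals(tracks, window, min_coverage)
  if (!length(va$included)) stop("no valid animals in the window")
  b <- bouts_in_window(tracks, behavior, window, va$included)
  responders <- unique(b$animal_id)
  n <- length(va$included)
  r <- length(responders)
  structure(list(n_valid = n, n_responding = r, probability = r / n,
                 ci95 = proportion_ci(r, n, method = ci_method),
                 responders = responders, exclusions = va$exclusions),
            class = "behavior_summary")
}

#' Behavior duration in a window
#'
#' Per valid responding animal, the total bout time of the behavior
#' clipped to the window; summarized as mean and standard error across
#' animals.
#'
#' @inheritParams behavior_probability
#' @return list of class `behavior_summary`: `per_animal` (named
#'   durations, s), `duration_mean`, `duration_se` (NA and flagged when
#'   fewer than 2 responders).
#' @export
behavior_duration <- function(tracks, behavior, window,
                              min_coverage = 0.95) {
  tracks <- check_tracks(tracks)
  va <- valid_animals(tracks, window, min_coverage)
  b <- bouts_in_window(tracks, behavior, window, va$included)
  per <- tapply(b$clipped, b$animal_id, sum)
  per <- stats::setNames(as.numeric(per), names(per))
  n <- length(per)
  structure(list(per_animal = per, n_responding = n,
                 duration_mean = if (n) mean(per) else NA_real_,
                 duration_se = if (n >= 2) stats::sd(per) / sqrt(n)
                               else NA_real_,
                 se_defined = n >= 2, exclusions = va$exclusions),
            class = "behavior_summary")
}

#' Compare behavior summaries between two groups
#'
#' Probabilities are compared with a chi-square test for proportions on
#' the 2x2 responder table; durations with a double-sided Welch t test on
#' the per-animal durations.
#'
#' @param summary_a,summary_b outputs of [behavior_probability()] (for
#'   `what = "probability"`) or [behavior_duration()] (for
#'   `what = "duration"`).
#' @param what `"probability"` or `"duration"`.
#' @param continuity Yates correction for the chi-square test (default
#'   off).
#' @return a test result (see [chi_square_proportions()] / [t_test()]).
#' @export
compare_groups <- function(summary_a, summary_b,
                           what = c("probability", "duration"),
                           continuity = FALSE) {
  what <- match.arg(what)
  if (what == "probability") {
    tab <- rbind(c(summary_a$n_responding,
                   summary_a$n_valid - summary_a$n_responding),
                 c(summary_b$n_responding,
                   summary_b$n_valid - summary_b$n_responding))
    chi_square_proportions(tab, continuity = continuity)
  } else {
    t_test(summary_a$per_animal, summary_b$per_animal,
           alternative = "two_sided")
  }
}
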