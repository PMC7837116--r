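#' Construct a stimulus-locked calcium imaging trial
#'
#' A uniformly sampled fluorescence trace (mean ROI intensity per frame)
#' with one stimulus epoch. Scoring needs at least 3 s of samples before
#' stimulus onset (the recent baseline) and 4.5 s after offset (the peak
#' window).
#'
#' @param times sample times, s (uniform; e.g. 6.61 frames/s).
#' @param fluorescence raw trace, arbitrary units.
#' @param stim_onset,stim_offset stimulus epoch, s (`onset < offset`).
#' @param modality `"mechanosensory"` (band k = 1.5) or `"nociceptive"`
#'   (k = 0.5).
#' @param animal_id,trial_id identifiers.
#' @return list of class `calcium_trial`.
#' @export
calcium_trial <- function(times, fluorescence, stim_onset, stim_offset,
                          modality = c("mechanosensory", "nociceptive"),
                          animal_id = "a1", trial_id = "t1") {
  modality <- match.arg(modality)
  stopifnot(length(times) == length(fluorescence),
            stim_onset < stim_offset)
  structure(list(times = times, fluorescence = fluorescence,
                 stim_onset = stim_onset, stim_offset = stim_offset,
                 modality = modality, animal_id = animal_id,
                 trial_id = trial_id),
            class = "calcium_trial")
}

default_k <- function(modality) {
  switch(modality, mechanosensory = 1.5, nociceptive = 0.5)
}

#' Delta-F over F0 of a trial
#'
#' `(F_t - F0) / F0` with the baseline `F0` defined as the median of the
#' whole trace.
#'
#' @param trial a [calcium_trial()] (or a raw numeric trace).
#' @return numeric series of the same length.
#' @export
delta_f_over_f <- function(trial) {
  f <- if (inherits(trial, "calcium_trial")) trial$fluorescence else trial
  if (!length(f)) stop("empty fluorescence trace")
  f0 <- stats::median(f)
  if (f0 == 0) stop("median fluorescence is zero; delta F/F0 undefined")
  (f - f0) / f0
}

trial_windows <- function(trial, peak_window_s = 4.5, baseline_s = 3,
                          window_from = c("offset", "onset")) {
  window_from <- match.arg(window_from)
  t <- trial$times
  w0 <- if (window_from == "offset") trial$stim_offset else trial$stim_onset
  post <- t > w0 & t <= w0 + peak_window_s
  base <- t >= trial$stim_onset - baseline_s & t < trial$stim_onset
  if (!any(base))
    stop("no samples in the recent-baseline window [onset - ", baseline_s,
         ", onset)")
  if (!any(post))
    stop("no samples in the response window (", window_from, ", ",
         window_from, " + ", peak_window_s, "]")
  if (max(t) < w0 + peak_window_s)
    stop("trace ends before the response window is fully covered")
  list(post = post, base = base)
}

#' Peak response of a trial
#'
#' Maximum delta-F/F0 in the 4.5 s window immediately after stimulation
#' offset, minus the recent baseline (mean delta-F/F0 of the 3 s preceding
#' stimulation onset). Window endpoints are half-open -- `(offset,
#' offset + 4.5]` and `[onset - 3, onset)` -- so boundary frames are never
#' double counted.
#'
#' @param trial a [calcium_trial()].
#' @param peak_window_s response-window length, s (default 4.5).
#' @param baseline_s recent-baseline length, s (default 3).
#' @return list with `peak` (relative maximum), `recent_baseline`, `dff`.
#' @export
peak_response <- function(trial, peak_window_s = 4.5, baseline_s = 3) {
  dff <- delta_f_over_f(trial)
  w <- trial_windows(trial, peak_window_s, baseline_s)
  base <- mean(dff[w$base])
  list(peak = max(dff[w$post]) - base, recent_baseline = base, dff = dff)
}

#' Classify a trial as responding or failed
#'
#' A trial has no detectable response when the mean delta-F/F0 of the
#' 4.5 s following stimulation offset lies within +/- k standard
#' deviations of the recent baseline (k = 1.5 for mechanosensory, 0.5 for
#' nociceptive stimulation). Failed trials are discarded from downstream
#' per-animal averages. The SD is the sample SD of the per-frame
#' delta-F/F0 in the 3 s baseline window.
#'
#' @param trial a [calcium_trial()].
#' @param k SD multiplier; defaults by modality.
#' @param window_from `"offset"` (default) or `"onset"`, the epoch edge
#'   the response window follows.
#' @return list with `responded`, `window_mean`, `recent_baseline`,
#'   `baseline_sd`, `k`.
#' @export
classify_response <- function(trial, k = default_k(trial$modality),
                              window_from = "offset") {
  dff <- delta_f_over_f(trial)
  w <- trial_windows(trial, window_from = window_from)
  base <- mean(dff[w$base])
  base_sd <- stats::sd(dff[w$base])
  wmean <- mean(dff[w$post])
  dev <- abs(wmean - base)
  responded <- if (is.na(base_sd) || base_sd == 0) dev > 0
               else dev > k * base_sd
  list(responded = responded, window_mean = wmean,
       recent_baseline = base, baseline_sd = base_sd, k = k)
}

#' Per-animal mean peak response
#'
#' Scores every trial, discards non-responding trials, and averages the
#' responding-trial peaks by animal. Animals with no responding trial are
#' excluded and listed.
#'
#' @param trials list of [calcium_trial()]s.
#' @param k SD multiplier; defaults by each trial's modality.
#' @return list with `summary` (data.frame: `animal_id`, `n_trials`,
#'   `n_responding`, `mean_peak`) and `excluded_animals`.
#' @export
animal_summary <- function(trials, k = NULL) {
  rows <- lapply(trials, function(tr) {
    kk <- k %||% default_k(tr$modality)
    data.frame(animal_id = tr$animal_id,
               responded = classify_response(tr, k = kk)$responded,
               peak = peak_response(tr)$peak)
  })
  df <- do.call(rbind, rows)
  per <- do.call(rbind, lapply(split(df, df$animal_id), function(g) {
    data.frame(animal_id = g$animal_id[1], n_trials = nrow(g),
               n_responding = sum(g$responded),
               mean_peak = if (any(g$responded))
                 mean(g$peak[g$responded]) else NA_real_)
  }))
  rownames(per) <- NULL
  list(summary = per[per$n_responding > 0, ],
       excluded_animals = per$animal_id[per$n_responding == 0])
}

#' Compare per-animal peak responses between groups
#'
#' One-sided Wilcoxon rank-sum test of experimental versus control
#' per-animal mean peaks (alternative `"greater"`: experimental responses
#' larger).
#'
#' @param experimental,control numeric vectors of per-animal mean peaks.
#' @param alternative passed to [wilcoxon_rank_sum()].
#' @return a test result (see [wilcoxon_rank_sum()]).
#' @export
group_comparison <- function(experimental, control,
                             alternative = "greater") {
  wilcoxon_rank_sum(experimental, control, alternative = alternative)
}
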