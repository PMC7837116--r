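track_row <- function(animal, type, start, end, behavior = NA,
                      group = "g") {
  data.frame(animal_id = animal, group = group, interval_type = type,
             behavior = behavior, start_s = start, end_s = end)
}

w15 <- behavior_window(30, 15)

test_that("coverage and collision filters exclude exactly the right animals", {
  tracks <- rbind(
    track_row("full", "tracked", 0, 60),
    # tracked for 94% of the window -> excluded
    track_row("gappy", "tracked", 0, 30.9),
    track_row("gappy", "tracked", 31.8, 60),
    # collision barely touching the window -> excluded
    track_row("bumped", "tracked", 0, 60),
    track_row("bumped", "collision", 44.999, 45.001),
    # collision entirely outside the window -> included
    track_row("nearmiss", "tracked", 0, 60),
    track_row("nearmiss", "collision", 10, 12))
  va <- valid_animals(tracks, w15)
  expect_setequal(va$included, c("full", "nearmiss"))
  expect_setequal(va$exclusions$animal_id, c("gappy", "bumped"))
  expect_equal(va$exclusions$reason[va$exclusions$animal_id == "gappy"],
               "coverage")
  expect_equal(va$exclusions$reason[va$exclusions$animal_id == "bumped"],
               "collision")
})

test_that("behavior probability counts animals with an intersecting bout", {
  animals <- sprintf("a%02d", 1:10)
  tracks <- do.call(rbind, lapply(animals, function(a)
    track_row(a, "tracked", 0, 60)))
  bouts <- do.call(rbind, lapply(animals[1:5], function(a)
    track_row(a, "bout", 35, 37, behavior = "bend")))
  bp <- behavior_probability(rbind(tracks, bouts), "bend", w15)
  expect_equal(bp$probability, 0.5)
  expect_equal(bp$n_valid, 10)
  expect_equal(unname(bp$ci95),
               unname(proportion_ci(5, 10, method = "wilson")))

  # a bout straddling the window onset still counts
  straddle <- rbind(track_row("a1", "tracked", 0, 60),
                    track_row("a1", "bout", 28, 31, behavior = "bend"))
  expect_equal(behavior_probability(straddle, "bend", w15)$probability, 1)
  # a bout entirely before the onset does not
  outside <- rbind(track_row("a1", "tracked", 0, 60),
                   track_row("a1", "bout", 20, 25, behavior = "bend"))
  expect_equal(behavior_probability(outside, "bend", w15)$probability, 0)

  none <- track_row("a1", "tracked", 0, 10)
  expect_error(behavior_probability(none, "bend", w15), "no valid animals")
})

test_that("durations are clipped to the window and summarized per animal", {
  tracks <- rbind(
    track_row("a1", "tracked", 0, 60),
    track_row("a1", "bout", 35, 37, behavior = "bend"),
    track_row("a2", "tracked", 0, 60),
    track_row("a2", "bout", 43, 48, behavior = "bend"))  # clipped at 45
  bd <- behavior_duration(tracks, "bend", w15)
  expect_equal(unname(bd$per_animal[c("a1", "a2")]), c(2, 2))
  expect_equal(bd$duration_mean, 2)
  expect_true(bd$se_defined)

  solo <- behavior_duration(tracks[1:2, ], "bend", w15)
  expect_false(solo$se_defined)
  expect_true(is.na(solo$duration_se))
})

test_that("excluded animals never influence the summaries", {
  base <- rbind(track_row("a1", "tracked", 0, 60),
                track_row("a1", "bout", 32, 33, behavior = "bend"),
                track_row("a2", "tracked", 0, 60))
  with_junk <- rbind(base,
                     track_row("lowcov", "tracked", 0, 31),
                     track_row("lowcov", "bout", 30.2, 30.8,
                               behavior = "bend"))
  for (fn in list(behavior_probability, behavior_duration)) {
    a <- fn(base, "bend", w15)
    b <- fn(with_junk, "bend", w15)
    a$exclusions <- b$exclusions <- NULL
    expect_equal(a, b)
  }
})

test_that("group comparisons delegate to the chi-square and t tests", {
  mk <- function(r, n) structure(list(n_valid = n, n_responding = r),
                                 class = "behavior_summary")
  same <- compare_groups(mk(30, 100), mk(30, 100))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  res <- compare_groups(mk(50, 100), mk(70, 100))
  tab <- rbind(c(50, 50), c(70, 30))
  expect_equal(res$statistic, oracle_chisq_stat(tab))
  expect_equal(res$p_value, pchisq(oracle_chisq_stat(tab), 1,
                                   lower.tail = FALSE))

  dur <- function(x) structure(list(per_animal = x),
                               class = "behavior_summary")
  t0 <- compare_groups(dur(c(1, 2, 3)), dur(c(3, 2, 1)), what = "duration")
  expect_equal(t0$statistic, 0)
})

test_that("simulated cohorts honor design probabilities and filters", {
  sim <- simulate_behavior(behavior_sim_config(
    groups = data.frame(group = "g", n_animals = 40, p_response = 1),
    gap_rate = 0, collision_rate = 0), seed = 8)
  bp <- behavior_probability(sim$tracks, "bend", behavior_window(30, 15))
  expect_equal(bp$probability, 1)

  # animals designed with a gap or collision are exactly the excluded ones
  sim2 <- simulate_behavior(behavior_sim_config(
    groups = data.frame(group = "g", n_animals = 60, p_response = 0.5),
    gap_rate = 0.3, collision_rate = 0.2), seed = 9)
  va <- valid_animals(sim2$tracks, behavior_window(30, 15))
  truth <- sim2$ground_truth$animals
  expect_setequal(va$exclusions$animal_id,
                  truth$animal_id[truth$has_gap | truth$has_collision])

  expect_identical(simulate_behavior(seed = 4), simulate_behavior(seed = 4))
})
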