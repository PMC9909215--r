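test_that("caregiver intervals exactly tile the session, for many seeds", {
  p <- default_config("13mo")
  for (seed in 1:8) {
    set.seed(seed)
    dur <- sample(300000:1200000, 1)
    cg <- simulate_caregiver_stream(dur, p)
    expect_equal(cg$onset_ms[1], 0L)
    expect_equal(cg$offset_ms[nrow(cg)], as.integer(dur))
    # each interval starts where the previous one ended: no gaps, no overlaps
    expect_equal(cg$onset_ms[-1], cg$offset_ms[-nrow(cg)])
    expect_true(all(cg$offset_ms > cg$onset_ms))
    expect_true(all(cg$category %in% caregiver_categories()))
  }
})

test_that("a single-category configuration yields one interval covering the session", {
  p <- default_config("13mo")
  p$transition_weights[] <- 0
  p$transition_weights["looking"] <- 1
  set.seed(1)
  cg <- simulate_caregiver_stream(60000, p)
  expect_equal(nrow(cg), 1)
  expect_equal(cg$category, "looking")
  expect_equal(c(cg$onset_ms, cg$offset_ms), c(0L, 60000L))

  p$transition_weights[] <- 0
  expect_error(simulate_caregiver_stream(60000, p), "degenerate")
})

test_that("the caregiver stream is reproducible under seed and varies across seeds", {
  p <- default_config("17mo")
  set.seed(99); a <- simulate_caregiver_stream(600000, p)
  set.seed(99); b <- simulate_caregiver_stream(600000, p)
  set.seed(100); c <- simulate_caregiver_stream(600000, p)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("per-session mean category counts match the calibration table", {
  # spot-checked against the per-meal frequency calibration for both periods;
  # 300 replicate sessions at the period's mean duration
  targets <- list(
    "13mo" = c(looking = 59.11, scooping = 55.50, feeding = 40.61),
    "17mo" = c(looking = 45.78, objects = 42.22, other_person = 13.44)
  )
  for (period in names(targets)) {
    p <- default_config(period)
    set.seed(2024)
    counts <- replicate(300, {
      cg <- simulate_caregiver_stream(p$mean_duration_s * 1000, p)
      tab <- table(factor(cg$category, levels = caregiver_categories()))
      as.integer(tab[names(targets[[period]])])
    })
    got <- rowMeans(counts)
    expect_equal(unname(got), unname(targets[[period]]),
                 tolerance = 0.15, ignore_attr = TRUE)
  }
})

test_that("pointing count has the analytic Poisson mean under homogeneous multipliers", {
  # all multipliers 1, base rate 1/min, fixed 18-minute sessions:
  # count ~ Poisson(18), so the mean over replicates must be close to 18
  p <- default_config("13mo")
  p$point_rate_multiplier[] <- 1
  p$base_point_rate_per_min <- 1
  p$look_point_coupling_prob <- 0
  p$base_look_rate_per_min <- 0
  set.seed(7)
  n_pts <- replicate(400, {
    cg <- simulate_caregiver_stream(18 * 60000, p)
    td <- simulate_toddler_events(cg, 18 * 60000, p)
    sum(td$category == "pointing")
  })
  expect_equal(mean(n_pts), 18, tolerance = 0.05)
})

test_that("default toddler rates reproduce the calibration pointing and look counts", {
  set.seed(41)
  for (period in period_levels()) {
    p <- default_config(period)
    counts <- replicate(250, {
      dur <- p$mean_duration_s * 1000
      td <- simulate_toddler_events(simulate_caregiver_stream(dur, p), dur, p)
      c(sum(td$category == "pointing"), sum(td$category == "face_look"))
    })
    target <- if (period == "13mo") c(13.28, 15.33) else c(18.89, 23.94)
    expect_equal(rowMeans(counts), target, tolerance = 0.25,
                 ignore_attr = TRUE)
  }
})

test_that("zero multipliers suppress pointing; forced coupling pairs every point with a look", {
  p <- default_config("13mo")
  p$point_rate_multiplier[] <- 0
  set.seed(3)
  cg <- simulate_caregiver_stream(600000, p)
  td <- simulate_toddler_events(cg, 600000, p)
  expect_equal(sum(td$category == "pointing"), 0)

  p2 <- default_config("13mo")
  p2$look_point_coupling_prob <- 1
  p2$base_look_rate_per_min <- 0
  set.seed(4)
  cg2 <- simulate_caregiver_stream(600000, p2)
  td2 <- simulate_toddler_events(cg2, 600000, p2)
  s <- dyad_session("s", "t", "c", "13mo", 600000, td2)
  cp <- coupled_pointing_proportion(s)
  expect_gt(cp$n_points, 0)
  expect_equal(cp$proportion, 1)
})

test_that("the default study design gives 36 sessions and scales with the design", {
  study <- simulate_study(simulation_config(seed = 5))
  expect_length(study$sessions, 36)
  expect_equal(sort(unique(vapply(study$sessions, `[[`, "", "period"))),
               period_levels())
  durations <- vapply(study$sessions, `[[`, 0L, "duration_ms")
  expect_true(all(durations >= 300000)) # truncation floor: 5 minutes

  tiny <- simulate_study(simulation_config(n_toddlers = 1,
                                           sessions_per_period = 1, seed = 5))
  expect_length(tiny$sessions, 2)
})

test_that("identical config and seed give byte-identical coding CSVs", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_coding_csv(simulate_study(small_sim_config(77))$sessions, f1)
  write_coding_csv(simulate_study(small_sim_config(77))$sessions, f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_coding_csv(simulate_study(small_sim_config(78))$sessions, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("per-session seeds do not shift when the number of toddlers changes", {
  big <- simulate_study(simulation_config(n_toddlers = 4,
                                          sessions_per_period = 2, seed = 9))
  small <- simulate_study(simulation_config(n_toddlers = 2,
                                            sessions_per_period = 2, seed = 9))
  ids <- vapply(small$sessions, `[[`, "", "session_id")
  for (i in seq_along(small$sessions)) {
    j <- match(ids[i], vapply(big$sessions, `[[`, "", "session_id"))
    expect_equal(small$sessions[[i]], big$sessions[[j]])
  }
})

test_that("raising a category's pointing multiplier raises its mean z monotonically", {
  grid <- c(0.25, 0.5, 1, 2, 4)
  reps <- 40
  mean_z <- vapply(seq_along(grid), function(g) {
    p <- default_config("13mo")
    p$point_rate_multiplier[["looking"]] <- grid[g]
    z <- vapply(seq_len(reps), function(r) {
      set.seed(6000 + 100 * g + r)
      dur <- 1146000
      cg <- simulate_caregiver_stream(dur, p)
      td <- simulate_toddler_events(cg, dur, p)
      s <- dyad_session("s", "t", "c", "13mo", dur, rbind(cg, td))
      ztab <- session_zscores(s)
      ztab$z[ztab$category == "looking"]
    }, 0)
    mean(z, na.rm = TRUE)
  }, 0)
  expect_equal(cor(mean_z, grid, method = "spearman"), 1)
})
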