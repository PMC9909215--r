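test_that("discretization assigns bins by midpoint coverage", {
  s <- tiled_session(10000)
  tl <- discretize(s, bin_width_ms = 100)
  expect_equal(tl$n_bins, 100)
  expect_true(all(tl$caregiver_label == "feeding"))
  expect_false(any(tl$pointing_active))

  # pointing [1000, 1500) with 100 ms bins covers midpoints 1050..1450,
  # i.e. bins 11..15 in 1-based indexing, and nothing else
  s2 <- make_session(10000,
                     cg = data.frame(category = "feeding", onset = 0,
                                     offset = 10000),
                     td = data.frame(category = "pointing", onset = 1000,
                                     offset = 1500))
  tl2 <- discretize(s2, bin_width_ms = 100)
  expect_equal(which(tl2$pointing_active), 11:15)

  empty <- dyad_session("s", "t", "c", "13mo", 1000)
  tl3 <- discretize(empty, bin_width_ms = 100)
  expect_true(all(tl3$caregiver_label == "none"))
  expect_false(any(tl3$pointing_active))

  expect_error(discretize(s, bin_width_ms = 0), "bin_width")
})

test_that("n_bins covers a duration that is not a multiple of the bin width", {
  s <- tiled_session(10050)
  tl <- discretize(s, bin_width_ms = 100)
  expect_equal(tl$n_bins, ceiling(10050 / 100))
})

test_that("overlapping caregiver codes resolve latest-onset-wins, regardless of row order", {
  cg <- data.frame(category = c("feeding", "looking"),
                   onset = c(0, 5000), offset = c(8000, 10000))
  s1 <- make_session(10000, cg = cg)
  s2 <- make_session(10000, cg = cg[2:1, ])
  tl1 <- discretize(s1, 100)
  tl2 <- discretize(s2, 100)
  expect_identical(tl1, tl2)
  # looking started later, so it owns the overlap [5000, 8000)
  expect_equal(tl1$caregiver_label[60], "looking")
  expect_equal(tl1$caregiver_label[40], "feeding")
})

test_that("contingency tables count bins and use e = p_c * f_r", {
  tab <- contingency_counts(100, 40, 10, 8)
  expect_equal(tab$e_rc, 4)
  expect_equal(tab$p_r, 0.4)
  expect_equal(tab$p_c, 0.1)
  # cells reconstruct and conserve N
  cells <- c(tab$o_rc, tab$f_r - tab$o_rc, tab$f_c - tab$o_rc,
             tab$n - tab$f_r - tab$f_c + tab$o_rc)
  expect_true(all(cells >= 0))
  expect_equal(sum(cells), tab$n)

  expect_error(contingency_counts(100, 40, 10, 45), "inconsistent")

  s <- make_session(10000,
                    cg = data.frame(category = "feeding", onset = 0,
                                    offset = 10000),
                    td = data.frame(category = "pointing", onset = 1000,
                                    offset = 1500))
  tl <- discretize(s, 100)
  tab2 <- contingency_table(tl, "feeding")
  expect_equal(tab2$f_r, 100) # category covers all bins
  expect_equal(tab2$o_rc, tab2$f_c)
  tab3 <- contingency_table(tl, "looking")
  expect_equal(c(tab3$f_r, tab3$o_rc, tab3$e_rc), c(0, 0, 0))
  expect_error(contingency_table(tl, "gestures"), "analysis category")
})

test_that("the adjusted residual matches hand computation and the chi-square oracle", {
  res <- adjusted_residual(contingency_counts(100, 40, 10, 8))
  expect_equal(res$z, (8 - 4) / sqrt(4 * 0.6 * 0.9), tolerance = 1e-12)
  expect_equal(res$reason_missing, "none")

  # observed equals expected -> exactly zero
  expect_equal(adjusted_residual(contingency_counts(100, 40, 10, 4))$z, 0)

  # degenerate margins are missing, with the margin named
  expect_equal(adjusted_residual(contingency_counts(100, 40, 0, 0))$reason_missing,
               "degenerate_column")
  expect_true(is.na(adjusted_residual(contingency_counts(100, 40, 0, 0))$z))
  expect_equal(adjusted_residual(contingency_counts(100, 0, 10, 0))$reason_missing,
               "degenerate_row")
  expect_equal(adjusted_residual(contingency_counts(100, 100, 10, 10))$reason_missing,
               "degenerate_row")
})

test_that("z agrees with the full 2x2 chi-square standardized residual on random tables", {
  set.seed(314)
  for (i in 1:300) {
    n <- sample(50:2000, 1)
    f_r <- sample(1:(n - 1), 1)
    f_c <- sample(1:(n - 1), 1)
    o_range <- max(0, f_r + f_c - n):min(f_r, f_c)
    o <- if (length(o_range) == 1) o_range else sample(o_range, 1)
    z <- adjusted_residual(contingency_counts(n, f_r, f_c, o))$z
    m <- matrix(c(o, f_r - o, f_c - o, n - f_r - f_c + o), 2)
    oracle <- suppressWarnings(stats::chisq.test(m, correct = FALSE))$stdres[1, 1]
    expect_equal(z, unname(oracle), tolerance = 1e-9)
  }
})

test_that("z is standard normal under an i.i.d. no-association null", {
  set.seed(271)
  tabs <- simulate_null_tables(2000, n_units = 2000, p_row = 0.3, p_col = 0.1)
  z <- adjusted_residual_z(tabs$n, tabs$f_r, tabs$f_c, tabs$o_rc)
  expect_lt(abs(mean(z)), 0.07) # 3 standard errors at 2,000 tables
  expect_gt(var(z), 0.9)
  expect_lt(var(z), 1.1)
})

test_that("z is strictly increasing in the joint count at fixed margins", {
  n <- 500; f_r <- 120; f_c <- 60
  o <- max(0, f_r + f_c - n):min(f_r, f_c)
  z <- adjusted_residual_z(n, f_r, f_c, o)
  expect_true(all(diff(z) > 0))
})

test_that("session z tables cover exactly the analysis categories and propagate missingness", {
  study <- simulate_study(small_sim_config(21))
  ztab <- session_zscores(study$sessions[[1]])
  expect_equal(ztab$category, analysis_categories())
  expect_true(all(is.finite(ztab$z) | ztab$reason_missing != "none"))

  # caregiver never points in this meal -> its z is missing, not zero
  s <- make_session(60000,
                    cg = data.frame(category = c("feeding", "looking"),
                                    onset = c(0, 30000), offset = c(30000, 60000)),
                    td = data.frame(category = "pointing", onset = 10000,
                                    offset = 11000))
  z <- session_zscores(s)
  expect_equal(z$reason_missing[z$category == "pointing_cg"], "degenerate_row")
  expect_true(is.na(z$z[z$category == "pointing_cg"]))
  expect_false(anyNA(z$z[z$category %in% c("feeding", "looking")]))

  # no pointing at all -> every category is degenerate_column
  s2 <- tiled_session(60000)
  z2 <- session_zscores(s2)
  expect_true(all(z2$reason_missing == "degenerate_column"))
})

test_that("a raised multiplier shows up as positive mean z across replicate sessions", {
  p <- default_config("13mo")
  p$point_rate_multiplier[["looking"]] <- 2
  set.seed(88)
  z <- replicate(60, {
    dur <- 1146000
    cg <- simulate_caregiver_stream(dur, p)
    td <- simulate_toddler_events(cg, dur, p)
    s <- dyad_session("s", "t", "c", "13mo", dur, rbind(cg, td))
    zt <- session_zscores(s)
    zt$z[zt$category == "looking"]
  })
  z <- z[!is.na(z)]
  # sign test: under no association P(z > 0) = 1/2
  expect_lt(binom.test(sum(z > 0), length(z), alternative = "greater")$p.value,
            0.001)
})

test_that("onset counting mode marks only the bins containing a pointing onset", {
  s <- make_session(10000,
                    cg = data.frame(category = "feeding", onset = 0,
                                    offset = 10000),
                    td = data.frame(category = "pointing", onset = 1000,
                                    offset = 1500))
  tl <- discretize(s, 100, pointing_mode = "onset")
  expect_equal(which(tl$pointing_active), 11)
})
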