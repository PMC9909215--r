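# Calibration surface: per-session mean counts of each caregiver behavior
# category and of toddler pointing / face-looks, by developmental period,
# together with session duration moments (seconds).
.calibration <- list(
  "13mo" = list(
    category_counts = c(
      feeding = 40.61, scooping = 55.50, objects = 53.78, touching = 29.61,
      looking = 59.11, pointing_cg = 5.61, other_person = 9.94,
      gestures = 3.78, self = 2.50, no_data = 0.06
    ),
    mean_duration_s = 1146, sd_duration_s = 231,
    point_count = 13.28, look_count = 15.33,
    coupling_prob = 0.3, age_months = 12.96, age_sd = 0.60
  ),
  "17mo" = list(
    category_counts = c(
      feeding = 27.06, scooping = 49.06, objects = 42.22, touching = 24.00,
      looking = 45.78, pointing_cg = 7.78, other_person = 13.44,
      gestures = 3.11, self = 3.00, no_data = 0.94
    ),
    mean_duration_s = 1022, sd_duration_s = 233,
    point_count = 18.89, look_count = 23.94,
    coupling_prob = 0.5, age_months = 17.28, age_sd = 0.48
  )
)

# Relative dwell lengths by category (unitless); the absolute scale is set so
# that the expected number of caregiver intervals per session matches the
# calibration counts. Watching-over episodes tend to be long, single
# caregiver points and scoops short.
.relative_dwell <- c(
  feeding = 1, scooping = 0.7, objects = 1, touching = 1, looking = 1.5,
  pointing_cg = 0.5, other_person = 1, gestures = 0.5, self = 0.5, no_data = 1
)

# Solve sampling weights w so that the stationary visit distribution of the
# no-self-transition chain (pi_i proportional to w_i * (1 - w_i)) matches a
# target visit distribution. Fixed-point iteration; exact for the target
# sizes used here.
solve_transition_weights <- function(target_pi, iter = 200) {
  target_pi <- target_pi / sum(target_pi)
  w <- target_pi
  for (it in seq_len(iter)) {
    w_new <- target_pi / pmax(1 - w, 1e-12)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < 1e-14) { w <- w_new; break }
    w <- w_new
  }
  w
}

#' Default simulation parameters for one developmental period
#'
#' Returns the generative parameters of the mealtime simulator calibrated so
#' that, at either period (13 or 17 months), the expected per-session counts
#' of the ten caregiver behavior categories, of toddler pointing, and of
#' toddler face-looks match the package's calibration table of per-meal
#' means, and session durations match the observed mean and SD. Pointing
#' rate multipliers default to 1 for every category (no built-in association
#' between caregiver activity and pointing); raise or lower individual
#' multipliers to inject an association.
#'
#' @param period `"13mo"` or `"17mo"`.
#' @return a list of class `period_params` with elements:
#'   `period`; `mean_duration_s`, `sd_duration_s`, `min_duration_s`
#'   (truncation floor, 300 s); `transition_weights` and `dwell_mean_s`
#'   (named over the ten caregiver categories); `base_point_rate_per_min`
#'   and `point_rate_multiplier` (named, all 1); `point_duration_ms`;
#'   `base_look_rate_per_min`; `look_point_coupling_prob`;
#'   `look_duration_ms`; `coupling_window_s`; `age_months`, `age_sd`.
#' @examples
#' p <- default_config("13mo")
#' round(p$transition_weights, 3)
#' @export
default_config <- function(period) {
  period <- match.arg(period, period_levels())
  cal <- .calibration[[period]]
  counts <- cal$category_counts
  pi_target <- counts / sum(counts)
  w <- solve_transition_weights(pi_target)
  # scale relative dwell so mean cycle length = duration / expected visits
  cycle_s <- cal$mean_duration_s / sum(counts)
  rel <- .relative_dwell[names(counts)]
  dwell <- rel * cycle_s / sum(pi_target * rel)
  mult <- stats::setNames(rep(1, length(counts)), names(counts))
  duration_min <- cal$mean_duration_s / 60
  base_point <- cal$point_count / duration_min
  base_look <- (cal$look_count - cal$coupling_prob * cal$point_count) /
    duration_min
  structure(
    list(
      period = period,
      mean_duration_s = cal$mean_duration_s,
      sd_duration_s = cal$sd_duration_s,
      min_duration_s = 300,
      transition_weights = w,
      dwell_mean_s = dwell,
      base_point_rate_per_min = base_point,
      point_rate_multiplier = mult,
      point_duration_ms = 1000L,
      base_look_rate_per_min = base_look,
      look_point_coupling_prob = cal$coupling_prob,
      look_duration_ms = 1000L,
      coupling_window_s = 2,
      age_months = cal$age_months,
      age_sd = cal$age_sd
    ),
    class = "period_params"
  )
}

#' Full study-level simulation configuration
#'
#' Bundles the study design (number of toddlers, periods, sessions per
#' period, master seed) with one [default_config()] parameter block per
#' period. The default design mirrors a longitudinal two-period observation
#' of six dyads with three mealtimes per period (36 sessions). Period
#' effects are expressed by editing the corresponding period block, e.g.
#' lowering `params[["17mo"]]$point_rate_multiplier[["touching"]]`.
#'
#' @param n_toddlers number of toddlers (dyads).
#' @param sessions_per_period mealtimes observed per toddler per period.
#' @param periods character vector of period labels.
#' @param params named list of `period_params`, one per period.
#' @param seed master integer seed; every session derives its own seed from
#'   it by a fixed counter scheme, so per-session streams are reproducible
#'   and do not shift when `n_toddlers` changes.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(n_toddlers = 6, sessions_per_period = 3,
                              periods = period_levels(),
                              params = NULL, seed = 1L) {
  if (is.null(params)) {
    params <- stats::setNames(lapply(periods, default_config), periods)
  }
  stopifnot(all(periods %in% names(params)), n_toddlers >= 1,
            sessions_per_period >= 1)
  structure(
    list(n_toddlers = as.integer(n_toddlers),
         sessions_per_period = as.integer(sessions_per_period),
         periods = periods, params = params, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# internal: per-session seed, independent of n_toddlers (counter scheme).
# Each master seed owns a disjoint 65,536-wide block (exact 32-bit
# arithmetic), so distinct master seeds never share session streams for
# designs up to ~20 toddlers.
derive_session_seed <- function(seed, toddler, period_idx, meal) {
  as.integer((abs(seed) %% 32767L) * 65536L +
               toddler * 3001L + period_idx * 701L + meal)
}

# internal: run code with the global RNG state restored afterwards
with_restored_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  force(code)
}

#' Simulate the caregiver's activity stream for one session
#'
#' Caregiver behavior is generated as a semi-Markov chain over the ten
#' coding categories: successive categories are drawn from
#' `transition_weights` with no immediate self-transition, and each visit
#' dwells for an exponential time with the category's mean, the final dwell
#' being truncated at the session end. The resulting intervals exactly tile
#' `[0, duration_ms]` with no gaps or overlaps. Uses the current RNG stream.
#'
#' @param duration_ms session length in ms.
#' @param params a `period_params` block (see [default_config()]).
#' @return event table (tibble) of caregiver intervals.
#' @export
simulate_caregiver_stream <- function(duration_ms, params) {
  stopifnot(duration_ms > 0)
  w <- params$transition_weights
  mu <- params$dwell_mean_s * 1000 # ms
  if (any(w < 0) || sum(w) <= 0) {
    stop("degenerate configuration: transition weights must be non-negative ",
         "with positive sum", call. = FALSE)
  }
  w <- w / sum(w)
  active <- which(w > 0)
  if (length(active) == 1L) {
    k <- active
    return(tibble::tibble(actor = "caregiver", category = names(w)[k],
                          onset_ms = 0L,
                          offset_ms = as.integer(round(duration_ms))))
  }
  pi_stat <- w * (1 - w); pi_stat <- pi_stat / sum(pi_stat)
  cw <- cumsum(w)
  state <- findInterval(stats::runif(1), cumsum(pi_stat)) + 1L
  states <- integer(0); dwells <- numeric(0); total <- 0
  while (total < duration_ms) {
    d <- stats::rexp(1, rate = 1 / mu[state])
    states <- c(states, state); dwells <- c(dwells, d)
    total <- total + d
    repeat {
      nxt <- findInterval(stats::runif(1), cw) + 1L
      if (nxt != state && w[nxt] > 0) break
    }
    state <- nxt
  }
  bounds <- round(pmin(cumsum(c(0, dwells)), duration_ms))
  bounds[length(bounds)] <- round(duration_ms)
  keep <- which(diff(bounds) > 0)
  tibble::tibble(
    actor = "caregiver",
    category = names(w)[states[keep]],
    onset_ms = as.integer(bounds[keep]),
    offset_ms = as.integer(bounds[keep + 1L])
  )
}

#' Simulate toddler pointing and face-look events for one session
#'
#' Toddler pointing is an inhomogeneous Poisson process whose instantaneous
#' rate is `base_point_rate_per_min` times the multiplier of the caregiver
#' category active at that moment; each pointing event lasts
#' `point_duration_ms`. Face-looks are a homogeneous baseline Poisson
#' process at `base_look_rate_per_min`, plus, with probability
#' `look_point_coupling_prob` per pointing event, one coupled look whose
#' onset is uniform within the +/- `coupling_window_s` window around the
#' pointing onset (clamped into the session, which keeps it inside the
#' window). All events are clipped to session bounds. Uses the current RNG
#' stream.
#'
#' @param caregiver_events event table tiling the session (see
#'   [simulate_caregiver_stream()]).
#' @inheritParams simulate_caregiver_stream
#' @return event table (tibble) of toddler `pointing` and `face_look`
#'   intervals.
#' @export
simulate_toddler_events <- function(caregiver_events, duration_ms, params) {
  stopifnot(duration_ms > 0)
  mult <- params$point_rate_multiplier
  if (any(mult < 0)) stop("point rate multipliers must be >= 0", call. = FALSE)
  rate_ms <- params$base_point_rate_per_min / 60000

  point_on <- numeric(0)
  if (nrow(caregiver_events) > 0 && rate_ms > 0) {
    len <- caregiver_events$offset_ms - caregiver_events$onset_ms
    m <- mult[caregiver_events$category]
    m[is.na(m)] <- 1 # categories without an explicit multiplier are neutral
    lam <- rate_ms * len * m
    k <- stats::rpois(length(lam), lam)
    if (sum(k) > 0) {
      idx <- rep.int(seq_along(k), k)
      point_on <- caregiver_events$onset_ms[idx] +
        stats::runif(sum(k)) * len[idx]
    }
  }
  point_on <- sort(point_on)

  look_on <- numeric(0)
  if (params$base_look_rate_per_min > 0) {
    k0 <- stats::rpois(1, params$base_look_rate_per_min / 60000 * duration_ms)
    look_on <- stats::runif(k0) * duration_ms
  }
  if (length(point_on) > 0 && params$look_point_coupling_prob > 0) {
    win <- params$coupling_window_s * 1000
    coupled <- stats::runif(length(point_on)) < params$look_point_coupling_prob
    if (any(coupled)) {
      t0 <- point_on[coupled]
      lo <- stats::runif(sum(coupled), t0 - win, t0 + win)
      look_on <- c(look_on, pmin(pmax(lo, 0), duration_ms))
    }
  }
  look_on <- sort(look_on)

  ev <- rbind(
    if (length(point_on) > 0) data.frame(
      actor = "toddler", category = "pointing",
      onset_ms = round(point_on),
      offset_ms = round(pmin(point_on + params$point_duration_ms,
                             duration_ms))
    ),
    if (length(look_on) > 0) data.frame(
      actor = "toddler", category = "face_look",
      onset_ms = round(look_on),
      offset_ms = round(pmin(look_on + params$look_duration_ms, duration_ms))
    )
  )
  if (is.null(ev)) return(empty_events())
  as_event_tibble(ev)
}

# internal: truncated-normal session duration (floor at min_duration_s)
draw_duration_ms <- function(params) {
  repeat {
    d <- stats::rnorm(1, params$mean_duration_s, params$sd_duration_s)
    if (d >= params$min_duration_s) return(round(d * 1000))
  }
}

# internal: simulate one complete session
simulate_session <- function(toddler, period_idx, meal, config) {
  period <- config$periods[period_idx]
  params <- config$params[[period]]
  set.seed(derive_session_seed(config$seed, toddler, period_idx, meal))
  duration_ms <- draw_duration_ms(params)
  cg <- simulate_caregiver_stream(duration_ms, params)
  td <- simulate_toddler_events(cg, duration_ms, params)
  dyad_session(
    session_id = sprintf("T%02d_%s_m%d", toddler, period, meal),
    toddler_id = sprintf("T%02d", toddler),
    caregiver_id = sprintf("C%d", (toddler - 1) %/% 3 + 1),
    period = period,
    duration_ms = duration_ms,
    events = rbind(cg, td),
    age_months = round(stats::rnorm(1, params$age_months, params$age_sd), 2)
  )
}

#' Simulate a complete longitudinal study
#'
#' Generates `n_toddlers * length(periods) * sessions_per_period` mealtime
#' sessions (36 under the default design), with session durations drawn from
#' each period's truncated normal and behavior streams from
#' [simulate_caregiver_stream()] and [simulate_toddler_events()]. Identical
#' config (including seed) gives identical output; the global RNG state is
#' left untouched.
#'
#' @param config a [simulation_config()].
#' @return a list of class `simulated_study` with elements `sessions` (list
#'   of [dyad_session()]) and `config` (the generative truth, echoed for
#'   parameter-recovery tests).
#' @examples
#' study <- simulate_study(simulation_config(n_toddlers = 1,
#'   sessions_per_period = 1, seed = 42))
#' length(study$sessions)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sessions <- with_restored_rng({
    design <- expand.grid(
      meal = seq_len(config$sessions_per_period),
      period_idx = seq_along(config$periods),
      toddler = seq_len(config$n_toddlers)
    )
    lapply(seq_len(nrow(design)), function(i) {
      simulate_session(design$toddler[i], design$period_idx[i],
                       design$meal[i], config)
    })
  })
  structure(list(sessions = sessions, config = config),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study> %d sessions (%d toddlers x %d periods x %d meals), seed %d\n",
              length(x$sessions), x$config$n_toddlers,
              length(x$config$periods), x$config$sessions_per_period,
              x$config$seed))
  invisible(x)
}

#' Simulate 2x2 contingency tables under the no-association null
#'
#' Generates replicate tables from `n_units` i.i.d. units in which row
#' presence (caregiver category active) has probability `p_row` and column
#' presence (toddler pointing) probability `p_col`, independently. The
#' margins are therefore Binomial and, given the margins, the joint count is
#' Hypergeometric — the exact conditional law of independent units, sampled
#' directly for speed. Used to check the null calibration of the adjusted
#' residual (approximately N(0, 1) under independence).
#'
#' @param n_tables number of replicate tables.
#' @param n_units units (time bins) per table.
#' @param p_row,p_col presence probabilities.
#' @return tibble with columns `n`, `f_r`, `f_c`, `o_rc`, one row per table.
#' @export
simulate_null_tables <- function(n_tables, n_units = 2000,
                                 p_row = 0.3, p_col = 0.1) {
  f_r <- stats::rbinom(n_tables, n_units, p_row)
  f_c <- stats::rbinom(n_tables, n_units, p_col)
  o <- stats::rhyper(n_tables, m = f_r, n = n_units - f_r, k = f_c)
  tibble::tibble(n = n_units, f_r = f_r, f_c = f_c, o_rc = o)
}
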