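# Small hand-built sessions used across test files.

# one caregiver interval per row of `cg`, one toddler interval per row of `td`
make_session <- function(duration_ms, cg = NULL, td = NULL,
                         session_id = "s1", toddler_id = "t1",
                         period = "13mo") {
  rows <- list()
  if (!is.null(cg)) {
    rows <- c(rows, list(data.frame(actor = "caregiver",
                                    category = cg$category,
                                    onset_ms = cg$onset, offset_ms = cg$offset)))
  }
  if (!is.null(td)) {
    rows <- c(rows, list(data.frame(actor = "toddler",
                                    category = td$category,
                                    onset_ms = td$onset, offset_ms = td$offset)))
  }
  ev <- if (length(rows)) do.call(rbind, rows) else pointseq::empty_events()
  dyad_session(session_id, toddler_id, "c1", period, duration_ms, ev)
}

# a session fully tiled by one caregiver category
tiled_session <- function(duration_ms = 10000, category = "feeding", ...) {
  make_session(duration_ms,
               cg = data.frame(category = category, onset = 0,
                               offset = duration_ms), ...)
}

# a small study config for fast end-to-end tests
small_sim_config <- function(seed, n_toddlers = 3, sessions_per_period = 2,
                             ...) {
  simulation_config(n_toddlers = n_toddlers,
                    sessions_per_period = sessions_per_period,
                    seed = seed, ...)
}

# apply pointing-rate multipliers to every period of a config
with_multipliers <- function(cfg, mult) {
  for (p in names(cfg$params)) {
    cfg$params[[p]]$point_rate_multiplier[names(mult)] <- mult
  }
  cfg
}
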