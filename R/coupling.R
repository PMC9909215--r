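#' Count coded event intervals
#'
#' Number of intervals (onsets) of a given actor and category in one
#' session. Abutting intervals are not merged: two codes `[0,1)` and
#' `[1,2)` count as two events, matching how onset frequencies are tallied
#' in interval codings.
#'
#' @param session a validated [dyad_session()].
#' @param actor `"caregiver"` or `"toddler"`.
#' @param category a legal category for that actor.
#' @return integer count.
#' @export
count_events <- function(session, actor, category) {
  stopifnot(inherits(session, "dyad_session"))
  check_category(actor, category)
  nrow(session_events(session, actor, category))
}

#' Per-session event frequencies
#'
#' Onset counts of toddler pointing, toddler face-looks, and each caregiver
#' category, for one session or a list of sessions — the per-meal
#' frequencies that descriptive tables and frequency models are built on.
#'
#' @param sessions a [dyad_session()] or list of them.
#' @return tibble with one row per session: identifiers, `duration_ms`,
#'   `pointing`, `face_look`, and one column per caregiver category.
#' @export
session_frequencies <- function(sessions) {
  if (inherits(sessions, "dyad_session")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    ev <- s$events
    cg <- table(factor(ev$category[ev$actor == "caregiver"],
                       levels = caregiver_categories()))
    out <- tibble::tibble(
      session_id = s$session_id, toddler_id = s$toddler_id,
      caregiver_id = s$caregiver_id, period = s$period,
      duration_ms = s$duration_ms,
      pointing = sum(ev$actor == "toddler" & ev$category == "pointing"),
      face_look = sum(ev$actor == "toddler" & ev$category == "face_look")
    )
    for (nm in names(cg)) out[[nm]] <- as.integer(cg[[nm]])
    out
  })
  do.call(rbind, rows)
}

#' Look-point temporal coupling within a window
#'
#' A pointing event with onset `t` is *coupled* iff at least one face-look
#' interval overlaps the window `[t - window_s, t + window_s]` (two seconds
#' before and after the point, by default). Overlap is closed at the
#' endpoints: a look ending exactly at `t - window_s` counts. Anchoring at
#' the pointing onset makes the proportion invariant to pointing duration;
#' `anchor = "interval"` instead extends the window around the whole
#' pointing interval, for sensitivity analysis.
#'
#' @param session a validated [dyad_session()].
#' @param window_s window half-width in seconds (> 0).
#' @param anchor `"onset"` (default) or `"interval"`.
#' @return list of class `coupling_result`: `session_id`, `n_points`,
#'   `n_coupled`, `proportion` (`NA` when the session has no pointing),
#'   `window_s`.
#' @export
coupled_pointing_proportion <- function(session, window_s = 2,
                                        anchor = c("onset", "interval")) {
  stopifnot(inherits(session, "dyad_session"), window_s > 0)
  anchor <- match.arg(anchor)
  pts <- session_events(session, "toddler", "pointing")
  looks <- session_events(session, "toddler", "face_look")
  w <- window_s * 1000
  n_points <- nrow(pts)
  n_coupled <- 0L
  if (n_points > 0 && nrow(looks) > 0) {
    lo <- if (anchor == "onset") pts$onset_ms - w else pts$onset_ms - w
    hi <- if (anchor == "onset") pts$onset_ms + w else pts$offset_ms + w
    for (i in seq_len(n_points)) {
      if (any(looks$offset_ms >= lo[i] & looks$onset_ms <= hi[i])) {
        n_coupled <- n_coupled + 1L
      }
    }
  }
  structure(
    list(session_id = session$session_id, n_points = n_points,
         n_coupled = n_coupled,
         proportion = if (n_points > 0) n_coupled / n_points else NA_real_,
         window_s = window_s),
    class = "coupling_result"
  )
}

#' @rdname coupled_pointing_proportion
#' @param sessions list of sessions.
#' @return `coupling_table()` returns a tibble, one row per session, with
#'   identifiers and the coupling fields.
#' @export
coupling_table <- function(sessions, window_s = 2,
                           anchor = c("onset", "interval")) {
  anchor <- match.arg(anchor)
  rows <- lapply(sessions, function(s) {
    cp <- coupled_pointing_proportion(s, window_s, anchor)
    tibble::tibble(
      session_id = s$session_id, toddler_id = s$toddler_id,
      period = s$period, n_points = cp$n_points, n_coupled = cp$n_coupled,
      proportion = cp$proportion, window_s = cp$window_s
    )
  })
  do.call(rbind, rows)
}

#' Correlation between pointing and face-look frequencies across sessions
#'
#' Pearson correlation, within one developmental period, between the
#' per-meal pointing count and the per-meal face-look count, with the
#' two-sided p-value from the t transform on `n - 2` degrees of freedom.
#'
#' @param freqs a [session_frequencies()] table.
#' @param period which period's sessions to use.
#' @return list of class `correlation_result`: `period`, `r`, `df`, `p`,
#'   `n`, and `reason_missing` (`"zero_variance"` when one variable is
#'   constant, in which case `r` and `p` are `NA`).
#' @export
pointing_look_correlation <- function(freqs, period) {
  f <- freqs[freqs$period == period, , drop = FALSE]
  n <- nrow(f)
  if (n < 3) stop("need at least 3 sessions in period ", period, call. = FALSE)
  if (stats::sd(f$pointing) == 0 || stats::sd(f$face_look) == 0) {
    return(structure(list(period = period, r = NA_real_, df = n - 2L,
                          p = NA_real_, n = n,
                          reason_missing = "zero_variance"),
                     class = "correlation_result"))
  }
  ct <- stats::cor.test(f$pointing, f$face_look, method = "pearson")
  structure(
    list(period = period, r = unname(ct$estimate),
         df = unname(ct$parameter), p = ct$p.value, n = n,
         reason_missing = "none"),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$reason_missing == "none") {
    cat(sprintf("<correlation_result> %s: r(%d) = %.3f, p = %.4f (n = %d)\n",
                x$period, x$df, x$r, x$p, x$n))
  } else {
    cat(sprintf("<correlation_result> %s: undefined (%s, n = %d)\n",
                x$period, x$reason_missing, x$n))
  }
  invisible(x)
}
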