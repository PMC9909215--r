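#' Construct a coded mealtime session
#'
#' A session is one continuous observation of a fixed caregiver-toddler dyad
#' (one lunchtime), carrying its identifiers, developmental period, duration,
#' and the list of coded behavior intervals. Event times are integer
#' milliseconds from session start; the 30 fps frame grid used during coding
#' is applied only at discretization, so storage is lossless.
#'
#' @param session_id,toddler_id,caregiver_id character labels.
#' @param period developmental period, one of [period_levels()].
#' @param duration_ms session length in integer milliseconds (> 0).
#' @param events a data frame with columns `actor` ("caregiver"/"toddler"),
#'   `category`, `onset_ms`, `offset_ms`. May have zero rows.
#' @param age_months toddler age in months at observation (optional).
#' @return an object of class `dyad_session`.
#' @examples
#' s <- dyad_session("s1", "t1", "c1", "13mo", 60000,
#'   events = data.frame(actor = "caregiver", category = "feeding",
#'                       onset_ms = 0, offset_ms = 60000))
#' validate_session(s)
#' @export
dyad_session <- function(session_id, toddler_id, caregiver_id, period,
                         duration_ms, events = empty_events(),
                         age_months = NA_real_) {
  period <- as.character(period)
  if (!period %in% period_levels()) {
    stop("unknown period label: ", period, call. = FALSE)
  }
  duration_ms <- as.integer(round(duration_ms))
  if (is.na(duration_ms) || duration_ms <= 0) {
    stop("duration_ms must be a positive integer", call. = FALSE)
  }
  events <- as_event_tibble(events)
  structure(
    list(
      session_id   = as.character(session_id),
      toddler_id   = as.character(toddler_id),
      caregiver_id = as.character(caregiver_id),
      period       = period,
      age_months   = as.numeric(age_months),
      duration_ms  = duration_ms,
      events       = events
    ),
    class = "dyad_session"
  )
}

#' @rdname dyad_session
#' @export
empty_events <- function() {
  tibble::tibble(
    actor = character(), category = character(),
    onset_ms = integer(), offset_ms = integer()
  )
}

# internal: coerce and order an event table
as_event_tibble <- function(events) {
  events <- tibble::as_tibble(events)
  required <- c("actor", "category", "onset_ms", "offset_ms")
  missing <- setdiff(required, names(events))
  if (length(missing) > 0) {
    stop("event table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  events <- events[required]
  events$actor <- as.character(events$actor)
  events$category <- as.character(events$category)
  events$onset_ms <- as.integer(round(events$onset_ms))
  events$offset_ms <- as.integer(round(events$offset_ms))
  if (nrow(events) > 0) {
    check_category(events$actor, events$category)
    bad <- which(events$offset_ms < events$onset_ms)
    if (length(bad) > 0) {
      stop("offset_ms < onset_ms at event row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    events <- events[order(events$onset_ms, events$offset_ms,
                           events$actor, events$category), ]
  }
  events
}

#' @export
print.dyad_session <- function(x, ...) {
  cat(sprintf(
    "<dyad_session> %s  toddler %s / caregiver %s  period %s  %.1f min, %d events\n",
    x$session_id, x$toddler_id, x$caregiver_id, x$period,
    x$duration_ms / 60000, nrow(x$events)
  ))
  invisible(x)
}

# internal: events of one actor (optionally one category)
session_events <- function(session, actor, category = NULL) {
  ev <- session$events
  ev <- ev[ev$actor == actor, , drop = FALSE]
  if (!is.null(category)) ev <- ev[ev$category == category, , drop = FALSE]
  ev
}

#' Validate a coded session
#'
#' Checks the structural contract of a session. Out-of-bounds events and
#' illegal labels are errors (the session is not analyzable); temporally
#' overlapping caregiver intervals and incomplete caregiver coverage are
#' warnings only, since caregiver coding is intended to be exclusive and
#' near-exhaustive but manual codings routinely have small gaps and overlaps.
#' Overlaps are resolved deterministically at discretization
#' (latest-onset-wins); coverage below 95\% of the session usually indicates
#' the caregiver left the camera frame without a `no_data` code.
#'
#' @param session a [dyad_session()].
#' @return a list of class `validation_report` with character vectors
#'   `errors` and `warnings`; the session is analyzable iff `errors` is empty.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "dyad_session"))
  errors <- character()
  warnings <- character()
  ev <- session$events

  if (nrow(ev) > 0) {
    oob <- which(ev$onset_ms < 0 | ev$offset_ms > session$duration_ms)
    for (i in oob) {
      errors <- c(errors, sprintf(
        "event %d (%s %s [%d, %d]) outside session bounds [0, %d]",
        i, ev$actor[i], ev$category[i], ev$onset_ms[i], ev$offset_ms[i],
        session$duration_ms
      ))
    }
    cg <- ev[ev$actor == "caregiver", , drop = FALSE]
    if (nrow(cg) > 1) {
      cg <- cg[order(cg$onset_ms), ]
      prev_end <- cummax(c(-1L, utils::head(cg$offset_ms, -1)))
      ovl <- which(cg$onset_ms < prev_end)
      for (i in ovl) {
        warnings <- c(warnings, sprintf(
          "caregiver intervals overlap near %d ms (%s vs preceding code)",
          cg$onset_ms[i], cg$category[i]
        ))
      }
    }
    if (nrow(cg) > 0) {
      covered <- sum(interval_union_length(cg$onset_ms, cg$offset_ms))
    } else {
      covered <- 0
    }
    if (covered < 0.95 * session$duration_ms) {
      warnings <- c(warnings, sprintf(
        "caregiver categories cover %.1f%% of the session (< 95%%)",
        100 * covered / session$duration_ms
      ))
    }
  } else {
    warnings <- c(warnings, "session has no events")
  }

  structure(list(errors = errors, warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d error(s), %d warning(s)\n",
              length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  error: ", e, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

# internal: total length of the union of intervals
interval_union_length <- function(onset, offset) {
  if (length(onset) == 0) return(0)
  o <- order(onset, offset)
  onset <- onset[o]; offset <- offset[o]
  total <- 0; cur_s <- onset[1]; cur_e <- offset[1]
  for (i in seq_along(onset)[-1]) {
    if (onset[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- onset[i]; cur_e <- offset[i]
    } else {
      cur_e <- max(cur_e, offset[i])
    }
  }
  total + (cur_e - cur_s)
}

# internal: assert a session validates without errors
assert_valid_session <- function(session) {
  rep <- validate_session(session)
  if (length(rep$errors) > 0) {
    stop("session ", session$session_id, " fails validation:\n  ",
         paste(rep$errors, collapse = "\n  "), call. = FALSE)
  }
  invisible(session)
}
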