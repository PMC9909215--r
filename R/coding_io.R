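#' Read and write the canonical coding CSV
#'
#' The interchange format is a long-format CSV, one coded behavior interval
#' per row, with mandatory header
#' `session_id, toddler_id, caregiver_id, period, age_months, duration_ms,
#' actor, category, onset_ms, offset_ms`. All times are integer milliseconds
#' from session start. A session with no events is carried by a single
#' metadata row whose `actor`, `category`, `onset_ms` and `offset_ms` fields
#' are empty, so that session duration and identity survive a round trip.
#'
#' `write_coding_csv()` and `read_coding_csv()` are exact inverses on valid
#' input (integer times are bit-exact).
#'
#' @param path file path of the CSV.
#' @param sessions a list of [dyad_session()] objects.
#' @return `read_coding_csv()` returns a list of `dyad_session` objects (one
#'   per distinct `session_id`, in order of first appearance);
#'   `write_coding_csv()` returns `path` invisibly.
#' @export
read_coding_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("session_id", "toddler_id", "caregiver_id", "period",
                "age_months", "duration_ms", "actor", "category",
                "onset_ms", "offset_ms")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("coding CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) return(list())

  bad_period <- !df$period %in% period_levels()
  if (any(bad_period)) {
    stop("unknown period label(s): ",
         paste(unique(df$period[bad_period]), collapse = ", "),
         " (row ", which(bad_period)[1] + 1L, ")", call. = FALSE)
  }

  is_meta <- df$actor == "" | is.na(df$actor)
  on <- suppressWarnings(as.integer(df$onset_ms))
  off <- suppressWarnings(as.integer(df$offset_ms))
  bad <- which(!is_meta & off < on)
  if (length(bad) > 0) {
    stop("offset_ms < onset_ms at file row ", bad[1] + 1L,
         " (session ", df$session_id[bad[1]], ")", call. = FALSE)
  }

  ids <- unique(df$session_id)
  lapply(ids, function(id) {
    rows <- df[df$session_id == id, , drop = FALSE]
    meta <- rows[1, ]
    ev_rows <- rows[!(rows$actor == "" | is.na(rows$actor)), , drop = FALSE]
    events <- if (nrow(ev_rows) > 0) {
      tibble::tibble(
        actor = ev_rows$actor,
        category = ev_rows$category,
        onset_ms = as.integer(ev_rows$onset_ms),
        offset_ms = as.integer(ev_rows$offset_ms)
      )
    } else {
      empty_events()
    }
    dyad_session(
      session_id = id,
      toddler_id = meta$toddler_id,
      caregiver_id = meta$caregiver_id,
      period = meta$period,
      duration_ms = as.integer(meta$duration_ms),
      events = events,
      age_months = suppressWarnings(as.numeric(meta$age_months))
    )
  })
}

#' @rdname read_coding_csv
#' @export
write_coding_csv <- function(sessions, path) {
  stopifnot(is.list(sessions))
  rows <- lapply(sessions, function(s) {
    stopifnot(inherits(s, "dyad_session"))
    ev <- s$events
    if (nrow(ev) == 0) {
      data.frame(
        session_id = s$session_id, toddler_id = s$toddler_id,
        caregiver_id = s$caregiver_id, period = s$period,
        age_months = s$age_months, duration_ms = s$duration_ms,
        actor = "", category = "", onset_ms = "", offset_ms = "",
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        session_id = s$session_id, toddler_id = s$toddler_id,
        caregiver_id = s$caregiver_id, period = s$period,
        age_months = s$age_months, duration_ms = s$duration_ms,
        actor = ev$actor, category = ev$category,
        onset_ms = as.character(ev$onset_ms),
        offset_ms = as.character(ev$offset_ms),
        stringsAsFactors = FALSE
      )
    }
  })
  out <- if (length(rows) > 0) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(
      session_id = character(), toddler_id = character(),
      caregiver_id = character(), period = character(),
      age_months = character(), duration_ms = character(),
      actor = character(), category = character(),
      onset_ms = character(), offset_ms = character()
    )
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}
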