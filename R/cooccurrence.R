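#' Discretize a session onto the coding frame grid
#'
#' Lays a grid of bins of width `bin_width_ms` over the session (bin `b`
#' covers `[b*w, (b+1)*w)`; `n_bins = ceiling(duration / w)`) and records,
#' per bin, the caregiver category active at the bin midpoint and whether
#' toddler pointing is active there. An interval `[onset, offset)` is active
#' in a bin iff it contains the bin midpoint. Where caregiver intervals
#' overlap, the interval with the latest onset wins (deterministic and
#' independent of file row order); overlaps should already have been flagged
#' by [validate_session()]. The default 33 ms bin approximates the 30 fps
#' frame grid of the original codings.
#'
#' @param session a validated [dyad_session()].
#' @param bin_width_ms bin width in ms (> 0).
#' @param pointing_mode `"frame"`: a bin is a pointing bin iff a pointing
#'   interval covers its midpoint; `"onset"`: iff a pointing onset falls in
#'   the bin. Frame mode is the default unit of co-occurrence analysis;
#'   onset mode is provided for sensitivity analysis.
#' @return a list of class `discretized_timeline` with `bin_width_ms`,
#'   `n_bins`, `caregiver_label` (character per bin, `"none"` where no
#'   caregiver code is active) and `pointing_active` (logical per bin).
#' @export
discretize <- function(session, bin_width_ms = 33,
                       pointing_mode = c("frame", "onset")) {
  stopifnot(inherits(session, "dyad_session"))
  pointing_mode <- match.arg(pointing_mode)
  if (bin_width_ms <= 0) stop("bin_width_ms must be > 0", call. = FALSE)
  w <- bin_width_ms
  n_bins <- as.integer(ceiling(session$duration_ms / w))

  label <- rep("none", n_bins)
  cg <- session_events(session, "caregiver")
  if (nrow(cg) > 0) {
    # latest onset wins: paint in onset order so later onsets overwrite
    cg <- cg[order(cg$onset_ms), , drop = FALSE]
    for (i in seq_len(nrow(cg))) {
      b <- bins_covering_midpoints(cg$onset_ms[i], cg$offset_ms[i], w, n_bins)
      if (length(b) > 0) label[b] <- cg$category[i]
    }
  }

  pointing <- rep(FALSE, n_bins)
  pt <- session_events(session, "toddler", "pointing")
  if (nrow(pt) > 0) {
    if (pointing_mode == "frame") {
      for (i in seq_len(nrow(pt))) {
        b <- bins_covering_midpoints(pt$onset_ms[i], pt$offset_ms[i], w, n_bins)
        pointing[b] <- TRUE
      }
    } else {
      b <- floor(pt$onset_ms / w) + 1L
      b <- b[b >= 1 & b <= n_bins]
      pointing[b] <- TRUE
    }
  }

  structure(
    list(bin_width_ms = w, n_bins = n_bins,
         caregiver_label = label, pointing_active = pointing,
         pointing_mode = pointing_mode),
    class = "discretized_timeline"
  )
}

# internal: 1-based bin indices whose midpoint m = (b - 0.5) * w satisfies
# onset <= m < offset
bins_covering_midpoints <- function(onset, offset, w, n_bins) {
  b_lo <- ceiling(onset / w + 0.5)
  b_hi <- ceiling(offset / w + 0.5) - 1
  b_lo <- max(1L, as.integer(b_lo))
  b_hi <- min(n_bins, as.integer(b_hi))
  if (b_hi < b_lo) integer(0) else seq.int(b_lo, b_hi)
}

#' Build the 2x2 co-occurrence contingency table for one category
#'
#' Over the `N` time bins of a discretized session, cross-classifies the
#' presence/absence of one caregiver behavior category (rows) against the
#' presence/absence of toddler pointing (columns). The expected joint
#' frequency is the overall pointing rate times the category's row
#' frequency, `e_rc = p_c * f_r`.
#'
#' @param timeline a [discretize()] result.
#' @param category one of [analysis_categories()].
#' @return object of class `cooccurrence_table`: list with `category`, `n`,
#'   `f_r`, `f_c`, `o_rc`, `p_r`, `p_c`, `e_rc`.
#' @export
contingency_table <- function(timeline, category) {
  stopifnot(inherits(timeline, "discretized_timeline"))
  if (!category %in% analysis_categories()) {
    stop("not an analysis category: ", category, call. = FALSE)
  }
  row <- timeline$caregiver_label == category
  col <- timeline$pointing_active
  contingency_counts(
    n = timeline$n_bins, f_r = sum(row), f_c = sum(col),
    o_rc = sum(row & col), category = category
  )
}

#' @rdname contingency_table
#' @param n,f_r,f_c,o_rc total units, row frequency, column frequency and
#'   observed joint frequency, for building a table directly from counts.
#' @export
contingency_counts <- function(n, f_r, f_c, o_rc, category = NA_character_) {
  cells <- c(o_rc, f_r - o_rc, f_c - o_rc, n - f_r - f_c + o_rc)
  if (any(cells < 0)) {
    stop("inconsistent contingency counts: cells ",
         paste(cells, collapse = ", "), call. = FALSE)
  }
  p_r <- f_r / n
  p_c <- f_c / n
  structure(
    list(category = category, n = n, f_r = f_r, f_c = f_c, o_rc = o_rc,
         p_r = p_r, p_c = p_c, e_rc = p_c * f_r),
    class = "cooccurrence_table"
  )
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat(sprintf("<cooccurrence_table> %s: N=%d f_r=%d f_c=%d o_rc=%d e_rc=%.3f\n",
              x$category, x$n, x$f_r, x$f_c, x$o_rc, x$e_rc))
  invisible(x)
}

#' Adjusted residual (z-score) of a 2x2 co-occurrence table
#'
#' The adjusted residual standardizes the difference between observed and
#' expected joint frequency,
#' `z = (o_rc - e_rc) / sqrt(e_rc * (1 - p_r) * (1 - p_c))`,
#' and is approximately standard normal when caregiver behavior and toddler
#' pointing are unassociated. Positive z: pointing co-occurs with the
#' category more than chance; negative: less. When a margin is degenerate
#' (the category or pointing occurs in no bin, or in every bin) the residual
#' is undefined and is reported as missing with a reason, not as zero.
#'
#' @param table a [contingency_table()] result.
#' @return object of class `adjusted_residual`: list with `category`, `z`
#'   (numeric or `NA`), and `reason_missing` (`"none"`, `"degenerate_row"`,
#'   or `"degenerate_column"`).
#' @examples
#' adjusted_residual(contingency_counts(100, 40, 10, 8))$z # about 2.72
#' @export
adjusted_residual <- function(table) {
  stopifnot(inherits(table, "cooccurrence_table"))
  reason <- "none"
  if (table$f_c == 0 || table$f_c == table$n) {
    reason <- "degenerate_column"
  } else if (table$f_r == 0 || table$f_r == table$n) {
    reason <- "degenerate_row"
  }
  z <- if (reason == "none") {
    adjusted_residual_z(table$n, table$f_r, table$f_c, table$o_rc)
  } else {
    NA_real_
  }
  structure(list(category = table$category, z = z, reason_missing = reason),
            class = "adjusted_residual")
}

#' @rdname adjusted_residual
#' @inheritParams contingency_counts
#' @details `adjusted_residual_z()` is the vectorized kernel over raw
#'   counts; margins must be non-degenerate.
#' @export
adjusted_residual_z <- function(n, f_r, f_c, o_rc) {
  p_r <- f_r / n
  p_c <- f_c / n
  e <- p_c * f_r
  (o_rc - e) / sqrt(e * (1 - p_r) * (1 - p_c))
}

#' Per-session adjusted residuals for all analysis categories
#'
#' Discretizes one session and returns one adjusted residual per analysis
#' category. Excluded caregiver categories (`gestures`, `self`, `no_data`)
#' keep their own bin labels — so they count toward `N` but never get a
#' z-score. Missing residuals (degenerate margins, e.g. the caregiver never
#' pointed in that meal) propagate as `NA` rather than zero, which shrinks
#' the degrees of freedom of downstream t-tests exactly as rare categories
#' should.
#'
#' @inheritParams discretize
#' @return tibble with one row per analysis category: `session_id`,
#'   `toddler_id`, `period`, `category`, `n`, `f_r`, `f_c`, `o_rc`, `e_rc`,
#'   `z`, `reason_missing`.
#' @export
session_zscores <- function(session, bin_width_ms = 33,
                            pointing_mode = c("frame", "onset")) {
  pointing_mode <- match.arg(pointing_mode)
  assert_valid_session(session)
  tl <- discretize(session, bin_width_ms, pointing_mode)
  cats <- analysis_categories()
  lab <- factor(tl$caregiver_label, levels = cats)
  n <- tl$n_bins
  f_r <- as.integer(table(lab))
  f_c <- sum(tl$pointing_active)
  o_rc <- as.integer(table(lab[tl$pointing_active]))
  e_rc <- (f_c / n) * f_r
  reason <- rep("none", length(cats))
  reason[f_r == 0 | f_r == n] <- "degenerate_row"
  reason[f_c == 0 | f_c == n] <- "degenerate_column"
  z <- rep(NA_real_, length(cats))
  ok <- reason == "none"
  z[ok] <- adjusted_residual_z(n, f_r[ok], f_c, o_rc[ok])
  tibble::tibble(
    session_id = session$session_id, toddler_id = session$toddler_id,
    period = session$period, category = cats,
    n = n, f_r = f_r, f_c = f_c, o_rc = o_rc, e_rc = e_rc,
    z = z, reason_missing = reason
  )
}

#' @rdname session_zscores
#' @param sessions list of validated sessions (a whole study).
#' @export
study_zscores <- function(sessions, bin_width_ms = 33,
                          pointing_mode = c("frame", "onset")) {
  pointing_mode <- match.arg(pointing_mode)
  do.call(rbind, lapply(sessions, session_zscores,
                        bin_width_ms = bin_width_ms,
                        pointing_mode = pointing_mode))
}
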