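#' Pipeline configuration
#'
#' Assembles (or reads from a YAML file) the configuration of a full
#' analysis run. Exactly one of `input` (path to a coding CSV) or
#' `simulation` (a list with `n_toddlers`, `sessions_per_period`, and
#' optional per-period parameter overrides) must be given.
#'
#' A `simulation` section may contain an `overrides` list, keyed by period
#' label, each entry a list of `period_params` fields to replace, with
#' `point_rate_multiplier` merged element-wise — e.g.
#' `overrides = list("17mo" = list(point_rate_multiplier = c(touching = 0.2)))`.
#'
#' @param input path to a coding CSV, or `NULL`.
#' @param simulation simulation section as above, or `NULL`.
#' @param bin_width_ms discretization bin width (ms).
#' @param window_s coupling window half-width (s).
#' @param mode pointing counting mode, `"frame"` or `"onset"`.
#' @param anchor coupling anchor, `"onset"` or `"interval"`.
#' @param alpha two-sided significance level.
#' @param out_dir directory for result tables.
#' @param seed master seed for simulated input.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            bin_width_ms = 33, window_s = 2,
                            mode = c("frame", "onset"),
                            anchor = c("onset", "interval"),
                            alpha = 0.05, out_dir = "pointseq_results",
                            seed = 1L) {
  mode <- match.arg(mode)
  anchor <- match.arg(anchor)
  if (is.null(input) == is.null(simulation)) {
    stop("exactly one of `input` and `simulation` must be given",
         call. = FALSE)
  }
  structure(
    list(input = input, simulation = simulation,
         bin_width_ms = bin_width_ms, window_s = window_s, mode = mode,
         anchor = anchor, alpha = alpha, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file with the fields above.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    y[intersect(names(y), c("input", "simulation", "bin_width_ms",
                            "window_s", "mode", "anchor", "alpha",
                            "out_dir", "seed"))]
  ))
}

# internal: build a sim_config from a pipeline `simulation` section
simulation_from_section <- function(sim, seed) {
  cfg <- simulation_config(
    n_toddlers = sim$n_toddlers %||% 6,
    sessions_per_period = sim$sessions_per_period %||% 3,
    seed = sim$seed %||% seed
  )
  for (period in names(sim$overrides %||% list())) {
    if (!period %in% names(cfg$params)) {
      stop("override for unknown period: ", period, call. = FALSE)
    }
    ov <- sim$overrides[[period]]
    for (field in names(ov)) {
      if (field == "point_rate_multiplier") {
        m <- unlist(ov[[field]])
        cfg$params[[period]]$point_rate_multiplier[names(m)] <- m
      } else {
        cfg$params[[period]][[field]] <- ov[[field]]
      }
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes simulate/load, validate, co-occurrence, coupling, and inference
#' in order, and writes every result table plus a run manifest to
#' `config$out_dir`. Identical config and seed give byte-identical output
#' files. Sessions failing validation abort the run with session-level
#' diagnostics and any partially written outputs are removed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `study_results`: `sessions`, `frequencies`,
#'   `zscores`, `coupling`, `category_tests`, `period_contrasts`,
#'   `period_models`, `correlations`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  # --- stage: obtain sessions ------------------------------------------
  if (!is.null(config$input)) {
    sessions <- read_coding_csv(config$input)
  } else {
    sessions <- simulate_study(
      simulation_from_section(config$simulation, config$seed))$sessions
  }
  if (length(sessions) == 0) stop("pipeline stage 'input': no sessions",
                                  call. = FALSE)

  # --- stage: validate -------------------------------------------------
  problems <- character()
  for (s in sessions) {
    rep <- validate_session(s)
    if (length(rep$errors) > 0) {
      problems <- c(problems, paste0(s$session_id, ": ",
                                     paste(rep$errors, collapse = "; ")))
    }
  }
  if (length(problems) > 0) {
    stop("pipeline stage 'validate' failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }

  # --- stage: per-session statistics -----------------------------------
  freqs <- session_frequencies(sessions)
  ztab <- study_zscores(sessions, config$bin_width_ms, config$mode)
  coup <- coupling_table(sessions, config$window_s, config$anchor)

  # --- stage: inference ------------------------------------------------
  cat_tests <- summarize_category_tests(ztab, alpha = config$alpha)
  contrasts <- period_contrast_per_category(ztab)
  both_periods <- length(unique(freqs$period)) == 2
  safe_fit <- function(df, response) {
    tryCatch(fit_period_model(df, response),
             error = function(e) degenerate_period_fit(
               response, df[!is.na(df$value), , drop = FALSE],
               conditionMessage(e)))
  }
  period_models <- if (both_periods) {
    list(
      pointing = safe_fit(
        data.frame(value = freqs$pointing, period = freqs$period,
                   toddler_id = freqs$toddler_id), "pointing_frequency"),
      face_look = safe_fit(
        data.frame(value = freqs$face_look, period = freqs$period,
                   toddler_id = freqs$toddler_id), "face_look_frequency"),
      coupling = safe_fit(
        data.frame(value = coup$proportion, period = coup$period,
                   toddler_id = coup$toddler_id), "coupling_proportion")
    )
  } else {
    list()
  }
  correlations <- lapply(intersect(period_levels(), unique(freqs$period)),
                         function(p) {
                           if (sum(freqs$period == p) >= 3) {
                             pointing_look_correlation(freqs, p)
                           }
                         })
  correlations <- Filter(Negate(is.null), correlations)

  results <- structure(
    list(sessions = sessions, frequencies = freqs, zscores = ztab,
         coupling = coup, category_tests = cat_tests,
         period_contrasts = contrasts, period_models = period_models,
         correlations = correlations, config = config),
    class = "study_results"
  )
  write_study_results(results)
  results
}

# internal: flatten period model fits for CSV output
period_models_table <- function(models) {
  rows <- lapply(models, function(f) {
    tibble::tibble(response = f$response, estimate = f$estimate, se = f$se,
                   F = f$F, num_df = f$num_df, den_df = f$den_df, p = f$p,
                   model = f$model, converged = f$converged, n = f$n,
                   note = f$note)
  })
  if (length(rows) == 0) {
    return(tibble::tibble(response = character(), estimate = numeric(),
                          se = numeric(), F = numeric(),
                          num_df = integer(), den_df = integer(),
                          p = numeric(), model = character(),
                          converged = logical(), n = integer(),
                          note = character()))
  }
  do.call(rbind, rows)
}

# internal: flatten correlation results
correlations_table <- function(correlations) {
  rows <- lapply(correlations, function(x) {
    tibble::tibble(period = x$period, r = x$r, df = x$df, p = x$p, n = x$n,
                   reason_missing = x$reason_missing)
  })
  if (length(rows) == 0) {
    return(tibble::tibble(period = character(), r = numeric(),
                          df = integer(), p = numeric(), n = integer(),
                          reason_missing = character()))
  }
  do.call(rbind, rows)
}

# internal: write all result CSVs + manifest; remove partial output on error
write_study_results <- function(results) {
  out <- results$config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(out, name)
    con <- file(path, open = "wb")
    on.exit(close(con), add = TRUE)
    utils::write.csv(df, con, row.names = FALSE, eol = "\n")
    written <<- c(written, path)
  }
  tryCatch({
    write_coding_csv(results$sessions, file.path(out, "sessions.csv"))
    written <- c(written, file.path(out, "sessions.csv"))
    emit(results$frequencies, "frequencies.csv")
    emit(results$zscores, "zscores.csv")
    emit(results$coupling, "coupling.csv")
    emit(results$category_tests, "category_tests.csv")
    emit(period_contrast_table(results$period_contrasts),
         "period_contrasts.csv")
    emit(period_models_table(results$period_models), "period_models.csv")
    emit(correlations_table(results$correlations), "correlations.csv")
    cfg <- results$config
    manifest <- list(
      tool = "pointseq",
      n_sessions = length(results$sessions),
      bin_width_ms = cfg$bin_width_ms, window_s = cfg$window_s,
      mode = cfg$mode, anchor = cfg$anchor, alpha = cfg$alpha,
      seed = cfg$seed,
      input = cfg$input %||% "simulated",
      simulation = cfg$simulation
    )
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
    written <- c(written, file.path(out, "manifest.yaml"))
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage 'write' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(results)
}

#' Render a plain-text study report
#'
#' Summarizes a [run_pipeline()] result as a plain-text report: per-period
#' descriptive means and SDs of duration and event frequencies (the
#' descriptive table), frequencies and coupling proportion by period, the
#' pooled per-category z-score tests, and the per-category period
#' contrasts.
#'
#' @param results a `study_results` object.
#' @param path optional file to write the report to.
#' @return the report as a character vector of lines (invisibly if `path`
#'   is given).
#' @export
render_report <- function(results, path = NULL) {
  stopifnot(inherits(results, "study_results"))
  if (length(results$sessions) == 0) {
    stop("report stage: no sessions in results", call. = FALSE)
  }
  if (nrow(results$zscores) == 0) {
    stop("report stage: missing co-occurrence stage output", call. = FALSE)
  }
  f <- results$frequencies
  periods <- intersect(period_levels(), unique(f$period))
  msd <- function(x) sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE),
                             stats::sd(x, na.rm = TRUE))
  lines <- c("== pointseq study report ==", "",
             sprintf("Sessions: %d   bin width: %g ms   coupling window: +/- %g s   mode: %s",
                     length(results$sessions), results$config$bin_width_ms,
                     results$config$window_s, results$config$mode), "",
             "-- Descriptive statistics per meal (mean (SD)) --")
  header <- sprintf("  %-28s %s", "measure",
                    paste(sprintf("%-18s", periods), collapse = ""))
  lines <- c(lines, header)
  add_measure <- function(label, values_by_period) {
    lines <<- c(lines, sprintf("  %-28s %s", label,
                               paste(sprintf("%-18s", values_by_period),
                                     collapse = "")))
  }
  add_measure("mealtime duration (min)",
              vapply(periods, function(p)
                msd(f$duration_ms[f$period == p] / 60000), ""))
  add_measure("toddler pointing",
              vapply(periods, function(p) msd(f$pointing[f$period == p]), ""))
  add_measure("toddler face looks",
              vapply(periods, function(p) msd(f$face_look[f$period == p]), ""))
  for (cat in caregiver_categories()) {
    add_measure(paste0("caregiver ", cat),
                vapply(periods, function(p) msd(f[[cat]][f$period == p]), ""))
  }
  cp <- results$coupling
  lines <- c(lines, "", "-- Look-point coupling proportion by period --")
  for (p in periods) {
    lines <- c(lines, sprintf("  %-8s %s", p,
                              msd(cp$proportion[cp$period == p])))
  }
  for (x in results$correlations) {
    lines <- c(lines, sprintf(
      "  pointing-look correlation %s: r(%d) = %.2f, p = %.3g",
      x$period, x$df, if (is.na(x$r)) NA else x$r, x$p))
  }
  lines <- c(lines, "", "-- Pointing vs caregiver category (pooled z-scores) --",
             sprintf("  %-14s %4s %8s %8s %5s %10s", "category", "n",
                     "mean_z", "t", "df", "p"))
  ct <- results$category_tests
  for (i in seq_len(nrow(ct))) {
    lines <- c(lines, sprintf("  %-14s %4d %8.3f %8.2f %5s %10.4g%s",
                              ct$category[i], ct$n[i], ct$mean_z[i],
                              ifelse(is.na(ct$t[i]), NA, ct$t[i]),
                              ifelse(is.na(ct$df[i]), "-", ct$df[i]),
                              ct$p[i],
                              ifelse(isTRUE(ct$significant[i]), " *", "")))
  }
  lines <- c(lines, "", "-- Period contrasts on z per category --")
  pct <- period_contrast_table(results$period_contrasts)
  for (i in seq_len(nrow(pct))) {
    if (pct$model[i] == "degenerate") {
      lines <- c(lines, sprintf("  %-14s (degenerate: %s)",
                                pct$category[i], pct$note[i]))
    } else {
      lines <- c(lines, sprintf(
        "  %-14s estimate %7.3f  F(%d, %d) = %6.2f  p = %.4g [%s]",
        pct$category[i], pct$estimate[i], pct$num_df[i], pct$den_df[i],
        pct$F[i], pct$p[i], pct$model[i]))
    }
  }
  pm <- period_models_table(results$period_models)
  if (nrow(pm) > 0) {
    lines <- c(lines, "", "-- Period models (frequencies, coupling) --")
    for (i in seq_len(nrow(pm))) {
      lines <- c(lines, sprintf(
        "  %-22s estimate %8.3f  F(%d, %d) = %6.2f  p = %.4g [%s]",
        pm$response[i], pm$estimate[i], pm$num_df[i], pm$den_df[i],
        pm$F[i], pm$p[i], pm$model[i]))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
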