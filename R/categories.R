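#' Behavior category sets
#'
#' The caregiver's activity during a mealtime is coded into ten mutually
#' exclusive categories; three of them (`gestures`, `self`, `no_data`) occur
#' too rarely to analyze reliably and are excluded from the sequential
#' statistics while still being legal in coded input. Toddler behavior is
#' coded as `pointing` events and `face_look` events (gaze at the caregiver's
#' face). `pointing_cg` denotes the *caregiver* pointing at objects,
#' distinguished from toddler `pointing`.
#'
#' @return `analysis_categories()`, `excluded_categories()` and
#'   `toddler_categories()` return character vectors of fixed labels;
#'   `caregiver_categories()` returns the union of the first two.
#' @examples
#' analysis_categories()
#' @export
analysis_categories <- function() {
  c("feeding", "scooping", "objects", "touching", "looking",
    "pointing_cg", "other_person")
}

#' @rdname analysis_categories
#' @export
excluded_categories <- function() {
  c("gestures", "self", "no_data")
}

#' @rdname analysis_categories
#' @export
caregiver_categories <- function() {
  c(analysis_categories(), excluded_categories())
}

#' @rdname analysis_categories
#' @export
toddler_categories <- function() {
  c("pointing", "face_look")
}

#' @rdname analysis_categories
#' @export
period_levels <- function() {
  c("13mo", "17mo")
}

# internal: stop unless category is legal for the actor
check_category <- function(actor, category) {
  ok <- (actor == "caregiver" & category %in% caregiver_categories()) |
    (actor == "toddler" & category %in% toddler_categories())
  if (!all(ok)) {
    bad <- unique(paste0(actor[!ok], ":", category[!ok]))
    stop("unknown actor/category combination(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
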