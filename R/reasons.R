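#' PICOS exclusion reasons in hierarchy order
#'
#' The seven exclusion-reason categories used during screening, ordered by
#' the fixed resolution hierarchy: when several reasons qualify for one
#' citation, the earliest reason in this vector is assigned. `study_design`
#' has the highest priority and `time` the lowest.
#'
#' @return Character vector of the seven reasons, highest priority first.
#' @export
#' @examples
#' exclusion_reasons()
exclusion_reasons <- function() {
  c("study_design", "population", "intervention", "comparator",
    "outcomes", "other", "time")
}

#' Priority rank of an exclusion reason
#'
#' @param reason Character vector of reason names.
#' @return Integer rank (1 = highest priority, `study_design`).
#' @export
reason_priority <- function(reason) {
  assert_reason(reason)
  match(reason, exclusion_reasons())
}

#' Resolve a set of qualifying reasons to the highest-priority one
#'
#' @param reasons Non-empty character vector of reason names.
#' @return The single reason with the highest priority.
#' @export
highest_priority_reason <- function(reasons) {
  if (length(reasons) == 0) fail("no qualifying reasons to resolve")
  assert_reason(reasons)
  reasons[which.min(match(reasons, exclusion_reasons()))]
}

assert_reason <- function(reason, allow_na = FALSE) {
  ok <- reason %in% exclusion_reasons() | (allow_na & is.na(reason))
  if (!all(ok)) {
    fail("unknown exclusion reason token(s): %s",
         paste(unique(reason[!ok]), collapse = ", "))
  }
  invisible(reason)
}
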