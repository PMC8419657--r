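#' Build an expanding overlapping window schedule
#'
#' All windows share one fixed origin; window end dates advance on a lattice
#' of `step_days` anchored at `anchor_end`, extended backward toward the
#' origin as long as an end falls strictly after it, and forward through
#' `final_end`.  With a 10-day step from origin 2019-12-30 anchored at
#' 2020-01-28 through 2020-06-26 this yields 18 windows ending 2020-01-08,
#' 2020-01-18, 2020-01-28, ..., 2020-06-26.
#'
#' @param origin Common start date of every window.
#' @param anchor_end End date of a known window defining the lattice phase.
#' @param step_days Days between consecutive window ends (default 10).
#' @param final_end Last window end; must lie on the lattice.
#' @return A tibble with columns `index`, `start`, `end`, `valid` (`NA` until
#'   [mark_valid()] is applied).
#' @export
#' @examples
#' sched <- build_schedule("2019-12-30", "2020-01-28", 10, "2020-06-26")
#' nrow(sched)  # 18
build_schedule <- function(origin, anchor_end, step_days = 10, final_end = anchor_end) {
  origin <- as_date_strict(origin, "origin")
  anchor_end <- as_date_strict(anchor_end, "anchor_end")
  final_end <- as_date_strict(final_end, "final_end")
  stopifnot(step_days >= 1)
  if (!(origin < anchor_end && anchor_end <= final_end)) {
    stop("need origin < anchor_end <= final_end", call. = FALSE)
  }
  span <- as.numeric(final_end - anchor_end)
  if (span %% step_days != 0) {
    stop("final_end ", format(final_end), " is not on the ", step_days,
         "-day lattice anchored at ", format(anchor_end), call. = FALSE)
  }
  forward <- seq(anchor_end, final_end, by = step_days)
  n_back <- (as.numeric(anchor_end - origin) - 1) %/% step_days
  backward <- if (n_back > 0) anchor_end - step_days * seq_len(n_back) else as.Date(character())
  ends <- sort(c(backward, forward))
  tibble::tibble(index = seq_along(ends), start = origin, end = ends,
                 valid = NA)
}

#' Mark windows containing at least one document as statistically valid
#'
#' A window is valid when at least one document's publication date falls in
#' the closed interval `[start, end]`.  Because windows expand from a common
#' origin, validity is monotone: once a window is valid all later windows
#' are too.
#'
#' @param schedule Window tibble from [build_schedule()].
#' @param documents Corpus tibble with a `pub_date` column.
#' @return The schedule with `valid` (logical) and `n_docs` (document count
#'   per window) filled in.
#' @export
mark_valid <- function(schedule, documents) {
  dates <- documents$pub_date
  schedule$n_docs <- vapply(seq_len(nrow(schedule)), function(i) {
    sum(dates >= schedule$start[i] & dates <= schedule$end[i])
  }, integer(1))
  schedule$valid <- schedule$n_docs >= 1L
  schedule
}
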