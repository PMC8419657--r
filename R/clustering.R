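#' Z-score item trajectories row-wise
#'
#' Each row is standardized with its own mean and sample standard deviation
#' so trajectories are compared by shape, not level.  Constant rows map to
#' all zeros and are recorded in the `"constant_items"` attribute.
#'
#' @param values Numeric matrix (items x windows) with at least 2 columns.
#' @return The standardized matrix with attribute `"constant_items"`.
#' @export
zscore_rows <- function(values) {
  stopifnot(is.matrix(values), ncol(values) >= 2)
  m <- rowMeans(values)
  s <- apply(values, 1, sd)
  constant <- s == 0
  z <- (values - m) / ifelse(constant, 1, s)
  z[constant, ] <- 0
  attr(z, "constant_items") <- rownames(values)[constant] %||% character()
  z
}

#' Agglomerative clustering of Z-scored heat trajectories
#'
#' Average linkage on Euclidean distances, cut into exactly `k` flat
#' clusters.  Rows are ordered lexicographically before clustering so tie
#' handling is deterministic; constant (all-equal) trajectories are dropped
#' with a message, since their zero Z-vectors distort the geometry.
#'
#' @param z Z-scored matrix from [zscore_rows()] (rownames = items).
#' @param k Number of flat clusters (default 7).
#' @return An object of class `heat_clusters`: list with `tree` (`hclust`),
#'   `assignment` (named integer, item -> cluster id), `k`, `z` (the rows
#'   clustered), and `dropped` (constant items excluded).
#' @export
cluster_items <- function(z, k = 7) {
  stopifnot(is.matrix(z), !is.null(rownames(z)))
  const <- apply(z, 1, function(r) sd(r) == 0)
  dropped <- rownames(z)[const]
  if (length(dropped)) {
    message("excluding ", length(dropped), " constant trajectories from clustering")
    z <- z[!const, , drop = FALSE]
  }
  if (k > nrow(z)) {
    stop("k = ", k, " exceeds the ", nrow(z), " clusterable items", call. = FALSE)
  }
  z <- z[order(rownames(z), method = "radix"), , drop = FALSE]
  tree <- hclust(dist(z), method = "average")
  assignment <- cutree(tree, k = k)
  structure(list(tree = tree, assignment = assignment, k = k, z = z,
                 dropped = dropped),
            class = "heat_clusters")
}

#' @export
print.heat_clusters <- function(x, ...) {
  cat("<heat_clusters> ", length(x$assignment), " items in ", x$k,
      " clusters (average linkage, Euclidean)\n", sep = "")
  print(table(x$assignment))
  invisible(x)
}

#' Per-cluster mean heat curves
#'
#' @param model A `heat_clusters` from [cluster_items()].
#' @return Numeric matrix (clusters x windows): the arithmetic mean of the
#'   member Z rows in each window.  Row names are cluster ids.
#' @export
mean_curves <- function(model) {
  sums <- rowsum(model$z, group = model$assignment)
  counts <- as.vector(table(model$assignment)[rownames(sums)])
  sums / counts
}

#' Extract rising-heat waves from a mean curve
#'
#' A wave is a maximal run of consecutive windows over which the curve is
#' strictly increasing.  Waves are ranked by their total rise; at most
#' `max_waves` are kept and returned in chronological order.  A wave's date
#' range runs from the end date of the window *preceding* the increasing run
#' (the last date before heat started building) through the run's final end
#' date.  An optional centered moving average can smooth the curve first.
#'
#' @param curve Numeric vector of per-window mean Z values.
#' @param dates Window end dates aligned with `curve` (defaults to
#'   `as.Date(names(curve))`).
#' @param max_waves Maximum number of waves to return (default 2).
#' @param smooth_width Odd width of a centered moving average applied before
#'   wave detection; 0 or 1 (default) disables smoothing.
#' @return Tibble with columns `wave`, `start`, `end`, `rise`,
#'   `start_window`, `end_window`; zero rows for a non-increasing curve.
#' @export
#' @examples
#' rising_waves(c(0, 1, 2, 1, 2, 3), as.Date("2020-01-08") + 10 * (0:5))
rising_waves <- function(curve, dates = NULL, max_waves = 2, smooth_width = 0) {
  if (is.null(dates)) dates <- as.Date(names(curve))
  stopifnot(length(dates) == length(curve), !anyNA(dates))
  if (smooth_width > 1) {
    stopifnot(smooth_width %% 2 == 1)
    half <- (smooth_width - 1) / 2
    curve <- vapply(seq_along(curve), function(i) {
      mean(curve[max(1, i - half):min(length(curve), i + half)])
    }, numeric(1))
  }
  inc <- diff(curve) > 0
  if (!any(inc)) {
    return(tibble::tibble(wave = integer(), start = as.Date(character()),
                          end = as.Date(character()), rise = numeric(),
                          start_window = integer(), end_window = integer()))
  }
  r <- rle(inc)
  step_end <- cumsum(r$lengths)
  step_start <- step_end - r$lengths + 1L
  runs <- which(r$values)
  waves <- tibble::tibble(
    start_window = step_start[runs],              # window preceding the run
    end_window = step_end[runs] + 1L,             # last window of the run
    rise = curve[step_end[runs] + 1L] - curve[step_start[runs]])
  waves <- waves[order(-waves$rise, waves$start_window), ]
  waves <- head(waves, max_waves)
  waves <- waves[order(waves$start_window), ]
  tibble::tibble(wave = seq_len(nrow(waves)),
                 start = dates[waves$start_window],
                 end = dates[waves$end_window],
                 rise = waves$rise,
                 start_window = waves$start_window,
                 end_window = waves$end_window)
}
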