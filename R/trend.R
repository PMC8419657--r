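#' Per-window minimum observed heat percentage
#'
#' The empirical distribution of these minima defines the range from which
#' missing cells are imputed: an item absent from a window's network had a
#' co-occurrence signal at or below the weakest observed item, so its value
#' is treated as missing not at random and replaced by a draw near the
#' observed floor.
#'
#' @param hm A `heat_matrix` from [assemble_heat_matrix()].
#' @return Named numeric vector, one minimum per valid window.
#' @export
window_minima <- function(hm) {
  values <- hm$values
  mins <- vapply(seq_len(ncol(values)), function(j) {
    col <- values[, j]
    if (all(is.na(col))) {
      stop("window ", colnames(values)[j], " has no observed values",
           call. = FALSE)
    }
    min(col, na.rm = TRUE)
  }, numeric(1))
  setNames(mins, colnames(values))
}

#' Minimum-value imputation of missing heat cells
#'
#' Every missing cell is replaced by an independent uniform draw from the
#' central `central_mass` interval of the empirical distribution of the
#' per-window minima (for the default 0.90, between their 5th and 95th
#' percentiles).  Observed cells are untouched.  Deterministic given `seed`.
#'
#' @inheritParams window_minima
#' @param central_mass Central fraction of the minima distribution to draw
#'   from (default 0.90).
#' @param seed Integer seed for the draws (the caller's RNG state is
#'   preserved); `NULL` uses the current RNG stream.
#' @return The completed numeric matrix, with attribute `"imputed"` (logical
#'   matrix marking imputed cells) and `"bounds"` (the draw interval).
#' @export
impute_heat <- function(hm, central_mass = 0.90, seed = NULL) {
  stopifnot(central_mass > 0, central_mass <= 1)
  values <- hm$values
  miss <- is.na(values)
  if (any(miss)) {
    mins <- window_minima(hm)
    if (length(unique(mins)) < 2) {
      warning("fewer than 2 distinct window minima; imputing the single minimum value")
      bounds <- rep(unique(mins), 2)
      draws <- rep(unique(mins), sum(miss))
    } else {
      alpha <- (1 - central_mass) / 2
      bounds <- unname(quantile(mins, probs = c(alpha, 1 - alpha)))
      draws <- with_seed(seed, runif(sum(miss), bounds[1], bounds[2]))
    }
    values[miss] <- draws
  } else {
    bounds <- c(NA_real_, NA_real_)
  }
  attr(values, "imputed") <- miss
  attr(values, "bounds") <- bounds
  values
}

#' One-sample t trend test of the current window against all prior windows
#'
#' Computes `t = (mean(priors) - current) / SE` where `SE` is the sample
#' standard deviation of the prior-window percentages divided by the square
#' root of their number, and the left-tail Student p-value with
#' `length(priors) - 1` degrees of freedom.  Under the left-tail convention a
#' *small* p flags a current value *above* the prior mean (t negative), i.e.
#' rising heat; use `tail = "right"` for declines.  Requires at least two
#' prior windows, which is why the first two valid windows of a schedule are
#' never testable.
#'
#' @param priors Numeric vector of the item's percentages in all prior valid
#'   windows (observed or imputed); length >= 2.
#' @param current The item's percentage in the current window.
#' @param tail `"left"` (default, flags rises) or `"right"` (flags declines).
#' @return A one-row tibble: `prior_mean`, `current`, `se`, `t`, `p`,
#'   `degenerate` (`TRUE` when the priors have zero spread; then p is 0.5 at
#'   equality, otherwise 0 or 1 by the sign of the deviation).
#' @export
#' @examples
#' trend_test(c(1, 2, 3), 4)  # t ~= -3.464, p ~= 0.037
trend_test <- function(priors, current, tail = c("left", "right")) {
  tail <- match.arg(tail)
  stopifnot(length(priors) >= 2, length(current) == 1)
  n <- length(priors)
  m <- mean(priors)
  se <- sd(priors) / sqrt(n)
  if (se == 0) {
    t_stat <- if (current == m) 0 else sign(m - current) * Inf
    p_left <- if (current == m) 0.5 else if (current > m) 0 else 1
    degen <- TRUE
  } else {
    t_stat <- (m - current) / se
    p_left <- pt(t_stat, df = n - 1)
    degen <- FALSE
  }
  p <- if (tail == "left") p_left else 1 - p_left
  tibble::tibble(prior_mean = m, current = current, se = se, t = t_stat,
                 p = p, degenerate = degen)
}

# vectorized trend tests over one completed matrix: returns list of matrices
# (items x testable windows) t, p, degenerate
trend_test_matrix <- function(completed, tail = "left") {
  k <- ncol(completed)
  stopifnot(k >= 3)
  wins <- 3:k
  t_m <- p_m <- matrix(NA_real_, nrow(completed), length(wins),
                       dimnames = list(rownames(completed), colnames(completed)[wins]))
  d_m <- matrix(FALSE, nrow(completed), length(wins),
                dimnames = dimnames(t_m))
  pm_m <- cur_m <- t_m
  for (idx in seq_along(wins)) {
    w <- wins[idx]
    priors <- completed[, seq_len(w - 1), drop = FALSE]
    n <- w - 1
    m <- rowMeans(priors)
    ss <- pmax(rowSums(priors^2) - n * m^2, 0)
    se <- sqrt(ss / (n - 1)) / sqrt(n)
    cur <- completed[, w]
    t_stat <- (m - cur) / se
    p_left <- pt(t_stat, df = n - 1)
    degen <- se == 0
    if (any(degen)) {
      t_stat[degen] <- ifelse(cur[degen] == m[degen], 0,
                              sign(m[degen] - cur[degen]) * Inf)
      p_left[degen] <- ifelse(cur[degen] == m[degen], 0.5,
                              ifelse(cur[degen] > m[degen], 0, 1))
    }
    t_m[, idx] <- t_stat
    p_m[, idx] <- if (tail == "left") p_left else 1 - p_left
    d_m[, idx] <- degen
    pm_m[, idx] <- m
    cur_m[, idx] <- cur
  }
  list(t = t_m, p = p_m, degenerate = d_m, prior_mean = pm_m, current = cur_m)
}

#' Detect items with significant heat variation
#'
#' Runs `n_iterations` independent minimum-value imputations of the heat
#' matrix; in each, tests every item at every eligible window (the third
#' valid window onward, so at least two priors exist) with [trend_test()];
#' then averages t and p across iterations.  An item/window pair is
#' significant when its mean p is below `alpha`.  No multiple-testing
#' correction is applied in the default mode, matching the procedure this
#' pipeline operationalizes; set `p_adjust` to a [stats::p.adjust()] method
#' to add one.
#'
#' @inheritParams impute_heat
#' @param alpha Significance level (default 0.05).
#' @param n_iterations Number of random imputation iterations to average
#'   (default 10).
#' @param tail Passed to the tests; `"left"` flags rising heat.
#' @param seed Base seed; iteration i uses `seed + i - 1`.
#' @param p_adjust `"none"` (default) or a method name for [stats::p.adjust()]
#'   applied per window across items.
#' @return A `trend_result`: tibble with columns `item`, `window` (index
#'   among valid windows), `end`, `prior_mean`, `current`, `t`, `p`,
#'   `significant`, `degenerate`, plus attributes `window_counts` (per-window
#'   significant counts), `significant_items` (deduplicated item set), and
#'   `completed` (the heat matrix completed with the imputation average).
#' @export
detect_significant_items <- function(hm, alpha = 0.05, n_iterations = 10,
                                     central_mass = 0.90, seed = 1L,
                                     tail = c("left", "right"),
                                     p_adjust = "none") {
  tail <- match.arg(tail)
  stopifnot(n_iterations >= 1)
  if (ncol(hm$values) < 3) {
    stop("need at least 3 valid windows to test trends", call. = FALSE)
  }
  sum_t <- sum_p <- sum_pm <- sum_cur <- sum_comp <- NULL
  any_degen <- NULL
  for (it in seq_len(n_iterations)) {
    completed <- impute_heat(hm, central_mass = central_mass,
                             seed = if (is.null(seed)) NULL else seed + it - 1L)
    res <- trend_test_matrix(completed, tail)
    if (is.null(sum_t)) {
      sum_t <- res$t; sum_p <- res$p; sum_pm <- res$prior_mean
      sum_cur <- res$current; any_degen <- res$degenerate
      sum_comp <- unclass_matrix(completed)
    } else {
      sum_t <- sum_t + res$t; sum_p <- sum_p + res$p
      sum_pm <- sum_pm + res$prior_mean; sum_cur <- sum_cur + res$current
      any_degen <- any_degen | res$degenerate
      sum_comp <- sum_comp + unclass_matrix(completed)
    }
  }
  mean_t <- sum_t / n_iterations
  mean_p <- sum_p / n_iterations
  if (p_adjust != "none") {
    mean_p <- apply(mean_p, 2, stats::p.adjust, method = p_adjust)
  }
  sig <- mean_p < alpha

  ends <- as.Date(colnames(mean_p))
  wins <- 3:ncol(hm$values)
  tbl <- tibble::tibble(
    item = rep(rownames(mean_p), times = length(wins)),
    window = rep(wins, each = nrow(mean_p)),
    end = rep(ends, each = nrow(mean_p)),
    prior_mean = as.vector(sum_pm / n_iterations),
    current = as.vector(sum_cur / n_iterations),
    t = as.vector(mean_t),
    p = as.vector(mean_p),
    significant = as.vector(sig),
    degenerate = as.vector(any_degen))
  tbl <- tbl[order(tbl$window, tbl$item, method = "radix"), ]

  counts <- tibble::tibble(window = wins, end = ends,
                           n_significant = colSums(sig))
  attr(tbl, "window_counts") <- counts
  attr(tbl, "significant_items") <- sort(unique(tbl$item[tbl$significant]),
                                         method = "radix")
  attr(tbl, "completed") <- sum_comp / n_iterations
  attr(tbl, "config") <- list(alpha = alpha, n_iterations = n_iterations,
                              central_mass = central_mass, seed = seed,
                              tail = tail, p_adjust = p_adjust)
  class(tbl) <- c("trend_result", class(tbl))
  tbl
}

unclass_matrix <- function(m) {
  attr(m, "imputed") <- NULL
  attr(m, "bounds") <- NULL
  m
}

#' Accessors for `trend_result` objects
#'
#' @param x A `trend_result` from [detect_significant_items()].
#' @return `significant_items()`: sorted character vector of items
#'   significant in at least one window.  `window_counts()`: tibble of
#'   per-window significant counts.  `completed_heat()`: the heat matrix with
#'   missing cells replaced by the average of the imputation iterations.
#' @export
significant_items <- function(x) attr(x, "significant_items")

#' @rdname significant_items
#' @export
window_counts <- function(x) attr(x, "window_counts")

#' @rdname significant_items
#' @export
completed_heat <- function(x) attr(x, "completed")

#' Correlation of significance values between two window-step schemes
#'
#' Runs the heat and trend stages under two expanding-window schedules that
#' differ only in their step length, and correlates the per-item mean
#' p-values at every end date the two schemes share (restricted to windows
#' eligible for testing in both).  Used as a robustness check that trend
#' significance does not hinge on the step choice.
#'
#' @param documents Corpus tibble.
#' @param origin,anchor_end,final_end Schedule parameters (see
#'   [build_schedule()]); scheme B's final end is snapped down to its own
#'   lattice.
#' @param step_a,step_b The two step lengths in days (defaults 10 and 20).
#' @param min_occurrence,normalization Passed to [assemble_heat_matrix()].
#' @param alpha,n_iterations,central_mass,seed Passed to
#'   [detect_significant_items()].
#' @return Tibble with one row per shared end date: `end`, `n_items` (items
#'   tested under both schemes), `r` (Pearson correlation of mean p; `NA`
#'   when fewer than 3 shared items).
#' @export
robustness_correlation <- function(documents, origin, anchor_end, final_end,
                                   step_a = 10, step_b = 20,
                                   min_occurrence = 2, normalization = "sum",
                                   alpha = 0.05, n_iterations = 10,
                                   central_mass = 0.90, seed = 1L) {
  run_scheme <- function(step) {
    fe <- as_date_strict(anchor_end) +
      step * ((as.numeric(as_date_strict(final_end) - as_date_strict(anchor_end))) %/% step)
    sched <- mark_valid(build_schedule(origin, anchor_end, step, fe), documents)
    hm <- assemble_heat_matrix(documents, sched, min_occurrence, normalization)
    detect_significant_items(hm, alpha = alpha, n_iterations = n_iterations,
                             central_mass = central_mass, seed = seed)
  }
  ta <- run_scheme(step_a)
  tb <- run_scheme(step_b)
  shared <- sort(as.Date(intersect(unique(ta$end), unique(tb$end)),
                         origin = "1970-01-01"))
  if (length(shared) == 0) stop("schemes share no testable end dates", call. = FALSE)
  out <- lapply(shared, function(e) {
    a <- ta[ta$end == e, c("item", "p")]
    b <- tb[tb$end == e, c("item", "p")]
    m <- merge(a, b, by = "item")
    r <- if (nrow(m) >= 3) suppressWarnings(cor(m$p.x, m$p.y)) else NA_real_
    tibble::tibble(end = e, n_items = nrow(m), r = r)
  })
  do.call(rbind, out)
}
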