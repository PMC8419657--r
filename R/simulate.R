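#' Monte-Carlo calibration of the trend test on synthetic corpora
#'
#' `simulate_type1_rate()` generates corpora in which every topic is
#' stationary (change points removed) and measures how often stationary
#' keywords are flagged, per eligible item/window test.  Because imputed
#' prior windows behave differently from observed ones, the rate is reported
#' both over all tests and restricted to items observed in every window
#' (where the null holds cleanly).  `simulate_power()` keeps the planted
#' change points and measures, per rising topic, how often its keywords are
#' flagged in at least one window ending on or after the change point.
#'
#' @param n_replicates Number of simulated corpora (default 200).
#' @param seed Base seed; replicate r uses `seed + 1009 * r`.
#' @param config A [pipeline_config()] supplying schedule and test settings.
#' @param topics Topic set (default [example_topics()]).
#' @param ... Passed to [generate_corpus()] (e.g. `docs_per_day`).
#' @return `simulate_type1_rate()`: list with `rate_fully_observed`,
#'   `rate_all`, `n_tests_fully_observed`, `n_tests_all`, and the
#'   per-replicate tibble.  `simulate_power()`: tibble with one row per
#'   rising topic: `topic`, `change_point`, `power` (share of replicates in
#'   which at least half the topic's keywords were flagged post-change) and
#'   `keyword_rate` (mean share of its keywords flagged post-change).
#' @export
simulate_type1_rate <- function(n_replicates = 200, seed = 1L,
                                config = pipeline_config(),
                                topics = example_topics(), ...) {
  stationary <- lapply(topics, function(t) {
    topic_spec(t$name, t$keywords, t$weight)
  })
  reps <- lapply(seq_len(n_replicates), function(r) {
    run <- simulate_one(stationary, config, seed + 1009L * r, ...)
    trend <- run$trend
    full <- rownames(run$hm$values)[!apply(is.na(run$hm$values), 1, any)]
    sub <- trend[trend$item %in% full, ]
    tibble::tibble(replicate = r,
                   n_tests_all = nrow(trend),
                   n_sig_all = sum(trend$significant),
                   n_tests_full = nrow(sub),
                   n_sig_full = sum(sub$significant))
  })
  reps <- do.call(rbind, reps)
  list(rate_fully_observed = sum(reps$n_sig_full) / sum(reps$n_tests_full),
       rate_all = sum(reps$n_sig_all) / sum(reps$n_tests_all),
       n_tests_fully_observed = sum(reps$n_tests_full),
       n_tests_all = sum(reps$n_tests_all),
       replicates = reps)
}

#' @rdname simulate_type1_rate
#' @export
simulate_power <- function(n_replicates = 200, seed = 1L,
                           config = pipeline_config(),
                           topics = example_topics(), ...) {
  rising <- Filter(function(t) !is.null(t$change_point) && t$multiplier > 1,
                   topics)
  if (!length(rising)) stop("no rising topic in the topic set", call. = FALSE)
  hits <- matrix(0, n_replicates, length(rising))
  rates <- matrix(0, n_replicates, length(rising))
  for (r in seq_len(n_replicates)) {
    run <- simulate_one(topics, config, seed + 1009L * r, ...)
    trend <- run$trend
    for (ti in seq_along(rising)) {
      cp <- rising[[ti]]$change_point
      kws <- rising[[ti]]$keywords
      post <- trend[trend$end >= cp & trend$item %in% kws, ]
      flagged <- tapply(post$significant, post$item, any)
      rate <- sum(flagged) / length(kws)
      rates[r, ti] <- rate
      hits[r, ti] <- rate >= 0.5
    }
  }
  tibble::tibble(
    topic = vapply(rising, `[[`, "", "name"),
    change_point = as.Date(vapply(rising, function(t) format(t$change_point), "")),
    power = colMeans(hits),
    keyword_rate = colMeans(rates))
}

# one replicate: corpus -> schedule -> heat -> trend
simulate_one <- function(topics, config, rep_seed, ...) {
  corp <- generate_corpus(topics = topics,
                          horizon = c(config$origin, config$final_end),
                          seed = rep_seed, ...)
  sched <- mark_valid(build_schedule(config$origin, config$anchor_end,
                                     config$step_days, config$final_end),
                      corp$documents)
  hm <- assemble_heat_matrix(corp$documents, sched, config$min_occurrence,
                             config$normalization)
  trend <- detect_significant_items(hm, alpha = config$alpha,
                                    n_iterations = config$n_iterations,
                                    central_mass = config$central_mass,
                                    seed = rep_seed + 1L, tail = config$tail)
  list(corpus = corp, hm = hm, trend = trend)
}
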