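#' Specify a synthetic research topic
#'
#' A topic is a pool of keywords drawn together (which induces their
#' co-occurrence), a baseline sampling weight, and an optional change point
#' at which the weight is multiplied (`> 1` plants a rise in heat, `< 1` a
#' decline).
#'
#' @param name Topic name (used as the cluster tag of linked policies).
#' @param keywords Character vector of terms in the topic's pool.
#' @param weight Positive baseline weight (default 1).
#' @param change_point Optional `Date` at which the weight switches.
#' @param multiplier Positive factor applied to `weight` from
#'   `change_point` onward (default 1 = stationary).
#' @return An object of class `topic_spec`.
#' @export
topic_spec <- function(name, keywords, weight = 1, change_point = NULL,
                       multiplier = 1) {
  stopifnot(nzchar(name), length(keywords) >= 1, all(nzchar(keywords)),
            weight > 0, multiplier > 0)
  if (!is.null(change_point)) change_point <- as_date_strict(change_point)
  structure(list(name = name, keywords = tolower(keywords), weight = weight,
                 change_point = change_point, multiplier = multiplier),
            class = "topic_spec")
}

#' Default synthetic topic set
#'
#' Six topics emulating the thematic structure of an emerging-epidemic
#' literature: two rising topics (severe disease markers planted to triple
#' in weight 60 days into the horizon, antibody testing at day 90), one
#' declining topic (paediatric/obstetric, weight divided by 3 at day 60),
#' and three stationary topics (mental health, epidemiology, virology).
#' Each pool holds six MeSH-like descriptors.
#'
#' @param horizon_start Date the horizon opens (default `"2019-12-30"`);
#'   change points are placed relative to it.
#' @return List of [topic_spec()] objects.
#' @export
example_topics <- function(horizon_start = "2019-12-30") {
  h0 <- as_date_strict(horizon_start)
  list(
    topic_spec("severe_disease",
               c("critical illness", "c-reactive protein", "interleukin-6",
                 "hospital mortality", "cytokine release syndrome",
                 "lymphocyte count"),
               change_point = h0 + 60, multiplier = 3),
    topic_spec("antibody_testing",
               c("immunoglobulin g", "immunoglobulin m", "serologic tests",
                 "antibodies, viral", "sensitivity and specificity",
                 "enzyme-linked immunosorbent assay"),
               change_point = h0 + 90, multiplier = 3),
    topic_spec("pediatric_obstetric",
               c("child", "infant, newborn", "pregnancy",
                 "pregnancy complications, infectious", "cesarean section",
                 "child, preschool"),
               change_point = h0 + 60, multiplier = 1 / 3),
    topic_spec("mental_health",
               c("mental health", "anxiety", "depression", "health personnel",
                 "stress, psychological", "surveys and questionnaires")),
    topic_spec("epidemiology",
               c("disease outbreaks", "epidemics", "quarantine",
                 "contact tracing", "incidence", "public health")),
    topic_spec("virology",
               c("spike glycoprotein, coronavirus", "virus replication",
                 "genome, viral", "phylogeny", "rna, viral", "virus shedding")))
}

#' Shared background keyword pool
#'
#' Generic descriptors attached to every document so the per-window networks
#' stay connected, as real MeSH-indexed corpora are.
#'
#' @return Character vector of 20 terms.
#' @export
example_background <- function() {
  c("humans", "adult", "middle aged", "aged", "female", "male", "china",
    "pandemics", "coronavirus infections", "pneumonia, viral",
    "betacoronavirus", "sars-cov-2", "risk factors", "retrospective studies",
    "tomography, x-ray computed", "real-time polymerase chain reaction",
    "hospitalization", "comorbidity", "prognosis", "time factors")
}

#' Generate a synthetic bibliographic corpus with known ground truth
#'
#' Documents arrive over the horizon with a linearly ramping daily rate
#' (default ~1/day rising to ~40/day, mimicking the explosive growth of an
#' emerging-topic literature).  Each document draws a topic with weights
#' that switch at the topics' change points, then samples part of that
#' topic's keyword pool plus a few shared background terms.  Byte-identical
#' output under the same seed.
#'
#' @param topics List of [topic_spec()] (default [example_topics()]).
#' @param horizon Length-2 vector of dates bounding arrivals (default
#'   2019-12-30 to 2020-06-26).
#' @param docs_per_day Length-2 numeric: arrival rate at the start and end
#'   of the horizon, interpolated linearly (default `c(1, 40)`).
#' @param n_docs Total documents; `NULL` (default) draws daily Poisson
#'   counts from the rate profile, otherwise exactly `n_docs` dates are
#'   sampled with probability proportional to it.
#' @param keywords_per_doc Range (min, max) of topic-pool terms per document
#'   (default `c(3, 6)`).
#' @param background Background pool (default [example_background()]).
#' @param background_per_doc Range of background terms per document
#'   (default `c(2, 4)`).
#' @param sampling `"stochastic"` (default) draws arrival counts, topics and
#'   keyword subsets at random.  `"deterministic"` builds a noise-free
#'   corpus for oracle checks: each day every topic receives
#'   `round(rate * weight / sum(weights))` documents, and every document
#'   carries its topic's full pool plus the full background pool, so a
#'   topic's normalized heat is exactly constant until its change point.
#' @param seed Integer seed (required for stochastic sampling; the caller's
#'   RNG is untouched).
#' @return List with `documents` (corpus tibble as from [parse_medline()])
#'   and `truth` (tibble: `topic`, `change_point`, `multiplier`,
#'   `direction`, `keywords` list-column).
#' @export
generate_corpus <- function(topics = example_topics(),
                            horizon = c("2019-12-30", "2020-06-26"),
                            docs_per_day = c(1, 40), n_docs = NULL,
                            keywords_per_doc = c(3, 6),
                            background = example_background(),
                            background_per_doc = c(2, 4),
                            sampling = c("stochastic", "deterministic"),
                            seed = NULL) {
  sampling <- match.arg(sampling)
  stopifnot(length(horizon) == 2, length(docs_per_day) == 2,
            all(docs_per_day >= 0), length(topics) >= 1)
  if (any(lengths(lapply(topics, `[[`, "keywords")) == 0)) {
    stop("topic keyword pools must be non-empty", call. = FALSE)
  }
  h <- as_date_strict(horizon, "horizon")
  days <- seq(h[1], h[2], by = 1)
  rate <- seq(docs_per_day[1], docs_per_day[2], length.out = length(days))

  if (sampling == "deterministic") {
    return(generate_corpus_deterministic(topics, days, rate, background))
  }
  if (is.null(seed)) stop("stochastic sampling requires a seed", call. = FALSE)
  with_seed(seed, {
    dates <- if (is.null(n_docs)) {
      rep(days, rpois(length(days), rate))
    } else {
      stopifnot(n_docs >= 1)
      sort(sample(days, n_docs, replace = TRUE, prob = rate))
    }
    n <- length(dates)
    if (n == 0) stop("rate profile produced an empty corpus", call. = FALSE)

    base_w <- vapply(topics, `[[`, numeric(1), "weight")
    cps <- lapply(topics, `[[`, "change_point")
    mult <- vapply(topics, `[[`, numeric(1), "multiplier")
    pools <- lapply(topics, `[[`, "keywords")

    k_top <- sample(seq(keywords_per_doc[1], keywords_per_doc[2]), n, replace = TRUE)
    k_bg <- sample(seq(background_per_doc[1], background_per_doc[2]), n, replace = TRUE)
    kw <- vector("list", n)
    for (i in seq_len(n)) {
      w <- base_w
      for (t in seq_along(topics)) {
        if (!is.null(cps[[t]]) && dates[i] >= cps[[t]]) w[t] <- w[t] * mult[t]
      }
      t_i <- sample.int(length(topics), 1, prob = w)
      pool <- pools[[t_i]]
      kw[[i]] <- c(sample(pool, min(k_top[i], length(pool))),
                   sample(background, min(k_bg[i], length(background))))
    }
    documents <- tibble::tibble(
      doc_id = sprintf("S%06d", seq_len(n)),
      pub_date = dates,
      keywords = kw,
      record_type = "journal article",
      date_flag = "day")
  })

  list(documents = documents, truth = topic_truth(topics))
}

# noise-free corpus: per-day per-topic counts follow the weight profile
# exactly and every document carries its full topic pool plus the whole
# background pool, so normalized heat is piecewise-constant in the truth
generate_corpus_deterministic <- function(topics, days, rate, background) {
  base_w <- vapply(topics, `[[`, numeric(1), "weight")
  cps <- lapply(topics, `[[`, "change_point")
  mult <- vapply(topics, `[[`, numeric(1), "multiplier")
  pools <- lapply(topics, `[[`, "keywords")

  dates <- list()
  topic_of <- list()
  for (di in seq_along(days)) {
    w <- base_w
    for (t in seq_along(topics)) {
      if (!is.null(cps[[t]]) && days[di] >= cps[[t]]) w[t] <- w[t] * mult[t]
    }
    n_td <- round(rate[di] * w / sum(w))
    for (t in seq_along(topics)) {
      if (n_td[t] > 0) {
        dates[[length(dates) + 1L]] <- rep(days[di], n_td[t])
        topic_of[[length(topic_of) + 1L]] <- rep(t, n_td[t])
      }
    }
  }
  dates <- as.Date(unlist(lapply(dates, format)), "%Y-%m-%d")
  topic_of <- unlist(topic_of)
  if (!length(dates)) stop("rate profile produced an empty corpus", call. = FALSE)
  documents <- tibble::tibble(
    doc_id = sprintf("S%06d", seq_along(dates)),
    pub_date = dates,
    keywords = lapply(topic_of, function(t) c(pools[[t]], background)),
    record_type = "journal article",
    date_flag = "day")
  list(documents = documents, truth = topic_truth(topics))
}

topic_truth <- function(topics) {
  tibble::tibble(
    topic = vapply(topics, `[[`, "", "name"),
    change_point = as.Date(vapply(topics, function(t)
      if (is.null(t$change_point)) NA_character_ else format(t$change_point), "")),
    multiplier = vapply(topics, `[[`, numeric(1), "multiplier"),
    direction = vapply(topics, function(t) {
      if (is.null(t$change_point) || t$multiplier == 1) "stable"
      else if (t$multiplier > 1) "rise" else "decline"
    }, ""),
    keywords = lapply(topics, `[[`, "keywords"))
}

#' Generate policy events lagged after planted topic change points
#'
#' For every changing topic in the requested directions, emits
#' `n_per_topic` policy events dated `change_point + lag_days` plus an
#' integer jitter drawn uniformly from `[-jitter_days, jitter_days]`, tagged
#' with the topic name.
#'
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @param lag_days Intended lag in days (default 8).
#' @param jitter_days Maximum absolute jitter in days (default 0).
#' @param n_per_topic Policies per changing topic (default 3).
#' @param directions Which planted directions receive policies (default
#'   `"rise"`; rising-heat stages are what policies are aligned against).
#' @param seed Integer seed.
#' @return Policy tibble with `title`, `release_date`, `cluster_tag`.
#' @export
generate_policies <- function(truth, lag_days = 8, jitter_days = 0,
                              n_per_topic = 3, directions = "rise", seed = 1L) {
  changing <- truth[!is.na(truth$change_point) & truth$direction %in% directions, ]
  if (nrow(changing) == 0) stop("ground truth has no changing topic", call. = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(changing)), function(i) {
      jit <- if (jitter_days > 0) {
        sample(seq(-jitter_days, jitter_days), n_per_topic, replace = TRUE)
      } else rep(0L, n_per_topic)
      tibble::tibble(
        title = sprintf("Guidance on %s (no. %d)", changing$topic[i],
                        seq_len(n_per_topic)),
        release_date = changing$change_point[i] + lag_days + jit,
        cluster_tag = changing$topic[i])
    })
    out <- do.call(rbind, rows)
    out[order(out$release_date, out$title), ]
  })
}

#' Label discovered clusters with ground-truth topic names
#'
#' Assigns each cluster the topic whose keyword pool contributes the most
#' member items (ties broken lexicographically); clusters with no
#' topic-pool member are left `NA`.
#'
#' @param model A `heat_clusters` from [cluster_items()].
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @return Named character vector, cluster id -> topic name.
#' @export
label_clusters <- function(model, truth) {
  ids <- sort(unique(model$assignment))
  labels <- vapply(ids, function(cl) {
    members <- names(model$assignment)[model$assignment == cl]
    hits <- vapply(seq_len(nrow(truth)), function(i)
      sum(members %in% truth$keywords[[i]]), integer(1))
    if (all(hits == 0)) NA_character_
    else sort(truth$topic[hits == max(hits)], method = "radix")[1]
  }, "")
  setNames(labels, as.character(ids))
}

#' Write a corpus as MEDLINE-format text
#'
#' Emits `PMID`, `DP`, `PT`, and `MH` fields per record, separated by blank
#' lines, so a generated corpus can exercise [parse_medline()] end to end.
#' Month names are written in English regardless of locale.
#'
#' @param documents Corpus tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_medline <- function(documents, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(documents))) {
    d <- documents$pub_date[i]
    dp <- paste(format(d, "%Y"), month.abb[as.integer(format(d, "%m"))],
                format(d, "%d"))
    writeLines(c(paste0("PMID- ", documents$doc_id[i]),
                 paste0("DP  - ", dp),
                 paste0("PT  - ", if (is.na(documents$record_type[i]))
                   "Journal Article" else documents$record_type[i]),
                 paste0("MH  - ", documents$keywords[[i]]),
                 ""), con)
  }
  invisible(path)
}
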