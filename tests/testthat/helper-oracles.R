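# Independent brute-force oracles and small fixture builders shared across
# the test files.  Everything here is deliberately naive (nested loops, no
# sparse algebra) so it cannot share a bug with the implementation.

# plain tibble corpus from a list of keyword vectors
toy_corpus <- function(kw_list, start = as.Date("2020-01-01"), dates = NULL) {
  n <- length(kw_list)
  tibble::tibble(
    doc_id = sprintf("D%03d", seq_len(n)),
    pub_date = if (is.null(dates)) start + seq_len(n) - 1 else as.Date(dates),
    keywords = lapply(kw_list, as.character),
    record_type = "journal article",
    date_flag = "day")
}

random_kw_list <- function(n_docs, vocab, seed, k_range = c(1, 4)) {
  set.seed(seed)
  lapply(seq_len(n_docs), function(i) {
    sample(vocab, sample(seq(k_range[1], min(k_range[2], length(vocab))), 1))
  })
}

# naive document-level full-counting co-occurrence network
bf_network <- function(kw_list, min_occ = 2, threshold_when = "before") {
  kw_list <- lapply(kw_list, unique)
  terms <- sort(unique(unlist(kw_list)))
  occ <- vapply(terms, function(t)
    sum(vapply(kw_list, function(k) t %in% k, TRUE)), numeric(1))
  kept <- terms[occ >= min_occ]
  universe <- if (threshold_when == "before") kept else terms
  link <- function(a, b)
    sum(vapply(kw_list, function(k) (a %in% k) && (b %in% k), TRUE))
  tls <- vapply(kept, function(a)
    sum(vapply(setdiff(universe, a), function(b) link(a, b), numeric(1)), 0),
    numeric(1))
  pairs <- if (length(kept) >= 2) utils::combn(kept, 2, simplify = FALSE) else list()
  weights <- vapply(pairs, function(p) link(p[1], p[2]), numeric(1))
  keep <- weights > 0
  list(items = kept, occurrence = occ[kept], tls = tls,
       links = tibble::tibble(
         item1 = vapply(pairs[keep], `[`, "", 1),
         item2 = vapply(pairs[keep], `[`, "", 2),
         weight = weights[keep]))
}

# naive average-linkage agglomeration; returns the membership vector after
# each merge (i.e. the partition with n-1, n-2, ..., 1 clusters)
bf_average_partitions <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  parts <- list()
  while (length(clusters) > 1) {
    best <- list(h = Inf, i = NA, j = NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best$h) best <- list(h = h, i = i, j = j)
      }
    }
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
    memb <- integer(nrow(x))
    for (ci in seq_along(clusters)) memb[clusters[[ci]]] <- ci
    parts[[length(parts) + 1L]] <- memb
  }
  parts
}

# canonical form of a partition label vector (first-appearance relabeling)
canonical_partition <- function(memb) {
  match(memb, unique(memb))
}

# minimal MEDLINE text for given ids/dates/keyword vectors
medline_text <- function(ids, dates, kw_list, pt = "Journal Article") {
  blocks <- mapply(function(id, d, kws) {
    dp <- if (is.na(d)) NULL else paste0("DP  - ", format(as.Date(d), "%Y"), " ",
                                         month.abb[as.integer(format(as.Date(d), "%m"))],
                                         " ", format(as.Date(d), "%d"))
    c(paste0("PMID- ", id), dp, paste0("PT  - ", pt),
      paste0("MH  - ", kws), "")
  }, ids, dates, kw_list, SIMPLIFY = FALSE)
  unlist(blocks)
}
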