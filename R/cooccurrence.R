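#' Build a keyword co-occurrence network
#'
#' Full counting at the document level: each document containing both terms
#' i and j contributes exactly 1 to the link `(i, j)`, regardless of how
#' often a term is repeated within the record.  A term's total link strength
#' (TLS) is the sum of its link counts over all other terms.  By default the
#' occurrence threshold is applied *before* links are counted, so links
#' between kept and dropped terms never contribute.
#'
#' @param documents Corpus tibble with a `keywords` list-column.
#' @param min_occurrence Minimum number of documents a term must appear in
#'   (default 2).
#' @param threshold_when `"before"` (default) filters terms below
#'   `min_occurrence` before counting links; `"after"` counts links among
#'   all terms first, so a kept term's TLS retains links to dropped terms.
#' @return An object of class `cooc_network`: a list with `items` (sorted
#'   terms passing the threshold), `occurrence`, `tls` (named numeric), and
#'   `links` (tibble `item1`, `item2`, `weight` with `item1 < item2`).
#' @export
#' @examples
#' docs <- tibble::tibble(doc_id = c("1", "2", "3"),
#'                        pub_date = as.Date("2020-01-01") + 0:2,
#'                        keywords = list(c("a", "b"), c("a", "b", "c"), "a"))
#' net <- build_network(docs, min_occurrence = 2)
#' net$tls  # a: 2, b: 2
build_network <- function(documents, min_occurrence = 2,
                          threshold_when = c("before", "after")) {
  threshold_when <- match.arg(threshold_when)
  stopifnot(min_occurrence >= 1)
  kw <- lapply(documents$keywords, function(k) unique(k[nzchar(k)]))
  nk <- lengths(kw)
  if (nrow(documents) == 0 || sum(nk) == 0) {
    return(new_cooc_network(character(), numeric(), numeric(),
                            empty_links(), min_occurrence, threshold_when))
  }
  terms <- sort(unique(unlist(kw)), method = "radix")
  inc <- Matrix::sparseMatrix(
    i = match(unlist(kw), terms),
    j = rep.int(seq_along(kw), nk),
    x = 1, dims = c(length(terms), length(kw)))
  occ <- Matrix::rowSums(inc)
  keep <- occ >= min_occurrence

  if (threshold_when == "before") {
    if (!any(keep)) {
      return(new_cooc_network(character(), numeric(), numeric(),
                              empty_links(), min_occurrence, threshold_when))
    }
    co <- Matrix::tcrossprod(inc[keep, , drop = FALSE])
    diag(co) <- 0
    items <- terms[keep]
    tls <- Matrix::rowSums(co)
    links <- links_from_matrix(co, items)
  } else {
    co <- Matrix::tcrossprod(inc)
    diag(co) <- 0
    tls_all <- Matrix::rowSums(co)
    items <- terms[keep]
    tls <- tls_all[keep]
    links <- links_from_matrix(co[keep, keep, drop = FALSE], items)
  }
  new_cooc_network(items, setNames(as.numeric(occ[keep]), items),
                   setNames(as.numeric(tls), items), links,
                   min_occurrence, threshold_when)
}

empty_links <- function() {
  tibble::tibble(item1 = character(), item2 = character(), weight = numeric())
}

links_from_matrix <- function(co, items) {
  tr <- methods::as(methods::as(co, "generalMatrix"), "TsparseMatrix")
  sel <- tr@i < tr@j & tr@x != 0
  links <- tibble::tibble(item1 = items[tr@i[sel] + 1L],
                          item2 = items[tr@j[sel] + 1L],
                          weight = tr@x[sel])
  links[order(links$item1, links$item2, method = "radix"), ]
}

new_cooc_network <- function(items, occurrence, tls, links, min_occurrence,
                             threshold_when) {
  structure(list(items = items, occurrence = occurrence, tls = tls,
                 links = links, min_occurrence = min_occurrence,
                 threshold_when = threshold_when),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("<cooc_network> ", length(x$items), " items, ", nrow(x$links),
      " links (min occurrence ", x$min_occurrence, ")\n", sep = "")
  invisible(x)
}

#' Normalize total link strengths to percentages
#'
#' Under the default sum normalization, `percentage(i) = 100 * tls(i) /
#' sum(tls)`, so the percentages of the items present in a window sum to 100
#' and remain comparable across windows whose raw maxima differ by orders of
#' magnitude.  `mode = "max"` instead scales by the window's maximum TLS.
#'
#' @param network A `cooc_network` from [build_network()].
#' @param mode `"sum"` (default) or `"max"`.
#' @return Named numeric vector of percentages (one entry per item).
#' @export
normalize_tls <- function(network, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  tls <- network$tls
  if (length(tls) == 0) return(setNames(numeric(), character()))
  denom <- if (mode == "sum") sum(tls) else max(tls)
  if (denom == 0) {
    warning("all total link strengths are zero; percentages set to 0")
    return(setNames(rep(0, length(tls)), names(tls)))
  }
  100 * tls / denom
}

#' Assemble the items-by-windows heat matrix
#'
#' For each valid window, builds the co-occurrence network of the documents
#' published in it and stores each item's normalized TLS percentage.  Items
#' absent from a window's network (because the window's corpus did not yet
#' support them at the occurrence threshold) are recorded as missing (`NA`);
#' this missingness is the input to minimum-value imputation.
#'
#' @param documents Corpus tibble.
#' @param schedule Window tibble processed by [mark_valid()].
#' @inheritParams build_network
#' @param normalization Passed to [normalize_tls()].
#' @return An object of class `heat_matrix`: list with `values` (numeric
#'   matrix, rows = items, columns = valid windows, `NA` = missing),
#'   `schedule` (the valid windows), and the settings used.
#' @export
assemble_heat_matrix <- function(documents, schedule, min_occurrence = 2,
                                 normalization = c("sum", "max"),
                                 threshold_when = c("before", "after")) {
  normalization <- match.arg(normalization)
  threshold_when <- match.arg(threshold_when)
  if (all(is.na(schedule$valid))) {
    stop("schedule has not been marked valid; run mark_valid() first",
         call. = FALSE)
  }
  vw <- schedule[!is.na(schedule$valid) & schedule$valid, ]
  if (nrow(vw) == 0) stop("no valid windows in schedule", call. = FALSE)

  pcts <- vector("list", nrow(vw))
  for (i in seq_len(nrow(vw))) {
    in_win <- documents$pub_date >= vw$start[i] & documents$pub_date <= vw$end[i]
    net <- build_network(documents[in_win, ], min_occurrence, threshold_when)
    pcts[[i]] <- normalize_tls(net, normalization)
  }
  # a window can hold documents yet no item above the occurrence threshold;
  # it contributes nothing and is dropped from the matrix
  nonempty <- lengths(pcts) > 0
  if (!all(nonempty)) {
    message(sum(!nonempty), " valid window(s) with no thresholded items dropped")
    vw <- vw[nonempty, ]
    pcts <- pcts[nonempty]
    if (nrow(vw) == 0) stop("no window has any thresholded item", call. = FALSE)
  }
  items <- sort(unique(unlist(lapply(pcts, names))), method = "radix")
  values <- matrix(NA_real_, nrow = length(items), ncol = nrow(vw),
                   dimnames = list(items, format(vw$end, "%Y-%m-%d")))
  for (i in seq_along(pcts)) {
    if (length(pcts[[i]])) values[names(pcts[[i]]), i] <- pcts[[i]]
  }
  structure(list(values = values, schedule = vw,
                 min_occurrence = min_occurrence,
                 normalization = normalization,
                 threshold_when = threshold_when),
            class = "heat_matrix")
}

#' @export
print.heat_matrix <- function(x, ...) {
  cat("<heat_matrix> ", nrow(x$values), " items x ", ncol(x$values),
      " valid windows; ", sum(is.na(x$values)), " missing cells\n", sep = "")
  invisible(x)
}
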