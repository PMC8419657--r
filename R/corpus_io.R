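#' Parse MEDLINE-format bibliographic records
#'
#' Reads the tag-value text format exported by PubMed (fields `PMID`, `DP`,
#' `MH`, `OT`, `PT`; continuation lines indented).  Keywords are taken from
#' the MeSH (`MH`) field by default; qualifier suffixes after `/` are
#' stripped, leading asterisks (major-topic markers) are removed, and terms
#' are lowercased, so `*Coronavirus Infections/epidemiology` becomes
#' `coronavirus infections`.  Records whose `DP` (publication date) cannot be
#' parsed are skipped and reported; month-only dates are assigned the first
#' day of the month and flagged.
#'
#' @param x Path to a MEDLINE file, or the MEDLINE text itself (a character
#'   vector of lines, or a single string containing newlines).
#' @param keyword_fields Fields supplying keywords: `"MH"` (MeSH, default)
#'   and/or `"OT"` (author keywords).
#' @return A tibble with one row per parsed record and columns `doc_id`,
#'   `pub_date` (`Date`), `keywords` (list of character), `record_type`, and
#'   `date_flag` (`"day"`, `"month_only"`, or `"year_only"`).  Records that
#'   were skipped are reported in the `"skipped"` attribute, retrievable with
#'   [medline_skip_report()].
#' @seealso [write_documents()], [read_policy_table()]
#' @export
#' @examples
#' txt <- c("PMID- 1", "DP  - 2020 Jan 24", "PT  - Journal Article",
#'          "MH  - Humans", "MH  - *Coronavirus Infections/epidemiology")
#' docs <- parse_medline(txt)
#' docs$keywords[[1]]
parse_medline <- function(x, keyword_fields = "MH") {
  stopifnot(all(keyword_fields %in% c("MH", "OT")))
  lines <- if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, blank[-length(blank)]))
  blocks <- split(lines[!blank], grp[!blank])
  blocks <- Filter(length, blocks)

  rows <- list()
  skipped <- list()
  seen_ids <- character()
  n_pmid_records <- 0L

  for (block in blocks) {
    rec <- fold_medline_block(block)
    if (is.null(rec)) next          # no PMID tag: not a record
    n_pmid_records <- n_pmid_records + 1L
    if (is.na(rec$id)) {
      skipped[[length(skipped) + 1L]] <- list(doc_id = NA_character_,
                                              reason = rec$reason)
      next
    }
    if (!is.null(rec$reason)) {     # malformed line inside the record
      skipped[[length(skipped) + 1L]] <- list(doc_id = rec$id, reason = rec$reason)
      next
    }
    if (rec$id %in% seen_ids) {
      skipped[[length(skipped) + 1L]] <- list(doc_id = rec$id,
                                              reason = "duplicate PMID")
      next
    }
    dp <- rec$values[rec$tags == "DP"]
    d <- if (length(dp)) parse_dp_date(dp[1]) else NULL
    if (is.null(d) || is.na(d$date)) {
      skipped[[length(skipped) + 1L]] <- list(
        doc_id = rec$id,
        reason = if (length(dp)) paste0("unparseable DP '", dp[1], "'") else "missing DP")
      next
    }
    kw <- normalize_keywords(rec$values[rec$tags %in% keyword_fields])
    pt <- rec$values[rec$tags == "PT"]
    seen_ids <- c(seen_ids, rec$id)
    rows[[length(rows) + 1L]] <- list(
      doc_id = rec$id, pub_date = d$date, keywords = kw,
      record_type = if (length(pt)) tolower(pt[1]) else NA_character_,
      date_flag = d$flag)
  }

  docs <- tibble::tibble(
    doc_id = vapply(rows, `[[`, "", "doc_id"),
    pub_date = as.Date(vapply(rows, function(r) as.character(r$pub_date), "")),
    keywords = lapply(rows, `[[`, "keywords"),
    record_type = vapply(rows, `[[`, "", "record_type"),
    date_flag = vapply(rows, `[[`, "", "date_flag"))
  if (nrow(docs) == 0) docs$pub_date <- as.Date(character())

  skip_tbl <- tibble::tibble(
    doc_id = vapply(skipped, function(s) s$doc_id %||% NA_character_, ""),
    reason = vapply(skipped, `[[`, "", "reason"))
  if (nrow(skip_tbl) > 0) {
    message(nrow(skip_tbl), " record(s) skipped while parsing MEDLINE input")
  }
  attr(docs, "skipped") <- skip_tbl
  attr(docs, "n_pmid_records") <- n_pmid_records
  docs
}

# Collapse a MEDLINE block into tag/value vectors, folding indented
# continuation lines into the preceding value.  Returns NULL if the block has
# no PMID tag; otherwise a list(id, tags, values, reason).
fold_medline_block <- function(block) {
  tag_re <- "^([A-Z][A-Z0-9]{0,3})\\s*- ?(.*)$"
  tags <- character()
  values <- character()
  reason <- NULL
  for (ln in block) {
    if (grepl("^\\s+\\S", ln) && length(values)) {
      values[length(values)] <- paste(values[length(values)], trimws(ln))
    } else if (grepl(tag_re, ln)) {
      m <- regmatches(ln, regexec(tag_re, ln))[[1]]
      tags <- c(tags, m[2])
      values <- c(values, trimws(m[3]))
    } else {
      reason <- paste0("malformed line '", trimws(ln), "'")
    }
  }
  if (!"PMID" %in% tags) return(NULL)
  id <- values[tags == "PMID"][1]
  if (!nzchar(id)) return(list(id = NA_character_, reason = "empty PMID",
                               tags = tags, values = values))
  list(id = id, tags = tags, values = values, reason = reason)
}

# Parse a MEDLINE DP value ("2020 Jan 24", "2020 Jan", "2020", "2020 Jan-Feb",
# "2020 Spring").  Month names are mapped explicitly so parsing does not
# depend on the locale.  Returns list(date, flag) or NULL.
parse_dp_date <- function(dp) {
  m <- regmatches(dp, regexec(
    "^\\s*(\\d{4})(?:\\s+([A-Za-z]{3})[A-Za-z./-]*)?(?:\\s+(\\d{1,2}))?", dp))[[1]]
  if (length(m) == 0 || !nzchar(m[2])) return(NULL)
  year <- as.integer(m[2])
  mon <- match(tolower(m[3]), tolower(month.abb))
  if (!nzchar(m[3]) || is.na(mon)) {
    return(list(date = as.Date(sprintf("%04d-01-01", year)), flag = "year_only"))
  }
  if (!nzchar(m[4])) {
    return(list(date = as.Date(sprintf("%04d-%02d-01", year, mon)),
                flag = "month_only"))
  }
  d <- suppressWarnings(as.Date(sprintf("%04d-%02d-%02d", year, mon,
                                        as.integer(m[4]))))
  if (is.na(d)) return(list(date = as.Date(NA), flag = "invalid"))
  list(date = d, flag = "day")
}

# lowercase, strip MeSH qualifier after '/', strip major-topic '*', dedupe
normalize_keywords <- function(terms) {
  if (!length(terms)) return(character())
  t <- sub("/.*$", "", terms)
  t <- sub("^\\*", "", t)
  t <- tolower(trimws(t))
  unique(t[nzchar(t)])
}

#' Report of records skipped by [parse_medline()]
#'
#' @param documents A tibble returned by [parse_medline()].
#' @return A tibble with columns `doc_id` and `reason`.
#' @export
medline_skip_report <- function(documents) {
  attr(documents, "skipped") %||%
    tibble::tibble(doc_id = character(), reason = character())
}

#' Write and re-read a document corpus in tabular interchange format
#'
#' TSV with columns `doc_id`, `pub_date`, `keywords` (terms joined by `|`),
#' `record_type`, `date_flag`.  Round-tripping a parsed corpus through this
#' format reproduces it exactly.
#'
#' @param documents Corpus tibble (see [parse_medline()]).
#' @param path Output (or input) file path.
#' @return `write_documents()` returns `path` invisibly; `read_documents()`
#'   returns the corpus tibble.
#' @export
write_documents <- function(documents, path) {
  df <- documents
  df$pub_date <- format(df$pub_date, "%Y-%m-%d")
  df$keywords <- vapply(df$keywords, paste, "", collapse = "|")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_documents
#' @export
read_documents <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = "NA",
                   colClasses = "character")
  tibble::tibble(
    doc_id = df$doc_id,
    pub_date = as.Date(df$pub_date),
    keywords = lapply(df$keywords, function(k)
      if (is.na(k) || !nzchar(k)) character() else strsplit(k, "|", fixed = TRUE)[[1]]),
    record_type = df$record_type,
    date_flag = df$date_flag)
}

#' Read a policy timeline table
#'
#' Reads a CSV/TSV table of policy events with a header row naming title,
#' date, and (optionally) cluster-tag columns.  Dates may be ISO
#' (`2020-02-19`) or dotted month.day (`1.27`), the latter resolved to
#' `study_year`.  Rows are returned sorted by release date.
#'
#' @param path Path to the delimited file (delimiter sniffed from the header).
#' @param study_year Year used to resolve dotted `M.DD` dates (default 2020).
#' @return A tibble with columns `title`, `release_date` (`Date`), and
#'   `cluster_tag` (`NA` when no tag column is present).
#' @export
read_policy_table <- function(path, study_year = 2020) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  pick <- function(cands) {
    hit <- which(nm %in% cands)
    if (length(hit)) hit[1] else NA_integer_
  }
  ti <- pick(c("title", "policy", "name"))
  di <- pick(c("release_date", "date", "release", "issued"))
  gi <- pick(c("cluster_tag", "tag", "cluster", "topic"))
  if (is.na(ti) || is.na(di)) {
    stop("policy table must have title and date columns (got: ",
         paste(names(df), collapse = ", "), ")", call. = FALSE)
  }
  title <- as.character(df[[ti]])
  if (any(!nzchar(trimws(title)))) {
    stop("row ", which(!nzchar(trimws(title)))[1], ": empty policy title",
         call. = FALSE)
  }
  dates <- parse_policy_dates(as.character(df[[di]]), study_year)
  tag <- if (!is.na(gi)) as.character(df[[gi]]) else rep(NA_character_, nrow(df))
  tag[!is.na(tag) & !nzchar(trimws(tag))] <- NA_character_
  out <- tibble::tibble(title = title, release_date = dates, cluster_tag = tag)
  out[order(out$release_date), ]
}

parse_policy_dates <- function(x, study_year) {
  safe_date <- function(s) {
    tryCatch(suppressWarnings(as.Date(s)), error = function(e) as.Date(NA))
  }
  out <- rep(as.Date(NA), length(x))
  for (i in seq_along(x)) {
    v <- trimws(x[i])
    d <- if (grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", v)) {
      safe_date(v)
    } else if (grepl("^\\d{1,2}\\.\\d{1,2}$", v)) {
      parts <- as.integer(strsplit(v, ".", fixed = TRUE)[[1]])
      safe_date(sprintf("%04d-%02d-%02d", study_year, parts[1], parts[2]))
    } else {
      as.Date(NA)
    }
    if (is.na(d)) {
      stop("row ", i, ": ambiguous or invalid policy date '", x[i], "'",
           call. = FALSE)
    }
    out[i] <- d
  }
  out
}
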