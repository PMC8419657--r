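`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce to Date, failing loudly with context
as_date_strict <- function(x, what = "date") {
  d <- tryCatch(as.Date(x), error = function(e) as.Date(NA))
  if (anyNA(d)) {
    stop("invalid ", what, ": ", paste(unique(x[is.na(d)]), collapse = ", "),
         call. = FALSE)
  }
  d
}

# Evaluate `expr` under a private RNG stream seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FNV-1a 32-bit hash of a character vector; used to fingerprint pipeline
# configurations in output headers.  Arithmetic is done on doubles split into
# 16-bit halves so the 32-bit multiply never loses precision.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# TSV writer used for all tabular artifacts: a single '# config: <hash>'
# comment line, then a header row.  Deterministic byte-for-byte under a fixed
# config (no timestamps).
write_tsv_artifact <- function(df, path, config_hash = NULL) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (inherits(df[[j]], "Date")) df[[j]] <- format(df[[j]], "%Y-%m-%d")
    if (is.list(df[[j]])) df[[j]] <- vapply(df[[j]], paste, "", collapse = "|")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(config_hash)) writeLines(paste0("# config: ", config_hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

read_tsv_artifact <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t", comment.char = "#",
                               stringsAsFactors = FALSE, check.names = FALSE,
                               na.strings = ""))
}
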