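#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults matching
#' the study design this pipeline operationalizes: 10-day expanding windows
#' from 30 Dec 2019 anchored at 28 Jan 2020 through 26 Jun 2020, keyword
#' occurrence threshold 2, sum normalization, alpha 0.05, 10 imputation
#' iterations over the central 90% of the window minima, 7 clusters, and a
#' 30-day policy-wave gap.
#'
#' @param origin,anchor_end,final_end Schedule dates (see [build_schedule()]).
#' @param step_days Window step in days (default 10).
#' @param min_occurrence Keyword occurrence threshold (default 2).
#' @param normalization `"sum"` or `"max"` (see [normalize_tls()]).
#' @param alpha Significance level (default 0.05).
#' @param n_iterations Imputation iterations (default 10).
#' @param central_mass Central fraction of window minima for imputation
#'   draws (default 0.90).
#' @param k Number of trajectory clusters (default 7).
#' @param gap_days Policy-wave grouping gap (default 30).
#' @param max_pair_lag Maximum wave-pair separation counted in lags
#'   (default 30; see [cluster_lag()]).
#' @param max_waves Rising waves kept per cluster (default 2).
#' @param smooth_width Curve smoothing width for wave detection (default 0).
#' @param tail Trend-test tail (default `"left"`, flags rises).
#' @param seed Base seed for all randomness (default 1).
#' @return A classed list; its FNV-1a fingerprint is embedded in every
#'   artifact [run_pipeline()] writes.
#' @export
pipeline_config <- function(origin = "2019-12-30", anchor_end = "2020-01-28",
                            final_end = "2020-06-26", step_days = 10,
                            min_occurrence = 2, normalization = "sum",
                            alpha = 0.05, n_iterations = 10,
                            central_mass = 0.90, k = 7, gap_days = 30,
                            max_pair_lag = 30, max_waves = 2,
                            smooth_width = 0, tail = "left", seed = 1L) {
  cfg <- list(origin = format(as_date_strict(origin)),
              anchor_end = format(as_date_strict(anchor_end)),
              final_end = format(as_date_strict(final_end)),
              step_days = step_days, min_occurrence = min_occurrence,
              normalization = normalization, alpha = alpha,
              n_iterations = n_iterations, central_mass = central_mass,
              k = k, gap_days = gap_days, max_pair_lag = max_pair_lag,
              max_waves = max_waves, smooth_width = smooth_width,
              tail = tail, seed = as.integer(seed))
  stopifnot(cfg$step_days >= 1, cfg$min_occurrence >= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$n_iterations >= 1,
            cfg$central_mass > 0, cfg$central_mass <= 1, cfg$k >= 1)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  fnv1a32(jsonlite::toJSON(unclass(config), auto_unbox = TRUE))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full heat-trend and policy-lag pipeline
#'
#' Orchestrates every stage: ingest, window schedule, heat matrix, trend
#' significance, trajectory clustering, rising-wave extraction, and (when
#' policies are supplied) policy alignment.  Reruns with the same
#' configuration and inputs produce identical results; when `out_dir` is
#' given, artifacts are written deterministically (no timestamps) with the
#' configuration fingerprint in every header.
#'
#' @param config A [pipeline_config()].
#' @param documents Corpus tibble, or `NULL` to read `medline`.
#' @param medline Path to a MEDLINE file (used when `documents` is `NULL`).
#' @param policies Policy tibble (`title`, `release_date`, `cluster_tag`),
#'   or `NULL` to read `policy_table`, or omit both to skip alignment.
#' @param policy_table Path to a policy CSV/TSV.
#' @param cluster_labels Optional named character vector (cluster id ->
#'   label) or a function of the `heat_clusters` model returning one; labels
#'   connect discovered clusters to policy `cluster_tag`s.  Clusters sharing
#'   a label are pooled before wave extraction.
#' @param out_dir Optional directory for the artifact bundle.
#' @return List with `config`, `hash`, `documents`, `schedule`, `heat`,
#'   `trend`, `clusters`, `curves`, `waves`, `policy_waves`, `lag_table`,
#'   and `overall_lag` (`NULL` where a stage did not apply).
#' @export
run_pipeline <- function(config = pipeline_config(), documents = NULL,
                         medline = NULL, policies = NULL, policy_table = NULL,
                         cluster_labels = NULL, out_dir = NULL) {
  hash <- config_hash(config)

  documents <- run_stage("ingest", {
    if (is.null(documents)) {
      if (is.null(medline)) stop("no documents and no medline path")
      if (!file.exists(medline)) stop("missing input path '", medline, "'")
      parse_medline(medline)
    } else documents
  })
  policies <- run_stage("ingest", {
    if (!is.null(policies)) policies
    else if (!is.null(policy_table)) {
      if (!file.exists(policy_table)) stop("missing input path '", policy_table, "'")
      read_policy_table(policy_table)
    } else NULL
  })

  schedule <- run_stage("schedule", {
    mark_valid(build_schedule(config$origin, config$anchor_end,
                              config$step_days, config$final_end), documents)
  })
  hm <- run_stage("heat", {
    assemble_heat_matrix(documents, schedule, config$min_occurrence,
                         config$normalization)
  })
  trend <- run_stage("trend", {
    detect_significant_items(hm, alpha = config$alpha,
                             n_iterations = config$n_iterations,
                             central_mass = config$central_mass,
                             seed = config$seed, tail = config$tail)
  })

  clusters <- curves <- waves <- NULL
  sig <- significant_items(trend)
  run_stage("cluster", {
    if (length(sig) < config$k) {
      stop("only ", length(sig), " significant items for k = ", config$k)
    }
    z <- zscore_rows(completed_heat(trend)[sig, , drop = FALSE])
    clusters <- cluster_items(z, k = config$k)
    curves <- mean_curves(clusters)
  })

  labels <- run_stage("cluster", {
    if (is.function(cluster_labels)) cluster_labels(clusters)
    else if (!is.null(cluster_labels)) cluster_labels
    else setNames(rownames(curves), rownames(curves))
  })

  waves <- run_stage("waves", {
    ends <- as.Date(colnames(hm$values))
    groups <- split(names(labels), unname(labels))
    out <- lapply(names(groups), function(lab) {
      members <- names(clusters$assignment)[
        as.character(clusters$assignment) %in% groups[[lab]]]
      curve <- colMeans(clusters$z[members, , drop = FALSE])
      w <- rising_waves(curve, ends, max_waves = config$max_waves,
                        smooth_width = config$smooth_width)
      if (nrow(w)) cbind(tibble::tibble(cluster = lab), w) else NULL
    })
    out <- do.call(rbind, out)
    if (is.null(out)) {
      tibble::tibble(cluster = character(), wave = integer(),
                     start = as.Date(character()), end = as.Date(character()),
                     rise = numeric(), start_window = integer(),
                     end_window = integer())
    } else tibble::as_tibble(out)
  })

  policy_waves <- lag_table <- overall <- NULL
  if (!is.null(policies)) {
    policy_waves <- run_stage("lag", group_policy_waves(policies, config$gap_days))
    shared <- intersect(unique(policy_waves$cluster), unique(waves$cluster))
    if (length(shared)) {
      lag_table <- run_stage("lag", {
        build_lag_table(policy_waves[policy_waves$cluster %in% shared, ],
                        waves[waves$cluster %in% shared, ],
                        max_pair_lag = config$max_pair_lag)
      })
      overall <- if (any(lag_table$defined)) {
        run_stage("lag", overall_mean_lag(lag_table))
      } else {
        message("no cluster has a defined lag; overall mean lag is NA")
        NA_real_
      }
    }
  }

  result <- list(config = config, hash = hash, documents = documents,
                 schedule = schedule, heat = hm, trend = trend,
                 clusters = clusters, curves = curves, waves = waves,
                 policy_waves = policy_waves, lag_table = lag_table,
                 overall_lag = overall)
  if (!is.null(out_dir)) {
    run_stage("write", write_pipeline_outputs(result, out_dir))
  }
  result
}

# Write the artifact bundle: TSVs with the config hash as a comment header
# plus one JSON summary.  Every file is a pure function of config + inputs.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- result$hash
  p <- function(f) file.path(out_dir, f)

  write_tsv_artifact(result$schedule, p("schedule.tsv"), h)

  hm <- result$heat
  heat_df <- data.frame(item = rownames(hm$values), hm$values,
                        check.names = FALSE)
  write_tsv_artifact(heat_df, p("heat_matrix.tsv"), h)

  write_tsv_artifact(result$trend, p("trend.tsv"), h)
  write_tsv_artifact(window_counts(result$trend), p("window_counts.tsv"), h)

  write_tsv_artifact(
    tibble::tibble(item = names(result$clusters$assignment),
                   cluster = unname(result$clusters$assignment)),
    p("clusters.tsv"), h)
  curves_df <- data.frame(cluster = rownames(result$curves), result$curves,
                          check.names = FALSE)
  write_tsv_artifact(curves_df, p("mean_curves.tsv"), h)
  write_tsv_artifact(result$waves, p("waves.tsv"), h)

  if (!is.null(result$policy_waves)) {
    write_tsv_artifact(result$policy_waves, p("policy_waves.tsv"), h)
  }
  if (!is.null(result$lag_table)) {
    write_tsv_artifact(result$lag_table, p("lag_table.tsv"), h)
    jsonlite::write_json(
      list(config = unclass(result$config), config_hash = h,
           lag_table = as.data.frame(lag_table_for_json(result$lag_table)),
           overall_mean_lag = result$overall_lag),
      p("lag_report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
      na = "null")
  }
  jsonlite::write_json(
    list(config_hash = h,
         n_documents = nrow(result$documents),
         n_windows = nrow(result$schedule),
         n_valid_windows = sum(result$schedule$valid),
         n_items = nrow(result$heat$values),
         n_significant_items = length(significant_items(result$trend)),
         n_clusters = result$config$k),
    p("run_log.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

lag_table_for_json <- function(lt) {
  lt <- as.data.frame(lt)
  lt
}
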