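# End-to-end orchestration: one configuration in, one artifact directory out.
#
# Patterns come either from the synthetic generator or from pattern tables on
# disk; each patient runs through cluster detection, TLS flagging and the full
# metric registry; cohort comparisons, cluster tables, size distributions and
# survival stratification are written as TSV/JSON under the output directory
# together with a run manifest. Identical configuration and seed give
# byte-identical metric tables.

#' Build and validate a pipeline configuration
#'
#' Defaults reproduce the analysis constants: L ladder spanning 10-600 um,
#' FD scale windows 10-40 and 200-600 um, LC detection at eps 20 um /
#' min_pts 5, TLS at 200 lymphocytes / 70 um.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param out_dir artifact directory (created if needed).
#' @param seed master seed for synthetic mode.
#' @param n_good,n_poor synthetic cohort sizes.
#' @param profiles synthetic outcome profiles (see [default_profiles()]).
#' @param window synthetic window.
#' @param files character vector of pattern tables (files mode).
#' @param manifest optional cohort manifest CSV with columns patient_id,
#'   outcome, rfs_months, event (files mode).
#' @param L_ladder,small_window,large_window grid constants.
#' @param cluster_params,tls_params detection constants.
#' @param rfs_metric registry metric used for survival stratification.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"), out_dir,
                            seed = 1, n_good = 24, n_poor = 12,
                            profiles = default_profiles(),
                            window = til_window(2000, 2000),
                            files = NULL, manifest = NULL,
                            L_ladder = default_L_ladder(),
                            small_window = c(10, 40),
                            large_window = c(200, 600),
                            cluster_params = tilspatial::cluster_params(),
                            tls_params = tilspatial::cluster_params(70, 200),
                            rfs_metric = "fd_delta_B_stroma") {
  mode <- match.arg(mode)
  if (length(L_ladder) == 0 || any(!is.finite(L_ladder)) || any(L_ladder <= 0))
    stop("config error: L_ladder must be non-empty and positive", call. = FALSE)
  if (mode == "files") {
    if (is.null(files) || length(files) == 0)
      stop("config error: files mode needs at least one pattern table", call. = FALSE)
  } else {
    if (n_good < 0 || n_poor < 0)
      stop("config error: cohort sizes must be >= 0", call. = FALSE)
  }
  if (!rfs_metric %in% metric_registry())
    stop("config error: unknown rfs_metric ", rfs_metric, call. = FALSE)
  structure(
    list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
         n_good = n_good, n_poor = n_poor, profiles = profiles,
         window = window, files = files, manifest = manifest,
         L_ladder = sort(unique(L_ladder)), small_window = small_window,
         large_window = large_window, cluster_params = cluster_params,
         tls_params = tls_params, rfs_metric = rfs_metric),
    class = "pipeline_config"
  )
}

load_cohort <- function(config) {
  if (config$mode == "synthetic") {
    synthesize_cohort(config$n_good, config$n_poor, config$profiles,
                      config$window, config$seed)
  } else {
    patterns <- lapply(config$files, read_pattern_table)
    names(patterns) <- vapply(patterns, `[[`, character(1), "patient_id")
    surv <- NULL
    if (!is.null(config$manifest)) {
      man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
      for (i in seq_along(patterns)) {
        j <- match(patterns[[i]]$patient_id, man$patient_id)
        if (!is.na(j) && man$outcome[j] %in% OUTCOME_LEVELS)
          patterns[[i]]$outcome <- man$outcome[j]
      }
      if (all(c("rfs_months", "event") %in% names(man)))
        surv <- man[c("patient_id", "outcome", "rfs_months", "event")]
    }
    list(patterns = patterns, survival = surv)
  }
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @return the output directory, invisibly. Artifacts: `patient_metrics.tsv`,
#'   `clusters.tsv`, `size_distributions.tsv`, `comparisons.json`,
#'   `km_curves.tsv` (+ `rfs_threshold.json`) when survival data exist, and
#'   `manifest.json` (configuration constants, seed, package version, skipped
#'   patients). A patient failing validation is skipped with a logged reason;
#'   the run fails if more than 20 percent are skipped.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- load_cohort(config)
  patterns <- cohort$patterns

  metrics <- list(); clusters_tab <- list(); skipped <- list()
  all_clusters <- list()
  for (pid in names(patterns)) {
    res <- tryCatch({
      pat <- patterns[[pid]]
      det <- detect_clusters(pat, config$cluster_params)
      cl <- detect_tls(pat, det$clusters, config$tls_params)
      summ <- patient_summary(pat, clusters = cl,
                              params = config$cluster_params,
                              tls_params = config$tls_params,
                              Ls = config$L_ladder,
                              small_window = config$small_window,
                              large_window = config$large_window)
      list(summary = summ, clusters = cl,
           table = cluster_table(cl, pid))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[pid]] <- conditionMessage(res)
    } else {
      metrics[[pid]] <- res$summary
      clusters_tab[[pid]] <- res$table
      all_clusters[[pid]] <- res$clusters
    }
  }
  if (length(skipped) > 0.2 * length(patterns))
    stop(sprintf("pipeline failed: %d of %d patients skipped",
                 length(skipped), length(patterns)), call. = FALSE)

  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  utils::write.table(metrics, file.path(config$out_dir, "patient_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ctab <- do.call(rbind, clusters_tab)
  utils::write.table(ctab, file.path(config$out_dir, "clusters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # pooled size distributions per outcome x type (descriptive export)
  dist_rows <- list()
  for (o in c("good", "poor")) {
    pids <- metrics$patient_id[metrics$outcome == o]
    pooled <- unlist(lapply(all_clusters[pids], identity), recursive = FALSE)
    for (ty in c("heterotypic", "pure_T")) {
      sd_ <- tryCatch(size_distribution(pooled, ty, o), error = function(e) NULL)
      if (!is.null(sd_)) {
        sd_$outcome <- o; sd_$lc_type <- ty
        dist_rows[[paste(o, ty)]] <- as.data.frame(sd_)
      }
    }
  }
  if (length(dist_rows) > 0)
    utils::write.table(do.call(rbind, dist_rows),
                       file.path(config$out_dir, "size_distributions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  comparisons <- compare_all_metrics(metrics)
  jsonlite::write_json(comparisons,
                       file.path(config$out_dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!is.null(cohort$survival) &&
      sum(metrics$outcome %in% c("good", "poor")) >= 3) {
    v <- stats::setNames(metrics[[config$rfs_metric]], metrics$patient_id)
    strat <- tryCatch(stratify_rfs(cohort$survival, v), error = function(e) NULL)
    if (!is.null(strat)) {
      utils::write.table(strat$km$curves,
                         file.path(config$out_dir, "km_curves.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(metric = config$rfs_metric, threshold = strat$threshold,
             logrank_p = strat$km$logrank_p),
        file.path(config$out_dir, "rfs_threshold.json"),
        auto_unbox = TRUE, digits = NA)
    }
    utils::write.table(cohort$survival,
                       file.path(config$out_dir, "survival.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    mode = config$mode, seed = config$seed,
    n_patients = length(patterns), n_analyzed = nrow(metrics),
    skipped = skipped,
    constants = list(
      L_ladder = config$L_ladder, small_window = config$small_window,
      large_window = config$large_window,
      cluster_eps = config$cluster_params$eps,
      cluster_min_pts = config$cluster_params$min_pts,
      tls_eps = config$tls_params$eps,
      tls_min_pts = config$tls_params$min_pts,
      rfs_metric = config$rfs_metric),
    package_version = as.character(utils::packageVersion("tilspatial")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' Compare every registry metric between good and poor patients
#'
#' @param metrics per-patient metrics table from [run_pipeline()] /
#'   [patient_summary()].
#' @return named list (metric -> means, n, t_p, t_p_welch, roc_auc, mw_p);
#'   metrics without at least two finite values per group are reported with
#'   a `skipped` reason.
#' @export
compare_all_metrics <- function(metrics) {
  out <- list()
  for (m in intersect(metric_registry(), names(metrics))) {
    g <- metrics[[m]][metrics$outcome == "good"]
    p <- metrics[[m]][metrics$outcome == "poor"]
    if (sum(is.finite(g)) >= 2 && sum(is.finite(p)) >= 2) {
      cmp <- compare_groups(g, p)
      out[[m]] <- cmp[c("mean_good", "mean_poor", "n_good", "n_poor",
                        "t_p", "t_p_welch", "roc_auc", "mw_p")]
    } else {
      out[[m]] <- list(skipped = "fewer than 2 finite values in a group")
    }
  }
  out
}

#' Render a human-readable summary of a completed run
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param file optional output path; default `report.txt` inside `run_dir`.
#' @return the report lines, invisibly.
#' @export
make_report <- function(run_dir, file = file.path(run_dir, "report.txt")) {
  need <- c("patient_metrics.tsv", "comparisons.json", "manifest.json")
  for (f in need) {
    if (!file.exists(file.path(run_dir, f)))
      stop("missing artifact for stage '", sub("\\..*$", "", f), "': ", f,
           call. = FALSE)
  }
  metrics <- utils::read.delim(file.path(run_dir, "patient_metrics.tsv"))
  comp <- jsonlite::read_json(file.path(run_dir, "comparisons.json"),
                              simplifyVector = TRUE)
  man <- jsonlite::read_json(file.path(run_dir, "manifest.json"),
                             simplifyVector = TRUE)
  lines <- c(
    sprintf("tilspatial run (%s mode, seed %s): %s of %s patients analyzed",
            man$mode, man$seed, man$n_analyzed, man$n_patients),
    sprintf("good %d / poor %d", sum(metrics$outcome == "good"),
            sum(metrics$outcome == "poor")),
    "",
    sprintf("%-36s %12s %12s %8s %8s %8s", "metric", "mean(good)",
            "mean(poor)", "t p", "ROC AUC", "MW p")
  )
  for (m in names(comp)) {
    c_ <- comp[[m]]
    if (!is.null(c_$skipped)) {
      lines <- c(lines, sprintf("%-36s skipped: %s", m, c_$skipped))
    } else {
      num <- function(z) if (is.null(z)) NA_real_ else suppressWarnings(as.numeric(z))
      lines <- c(lines, sprintf("%-36s %12.4g %12.4g %8.3g %8.3f %8.3g", m,
                                num(c_$mean_good), num(c_$mean_poor),
                                num(c_$t_p), num(c_$roc_auc), num(c_$mw_p)))
    }
  }
  if (length(man$skipped) > 0) {
    lines <- c(lines, "", "skipped patients:",
               sprintf("  %s: %s", names(man$skipped), unlist(man$skipped)))
  }
  writeLines(lines, file)
  invisible(lines)
}

#' Headline benchmark metrics from a converted deposited cohort
#'
#' Runs the files-mode pipeline over pattern CSVs converted from a deposited
#' point-pattern record (see [read_deposited_patterns()]) and extracts the
#' cohort means of the headline metrics: B-in-islands density, stromal-B FD
#' difference, heterotypic LC count per cm^2, mean heterotypic LC-island
#' distance, and overall B density, per outcome group.
#'
#' @param csv_dir directory of per-patient pattern CSVs.
#' @param manifest cohort manifest CSV (patient_id, outcome, rfs_months,
#'   event).
#' @param out_dir artifact directory.
#' @return named list of group means.
#' @export
benchmark_deposited <- function(csv_dir, manifest,
                                out_dir = file.path(csv_dir, "benchmark_run")) {
  files <- list.files(csv_dir, pattern = "\\.csv$", full.names = TRUE)
  config <- pipeline_config("files", out_dir = out_dir, files = files,
                            manifest = manifest)
  run_pipeline(config)
  metrics <- utils::read.delim(file.path(out_dir, "patient_metrics.tsv"))
  gm <- function(metric, o) mean(metrics[[metric]][metrics$outcome == o],
                                 na.rm = TRUE)
  list(
    density_B_island_good = gm("density_B_island", "good"),
    density_B_island_poor = gm("density_B_island", "poor"),
    fd_delta_B_stroma_good = gm("fd_delta_B_stroma", "good"),
    fd_delta_B_stroma_poor = gm("fd_delta_B_stroma", "poor"),
    lc_count_per_cm2_heterotypic_good = gm("lc_count_per_cm2_heterotypic", "good"),
    lc_count_per_cm2_heterotypic_poor = gm("lc_count_per_cm2_heterotypic", "poor"),
    mean_island_distance_heterotypic_good = gm("mean_island_distance_heterotypic", "good"),
    mean_island_distance_heterotypic_poor = gm("mean_island_distance_heterotypic", "poor"),
    density_B_any_good = gm("density_B_any", "good"),
    density_B_any_poor = gm("density_B_any", "poor")
  )
}
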