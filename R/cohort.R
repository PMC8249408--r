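# Per-patient metric assembly and cohort-level statistics.
#
# Cohort values are always means of per-patient values (cells are never pooled
# across patients before averaging). Group comparison reports the classical
# equal-variance two-sided Student t-test (a Welch variant alongside), the ROC
# AUC as the probability that a random good value exceeds a random poor value
# with ties counted 1/2, and the two-sided Mann-Whitney p-value. Relapse-free
# survival uses the product-limit estimator with a threshold placed so that
# two thirds of patients fall in the upper stratum.

#' Names of the per-patient metric registry
#'
#' Every [patient_summary()] row carries exactly these metric columns; a
#' metric that cannot be computed for a patient (for instance a fractal
#' dimension with too few occupied squares, or a cluster-type summary with no
#' clusters of the type) is `NA` -- explicitly missing, never silently zero.
#'
#' @return character vector of metric names.
#' @export
metric_registry <- function() {
  c(
    "density_B_any", "density_B_island", "density_B_stroma",
    "density_T_any", "density_T_island", "density_T_stroma",
    "density_lymph_any", "density_lymph_island", "density_lymph_stroma",
    "density_isolated_lymph_island", "density_isolated_B_island",
    "density_isolated_T_island", "density_isolated_lymph_stroma",
    "density_isolated_B_stroma", "density_isolated_T_stroma",
    "occ_auc_B_stroma", "occ_auc_T_stroma",
    "occ_auc_B_island", "occ_auc_T_island",
    "occ_auc_B_het_lc", "occ_auc_T_het_lc", "occ_auc_T_pure_lc",
    "fd_small_B_stroma", "fd_large_B_stroma", "fd_delta_B_stroma",
    "fd_small_T_stroma", "fd_large_T_stroma", "fd_delta_T_stroma",
    "fd_delta_B_island", "fd_delta_T_island",
    "fd_delta_B_het_lc", "fd_delta_T_het_lc", "fd_delta_T_pure_lc",
    "lc_count_per_cm2_all", "lc_count_per_cm2_heterotypic",
    "lc_count_per_cm2_pure_T",
    "mean_lc_size_heterotypic", "median_lc_size_heterotypic",
    "mean_lc_size_pure_T", "median_lc_size_pure_T",
    "mean_island_distance_heterotypic", "median_island_distance_heterotypic",
    "mean_island_distance_pure_T", "median_island_distance_pure_T",
    "frac_isolated_lymph_island", "frac_isolated_lymph_stroma",
    "frac_B_in_lc", "frac_T_in_lc", "frac_lymph_in_tls", "frac_B_in_tls",
    "mean_B_prop_het_lc", "tls_count"
  )
}

safe_metric <- function(expr) {
  tryCatch(expr, error = function(e) NA_real_, warning = function(w) {
    tryCatch(suppressWarnings(expr), error = function(e) NA_real_)
  })
}

#' Assemble the full per-patient metric registry
#'
#' Runs cluster detection (unless supplied), TLS flagging and membership
#' annotation, then computes every metric in [metric_registry()]: densities by
#' phenotype, tissue compartment and isolation; occupancy AUCs and fractal
#' dimension small/large/difference for the registry's binary questions; LC
#' counts per cm^2, size and island-distance summaries per cluster type;
#' membership fractions; and TLS summaries.
#'
#' @param pattern a valid `til_pattern`.
#' @param clusters optional precomputed cluster list (TLS flags will be added
#'   if absent).
#' @param params [cluster_params()] for LC detection.
#' @param tls_params [cluster_params()] for TLS flagging.
#' @param Ls L-ladder for occupancy and FD.
#' @param small_window,large_window FD scale windows in micrometers.
#' @return one-row data frame: `patient_id`, `outcome`, then the registry.
#' @export
patient_summary <- function(pattern, clusters = NULL,
                            params = cluster_params(),
                            tls_params = cluster_params(70, 200),
                            Ls = default_L_ladder(),
                            small_window = c(10, 40),
                            large_window = c(200, 600)) {
  if (is.null(clusters)) {
    det <- detect_clusters(pattern, params)
    clusters <- det$clusters
  }
  clusters <- detect_tls(pattern, clusters, tls_params)
  ann <- annotate_membership(pattern, clusters)
  area <- pattern$roi$area_mm2
  out <- stats::setNames(as.list(rep(NA_real_, length(metric_registry()))),
                         metric_registry())

  dens <- function(ph, sc, ms = "any")
    safe_metric(region_density(ann, ph, sc, ms)$density)
  out$density_B_any <- dens("B", "any")
  out$density_B_island <- dens("B", "cancer_island")
  out$density_B_stroma <- dens("B", "stroma")
  out$density_T_any <- dens("T", "any")
  out$density_T_island <- dens("T", "cancer_island")
  out$density_T_stroma <- dens("T", "stroma")
  out$density_lymph_any <- dens("lymphocyte", "any")
  out$density_lymph_island <- dens("lymphocyte", "cancer_island")
  out$density_lymph_stroma <- dens("lymphocyte", "stroma")
  out$density_isolated_lymph_island <- dens("lymphocyte", "cancer_island", "isolated_only")
  out$density_isolated_B_island <- dens("B", "cancer_island", "isolated_only")
  out$density_isolated_T_island <- dens("T", "cancer_island", "isolated_only")
  out$density_isolated_lymph_stroma <- dens("lymphocyte", "stroma", "isolated_only")
  out$density_isolated_B_stroma <- dens("B", "stroma", "isolated_only")
  out$density_isolated_T_stroma <- dens("T", "stroma", "isolated_only")

  questions <- list(
    B_stroma = binary_question("B", "stroma"),
    T_stroma = binary_question("T", "stroma"),
    B_island = binary_question("B", "cancer_island"),
    T_island = binary_question("T", "cancer_island"),
    B_het_lc = binary_question("B", membership_scope = "in_heterotypic_lc"),
    T_het_lc = binary_question("T", membership_scope = "in_heterotypic_lc"),
    T_pure_lc = binary_question("T", membership_scope = "in_pure_t_lc")
  )
  for (qn in names(questions)) {
    curve <- safe_metric({
      occupancy_curve(ann, Ls, questions[[qn]])
    })
    if (length(curve) == 1 && is.na(curve)) next
    out[[paste0("occ_auc_", qn)]] <- safe_metric(occupancy_auc(curve))
    fs <- tryCatch(fit_fd_curve(curve, small_window), error = function(e) NULL)
    fl <- tryCatch(fit_fd_curve(curve, large_window), error = function(e) NULL)
    small_name <- paste0("fd_small_", qn)
    large_name <- paste0("fd_large_", qn)
    if (small_name %in% names(out) && !is.null(fs)) out[[small_name]] <- fs$slope_s
    if (large_name %in% names(out) && !is.null(fl)) out[[large_name]] <- fl$slope_s
    if (!is.null(fs) && !is.null(fl))
      out[[paste0("fd_delta_", qn)]] <- fl$slope_s - fs$slope_s
  }
  types <- vapply(clusters, `[[`, character(1), "lc_type")
  sizes <- vapply(clusters, `[[`, numeric(1), "size_s")
  area_cm2 <- area / 100
  out$lc_count_per_cm2_all <- length(clusters) / area_cm2
  out$lc_count_per_cm2_heterotypic <- sum(types == "heterotypic") / area_cm2
  out$lc_count_per_cm2_pure_T <- sum(types == "pure_T") / area_cm2

  dist_tab <- if (length(clusters) > 0)
    suppressWarnings(cluster_island_distances(clusters, pattern))
  else NULL
  for (ty in c("heterotypic", "pure_T")) {
    sel <- types == ty
    if (any(sel)) {
      out[[paste0("mean_lc_size_", ty)]] <- mean(sizes[sel])
      out[[paste0("median_lc_size_", ty)]] <- stats::median(sizes[sel])
      d <- dist_tab$distance_um[dist_tab$lc_type == ty]
      if (length(d) > 0 && all(is.finite(d))) {
        out[[paste0("mean_island_distance_", ty)]] <- mean(d)
        out[[paste0("median_island_distance_", ty)]] <- stats::median(d)
      }
    }
  }

  mf <- membership_fractions(ann)
  pick <- function(sc, g, col) {
    v <- mf[[col]][mf$tissue_scope == sc & mf$phenotype_group == g]
    if (length(v) == 1) v else NA_real_
  }
  out$frac_isolated_lymph_island <- pick("cancer_island", "lymphocyte", "frac_isolated")
  out$frac_isolated_lymph_stroma <- pick("stroma", "lymphocyte", "frac_isolated")
  out$frac_B_in_lc <- pick("any", "B", "frac_in_lc")
  out$frac_T_in_lc <- pick("any", "T", "frac_in_lc")
  out$frac_lymph_in_tls <- pick("any", "lymphocyte", "frac_in_tls")
  out$frac_B_in_tls <- pick("any", "B", "frac_in_tls")
  out$mean_B_prop_het_lc <- safe_metric(
    composition_proportions(clusters, "heterotypic")[["B"]])
  out$tls_count <- sum(vapply(clusters, `[[`, logical(1), "is_tls"))

  cbind(data.frame(patient_id = pattern$patient_id, outcome = pattern$outcome,
                   stringsAsFactors = FALSE),
        as.data.frame(out))
}

#' ROC area under the curve by pair counting semantics
#'
#' `P(good > poor) + P(good = poor) / 2`, computed from ranks (the scaled
#' Mann-Whitney U statistic). The metric's direction is not flipped: values
#' below 0.5 mean the poor group tends to be larger.
#'
#' @param values_good,values_poor numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(values_good, values_poor) {
  ng <- length(values_good); np <- length(values_poor)
  if (ng == 0 || np == 0) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(values_good, values_poor))
  (sum(r[seq_len(ng)]) - ng * (ng + 1) / 2) / (ng * np)
}

#' Compare a metric between outcome groups
#'
#' @param values_good,values_poor per-patient metric values (NAs dropped).
#' @return list of class `cohort_comparison`: group means and sizes,
#'   `t_p` (two-sided equal-variance Student t-test), `t_p_welch`,
#'   `roc_auc`, `mw_p` (two-sided Mann-Whitney).
#' @export
compare_groups <- function(values_good, values_poor) {
  values_good <- values_good[is.finite(values_good)]
  values_poor <- values_poor[is.finite(values_poor)]
  if (length(values_good) == 0 || length(values_poor) == 0)
    stop("both groups must contain values", call. = FALSE)
  degenerate <- stats::var(c(values_good, values_poor)) == 0
  t_p <- if (length(values_good) >= 2 && length(values_poor) >= 2 && !degenerate)
    stats::t.test(values_good, values_poor, var.equal = TRUE)$p.value
  else if (degenerate) 1 else NA_real_
  t_p_welch <- if (length(values_good) >= 2 && length(values_poor) >= 2 && !degenerate)
    stats::t.test(values_good, values_poor)$p.value
  else if (degenerate) 1 else NA_real_
  mw_p <- suppressWarnings(
    stats::wilcox.test(values_good, values_poor, exact = FALSE)$p.value)
  structure(
    list(mean_good = mean(values_good), mean_poor = mean(values_poor),
         n_good = length(values_good), n_poor = length(values_poor),
         t_p = t_p, t_p_welch = t_p_welch,
         roc_auc = roc_auc(values_good, values_poor), mw_p = mw_p),
    class = "cohort_comparison"
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf(
    "<cohort_comparison> good %.4g (n=%d) vs poor %.4g (n=%d): t p=%.3g, ROC AUC=%.3f, MW p=%.3g\n",
    x$mean_good, x$n_good, x$mean_poor, x$n_poor, x$t_p, x$roc_auc, x$mw_p))
  invisible(x)
}

#' Two-thirds survival-stratification threshold
#'
#' Places the threshold so that two thirds of patients fall in the upper
#' stratum and one third in the lower: the ceiling(n/3)-th smallest value,
#' interpolated midway to the next distinct value. If ties straddle the cut,
#' the largest midpoint threshold keeping at least floor(2n/3) patients
#' strictly above is chosen; failing that, the midpoint whose upper stratum is
#' largest.
#'
#' @param values per-patient metric (>= 3 values, not all identical).
#' @return scalar threshold.
#' @export
rfs_threshold <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("need >= 3 values", call. = FALSE)
  d <- sort(unique(values))
  if (length(d) == 1) stop("degenerate threshold: all values identical", call. = FALSE)
  target <- floor(2 * n / 3)
  mids <- (utils::head(d, -1) + utils::tail(d, -1)) / 2
  above <- vapply(mids, function(m) sum(values > m), numeric(1))
  feasible <- above >= target
  if (any(feasible)) max(mids[feasible])
  else mids[which.max(above)]
}

#' Kaplan-Meier estimate per stratum
#'
#' Product-limit estimator via the survival package; censored records shrink
#' the risk set only. A log-rank test accompanies the curves as a standard
#' companion statistic.
#'
#' @param records data frame with columns `time` (> 0), `event` (0/1) and
#'   `stratum`.
#' @return list with `curves` (data frame stratum, time, n_risk, n_event,
#'   surv) and `logrank_p` (`NA` with a single stratum).
#' @export
km_estimate <- function(records) {
  stopifnot(all(c("time", "event", "stratum") %in% names(records)),
            all(records$time > 0))
  records$stratum <- as.factor(records$stratum)
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum,
                           data = records)
  strata_names <- if (is.null(fit$strata)) levels(records$stratum)[1]
  else sub("^stratum=", "", names(fit$strata))
  stratum <- rep(strata_names,
                 if (is.null(fit$strata)) length(fit$time) else fit$strata)
  curves <- data.frame(stratum = stratum, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       surv = fit$surv, stringsAsFactors = FALSE)
  logrank_p <- if (nlevels(records$stratum) > 1) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ stratum,
                             data = records)
    stats::pchisq(sd$chisq, df = nlevels(records$stratum) - 1,
                  lower.tail = FALSE)
  } else NA_real_
  list(curves = curves, logrank_p = logrank_p)
}

#' Stratify survival records by a metric threshold
#'
#' @param survival_tab data frame (patient_id, rfs_months, event).
#' @param metric named numeric vector (names = patient ids) or data frame
#'   with patient_id and value columns.
#' @param threshold cut value; default from [rfs_threshold()].
#' @return list: `records` with `stratum` in {above_threshold,
#'   below_threshold}, `threshold`, `km` from [km_estimate()].
#' @export
stratify_rfs <- function(survival_tab, metric, threshold = NULL) {
  if (is.data.frame(metric)) {
    metric <- stats::setNames(metric[[2]], metric[[1]])
  }
  v <- metric[survival_tab$patient_id]
  ok <- is.finite(v)
  tab <- survival_tab[ok, , drop = FALSE]
  v <- v[ok]
  if (is.null(threshold)) threshold <- rfs_threshold(v)
  records <- data.frame(
    patient_id = tab$patient_id,
    time = tab$rfs_months, event = tab$event,
    stratum = ifelse(v > threshold, "above_threshold", "below_threshold"),
    stringsAsFactors = FALSE
  )
  list(records = records, threshold = threshold, km = km_estimate(records))
}
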