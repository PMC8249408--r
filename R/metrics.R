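# Region-resolved densities, membership fractions, and LC-to-cancer-island
# distances. Every density uses the full ROI area as denominator, never the
# island or stroma area alone, so densities over tissue compartments add up
# exactly to the overall density.

#' Region- and membership-resolved cell density
#'
#' Counts cells matching a phenotype set, tissue scope and membership scope,
#' divided by the full ROI area in mm^2.
#'
#' @param pattern a `til_pattern` (annotated via [annotate_membership()] when
#'   a membership scope is used).
#' @param phenotypes phenotype set (expanded as in [binary_question()]).
#' @param tissue_scope `any`, `cancer_island` or `stroma`.
#' @param membership_scope `any`, `isolated_only`, `in_lc_only`,
#'   `in_heterotypic_lc` or `in_pure_t_lc`.
#' @return list with `count` and `density` (cells per mm^2).
#' @export
region_density <- function(pattern, phenotypes, tissue_scope = "any",
                           membership_scope = "any") {
  if (pattern$roi$area_mm2 <= 0) stop("ROI area must be positive", call. = FALSE)
  q <- binary_question(phenotypes, tissue_scope, membership_scope)
  count <- sum(cells_matching(pattern, q))
  list(count = count, density = count / pattern$roi$area_mm2)
}

#' Fractions of lymphocytes isolated, in LCs, and in TLS
#'
#' Computed overall and per tissue scope and phenotype group. Within each
#' scope the isolated and in-LC fractions sum to 1 and the TLS fraction is at
#' most the in-LC fraction. Scopes holding zero lymphocytes report `NA`
#' fractions (missing, not zero).
#'
#' @param pattern an annotated `til_pattern` (see [annotate_membership()]).
#' @return data frame with columns `tissue_scope`, `phenotype_group`,
#'   `n_lymphocytes`, `frac_isolated`, `frac_in_lc`, `frac_in_tls`.
#' @export
membership_fractions <- function(pattern) {
  cells <- pattern$cells
  if (is.null(cells$in_lc))
    stop("pattern must be annotated with annotate_membership()", call. = FALSE)
  scopes <- c("any", "cancer_island", "stroma")
  groups <- list(lymphocyte = LYMPHOCYTE_PHENOTYPES, B = "B",
                 T = T_LINEAGE_PHENOTYPES)
  rows <- list()
  for (sc in scopes) for (g in names(groups)) {
    sel <- cells$phenotype %in% groups[[g]]
    if (sc != "any") sel <- sel & cells$tissue_category == sc
    n <- sum(sel)
    rows[[length(rows) + 1L]] <- data.frame(
      tissue_scope = sc, phenotype_group = g, n_lymphocytes = n,
      frac_isolated = if (n > 0) sum(sel & !cells$in_lc) / n else NA_real_,
      frac_in_lc = if (n > 0) sum(sel & cells$in_lc) / n else NA_real_,
      frac_in_tls = if (n > 0) sum(sel & cells$is_tls) / n else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Shortest distance from a cluster to the nearest cancer island
#'
#' Exact minimum Euclidean distance over all (cluster member, cancer cell)
#' pairs, where cancer cells are those with phenotype `cancer` carrying the
#' `cancer_island` tissue mark. Zero iff a member coincides with a cancer
#' cell; `NA` with a warning when the pattern has no cancer cells.
#'
#' @param cluster a `til_cluster`.
#' @param pattern the pattern it was detected on.
#' @return distance in micrometers (scalar).
#' @export
cluster_island_distance <- function(cluster, pattern) {
  cells <- pattern$cells
  tgt <- cells$phenotype == "cancer" & cells$tissue_category == "cancer_island"
  if (!any(tgt)) {
    warning("pattern has no cancer-island cells; distance is NA", call. = FALSE)
    return(NA_real_)
  }
  idx <- match(cluster$members, cells$cell_id)
  tx <- cells$x[tgt]; ty <- cells$y[tgt]
  best <- Inf
  # block over members to bound the pairwise matrix
  for (chunk in split(idx, ceiling(seq_along(idx) / 512))) {
    dx <- outer(cells$x[chunk], tx, "-")
    dy <- outer(cells$y[chunk], ty, "-")
    best <- min(best, min(dx^2 + dy^2))
  }
  sqrt(best)
}

#' Distances for every cluster in a pattern
#'
#' @param clusters cluster list from [detect_clusters()].
#' @param pattern the pattern they were detected on.
#' @param patient_id id stamped on every row.
#' @return data frame (patient_id, cluster_id, lc_type, size, distance_um).
#' @export
cluster_island_distances <- function(clusters, pattern,
                                     patient_id = pattern$patient_id) {
  data.frame(
    patient_id = rep(patient_id, length(clusters)),
    cluster_id = vapply(clusters, `[[`, numeric(1), "cluster_id"),
    lc_type = vapply(clusters, `[[`, character(1), "lc_type"),
    size = vapply(clusters, `[[`, numeric(1), "size_s"),
    distance_um = vapply(clusters, cluster_island_distance, numeric(1),
                         pattern = pattern),
    stringsAsFactors = FALSE
  )
}

#' Pearson correlation between per-patient LC size and island distance
#'
#' @param mean_size,mean_distance numeric vectors, one entry per patient.
#' @return list with `r`, `p` (two-sided, t transform), `n`.
#' @export
size_distance_correlation <- function(mean_size, mean_distance) {
  ok <- is.finite(mean_size) & is.finite(mean_distance)
  x <- mean_size[ok]; y <- mean_distance[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
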