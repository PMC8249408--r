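# Density-based detection and typing of lymphocyte clusters (LCs).
#
# An LC is at least `min_pts` lymphocytes within a circle of radius `eps`:
# defaults eps = 20 um (circle radius, i.e. a 40 um diameter) and min_pts = 5
# counting the center cell, so five contiguous 10 um cells along a line form
# one cluster. Clustering is DBSCAN semantics: core cells have >= min_pts
# lymphocytes (themselves included) within eps; clusters are maximal
# density-connected sets of core cells plus their border cells; remaining
# lymphocytes are "isolated". Border cells reachable from several clusters
# join the cluster of their lowest-indexed core neighbor in stable input
# order, which makes the partition deterministic. Tertiary lymphoid
# structures (TLS) are the dense subset of LCs holding >= 200 lymphocytes
# within a 70 um radius.

#' Density-clustering parameters
#'
#' @param eps neighborhood radius in micrometers (> 0).
#' @param min_pts minimum neighborhood count including the center cell (>= 2).
#' @return object of class `cluster_params`.
#' @export
cluster_params <- function(eps = 20, min_pts = 5) {
  if (!is.finite(eps) || eps <= 0) stop("eps must be > 0", call. = FALSE)
  if (!is.finite(min_pts) || min_pts < 2) stop("min_pts must be >= 2", call. = FALSE)
  structure(list(eps = eps, min_pts = as.integer(min_pts)),
            class = "cluster_params")
}

# Neighbor lists within eps via grid binning (indices include self).
neighbor_lists <- function(x, y, eps) {
  m <- length(x)
  bx <- floor(x / eps); by <- floor(y / eps)
  key <- paste(bx, by)
  bins <- split(seq_len(m), key)
  lapply(seq_len(m), function(i) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(bx[i] + dx, by[i] + dy)
      b <- bins[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    sort(cand[d2 <= eps^2])
  })
}

#' Detect lymphocyte clusters by density-based clustering
#'
#' Runs on the pattern's lymphocytes only (B and all T-lineage phenotypes
#' pooled); cancer and other cells are ignored. Every lymphocyte ends up in
#' exactly one cluster or in the isolated set.
#'
#' @param pattern a valid `til_pattern`.
#' @param params a [cluster_params()]; defaults eps 20 um, min_pts 5.
#' @return list with `clusters` (list of `til_cluster`: `cluster_id`,
#'   `members` cell ids in input order, `size_s`, `composition` per-phenotype
#'   counts, `lc_type`, `is_tls` (FALSE until [detect_tls()]), `centroid`) and
#'   `isolated` (character vector of cell ids). No lymphocytes gives an empty
#'   result, not an error.
#' @export
detect_clusters <- function(pattern, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  cells <- pattern$cells
  lidx <- which(is_lymphocyte(cells$phenotype))
  m <- length(lidx)
  if (m == 0) return(list(clusters = list(), isolated = character(0)))
  x <- cells$x[lidx]; y <- cells$y[lidx]
  nb <- neighbor_lists(x, y, params$eps)
  is_core <- vapply(nb, length, integer(1)) >= params$min_pts

  label <- rep(NA_integer_, m)
  next_label <- 0L
  for (i in seq_len(m)) {
    if (!is_core[i] || !is.na(label[i])) next
    next_label <- next_label + 1L
    queue <- i
    label[i] <- next_label
    while (length(queue) > 0) {
      j <- queue[[1]]; queue <- queue[-1]
      core_nb <- nb[[j]][is_core[nb[[j]]]]
      new <- core_nb[is.na(label[core_nb])]
      label[new] <- next_label
      queue <- c(queue, new)
    }
  }
  # border cells: non-core with >= 1 core neighbor join the cluster of the
  # lowest-indexed core neighbor
  for (i in seq_len(m)) {
    if (is_core[i] || !is.na(label[i])) next
    core_nb <- nb[[i]][is_core[nb[[i]]]]
    if (length(core_nb) > 0) label[i] <- label[min(core_nb)]
  }

  clusters <- vector("list", next_label)
  for (k in seq_len(next_label)) {
    mem <- which(label == k)
    idx <- lidx[mem]
    comp <- table(factor(cells$phenotype[idx], levels = LYMPHOCYTE_PHENOTYPES))
    clusters[[k]] <- structure(
      list(cluster_id = k,
           members = cells$cell_id[idx],
           size_s = length(idx),
           composition = as.integer(comp),
           lc_type = classify_composition(comp),
           is_tls = FALSE,
           centroid = c(mean(cells$x[idx]), mean(cells$y[idx]))),
      class = "til_cluster"
    )
    names(clusters[[k]]$composition) <- LYMPHOCYTE_PHENOTYPES
  }
  list(clusters = clusters,
       isolated = cells$cell_id[lidx[is.na(label)]])
}

classify_composition <- function(comp) {
  n_b <- comp[["B"]]
  n_t <- sum(comp[T_LINEAGE_PHENOTYPES])
  if (n_b > 0 && n_t > 0) "heterotypic"
  else if (n_b > 0) "pure_B"
  else "pure_T"
}

#' Classify a cluster by its B/T composition
#'
#' Pure T if no B member, pure B if no T-lineage member, otherwise
#' heterotypic.
#'
#' @param cluster a `til_cluster`.
#' @return one of `"pure_T"`, `"heterotypic"`, `"pure_B"`.
#' @export
classify_cluster <- function(cluster) {
  if (cluster$size_s == 0) stop("empty cluster", call. = FALSE)
  classify_composition(cluster$composition)
}

#' Flag tertiary lymphoid structures among detected clusters
#'
#' A cluster is a TLS iff a second density pass over its own members with
#' eps = 70 um and min_pts = 200 yields at least one core cell, i.e. some
#' member has >= 200 of the cluster's lymphocytes within a 70 um radius. TLS
#' are a subset of LCs: flags never change cluster membership.
#'
#' @param pattern the `til_pattern` the clusters were detected on.
#' @param clusters cluster list from [detect_clusters()].
#' @param params TLS criterion as a [cluster_params()]; default
#'   `cluster_params(eps = 70, min_pts = 200)`.
#' @return the cluster list with `is_tls` flags set.
#' @export
detect_tls <- function(pattern, clusters,
                       params = cluster_params(eps = 70, min_pts = 200)) {
  cells <- pattern$cells
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    if (cl$size_s < params$min_pts) next
    idx <- match(cl$members, cells$cell_id)
    nb <- neighbor_lists(cells$x[idx], cells$y[idx], params$eps)
    if (any(vapply(nb, length, integer(1)) >= params$min_pts))
      clusters[[k]]$is_tls <- TRUE
  }
  clusters
}

#' Annotate a pattern's cells with cluster membership
#'
#' Adds `in_lc`, `lc_type` and `is_tls` columns so membership-scoped binary
#' questions and densities can be evaluated.
#'
#' @param pattern a `til_pattern`.
#' @param clusters cluster list (after [detect_tls()] if TLS scopes are used).
#' @return the pattern with annotated cells.
#' @export
annotate_membership <- function(pattern, clusters) {
  cells <- pattern$cells
  cells$in_lc <- FALSE
  cells$lc_type <- NA_character_
  cells$is_tls <- FALSE
  for (cl in clusters) {
    idx <- match(cl$members, cells$cell_id)
    cells$in_lc[idx] <- TRUE
    cells$lc_type[idx] <- cl$lc_type
    cells$is_tls[idx] <- cl$is_tls
  }
  pattern$cells <- cells
  pattern
}

#' Normalized cluster-size distribution and cumulative fraction
#'
#' For clusters of one type and outcome: `P(s)` is the number of clusters of
#' size `s`, `N` the total number of lymphocytes in those clusters, the
#' normalized distribution is `P(s)/N`, and the cumulative fraction
#' `f(s) = sum_{s' <= s} P(s') s' / N` is the fraction of those lymphocytes in
#' clusters of size `s` or smaller. By construction
#' `sum_s P(s) s / N = 1` exactly and `f` is non-decreasing with
#' `f(max s) = 1`.
#'
#' @param clusters cluster list.
#' @param type_i `"pure_T"` or `"heterotypic"` (pure-B clusters are excluded
#'   from size distributions).
#' @param outcome_o outcome label carried into the result.
#' @return data frame of class `cluster_size_distribution` with columns `s`,
#'   `P`, `P_over_N`, `f`; attributes `total_N`, `type_i`, `outcome_o`.
#' @export
size_distribution <- function(clusters, type_i = c("heterotypic", "pure_T"),
                              outcome_o = "unlabeled") {
  type_i <- match.arg(type_i)
  sizes <- vapply(clusters, `[[`, numeric(1), "size_s")[
    vapply(clusters, `[[`, character(1), "lc_type") == type_i]
  if (length(sizes) == 0)
    stop("no clusters of type ", type_i, call. = FALSE)
  tab <- table(sizes)
  s <- as.integer(names(tab))
  P <- as.integer(tab)
  total_N <- sum(P * s)
  out <- data.frame(s = s, P = P, P_over_N = P / total_N,
                    f = cumsum(P * s) / total_N)
  attr(out, "total_N") <- total_N
  attr(out, "type_i") <- type_i
  attr(out, "outcome_o") <- outcome_o
  class(out) <- c("cluster_size_distribution", "data.frame")
  out
}

#' Mean per-phenotype lymphocyte proportions across clusters
#'
#' Within each cluster, phenotype proportions are taken over lymphocyte
#' members (they sum to 1); the unweighted mean across the clusters is
#' returned. Cohort-level summaries average the per-patient values.
#'
#' @param clusters cluster list.
#' @param type_i cluster type to include, or `"TLS"` for flagged TLS.
#' @return named numeric vector of mean proportions over
#'   [LYMPHOCYTE_PHENOTYPES].
#' @export
composition_proportions <- function(clusters,
                                    type_i = c("heterotypic", "pure_T",
                                               "pure_B", "TLS")) {
  type_i <- match.arg(type_i)
  keep <- if (type_i == "TLS") vapply(clusters, `[[`, logical(1), "is_tls")
  else vapply(clusters, `[[`, character(1), "lc_type") == type_i
  sel <- clusters[keep]
  if (length(sel) == 0) stop("no clusters of type ", type_i, call. = FALSE)
  props <- vapply(sel, function(cl) cl$composition / sum(cl$composition),
                  numeric(length(LYMPHOCYTE_PHENOTYPES)))
  out <- rowMeans(props)
  names(out) <- LYMPHOCYTE_PHENOTYPES
  out
}

#' Tabulate clusters for export
#'
#' @param clusters cluster list.
#' @param patient_id id stamped on every row.
#' @return data frame (patient_id, cluster_id, size, lc_type, is_tls,
#'   centroid_x, centroid_y, n_B, n_T, n_CD8, n_Th, n_Treg).
#' @export
cluster_table <- function(clusters, patient_id = "patient") {
  if (length(clusters) == 0) {
    return(data.frame(patient_id = character(0), cluster_id = integer(0),
                      size = integer(0), lc_type = character(0),
                      is_tls = logical(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), n_B = integer(0),
                      n_T = integer(0), n_CD8 = integer(0), n_Th = integer(0),
                      n_Treg = integer(0)))
  }
  data.frame(
    patient_id = patient_id,
    cluster_id = vapply(clusters, `[[`, numeric(1), "cluster_id"),
    size = vapply(clusters, `[[`, numeric(1), "size_s"),
    lc_type = vapply(clusters, `[[`, character(1), "lc_type"),
    is_tls = vapply(clusters, `[[`, logical(1), "is_tls"),
    centroid_x = vapply(clusters, function(cl) cl$centroid[1], numeric(1)),
    centroid_y = vapply(clusters, function(cl) cl$centroid[2], numeric(1)),
    n_B = vapply(clusters, function(cl) cl$composition[["B"]], integer(1)),
    n_T = vapply(clusters, function(cl) cl$composition[["T"]], integer(1)),
    n_CD8 = vapply(clusters, function(cl) cl$composition[["T_CD8"]], integer(1)),
    n_Th = vapply(clusters, function(cl) cl$composition[["T_helper"]], integer(1)),
    n_Treg = vapply(clusters, function(cl) cl$composition[["Treg"]], integer(1)),
    stringsAsFactors = FALSE
  )
}
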