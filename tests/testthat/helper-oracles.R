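# Independent brute-force oracles and small fixture builders shared across the
# suite. The oracles deliberately use the naive O(n^2) formulation so they
# share no code path with the package implementation.

# DBSCAN by full distance matrix and transitive closure over core points.
# Returns integer labels in input order (NA = noise); border cells join the
# cluster of their lowest-indexed core neighbor.
oracle_dbscan <- function(x, y, eps, min_pts) {
  m <- length(x)
  if (m == 0) return(integer(0))
  d2 <- as.matrix(stats::dist(cbind(x, y)))^2
  nb <- d2 <= eps^2          # self included (distance 0)
  core <- rowSums(nb) >= min_pts
  lab <- rep(NA_integer_, m)
  nl <- 0L
  for (i in which(core)) {
    if (!is.na(lab[i])) next
    nl <- nl + 1L
    lab[i] <- nl
    repeat {
      members <- which(core & !is.na(lab) & lab == nl)
      front <- which(core & is.na(lab) &
                       apply(nb[, members, drop = FALSE], 1, any))
      if (length(front) == 0) break
      lab[front] <- nl
    }
  }
  for (i in which(!core)) {
    cn <- which(nb[i, ] & core)
    if (length(cn) > 0) lab[i] <- lab[min(cn)]
  }
  lab
}

# Labels in lymphocyte input order from a detect_clusters() result.
labels_from_clusters <- function(pattern, det) {
  cells <- pattern$cells
  lid <- cells$cell_id[is_lymphocyte(cells$phenotype)]
  lab <- rep(NA_integer_, length(lid))
  for (k in seq_along(det$clusters)) {
    lab[match(det$clusters[[k]]$members, lid)] <- k
  }
  lab
}

# ROC AUC by exhaustive pair counting.
oracle_auc <- function(good, poor) {
  s <- 0
  for (g in good) for (p in poor) s <- s + (g > p) + 0.5 * (g == p)
  s / (length(good) * length(poor))
}

# Minimum lymphocyte-to-cancer distance by explicit double loop.
oracle_min_distance <- function(mx, my, tx, ty) {
  best <- Inf
  for (i in seq_along(mx)) for (j in seq_along(tx)) {
    best <- min(best, sqrt((mx[i] - tx[j])^2 + (my[i] - ty[j])^2))
  }
  best
}

# A small valid pattern: one B in stroma, one T in a cancer island, one
# cancer cell.
fixture_pattern_3 <- function(roi_area = 1.0) {
  cells <- data.frame(
    cell_id = c("a", "b", "c"),
    x = c(10, 400, 410), y = c(10, 400, 410),
    phenotype = c("B", "T", "cancer"),
    tissue_category = c("stroma", "cancer_island", "cancer_island"),
    stringsAsFactors = FALSE
  )
  til_pattern(cells, roi_area, patient_id = "fix3")
}

# n lymphocytes at given coordinates, as a pattern with unit-area ROI.
lymph_pattern <- function(x, y, phenotype = "T", roi_area = 1.0, extra = NULL) {
  cells <- data.frame(
    cell_id = sprintf("L%03d", seq_along(x)),
    x = x, y = y,
    phenotype = rep_len(phenotype, length(x)),
    tissue_category = "stroma",
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) cells <- rbind(cells, extra)
  til_pattern(cells, roi_area)
}

# Uniform points in a disc, deterministic given seed.
disc_points <- function(n, cx, cy, r, seed = 1) {
  set.seed(seed)
  rad <- r * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  list(x = cx + rad * cos(th), y = cy + rad * sin(th))
}
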