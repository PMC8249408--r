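# Synthetic tissue generator.
#
# Emulates the statistical structure the downstream analysis assumes: cancer
# cells aggregated on disc-shaped islands interspersed with stroma, a dispersed
# (Poisson) lymphocyte component, and a clustered (Thomas-type) component whose
# parents sit at a controlled offset from island boundaries. Phenotypes are B
# with a profile-specific probability, else T. All generators are deterministic
# given a seed. Intensities are per mm^2; lengths are micrometers.

#' Rectangular simulation window
#' @param width,height side lengths in micrometers.
#' @return object of class `til_window`.
#' @export
til_window <- function(width = 3000, height = 3000) {
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop("window sides must be positive", call. = FALSE)
  structure(list(width = width, height = height), class = "til_window")
}

window_area_mm2 <- function(window) window$width * window$height / 1e6

window_roi <- function(window) {
  b <- rbind(c(0, 0), c(window$width, 0),
             c(window$width, window$height), c(0, window$height))
  roi(area_mm2 = window_area_mm2(window), boundary = b)
}

cells_frame <- function(x, y, phenotype, tissue_category, prefix = "c") {
  n <- length(x)
  data.frame(
    cell_id = if (n > 0) sprintf("%s%06d", prefix, seq_len(n)) else character(0),
    x = as.numeric(x), y = as.numeric(y),
    phenotype = rep_len(phenotype, n),
    tissue_category = rep_len(tissue_category, n),
    stringsAsFactors = FALSE
  )
}

#' Probability a grid square holds at least one point of a Poisson process
#'
#' Closed form `1 - exp(-lambda L^2)` for a homogeneous Poisson process;
#' the analytic oracle behind the occupancy tests.
#'
#' @param intensity points per mm^2.
#' @param L square side in micrometers.
#' @return probability in `[0, 1]`.
#' @export
expected_poisson_occupancy <- function(intensity, L) {
  if (any(intensity < 0)) stop("intensity must be >= 0", call. = FALSE)
  if (any(L <= 0)) stop("L must be > 0", call. = FALSE)
  1 - exp(-(intensity / 1e6) * L^2)
}

#' Sample a homogeneous Poisson point pattern
#'
#' @param intensity points per mm^2 (>= 0).
#' @param window a [til_window()].
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param phenotype,tissue_category marks assigned to every point.
#' @param patient_id,outcome pattern metadata.
#' @return a `til_pattern` whose ROI is the window.
#' @export
sample_poisson <- function(intensity, window = til_window(), seed = NULL,
                           phenotype = "B", tissue_category = "stroma",
                           patient_id = "poisson", outcome = "unlabeled") {
  if (!is.finite(intensity) || intensity < 0)
    stop("intensity must be a non-negative number", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, intensity * window_area_mm2(window))
  cells <- cells_frame(stats::runif(n, 0, window$width),
                       stats::runif(n, 0, window$height),
                       phenotype, tissue_category)
  til_pattern(cells, window_roi(window), patient_id = patient_id,
              outcome = outcome)
}

#' Sample a Thomas cluster point pattern
#'
#' Stationary Thomas process restricted to the window: Poisson parents with
#' `mean_offspring` Poisson offspring each, displaced by an isotropic Gaussian
#' of standard deviation `sigma`. Parents are drawn on a 3-sigma buffered
#' window and offspring are thinned by the exact probability of landing inside
#' the window (truncated-normal conditional sampling), so the expected total is
#' `parent_intensity * mean_offspring * area` without edge bias.
#'
#' @param parent_intensity parents per mm^2.
#' @param mean_offspring mean offspring per parent.
#' @param sigma offspring displacement SD in micrometers.
#' @inheritParams sample_poisson
#' @return a `til_pattern`.
#' @export
sample_thomas <- function(parent_intensity, mean_offspring, sigma,
                          window = til_window(), seed = NULL,
                          phenotype = "B", tissue_category = "stroma",
                          patient_id = "thomas", outcome = "unlabeled") {
  if (any(c(parent_intensity, mean_offspring, sigma) < 0))
    stop("all Thomas parameters must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  buf <- 3 * sigma
  bw <- window$width + 2 * buf
  bh <- window$height + 2 * buf
  n_par <- stats::rpois(1, parent_intensity * bw * bh / 1e6)
  if (n_par == 0 || mean_offspring == 0) {
    cells <- cells_frame(numeric(0), numeric(0), phenotype, tissue_category)
    return(til_pattern(cells, window_roi(window), patient_id = patient_id,
                       outcome = outcome))
  }
  px <- stats::runif(n_par, -buf, window$width + buf)
  py <- stats::runif(n_par, -buf, window$height + buf)
  if (sigma == 0) {
    p_in <- as.numeric(px >= 0 & px <= window$width &
                         py >= 0 & py <= window$height)
    lo_x <- hi_x <- lo_y <- hi_y <- NULL
  } else {
    lo_x <- stats::pnorm((0 - px) / sigma)
    hi_x <- stats::pnorm((window$width - px) / sigma)
    lo_y <- stats::pnorm((0 - py) / sigma)
    hi_y <- stats::pnorm((window$height - py) / sigma)
    p_in <- (hi_x - lo_x) * (hi_y - lo_y)
  }
  n_off <- stats::rpois(n_par, mean_offspring * p_in)
  keep <- n_off > 0
  idx <- rep(which(keep), n_off[keep])
  if (length(idx) == 0) {
    cells <- cells_frame(numeric(0), numeric(0), phenotype, tissue_category)
    return(til_pattern(cells, window_roi(window), patient_id = patient_id,
                       outcome = outcome))
  }
  if (sigma == 0) {
    x <- px[idx]; y <- py[idx]
  } else {
    ux <- stats::runif(length(idx), lo_x[idx], hi_x[idx])
    uy <- stats::runif(length(idx), lo_y[idx], hi_y[idx])
    x <- px[idx] + sigma * stats::qnorm(ux)
    y <- py[idx] + sigma * stats::qnorm(uy)
    # numeric safety at the truncation boundary
    x <- pmin(pmax(x, 0), window$width)
    y <- pmin(pmax(y, 0), window$height)
  }
  cells <- cells_frame(x, y, phenotype, tissue_category)
  til_pattern(cells, window_roi(window), patient_id = patient_id,
              outcome = outcome)
}

#' Generate disc-shaped cancer islands with a cancer-cell point sample
#'
#' Discs lie fully inside the window; radii are log-normal around
#' `radius_mean`. Cancer cells are sampled uniformly on each disc at
#' `cells_per_mm2`. The returned `contains(x, y)` closure labels arbitrary
#' points by disc containment (used to assign tissue categories to synthetic
#' lymphocytes).
#'
#' @param count number of islands (>= 0).
#' @param radius_mean mean disc radius in micrometers.
#' @param window a [til_window()].
#' @param seed integer seed or `NULL`.
#' @param cells_per_mm2 cancer-cell intensity on the discs.
#' @param radius_cv lognormal coefficient of variation of the radii.
#' @return list with `islands` (data frame cx, cy, r), `cells` (cancer-cell
#'   data frame), and `contains` (vectorized membership function).
#' @export
make_cancer_islands <- function(count, radius_mean, window = til_window(),
                                seed = NULL, cells_per_mm2 = 2000,
                                radius_cv = 0.15) {
  if (count < 0) stop("count must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (count == 0) {
    islands <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0))
  } else {
    r <- radius_mean * stats::rlnorm(count, -radius_cv^2 / 2, radius_cv)
    r <- pmin(r, min(window$width, window$height) / 2 - 1e-9)
    islands <- data.frame(
      cx = stats::runif(count, r, window$width - r),
      cy = stats::runif(count, r, window$height - r),
      r = r
    )
  }
  contains <- function(x, y) {
    inside <- rep(FALSE, length(x))
    for (i in seq_len(nrow(islands))) {
      inside <- inside | ((x - islands$cx[i])^2 + (y - islands$cy[i])^2
                          <= islands$r[i]^2)
    }
    inside
  }
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(nrow(islands))) {
    n_i <- stats::rpois(1, cells_per_mm2 * pi * islands$r[i]^2 / 1e6)
    if (n_i == 0) next
    rad <- islands$r[i] * sqrt(stats::runif(n_i))
    th <- stats::runif(n_i, 0, 2 * pi)
    xs <- c(xs, islands$cx[i] + rad * cos(th))
    ys <- c(ys, islands$cy[i] + rad * sin(th))
  }
  cells <- cells_frame(xs, ys, "cancer", "cancer_island", prefix = "ca")
  list(islands = islands, cells = cells, contains = contains)
}

#' Outcome profile for the synthetic generator
#'
#' Bundles the rates that shape one synthetic patient. Defaults (see
#' [default_profiles()]) encode the qualitative good-versus-poor contrasts the
#' analysis is designed to detect; they are a constructed test bed, not a
#' calibrated model of tumor biology.
#'
#' @param lymphocyte_intensity dispersed (Poisson) lymphocyte rate, per mm^2.
#' @param b_fraction probability a lymphocyte is a B cell.
#' @param cluster_parent_intensity cluster parents per mm^2.
#' @param mean_cluster_size mean lymphocytes per cluster parent.
#' @param cluster_dispersion_sigma within-cluster Gaussian SD, micrometers.
#' @param island_count number of cancer islands.
#' @param island_radius_mean mean island radius, micrometers.
#' @param island_infiltration_rate island-infiltrating lymphocytes per mm^2.
#' @param lc_island_offset mean distance from island boundary to cluster
#'   parents, micrometers.
#' @return object of class `outcome_profile`.
#' @export
outcome_profile <- function(lymphocyte_intensity = 100, b_fraction = 0.3,
                            cluster_parent_intensity = 8, mean_cluster_size = 15,
                            cluster_dispersion_sigma = 12, island_count = 12,
                            island_radius_mean = 60,
                            island_infiltration_rate = 10,
                            lc_island_offset = 80) {
  p <- list(lymphocyte_intensity = lymphocyte_intensity,
            b_fraction = b_fraction,
            cluster_parent_intensity = cluster_parent_intensity,
            mean_cluster_size = mean_cluster_size,
            cluster_dispersion_sigma = cluster_dispersion_sigma,
            island_count = island_count,
            island_radius_mean = island_radius_mean,
            island_infiltration_rate = island_infiltration_rate,
            lc_island_offset = lc_island_offset)
  rates <- unlist(p)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all profile rates must be finite and >= 0", call. = FALSE)
  if (b_fraction > 1) stop("b_fraction must be in [0, 1]", call. = FALSE)
  structure(p, class = "outcome_profile")
}

#' Default good/poor outcome profiles
#'
#' Good outcome: more dispersed lymphocytes, many small tight clusters close to
#' cancer islands, heavier island infiltration, lower B fraction. Poor outcome:
#' fewer dispersed lymphocytes, few large clusters far from islands, sparse
#' infiltration, higher B fraction. These directions mirror the contrasts the
#' cohort analysis is expected to recover.
#'
#' @return named list with elements `good` and `poor`.
#' @export
default_profiles <- function() {
  list(
    good = outcome_profile(
      lymphocyte_intensity = 120, b_fraction = 0.30,
      cluster_parent_intensity = 12, mean_cluster_size = 10,
      cluster_dispersion_sigma = 10, island_count = 12,
      island_radius_mean = 60, island_infiltration_rate = 25,
      lc_island_offset = 40
    ),
    poor = outcome_profile(
      lymphocyte_intensity = 50, b_fraction = 0.40,
      cluster_parent_intensity = 5, mean_cluster_size = 30,
      cluster_dispersion_sigma = 15, island_count = 12,
      island_radius_mean = 60, island_infiltration_rate = 5,
      lc_island_offset = 150
    )
  )
}

#' Synthesize one patient's marked point pattern
#'
#' Composite of (i) cancer cells on islands, (ii) a dispersed Poisson
#' lymphocyte component, (iii) a clustered Thomas-type component whose parents
#' sit at `lc_island_offset` from island boundaries, and (iv) island
#' infiltrating lymphocytes. Phenotypes are i.i.d. B with probability
#' `b_fraction`, else T; tissue category follows disc containment; the ROI is
#' the window.
#'
#' @param profile an [outcome_profile()].
#' @param window a [til_window()]; default 2 x 2 mm.
#' @param seed integer seed or `NULL`.
#' @param patient_id,outcome metadata.
#' @return a `til_pattern`.
#' @export
synthesize_patient <- function(profile, window = til_window(2000, 2000),
                               seed = NULL, patient_id = "synthetic",
                               outcome = "unlabeled") {
  stopifnot(inherits(profile, "outcome_profile"))
  if (!is.null(seed)) set.seed(seed)
  area <- window_area_mm2(window)
  isl <- make_cancer_islands(profile$island_count, profile$island_radius_mean,
                             window)

  # dispersed component
  n_disp <- stats::rpois(1, profile$lymphocyte_intensity * area)
  lx <- stats::runif(n_disp, 0, window$width)
  ly <- stats::runif(n_disp, 0, window$height)

  # clustered component: parents offset from island boundaries
  n_par <- stats::rpois(1, profile$cluster_parent_intensity * area)
  if (n_par > 0) {
    if (nrow(isl$islands) > 0 && profile$lc_island_offset > 0) {
      j <- sample.int(nrow(isl$islands), n_par, replace = TRUE)
      d <- abs(stats::rnorm(n_par, profile$lc_island_offset,
                            profile$lc_island_offset / 4))
      th <- stats::runif(n_par, 0, 2 * pi)
      ppx <- isl$islands$cx[j] + (isl$islands$r[j] + d) * cos(th)
      ppy <- isl$islands$cy[j] + (isl$islands$r[j] + d) * sin(th)
      ok <- ppx >= 0 & ppx <= window$width & ppy >= 0 & ppy <= window$height
      ppx <- ppx[ok]; ppy <- ppy[ok]
    } else {
      ppx <- stats::runif(n_par, 0, window$width)
      ppy <- stats::runif(n_par, 0, window$height)
    }
    n_off <- stats::rpois(length(ppx), profile$mean_cluster_size)
    idx <- rep(seq_along(ppx), n_off)
    cx <- ppx[idx] + stats::rnorm(length(idx), 0, profile$cluster_dispersion_sigma)
    cy <- ppy[idx] + stats::rnorm(length(idx), 0, profile$cluster_dispersion_sigma)
    ok <- cx >= 0 & cx <= window$width & cy >= 0 & cy <= window$height
    lx <- c(lx, cx[ok]); ly <- c(ly, cy[ok])
  }

  # island-infiltrating lymphocytes
  if (nrow(isl$islands) > 0 && profile$island_infiltration_rate > 0) {
    n_inf <- stats::rpois(1, profile$island_infiltration_rate * area)
    if (n_inf > 0) {
      w <- isl$islands$r^2
      j <- sample.int(nrow(isl$islands), n_inf, replace = TRUE, prob = w)
      rad <- isl$islands$r[j] * sqrt(stats::runif(n_inf))
      th <- stats::runif(n_inf, 0, 2 * pi)
      lx <- c(lx, isl$islands$cx[j] + rad * cos(th))
      ly <- c(ly, isl$islands$cy[j] + rad * sin(th))
    }
  }

  n_lymph <- length(lx)
  pheno <- ifelse(stats::runif(n_lymph) < profile$b_fraction, "B", "T")
  tissue <- ifelse(isl$contains(lx, ly), "cancer_island", "stroma")
  lymph <- cells_frame(lx, ly, "B", "stroma", prefix = "ly")
  lymph$phenotype <- pheno
  lymph$tissue_category <- tissue
  cells <- rbind(isl$cells, lymph)
  til_pattern(cells, window_roi(window), patient_id = patient_id,
              outcome = outcome)
}

#' Synthesize a labeled cohort with a relapse-free-survival table
#'
#' Good patients are event-free for at least 60 months; poor patients relapse
#' within 36 months. Per-patient seeds are spawned from the master seed with a
#' counter so results do not depend on cohort ordering.
#'
#' @param n_good,n_poor cohort sizes.
#' @param profiles named list with `good` and `poor` [outcome_profile()]s.
#' @param window a [til_window()].
#' @param seed master integer seed.
#' @return list with `patterns` (list of `til_pattern`) and `survival`
#'   (data frame patient_id, outcome, rfs_months, event).
#' @export
synthesize_cohort <- function(n_good = 24, n_poor = 12,
                              profiles = default_profiles(),
                              window = til_window(2000, 2000), seed = 1) {
  stopifnot(n_good >= 0, n_poor >= 0)
  set.seed(seed)
  n <- n_good + n_poor
  sub_seeds <- if (n > 0) sample.int(.Machine$integer.max - 1L, n) else integer(0)
  outcomes <- rep(c("good", "poor"), c(n_good, n_poor))
  ids <- sprintf("%s_%02d", outcomes, c(seq_len(n_good), seq_len(n_poor)))
  rfs <- numeric(n); event <- integer(n)
  if (n_good > 0) rfs[seq_len(n_good)] <- stats::runif(n_good, 60, 120)
  if (n_poor > 0) rfs[n_good + seq_len(n_poor)] <- stats::runif(n_poor, 6, 36)
  event[outcomes == "poor"] <- 1L
  patterns <- vector("list", n)
  for (i in seq_len(n)) {
    patterns[[i]] <- synthesize_patient(profiles[[outcomes[i]]], window,
                                        seed = sub_seeds[i],
                                        patient_id = ids[i],
                                        outcome = outcomes[i])
  }
  names(patterns) <- ids
  list(
    patterns = patterns,
    survival = data.frame(patient_id = ids, outcome = outcomes,
                          rfs_months = rfs, event = event,
                          stringsAsFactors = FALSE)
  )
}
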