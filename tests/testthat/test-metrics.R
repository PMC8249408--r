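# Densities, membership fractions, cluster-island distances, correlation.

test_that("densities use the full ROI area and partition over compartments", {
  cells <- data.frame(
    cell_id = sprintf("c%d", 1:5),
    x = c(10, 20, 30, 200, 300), y = rep(10, 5),
    phenotype = c("B", "B", "B", "B", "T"),
    tissue_category = c("cancer_island", "cancer_island", "cancer_island",
                        "stroma", "stroma"))
  pat <- til_pattern(cells, 1.5)
  expect_equal(region_density(pat, "B", "cancer_island")$density, 2.0)
  expect_equal(region_density(pat, "B", "stroma")$density, 1 / 1.5)

  # islands + stroma = overall, exactly, for several phenotype sets
  prof <- default_profiles()$good
  syn <- synthesize_patient(prof, seed = 21)
  for (ph in list("B", "T", "lymphocyte", "cancer")) {
    d_any <- region_density(syn, ph, "any")$density
    d_isl <- region_density(syn, ph, "cancer_island")$density
    d_str <- region_density(syn, ph, "stroma")$density
    expect_equal(d_isl + d_str, d_any, tolerance = 1e-12)
  }
})

test_that("membership fractions partition lymphocytes and flag empty scopes as missing", {
  five <- seq(0, 40, by = 10)
  pat <- lymph_pattern(c(five, 200, 300, 400, 500, 600),
                       c(rep(0, 5), rep(300, 5)))
  det <- detect_clusters(pat)
  ann <- annotate_membership(pat, detect_tls(pat, det$clusters))
  mf <- membership_fractions(ann)
  row <- mf[mf$tissue_scope == "any" & mf$phenotype_group == "lymphocyte", ]
  expect_equal(row$frac_in_lc, 0.5)
  expect_equal(row$frac_isolated, 0.5)
  expect_true(row$frac_in_tls <= row$frac_in_lc)
  # no B cells anywhere: fractions are NA, not zero
  expect_true(is.na(mf$frac_in_lc[mf$phenotype_group == "B" &
                                    mf$tissue_scope == "any"]))

  lonely <- lymph_pattern(c(0, 200, 400), c(0, 0, 0))
  det0 <- detect_clusters(lonely)
  ann0 <- annotate_membership(lonely, det0$clusters)
  mf0 <- membership_fractions(ann0)
  expect_equal(mf0$frac_isolated[mf0$tissue_scope == "any" &
                                   mf0$phenotype_group == "lymphocyte"], 1)

  # partition property across random synthetic patients
  for (s in 1:5) {
    syn <- synthesize_patient(default_profiles()$poor, seed = 600 + s)
    d <- detect_clusters(syn)
    a <- annotate_membership(syn, d$clusters)
    m <- membership_fractions(a)
    ok <- !is.na(m$frac_isolated)
    expect_equal(m$frac_isolated[ok] + m$frac_in_lc[ok], rep(1, sum(ok)),
                 tolerance = 1e-12)
  }
})

test_that("cluster-island distances reproduce exact geometry and the brute-force oracle", {
  five <- seq(0, 40, by = 10)
  extra <- data.frame(cell_id = c("ca1", "ca2"),
                      x = c(-30, 200), y = c(40, 300),
                      phenotype = "cancer", tissue_category = "cancer_island")
  pat <- lymph_pattern(five, rep(0, 5), extra = extra)
  det <- detect_clusters(pat)
  # nearest member at (0, 0), nearest cancer cell at (-30, 40): 3-4-5 triangle
  expect_equal(cluster_island_distance(det$clusters[[1]], pat), 50)

  coincident <- data.frame(cell_id = "ca3", x = 20, y = 0,
                           phenotype = "cancer", tissue_category = "cancer_island")
  pat0 <- lymph_pattern(five, rep(0, 5), extra = coincident)
  det0 <- detect_clusters(pat0)
  expect_equal(cluster_island_distance(det0$clusters[[1]], pat0), 0)

  none <- lymph_pattern(five, rep(0, 5))
  detn <- detect_clusters(none)
  expect_warning(d <- cluster_island_distance(detn$clusters[[1]], none),
                 "no cancer")
  expect_true(is.na(d))

  # oracle equivalence and translation invariance on random instances
  for (s in 1:10) {
    set.seed(s)
    pk <- disc_points(8, 100, 100, 10, seed = s)
    tx <- runif(20, 0, 500); ty <- runif(20, 0, 500)
    extra <- data.frame(cell_id = sprintf("t%02d", 1:20), x = tx, y = ty,
                        phenotype = "cancer", tissue_category = "cancer_island")
    p <- lymph_pattern(pk$x, pk$y, extra = extra)
    dd <- detect_clusters(p)
    got <- cluster_island_distance(dd$clusters[[1]], p)
    expect_equal(got, oracle_min_distance(pk$x, pk$y, tx, ty), tolerance = 1e-12)

    shift <- p
    shift$cells$x <- shift$cells$x + 137.5
    shift$cells$y <- shift$cells$y + 21.25
    ds <- detect_clusters(shift)
    expect_equal(cluster_island_distance(ds$clusters[[1]], shift), got,
                 tolerance = 1e-9)
  }
})

test_that("size-distance correlation matches the direct covariance formula", {
  expect_equal(size_distance_correlation(1:10, 2 * (1:10) + 3)$r, 1)
  expect_equal(size_distance_correlation(1:10, -(1:10))$r, -1)

  set.seed(77)
  xs <- runif(10, 5, 50); ys <- xs * 2 + rnorm(10, 0, 10)
  res <- size_distance_correlation(xs, ys)
  direct <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  expect_equal(res$r, direct, tolerance = 1e-12)
  tstat <- direct * sqrt(8 / (1 - direct^2))
  expect_equal(res$p, 2 * stats::pt(-abs(tstat), df = 8), tolerance = 1e-12)

  expect_error(size_distance_correlation(c(1, 2), c(3, 4)), ">= 3")
  expect_error(size_distance_correlation(rep(1, 5), 1:5), "constant")
})

test_that("good cohorts put clusters nearer islands than poor cohorts", {
  profs <- default_profiles()
  wins <- 0
  for (s in 1:10) {
    dists <- vapply(c("good", "poor"), function(o) {
      pat <- synthesize_patient(profs[[o]], seed = 700 + s)
      det <- detect_clusters(pat)
      tab <- suppressWarnings(cluster_island_distances(det$clusters, pat))
      mean(tab$distance_um[tab$lc_type == "heterotypic"], na.rm = TRUE)
    }, numeric(1))
    wins <- wins + (dists[["good"]] < dists[["poor"]])
  }
  expect_gte(wins, 9)
})
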