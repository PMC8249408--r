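# Grid overlay, occupancy curves and AUC, fractal-dimension fits.

test_that("overlay counts match hand-placed configurations", {
  q <- binary_question("B")
  four <- lymph_pattern(c(5, 15, 5, 15), c(5, 5, 15, 15), phenotype = "B")
  r10 <- overlay_counts(four, 10, q, origin = c(0, 0))
  expect_equal(r10$n, 4); expect_equal(r10$N, 4); expect_equal(r10$occupancy, 1)
  r20 <- overlay_counts(four, 20, q, origin = c(0, 0))
  expect_equal(r20$n, 1); expect_equal(r20$N, 1)

  one <- lymph_pattern(50, 50, phenotype = "B")
  for (L in c(10, 57, 600)) {
    r <- overlay_counts(one, L, q)
    expect_equal(r$n, 1); expect_equal(r$N, 1)
  }

  # question matching an absent phenotype: n = 0 but tissue squares remain
  qT <- binary_question("T_CD8")
  r <- overlay_counts(four, 10, qT, origin = c(0, 0))
  expect_equal(r$n, 0); expect_equal(r$N, 4); expect_equal(r$occupancy, 0)

  empty <- til_pattern(
    data.frame(cell_id = character(0), x = numeric(0), y = numeric(0),
               phenotype = character(0), tissue_category = character(0)),
    1.0)
  expect_error(overlay_counts(empty, 10, q), "no cells")
})

test_that("occupancy curves are deterministic, bounded and nested under dyadic grids", {
  q <- binary_question("B")
  for (s in 1:5) {
    set.seed(s)
    pat <- lymph_pattern(runif(150, 0, 500), runif(150, 0, 500), "B")
    cv <- occupancy_curve(pat, c(10, 20, 40), q, origin = c(0, 0))
    expect_true(all(cv$occupancy >= 0 & cv$occupancy <= 1))
    expect_true(all(cv$n <= cv$N))
    # shared-origin dyadic nesting: coarser grids occupy no more squares
    expect_true(all(diff(cv$n) <= 0))
    # any dyadic two-point slope lies in [0, 2]
    slope <- log(cv$n[1] / cv$n[2]) / log(2)
    expect_gte(slope, 0); expect_lte(slope, 2)
  }
})

test_that("occupancy AUC reproduces hand-computed trapezoids", {
  const1 <- lymph_pattern(50, 50, phenotype = "B")
  cv <- occupancy_curve(const1, c(10, 600), binary_question("B"))
  expect_equal(occupancy_auc(cv), log(600 / 10), tolerance = 1e-12)

  two_pt <- structure(
    data.frame(L = c(10, 100), n = c(2, 8), N = c(10, 10),
               occupancy = c(0.2, 0.8)),
    class = c("box_count_curve", "data.frame"))
  expect_equal(occupancy_auc(two_pt), 0.5 * (0.2 + 0.8) * log(10),
               tolerance = 1e-12)
  expect_equal(occupancy_auc(two_pt, abscissa = "linear"),
               0.5 * (0.2 + 0.8) * 90, tolerance = 1e-12)

  zero <- two_pt; zero$occupancy <- c(0, 0)
  expect_equal(occupancy_auc(zero), 0)
  expect_error(occupancy_auc(two_pt[1, ]), ">= 2")
})

test_that("FD fits recover limiting slopes: flat for a point, 2 for a filled plane", {
  q <- binary_question("B")
  one <- lymph_pattern(50, 50, phenotype = "B")
  f <- fit_fractal_dimension(one, q, Ls = c(10, 20, 40), scale_window = c(10, 40))
  expect_equal(f$slope_s, 0, tolerance = 1e-12)
  d <- fd_difference(one, q, Ls_small = c(10, 20, 40),
                     Ls_large = c(200, 400, 600))
  expect_equal(d$delta_s, 0, tolerance = 1e-12)

  # dense square lattice: every box occupied, n(L) = (extent/L)^2 exactly
  g <- seq(2.5, 1197.5, by = 5)
  lattice <- til_pattern(
    data.frame(cell_id = sprintf("p%06d", seq_len(length(g)^2)),
               x = rep(g, each = length(g)), y = rep(g, length(g)),
               phenotype = "B", tissue_category = "stroma"),
    roi(boundary = rbind(c(0, 0), c(1200, 0), c(1200, 1200), c(0, 1200))))
  f2 <- fit_fractal_dimension(lattice, q, Ls = c(200, 300, 400, 600),
                              scale_window = c(200, 600))
  expect_equal(f2$slope_s, 2, tolerance = 0.02)
})

test_that("small-scale Poisson slope matches the closed-form least squares", {
  # analytic: slope of ln[(1-exp(-lambda L^2))/L^2] vs ln(1/L) = 0.1511
  Ls <- c(10, 15, 20, 30, 40)
  lam <- 3e-4
  y <- log((1 - exp(-lam * Ls^2)) / Ls^2)
  x <- log(1 / Ls)
  analytic <- unname(coef(stats::lm(y ~ x))[2])
  expect_equal(analytic, 0.1511, tolerance = 1e-3)

  slopes <- vapply(1:5, function(s) {
    pat <- sample_poisson(300, til_window(3000, 3000), seed = 300 + s)
    fit_fractal_dimension(pat, binary_question("B"), Ls = Ls,
                          scale_window = c(10, 40),
                          denominator = "window")$slope_s
  }, numeric(1))
  expect_lt(abs(mean(slopes) - analytic), 0.03)
})

test_that("FD slope is invariant to rescaling n and drops empty scales", {
  pat <- sample_poisson(300, til_window(3000, 3000), seed = 42)
  q <- binary_question("B")
  cv <- occupancy_curve(pat, default_L_ladder(), q, denominator = "window")
  f1 <- tilspatial:::fit_fd_curve(cv, c(10, 40))
  cv3 <- cv; cv3$n <- cv3$n * 3
  f3 <- tilspatial:::fit_fd_curve(cv3, c(10, 40))
  expect_equal(f1$slope_s, f3$slope_s, tolerance = 1e-12)
  expect_equal(f3$intercept, f1$intercept + log(3), tolerance = 1e-9)

  # fewer than 3 usable scales is an explicit insufficient-data error
  sparse <- lymph_pattern(c(5, 500), c(5, 500), "B")
  expect_error(
    fit_fractal_dimension(sparse, q, Ls = c(10, 20), scale_window = c(10, 40)),
    "insufficient")
})

test_that("clustering lowers the FD difference relative to Poisson", {
  w <- til_window(3000, 3000)
  q <- binary_question("B")
  wins <- 0
  for (s in 1:20) {
    th <- sample_thomas(6, 50, 15, w, seed = 1000 + s)
    po <- sample_poisson(300, w, seed = 2000 + s)
    d_th <- fd_difference(th, q, denominator = "window")$delta_s
    d_po <- fd_difference(po, q, denominator = "window")$delta_s
    wins <- wins + (d_th < d_po)
  }
  expect_gte(wins, 18)
})

test_that("membership-scoped questions require annotation and then filter correctly", {
  pts <- disc_points(8, 100, 100, 10, seed = 3)
  pat <- lymph_pattern(c(pts$x, 400), c(pts$y, 400),
                       phenotype = c(rep("T", 4), rep("B", 4), "B"))
  q <- binary_question("B", membership_scope = "in_heterotypic_lc")
  expect_error(cells_matching(pat, q), "annotate_membership")
  det <- detect_clusters(pat)
  ann <- annotate_membership(pat, det$clusters)
  hit <- cells_matching(ann, q)
  expect_equal(sum(hit), 4) # the 4 clustered B cells, not the isolated one
})
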