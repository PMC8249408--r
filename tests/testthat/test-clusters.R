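# Density-based LC detection, typing, TLS flagging, size distributions.

test_that("five contiguous 10-um-spaced cells form one cluster; four do not", {
  five <- lymph_pattern(seq(0, 40, by = 10), rep(0, 5))
  det <- detect_clusters(five)
  expect_length(det$clusters, 1)
  expect_equal(det$clusters[[1]]$size_s, 5)
  expect_length(det$isolated, 0)

  four <- lymph_pattern(c(0, 5, 10, 15), rep(0, 4)) # all pairwise <= 20 um
  det4 <- detect_clusters(four)
  expect_length(det4$clusters, 0)
  expect_length(det4$isolated, 4)
})

test_that("widely scattered lymphocytes stay isolated", {
  g <- expand.grid(x = seq(0, 450, by = 50), y = seq(0, 450, by = 50))
  pat <- lymph_pattern(g$x, g$y)
  det <- detect_clusters(pat)
  expect_length(det$clusters, 0)
  expect_length(det$isolated, 100)
})

test_that("detection matches the brute-force density-connectivity oracle", {
  for (s in 1:20) {
    set.seed(s)
    n <- 150
    # mixture of clumps and background so clusters actually form
    cx <- runif(8, 50, 450); cy <- runif(8, 50, 450)
    j <- sample.int(8, n, replace = TRUE)
    x <- c(cx[j] + rnorm(n, 0, 12), runif(50, 0, 500))
    y <- c(cy[j] + rnorm(n, 0, 12), runif(50, 0, 500))
    pat <- lymph_pattern(x, y, phenotype = sample(c("B", "T"), n + 50, TRUE))
    det <- detect_clusters(pat)
    got <- labels_from_clusters(pat, det)
    want <- oracle_dbscan(x, y, eps = 20, min_pts = 5)
    expect_identical(got, want)
  }
})

test_that("every lymphocyte lands in exactly one cluster or the isolated set", {
  prof <- default_profiles()
  for (s in 1:5) {
    pat <- synthesize_patient(prof[[1 + s %% 2]], seed = 400 + s)
    det <- detect_clusters(pat)
    member_ids <- unlist(lapply(det$clusters, `[[`, "members"))
    expect_false(anyDuplicated(member_ids) > 0)
    lymph_ids <- pat$cells$cell_id[is_lymphocyte(pat$cells$phenotype)]
    expect_setequal(c(member_ids, det$isolated), lymph_ids)
    # cancer cells never appear in clusters
    expect_length(intersect(member_ids,
                            pat$cells$cell_id[pat$cells$phenotype == "cancer"]), 0)
  }
})

test_that("clusters classify by composition", {
  pureT <- detect_clusters(lymph_pattern(seq(0, 40, 10), rep(0, 5), "T"))
  expect_equal(pureT$clusters[[1]]$lc_type, "pure_T")
  expect_equal(classify_cluster(pureT$clusters[[1]]), "pure_T")

  pureB <- detect_clusters(lymph_pattern(seq(0, 40, 10), rep(0, 5), "B"))
  expect_equal(pureB$clusters[[1]]$lc_type, "pure_B")

  pts <- disc_points(10, 50, 50, 15, seed = 2)
  het <- detect_clusters(lymph_pattern(pts$x, pts$y,
                                       c(rep("B", 3), rep("T", 7))))
  expect_length(het$clusters, 1)
  expect_equal(het$clusters[[1]]$lc_type, "heterotypic")
  comp <- het$clusters[[1]]$composition
  expect_equal(comp[["B"]] / sum(comp), 0.3)
  # subtype T lineage counts as T for typing
  mix <- detect_clusters(lymph_pattern(seq(0, 40, 10), rep(0, 5),
                                       c("B", "T_CD8", "Treg", "T_helper", "B")))
  expect_equal(mix$clusters[[1]]$lc_type, "heterotypic")
})

test_that("the TLS rule flags 200 lymphocytes within a 70-um circle and only that", {
  # 200 cells packed in a radius-35 disc: every pair within 70 um
  pk <- disc_points(200, 500, 500, 35, seed = 11)
  pat <- lymph_pattern(pk$x, pk$y, phenotype = rep(c("B", "T"), 100))
  det <- detect_clusters(pat)
  expect_length(det$clusters, 1)
  cl <- detect_tls(pat, det$clusters)
  expect_true(cl[[1]]$is_tls)
  # flags never change membership
  expect_identical(cl[[1]]$members, det$clusters[[1]]$members)

  # 199 cells: below the hard count threshold
  pk199 <- disc_points(199, 500, 500, 35, seed = 11)
  pat199 <- lymph_pattern(pk199$x, pk199$y)
  det199 <- detect_clusters(pat199)
  cl199 <- detect_tls(pat199, det199$clusters)
  expect_false(any(vapply(cl199, `[[`, logical(1), "is_tls")))

  # 200 members spread over 1 mm^2: neighborhood counts far below 200
  g <- expand.grid(x = seq(25, 975, length.out = 15),
                   y = seq(25, 975, length.out = 14))[1:200, ]
  spread_pat <- lymph_pattern(g$x, g$y)
  fake_cluster <- structure(
    list(cluster_id = 1L, members = spread_pat$cells$cell_id, size_s = 200,
         composition = c(B = 0L, T = 200L, T_CD8 = 0L, T_helper = 0L, Treg = 0L),
         lc_type = "pure_T", is_tls = FALSE, centroid = c(500, 500)),
    class = "til_cluster")
  flagged <- detect_tls(spread_pat, list(fake_cluster))
  expect_false(flagged[[1]]$is_tls)
})

test_that("size distributions satisfy the normalization and cumulative-fraction identities", {
  mk <- function(sizes, type = "heterotypic") lapply(seq_along(sizes), function(i)
    structure(list(cluster_id = i, members = character(sizes[i]),
                   size_s = sizes[i],
                   composition = c(B = 1L, T = sizes[i] - 1L, T_CD8 = 0L,
                                   T_helper = 0L, Treg = 0L),
                   lc_type = type, is_tls = FALSE, centroid = c(0, 0)),
              class = "til_cluster"))
  d <- size_distribution(mk(c(5, 5, 10)), "heterotypic", "good")
  expect_equal(attr(d, "total_N"), 20)
  expect_equal(d$P[d$s == 5], 2)
  expect_equal(d$P_over_N[d$s == 5], 0.1)
  expect_equal(d$f, c(0.5, 1))
  expect_equal(sum(d$P * d$s) / attr(d, "total_N"), 1) # exact

  single <- size_distribution(mk(5), "heterotypic")
  expect_equal(single$P_over_N, 0.2)
  expect_equal(single$f, 1)

  expect_error(size_distribution(mk(c(5, 5), "pure_T"), "heterotypic"),
               "no clusters")
})

test_that("normalization holds to machine precision on synthetic patients", {
  prof <- default_profiles()
  for (s in 1:6) {
    pat <- synthesize_patient(prof[[1 + s %% 2]], seed = 500 + s)
    det <- detect_clusters(pat)
    for (ty in c("heterotypic", "pure_T")) {
      d <- tryCatch(size_distribution(det$clusters, ty), error = function(e) NULL)
      if (is.null(d)) next
      expect_equal(sum(d$P * d$s) / attr(d, "total_N"), 1, tolerance = 1e-15)
      expect_true(all(diff(d$f) >= 0))
      expect_equal(d$f[length(d$f)], 1, tolerance = 1e-15)
    }
  }
})

test_that("composition proportions average per cluster, then across clusters", {
  p1 <- disc_points(10, 50, 50, 15, seed = 4)
  p2 <- disc_points(10, 300, 300, 15, seed = 5)
  pat <- lymph_pattern(c(p1$x, p2$x), c(p1$y, p2$y),
                       phenotype = c(rep("B", 2), rep("T", 8),
                                     rep("B", 4), rep("T", 6)))
  det <- detect_clusters(pat)
  expect_length(det$clusters, 2)
  pr <- composition_proportions(det$clusters, "heterotypic")
  expect_equal(pr[["B"]], mean(c(0.2, 0.4)))
  expect_equal(sum(pr), 1)
  expect_error(composition_proportions(det$clusters, "pure_T"), "no clusters")
})
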