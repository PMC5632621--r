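test_that("Schoener's D: closed-form cases, symmetry, range", {
  p <- matrix(c(0.5, 0.5, 0, 0), 2, 2)
  expect_equal(schoener_d(p, p), 1)
  q <- matrix(c(0, 0, 0.5, 0.5), 2, 2)
  expect_equal(schoener_d(p, q), 0)            # disjoint supports
  expect_equal(schoener_d(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)), 0.5)

  set.seed(21)
  for (i in 1:25) {
    a <- matrix(rexp(36), 6, 6); a <- a / sum(a)
    b <- matrix(rexp(36), 6, 6); b <- b / sum(b)
    d <- schoener_d(a, b)
    expect_identical(d, schoener_d(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
  }
  expect_error(schoener_d(p, matrix(1, 1, 1)), "shape")
  expect_error(schoener_d(p * 2, p), "sum to 1")
})

test_that("D is non-increasing under mixing away from a disjoint niche", {
  p1 <- matrix(0, 4, 4); p1[1:2, 1:2] <- 1 / 4
  p2 <- matrix(0, 4, 4); p2[3:4, 3:4] <- 1 / 4
  d <- vapply(seq(0, 1, by = 0.1), function(t)
    schoener_d(p1, (1 - t) * p1 + t * p2), numeric(1))
  expect_true(all(diff(d) <= 1e-12))
})

test_that("Levins breadth: uniform, point-mass and hand-computed cases", {
  n <- 16
  uni <- levins_breadth(matrix(1 / n, 4, 4))
  expect_equal(uni$B, n)
  expect_equal(uni$B_norm, 1)
  point <- matrix(0, 4, 4); point[2, 3] <- 1
  pt <- levins_breadth(point)
  expect_equal(pt$B, 1)
  expect_equal(pt$B_norm, 0)
  expect_equal(levins_breadth(c(0.5, 0.5, 0))$B, 2)
  expect_error(levins_breadth(matrix(0, 2, 2)), "zero")
})

test_that("equivalency: identical samples are never 'Different'; disjoint niches floor the p-value", {
  cl <- separated_clouds(30, gap = 0, seed = 31)
  res <- equivalency_test(cl$a, cl$a, cl$bg, reps = 50, R = 60, seed = 5)
  expect_equal(res$D, 1)
  expect_identical(res$equivalent, "ns")
  expect_gt(res$equivalency_p, 0.5)

  # centroids many bandwidths apart: observed D below the entire null
  sep <- separated_clouds(30, gap = 18, seed = 32)
  for (s in c(1, 2)) {
    r <- equivalency_test(sep$a, sep$b, sep$bg, reps = 50, R = 60, seed = s)
    expect_equal(r$equivalency_p, 1 / 51)
    expect_identical(r$equivalent, "Different")
  }
  expect_error(equivalency_test(cl$a[1:3, ], cl$a, cl$bg), "at least 5")
  expect_error(equivalency_test(cl$a, cl$b, cl$bg, reps = 0), "reps")
})

test_that("randomized tests reproduce bit-identically under a fixed seed", {
  cl <- separated_clouds(25, gap = 3, seed = 33)
  r1 <- equivalency_test(cl$a, cl$b, cl$bg, reps = 30, R = 50, seed = 99)
  r2 <- equivalency_test(cl$a, cl$b, cl$bg, reps = 30, R = 50, seed = 99)
  expect_identical(r1$null_D, r2$null_D)
  g_a <- build_grid(cl$a, cl$bg, R = 50)
  s1 <- similarity_test(g_a, cl$b, cl$bg, reps = 30, seed = 99)
  s2 <- similarity_test(g_a, cl$b, cl$bg, reps = 30, seed = 99)
  expect_identical(s1$null_D, s2$null_D)
})

test_that("similarity on a symmetric pair is direction-independent up to MC error", {
  cl <- separated_clouds(40, gap = 2, seed = 34)
  g_a <- build_grid(cl$a, cl$bg, R = 60)
  g_b <- build_grid(cl$b, cl$bg, R = 60)
  ab <- similarity_test(g_a, cl$b, cl$bg, reps = 200, seed = 7)
  ba <- similarity_test(g_b, cl$a, cl$bg, reps = 200, seed = 8)
  expect_lt(abs(ab$similarity_p_similar - ba$similarity_p_similar), 0.15)
})

test_that("a lineage spread uniformly over its background is rarely significant in either tail", {
  set.seed(36)
  bg <- cbind(runif(1500, -3, 3), runif(1500, -3, 3))
  a <- cbind(rnorm(40, -1, 0.5), rnorm(40, 0, 0.5))
  g_a <- build_grid(a, bg, R = 60)
  neither <- vapply(seq_len(50), function(i) {
    b <- cbind(runif(40, -3, 3), runif(40, -3, 3))
    s <- similarity_test(g_a, b, bg, reps = 100, seed = 500 + i)
    s$verdict == "ns"
  }, logical(1))
  # nominal ~>= 0.9; 0.82 allows two binomial SEs at 50 runs
  expect_gte(mean(neither), 0.82)
})

test_that("similarity p-values respect the +1 convention bounds", {
  cl <- separated_clouds(20, gap = 1, seed = 35)
  g_a <- build_grid(cl$a, cl$bg, R = 50)
  s <- similarity_test(g_a, cl$b, cl$bg, reps = 40, seed = 3)
  expect_gte(s$similarity_p_similar, 1 / 41)
  expect_gte(s$similarity_p_different, 1 / 41)
  expect_lte(s$similarity_p_similar, 1)
  expect_lte(s$similarity_p_different, 1)
})

test_that("compare_all returns all pairs, breadths and is seed-deterministic", {
  sim <- simulate_study(seed = 42, n_vars = 4, grid_dims = c(60, 60))
  occ <- suppressMessages(extract_env(sim$occurrences, sim$rasters))
  bg <- env_background(sim$rasters)[paste0("bio", 1:4)]
  res <- compare_all(occ, bg, R = 50, reps = 20, seed = 11)
  expect_equal(nrow(res$comparisons), 3L)     # 3 lineages -> 3 pairs
  expect_equal(nrow(res$breadth), 3L)
  expect_equal(sum(res$pca$explained), 1, tolerance = 1e-9)

  res2 <- compare_all(occ[sample(nrow(occ)), ], bg, R = 50, reps = 20, seed = 11)
  expect_equal(tidy(res), tidy(res2))         # input order irrelevant

  # engineered structure: the overlapping pair has the highest D and all
  # pairs with distinct samples are non-equivalent
  cmp <- tidy(res)
  top <- cmp[which.max(cmp$D), ]
  expect_setequal(c(top$lineage_a, top$lineage_b),
                  c("lineage_INV", "lineage_OW"))
  expect_true(all(cmp$equivalency_verdict == "Different"))
})

test_that("comparison CSV export mirrors the tidy table", {
  sim <- simulate_study(seed = 43, n_vars = 4, grid_dims = c(50, 50))
  occ <- suppressMessages(extract_env(sim$occurrences, sim$rasters))
  bg <- env_background(sim$rasters)[paste0("bio", 1:4)]
  res <- compare_all(occ, bg, R = 40, reps = 10, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_comparison_csv(res, path, dump_nulls = TRUE)
  back <- read.csv(path)
  expect_equal(nrow(back), 3L)
  expect_true(all(c("D", "similarity_ab_p", "similarity_ba_p",
                    "equivalency_p") %in% names(back)))
  nulls <- read.csv(sub("\\.csv$", "_nulls.csv", path))
  expect_equal(nrow(nulls), 3L * 3L * 10L)
})
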