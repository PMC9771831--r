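test_that("dice matches its closed-form examples and conventions", {
  cube <- array(FALSE, c(8, 8, 8)); cube[3:4, 3:4, 3:4] <- TRUE
  expect_equal(dice(cube, cube), 1.0)
  other <- array(FALSE, c(8, 8, 8)); other[6:7, 6:7, 6:7] <- TRUE
  expect_equal(dice(cube, other), 0.0)
  shifted <- array(FALSE, c(8, 8, 8)); shifted[3:4, 3:4, 4:5] <- TRUE
  expect_equal(dice(cube, shifted), 2 * 4 / (8 + 8))
  empty <- array(FALSE, c(8, 8, 8))
  expect_equal(dice(empty, empty), 1.0)        # agreement on absence
  expect_equal(dice(cube, shifted), dice(shifted, cube))
  expect_error(dice(cube, other[1:4, , ]), "grid")
})

test_that("volume similarity follows Eq. 2 and is grid-free", {
  a <- array(FALSE, c(10, 10, 10)); a[1:5, 1, 1] <- TRUE   # 5 voxels
  b <- array(FALSE, c(10, 10, 10)); b[6:10, 2, 1] <- TRUE  # disjoint, 5
  expect_equal(volume_similarity(a, b), 1.0)
  none <- array(FALSE, c(10, 10, 10))
  expect_equal(volume_similarity(a, none), 0.0)
  g <- array(FALSE, c(6, 6, 6)); g[1:60] <- TRUE           # 60 mm^3
  p <- array(FALSE, c(9, 9, 9)); p[1:40] <- TRUE           # 40 mm^3
  expect_equal(volume_similarity(g, p), 1 - 20 / 100)
  # identical values on a native grid and a tight crop
  big <- array(FALSE, c(20, 20, 20)); big[4:9, 4:9, 4:9] <- TRUE
  small <- big[3:12, 3:12, 3:12]
  pred_big <- array(FALSE, c(20, 20, 20)); pred_big[5:9, 4:9, 4:9] <- TRUE
  pred_small <- pred_big[3:12, 3:12, 3:12]
  expect_equal(volume_similarity(big, pred_big),
               volume_similarity(small, pred_small))
  expect_error(volume_similarity(none, none), "undefined")
})

test_that("boundary voxels are the 6-connectivity surface", {
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_equal(nrow(boundary_voxels(one)), 1)
  cube3 <- array(FALSE, c(7, 7, 7)); cube3[3:5, 3:5, 3:5] <- TRUE
  expect_equal(nrow(boundary_voxels(cube3)), 26)    # all but the center
  full <- array(TRUE, c(4, 4, 4))
  expect_equal(nrow(boundary_voxels(full)), 4^3 - 2^3)   # faces only
  expect_error(boundary_voxels(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("hausdorff distances match hand-constructed geometries", {
  a <- array(FALSE, c(10, 10, 10)); a[2, , ] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[5, , ] <- TRUE
  expect_equal(hausdorff_distance(a, b, percentile = 100), 3.0)
  expect_equal(hausdorff_distance(a, b, percentile = 95), 3.0)
  expect_equal(hausdorff_distance(a, a, percentile = 100), 0.0)
  expect_equal(hausdorff_distance(a, a, percentile = 95), 0.0)
  # one gross outlier: HD sees it, HD95 does not
  g <- array(FALSE, c(30, 25, 10)); g[1, 1:20, 1] <- TRUE
  p <- g; p[12, 1, 1] <- TRUE     # lone voxel 11 mm away
  hd <- hausdorff_distance(g, p, percentile = 100)
  hd95 <- hausdorff_distance(g, p, percentile = 95)
  expect_equal(hd, 11.0)
  expect_lt(hd95, hd)
  expect_warning(out <- hausdorff_distance(array(FALSE, c(4, 4, 4)), a[1:4, 1:4, 1:4]),
                 "empty")
  expect_true(is.na(out))
})

test_that("metrics agree with brute-force oracles on random masks", {
  set.seed(2024)
  n_cases <- 200
  for (rep in seq_len(n_cases)) {
    d <- sample(4:16, 3, replace = TRUE)
    sp <- sample(c(1, 0.8, 1.25), 3, replace = TRUE)
    G <- random_mask(d, p = stats::runif(1, 0.05, 0.5))
    P <- random_mask(d, p = stats::runif(1, 0.05, 0.5))
    expect_equal(dice(G, P), oracle_dice(G, P), tolerance = 1e-9)
    expect_equal(volume_similarity(G, P, sp, sp),
                 1 - abs(sum(G) - sum(P)) / (sum(G) + sum(P)),
                 tolerance = 1e-9)
    if (rep <= 60) {   # pairwise-distance oracle on a subset
      expect_equal(hausdorff_distance(G, P, sp, 100),
                   oracle_hausdorff(G, P, sp, 100), tolerance = 1e-9)
      expect_equal(hausdorff_distance(G, P, sp, 95),
                   oracle_hausdorff(G, P, sp, 95), tolerance = 1e-9)
      expect_lte(hausdorff_distance(G, P, sp, 95),
                 hausdorff_distance(G, P, sp, 100) + 1e-12)
      expect_equal(hausdorff_distance(G, P, sp, 100),
                   hausdorff_distance(P, G, sp, 100), tolerance = 1e-12)
    }
  }
})

test_that("per-structure reports flag absent structures and average the rest", {
  cs <- small_case()
  rep0 <- per_structure_report(cs$labels, cs$labels)
  main <- rep0[1:27, ]
  expect_true(all(main$dice[main$present] == 1))
  expect_true(all(main$hd_mm[main$present] == 0))
  macro <- attr(rep0, "macro")
  expect_equal(unname(macro["dice"]), 1)
  # drop one structure from both: flagged and excluded
  g2 <- cs$labels; g2$data[g2$data == 7L] <- 0L
  p2 <- g2
  rep2 <- per_structure_report(g2, p2)
  expect_false(rep2$present[rep2$label_id == 7])
  expect_equal(unname(attr(rep2, "macro")["n_present"]), 26)
  # macro mean equals the arithmetic mean of present rows
  pred <- cs$labels
  pred$data[pred$data == 3L] <- 2L
  rep3 <- per_structure_report(cs$labels, pred)
  m3 <- rep3[1:27, ]
  expect_equal(unname(attr(rep3, "macro")["dice"]),
               mean(m3$dice[m3$present]))
  expect_error(per_structure_report(cs$labels,
                                    cb_labels(array(0L, c(4, 4, 4)))),
               "grids differ")
})

test_that("ICC(3,1) matches an aov-based variance oracle", {
  set.seed(77)
  subj <- rnorm(12, 100, 15)
  s1 <- subj + rnorm(12, 0, 3)
  s2 <- subj + rnorm(12, 0, 3)
  res <- icc_agreement(s1, s2)
  # oracle via two-way ANOVA mean squares
  df <- data.frame(y = c(s1, s2), subj = factor(rep(1:12, 2)),
                   rater = factor(rep(1:2, each = 12)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]$`Mean Sq`
  icc_oracle <- (ms[1] - ms[3]) / (ms[1] + ms[3])
  expect_equal(res$icc, icc_oracle, tolerance = 1e-10)
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
})

test_that("ICC edge cases behave as documented", {
  x <- c(10, 20, 30, 40, 50)
  expect_equal(icc_agreement(x, x)$icc, 1.0)
  expect_equal(icc_agreement(x, x + 7)$icc, 1.0)   # consistency ignores offset
  expect_error(icc_agreement(x[1:2], x[1:2]), "at least 3")
  expect_error(icc_agreement(rep(5, 6), rep(5, 6)), "variance")
  # independent pairs: ICC near zero (seed-averaged)
  set.seed(123)
  iccs <- replicate(20, icc_agreement(rnorm(50), rnorm(50))$icc)
  expect_lt(abs(mean(iccs)), 0.3)
})

test_that("paired wilcoxon matches exhaustive sign enumeration at n = 6", {
  a <- c(12.1, 14.3, 9.8, 16.2, 11.0, 13.7)
  b <- c(11.0, 12.9, 10.5, 13.1, 10.2, 12.8)
  res <- paired_wilcoxon(a, b)
  expect_equal(res$p_value, oracle_signed_rank(a - b), tolerance = 1e-10)
  # swapping the samples flips the statistic's orientation, p unchanged
  res2 <- paired_wilcoxon(b, a)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
  n <- 6
  expect_equal(res$statistic + res2$statistic, n * (n + 1) / 2)
  expect_error(paired_wilcoxon(a, a), "zero")
  expect_error(paired_wilcoxon(a[1:3], b[1:3]), "at least 5")
})

test_that("outlier scan flags gross deviations per class", {
  expect_false(any(outlier_scan(rep(3.3, 10))))
  v <- c(rnorm(20, 0.9, 0.005), 0.2)
  fl <- outlier_scan(v)
  expect_true(fl[21])
  expect_false(any(fl[1:20]))
  # invariant to affine rescaling within a class
  expect_identical(outlier_scan(v), outlier_scan(10 * v + 3))
  # per-class grouping
  cl <- rep(c("a", "b"), each = 10)
  vals <- c(rnorm(10), rnorm(10, 100, 0.01))
  expect_identical(outlier_scan(vals, cl),
                   c(outlier_scan(vals[1:10]), outlier_scan(vals[11:20])))
})
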