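test_that("roc_auc matches pair counting on the worked examples", {
  expect_equal(roc_auc(c(0.1, 0.2), c(0.3, 0.4))$auc, 1.0)
  expect_equal(roc_auc(c(0.2, 0.35), c(0.3, 0.4))$auc, 0.75)
  # one shared value contributes half a pair
  expect_equal(roc_auc(c(0.3, 0.1), c(0.3, 0.5))$auc,
               auc_bruteforce(c(0.3, 0.1), c(0.3, 0.5)))
  expect_error(roc_auc(numeric(0), 1), "nonempty")
})

test_that("roc_auc equals the brute-force oracle and its own trapezoid on random instances", {
  set.seed(7)
  for (rep in 1:60) {
    np <- sample(2:12, 1); nc <- sample(2:12, 1)
    # mix of continuous and heavily tied data
    gen <- if (rep %% 2) function(n) runif(n) else function(n) sample(1:4, n, TRUE) / 10
    p <- gen(np); c0 <- gen(nc)
    r <- roc_auc(p, c0)
    expect_equal(r$auc, auc_bruteforce(p, c0), tolerance = 1e-12)
    expect_equal(roc_trapezoid(r), r$auc, tolerance = 1e-10)
    # orientation flip maps AUC -> 1 - AUC
    expect_equal(roc_auc(p, c0, "higher")$auc, 1 - r$auc, tolerance = 1e-12)
  }
})

test_that("delong_test is null for identical scorers and antisymmetric", {
  set.seed(11)
  lab <- rep(c(TRUE, FALSE), c(10, 8))
  a <- runif(18)
  r <- delong_test(a, a, lab)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  b <- runif(18)
  r1 <- delong_test(a, b, lab)
  r2 <- delong_test(b, a, lab)
  expect_equal(r1$z, -r2$z, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_error(delong_test(a, b[-1], lab), "aligned")
})

test_that("delong variance matches the enumerated placement-value oracle", {
  # tiny paired design with distinct scores
  a <- c(0.9, 0.7, 0.8, 0.3, 0.2, 0.4)   # scores, higher = patient-like
  b <- c(0.8, 0.6, 0.4, 0.5, 0.1, 0.35)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- delong_test(a, b, lab, orientation = "higher")
  oa <- placement_oracle(a[lab], a[!lab])
  ob <- placement_oracle(b[lab], b[!lab])
  expect_equal(r$auc_a, oa$auc, tolerance = 1e-12)
  expect_equal(r$auc_b, ob$auc, tolerance = 1e-12)
  # covariance structure: reconstruct the z statistic from the oracle pieces
  v10a <- sapply(a[lab], function(x) mean(x > a[!lab]) )
  v10b <- sapply(b[lab], function(x) mean(x > b[!lab]) )
  v01a <- sapply(a[!lab], function(y) mean(a[lab] > y))
  v01b <- sapply(b[!lab], function(y) mean(b[lab] > y))
  vd <- (var(v10a) + var(v10b) - 2 * cov(v10a, v10b)) / 3 +
    (var(v01a) + var(v01b) - 2 * cov(v01a, v01b)) / 3
  expect_equal(r$z, (oa$auc - ob$auc) / sqrt(vd), tolerance = 1e-10)
})

test_that("delong_test cross-checks against the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  lab <- rep(c(TRUE, FALSE), c(12, 10))
  a <- runif(22); b <- a * 0.5 + runif(22) * 0.5
  r <- delong_test(a, b, lab, orientation = "higher")
  ra <- pROC::roc(lab, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(lab, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(r$p, ref$p.value, tolerance = 1e-8)
  expect_equal(abs(r$z), abs(unname(ref$statistic)), tolerance = 1e-8)
})

test_that("spearman_total ranks subject totals with average-rank ties", {
  mk_cohort <- function(tot_rd, tot_mrss) {
    n <- length(tot_rd)
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(subject_id = sprintf("P%02d", i), group = "patient",
                 site = paste0("s", 1:6), wavelength = 851,
                 spatial_frequency = 0.15,
                 mean_rd = tot_rd[i] / 6, mrss = c(tot_mrss[i], rep(0, 5)))
    }))
  }
  up <- mk_cohort(c(1, 2, 3, 4), c(0, 1, 2, 3))
  expect_equal(spearman_total(up, 851, 0.15)$rho, 1)
  dn <- mk_cohort(c(4, 3, 2, 1), c(0, 1, 2, 3))
  expect_equal(spearman_total(dn, 851, 0.15)$rho, -1)
  # average-rank ties: x = {1,2,2,4}, y = {10,20,20,40} -> rho = 1
  tied <- mk_cohort(c(1, 2, 2, 4) * 6, c(1, 2, 2, 3))
  expect_equal(spearman_total(tied, 851, 0.15)$rho,
               cor(rank(c(1, 2, 2, 4)), rank(c(1, 2, 2, 3))), tolerance = 1e-12)
  # invariance under strictly monotone transforms of either total
  tr <- mk_cohort(exp(c(1, 2, 3, 4)), c(0, 1, 2, 3))
  expect_equal(spearman_total(tr, 851, 0.15)$rho, 1)
  # incomplete subjects are excluded with a message
  inc <- rbind(up, data.frame(subject_id = "P99", group = "patient",
                              site = "s1", wavelength = 851,
                              spatial_frequency = 0.15, mean_rd = 1, mrss = 2))
  expect_message(r <- spearman_total(inc, 851, 0.15), "excluded")
  expect_equal(r$n_excluded, 1L)
  expect_error(suppressMessages(spearman_total(up[up$subject_id %in%
    c("P01", "P02"), ], 851, 0.15)), "at least 3")
})

test_that("rank_sum_test reproduces the exact small-sample p-value and the U identity", {
  r0 <- rank_sum_test(c(1, 2, 3), c(1, 2, 3) + 1e-9)
  expect_gt(r0$p, 0.6) # near-identical groups are not separable
  r <- rank_sum_test(1:3, 4:6)
  expect_equal(r$p, 0.1, tolerance = 1e-12) # 2 of 20 orderings as extreme
  expect_equal(r$U, 0)
  p <- c(0.3, 0.5, 0.8, 0.2); c0 <- c(0.4, 0.9, 0.7)
  up <- rank_sum_test(p, c0)$U
  uc <- rank_sum_test(c0, p)$U
  expect_equal(up + uc, length(p) * length(c0))
})

test_that("build_heatmaps finds a planted perfectly separating cell", {
  set.seed(17)
  wls <- c(691, 851); fxs <- c(0.05, 0.15, 0.3)
  rows <- list()
  for (wl in wls) for (fx in fxs) {
    sep <- (wl == 851 && fx == 0.15)
    for (g in c("patient", "control")) for (i in 1:6) {
      rd <- if (sep && g == "patient") runif(1, 0.1, 0.2) else
        if (sep) runif(1, 0.4, 0.5) else runif(1, 0.2, 0.5)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = paste0(substr(g, 1, 1), i), group = g, site = "hand_left",
        wavelength = wl, spatial_frequency = fx, mean_rd = rd,
        mrss = if (g == "patient") 2L else 0L)
    }
  }
  cohort <- do.call(rbind, rows)
  hm <- build_heatmaps(cohort, "auc")
  expect_equal(dim(hm$values), c(2L, 3L))
  expect_equal(hm$values["851", "0.15"], 1.0)
  expect_equal(hm$argmax$wavelength, 851)
  expect_equal(hm$argmax$spatial_frequency, 0.15)
  # permutation invariance under subject relabeling
  cohort2 <- cohort
  cohort2$subject_id <- paste0("x", cohort2$subject_id)
  hm2 <- build_heatmaps(cohort2, "auc")
  expect_identical(hm$values, hm2$values)
})

test_that("race stratification filters rows before the grid is built", {
  co <- gen_cohort(n_patient = 10, n_control = 8, seed = 23)
  hm_all <- build_heatmaps(co, "auc")
  hm_w <- build_heatmaps(co, "auc", stratum = "White")
  expect_false(identical(hm_all$values, hm_w$values))
  expect_error(build_heatmaps(co, "auc", stratum = "Martian"), "no rows")
  co$race <- NULL
  expect_error(build_heatmaps(co, "auc", stratum = "White"), "no 'race' column")
})

test_that("rank_sum_grid covers every cell and Bonferroni only inflates p", {
  co <- gen_cohort(wavelengths = c(811, 851), spatial_frequencies = c(0.1, 0.2),
                   effect_cell = c(851, 0.2), effect_size_d = 2, seed = 29)
  p <- rank_sum_grid(co)
  expect_equal(dim(p), c(2L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(p["851", "0.2"], 0.001) # the planted cell separates strongly
  pb <- rank_sum_grid(co, adjust = "bonferroni")
  expect_true(all(pb >= p))
  expect_equal(pmin(1, p * 4), pb)
})

test_that("cohort_table validates its schema", {
  expect_error(cohort_table(data.frame(a = 1)), "lacks columns")
  good <- data.frame(subject_id = "P1", group = "patient", site = "hand_left",
                     wavelength = 851, spatial_frequency = 0.15,
                     mean_rd = 0.5, mrss = 2L)
  expect_s3_class(cohort_table(good), "cohort_table")
  bad <- good; bad$mrss <- 7L
  expect_error(cohort_table(bad), "0..3")
  bad2 <- good; bad2$group <- "sick"
  expect_error(cohort_table(bad2), "patient")
})
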