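test_that("Bland-Altman statistics match hand computation", {
  # differences (2, -3, 1): bias 0, sd sqrt(7)
  pairs <- make_pairs(sbp_ref = c(120, 130, 140),
                      sbp_pred = c(122, 127, 141))
  ba <- bland_altman(pairs, "sbp")
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, sqrt(7))
  expect_equal(unname(ba$loa), c(-1.96, 1.96) * sqrt(7))
  expect_true(ba$ci[1] <= ba$bias && ba$bias <= ba$ci[2])
})

test_that("Bland-Altman handles identity, offsets and permutations", {
  x <- c(118, 125, 133, 147, 152, 160)
  ident <- bland_altman(make_pairs(x), "sbp")
  expect_equal(ident$bias, 0)
  expect_equal(ident$sd, 0)
  expect_true(is.na(ident$p))
  off <- bland_altman(make_pairs(x, x + 5), "sbp")
  expect_equal(off$bias, 5)
  expect_equal(off$sd, 0)
  expect_equal(unname(off$loa), c(5, 5))
  set.seed(3)
  pairs <- make_pairs(x, x + stats::rnorm(6))
  perm <- pairs[sample(6), ]
  b1 <- bland_altman(pairs, "sbp"); b2 <- bland_altman(perm, "sbp")
  expect_equal(b1$bias, b2$bias)
  expect_equal(b1$sd, b2$sd)
  expect_equal(b1$p, b2$p)
})

test_that("Spearman correlation is monotone-invariant with correct sign", {
  x <- c(105, 118, 122, 131, 140, 150, 163)
  expect_equal(spearman_corr(make_pairs(x, exp(x / 50)), "sbp")$r, 1)
  expect_equal(spearman_corr(make_pairs(x, rev(x)), "sbp")$r, -1)
  expect_true(is.na(spearman_corr(make_pairs(x, rep(120, 7)), "sbp")$r))
  # ten-pair fixture against the rank formula 1 - 6*sum(d^2)/(n(n^2-1))
  set.seed(11)
  a <- sample(100:180, 10); b <- sample(100:180, 10)
  d <- rank(a) - rank(b)
  oracle <- 1 - 6 * sum(d^2) / (10 * (100 - 1))
  expect_equal(spearman_corr(make_pairs(a, b), "sbp")$r, oracle,
               tolerance = 1e-12)
})

test_that("zone labels reproduce the worked reference cases", {
  expect_equal(zone_of(140, 140), "A")
  expect_equal(zone_of(140, 100), "C")
  expect_equal(zone_of(140, 80), "E")
  expect_equal(zone_of(140, 128.35), "A")
  expect_equal(zone_of(140, 128.30), "B")
  expect_equal(zone_of(140, c(150, 160, 170, 190, 200)),
               c("A", "B", "C", "D", "E"))
  expect_error(zone_of(0, 100), "positive")
})

test_that("zone assignment is symmetric and monotone in deviation", {
  ref <- 133
  devs <- seq(0, 0.6, by = 0.01)
  up <- zone_of(rep(ref, length(devs)), ref * (1 + devs))
  dn <- zone_of(rep(ref, length(devs)), ref * (1 - devs))
  expect_equal(up, dn)
  expect_true(all(diff(match(up, LETTERS)) >= 0))
})

test_that("zone boundaries reproduce the printed reference values", {
  zb <- zone_boundaries(140)
  expect_equal(zb$lower, c(128.3, 116.7, 93.3, 81.7))
  expect_equal(zb$upper, c(151.7, 163.3, 186.7, 198.3))
  # symmetric about any reference before rounding
  zb2 <- zone_boundaries(120)
  expect_equal(zb2$upper - 120, 120 - zb2$lower)
})

test_that("half-up rounding differs from banker's rounding where it must", {
  expect_equal(round_half_up(128.35, 1), 128.4)
  expect_equal(round_half_up(-128.35, 1), -128.4)
  expect_equal(round_half_up(128.333, 1), 128.3)
})

test_that("error grid partitions and counts correctly", {
  x <- c(110, 125, 140, 155, 170)
  perfect <- error_grid(make_pairs(x), "sbp")
  expect_equal(perfect$percent$A, 100)
  # one engineered pair per zone, built from the zone boundaries
  ref <- rep(140, 5)
  pred <- c(140, 140 * (1 + 1.5 / 12), 140 * (1 + 3 / 12),
            140 * (1 + 4.5 / 12), 140 * (1 + 6 / 12))
  eg <- error_grid(data.frame(sbp_ref = ref, sbp_pred = pred,
                              dbp_ref = 80, dbp_pred = 80), "sbp")
  expect_equal(unlist(eg$counts), c(A = 1, B = 1, C = 1, D = 1, E = 1))
  set.seed(8)
  rnd <- make_pairs(stats::runif(40, 95, 170),
                    stats::runif(40, 60, 220))
  expect_equal(Reduce(`+`, error_grid(rnd, "sbp")$percent), 100)
})

test_that("subgroup errors follow the reference-based grouping", {
  # low: SBP < 110 and DBP < 70; high: SBP > 140 or DBP > 90
  pairs <- data.frame(
    sbp_ref = c(105, 104, 103, 102, 101, 125, 126, 127, 150, 151),
    dbp_ref = c(65, 64, 63, 62, 61, 80, 81, 79, 95, 96),
    sbp_pred = c(106, 106, 106, 106, 106, 125, 126, 127, 150, 151),
    dbp_pred = c(65, 64, 63, 62, 61, 80, 81, 79, 95, 96))
  pairs$sbp_pred[1:5] <- pairs$sbp_ref[1:5] + 1:5
  tab <- subgroup_errors(pairs)
  expect_equal(sum(tab$n[tab$target == "sbp"]), nrow(pairs))
  low_sbp <- tab[tab$subgroup == "low" & tab$target == "sbp", ]
  expect_equal(low_sbp$mean, 3)
  expect_equal(low_sbp$median, 3)
  expect_equal(c(low_sbp$q25, low_sbp$q75), c(2, 4))
  mid_sbp <- tab[tab$subgroup == "middle" & tab$target == "sbp", ]
  expect_equal(mid_sbp$mean, 0)
  expect_true(is.na(mid_sbp$p))  # degenerate all-zero errors
})

test_that("an empty subgroup yields a warned null row", {
  pairs <- make_pairs(c(125, 130, 135), c(126, 131, 136))
  w <- capture_warnings(tab <- subgroup_errors(pairs))
  expect_true(any(grepl("empty subgroup", w)))
  expect_equal(tab$n[tab$subgroup == "low"], c(0L, 0L))
  expect_true(all(is.na(tab$mean[tab$subgroup == "low"])))
})

test_that("hypertension classification metrics match the confusion table", {
  pairs <- make_pairs(c(150, 155, 120, 125, 145, 130),
                      c(151, 154, 121, 126, 146, 131))
  cl <- classify_hypertension(pairs, "hypertension")
  expect_equal(cl$sensitivity, 100)
  expect_equal(cl$specificity, 100)
  expect_equal(cl$accuracy, 100)
  # constructed table: TP 8, FN 2, TN 85, FP 5 -> sens 80%, spec 94.4%
  n <- 100
  sbp_ref <- c(rep(150, 10), rep(120, 90))
  sbp_pred <- c(rep(150, 8), rep(120, 2), rep(150, 5), rep(120, 85))
  pairs2 <- data.frame(sbp_ref = sbp_ref, sbp_pred = sbp_pred,
                       dbp_ref = 80, dbp_pred = 80)
  cl2 <- classify_hypertension(pairs2, "hypertension")
  expect_equal(unlist(cl2$confusion), c(tp = 8, fp = 5, tn = 85, fn = 2))
  expect_equal(cl2$sensitivity, 80)
  expect_equal(cl2$specificity, 100 * 85 / 90, tolerance = 1e-9)
  expect_equal(cl2$accuracy, 93)
})

test_that("degenerate scores give chance-level AUC, single-class warns", {
  pairs <- data.frame(sbp_ref = c(150, 150, 120, 120),
                      sbp_pred = rep(130, 4),
                      dbp_ref = 80, dbp_pred = 80)
  cl <- classify_hypertension(pairs, "hypertension")
  expect_equal(cl$auc, 0.5)
  single <- make_pairs(c(120, 125, 130), c(121, 126, 131))
  expect_warning(cls <- classify_hypertension(single, "hypertension"),
                 "single-class")
  expect_true(is.na(cls$sensitivity))
})

test_that("prehypertension uses the 130/85 threshold pair", {
  pairs <- make_pairs(sbp_ref = c(132, 128, 120),
                      sbp_pred = c(132, 128, 120),
                      dbp_ref = c(80, 86, 70), dbp_pred = c(80, 86, 70))
  cl <- classify_hypertension(pairs, "prehypertension")
  # 132 > 130 positive; 86 > 85 positive; third negative
  expect_equal(unlist(cl$confusion), c(tp = 2, fp = 0, tn = 1, fn = 0))
})

test_that("full evaluation report carries every section", {
  set.seed(14)
  ref <- stats::runif(30, 95, 170)
  pairs <- make_pairs(ref, ref + stats::rnorm(30, 0, 4))
  rep1 <- evaluate_predictions(pairs)
  expect_equal(rep1$n, 30)
  expect_named(rep1$bland_altman, c("sbp", "dbp"))
  expect_equal(Reduce(`+`, rep1$error_grid$sbp$percent), 100)
  expect_true(all(c("low", "middle", "high") %in% rep1$subgroups$subgroup))
  expect_true(rep1$classification$hypertension$auc >= 0 &&
                rep1$classification$hypertension$auc <= 1)
})

test_that("agreement on a noisy-but-unbiased cohort stays inside the limits", {
  set.seed(25)
  n <- 400
  ref <- stats::runif(n, 95, 170)
  pred <- ref + stats::rnorm(n, 0, sqrt(3^2 + 2^2))
  ba <- bland_altman(make_pairs(ref, pred), "sbp")
  expect_lt(abs(ba$bias), 3 * ba$sd / sqrt(n))
  inside <- mean(ba$diffs >= ba$loa[1] & ba$diffs <= ba$loa[2])
  expect_gt(inside, 0.93)  # ~95% within binomial tolerance
})
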