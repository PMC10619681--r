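test_that("Wilcoxon exact path agrees with full permutation enumeration", {
  # hand-derived anchor: complete separation of 3 vs 3 gives p = 2/20
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)
  expect_equal(w$direction, -1)

  # identical samples: p = 1
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2))$p_value, 1)

  # symmetry: swapped arguments give the same p, negated direction
  set.seed(3)
  x <- rnorm(5); y <- rnorm(7) + 1
  expect_equal(wilcoxon_rank_sum(x, y)$p_value, wilcoxon_rank_sum(y, x)$p_value)
  expect_equal(wilcoxon_rank_sum(x, y)$direction,
               -wilcoxon_rank_sum(y, x)$direction)

  # exact p equals brute-force enumeration for tie-free samples, n1,n2 <= 6
  set.seed(17)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2) + runif(1, -1, 1)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, wilcoxon_permutation_p(x, y),
                 tolerance = 1e-12)
  }

  # approximate path close to exact at n1 = n2 = 8, no ties
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8) + runif(1, -0.5, 0.5)
    p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    p_approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(0.03)$q, 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.9))$q, c(0.03, 0.03, 0.9))

  # against the hand formula on random p-values
  set.seed(21)
  p <- runif(25)^2
  q_hand <- {
    o <- order(p)
    m <- length(p)
    q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
    out <- numeric(m); out[o] <- pmin(q_sorted, 1); out
  }
  adj <- bh_adjust(p, fdr = 0.20)
  expect_equal(adj$q, q_hand)
  expect_equal(adj$significant, q_hand <= 0.20)
  # q-values are monotone in p-rank and never below p
  expect_true(all(adj$q >= adj$p))
  expect_true(all(diff(adj$q[order(adj$p)]) >= -1e-12))
})

test_that("AUC equals brute-force pair counting, with ties and both labels", {
  expect_equal(roc_auc(c(3, 5, 1, 4), rep(c("case", "ctl"), each = 2), "case"),
               0.75)
  # perfectly separated and fully tied scores
  expect_equal(roc_auc(c(5, 6, 1, 2), rep(c("case", "ctl"), each = 2), "case"), 1)
  expect_equal(roc_auc(rep(1, 10), rep(c("case", "ctl"), 5), "case"), 0.5)

  set.seed(9)
  for (i in 1:20) {
    n1 <- sample(2:25, 1); n2 <- sample(2:25, 1)
    cases <- sample(1:10, n1, replace = TRUE) + sample(c(0, 0.5), n1, TRUE)
    controls <- sample(1:10, n2, replace = TRUE)
    scores <- c(cases, controls)
    labels <- rep(c("case", "ctl"), c(n1, n2))
    a <- roc_auc(scores, labels, "case")
    expect_equal(a, auc_pairs(cases, controls), tolerance = 1e-12)
    # label swap complements the AUC
    expect_equal(roc_auc(scores, labels, "ctl"), 1 - a, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("case", 3), "case"), class = "glyco_schema_error")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  scores <- c(rnorm(30, 1), rnorm(40))
  labels <- rep(c(1, 0), c(30, 40))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, direction = "<",
                                        levels = c(0, 1), quiet = TRUE)))
  expect_equal(roc_auc(scores, labels, positive = 1), ref, tolerance = 1e-12)
})

test_that("ROC curves carry endpoints and a monotone sens/spec trade-off", {
  set.seed(2)
  scores <- c(rnorm(15, 1), rnorm(15))
  labels <- rep(c("case", "ctl"), each = 15)
  rc <- roc_curve(scores, labels, "case")
  expect_true(any(rc$sensitivity == 1 & rc$specificity == 0))
  expect_true(any(rc$sensitivity == 0 & rc$specificity == 1))
  # rows run from high to low threshold: sensitivity rises as specificity falls
  expect_true(all(diff(rc$sensitivity) >= 0))
  expect_true(all(diff(rc$specificity) <= 0))
})

test_that("operating points use empirical thresholds without interpolation", {
  rc <- roc_curve(c(3, 5, 1, 4), rep(c("case", "ctl"), each = 2), "case")
  # specificity >= 0.9 forces the threshold above 4: only one case remains
  expect_equal(operating_point(rc, "specificity", 0.90), 0.5)
  expect_equal(operating_point(rc, "sensitivity", 0.90), 0.5)

  # perfect marker: 1.0 at either fixed level
  rc_perf <- roc_curve(c(9, 8, 1, 2), rep(c("case", "ctl"), each = 2), "case")
  expect_equal(operating_point(rc_perf, "specificity"), 1)
  expect_equal(operating_point(rc_perf, "sensitivity"), 1)

  # useless marker at large n: complementary metric ~ 1 - level
  set.seed(8)
  scores <- rnorm(1000)
  labels <- rep(c("case", "ctl"), 500)
  rc_null <- roc_curve(scores, labels, "case")
  expect_lt(abs(operating_point(rc_null, "specificity", 0.9) - 0.1), 0.05)
})

test_that("marker evaluation links U to AUC and ranks a designed marker first", {
  cfg <- small_config(effect_map = dplyr::mutate(null_effect_map(),
                                                 early = ifelse(class == "fucosylation_4",
                                                                0.98, early)))
  co <- generate_cohort(cfg, seed = 101)
  dat <- impute_min(normalize_to_standard(co$quant, co$heavy)) |>
    dplyr::rename(marker_id = compound_id)
  ev <- evaluate_markers(dat, co$meta, c("control", "early"))
  expect_s3_class(ev, "marker_eval")

  # the designed strong markers top the AUC ranking
  designed <- co$truth$compounds$compound_id[co$truth$compounds$designed_auc_early > 0.9]
  top <- ev$marker[which.max(ev$auc_oriented)]
  expect_true(top %in% designed)

  # U / (n1 n2) = AUC for every marker (independent recomputation)
  for (m in sample(ev$marker, 8)) {
    vals <- dat[dat$marker_id == m, ]
    x <- vals$area[vals$sample_id %in% co$meta$sample_id[co$meta$group == "early"]]
    y <- vals$area[vals$sample_id %in% co$meta$sample_id[co$meta$group == "control"]]
    u <- wilcoxon_rank_sum(x, y)$statistic
    expect_equal(u / (length(x) * length(y)),
                 ev$auc_fixed[ev$marker == m], tolerance = 1e-12)
  }

  expect_error(evaluate_markers(dat, co$meta, c("early", "early")),
               class = "glyco_schema_error")

  g <- glance(ev)
  expect_equal(g$n_markers, nrow(ev))
  expect_true(all(c("band_gt90", "nested_gt70") %in% names(g)))
  expect_s3_class(tidy(ev), "tbl_df")
  expect_false(inherits(tidy(ev), "marker_eval"))
})

test_that("permuted labels keep BH-significant markers near the null expectation", {
  co <- generate_cohort(small_config(effect_map = null_effect_map()), seed = 55)
  dat <- impute_min(normalize_to_standard(co$quant, co$heavy)) |>
    dplyr::rename(marker_id = compound_id)
  meta_perm <- co$meta
  set.seed(99)
  meta_perm$group <- sample(meta_perm$group)
  ev <- evaluate_markers(dat, meta_perm, c("control", "early"))
  # under the global null BH rarely flags anything at 20%
  expect_lte(mean(ev$significant), 0.20)
})

test_that("stratified evaluation skips small strata and matches the whole cohort", {
  co <- generate_cohort(small_config(), seed = 77)
  dat <- impute_min(normalize_to_standard(co$quant, co$heavy)) |>
    dplyr::rename(marker_id = compound_id)

  # a stratum with fewer than min_n per group is skipped with a reason
  meta_small <- co$meta
  meta_small$phenotype <- rep(c("2-1", "2-2"), c(9, nrow(meta_small) - 9))
  res <- suppressMessages(
    stratified_evaluate(dat, meta_small, c("control", "early"),
                        stratum = "phenotype", min_n = 10)
  )
  expect_false("2-1" %in% names(res$strata))
  expect_true(nrow(res$skipped) >= 1)

  # a stratum equal to the whole cohort reproduces the unstratified result
  meta_one <- dplyr::mutate(co$meta, stratum_all = "all")
  res_one <- stratified_evaluate(dat, meta_one, c("control", "early"),
                                 stratum = "stratum_all", min_n = 2)
  expect_equal(tibble::as_tibble(res_one$strata[["all"]])[, c("marker", "p", "auc_fixed")],
               tibble::as_tibble(res_one$whole)[, c("marker", "p", "auc_fixed")])
  expect_equal(res_one$comparison$auc_delta, rep(0, nrow(res_one$comparison)))
})
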