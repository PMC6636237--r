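test_that("outcome classification follows the location and precision rules", {
  gold_ep <- diagnosis("ectopic", "tubal")
  # the dangerous error: a tubal pregnancy read as intrauterine
  f <- classify_outcome(gold_ep, diagnosis("intrauterine"))
  expect_true(f[["fn_ep"]])
  expect_false(f[["correct_location"]])
  # a conclusion identical to gold is correct and exact, with no FP/FN
  f <- classify_outcome(gold_ep, gold_ep)
  expect_equal(unname(f), c(TRUE, TRUE, FALSE, FALSE))
  # ectopic recognized but site not stated: correct, not exact
  f <- classify_outcome(gold_ep, diagnosis("ectopic", "unspecified"))
  expect_true(f[["correct_location"]])
  expect_false(f[["exact_diagnosis"]])
  # an indeterminate conclusion locates nothing: neither correct nor a FP
  f <- classify_outcome(diagnosis("intrauterine"),
                        diagnosis("pregnancy_of_unknown_location"))
  expect_false(f[["correct_location"]])
  expect_false(f[["fp_ep"]])
  # indeterminate on an ectopic gold is a missed ectopic
  f <- classify_outcome(gold_ep, diagnosis("pregnancy_of_unknown_location"))
  expect_true(f[["fn_ep"]])
  expect_error(classify_outcome(diagnosis("pregnancy_of_unknown_location"),
                                gold_ep), "definite")
})

test_that("classification invariants hold over the full diagnosis cross-product", {
  golds <- list(diagnosis("intrauterine"), diagnosis("ectopic", "tubal"),
                diagnosis("ectopic", "interstitial"), diagnosis("ectopic"))
  for (gold in golds) {
    for (concl in all_diagnoses()) {
      f <- classify_outcome(gold, concl)
      if (f[["exact_diagnosis"]]) expect_true(f[["correct_location"]])
      if (f[["fn_ep"]]) {
        expect_equal(gold$location_class, "ectopic")
        expect_false(f[["correct_location"]])
      }
      if (f[["fp_ep"]]) {
        expect_false(gold$location_class == "ectopic")
        expect_false(f[["correct_location"]])
      }
    }
  }
})

test_that("integer percentages reproduce the published table arithmetic", {
  expect_identical(proportion_pct(52, 64), 81L)
  expect_identical(proportion_pct(39, 64), 61L)
  expect_identical(proportion_pct(49, 64), 77L)
  expect_identical(proportion_pct(30, 64), 47L)
  expect_identical(proportion_pct(13, 64), 20L) # correct-location difference
  expect_identical(proportion_pct(19, 64), 30L) # 29.6875 rounds half-up to 30
  expect_identical(proportion_pct(0, 64), 0L)
  expect_error(proportion_pct(5, 0), "positive")
  expect_error(proportion_pct(65, 64), "count")
})

test_that("percent change reproduces the published quality and image-count deltas", {
  expect_identical(pct_change(12.5, 10.2), 23L)
  expect_identical(pct_change(4.64, 6.33), -27L)
  expect_identical(pct_change(4.12, 3.42), 20L)
  expect_identical(pct_change(14.7, 6.4), 130L)
  expect_error(pct_change(1, 0), "nonzero")
})

test_that("the paired t statistic matches hand computation and stats::t.test", {
  pt <- paired_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(pt$t_statistic, -2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(round(pt$t_statistic, 4), -3.4641)
  expect_equal(pt$degrees_freedom, 2L)
  expect_equal(pt$difference, -2)

  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    pt <- paired_t(x, y)
    ref <- stats::t.test(x, y, paired = TRUE)
    expect_equal(pt$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(pt$p_value, ref$p.value, tolerance = 1e-10)
    # independent route: integrate the t density
    expect_equal(pt$p_value, quadrature_t_p(pt$t_statistic, n - 1),
                 tolerance = 1e-7)
  }

  expect_error(paired_t(1:3, 1:2), "equal length")
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "zero variance")
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "zero variance")
})

test_that("the exact McNemar p value equals binomial-tail enumeration", {
  expect_equal(mcnemar_exact(4, 4), 1)
  expect_equal(mcnemar_exact(13, 0), 2 * 0.5^13)
  expect_equal(round(mcnemar_exact(15, 2), 5), 0.00235)
  for (n in 1:20)
    for (b in 0:n) {
      expect_equal(mcnemar_exact(b, n - b), enum_mcnemar(b, n - b),
                   tolerance = 1e-12)
      expect_equal(mcnemar_exact(b, n - b), mcnemar_exact(n - b, b)) # symmetry
      p <- mcnemar_exact(b, n - b)
      expect_gt(p, 0); expect_lte(p, 1)
    }
  expect_error(mcnemar_exact(0, 0), "undefined")
  expect_error(mcnemar_exact(-1, 2), "nonnegative")
  expect_error(mcnemar_exact(1.5, 2), "nonnegative")
})

test_that("weighted kappa matches hand-built contingency computations", {
  expect_equal(weighted_kappa(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(weighted_kappa(rep(2, 5), rep(2, 5), categories = 1:3), 1)
  # full reversal on a 3-point scale, hand-computed:
  # linear: Po = 1/3, Pe = 5/9 -> kappa = -1/2; quadratic: -1
  expect_equal(weighted_kappa(c(1, 2, 3), c(3, 2, 1), categories = 1:3,
                              weights = "linear"), -0.5)
  expect_equal(weighted_kappa(c(1, 2, 3), c(3, 2, 1), categories = 1:3,
                              weights = "quadratic"), -1)

  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    r1 <- sample(1:5, n, replace = TRUE)
    r2 <- sample(1:5, n, replace = TRUE)
    for (w in c("linear", "quadratic")) {
      k <- weighted_kappa(r1, r2, categories = 1:5, weights = w)
      expect_equal(k, hand_weighted_kappa(r1, r2, 1:5, w), tolerance = 1e-12)
      expect_lte(k, 1)
      if (!all(r1 == r2)) expect_lt(k, 1)
      # invariant under an order/spacing-preserving relabeling
      expect_equal(weighted_kappa(r1 * 10 + 3, r2 * 10 + 3,
                                  categories = (1:5) * 10 + 3, weights = w),
                   k, tolerance = 1e-12)
    }
  }
  expect_error(weighted_kappa(1:3, 1:2), "equal length")
  expect_error(weighted_kappa(c(1, 9), c(1, 2), categories = 1:5),
               "outside")
})

test_that("Wald intervals for proportion differences behave as stated", {
  ci <- wald_ci_diff(0.8125, 0.6094, 64)
  expect_equal(unname(round(ci, 1)), c(5.0, 35.6))
  # symmetric null centers at zero
  ci0 <- wald_ci_diff(0.5, 0.5, 1e6)
  expect_equal(unname(ci0[1]), -unname(ci0[2]), tolerance = 1e-9)
  expect_lt(abs(mean(ci0)), 0.2)
  # width shrinks monotonically with n
  widths <- vapply(c(10, 50, 250, 1250), function(n)
    diff(unname(wald_ci_diff(0.7, 0.5, n))), numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(wald_ci_diff(1.2, 0.5, 10), "\\[0, 1\\]")
})

test_that("study summaries recompute the published outcome counts from records", {
  summ <- summarize_study(table2_records())
  t2 <- summ$table2
  expect_equal(summ$n_per_mode, 64L)
  expect_equal(t2$n_assisted, c(52L, 49L, 1L, 3L))
  expect_equal(t2$n_nonassisted, c(39L, 30L, 8L, 3L))
  expect_equal(t2$pct_assisted[1:2], c(81L, 77L))
  expect_equal(t2$pct_nonassisted[1:2], c(61L, 47L))
  expect_equal(t2$difference_n[1:2], c(13L, 19L))
  expect_equal(t2$difference_pct[1:2], c(20L, 30L))
})

test_that("summary means equal brute-force arithmetic on random record sets", {
  set.seed(31)
  recs <- run_study(study_design(seed = 202))
  summ <- summarize_study(recs)
  for (i in seq_len(nrow(summ$table1))) {
    col <- c("image_count", "duration_min", "quality_score", "trust_level")[i]
    expect_equal(summ$table1$mean_assisted[i],
                 mean(recs[[col]][recs$mode == "assisted"]))
    expect_equal(summ$table1$mean_nonassisted[i],
                 mean(recs[[col]][recs$mode == "nonassisted"]))
  }
  # discordant counts feed the McNemar test consistently
  cr <- classify_records(recs)
  a <- cr[cr$mode == "assisted", ]; b <- cr[cr$mode == "nonassisted", ]
  a <- a[order(a$case_id, a$operator_id), ]; b <- b[order(b$case_id, b$operator_id), ]
  db <- sum(a$correct_location & !b$correct_location)
  dc <- sum(!a$correct_location & b$correct_location)
  expect_equal(summ$table2$discordant_b[1], db)
  expect_equal(summ$table2$discordant_c[1], dc)
  expect_equal(summ$table2$p_value[1], mcnemar_exact(db, dc))
})

test_that("a single pair of identical records summarizes to zero differences", {
  rec <- data.frame(case_id = "c1", operator_id = "op1",
                    mode = c("assisted", "nonassisted"),
                    gold_location = "intrauterine", gold_site = "",
                    concl_location = "intrauterine", concl_site = "",
                    image_count = 5L, duration_min = 10, quality_score = 12L,
                    trust_level = 4L, stringsAsFactors = FALSE)
  summ <- summarize_study(rec)
  expect_true(all(summ$table1$difference == 0))
  expect_true(all(is.na(summ$table1$p_value))) # t undefined on one pair
  expect_true(all(summ$table2$difference_n == 0))
})

test_that("unpaired records are rejected", {
  recs <- table2_records()
  expect_error(summarize_study(recs[-1, ]), "pair")
})

test_that("scan records round-trip through CSV", {
  recs <- table2_records()
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_scan_records(recs, f)
  recs2 <- read_scan_records(f)
  expect_equal(recs2, recs)
})
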