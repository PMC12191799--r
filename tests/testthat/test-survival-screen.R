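test_that("median_stratify sends median ties low and partitions the cohort", {
  v <- setNames(c(1, 2, 3, 4, 5), paste0("s", 1:5))
  g <- median_stratify(v)
  expect_setequal(g$low_ids, c("s1", "s2", "s3"))
  expect_setequal(g$high_ids, c("s4", "s5"))
  expect_identical(g$median_value, 3)

  v2 <- setNames(c(1, 1, 2, 2), paste0("s", 1:4))
  g2 <- median_stratify(v2)
  expect_identical(g2$median_value, 1.5)
  expect_setequal(g2$low_ids, c("s1", "s2"))

  # 189 distinct values: 95 low / 94 high
  v3 <- setNames(sample(seq_len(189)), sprintf("p%03d", 1:189))
  g3 <- median_stratify(v3)
  expect_length(g3$low_ids, 95L)
  expect_length(g3$high_ids, 94L)

  expect_error(median_stratify(setNames(rep(1, 6), paste0("s", 1:6))), "degenerate")
  expect_error(median_stratify(setNames(1:3, paste0("s", 1:3))), "4 subjects")
  expect_error(median_stratify(1:5), "named")
})

test_that("km_logrank agrees with the risk-set enumeration oracle", {
  # 6-subject fixture: times 1..6, alternating groups, all events
  coh <- make_cohort(1:6)
  g <- list(
    low_ids = coh$subject_id[c(1, 3, 5)],
    high_ids = coh$subject_id[c(2, 4, 6)],
    median_value = NA_real_
  )
  class(g) <- "stratified_groups"
  p_pkg <- km_logrank(g, coh)
  p_oracle <- logrank_oracle_p(1:6, rep(TRUE, 6), c(FALSE, TRUE)[c(1, 2, 1, 2, 1, 2)])
  expect_equal(p_pkg, p_oracle, tolerance = 1e-12)

  # larger random fixtures with censoring and ties
  withr::with_seed(44, {
    for (rep in 1:5) {
      n <- 30
      time <- sample(1:40, n, replace = TRUE)
      ev <- runif(n) < 0.8
      high <- runif(n) < 0.5
      if (!any(high) || all(high) || !any(ev)) next
      coh2 <- make_cohort(time, events = ev)
      g2 <- structure(
        list(
          low_ids = coh2$subject_id[!high],
          high_ids = coh2$subject_id[high], median_value = NA_real_
        ),
        class = "stratified_groups"
      )
      expect_equal(km_logrank(g2, coh2), logrank_oracle_p(time, ev, high),
        tolerance = 1e-10
      )
    }
  })
})

test_that("km_logrank is ~1 for identical groups and uniform under the null", {
  # two groups with identical survival records
  coh <- make_cohort(rep(c(5, 10, 20, 40), 2))
  g <- structure(
    list(
      low_ids = coh$subject_id[1:4], high_ids = coh$subject_id[5:8],
      median_value = NA_real_
    ),
    class = "stratified_groups"
  )
  expect_equal(km_logrank(g, coh), 1, tolerance = 1e-9)

  # permuted labels under the null give approximately uniform p-values
  withr::with_seed(202, {
    n <- 40
    time <- rexp(n, 1 / 500)
    ev <- rep(TRUE, n)
    ps <- replicate(1000, {
      high <- sample(rep(c(TRUE, FALSE), each = n / 2))
      p <- ratiosurv:::.logrank_p(high, time, ev)
    })
    ks <- suppressWarnings(ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("cox_hr is reciprocal under label swap and ~1 for identical groups", {
  withr::with_seed(77, {
    coh <- make_cohort(sample(30:2000, 60))
    high <- rep(c(TRUE, FALSE), 30)
    g <- structure(
      list(
        low_ids = coh$subject_id[!high], high_ids = coh$subject_id[high],
        median_value = NA_real_
      ),
      class = "stratified_groups"
    )
    g_swap <- structure(
      list(low_ids = g$high_ids, high_ids = g$low_ids, median_value = NA_real_),
      class = "stratified_groups"
    )
    hr <- cox_hr(g, coh)
    expect_gt(as.numeric(hr), 0)
    expect_equal(as.numeric(hr) * as.numeric(cox_hr(g_swap, coh)), 1,
      tolerance = 1e-6
    )
    expect_true(is.finite(attr(hr, "wald_p")))
  })

  coh2 <- make_cohort(rep(c(5, 10, 20, 40, 80), 2))
  g2 <- structure(
    list(
      low_ids = coh2$subject_id[1:5], high_ids = coh2$subject_id[6:10],
      median_value = NA_real_
    ),
    class = "stratified_groups"
  )
  expect_equal(as.numeric(cox_hr(g2, coh2)), 1, tolerance = 1e-6)
})

test_that("improvement_filter implements the 10%-more-significant rule", {
  expect_true(improvement_filter(0.009, 0.01))
  expect_false(improvement_filter(0.0095, 0.01))
  for (p in c(1e-8, 1e-3, 0.5, 1)) expect_false(improvement_filter(p, p))
  # configurable factor
  expect_true(improvement_filter(0.0095, 0.01, factor = 0.95))
  expect_true(is.na(improvement_filter(NA, 0.01)))
})

test_that("screen_all excludes the anchor, skips degenerates, and stores consistent records", {
  cfg <- simulation_config(n_subjects = 40, n_features = 25, seed = 14)
  expr <- generate_expression(cfg)
  coh <- generate_survival(cfg, expr)
  lg <- log2p4_transform(expr)
  # plant a feature identical to the anchor: its ratio is constant 1,
  # which is degenerate for the screen
  flat <- unclass(expr)
  flat["G00007", ] <- flat["OPCML", ]
  lgf <- log2p4_transform(expression_matrix(flat, "normalized"))
  ratios <- compute_ratios(lgf, "OPCML")
  rec <- screen_all(ratios, lgf, coh)

  expect_false("OPCML" %in% rec$feature_id)
  expect_identical(rec$feature_id, sort(rec$feature_id))
  expect_identical(rec$skipped_reason[rec$feature_id == "G00007"], "degenerate")
  expect_true(is.na(rec$cox_hr[rec$feature_id == "G00007"]))

  # stored km_p_ratio regenerates exactly from the stored stratification rule
  for (f in c("G00003", "G00012")) {
    v <- ratios[f, ]
    g <- median_stratify(v)
    expect_identical(km_logrank(g, coh), rec$km_p_ratio[rec$feature_id == f])
    expect_identical(
      as.numeric(cox_hr(g, coh)), rec$cox_hr[rec$feature_id == f]
    )
  }

  # hr_sym/hr_z columns are consistent with the standalone functions
  ok <- !is.na(rec$cox_hr)
  expect_equal(rec$hr_sym[ok], hr_sym(rec$cox_hr[ok]))
  expect_equal(rec$hr_z[ok], z_standardize(rec$hr_sym[ok])$hr_z)
})

test_that("screen_all is invariant to subject order", {
  cfg <- simulation_config(n_subjects = 30, n_features = 15, seed = 17)
  expr <- generate_expression(cfg)
  coh <- generate_survival(cfg, expr)
  lg <- log2p4_transform(expr)
  ratios <- compute_ratios(lg, "OPCML")
  rec1 <- screen_all(ratios, lg, coh)

  perm <- withr::with_seed(1, sample.int(30))
  coh_p <- coh[perm, ]
  class(coh_p) <- class(coh)
  rec2 <- screen_all(
    ratios[, perm, drop = FALSE], lg[, perm, drop = FALSE], coh_p
  )
  expect_identical(rec1, rec2)
})

test_that("screen_all holds its type-I error near 0.05 on an all-null cohort", {
  cfg <- simulation_config(n_subjects = 189, n_features = 1200, seed = 23)
  expr <- generate_expression(cfg)
  coh <- generate_survival(cfg, expr)
  lg <- log2p4_transform(expr)
  rec <- screen_all(compute_ratios(lg, "OPCML"), lg, coh,
    compute_baseline = FALSE
  )
  frac <- mean(rec$km_p_ratio < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})
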