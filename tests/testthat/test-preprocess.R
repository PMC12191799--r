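test_that("filter_cohort applies strict day bounds, stage match, and is idempotent", {
  coh <- make_cohort(c(1, 3650, 3649, 500), ids = c("a", "b", "c", "d"))
  coh$days_to_death[1] <- 1L
  # boundary strictness: 0 and 3650 excluded, 1 and 3649 retained
  coh2 <- make_cohort(c(1, 3649), ids = c("x", "y"))
  got <- filter_cohort(make_cohort(c(1, 3650, 3649), ids = c("x", "z", "y")))
  expect_identical(got$subject_id, c("x", "y"))

  # stage mismatch empties the cohort with a warning, not an error
  expect_warning(
    out <- filter_cohort(coh, stage_filter = "IV"),
    "no subjects"
  )
  expect_identical(nrow(out), 0L)

  # idempotence
  once <- filter_cohort(coh)
  expect_identical(filter_cohort(once), once)
})

test_that("filter_cohort retains 189 of a 200-subject cohort with 11 out-of-range records", {
  withr::with_seed(21, {
    days <- sample(10:3600, 200, replace = TRUE)
    bad <- sample(200, 11)
    # 4 too early/zero, 4 at/after the horizon, 3 censored records
    days[bad[1:4]] <- 0L
    days[bad[5:8]] <- sample(c(3650L, 4000L), 4, replace = TRUE)
    events <- rep(TRUE, 200)
    events[bad[9:11]] <- FALSE
    days[bad[9:11]] <- 100L  # in range but censored -> excluded
    coh <- clinical_cohort(sprintf("P%03d", 1:200), pmax(days, 1L),
      event = events
    )
    coh$days_to_death[bad[1:4]] <- 0L  # force the true zeros back in
    kept <- filter_cohort(coh)
    expect_identical(nrow(kept), 189L)
  })
})

test_that("remove_anchor_outliers drops exactly the extreme-anchor subject", {
  # one subject planted 16.2 sd above the mean of the others
  withr::with_seed(5, base <- rnorm(99, mean = 100, sd = 10))
  subjects <- sprintf("S%03d", 1:100)
  # 16.2 sd above the mean of the clean values; even after the outlier
  # inflates the pooled sd its own Z-score stays far beyond the cut
  v <- c(base, mean(base) + 16.2 * sd(base))
  vals <- rbind(v, runif(100, 1, 50))
  rownames(vals) <- c("OPCML", "G1")
  colnames(vals) <- subjects
  expr <- expression_matrix(vals, "normalized")
  out <- remove_anchor_outliers(expr, "OPCML", z_threshold = 6)
  rep <- attr(out, "outliers_removed")
  expect_identical(rep$subject_id, "S100")
  expect_gt(rep$z, 6)
  expect_identical(colnames(out), subjects[-100])

  # zero variance: Z undefined, nothing removed
  flat <- make_expr(rep(1, 8), c("OPCML", "G1"), sprintf("s%d", 1:4))
  kept <- remove_anchor_outliers(flat, "OPCML")
  expect_identical(ncol(kept), 4L)
  expect_identical(nrow(attr(kept, "outliers_removed")), 0L)

  # infinite threshold is the identity
  expect_identical(
    colnames(remove_anchor_outliers(expr, "OPCML", z_threshold = Inf)),
    subjects
  )
  expect_error(remove_anchor_outliers(expr, "NOPE"), "not found")
})

test_that("log2p4_transform maps the worked values and flips the transform state", {
  expr <- make_expr(c(0, 4, 60, 1020), c("OPCML", "G1"), c("s1", "s2"))
  lg <- log2p4_transform(expr)
  expect_equal(unclass(lg)[, 1], c(OPCML = 2, G1 = 3))
  expect_equal(unclass(lg)[, 2], c(OPCML = 6, G1 = 10))
  expect_identical(transform_state(lg), "log2p4")
  expect_gte(min(lg), 2)
  expect_error(log2p4_transform(lg), "already transformed")
})

test_that("compute_ratios reproduces the hand formula and bounds", {
  # single-cell oracle on pre-transform values
  withr::with_seed(31, {
    raw <- matrix(runif(5 * 6, 0, 3000), nrow = 5)
    rownames(raw) <- c("OPCML", paste0("G", 1:4))
    colnames(raw) <- paste0("s", 1:6)
    expr <- expression_matrix(raw, "normalized")
    r <- compute_ratios(log2p4_transform(expr), "OPCML")
    expect_equal(
      r["G3", "s4"],
      log2(raw["OPCML", "s4"] + 4) / log2(raw["G3", "s4"] + 4)
    )
    # anchor row excluded; all entries positive and inside the analytic band
    expect_false("OPCML" %in% rownames(r))
    M <- max(raw)
    expect_true(all(r > 0))
    expect_true(all(r >= 2 / log2(M + 4) & r <= log2(M + 4) / 2))
  })

  # a gene identical to the anchor would give a ratio of exactly 1
  same <- make_expr(c(8, 8, 40, 40), c("OPCML", "G1"), c("s1", "s2"))
  r1 <- compute_ratios(log2p4_transform(same), "OPCML")
  expect_equal(unname(r1["G1", ]), c(1, 1))

  expect_error(
    compute_ratios(make_expr(1:4, c("A", "B"), c("s1", "s2")), "A"),
    "log2"
  )
})

test_that("align_subjects drops non-shared subjects with a warning and matches order", {
  expr <- make_expr(1:8, c("OPCML", "G1"), sprintf("s%d", 1:4))
  coh <- make_cohort(c(10, 20, 30), ids = c("s4", "s2", "s9"))
  expect_warning(al <- align_subjects(expr, coh), "dropped")
  expect_setequal(colnames(al$expr), c("s2", "s4"))
  expect_identical(colnames(al$expr), al$cohort$subject_id)
})
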