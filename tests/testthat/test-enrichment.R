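test_that("ora_test equals brute-force enumeration on small universes", {
  # perfect overlap: p = 1 / C(20, 5)
  uni <- sprintf("g%02d", 1:20)
  res <- ora_test(uni[1:5], uni[1:5], uni)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)

  # assorted instances vs the combinatorial oracle
  cases <- list(
    list(N = 12, K = 4, q = 5, hit = 2),
    list(N = 15, K = 6, q = 4, hit = 3),
    list(N = 20, K = 5, q = 5, hit = 1),
    list(N = 10, K = 3, q = 3, hit = 0)
  )
  for (cs in cases) {
    uni <- sprintf("u%02d", seq_len(cs$N))
    set <- uni[seq_len(cs$K)]
    # build a query with exactly `hit` overlapping genes
    query <- c(set[seq_len(cs$hit)], rev(setdiff(uni, set))[seq_len(cs$q - cs$hit)])
    got <- ora_test(query, set, uni)
    expect_identical(got$k, as.integer(cs$hit))
    expect_equal(
      got$p_value,
      ora_oracle_p(cs$hit, set, uni, cs$q),
      tolerance = 1e-12,
      info = sprintf("N=%d K=%d q=%d hit=%d", cs$N, cs$K, cs$q, cs$hit)
    )
  }
})

test_that("fold enrichment follows (k/n)/(K/N)", {
  uni <- sprintf("u%03d", 1:200)
  set <- uni[1:20]
  # k=4 of a 10-gene query against a 20-gene set in a 200-gene universe
  query <- c(set[1:4], uni[101:106])
  expect_equal(ora_test(query, set, uni)$fold_enrichment, 4.0)
  # chance-level overlap: k=1, n=10, K=20, N=200
  query1 <- c(set[1], uni[101:109])
  expect_equal(ora_test(query1, set, uni)$fold_enrichment, 1.0)
  expect_error(ora_test(character(), set, uni), "query")
  expect_error(ora_test("u001", set, character()), "universe")
})

test_that("random gene sets show chance-level fold enrichment on average", {
  withr::with_seed(55, {
    uni <- sprintf("u%03d", 1:300)
    query <- sample(uni, 50)
    folds <- replicate(40, ora_test(query, sample(uni, 20), uni)$fold_enrichment)
    expect_gt(mean(folds), 0.7)
    expect_lt(mean(folds), 1.3)
  })
})

test_that("bh_adjust reproduces the step-up computation", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  withr::with_seed(66, {
    p <- runif(50)^2
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    # monotone on sorted input
    expect_true(all(diff(bh_adjust(sort(p))) >= 0))
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("dedup_functions keeps the most conservative duplicate and is idempotent", {
  fns <- data.frame(
    function_id = c("A", "B", "A", "C", "B"),
    p_value = c(1e-9, 0.01, 1e-5, 0.2, 0.01),
    stringsAsFactors = FALSE
  )
  out <- dedup_functions(fns)
  expect_identical(out$function_id, c("B", "A", "C"))
  expect_identical(out$p_value[out$function_id == "A"], 1e-5)
  # tie in p: first occurrence of B retained (row 2 of the input)
  expect_identical(out$p_value[out$function_id == "B"], 0.01)
  expect_identical(dedup_functions(out), out)
  # all-unique input passes through
  uniq <- data.frame(function_id = c("X", "Y"), p_value = c(0.1, 0.2))
  expect_identical(dedup_functions(uniq), uniq)
})

test_that("label_majority applies the strict >4x rule with zero-count handling", {
  expect_identical(label_majority(5, 1), "dependent")
  expect_identical(label_majority(4, 1), "independent")
  expect_identical(label_majority(3, 0), "dependent")
  expect_identical(label_majority(0, 2), "independent")
  expect_true(is.na(label_majority(0, 0)))
  expect_identical(
    label_majority(c(5, 4, 3), c(1, 1, 0)),
    c("dependent", "independent", "dependent")
  )
})

test_that("cluster_functions recovers planted membership blocks and ignores labels", {
  withr::with_seed(71, {
    blocks <- list(sprintf("a%02d", 1:12), sprintf("b%02d", 1:12), sprintf("c%02d", 1:12))
    fns <- do.call(rbind, lapply(1:30, function(i) {
      blk <- blocks[[(i - 1) %% 3 + 1]]
      data.frame(
        function_id = sprintf("F%02d", i),
        p_value = runif(1, 1e-6, 0.04),
        member_hits = I(list(sample(blk, 8))),
        stringsAsFactors = FALSE
      )
    }))
    out <- cluster_functions(fns, k = 3)
    truth <- rep(1:3, 10)
    # same planted block <=> same cluster id (up to relabeling)
    expect_identical(
      length(unique(paste(out$cluster_id, truth))), 3L
    )

    # relabeling genes leaves the clustering unchanged
    relab <- fns
    relab$member_hits <- I(lapply(fns$member_hits, function(g) paste0("X_", g)))
    expect_identical(cluster_functions(relab, k = 3)$cluster_id, out$cluster_id)
  })

  # identical member sets cluster together at distance 0; disjoint sets split
  two <- data.frame(
    function_id = c("P", "Q", "R"),
    p_value = c(0.01, 0.01, 0.01),
    member_hits = I(list(c("x", "y"), c("x", "y"), c("z", "w"))),
    stringsAsFactors = FALSE
  )
  out2 <- cluster_functions(two, k = 2)
  expect_identical(out2$cluster_id[1], out2$cluster_id[2])
  expect_false(out2$cluster_id[3] == out2$cluster_id[1])

  expect_error(cluster_functions(two, k = 5), "exceeds")
})

test_that("enrich_functions flags the planted set with exact composition counts", {
  cfg <- simulation_config(
    n_subjects = 189, n_features = 200,
    effect_feature_ids = sprintf("G%05d", c(10, 20, 30, 40)),
    true_log_hazard = log(2.2), seed = 29
  )
  expr <- generate_expression(cfg)
  coh <- generate_survival(cfg, expr)
  lg <- log2p4_transform(expr)
  rec <- screen_all(compute_ratios(lg, "OPCML"), lg, coh)
  rec <- classify_groups(rec, group_thresholds())
  sets <- generate_gene_sets(cfg, n_sets = 8, planted_overlap = 1)
  en <- enrich_functions(rec, sets, alpha = 0.05)

  expect_true("PLANTED_SET" %in% en$function_id)
  top <- en[en$function_id == "PLANTED_SET", ]
  expect_lte(top$p_adjusted, 0.05)
  expect_gt(top$fold_enrichment, 1)
  hits <- top$member_hits[[1]]
  expect_identical(
    top$n_opcml_plus + top$n_genei_plus, length(hits)
  )
  expect_true(all(hits %in% rec$feature_id[rec$group != "ns"]))
})
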