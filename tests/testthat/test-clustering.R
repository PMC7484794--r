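test_that("square-root z-scaling centers rows and flags flat proteins", {
  x <- rbind(flat = c(4, 4, 4, 4, 4), spike = c(0, 0, 0, 0, 4))
  z <- transform_and_scale(x)
  expect_equal(unname(z["flat", ]), rep(0, 5))
  expect_equal(attr(z, "zero_variance"), "flat")
  # sqrt(spike) = (0,0,0,0,2); n-1 sd = 0.894
  expect_equal(unname(z["spike", ]),
               c(-0.447, -0.447, -0.447, -0.447, 1.789), tolerance = 1e-3)
  set.seed(3)
  y <- matrix(rexp(40), 8, 5)
  zy <- transform_and_scale(y)
  expect_equal(unname(rowMeans(zy)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(zy, 1, sd)), rep(1, 8), tolerance = 1e-12)
  expect_error(transform_and_scale(matrix(1, 3, 1)), "insufficient-data")
})

test_that("Ward/Euclidean clustering merges tight groups first", {
  z <- rbind(a = c(0, 0, 0), b = c(3, 4, 0))
  cl <- hierarchical_two_way(z)
  expect_equal(cl$row_hclust$height, 5)  # two singletons merge at their distance
  # two tight planted pairs: first two merges are within pairs
  z4 <- rbind(a = c(0, 0), b = c(0.1, 0), c = c(10, 10), d = c(10.1, 10))
  cl4 <- hierarchical_two_way(z4)
  first_two <- cl4$row_hclust$merge[1:2, ]
  merged_pairs <- apply(abs(first_two), 1,
                        function(r) paste(sort(r), collapse = "-"))
  expect_setequal(merged_pairs, c("1-2", "3-4"))
  expect_error(hierarchical_two_way(rbind(c(NA, 1), c(0, 1))), "invalid-input")
})

test_that("clustering is deterministic for identical input", {
  set.seed(5)
  z <- matrix(rnorm(60), 12, 5)
  c1 <- hierarchical_two_way(z)
  c2 <- hierarchical_two_way(z)
  expect_identical(c1$row_hclust$merge, c2$row_hclust$merge)
  expect_identical(c1$row_order, c2$row_order)
})

test_that("SC rule requires enrichment AND consistent controls", {
  copies <- rbind(
    good    = c(10, 11, 9, 10, 25),   # enriched 25 >= 1.5*11, CV ~ 0.082
    noisy   = c(10, 2, 15, 8, 25),    # enriched but CV ~ 0.62 > 0.5
    new     = c(0, 0, 0, 0, 7),       # capture-only
    stable  = c(10, 10, 10, 10, 11))  # consistent but not enriched
  m <- cm_from_copies(copies, captured = 5)
  sc <- identify_sc_cluster(m, enrichment_factor = 1.5, max_control_cv = 0.5)
  expect_setequal(sc, c("good", "new"))
  # the CV that excludes 'noisy' is the sample (n-1) statistic
  expect_equal(sd(c(10, 11, 9, 10)) / 10, 0.0816, tolerance = 1e-3)
})

test_that("raising the enrichment factor never grows the SC set", {
  exp <- generate_corona_experiment(corona_benchmark_config(seed = 4))
  m <- build_corona_matrix(exp$records, exp$samples)
  prev <- identify_sc_cluster(m, enrichment_factor = 1)
  for (f in c(1.25, 1.5, 2, 3, 5)) {
    cur <- identify_sc_cluster(m, enrichment_factor = f)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("SC types split by the hard/soft copy ratio band", {
  copies <- rbind(
    t1 = c(20, 20, 20, 20, 25),  # soft 5, hard/soft = 4 -> type1
    t3 = c(10, 10, 10, 10, 40),  # soft 30, soft/hard = 3 -> type3
    t2 = c(10, 10, 10, 10, 18),  # ratios 1.25 / 0.8 -> type2
    nw = c(0, 0, 0, 0, 6))       # hard 0 -> new
  m <- cm_from_copies(copies, captured = 5)
  cls <- classify_sc_types(m, rownames(copies), similarity_ratio = 1.5)
  expect_equal(cls$sc_type, c("type1", "type3", "type2", "new"))
  expect_equal(cls$hard_copies, c(20, 10, 10, 0))
  expect_equal(cls$soft_copies, c(5, 30, 8, 6))
  # proteins outside the SC set carry no type
  cls2 <- classify_sc_types(m, c("t1"))
  expect_equal(cls2$sc_type[cls2$accession == "t3"], "not_applicable")
  expect_equal(cls2$cluster[cls2$accession == "t3"], "HC")
  # capture below the hard baseline floors soft at zero
  m3 <- cm_from_copies(rbind(dn = c(10, 10, 10, 10, 4)), captured = 5)
  c3 <- classify_sc_types(m3, "dn")
  expect_equal(c3$soft_copies, 0)
  expect_equal(c3$sc_type, "type1")
})

test_that("fold increase is captured over mean control, flagging new proteins", {
  copies <- rbind(up = c(10, 10, 10, 10, 57),
                  nw = c(0, 0, 0, 0, 3),
                  id = c(8, 8, 8, 8, 8),
                  ab = c(0, 0, 0, 0, 0))
  m <- cm_from_copies(copies, captured = 5)
  fi <- fold_increase(m)
  expect_equal(fi$fold[fi$accession == "up"], 5.7)
  expect_equal(fi$label[fi$accession == "nw"], "New")
  expect_equal(fi$fold[fi$accession == "id"], 1)
  expect_equal(fi$label[fi$accession == "ab"], "undefined")
})

test_that("composition summary partitions copy totals between clusters", {
  copies <- rbind(h1 = c(30, 30, 30, 30, 30),
                  h2 = c(10, 10, 10, 10, 10),
                  s1 = c(5, 5, 5, 5, 15))
  m <- cm_from_copies(copies, captured = 5)
  cls <- classify_sc_types(m, "s1")
  comp <- composition_summary(m, cls)
  expect_equal(comp$totals$control_total, c(40, 5))
  expect_equal(comp$totals$captured_total, c(40, 15))
  expect_equal(sum(comp$totals$control_percent), 100)
  expect_equal(sum(comp$percentages$control_percent), 100, tolerance = 1e-9)
  expect_equal(sum(comp$percentages$captured_percent), 100, tolerance = 1e-9)
  # no SC proteins -> zero SC contribution
  cls0 <- classify_sc_types(m, character(0))
  comp0 <- composition_summary(m, cls0)
  expect_equal(comp0$totals$captured_percent[comp0$totals$cluster == "SC"], 0)
})

test_that("captured sample is the column-dendrogram outlier under dominant enrichment", {
  for (s in 1:5) {
    cfg <- corona_sim_config(n_proteins = 50,
                             n_sc = c(type1 = 0, type2 = 0, type3 = 20, new = 10),
                             control_noise_cv = 0.05, seed = s)
    exp <- generate_corona_experiment(cfg)
    m <- build_corona_matrix(exp$records, exp$samples)
    cl <- hierarchical_two_way(transform_and_scale(m))
    expect_true(any(cl$col_hclust$merge[4, ] == -5))
  }
})

test_that("dendrogram cut matching recovers a planted SC branch", {
  cfg <- corona_sim_config(n_proteins = 50,
                           n_sc = c(type1 = 0, type2 = 0, type3 = 20, new = 10),
                           control_noise_cv = 0.05, seed = 2)
  exp <- generate_corona_experiment(cfg)
  m <- build_corona_matrix(exp$records, exp$samples)
  cl <- hierarchical_two_way(transform_and_scale(m))
  sc <- identify_sc_cluster(m)
  cut <- best_matching_cut(cl, sc)
  expect_gte(cut$jaccard, 0.8)
})
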