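# straightforward direct evaluation of the NCR definition, kept
# independent of the package implementation
ncr_oracle <- function(n, c) {
  m <- (n + c) / 2
  f <- vapply(m, function(x) mean(m <= x), numeric(1))
  log10((n + min(n)) / (c + min(c))) * f
}

test_that("NCR matches hand-worked values on the 4-peak table", {
  n <- c(10, 100, 5, 50)
  c_ <- c(10, 10, 5, 50)
  # ratios (1, 7, 1, 1); ECDF of means (10, 55, 5, 50) = (.5, 1, .25, .75)
  expect_equal(compute_ncr(n, c_), c(0, log10(7), 0, 0), tolerance = 1e-12)
  expect_equal(compute_ncr(n, c_), ncr_oracle(n, c_), tolerance = 1e-12)
  # single peak with n = c: ratio 1, ECDF 1
  expect_equal(compute_ncr(10, 10), 0)
})

test_that("NCR equals the oracle on 1000 random paired-count tables", {
  set.seed(21)
  for (rep in 1:1000) {
    k <- sample(2:12, 1)
    n <- rpois(k, sample(c(5, 50, 500), 1))
    c_ <- rpois(k, sample(c(5, 50, 500), 1))
    if (all(n + c_ == 0)) n[1] <- 1
    expect_equal(compute_ncr(n, c_), ncr_oracle(n, c_), tolerance = 1e-12)
  }
})

test_that("NCR invariances hold", {
  set.seed(22)
  n <- rpois(200, 40); c_ <- rpois(200, 40)
  ncr <- compute_ncr(n, c_)
  # reordering peaks permutes the output identically
  p <- sample(200)
  expect_equal(compute_ncr(n[p], c_[p]), ncr[p])
  # a peak with n = c at the sample-maximal mean gets exactly 0
  n2 <- c(n, 10000); c2 <- c(c_, 10000)
  expect_equal(compute_ncr(n2, c2)[201], 0)
  # zero numerator with zero minimum flags -Inf
  expect_true(is.infinite(compute_ncr(c(0, 5), c(3, 4))[1]))
  expect_error(compute_ncr(numeric(0), numeric(0)), "empty")
})

test_that("control sample without N/C asymmetry yields no fusion calls", {
  ann <- fixture_annotation(seed = 30)
  sim <- simulate_fusion_experiment(ann, frac_fusion = 0, nc_fold = 1,
                                    seed = 31)
  fc <- call_fusion_sites(sim$peaks, sim$signals$n_count,
                          sim$signals$c_count, seed = 31)
  expect_false(fc$ncr_partition$partitioned)
  expect_equal(sum(fc$table$is_fusion), 0)
  expect_true(all(!fc$table$ncr_pass))
})

test_that("planted fusion peaks are recovered with high sensitivity and precision", {
  ann <- fixture_annotation(seed = 32)
  sim <- simulate_fusion_experiment(ann, n_peaks = 1000, frac_fusion = 0.05,
                                    nc_fold = 4, seed = 33)
  fc <- call_fusion_sites(sim$peaks, sim$signals$n_count,
                          sim$signals$c_count, seed = 33)
  expect_true(fc$ncr_partition$partitioned)
  expect_true(fc$width_partition$partitioned)
  called <- fc$table$peak_id[fc$table$is_fusion]
  truth <- sim$truth$fusion_peaks
  expect_gte(mean(truth %in% called), 0.9)   # sensitivity
  expect_gte(mean(called %in% truth), 0.9)   # precision
  # flag consistency: is_fusion is exactly the conjunction
  expect_equal(fc$table$is_fusion, fc$table$ncr_pass & fc$table$width_pass)
})

test_that("uniformly wide peak sets leave the width mixture unpartitioned", {
  # every peak planted as a wide fusion site: there is no narrow/wide
  # contrast left, and on the log scale the single lognormal width
  # population must be declared unpartitioned instead of calling sites
  ann <- fixture_annotation(seed = 34)
  sim <- simulate_fusion_experiment(ann, n_peaks = 300, frac_wide = 1,
                                    frac_fusion = 1, seed = 35)
  fc <- call_fusion_sites(sim$peaks, sim$signals$n_count,
                          sim$signals$c_count, width_transform = "log10",
                          seed = 35)
  expect_false(fc$width_partition$partitioned)
  expect_equal(sum(fc$table$is_fusion), 0)
  expect_true(all(!fc$table$width_pass))
})

test_that("peak categories follow TSS > gene body > intergenic precedence", {
  genes <- gene_models(c("g1", "g2"), c("c1", "c1"), c(10000, 50000),
                       c(30000, 70000), c("+", "+"))
  peaks <- genomic_intervals(
    rep("c1", 5),
    c(9500,  15000, 80000, 49500, 29500),
    c(10500, 16000, 81000, 50500, 30500))
  # peak 1 spans the g1 TSS window; peak 2 sits in the g1 body;
  # peak 3 is intergenic; peak 4 spans the g2 TSS; peak 5 straddles the
  # g1 3' end (gene body, not TSS)
  cats <- annotate_peak_categories(peaks, genes, tss_halfwidth = 1000)
  expect_equal(as.character(cats),
               c("TSS", "gene_body", "intergenic", "TSS", "gene_body"))
  expect_error(annotate_peak_categories(peaks, genes, 0), "positive")
})

test_that("category comparison reproduces the exact hypergeometric Fisher p", {
  a <- factor(rep(c("TSS", "gene_body"), c(3, 2)),
              levels = c("TSS", "gene_body", "intergenic"))
  b <- factor(rep(c("TSS", "gene_body"), c(1, 4)),
              levels = c("TSS", "gene_body", "intergenic"))
  res <- compare_peak_categories(a, b)
  tssr <- res[res$category == "TSS", ]
  # enumerate tables with the same margins for the two-sided exact test:
  # a ~ hypergeometric(a+b, c+d, a+c) with a=3, b=1, c=2, d=4
  probs <- dhyper(0:4, 4, 6, 5)
  p_ref <- sum(probs[probs <= probs[3 + 1] * (1 + 1e-7)])
  expect_equal(tssr$p_value, p_ref, tolerance = 1e-12)
  expect_equal(tssr$p_value, fisher.test(matrix(c(3, 2, 1, 4), 2))$p.value,
               tolerance = 1e-12)
})

test_that("target assignment, recurrence and missing-target set operations", {
  genes <- gene_models(c("g1", "g2", "g3"), rep("c1", 3),
                       c(1e4, 5e4, 9e4), c(3e4, 7e4, 11e4), rep("+", 3))
  peaks <- genomic_intervals("c1", c(15000, 95000), c(16000, 96000),
                             name = c("p1", "p2"))
  t1 <- assign_targets(peaks, c(TRUE, FALSE), genes)
  expect_equal(t1, "g1")
  expect_equal(assign_targets(peaks, c(FALSE, FALSE), genes), character(0))

  sets <- list(s1 = c("A", "B"), s2 = c("A", "B"), s3 = c("A", "C"),
               s4 = c("A", "B"), s5 = c("A", "B"), s6 = "A", s7 = "B",
               s8 = "B")
  expect_equal(recurrent_targets(sets, 5), c("A", "B"))
  # 5-of-8 included, 4-of-8 excluded
  expect_false("C" %in% recurrent_targets(sets, 5))
  expect_error(recurrent_targets(sets, 0), "min_samples")

  # brute-force membership counting oracle on random sets
  set.seed(41)
  rnd <- lapply(1:6, function(i) sample(LETTERS[1:10], sample(3:8, 1)))
  for (k in 1:6) {
    ref <- names(which(table(unlist(rnd)) >= k))
    expect_equal(recurrent_targets(rnd, k), sort(ref))
  }

  expect_equal(missing_targets(c("A", "B", "C"), "B"), c("A", "C"))
  expect_equal(missing_targets(c("A", "B"), c("A", "B")), character(0))
})

test_that("deleting a sample's fusion peaks at specific genes makes them missing targets", {
  ann <- fixture_annotation(seed = 50)
  set.seed(51)
  shared_genes <- sample(ann$gene_id, 50)
  cohort <- lapply(1:6, function(s) {
    sim <- simulate_fusion_experiment(ann, fusion_genes = shared_genes,
                                      seed = 60 + s)
    fc <- call_fusion_sites(sim$peaks, sim$signals$n_count,
                            sim$signals$c_count, seed = 60 + s)
    assign_targets(sim$peaks, fc$table$is_fusion, ann)
  })
  rec <- recurrent_targets(cohort, 5)
  # a sample planted with three genes dropped from the shared program
  dropped <- shared_genes[1:3]
  kept_genes <- c(setdiff(shared_genes, dropped), sample(
    setdiff(ann$gene_id, shared_genes), 3))
  sim <- simulate_fusion_experiment(ann, fusion_genes = kept_genes,
                                    seed = 70)
  fc <- call_fusion_sites(sim$peaks, sim$signals$n_count,
                          sim$signals$c_count, seed = 70)
  own <- assign_targets(sim$peaks, fc$table$is_fusion, ann)
  miss <- missing_targets(rec, own)
  expect_true(all(dropped %in% miss))
  expect_true(all(miss %in% c(dropped, setdiff(rec, kept_genes))))
})

test_that("NCR clustering and PCA behave on planted structure", {
  expect_error(ncr_cluster(matrix(1, 5, 1)), "2 samples")
  # identical columns merge at height 0
  m <- matrix(rnorm(40), 20, 2)
  m <- cbind(m, m[, 1])
  hc <- ncr_cluster(m)
  expect_equal(min(hc$height), 0)
  # two planted sample blocks are recovered by cutting at 2
  set.seed(55)
  prof_a <- rnorm(30); prof_b <- rnorm(30, 3)
  blocks <- cbind(sapply(1:4, function(i) prof_a + rnorm(30, 0, .1)),
                  sapply(1:4, function(i) prof_b + rnorm(30, 0, .1)))
  grp <- cutree(ncr_cluster(blocks), 2)
  expect_equal(length(unique(grp[1:4])), 1)
  expect_equal(length(unique(grp[5:8])), 1)
  expect_false(grp[1] == grp[5])
  # rank-1 matrix: first PC explains everything
  r1 <- outer(rnorm(25), c(1, 2, 3, 4))
  pc <- ncr_pca(r1)
  expect_equal(pc$variance_fraction[1], 1, tolerance = 1e-10)
})

test_that("group signal test matches closed forms and detects shifts", {
  x <- c(1, 2, 3, 4)
  r <- group_signal_test(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # agreement with stats::t.test on ordinary data
  set.seed(56)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  r2 <- group_signal_test(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r2$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r2$p_value, tt$p.value, tolerance = 1e-12)
  rw <- group_signal_test(a, b, var_equal = FALSE)
  tw <- t.test(a, b)
  expect_equal(rw$p_value, tw$p.value, tolerance = 1e-12)
  # strong separation
  set.seed(57)
  expect_lt(group_signal_test(rnorm(100), rnorm(100, 2))$p_value, 1e-6)
  # degenerate zero-variance groups hit the sd floor, not a crash
  r3 <- group_signal_test(c(0, 0), c(1, 1), sd_floor = 1e-3)
  expect_equal(r3$statistic, -1 / 1e-3)
  expect_error(group_signal_test(1, c(1, 2)), "at least 2")
})
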