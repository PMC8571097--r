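sc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ann <- fixture_annotation(n_genes = 400, seed = 11)
      set.seed(12)
      pg <- sample(ann$gene_id, 16)
      sim <- simulate_single_cells(ann, n_cells = 300,
                                   program_genes_a = pg[1:8],
                                   program_genes_b = pg[9:16],
                                   frac_program_a = 0.15, seed = 13)
      agg <- call_fixture_peaks(sim$fragments)
      qc <- qc_cells(sim$fragments, agg)
      keep <- qc$barcode[qc$passed_qc]
      frags <- sim$fragments[sim$fragments$barcode %in% keep, ]
      binned <- bin_cells(frags, tiny_genome)
      lsi <- lsi_embed(binned$matrix, n_components = 20, seed = 14)
      gs <- gene_scores(binned, ann)
      cache <<- list(ann = ann, pa = pg[1:8], pb = pg[9:16], sim = sim,
                     qc = qc, frags = frags, binned = binned, lsi = lsi,
                     gs = gs, imp = impute_scores(gs, lsi$components))
    }
    cache
  }
})

test_that("cell QC applies the read floor and the FRiP moment rule", {
  peaks <- genomic_intervals("c1", 0, 1000)
  mk_cell <- function(bc, n_in, n_out) {
    rbind(
      if (n_in) data.frame(chrom = "c1", start = seq_len(n_in),
                           end = seq_len(n_in) + 100, barcode = bc,
                           count = 1),
      if (n_out) data.frame(chrom = "c1", start = 5000 + seq_len(n_out),
                            end = 5100 + seq_len(n_out), barcode = bc,
                            count = 1))
  }
  # boundary: 299 fragments removed, 300 retained
  fr <- rbind(mk_cell("low", 299, 0), mk_cell("ok", 300, 0))
  qc <- qc_cells(fr, peaks)
  expect_false(qc$passed_qc[qc$barcode == "low"])
  expect_true(qc$passed_qc[qc$barcode == "ok"])
  # identical FRiP everywhere: sigma = 0 keeps all read-passing cells
  fr2 <- rbind(mk_cell("a", 300, 0), mk_cell("b", 400, 0))
  expect_true(all(qc_cells(fr2, peaks)$passed_qc))
  expect_error(qc_cells(mk_cell("tiny", 10, 0), peaks), "no cells pass")
  # planted low-FRiP outliers are exactly the removals
  normal <- do.call(rbind, lapply(sprintf("n%02d", 1:30), function(b)
    mk_cell(b, 380, 20)))   # FRiP 0.95
  outlier <- do.call(rbind, lapply(sprintf("o%02d", 1:3), function(b)
    mk_cell(b, 100, 300)))  # FRiP 0.25
  qc3 <- qc_cells(rbind(normal, outlier), peaks)
  expect_equal(sort(qc3$barcode[!qc3$passed_qc]), sprintf("o%02d", 1:3))
})

test_that("binning assigns midpoints and conserves counts", {
  cs <- c(c1 = 20000)
  fr <- data.frame(chrom = "c1", start = 4999, end = 5101, barcode = "x",
                   count = 1)
  b <- bin_cells(fr, cs)
  # midpoint 5050 lands in bin [5000, 10000)
  expect_equal(unname(b$matrix[1, "c1:5000-10000"]), 1)
  # hand-tallied toy: 2 cells, 10 fragments
  mids <- c(100, 4999, 5000, 9999, 10000, 15000, 19998, 2500, 7500, 12500)
  fr2 <- data.frame(chrom = "c1", start = mids - 1, end = mids + 1,
                    barcode = rep(c("x", "y"), 5), count = 1)
  b2 <- bin_cells(fr2, cs)
  expect_equal(sum(b2$matrix), 10)
  ref <- matrix(0, 2, 4, dimnames = list(c("x", "y"), colnames(b2$matrix)))
  for (i in seq_along(mids))
    ref[fr2$barcode[i], mids[i] %/% 5000 + 1] <-
      ref[fr2$barcode[i], mids[i] %/% 5000 + 1] + 1
  expect_equal(as.matrix(b2$matrix), ref)
  # fragments beyond bounds are named errors
  bad <- data.frame(chrom = "c1", start = 19990, end = 20010,
                    barcode = "x", count = 1)
  expect_error(bin_cells(bad, cs), "beyond")
  expect_error(bin_cells(fr, c(c9 = 100)), "unknown")
})

test_that("full single-cell stage conserves mass and separates populations", {
  fx <- sc_fixture()
  expect_equal(sum(fx$binned$matrix), sum(fx$frags$count))
  # binarization is implicit in LSI: same embedding for doubled counts
  dbl <- fx$binned$matrix * 2
  l2 <- lsi_embed(dbl, n_components = 20, seed = 14)
  expect_equal(abs(cor(fx$lsi$all_components[, 1], l2$all_components[, 1])),
               1, tolerance = 1e-6)
  expect_error(lsi_embed(fx$binned$matrix[1, , drop = FALSE]), "2 cells")
})

test_that("LSI separates two cell populations with disjoint profiles", {
  ann <- fixture_annotation(n_genes = 400, seed = 21)
  set.seed(22)
  pg <- sample(ann$gene_id, 16)
  # two simulations with different seeds draw different housekeeping
  # weights: two distinct populations
  s1 <- simulate_single_cells(ann, 120, pg[1:8], pg[9:16], seed = 23)
  s2 <- simulate_single_cells(ann, 120, pg[1:8], pg[9:16], seed = 24)
  s2$fragments$barcode <- sub("cell", "pop2_", s2$fragments$barcode)
  fr <- rbind(s1$fragments, s2$fragments)
  b <- bin_cells(fr, tiny_genome)
  lsi <- lsi_embed(b$matrix, n_components = 15, seed = 25)
  pop <- ifelse(grepl("pop2", rownames(lsi$components)), 2, 1)
  nn <- RANN::nn2(lsi$components, k = 16)$nn.idx[, -1]
  purity <- mean(matrix(pop[nn], nrow(nn)) == pop)
  expect_gte(purity, 0.95)
  # UMAP is deterministic under a fixed seed and separates the populations
  u1 <- umap_embed(lsi$components, seed = 26)
  u2 <- umap_embed(lsi$components, seed = 26)
  expect_identical(u1, u2)
  expect_gt(mean_silhouette(u1, pop), 0.5)
  expect_error(umap_embed(lsi$components[1:10, ], n_neighbors = 15),
               "n_neighbors")
})

test_that("a single population shows no spurious UMAP separation", {
  fx <- sc_fixture()
  u <- umap_embed(fx$lsi$components, seed = 31)
  set.seed(32)
  halves <- sample(rep(1:2, length.out = nrow(u)))
  expect_lt(abs(mean_silhouette(u, halves)), 0.1)
})

test_that("gene scores sum to the normalization target and match a hand tally", {
  fx <- sc_fixture()
  sums <- rowSums(fx$gs)
  expect_true(all(abs(sums - 1e4) < 1e-6 | sums == 0))
  # toy: 3 genes, 2 cells, hand-tallied bin overlap sums
  genes <- gene_models(c("g1", "g2", "g3"), "c1",
                       c(0, 6000, 12000), c(4000, 9000, 16000),
                       c("+", "+", "-"))
  cs <- c(c1 = 20000)
  mids <- c(500, 7000, 13000, 500, 500, 18000)
  fr <- data.frame(chrom = "c1", start = mids - 10, end = mids + 10,
                   barcode = rep(c("u", "v"), c(3, 3)), count = 1)
  b <- bin_cells(fr, cs, bin_width = 1000)
  gst <- gene_scores(b, genes, flank = 0, target_sum = 100)
  # u: one fragment per gene -> 1/3 of target each
  expect_equal(unname(gst["u", ]), c(100 / 3, 100 / 3, 100 / 3))
  # v: two fragments in g1, one outside every gene
  expect_equal(unname(gst["v", ]), c(100, 0, 0))
})

test_that("imputation is identity at t=0 and a convex local average after", {
  fx <- sc_fixture()
  expect_identical(impute_scores(fx$gs, fx$lsi$components, t = 0), fx$gs)
  imp <- fx$imp
  expect_true(all(imp >= min(fx$gs) - 1e-9 & imp <= max(fx$gs) + 1e-9))
  # per-gene: imputed values stay inside the raw range (convexity)
  g <- fx$pa[1]
  expect_gte(min(imp[, g]), min(fx$gs[, g]) - 1e-9)
  expect_lte(max(imp[, g]), max(fx$gs[, g]) + 1e-9)
  # fully connected graph at large t approaches the population mean
  n <- nrow(fx$gs)
  deep <- impute_scores(fx$gs, matrix(0, n, 2) + rnorm(2 * n, 0, 1e-9),
                        k = n - 1, t = 50)
  expect_equal(unname(deep[1, g]), mean(fx$gs[, g]), tolerance = 0.05)
  expect_error(impute_scores(fx$gs, fx$lsi$components, k = n), "smaller")
  # imputation increases within-program gene-gene correlation
  raw_r <- mean(cor(fx$gs[, fx$pa])[upper.tri(diag(8))])
  imp_r <- mean(cor(imp[, fx$pa])[upper.tri(diag(8))])
  expect_gt(imp_r, raw_r)
})

test_that("normalized dispersion is mean-bin centered and ranks bimodal genes", {
  fx <- sc_fixture()
  disp <- normalized_dispersion(fx$imp)
  # mean ~0 within every mean-bin
  for (b in unique(disp$bin))
    expect_lt(abs(mean(disp$norm_dispersion[disp$bin == b])), 1e-6)
  # program-A genes (on in a 15% minority) out-disperse same-bin genes
  agenes <- disp[disp$gene_id %in% fx$pa, ]
  for (i in seq_len(nrow(agenes))) {
    peers <- disp[disp$bin == agenes$bin[i] &
                  !(disp$gene_id %in% c(fx$pa, fx$pb)), ]
    if (nrow(peers) > 3)
      expect_gt(agenes$norm_dispersion[i], mean(peers$norm_dispersion))
  }
  # constant gene: dispersion 0, normalized dispersion <= 0 in its bin
  m <- cbind(fx$imp, constgene = 5)
  d2 <- normalized_dispersion(m)
  cg <- d2[d2$gene_id == "constgene", ]
  expect_equal(cg$dispersion, 0)
  expect_lte(cg$norm_dispersion, 0)
})

test_that("dispersion group comparison finds the planted heterogeneity", {
  fx <- sc_fixture()
  disp <- normalized_dispersion(fx$imp)
  ctrl <- setdiff(disp$gene_id, c(fx$pa, fx$pb))
  res <- compare_dispersion(disp, list(missing_target = fx$pa,
                                       control = ctrl))
  expect_gt(res$mean_a, res$mean_b)
  expect_lt(res$p_value, 0.01)
})

test_that("program correlation recovers the planted anticorrelated groups", {
  fx <- sc_fixture()
  pg <- c(fx$pa, fx$pb)
  pr <- program_correlation(fx$imp, pg, seed = 33)
  r <- pr$correlation
  expect_equal(unname(diag(r)), rep(1, 16))
  within_a <- r[fx$pa, fx$pa][upper.tri(diag(8))]
  within_b <- r[fx$pb, fx$pb][upper.tri(diag(8))]
  cross <- r[fx$pa, fx$pb]
  expect_gt(mean(within_a), 0.5)
  expect_gt(mean(within_b), 0.5)
  expect_lt(mean(cross), 0)
  # the 2-group partition matches the planted assignment exactly
  expect_equal(length(unique(pr$groups[fx$pa])), 1)
  expect_equal(length(unique(pr$groups[fx$pb])), 1)
  expect_false(pr$groups[fx$pa[1]] == pr$groups[fx$pb[1]])
  # high-cell fraction of program-A genes matches the planted on-fraction
  planted <- mean(fx$sim$truth$program[fx$qc$barcode[fx$qc$passed_qc]] == "A")
  expect_equal(unname(pr$high_cell_fraction[fx$pa]), rep(planted, 8),
               tolerance = 0.34)
  expect_true(all(abs(pr$high_cell_fraction[fx$pa] - 0.15) <= 0.05))
  # constant genes are excluded with a warning
  m <- cbind(fx$imp, cg = 7)
  expect_warning(program_correlation(m, c(pg, "cg"), seed = 34),
                 "constant")
  expect_error(program_correlation(fx$imp, fx$pa[1:3]), "4 genes")
})
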