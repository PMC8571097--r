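#' Single-cell fragment QC: read depth and FRiP filters
#'
#' Cells are kept when they have at least `min_fragments` fragments and a
#' fraction of reads in peaks (FRiP) no lower than `mu - 2 sigma`, where
#' mu and sigma are the moments of the FRiP distribution over the cells
#' that already passed the read filter (a Gaussian moment fit of the
#' "normal" FRiP distribution). If sigma is zero every cell passes the
#' FRiP rule.
#'
#' @param fragments fragment data frame with cell barcodes.
#' @param aggregate_peaks interval data frame of peaks called on the
#'   aggregate of all cells.
#' @param min_fragments minimum fragment count per cell (default 300).
#' @param frip_sds how many sigmas below the mean the FRiP cutoff sits.
#' @return data frame with `barcode`, `n_fragments`, `frip`, `passed_qc`.
#' @export
qc_cells <- function(fragments, aggregate_peaks, min_fragments = 300,
                     frip_sds = 2) {
  totals <- rowsum(fragments$count, fragments$barcode)
  barcodes <- rownames(totals)
  n_frag <- totals[, 1]
  in_peak <- numeric(length(barcodes))
  names(in_peak) <- barcodes
  hits <- overlap_join(fragments, aggregate_peaks)
  if (nrow(hits)) {
    hit_frag <- unique(hits$query)
    ip <- rowsum(fragments$count[hit_frag], fragments$barcode[hit_frag])
    in_peak[rownames(ip)] <- ip[, 1]
  }
  frip <- ifelse(n_frag > 0, in_peak / n_frag, NA_real_)
  read_pass <- n_frag >= min_fragments
  if (!any(read_pass)) stop("no cells pass the read-count filter")
  mu <- mean(frip[read_pass]); sig <- sd(frip[read_pass])
  frip_pass <- if (is.na(sig) || sig == 0) rep(TRUE, length(frip))
               else frip >= mu - frip_sds * sig
  data.frame(barcode = barcodes, n_fragments = n_frag, frip = frip,
             passed_qc = read_pass & frip_pass, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bin single-cell fragments into fixed genome windows
#'
#' Bins tile each chromosome from 0 with fixed width (the last bin may be
#' short); fragments are assigned to the bin containing their midpoint, so
#' total counts are conserved.
#'
#' @param fragments fragment data frame (QC-passed cells).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param bin_width bin width in bp (default 5000).
#' @return list with `matrix` (sparse cells x bins, `dgCMatrix`) and
#'   `bins` (interval data frame, columns aligned to the matrix).
#' @export
bin_cells <- function(fragments, chrom_sizes, bin_width = 5000) {
  if (is.null(names(chrom_sizes))) stop("chrom_sizes must be named")
  if (bin_width <= 0) stop("bin_width must be positive")
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    starts <- seq(0, chrom_sizes[[ch]] - 1, by = bin_width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_width, chrom_sizes[[ch]]),
               stringsAsFactors = FALSE)
  }))
  bins$name <- paste0(bins$chrom, ":", bins$start, "-", bins$end)
  if (nrow(fragments) == 0)
    stop("no fragments to bin")
  unknown <- !fragments$chrom %in% names(chrom_sizes)
  if (any(unknown))
    stop("fragment on unknown chromosome at record ", which(unknown)[1])
  over <- fragments$end > chrom_sizes[fragments$chrom]
  if (any(over))
    stop("fragment beyond chromosome bounds at record ", which(over)[1])
  mid <- floor((fragments$start + fragments$end) / 2)
  # direct arithmetic bin lookup; bins are dense per chromosome
  chrom_offset <- c(0, cumsum(ceiling(unlist(chrom_sizes) / bin_width)))
  names(chrom_offset) <- c(names(chrom_sizes), "_end")
  bin_idx <- chrom_offset[fragments$chrom] + mid %/% bin_width + 1
  cells <- sort(unique(fragments$barcode))
  mat <- Matrix::sparseMatrix(
    i = match(fragments$barcode, cells), j = as.integer(bin_idx),
    x = fragments$count, dims = c(length(cells), nrow(bins)),
    dimnames = list(cells, bins$name))
  list(matrix = mat, bins = bins)
}

#' Latent semantic indexing of a cell-by-bin matrix
#'
#' The matrix is binarized (any count > 0 becomes 1), term frequencies are
#' computed per cell, bins are weighted by inverse document frequency
#' `log(1 + n_cells / (1 + bin frequency))`, and the weighted matrix is
#' reduced by truncated SVD. Components whose absolute Pearson correlation
#' with log total fragment count exceeds `depth_cor_limit` are flagged as
#' depth components and excluded from `components` (all components remain
#' available in `all_components`).
#'
#' @param mat cells x bins count matrix (sparse or dense).
#' @param n_components number of singular vectors (default 30).
#' @param depth_cor_limit absolute depth-correlation cutoff (default 0.9).
#' @param seed seed for the randomized SVD.
#' @return list with `components` (cells x retained components),
#'   `all_components`, `singular_values`, `depth_correlation`, `kept`.
#' @export
lsi_embed <- function(mat, n_components = 30, depth_cor_limit = 0.9,
                      seed = 1) {
  if (nrow(mat) < 2) stop("need at least 2 cells")
  depth <- Matrix::rowSums(mat)
  if (any(depth == 0)) stop("cell with zero fragments: ",
                            rownames(mat)[which(depth == 0)[1]])
  bin <- mat
  bin@x <- rep(1, length(bin@x))
  nonempty <- sum(Matrix::colSums(bin) > 0)
  if (nonempty < n_components)
    stop("need at least ", n_components, " non-empty bins, got ", nonempty)
  tf <- bin / Matrix::rowSums(bin)
  idf <- log(1 + nrow(bin) / (1 + Matrix::colSums(bin)))
  x <- tf %*% Matrix::Diagonal(x = idf)
  n_components <- min(n_components, nrow(mat) - 1)
  set.seed(seed)
  sv <- irlba::irlba(x, nv = n_components)
  comps <- sv$u %*% diag(sv$d, n_components, n_components)
  rownames(comps) <- rownames(mat)
  colnames(comps) <- paste0("LSI", seq_len(ncol(comps)))
  dcor <- apply(comps, 2, function(cc) {
    s <- sd(cc)
    if (s == 0) 0 else cor(cc, log(depth))
  })
  kept <- abs(dcor) <= depth_cor_limit
  if (!any(kept)) stop("all LSI components are depth-correlated")
  list(components = comps[, kept, drop = FALSE], all_components = comps,
       singular_values = sv$d, depth_correlation = dcor, kept = kept)
}

#' UMAP embedding of LSI components
#'
#' Deterministic given the seed (single-threaded layout optimization).
#'
#' @param components cells x components matrix (from [lsi_embed()]).
#' @param n_neighbors UMAP neighborhood size (default 15).
#' @param seed integer seed.
#' @return n x 2 coordinate matrix.
#' @export
umap_embed <- function(components, n_neighbors = 15, seed = 1) {
  if (nrow(components) <= n_neighbors)
    stop("need more cells than n_neighbors (", n_neighbors, ")")
  set.seed(seed)
  coords <- uwot::umap(components, n_neighbors = n_neighbors,
                       n_threads = 1, n_sgd_threads = 1, batch = TRUE,
                       verbose = FALSE)
  rownames(coords) <- rownames(components)
  coords
}

#' Raw gene activity scores from binned fragments
#'
#' A cell's score for a gene is the sum of its counts in all bins
#' overlapping the gene body extended by `flank` on both sides; per-cell
#' scores are then scaled to sum to `target_sum`.
#'
#' @param binned output of [bin_cells()].
#' @param genes gene-model data frame.
#' @param flank extension in bp around the gene body (default 2000).
#' @param target_sum per-cell normalization target (default 1e4).
#' @return cells x genes dense matrix of normalized scores.
#' @export
gene_scores <- function(binned, genes, flank = 2000, target_sum = 1e4) {
  if (nrow(genes) == 0) stop("annotation must be non-empty")
  ext <- genomic_intervals(genes$chrom, pmax(0, genes$start - flank),
                           genes$end + flank, name = genes$gene_id)
  hits <- overlap_join(ext, binned$bins)
  n_genes <- nrow(genes)
  if (length(setdiff(seq_len(n_genes), unique(hits$query))))
    warning("gene(s) with no overlapping bins score 0")
  ind <- Matrix::sparseMatrix(i = hits$subject, j = hits$query, x = 1,
                              dims = c(nrow(binned$bins), n_genes))
  raw <- as.matrix(binned$matrix %*% ind)
  colnames(raw) <- genes$gene_id
  tot <- rowSums(raw)
  scale_f <- ifelse(tot > 0, target_sum / tot, 0)
  raw * scale_f
}

#' Diffusion imputation of gene scores over the cell kNN graph
#'
#' Builds the k-nearest-neighbor graph in component space (each cell's
#' neighborhood includes itself), forms the row-stochastic uniform
#' transition matrix, and applies it `t` times to the raw scores. Each
#' imputed value is a convex combination of raw values in the cell's
#' t-step neighborhood.
#'
#' @param scores cells x genes raw score matrix.
#' @param components cells x components matrix defining the graph metric.
#' @param k neighborhood size including self (default 15).
#' @param t diffusion steps (default 3); `t = 0` returns the input.
#' @return imputed cells x genes matrix.
#' @export
impute_scores <- function(scores, components, k = 15, t = 3) {
  n <- nrow(components)
  if (k >= n) stop("k must be smaller than the number of cells")
  stopifnot(nrow(scores) == n)
  if (t == 0) return(scores)
  nn <- RANN::nn2(components, k = k)
  w <- Matrix::sparseMatrix(i = rep(seq_len(n), k),
                            j = as.vector(nn$nn.idx),
                            x = 1 / k, dims = c(n, n))
  out <- scores
  for (s in seq_len(t)) out <- as.matrix(w %*% out)
  dimnames(out) <- dimnames(scores)
  out
}

#' Normalized dispersion of gene scores across cells
#'
#' Dispersion is variance over mean per gene; genes are placed into
#' `n_bins` equal-count bins by mean score, and the normalized dispersion
#' is the z-score of dispersion within its bin (0 when the bin has no
#' spread). Genes with zero mean are excluded with a warning.
#'
#' @param scores cells x genes matrix (typically imputed).
#' @param n_bins number of mean bins (default 20).
#' @return data frame with `gene_id`, `mean`, `dispersion`,
#'   `norm_dispersion`, `bin`.
#' @export
normalized_dispersion <- function(scores, n_bins = 20) {
  mu <- colMeans(scores)
  keep <- mu > 0
  if (!all(keep)) warning(sum(!keep), " gene(s) with zero mean excluded")
  mu <- mu[keep]
  if (length(mu) < n_bins)
    stop("need at least ", n_bins, " genes with positive mean")
  v <- apply(scores[, keep, drop = FALSE], 2, var)
  disp <- v / mu
  ranks <- rank(mu, ties.method = "first")
  bin <- ceiling(ranks / length(mu) * n_bins)
  nd <- numeric(length(disp))
  for (b in unique(bin)) {
    idx <- bin == b
    s <- sd(disp[idx])
    nd[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  data.frame(gene_id = names(mu), mean = mu, dispersion = disp,
             norm_dispersion = nd, bin = bin, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Compare normalized dispersion between gene groups
#'
#' Pairwise two-sided two-sample t tests (uncorrected) on normalized
#' dispersion.
#'
#' @param dispersion_table output of [normalized_dispersion()].
#' @param groups named list of gene-id vectors.
#' @return data frame of pairwise results.
#' @export
compare_dispersion <- function(dispersion_table, groups) {
  nd <- setNames(dispersion_table$norm_dispersion, dispersion_table$gene_id)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  out <- lapply(pairs, function(p) {
    a <- nd[intersect(groups[[p[1]]], names(nd))]
    b <- nd[intersect(groups[[p[2]]], names(nd))]
    tt <- group_signal_test(a, b)
    data.frame(group_a = p[1], group_b = p[2], mean_a = tt$mean_a,
               mean_b = tt$mean_b, statistic = tt$statistic,
               p_value = tt$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Covariance grouping of genes into anticorrelated programs
#'
#' Computes the Pearson correlation of imputed gene scores across cells,
#' groups genes by average-linkage hierarchical clustering on `1 - r` cut
#' into two groups, and reports each gene's "high-cell fraction": the
#' fraction of cells whose score exceeds the intersection threshold of a
#' two-component mixture fit on that gene's scores (`NA` when the fit
#' does not partition).
#'
#' @param scores cells x genes matrix (imputed scores).
#' @param gene_ids genes to analyze (>= 4, with >= 20 cells).
#' @param seed seed for the per-gene mixture fits.
#' @return list with `correlation`, `groups` (named integer vector in
#'   1/2), `high_cell_fraction`, `hclust`.
#' @export
program_correlation <- function(scores, gene_ids, seed = 1) {
  if (length(gene_ids) < 4) stop("need at least 4 genes")
  if (nrow(scores) < 20) stop("need at least 20 cells")
  sub <- scores[, gene_ids, drop = FALSE]
  sds <- apply(sub, 2, sd)
  if (any(sds == 0)) {
    warning("constant gene(s) excluded: ",
            paste(gene_ids[sds == 0], collapse = ", "))
    sub <- sub[, sds > 0, drop = FALSE]
    if (ncol(sub) < 4) stop("fewer than 4 non-constant genes remain")
  }
  r <- cor(sub)
  hc <- hclust(as.dist(1 - r), method = "average")
  grp <- cutree(hc, k = 2)
  hcf <- vapply(colnames(sub), function(g) {
    f <- tryCatch(fit_gmm2(sub[, g], seed = seed), error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    part <- assess_partition(sub[, g], f)
    if (!part$partitioned) return(NA_real_)
    mean(sub[, g] > part$threshold)
  }, numeric(1))
  list(correlation = r, groups = grp, high_cell_fraction = hcf, hclust = hc)
}
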