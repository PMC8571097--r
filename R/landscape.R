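#' Merge peak sets into non-overlapping regions
#'
#' Union of all intervals with overlapping or book-ended intervals
#' coalesced; output sorted by (chrom, start). Idempotent.
#'
#' @param peak_sets a list of interval data frames (or a single one).
#' @return interval data frame of merged regions.
#' @export
merge_peaks <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  if (length(peak_sets) < 1) stop("need at least one peak set")
  all_pk <- do.call(rbind, lapply(peak_sets, function(p)
    p[, c("chrom", "start", "end")]))
  if (nrow(all_pk) == 0) return(genomic_intervals(character(0), integer(0), integer(1)[0]))
  red <- GenomicRanges::reduce(as_granges0(all_pk))
  red <- GenomicRanges::sort(red)
  genomic_intervals(as.character(GenomicRanges::seqnames(red)),
                    GenomicRanges::start(red) - 1L,
                    GenomicRanges::end(red))
}

#' Lognormal-ECDF count filter
#'
#' Fits a lognormal by maximum likelihood to the positive entries of a
#' raw count matrix, and finds the largest count value, among values below
#' the distribution's median, whose empirical CDF diverges from the fitted
#' CDF by more than `max_divergence` in absolute value. Entries below that
#' threshold are masked to zero and rows left all-zero are dropped. On
#' counts genuinely drawn from a lognormal the divergence stays below the
#' tolerance and the threshold is 0 (nothing is removed); a contaminating
#' block of low counts inflates the empirical left tail and is cut away.
#'
#' @param mat numeric matrix of raw counts (regions x samples), needing at
#'   least 100 positive entries.
#' @param max_divergence maximum tolerated |ECDF - fitted CDF| (default
#'   0.05).
#' @return list with `matrix` (filtered), `threshold`, `kept_rows`
#'   (logical over input rows), and `divergence` (data frame of candidate
#'   value, empirical and fitted CDF, absolute divergence).
#' @export
lognormal_filter <- function(mat, max_divergence = 0.05) {
  pos <- mat[mat > 0]
  if (length(pos) < 100)
    stop("need at least 100 positive entries, got ", length(pos))
  if (max(pos) == min(pos)) stop("degenerate fit: all positive entries equal")
  fit <- MASS::fitdistr(pos, "lognormal")
  meanlog <- fit$estimate[["meanlog"]]; sdlog <- fit$estimate[["sdlog"]]
  emp <- ecdf(pos)
  # candidate thresholds live below the fitted distribution's median
  vals <- sort(unique(pos[pos < exp(meanlog)]))
  div <- data.frame(value = vals, empirical = emp(vals),
                    fitted = plnorm(vals, meanlog, sdlog))
  div$divergence <- abs(div$empirical - div$fitted)
  over <- div$value[div$divergence > max_divergence]
  threshold <- if (length(over)) max(over) else 0
  out <- mat
  out[out < threshold] <- 0
  kept <- rowSums(out) > 0
  list(matrix = out[kept, , drop = FALSE], threshold = threshold,
       kept_rows = kept, divergence = div,
       meanlog = meanlog, sdlog = sdlog)
}

#' Log-transform and column z-score a count matrix
#'
#' `x -> log10(x + 1)`, then each column centered to mean 0 and scaled to
#' sd 1.
#'
#' @param mat numeric matrix (regions x samples).
#' @return transformed matrix of the same shape.
#' @export
transform_zscore <- function(mat) {
  lg <- log10(mat + 1)
  sds <- apply(lg, 2, sd)
  zero <- which(sds == 0)
  if (length(zero))
    stop("zero-variance column: ",
         paste(colnames(mat)[zero] %||% zero, collapse = ", "))
  scale(lg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PCA followed by t-SNE embedding
#'
#' PCA over rows as observations; all components contributing more than
#' `min_variance` of the variance are passed to Barnes-Hut t-SNE with
#' perplexity defaulting to the nearest integer to the square root of the
#' number of rows. Duplicate rows are not removed.
#'
#' @param mat numeric matrix (observations x features), typically the
#'   z-scored region-count matrix (regions as observations) or its
#'   transpose (samples as observations).
#' @param perplexity t-SNE perplexity; `NULL` for the sqrt rule.
#' @param min_variance variance-fraction cutoff for component selection.
#' @param seed integer seed (t-SNE is stochastic).
#' @return list with `pcs` (retained scores), `variance_fraction` (all
#'   components), `n_components`, `coords` (n x 2 t-SNE coordinates),
#'   `perplexity`.
#' @export
pca_tsne <- function(mat, perplexity = NULL, min_variance = 0.01, seed = 1) {
  n <- nrow(mat)
  if (is.null(perplexity)) perplexity <- round(sqrt(n))
  if (n - 1 < 3 * perplexity)
    stop("perplexity ", perplexity, " infeasible for ", n,
         " rows; need perplexity <= ", floor((n - 1) / 3))
  p <- prcomp(mat, center = TRUE, scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  keep <- which(vf > min_variance)
  if (length(keep) < 1) keep <- 1L
  pcs <- p$x[, keep, drop = FALSE]
  set.seed(seed)
  ts <- Rtsne::Rtsne(pcs, dims = 2, perplexity = perplexity,
                     check_duplicates = FALSE, pca = FALSE, verbose = FALSE)
  list(pcs = pcs, variance_fraction = vf, n_components = length(keep),
       coords = ts$Y, perplexity = perplexity)
}

#' Density-peak clustering of 2-D coordinates
#'
#' Local density rho_i is a Gaussian kernel sum with cutoff distance d_c
#' at the `dc_percentile` of all pairwise distances; delta_i is the
#' distance to the nearest point of higher density (the global density
#' peak takes the maximum distance). Every non-center point inherits, in
#' order of decreasing density, the label of its nearest higher-density
#' neighbor.
#'
#' Two center-selection rules are available. The default `gamma_gap`
#' rule scales rho and delta to `[0, 1]`, ranks points by the product
#' gamma = rho x delta (the decision-graph outlier score), and takes
#' centers down to the largest relative gap in the sorted gamma sequence;
#' true cluster apexes combine high density with anomalously large delta
#' and stand out from the rest by orders of magnitude, so the gap locates
#' the cluster count robustly. The `percentile` rule instead declares
#' centers where rho and delta both exceed the `center_percentile` of
#' their distributions; it is retained for compatibility but is fragile
#' for clusters of comparable density, where an apex of a slightly
#' sparser cluster routinely falls below the global density percentile.
#'
#' @param coords numeric matrix n x 2.
#' @param center_rule `"gamma_gap"` (default) or `"percentile"`.
#' @param center_percentile percentile (0-100) for the `percentile` rule.
#' @param dc_percentile percentile (0-100) of pairwise distances for the
#'   kernel cutoff.
#' @param max_centers largest cluster count considered by `gamma_gap`.
#' @return list with `rho`, `delta`, `gamma`, `cluster` (integer labels),
#'   `centers` (indices), `dc`.
#' @export
density_peak_cluster <- function(coords,
                                 center_rule = c("gamma_gap", "percentile"),
                                 center_percentile = 95, dc_percentile = 2,
                                 max_centers = 30) {
  center_rule <- match.arg(center_rule)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 10) stop("need at least 10 points")
  d <- as.matrix(dist(coords))
  dc <- quantile(d[upper.tri(d)], dc_percentile / 100, names = FALSE)
  if (dc == 0) {
    if (all(d == 0)) {
      warning("all points identical; returning a single cluster")
      return(list(rho = rep(n - 1, n), delta = rep(0, n),
                  gamma = rep(0, n), cluster = rep(1L, n), centers = 1L,
                  dc = 0))
    }
    dc <- min(d[d > 0])
  }
  rho <- rowSums(exp(-(d / dc)^2)) - 1
  ord <- order(rho, decreasing = TRUE)
  delta <- numeric(n)
  nn_higher <- integer(n)
  delta[ord[1]] <- max(d[ord[1], ])
  nn_higher[ord[1]] <- ord[1]
  for (k in seq(2, n)) {
    i <- ord[k]
    prev <- ord[seq_len(k - 1)]
    j <- prev[which.min(d[i, prev])]
    delta[i] <- d[i, j]
    nn_higher[i] <- j
  }
  gamma <- (rho / max(rho)) * (delta / max(delta))
  centers <- if (center_rule == "percentile") {
    which(rho > quantile(rho, center_percentile / 100) &
          delta > quantile(delta, center_percentile / 100))
  } else {
    gord <- order(gamma, decreasing = TRUE)
    kmax <- min(max_centers, n - 1)
    gs <- gamma[gord[seq_len(kmax + 1)]]
    ratios <- gs[seq_len(kmax)] / pmax(gs[seq_len(kmax) + 1],
                                       .Machine$double.xmin)
    gord[seq_len(which.max(ratios))]
  }
  if (length(centers) == 0) {
    warning("no density-peak centers found; returning a single cluster")
    centers <- ord[1]
  }
  cluster <- integer(n)
  cluster[centers] <- seq_along(centers)
  for (i in ord) {
    if (cluster[i] == 0) cluster[i] <- cluster[nn_higher[i]]
  }
  list(rho = rho, delta = delta, gamma = gamma, cluster = cluster,
       centers = centers, dc = dc)
}

#' Cluster profiles, per-region lineage assignment and genome coverage
#'
#' `cluster_profiles`: per-cluster column means of the z-scored matrix.
#' `region_lineage`: for each region, the lineage whose samples have the
#' maximal mean z-score (ties resolved to the lexicographically first
#' lineage and flagged). `coverage_fraction`: total bases covered by a
#' peak set divided by the genome length.
#'
#' @param zmat z-scored matrix (regions x samples).
#' @param labels integer cluster labels per region.
#' @param lineage_map named character vector mapping each sample (column)
#'   to its lineage.
#' @return list with `profiles` (cluster x sample matrix), `lineage`
#'   (character per region), `lineage_tied` (logical per region).
#' @export
summarize_clusters <- function(zmat, labels, lineage_map) {
  if (!all(colnames(zmat) %in% names(lineage_map)))
    stop("lineage_map missing sample(s): ",
         paste(setdiff(colnames(zmat), names(lineage_map)), collapse = ", "))
  stopifnot(length(labels) == nrow(zmat))
  profiles <- rowsum(zmat, labels) / as.vector(table(labels))
  lineages <- sort(unique(lineage_map[colnames(zmat)]))
  lin_means <- sapply(lineages, function(lv) {
    cols <- which(lineage_map[colnames(zmat)] == lv)
    rowMeans(zmat[, cols, drop = FALSE])
  })
  best <- apply(lin_means, 1, which.max)
  tied <- apply(lin_means, 1, function(r) sum(r == max(r)) > 1)
  list(profiles = profiles, lineage = lineages[best], lineage_tied = tied)
}

#' @rdname summarize_clusters
#' @param peaks interval data frame of one sample's peak regions.
#' @param genome_length total genome length in bp.
#' @export
coverage_fraction <- function(peaks, genome_length) {
  if (genome_length <= 0) stop("genome_length must be positive")
  merged <- merge_peaks(peaks)
  sum(interval_width(merged)) / genome_length
}
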