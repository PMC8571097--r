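#' Quantify histone-mark signal in promoter windows
#'
#' Counts fragments whose midpoint falls in the 2-kb (by default) window
#' around each gene's TSS: `[tss - half_width, tss + half_width)`, clipped
#' at chromosome start.
#'
#' @param fragments fragment data frame (see [read_fragments()]).
#' @param genes gene-model data frame.
#' @param half_width window half-width in bp (> 0).
#' @return numeric matrix genes x barcodes (samples).
#' @export
quantify_tss_windows <- function(fragments, genes, half_width = 1000) {
  if (half_width <= 0) stop("half_width must be positive")
  win <- tss_windows(genes, half_width)
  count_fragments_in_intervals(fragments, win, mode = "midpoint")
}

#' Call bivalent promoters from paired H3K4me3 / H3K27me3 counts
#'
#' For each mark independently, fits a two-component Gaussian mixture to
#' `log10(count + 1)` over genes to separate enriched from non-enriched
#' promoters, asserting enrichment for genes residing in the upper
#' (enriched) component by posterior responsibility. A gene enriched for
#' both marks is bivalent. If a mark's mixture fails to partition, no gene
#' is enriched for that mark and a warning is raised.
#'
#' @param k4_counts,k27_counts non-negative per-gene counts for the active
#'   (H3K4me3) and repressive (H3K27me3) marks, same gene order.
#' @param gene_ids character vector of gene identifiers.
#' @param min_separation partition criterion, see [assess_partition()].
#' @param seed seed for the mixture fits.
#' @return data frame with `gene_id`, `k4_enriched`, `k27_enriched` and
#'   `status` in `bivalent`, `K4_only`, `K27_only`, `neither`; the two
#'   fits are attached as attributes `k4_fit` / `k27_fit`.
#' @export
call_bivalency <- function(k4_counts, k27_counts, gene_ids,
                           min_separation = 1.0, seed = 1) {
  stopifnot(length(k4_counts) == length(k27_counts),
            length(gene_ids) == length(k4_counts))
  if (length(gene_ids) < 10) stop("need at least 10 genes")
  enrich <- function(counts, mark) {
    x <- log10(counts + 1)
    fit <- fit_gmm2(x, seed = seed)
    part <- assess_partition(x, fit, min_separation)
    if (!part$partitioned) {
      warning("mixture failed to partition ", mark,
              " promoter counts; no gene called enriched")
      return(list(enriched = rep(FALSE, length(counts)), fit = fit))
    }
    cls <- classify_upper(x, fit, "posterior", part)
    list(enriched = !is.na(cls) & cls, fit = fit)
  }
  k4 <- enrich(k4_counts, "H3K4me3")
  k27 <- enrich(k27_counts, "H3K27me3")
  status <- ifelse(k4$enriched & k27$enriched, "bivalent",
            ifelse(k4$enriched, "K4_only",
            ifelse(k27$enriched, "K27_only", "neither")))
  out <- data.frame(gene_id = gene_ids, k4_enriched = k4$enriched,
                    k27_enriched = k27$enriched,
                    status = factor(status, levels = c("bivalent", "K4_only",
                                                       "K27_only", "neither")),
                    stringsAsFactors = FALSE)
  attr(out, "k4_fit") <- k4$fit
  attr(out, "k27_fit") <- k27$fit
  out
}

#' Bivalency fractions across gene groups with pairwise Fisher tests
#'
#' For disjoint gene groups (typically oncoprotein targets, missing
#' targets and unbound controls), reports the fraction of bivalent genes
#' per group and the two-sided Fisher exact test for every pair of groups
#' on the 2x2 table (bivalent vs not, group A vs group B).
#'
#' @param calls output of [call_bivalency()].
#' @param groups named list of character vectors of gene ids; every group
#'   must be non-empty and present in `calls`.
#' @return list with `fractions` (data frame: group, n, n_bivalent,
#'   fraction) and `tests` (data frame of pairwise Fisher results).
#' @export
group_bivalency_fractions <- function(calls, groups) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list")
  biv <- setNames(calls$status == "bivalent", calls$gene_id)
  frac <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    if (length(ids) == 0) stop("empty group: ", g)
    if (!all(ids %in% names(biv)))
      stop("group ", g, " contains gene ids absent from the calls")
    data.frame(group = g, n = length(ids), n_bivalent = sum(biv[ids]),
               fraction = mean(biv[ids]), stringsAsFactors = FALSE)
  })
  frac <- do.call(rbind, frac)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  tests <- lapply(pairs, function(p) {
    a <- biv[groups[[p[1]]]]; b <- biv[groups[[p[2]]]]
    tab <- matrix(c(sum(a), sum(!a), sum(b), sum(!b)), 2)
    ft <- fisher.test(tab)
    data.frame(group_a = p[1], group_b = p[2],
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  list(fractions = frac, tests = do.call(rbind, tests))
}
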