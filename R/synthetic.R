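#' Generate a synthetic gene annotation
#'
#' Gene lengths are lognormal with median 20 kb; genes are packed without
#' overlap onto the given chromosomes (gaps drawn by uniform stick
#' breaking) with random strands. Deterministic given the seed.
#'
#' @param n_genes number of genes.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param seed integer seed.
#' @param median_length median gene length in bp (default 20000).
#' @param sdlog lognormal sd of log gene length.
#' @return gene-model data frame (see [gene_models()]).
#' @export
make_annotation <- function(n_genes, chrom_lengths, seed,
                            median_length = 20000, sdlog = 0.6) {
  if (n_genes == 0)
    return(gene_models(character(0), character(0), integer(0),
                       integer(1)[0], character(0)))
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  set.seed(seed)
  lens <- round(rlnorm(n_genes, log(median_length), sdlog))
  # apportion genes to chromosomes proportional to length
  share <- chrom_lengths / sum(chrom_lengths)
  n_per <- floor(share * n_genes)
  rem <- n_genes - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1
  idx <- split(seq_len(n_genes), rep(names(chrom_lengths), n_per))
  rows <- lapply(names(chrom_lengths), function(ch) {
    ids <- idx[[ch]]
    if (is.null(ids) || length(ids) == 0) return(NULL)
    gl <- lens[ids]
    free <- chrom_lengths[[ch]] - sum(gl)
    if (free < 0)
      stop("infeasible packing: genes exceed length of ", ch)
    gaps <- diff(c(0, sort(runif(length(gl))), 1)) * free
    starts <- cumsum(gaps[-length(gaps)] + c(0, gl[-length(gl)]))
    data.frame(gene_idx = ids, chrom = ch, start = round(starts),
               end = round(starts) + gl, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$gene_idx), ]
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  gene_models(sprintf("gene%05d", seq_len(n_genes)), df$chrom, df$start,
              df$end, strand)
}

lnorm_pars <- function(m, s) {
  sdl <- sqrt(log(1 + s^2 / m^2))
  c(meanlog = log(m) - sdl^2 / 2, sdlog = sdl)
}

#' Simulate a dual-antibody fusion-oncoprotein profiling experiment
#'
#' Emulates one sample of paired N-terminal / C-terminal antibody peak
#' counts. Narrow peaks (~1.5 kb, gamma widths) sit over TSSs (a minority
#' placed intergenically); wide peaks are lognormal with mean 8.2 +/- 4 kb
#' and extend over gene bodies; fusion peaks are a planted subset of wide
#' peaks with widths lognormal mean 13.1 +/- 10 kb and N-terminal count
#' mean `nc_fold` times the C-terminal mean. Counts are negative binomial
#' with mean proportional to width times depth, modulated by independent
#' per-peak antibody-efficiency factors for the two termini (lognormal,
#' `ab_sdlog`), calibrated so a control sample's N-vs-C count correlation
#' lands near the 0.8-0.9 observed for wild-type profiles.
#'
#' @param annotation gene-model data frame.
#' @param n_peaks number of peaks (default 1000).
#' @param frac_wide fraction of wide peaks (default 0.075).
#' @param frac_fusion fraction of fusion peaks (default 0.05; must not
#'   exceed `frac_wide`).
#' @param nc_fold N-over-C fold change at fusion peaks (default 4).
#' @param depth expected count per kb of peak per terminus (default 40).
#' @param ab_sdlog sdlog of the per-peak antibody-efficiency factors.
#' @param nb_size negative-binomial size (inverse dispersion).
#' @param fusion_genes optional character vector of gene ids at which to
#'   plant the fusion peaks (defaults to a random draw).
#' @param intergenic_frac fraction of narrow peaks placed off-gene.
#' @param seed integer seed.
#' @return list with `peaks` (interval data frame, named), `signals`
#'   (data frame `peak_id`, `n_count`, `c_count`), and `truth` (list:
#'   `fusion_peaks`, `fusion_genes`, `wide_peaks`, `params`).
#' @export
simulate_fusion_experiment <- function(annotation, n_peaks = 1000,
                                       frac_wide = 0.075,
                                       frac_fusion = 0.05, nc_fold = 4,
                                       depth = 40, ab_sdlog = 0.06,
                                       nb_size = 100, fusion_genes = NULL,
                                       intergenic_frac = 0.1, seed = 1) {
  if (frac_fusion > frac_wide)
    stop("frac_fusion must not exceed frac_wide")
  if (any(c(frac_wide, frac_fusion) < 0) || frac_wide > 1)
    stop("fractions must lie in [0, 1]")
  set.seed(seed)
  n_wide <- round(frac_wide * n_peaks)
  n_fus <- round(frac_fusion * n_peaks)
  n_narrow <- n_peaks - n_wide
  if (n_wide > nrow(annotation))
    stop("not enough genes to host the wide peaks")

  # wide peaks over gene bodies of distinct genes; fusion peaks first
  body_genes <- if (!is.null(fusion_genes)) {
    if (!all(fusion_genes %in% annotation$gene_id))
      stop("fusion_genes absent from annotation")
    if (length(fusion_genes) != n_fus)
      stop("fusion_genes must have length ", n_fus)
    c(fusion_genes,
      sample(setdiff(annotation$gene_id, fusion_genes), n_wide - n_fus))
  } else {
    sample(annotation$gene_id, n_wide)
  }
  gi <- match(body_genes, annotation$gene_id)
  pw <- lnorm_pars(8200, 4000)
  pf <- lnorm_pars(13100, 10000)
  wide_w <- round(rlnorm(n_wide, pw["meanlog"], pw["sdlog"]))
  if (n_fus > 0)
    wide_w[seq_len(n_fus)] <- round(rlnorm(n_fus, pf["meanlog"], pf["sdlog"]))
  wide_w <- pmax(wide_w, 2500)
  # start inside the gene body, clear of the promoter window
  off <- ifelse(annotation$strand[gi] == "+", 1500, -1500)
  wide_start <- ifelse(annotation$strand[gi] == "+",
                       annotation$tss[gi] + 1500,
                       pmax(0, annotation$tss[gi] - 1500 - wide_w))
  wide_df <- data.frame(chrom = annotation$chrom[gi], start = wide_start,
                        end = wide_start + wide_w)

  # narrow peaks centered on TSSs of the remaining genes (with replacement
  # if the annotation is small), a minority placed intergenically
  narrow_w <- round(1000 + rgamma(n_narrow, shape = 3, scale = 170))
  host <- sample(setdiff(seq_len(nrow(annotation)), gi), n_narrow,
                 replace = n_narrow > nrow(annotation) - n_wide)
  centers <- annotation$tss[host]
  n_inter <- round(intergenic_frac * n_narrow)
  if (n_inter > 0) {
    chroms <- unique(annotation$chrom)
    pick <- sample(chroms, n_inter, replace = TRUE)
    span <- vapply(chroms, function(ch)
      max(annotation$end[annotation$chrom == ch]), numeric(1))
    centers[seq_len(n_inter)] <- round(runif(n_inter) * span[pick]) + 2e6
    narrow_chrom <- annotation$chrom[host]
    narrow_chrom[seq_len(n_inter)] <- pick
  } else narrow_chrom <- annotation$chrom[host]
  narrow_df <- data.frame(chrom = narrow_chrom,
                          start = pmax(0, centers - narrow_w %/% 2),
                          end = pmax(0, centers - narrow_w %/% 2) + narrow_w)

  pk <- rbind(wide_df, narrow_df)
  peaks <- genomic_intervals(pk$chrom, pk$start, pk$end,
                             name = sprintf("peak%05d", seq_len(n_peaks)))
  is_fus <- c(rep(TRUE, n_fus), rep(FALSE, n_peaks - n_fus))
  is_wide <- c(rep(TRUE, n_wide), rep(FALSE, n_narrow))

  mu <- interval_width(peaks) / 1000 * depth
  eff_n <- rlnorm(n_peaks, 0, ab_sdlog)
  eff_c <- rlnorm(n_peaks, 0, ab_sdlog)
  c_count <- rnbinom(n_peaks, mu = mu * eff_c, size = nb_size)
  n_count <- rnbinom(n_peaks, mu = mu * eff_n * ifelse(is_fus, nc_fold, 1),
                     size = nb_size)
  signals <- data.frame(peak_id = peaks$name, n_count = n_count,
                        c_count = c_count, stringsAsFactors = FALSE)
  list(peaks = peaks, signals = signals,
       truth = list(fusion_peaks = peaks$name[is_fus],
                    fusion_genes = body_genes[seq_len(n_fus)],
                    wide_peaks = peaks$name[is_wide],
                    params = list(n_peaks = n_peaks, frac_wide = frac_wide,
                                  frac_fusion = frac_fusion,
                                  nc_fold = nc_fold, depth = depth,
                                  ab_sdlog = ab_sdlog, nb_size = nb_size,
                                  seed = seed)))
}

#' Simulate promoter-window counts for two histone marks
#'
#' Assigns each gene a planted status (bivalent, K4-only, K27-only or
#' neither) and draws negative-binomial promoter counts per mark:
#' background mean `depth`, enriched mean `effect_fold * depth`.
#'
#' @param annotation gene-model data frame.
#' @param frac_k4,frac_k27 fractions of genes enriched for each mark
#'   (bivalent genes are enriched for both and count toward both).
#' @param frac_bivalent fraction of genes enriched for both marks; must
#'   not exceed `min(frac_k4, frac_k27)`.
#' @param effect_fold enrichment fold over background (default 8).
#' @param depth background mean count (default 20).
#' @param nb_size negative-binomial size.
#' @param seed integer seed.
#' @return list with `counts` (data frame `gene_id`, `k4_count`,
#'   `k27_count`) and `truth` (list: `status` named character vector,
#'   `bivalent_genes`, `params`).
#' @export
simulate_promoter_marks <- function(annotation, frac_k4 = 0.4,
                                    frac_k27 = 0.25, frac_bivalent = 0.1,
                                    effect_fold = 8, depth = 20,
                                    nb_size = 10, seed = 1) {
  fr <- c(frac_k4, frac_k27, frac_bivalent)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (frac_bivalent > min(frac_k4, frac_k27))
    stop("frac_bivalent must not exceed min(frac_k4, frac_k27)")
  set.seed(seed)
  n <- nrow(annotation)
  n_biv <- round(frac_bivalent * n)
  n_k4 <- round((frac_k4 - frac_bivalent) * n)
  n_k27 <- round((frac_k27 - frac_bivalent) * n)
  status <- rep("neither", n)
  pick <- sample(n, n_biv + n_k4 + n_k27)
  status[pick[seq_len(n_biv)]] <- "bivalent"
  if (n_k4 > 0) status[pick[n_biv + seq_len(n_k4)]] <- "K4_only"
  if (n_k27 > 0) status[pick[n_biv + n_k4 + seq_len(n_k27)]] <- "K27_only"
  k4_mu <- ifelse(status %in% c("bivalent", "K4_only"),
                  effect_fold * depth, depth)
  k27_mu <- ifelse(status %in% c("bivalent", "K27_only"),
                   effect_fold * depth, depth)
  counts <- data.frame(gene_id = annotation$gene_id,
                       k4_count = rnbinom(n, mu = k4_mu, size = nb_size),
                       k27_count = rnbinom(n, mu = k27_mu, size = nb_size),
                       stringsAsFactors = FALSE)
  list(counts = counts,
       truth = list(status = setNames(status, annotation$gene_id),
                    bivalent_genes = annotation$gene_id[status == "bivalent"],
                    params = list(frac_k4 = frac_k4, frac_k27 = frac_k27,
                                  frac_bivalent = frac_bivalent,
                                  effect_fold = effect_fold, depth = depth,
                                  nb_size = nb_size, seed = seed)))
}

#' Simulate single-cell fragments with two anticorrelated gene programs
#'
#' Each cell carries program A with probability `frac_program_a`, else
#' program B. Program-on genes emit fragments at `on_weight`; program-off
#' genes at `off_weight`; all remaining (housekeeping) genes at gene-
#' specific lognormal weights shared by every cell. Per-cell depth is
#' negative binomial; fragments are placed uniformly within the emitting
#' gene. Because a cell's fragments are multinomial at fixed depth, the
#' two programs are anticorrelated across cells by construction.
#'
#' @param annotation gene-model data frame.
#' @param n_cells number of cells.
#' @param program_genes_a,program_genes_b disjoint character vectors of
#'   gene ids.
#' @param frac_program_a probability a cell carries program A (default
#'   0.15, a minority program).
#' @param per_cell_depth mean fragments per cell (default 800).
#' @param on_weight,off_weight emission weights of program genes in the
#'   on / off state (housekeeping weights have mean ~1).
#' @param frag_width emitted fragment width in bp.
#' @param nb_size negative-binomial size of the per-cell depth.
#' @param seed integer seed.
#' @return list with `fragments` (data frame), `truth` (list: `program`
#'   named character vector over cells, `hk_weights`, `params`).
#' @export
simulate_single_cells <- function(annotation, n_cells,
                                  program_genes_a, program_genes_b,
                                  frac_program_a = 0.15,
                                  per_cell_depth = 800, on_weight = 12,
                                  off_weight = 0.15, frag_width = 200,
                                  nb_size = 10, seed = 1) {
  if (length(intersect(program_genes_a, program_genes_b)))
    stop("program gene sets must be disjoint")
  if (!all(c(program_genes_a, program_genes_b) %in% annotation$gene_id))
    stop("program genes absent from annotation")
  set.seed(seed)
  n_genes <- nrow(annotation)
  hk_w <- rlnorm(n_genes, 0, 0.5)
  names(hk_w) <- annotation$gene_id
  ia <- match(program_genes_a, annotation$gene_id)
  ib <- match(program_genes_b, annotation$gene_id)
  program <- ifelse(runif(n_cells) < frac_program_a, "A", "B")
  depth_per_cell <- pmax(1, rnbinom(n_cells, mu = per_cell_depth,
                                    size = nb_size))
  frags <- vector("list", n_cells)
  glen <- annotation$end - annotation$start
  for (ci in seq_len(n_cells)) {
    w <- hk_w
    w[ia] <- if (program[ci] == "A") on_weight else off_weight
    w[ib] <- if (program[ci] == "B") on_weight else off_weight
    gene <- sample.int(n_genes, depth_per_cell[ci], replace = TRUE,
                       prob = w)
    pos <- annotation$start[gene] +
      floor(runif(depth_per_cell[ci]) * pmax(1, glen[gene] - frag_width))
    frags[[ci]] <- data.frame(chrom = annotation$chrom[gene], start = pos,
                              end = pos + frag_width,
                              barcode = sprintf("cell%04d", ci), count = 1,
                              stringsAsFactors = FALSE)
  }
  fragments <- do.call(rbind, frags)
  fragments <- fragments[order(fragments$chrom, fragments$start), ]
  rownames(fragments) <- NULL
  list(fragments = fragments,
       truth = list(program = setNames(program,
                                       sprintf("cell%04d", seq_len(n_cells))),
                    hk_weights = hk_w,
                    params = list(n_cells = n_cells,
                                  frac_program_a = frac_program_a,
                                  per_cell_depth = per_cell_depth,
                                  on_weight = on_weight,
                                  off_weight = off_weight, seed = seed)))
}

#' Simulate a multi-sample chromatin-landscape count matrix
#'
#' Regions fall into classes: shared (high in every sample),
#' lineage-specific (high in all samples of one lineage) and
#' sample-specific noise (high in a single random sample). Under
#' `structure = "sample"` the lineage-class regions are instead high in a
#' random sample subset of the same size, removing lineage block
#' structure while keeping truth labels — the negative control for
#' lineage separation.
#'
#' @param n_regions number of regions (default 2000).
#' @param samples_per_lineage samples per lineage (default 4).
#' @param lineages lineage labels.
#' @param frac_shared fraction of shared regions.
#' @param frac_lineage_specific fraction of lineage-specific regions
#'   (split evenly across lineages); `frac_shared + frac_lineage_specific
#'   <= 1`.
#' @param depth background median count.
#' @param fold enrichment fold of "high" cells of the matrix.
#' @param sdlog lognormal spread of counts around their expected value.
#' @param region_sdlog sdlog of the per-region baseline intensity; the
#'   continuous intensity spectrum makes the marginal count distribution
#'   approximately lognormal, which is what the downstream filter
#'   assumes of such matrices.
#' @param structure `"lineage"` (default) or `"sample"` (no lineage
#'   blocks).
#' @param region_width_mean mean region width in bp.
#' @param chrom_lengths named vector for region placement.
#' @param seed integer seed.
#' @return list with `matrix` (regions x samples raw counts), `regions`
#'   (interval data frame), `samples` (data frame `sample_id`, `lineage`),
#'   `truth` (list: `region_class`, `region_lineage`, `params`).
#' @export
simulate_landscape <- function(n_regions = 2000, samples_per_lineage = 4,
                               lineages = c("ALL", "AML", "MPAL"),
                               frac_shared = 0.2,
                               frac_lineage_specific = 0.3, depth = 50,
                               fold = 6, sdlog = 0.4, region_sdlog = 1,
                               structure = c("lineage", "sample"),
                               region_width_mean = 2000,
                               chrom_lengths = c(chrL = 2e8), seed = 1) {
  structure <- match.arg(structure)
  if (frac_shared + frac_lineage_specific > 1)
    stop("frac_shared + frac_lineage_specific must not exceed 1")
  set.seed(seed)
  samples <- data.frame(
    sample_id = paste0(rep(lineages, each = samples_per_lineage), "_",
                       seq_len(samples_per_lineage)),
    lineage = rep(lineages, each = samples_per_lineage),
    stringsAsFactors = FALSE)
  n_s <- nrow(samples)
  n_shared <- round(frac_shared * n_regions)
  n_lin_tot <- round(frac_lineage_specific * n_regions)
  n_per_lin <- floor(n_lin_tot / length(lineages))
  cls <- c(rep("shared", n_shared),
           rep(lineages, each = n_per_lin),
           rep("sample_specific",
               n_regions - n_shared - n_per_lin * length(lineages)))
  cls <- sample(cls)
  high <- matrix(FALSE, n_regions, n_s)
  for (i in seq_len(n_regions)) {
    high[i, ] <- if (cls[i] == "shared") TRUE
    else if (cls[i] %in% lineages) {
      if (structure == "lineage") samples$lineage == cls[i]
      else seq_len(n_s) %in% sample(n_s, samples_per_lineage)
    } else seq_len(n_s) == sample(n_s, 1)
  }
  base <- exp(rnorm(n_regions, 0, region_sdlog))
  mu <- base * ifelse(high, depth * fold, depth)
  counts <- matrix(round(rlnorm(length(mu), log(mu), sdlog)),
                   n_regions, n_s)
  # non-overlapping regions laid out with random gaps
  widths <- pmax(500, round(rlnorm(n_regions, log(region_width_mean), 0.5)))
  total <- sum(widths)
  if (total > 0.9 * sum(chrom_lengths))
    stop("regions do not fit the genome")
  gaps <- diff(c(0, sort(runif(n_regions)))) *
    (sum(chrom_lengths) - total)
  starts <- cumsum(gaps + c(0, widths[-n_regions]))
  regions <- genomic_intervals(names(chrom_lengths)[1], round(starts),
                               round(starts) + widths,
                               name = sprintf("region%05d",
                                              seq_len(n_regions)))
  dimnames(counts) <- list(regions$name, samples$sample_id)
  list(matrix = counts, regions = regions, samples = samples,
       truth = list(region_class = setNames(cls, regions$name),
                    region_lineage = setNames(
                      ifelse(cls %in% lineages, cls, NA_character_),
                      regions$name),
                    params = list(n_regions = n_regions,
                                  samples_per_lineage = samples_per_lineage,
                                  frac_shared = frac_shared,
                                  frac_lineage_specific = frac_lineage_specific,
                                  depth = depth, fold = fold,
                                  sdlog = sdlog,
                                  region_sdlog = region_sdlog,
                                  structure = structure,
                                  seed = seed)))
}

#' Minimal threshold-and-merge peak caller (fixture plumbing)
#'
#' Calls peaks as maximal runs of genome positions whose pooled fragment
#' coverage reaches `min_total`, merging runs separated by at most
#' `merge_gap` bp. This is deliberately simple scaffolding for building
#' aggregate peak sets from synthetic fragments, not a production peak
#' caller.
#'
#' @param fragments fragment data frame.
#' @param merge_gap maximum gap merged into one peak (bp).
#' @param min_total minimum pooled coverage.
#' @return interval data frame of peaks.
#' @export
call_fixture_peaks <- function(fragments, merge_gap = 100, min_total = 5) {
  if (nrow(fragments) == 0)
    return(genomic_intervals(character(0), integer(0), integer(1)[0]))
  gr <- as_granges0(fragments)
  cov <- GenomicRanges::coverage(gr, weight = fragments$count)
  out <- lapply(names(cov), function(ch) {
    sl <- IRanges::slice(cov[[ch]], lower = min_total, rangesOnly = TRUE)
    if (length(sl) == 0) return(NULL)
    red <- IRanges::reduce(sl, min.gapwidth = merge_gap + 1)
    data.frame(chrom = ch, start = IRanges::start(red) - 1L,
               end = IRanges::end(red), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(genomic_intervals(character(0), integer(0), integer(1)[0]))
  genomic_intervals(out$chrom, out$start, out$end,
                    name = sprintf("aggpeak%05d", seq_len(nrow(out))))
}

#' Expand per-interval counts into fragment records
#'
#' Utility for exercising the fragment-level readers and quantifiers on
#' synthetic count tables: emits `counts[i]` single-count fragment
#' records placed uniformly inside interval `i`.
#'
#' @param intervals interval data frame.
#' @param counts non-negative integer vector, one per interval.
#' @param barcode barcode attached to every record.
#' @param frag_width fragment width in bp.
#' @param seed integer seed.
#' @return fragment data frame.
#' @export
counts_to_fragments <- function(intervals, counts, barcode,
                                frag_width = 200, seed = 1) {
  stopifnot(nrow(intervals) == length(counts))
  set.seed(seed)
  idx <- rep(seq_len(nrow(intervals)), counts)
  if (length(idx) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), barcode = character(0),
                      count = numeric(0)))
  span <- pmax(1, interval_width(intervals)[idx] - frag_width)
  pos <- intervals$start[idx] + floor(runif(length(idx)) * span)
  out <- data.frame(chrom = intervals$chrom[idx], start = pos,
                    end = pos + frag_width, barcode = barcode, count = 1,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), ]
}
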