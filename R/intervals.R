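#' chromfusion: chromatin profiling analysis of fusion-oncoprotein targets
#'
#' Downstream analysis of dual-antibody CUT&RUN / CUT&Tag chromatin
#' profiling: NCR-based fusion-oncoprotein site calling, bivalent promoter
#' calling, chromatin-landscape embedding and clustering, and single-cell
#' chromatin heterogeneity, together with seeded synthetic-data generators
#' carrying planted ground truth.
#'
#' All genomic coordinates throughout the package are 0-based, half-open
#' (BED convention): an interval covers bases `start .. end - 1` and two
#' intervals that merely abut do not overlap.
#'
#' @keywords internal
#' @aliases chromfusion-package
#' @importFrom stats dnorm ecdf quantile median sd var cor prcomp hclust
#'   cutree dist as.dist fisher.test t.test rnbinom rlnorm rgamma runif
#'   rbinom pnorm plnorm setNames aggregate complete.cases pt
#' @importFrom utils head tail
"_PACKAGE"

STRANDS <- c("+", "-", ".")

#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` and
#' optionally `name`, `score`, `strand`, using 0-based half-open
#' coordinates. This constructor validates the invariants shared by every
#' quantification step.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `start < end`.
#' @param name optional character vector of interval names.
#' @param score optional numeric vector.
#' @param strand optional vector in `+`, `-`, `.`.
#' @return a `data.frame` of intervals.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL,
                              strand = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be non-missing integers")
  if (any(start < 0)) stop("interval start must be >= 0")
  bad <- which(start >= end)
  if (length(bad))
    stop("invalid interval (start >= end) at position ", bad[1])
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    if (!all(strand %in% STRANDS)) stop("strand must be one of +, -, .")
    df$strand <- strand
  }
  df
}

#' Interval widths
#' @param intervals interval data frame.
#' @return numeric vector `end - start`.
#' @export
interval_width <- function(intervals) intervals$end - intervals$start

# 0-based half-open -> GRanges (1-based closed); internal
as_granges0 <- function(intervals, seqlevels = NULL) {
  GenomicRanges::GRanges(
    seqnames = factor(intervals$chrom,
                      levels = seqlevels %||% unique(intervals$chrom)),
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end))
}

#' Read genomic intervals from BED-family files
#'
#' Parses tab-separated BED3, BED6 or bedGraph records into 0-based
#' half-open intervals. Malformed coordinates are reported with their line
#' number.
#'
#' @param path file path.
#' @param format one of `"BED3"`, `"BED6"`, `"bedGraph"`.
#' @return interval data frame (see [genomic_intervals()]).
#' @export
read_intervals <- function(path, format = c("BED3", "BED6", "bedGraph")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  ncols <- switch(format, BED3 = 3L, BED6 = 6L, bedGraph = 4L)
  if (file.size(path) == 0)
    return(genomic_intervals(character(0), integer(0), integer(1)[0]))
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE)
  if (nrow(dt) == 0)
    return(genomic_intervals(character(0), integer(0), integer(1)[0]))
  if (ncol(dt) < ncols)
    stop("expected at least ", ncols, " columns for ", format,
         ", found ", ncol(dt))
  start <- suppressWarnings(as.numeric(dt[[2]]))
  end <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad))
    stop("malformed interval at line ", bad[1], " of ", path,
         " (start >= end, negative, or non-numeric)")
  out <- switch(format,
    BED3 = genomic_intervals(dt[[1]], start, end),
    BED6 = genomic_intervals(dt[[1]], start, end, name = dt[[4]],
                             score = suppressWarnings(as.numeric(dt[[5]])),
                             strand = dt[[6]]),
    bedGraph = genomic_intervals(dt[[1]], start, end,
                                 score = suppressWarnings(as.numeric(dt[[4]]))))
  out
}

#' Write genomic intervals in the dialect [read_intervals()] accepts
#' @param intervals interval data frame.
#' @param path output path.
#' @param format one of `"BED3"`, `"BED6"`, `"bedGraph"`.
#' @export
write_intervals <- function(intervals, path,
                            format = c("BED3", "BED6", "bedGraph")) {
  format <- match.arg(format)
  df <- switch(format,
    BED3 = intervals[, c("chrom", "start", "end")],
    BED6 = data.frame(intervals$chrom, intervals$start, intervals$end,
                      if (is.null(intervals$name)) "." else intervals$name,
                      if (is.null(intervals$score)) 0 else intervals$score,
                      if (is.null(intervals$strand)) "." else intervals$strand),
    bedGraph = data.frame(intervals$chrom, intervals$start, intervals$end,
                          if (is.null(intervals$score)) 0 else intervals$score))
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fragments file
#'
#' Fragments are 5-column tab-separated records
#' `chrom, start, end, barcode, count` (the de facto single-cell fragments
#' dialect); the same reader serves bulk inputs, where the barcode is a
#' sample identifier. Records are returned sorted by `(chrom, start)`.
#'
#' @param path file path.
#' @return data frame with columns `chrom`, `start`, `end`, `barcode`,
#'   `count`.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), barcode = character(0),
                      count = numeric(0))
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE)
  if (nrow(dt) == 0) return(empty)
  if (ncol(dt) != 5) stop("fragments file must have 5 columns, found ", ncol(dt))
  names(dt) <- c("chrom", "start", "end", "barcode", "count")
  dt$chrom <- as.character(dt$chrom); dt$barcode <- as.character(dt$barcode)
  bad <- which(dt$start >= dt$end)
  if (length(bad)) stop("malformed fragment (start >= end) at line ", bad[1])
  bad <- which(dt$count < 1)
  if (length(bad)) stop("fragment count < 1 at line ", bad[1])
  dt[order(dt$chrom, dt$start), , drop = FALSE]
}

#' Write a fragments file
#' @param fragments fragment data frame.
#' @param path output path.
#' @export
write_fragments <- function(fragments, path) {
  data.table::fwrite(
    fragments[, c("chrom", "start", "end", "barcode", "count")],
    path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Overlap join between two interval sets
#'
#' Emits a pair (query index, subject index) for every pair of intervals
#' sharing at least one base on the same chromosome. Half-open semantics:
#' end-abutting intervals do not overlap.
#'
#' @param query,subject interval data frames.
#' @return data frame with integer columns `query`, `subject`.
#' @export
overlap_join <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(data.frame(query = integer(0), subject = integer(0)))
  levs <- union(unique(query$chrom), unique(subject$chrom))
  hits <- GenomicRanges::findOverlaps(as_granges0(query, levs),
                                      as_granges0(subject, levs))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

#' Count fragments in intervals
#'
#' Builds an intervals-by-barcodes count matrix. Under `any_overlap` a
#' fragment contributes its count to every interval it overlaps; under
#' `midpoint` it contributes to the unique interval containing
#' `floor((start + end) / 2)` (half-open), which avoids double counting
#' across adjacent fixed windows.
#'
#' @param fragments fragment data frame.
#' @param intervals interval data frame (non-empty).
#' @param mode `"any_overlap"` or `"midpoint"`.
#' @return numeric matrix, rows = intervals (named from `name` column or
#'   `chrom:start-end`), columns = barcodes.
#' @export
count_fragments_in_intervals <- function(fragments, intervals,
                                         mode = c("any_overlap", "midpoint")) {
  mode <- match.arg(mode)
  if (nrow(intervals) == 0) stop("intervals must be non-empty")
  rid <- interval_ids(intervals)
  barcodes <- sort(unique(fragments$barcode))
  mat <- matrix(0, nrow(intervals), max(length(barcodes), 1),
                dimnames = list(rid, if (length(barcodes)) barcodes else "none"))
  if (nrow(fragments) == 0) return(mat[, 0, drop = FALSE])
  frag_iv <- if (mode == "midpoint") {
    mid <- floor((fragments$start + fragments$end) / 2)
    genomic_intervals(fragments$chrom, mid, mid + 1)
  } else {
    genomic_intervals(fragments$chrom, fragments$start, fragments$end)
  }
  hits <- overlap_join(frag_iv, intervals)
  if (nrow(hits)) {
    j <- match(fragments$barcode[hits$query], barcodes)
    inc <- fragments$count[hits$query]
    idx <- cbind(hits$subject, j)
    # accumulate duplicates
    key <- paste(idx[, 1], idx[, 2])
    agg <- rowsum(inc, key)
    ij <- do.call(rbind, strsplit(rownames(agg), " "))
    mat[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] <- agg[, 1]
  }
  mat
}

interval_ids <- function(intervals) {
  if (!is.null(intervals$name) && !anyDuplicated(intervals$name))
    intervals$name
  else
    paste0(intervals$chrom, ":", intervals$start, "-", intervals$end)
}

#' Gene models with transcription start sites
#'
#' A gene model is an interval with a `gene_id` and a strand-aware TSS:
#' `start` for `+` genes and `end - 1` for `-` genes (0-based).
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom,start,end coordinates, 0-based half-open.
#' @param strand `+` or `-` per gene.
#' @return data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand) {
  if (anyDuplicated(gene_id)) stop("duplicate gene_id")
  iv <- genomic_intervals(chrom, start, end, strand = strand)
  tss <- ifelse(iv$strand == "-", iv$end - 1, iv$start)
  data.frame(gene_id = as.character(gene_id), chrom = iv$chrom,
             start = iv$start, end = iv$end, strand = iv$strand, tss = tss,
             stringsAsFactors = FALSE)
}

#' TSS windows for a gene annotation
#'
#' Symmetric half-open windows `[tss - half_width, tss + half_width)`,
#' clipped at 0.
#'
#' @param genes gene-model data frame (see [gene_models()]).
#' @param half_width window half-width in bp (default 1000, i.e. a 2-kb
#'   window around the TSS).
#' @return interval data frame named by `gene_id`.
#' @export
tss_windows <- function(genes, half_width = 1000) {
  if (half_width <= 0) stop("half_width must be positive")
  genomic_intervals(genes$chrom, pmax(0, genes$tss - half_width),
                    genes$tss + half_width, name = genes$gene_id)
}

#' Read / write a count matrix as TSV
#'
#' TSV dialect: header row of sample identifiers, first column of row
#' identifiers.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_count_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  if (anyDuplicated(rownames(m))) stop("duplicate row identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate column identifiers")
  m
}

#' @rdname read_count_matrix
#' @param mat numeric matrix with dimnames.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
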