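# Shared fixture builders; everything is generated in code at test time.

tiny_genome <- c(chrA = 2.5e7, chrB = 2.5e7)

fixture_annotation <- function(n_genes = 400, seed = 1) {
  make_annotation(n_genes, tiny_genome, seed = seed)
}

# brute-force O(n*m) overlap oracle on 0-based half-open intervals
brute_overlap <- function(query, subject) {
  out <- list()
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chrom[i] == subject$chrom[j] &&
        query$start[i] < subject$end[j] && subject$start[j] < query$end[i])
      out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(query = integer(0), subject = integer(0)))
  m <- do.call(rbind, out)
  data.frame(query = m[, 1], subject = m[, 2])
}

random_intervals <- function(n, seed, max_pos = 1e6, chroms = c("c1", "c2")) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start,
                    start + sample.int(5000, n, replace = TRUE),
                    name = sprintf("iv%04d", seq_len(n)))
}

# adjusted Rand index (independent of any clustering package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# mean silhouette over a 2-level grouping, plain implementation
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
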