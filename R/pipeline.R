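#' Default pipeline configuration
#'
#' A nested list holding every tunable of the four analysis stages plus
#' the synthetic-data generators that feed them. All stochastic stages
#' derive their seeds from the single top-level `seed`.
#'
#' @param seed master integer seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    annotation = list(n_genes = 400, chrom_lengths = c(chrA = 2.5e7,
                                                       chrB = 2.5e7)),
    fusion = list(n_peaks = 1000, frac_wide = 0.075, frac_fusion = 0.05,
                  nc_fold = 4, depth = 40, ab_sdlog = 0.06, nb_size = 100,
                  tss_halfwidth = 1000, width_transform = "identity",
                  ncr_rule = "above_threshold", min_separation = 1,
                  min_samples = 5),
    bivalency = list(frac_k4 = 0.4, frac_k27 = 0.25, frac_bivalent = 0.2,
                     effect_fold = 8, depth = 20, nb_size = 10,
                     half_width = 1000),
    landscape = list(n_regions = 1000, samples_per_lineage = 3,
                     frac_shared = 0.2, frac_lineage_specific = 0.3,
                     depth = 50, fold = 6, sdlog = 0.4, region_sdlog = 1,
                     max_divergence = 0.05, center_percentile = 95,
                     dc_percentile = 2),
    sc = list(n_cells = 300, per_cell_depth = 800, n_program_genes = 8,
              frac_program_a = 0.15, min_fragments = 300, bin_width = 5000,
              n_components = 20, k_impute = 15, t_impute = 3, n_bins = 20)
  )
}

#' Validate a pipeline configuration
#'
#' Strict structural validation against [default_config()]: unknown keys
#' are rejected (all offenders listed), missing keys are rejected, and
#' every stochastic stage must have a seed (inherited from the top-level
#' `seed`).
#'
#' @param config nested configuration list.
#' @return the validated config, invisibly.
#' @export
validate_config <- function(config) {
  template <- default_config()
  problems <- character(0)
  check <- function(cfg, tpl, path) {
    unknown <- setdiff(names(cfg), names(tpl))
    missing <- setdiff(names(tpl), names(cfg))
    if (length(unknown))
      problems <<- c(problems, paste0("unknown key: ", path, unknown))
    if (length(missing))
      problems <<- c(problems, paste0("missing key: ", path, missing))
    for (k in intersect(names(cfg), names(tpl)))
      if (is.list(tpl[[k]])) check(cfg[[k]], tpl[[k]], paste0(path, k, "$"))
  }
  check(config, template, "")
  if (!is.numeric(config$seed) || length(config$seed) != 1)
    problems <- c(problems, "seed must be a single integer")
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  invisible(config)
}

#' Run the synthetic-data pipeline end to end
#'
#' Simulates inputs for the requested stages, runs each stage's analysis,
#' writes the stage outputs as plain-text tables under `outdir`, and
#' writes a manifest (parameters, seeds, output digests) as JSON.
#' Identical configuration implies identical output digests.
#'
#' @param config configuration from [default_config()], already validated.
#' @param stages subset of `c("fusion", "bivalency", "landscape", "sc")`.
#' @param outdir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("fusion", "bivalency", "landscape",
                                    "sc"),
                         outdir = tempfile("chromfusion_run_")) {
  validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
    outputs <<- c(outputs, path)
  }

  ann <- make_annotation(config$annotation$n_genes,
                         config$annotation$chrom_lengths, seed = seed)

  if ("fusion" %in% stages) {
    cf <- config$fusion
    sim <- simulate_fusion_experiment(
      ann, n_peaks = cf$n_peaks, frac_wide = cf$frac_wide,
      frac_fusion = cf$frac_fusion, nc_fold = cf$nc_fold, depth = cf$depth,
      ab_sdlog = cf$ab_sdlog, nb_size = cf$nb_size, seed = seed + 101)
    calls <- call_fusion_sites(sim$peaks, sim$signals$n_count,
                               sim$signals$c_count,
                               width_transform = cf$width_transform,
                               ncr_rule = cf$ncr_rule,
                               min_separation = cf$min_separation,
                               seed = seed + 102)
    targets <- assign_targets(sim$peaks, calls$table$is_fusion, ann,
                              cf$tss_halfwidth)
    cat_tab <- data.frame(
      peak_id = sim$peaks$name,
      category = annotate_peak_categories(sim$peaks, ann,
                                          cf$tss_halfwidth))
    emit(cbind(sim$peaks, calls$table[, -1]), "fusion_calls.tsv")
    emit(cat_tab, "fusion_categories.tsv")
    emit(data.frame(gene_id = targets), "fusion_targets.tsv")
  }

  if ("bivalency" %in% stages) {
    cb <- config$bivalency
    sim <- simulate_promoter_marks(
      ann, frac_k4 = cb$frac_k4, frac_k27 = cb$frac_k27,
      frac_bivalent = cb$frac_bivalent, effect_fold = cb$effect_fold,
      depth = cb$depth, nb_size = cb$nb_size, seed = seed + 201)
    calls <- call_bivalency(sim$counts$k4_count, sim$counts$k27_count,
                            sim$counts$gene_id, seed = seed + 202)
    emit(calls, "bivalency_calls.tsv")
  }

  if ("landscape" %in% stages) {
    cl <- config$landscape
    sim <- simulate_landscape(
      n_regions = cl$n_regions,
      samples_per_lineage = cl$samples_per_lineage,
      frac_shared = cl$frac_shared,
      frac_lineage_specific = cl$frac_lineage_specific, depth = cl$depth,
      fold = cl$fold, sdlog = cl$sdlog, region_sdlog = cl$region_sdlog,
      seed = seed + 301)
    filt <- lognormal_filter(sim$matrix, cl$max_divergence)
    z <- transform_zscore(filt$matrix)
    emb <- pca_tsne(z, seed = seed + 302)
    dpc <- density_peak_cluster(emb$coords, cl$center_percentile,
                                cl$dc_percentile)
    lin_map <- setNames(sim$samples$lineage, sim$samples$sample_id)
    summ <- summarize_clusters(z, dpc$cluster, lin_map)
    emit(data.frame(region = rownames(z), x = emb$coords[, 1],
                    y = emb$coords[, 2], rho = dpc$rho, delta = dpc$delta,
                    cluster = dpc$cluster, lineage = summ$lineage),
         "landscape_embedding.tsv")
    emit(data.frame(cluster = rownames(summ$profiles), summ$profiles,
                    check.names = FALSE), "landscape_profiles.tsv")
  }

  if ("sc" %in% stages) {
    cs <- config$sc
    set.seed(seed + 400)
    pg <- sample(ann$gene_id, 2 * cs$n_program_genes)
    sim <- simulate_single_cells(
      ann, n_cells = cs$n_cells,
      program_genes_a = pg[seq_len(cs$n_program_genes)],
      program_genes_b = pg[cs$n_program_genes + seq_len(cs$n_program_genes)],
      frac_program_a = cs$frac_program_a,
      per_cell_depth = cs$per_cell_depth, seed = seed + 401)
    agg <- call_fixture_peaks(sim$fragments)
    qc <- qc_cells(sim$fragments, agg, min_fragments = cs$min_fragments)
    keep <- qc$barcode[qc$passed_qc]
    frags <- sim$fragments[sim$fragments$barcode %in% keep, ]
    binned <- bin_cells(frags, config$annotation$chrom_lengths,
                        cs$bin_width)
    lsi <- lsi_embed(binned$matrix, n_components = cs$n_components,
                     seed = seed + 402)
    um <- umap_embed(lsi$components, seed = seed + 403)
    gs <- gene_scores(binned, ann)
    imp <- impute_scores(gs, lsi$components, k = cs$k_impute,
                         t = cs$t_impute)
    disp <- normalized_dispersion(imp, n_bins = cs$n_bins)
    prog <- program_correlation(imp, pg, seed = seed + 404)
    emit(qc, "sc_qc.tsv")
    emit(data.frame(barcode = rownames(um), umap1 = um[, 1],
                    umap2 = um[, 2]), "sc_umap.tsv")
    emit(disp, "sc_dispersion.tsv")
    emit(data.frame(gene_id = names(prog$groups), group = prog$groups,
                    high_cell_fraction = prog$high_cell_fraction),
         "sc_programs.tsv")
  }

  manifest <- list(config = config, stages = stages,
                   outputs = basename(outputs),
                   digests = as.list(tools::md5sum(sort(outputs))))
  names(manifest$digests) <- basename(names(manifest$digests))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
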