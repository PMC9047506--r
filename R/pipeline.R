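#' Run the full simulate -> filter -> scan -> annotate -> DE -> integrate
#' pipeline on a synthetic experiment
#'
#' Generates a truth-known F2 bulked-segregant experiment from `config`,
#' then runs every analysis stage: chi-square segregation test on the F2
#' phenotypes, SNP-index filtering, delta(SNP index) scan with the
#' simulated null band, candidate-region merging, variant-effect
#' annotation of candidate sites, negative-binomial differential
#' expression with the three-contrast intersection, and the BSA x BSR
#' candidate-gene integration. All randomness derives from
#' `config$rng_seed`, so runs are byte-identical for identical inputs.
#'
#' @param config a [sim_config()].
#' @param high_parent parent whose allele defines the SNP index.
#' @param n_reps,level null-band replicates and level.
#' @param min_depth,low_index filter thresholds.
#' @param merge_gap,min_sites region-merging parameters.
#' @param alpha,lfc_threshold DEG thresholds.
#' @param de_lfc log2 fold change applied to the causal gene in the BY
#'   group (negative = down in the sterile bulk).
#' @param n_extra_de number of additional random DE genes.
#' @param expr_overrides named list overriding [expression_spec()]
#'   arguments (e.g. `dispersion`).
#' @param out_dir optional directory; when given, stage outputs (FASTA,
#'   GFF3, VCF, TSVs, BED, report) are written there.
#' @return A `bulkscan_report` list with every stage's result and the
#'   simulation truth.
#' @export
run_pipeline <- function(config,
                         high_parent = "AYP1",
                         n_reps = 1000, level = 0.95,
                         min_depth = 7, low_index = 0.3,
                         merge_gap = 1e6, min_sites = 3,
                         alpha = 0.05, lfc_threshold = 1,
                         de_lfc = -3, n_extra_de = 20,
                         expr_overrides = list(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome <- simulate_genome_and_genes(config)
  population <- simulate_f2_population(config)

  phenos <- vapply(population, `[[`, "", "phenotype")
  segregation <- chi_square_segregation(sum(phenos == "fertile"),
                                        sum(phenos == "sterile"))

  sites <- select_and_sequence_bulks(population, config, genome$snps)
  records <- snp_index_table(sites, high_parent = high_parent)
  filt <- apply_filters(records, min_depth = min_depth, low_index = low_index)
  scan <- bsa_scan(filt$retained, n_bulk = config$n_bulk,
                   n_reps = n_reps, level = level,
                   seed = seed_child(config$rng_seed, "nullband"))
  regions <- call_candidates_and_merge(scan, merge_gap = merge_gap,
                                       min_sites = min_sites)

  cand_sites <- as.data.frame(scan)[scan$is_candidate,
                                    c("chrom", "pos", "ref", "alt"),
                                    drop = FALSE]
  effects <- classify_variant_effects(cand_sites, genome$genes,
                                      genome$sequences)
  bsa_genes <- genes_in_regions(effects, regions)

  # Expression: the causal gene plus extra random DE genes perturbed in BY.
  gene_ids <- genome$genes$genes$gene_id
  extra_pool <- setdiff(gene_ids, genome$truth$causal_gene)
  extra <- with_seed(seed_child(config$rng_seed, "despec"), {
    n <- min(n_extra_de, length(extra_pool))
    list(genes = sample(extra_pool, n),
         lfc = sample(c(-3, -2, 2, 3), n, replace = TRUE))
  })
  spec_args <- c(list(gene_ids = gene_ids,
                      de_genes = c(genome$truth$causal_gene, extra$genes),
                      lfc = c(de_lfc, extra$lfc)),
                 expr_overrides)
  spec <- do.call(expression_spec, spec_args)
  counts <- simulate_expression_counts(spec, seed = config$rng_seed)

  contrasts <- c(KY = "KY", AYP1 = "AYP1", XAP1 = "XAP1")
  de_results <- lapply(contrasts, function(g)
    nb_test_contrast(counts, group_b = g))
  names(de_results) <- paste0("BY_vs_", names(contrasts))
  degs <- call_and_intersect_degs(de_results, alpha = alpha,
                                  lfc = lfc_threshold)

  cds <- genome$genes$cds
  tx_len <- tapply(cds$end - cds$start + 1L, cds$gene_id, sum)
  fpkm <- compute_fpkm(counts, tx_len[gene_ids])
  grp <- attr(counts, "groups")
  expr_summary <- vapply(SAMPLES, function(g)
    rowMeans(fpkm[, grp == g, drop = FALSE]), numeric(nrow(fpkm)))

  final <- integrate_bsa_bsr(bsa_genes, degs$shared_up, degs$shared_down,
                             expression_summary = expr_summary)

  report <- structure(list(
    config = config, segregation = segregation,
    n_snps = nrow(sites), filter_tally = filt$tally,
    scan = scan, regions = regions, effects = effects,
    bsa_genes = bsa_genes, degs = degs, expression_spec = spec,
    candidate_genes = final, truth = c(genome$truth,
                                       list(de_genes = spec$de_genes,
                                            de_lfc = spec$lfc))
  ), class = "bulkscan_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_reference_fasta(genome$sequences, file.path(out_dir, "reference.fa"))
    write_gene_models_gff3(genome$genes, file.path(out_dir, "genes.gff3"))
    write_snp_vcf(sites, file.path(out_dir, "variants.vcf"))
    write_counts_tsv(counts, file.path(out_dir, "counts.tsv"))
    scan_df <- as.data.frame(scan)[, c("chrom", "pos", "delta", "ci_low",
                                       "ci_high", "is_candidate")]
    write.table(scan_df, file.path(out_dir, "scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(regions)) write_regions_bed(regions, file.path(out_dir, "regions.bed"))
    writeLines(format_report(report), file.path(out_dir, "report.txt"))
    truth_df <- data.frame(key = c("causal_gene", "causal_chrom", "causal_pos"),
                           value = c(genome$truth$causal_gene,
                                     genome$truth$causal_chrom,
                                     genome$truth$causal_pos))
    write.table(truth_df, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  report
}

#' Format a pipeline report as text
#'
#' A deterministic, human-readable summary mirroring the candidate-gene
#' table shape: gene, position span, variant effect, DE direction,
#' per-group mean expression.
#'
#' @param report a `bulkscan_report` from [run_pipeline()].
#' @return Character vector of lines.
#' @export
format_report <- function(report) {
  seg <- report$segregation
  lines <- c(
    "== bulked segregant analysis report ==",
    sprintf("seed: %d", report$config$rng_seed),
    sprintf("segregation: %d fertile / %d sterile; chi2 = %.4f (critical %.3f) -> %s",
            seg$n_fertile, seg$n_sterile, seg$chi2, seg$critical,
            if (seg$consistent) "consistent with 3:1" else "NOT consistent with 3:1"),
    sprintf("snps simulated: %d; retained after filters: %d",
            report$n_snps, report$filter_tally[["retained"]]),
    sprintf("rejections: %s",
            paste(sprintf("%s=%d",
                          setdiff(names(report$filter_tally), "retained"),
                          report$filter_tally[setdiff(names(report$filter_tally),
                                                      "retained")]),
                  collapse = ", ")),
    sprintf("candidate sites outside the %.0f%% band: %d",
            100 * attr(report$scan, "level"), sum(report$scan$is_candidate)),
    sprintf("candidate regions: %d", nrow(report$regions)))
  for (i in seq_len(nrow(report$regions)))
    lines <- c(lines, sprintf("  region %d: %s:%d-%d (%d sites)", i,
                              report$regions$chrom[i], report$regions$start[i],
                              report$regions$end[i], report$regions$n_sites[i]))
  pc <- report$degs$per_contrast
  lines <- c(lines,
    sprintf("DEGs per contrast: %s",
            paste(sprintf("%s up=%d down=%d", colnames(pc), pc["up", ],
                          pc["down", ]), collapse = "; ")),
    sprintf("shared DEGs: up=%d down=%d", length(report$degs$shared_up),
            length(report$degs$shared_down)),
    sprintf("candidate genes (region + consequential variant + shared DEG): %d",
            nrow(report$candidate_genes)))
  cg <- report$candidate_genes
  for (i in seq_len(nrow(cg))) {
    expr_cols <- grep("^expr_", names(cg), value = TRUE)
    expr <- paste(sprintf("%s=%.2f", sub("^expr_", "", expr_cols),
                          unlist(cg[i, expr_cols])), collapse = " ")
    lines <- c(lines, sprintf("  %s %s:%d-%d %s %s %s", cg$gene_id[i],
                              cg$chrom[i], cg$start[i], cg$end[i],
                              cg$worst_effect[i], cg$direction[i], expr))
  }
  lines
}

#' @export
print.bulkscan_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}
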