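test_that("SNP placement follows the requested density, including the degenerate case", {
  cfg <- small_config(snp_density = 1e-3, rng_seed = 7L)
  g <- simulate_genome_and_genes(cfg)
  n <- nrow(g$snps)
  # ~Poisson(1000): 5 sigma band
  expect_gt(n, 1000 - 5 * sqrt(1000))
  expect_lt(n, 1000 + 5 * sqrt(1000))
  expect_true(any(g$snps$causal))
  expect_equal(g$snps$pos[g$snps$causal], cfg$causal_pos)

  cfg0 <- small_config(snp_density = 0)
  g0 <- simulate_genome_and_genes(cfg0)
  expect_equal(nrow(g0$snps), 1L)
  expect_true(g0$snps$causal)
})

test_that("every generated gene has a clean, translatable CDS and genes do not overlap", {
  cfg <- small_config(genes_per_mb = 15, rng_seed = 3L)
  g <- simulate_genome_and_genes(cfg)
  seqs <- as.character(g$sequences)
  for (gid in g$genes$genes$gene_id) {
    gene <- g$genes$genes[g$genes$genes$gene_id == gid, ]
    cds_segs <- g$genes$cds[g$genes$cds$gene_id == gid, ]
    cds <- oracle_splice(seqs[[gene$chrom]], cds_segs, gene$strand)
    expect_equal(nchar(cds) %% 3, 0)
    prot <- oracle_translate(cds)
    expect_equal(substr(prot, 1, 1), "M")
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("*", substr(prot, 1, nchar(prot) - 1), fixed = TRUE))
  }
  gd <- g$genes$genes
  for (ch in unique(gd$chrom)) {
    d <- gd[gd$chrom == ch, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
  # reference bases at SNP positions match the recorded ref allele
  expect_true(all(substring(seqs[g$snps$chrom], g$snps$pos, g$snps$pos) == g$snps$ref))
})

test_that("F2 phenotypes segregate 3:1 and the recessive rule is exact", {
  cfg <- small_config(rng_seed = 1L)
  frac <- vapply(1:1000, function(s) {
    pop <- simulate_f2_population(small_config(rng_seed = s))
    mean(vapply(pop, `[[`, "", "phenotype") == "sterile")
  }, numeric(1))
  se <- sqrt(0.25 * 0.75 / (1000 * 200))
  expect_lt(abs(mean(frac) - 0.25), 3 * se)

  pop <- simulate_f2_population(cfg)
  for (ind in pop[1:50]) {
    pair <- ind$chromosomes[[cfg$causal_chrom]]
    homo <- all(vapply(pair, function(g) {
      idx <- findInterval(cfg$causal_pos, g$breaks)
      ori <- if (idx %% 2 == 0) g$first else setdiff(c("XAP1", "AYP1"), g$first)
      ori == cfg$causal_origin
    }, logical(1)))
    expect_equal(ind$phenotype == "sterile", homo)
  }
})

test_that("zero recombination gives single-origin chromosome copies", {
  cfg <- small_config(recomb_rate = 0, rng_seed = 9L)
  pop <- simulate_f2_population(cfg)
  breaks <- unlist(lapply(pop, function(ind)
    lapply(ind$chromosomes, function(pair) c(pair[[1]]$breaks, pair[[2]]$breaks))))
  expect_equal(length(breaks), 0L)
})

test_that("bulk sequencing has the expected allele frequencies at, near and away from the causal locus", {
  cfg <- sim_config(chromosome_lengths = c(chrA = 1e6, chrB = 1e6),
                    snp_density = 1e-4, causal_chrom = "chrA",
                    causal_pos = 5e5, seq_error = 0, rng_seed = 5L)
  g <- simulate_genome_and_genes(cfg)
  pop <- simulate_f2_population(cfg)
  sites <- select_and_sequence_bulks(pop, cfg, g$snps)

  # parents strictly homozygous when seq_error = 0
  for (p in c("XAP1", "AYP1")) {
    minor <- pmin(sites[[paste0(p, "_ref")]], sites[[paste0(p, "_alt")]])
    expect_true(all(minor == 0))
  }
  # causal SNP: all BY plants are homozygous for the sterile allele
  cs <- sites[g$snps$causal, ]
  expect_equal(cs$BY_alt / (cs$BY_ref + cs$BY_alt), 1.0)

  # KY bulk at the causal SNP: expected frequency 1/3; unlinked chromosome:
  # 0.5. Averaged over replicate experiments.
  ky_f <- unlinked_f <- numeric(20)
  for (s in 1:20) {
    cfg_s <- sim_config(chromosome_lengths = c(chrA = 1e6, chrB = 1e6),
                        snp_density = 1e-4, causal_chrom = "chrA",
                        causal_pos = 5e5, seq_error = 0, rng_seed = s)
    g_s <- simulate_genome_and_genes(cfg_s)
    pop_s <- simulate_f2_population(cfg_s)
    st <- select_and_sequence_bulks(pop_s, cfg_s, g_s$snps)
    cs <- st[g_s$snps$causal, ]
    ky_f[s] <- cs$KY_alt / (cs$KY_ref + cs$KY_alt)
    unl <- st[st$chrom == "chrB", ]
    alt_par_frac <- ifelse(unl$alt_parent == cfg_s$causal_origin,
                           unl$BY_alt / (unl$BY_ref + unl$BY_alt),
                           unl$BY_ref / (unl$BY_ref + unl$BY_alt))
    unlinked_f[s] <- mean(alt_par_frac, na.rm = TRUE)
  }
  expect_lt(abs(mean(ky_f) - 1 / 3), 0.06)
  expect_lt(abs(mean(unlinked_f) - 0.5), 0.05)
})

test_that("bulk selection fails loudly when too few sterile plants exist", {
  cfg <- small_config(n_f2 = 60, n_bulk = 30, rng_seed = 2L)
  g <- simulate_genome_and_genes(cfg)
  pop <- simulate_f2_population(cfg)
  expect_error(select_and_sequence_bulks(pop, cfg, g$snps), "sterile")
})

test_that("expression counts follow the NB group-multiplier model", {
  genes <- sprintf("g%04d", 1:1500)
  de <- genes[1:300]
  spec <- expression_spec(genes, de_genes = de, lfc = rep(2, 300),
                          dispersion = 0.05, baseline_meanlog = 5)
  counts <- simulate_expression_counts(spec, seed = 21L)
  grp <- attr(counts, "groups")
  base <- attr(counts, "baseline")
  by_mean <- rowMeans(counts[, grp == "BY"])
  ky_mean <- rowMeans(counts[, grp == "KY"])
  # lfc +2 multiplies the BY mean by 4; null genes are unchanged
  expect_lt(abs(mean(by_mean[de] / base[de]) - 4), 0.25)
  expect_lt(abs(mean(by_mean[setdiff(genes, de)] / base[setdiff(genes, de)]) - 1), 0.1)
  expect_lt(abs(mean(ky_mean / base) - 1), 0.1)

  # dispersion -> 0 approaches Poisson (variance ~ mean)
  spec_p <- expression_spec(genes, dispersion = 1e-8, baseline_meanlog = 4)
  cp <- simulate_expression_counts(spec_p, seed = 22L)
  g12 <- cp[, attr(cp, "groups") == "KY"]
  ratio <- apply(g12, 1, var) / pmax(rowMeans(g12), 1)
  expect_lt(abs(mean(ratio) - 1), 0.1)

  # lfc = +2 at baseline 100 -> BY mean 400
  spec1 <- expression_spec(c("a", "b"), de_genes = "a", lfc = 2,
                           dispersion = 1e-8, n_reps = 200,
                           baseline_meanlog = log(100), baseline_sdlog = 1e-9)
  c1 <- simulate_expression_counts(spec1, seed = 1L)
  expect_lt(abs(mean(c1["a", attr(c1, "groups") == "BY"]) - 400), 10)
  expect_lt(abs(mean(c1["b", attr(c1, "groups") == "BY"]) - 100), 5)
})

test_that("identical seeds give byte-identical simulator output, down to the VCF", {
  cfg <- small_config(rng_seed = 33L)
  run <- function() {
    g <- simulate_genome_and_genes(cfg)
    pop <- simulate_f2_population(cfg)
    sites <- select_and_sequence_bulks(pop, cfg, g$snps)
    list(g = g, sites = sites)
  }
  a <- run(); b <- run()
  expect_identical(as.character(a$g$sequences), as.character(b$g$sequences))
  expect_identical(a$g$snps, b$g$snps)
  expect_identical(a$sites, b$sites)
  fa <- tempfile(fileext = ".vcf"); fb <- tempfile(fileext = ".vcf")
  write_snp_vcf(a$sites, fa); write_snp_vcf(b$sites, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("a configuration survives the key=value file roundtrip", {
  cfg <- sim_config(chromosome_lengths = c(chr1 = 2e6, chr2 = 1e6),
                    snp_density = 3e-4, causal_chrom = "chr2",
                    causal_pos = 4e5, causal_origin = "XAP1",
                    seq_error = 0.002, rng_seed = 99L)
  path <- tempfile(fileext = ".cfg")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back, cfg)
})
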