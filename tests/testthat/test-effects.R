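# A hand-built toy locus: 10 bp of flank, then a single-exon gene whose
# CDS is ATG GCT TAT TGG TAA, then 10 bp of flank. Every codon-table case
# is exercised at a known coordinate.
toy_models <- function(strand = "+") {
  cds <- "ATGGCTTATTGGTAA"
  gene_seq <- paste0("AAAAA", cds, "CCCCC")  # 5 bp UTRs
  flank <- "GGGGGGGGGG"
  chrom_seq <- if (strand == "+") paste0(flank, gene_seq, flank)
    else paste0(flank, oracle_revcomp(gene_seq), flank)
  gstart <- 11L; gend <- gstart + nchar(gene_seq) - 1L
  cds_iv <- if (strand == "+") c(gstart + 5L, gstart + 19L)
    else c(gend - 19L, gend - 5L)
  list(seq = setNames(chrom_seq, "chrT"),
       genes = list(
         genes = data.frame(gene_id = "T1", chrom = "chrT", strand = strand,
                            start = gstart, end = gend, stringsAsFactors = FALSE),
         exons = data.frame(gene_id = "T1", chrom = "chrT",
                            start = gstart, end = gend, stringsAsFactors = FALSE),
         cds = data.frame(gene_id = "T1", chrom = "chrT",
                          start = cds_iv[1], end = cds_iv[2],
                          stringsAsFactors = FALSE)))
}

test_that("codon-level classification covers all coding categories on the plus strand", {
  m <- toy_models("+")
  cds_start <- m$genes$cds$start
  sites <- data.frame(
    chrom = "chrT",
    pos = cds_start + c(2L, 5L, 8L, 11L, 14L),
    ref = c("G", "T", "T", "G", "A"),
    alt = c("A", "C", "A", "A", "C"),
    stringsAsFactors = FALSE)
  # ATG->ATA (M->I), GCT->GCC (A->A), TAT->TAA (Y->*), TGG->TAG (W->*),
  # TAA->TAC (*->Y)
  eff <- classify_variant_effects(sites, m$genes, m$seq)
  expect_equal(eff$category,
               c("nonsynonymous", "synonymous", "stopgain", "stopgain", "stoploss"))
  expect_equal(eff$ref_aa, c("M", "A", "Y", "W", "*"))
  expect_equal(eff$alt_aa, c("I", "A", "*", "*", "Y"))
  expect_equal(eff$gene_id, rep("T1", 5))
})

test_that("the same biology classifies identically on the minus strand", {
  m <- toy_models("-")
  # genomic coordinates mirror; alleles are complements of the plus case
  cds_end <- m$genes$cds$end
  sites <- data.frame(
    chrom = "chrT",
    pos = cds_end - c(2L, 5L, 8L, 11L, 14L),
    ref = c("C", "A", "A", "C", "T"),
    alt = c("T", "G", "T", "T", "G"),
    stringsAsFactors = FALSE)
  eff <- classify_variant_effects(sites, m$genes, m$seq)
  expect_equal(eff$category,
               c("nonsynonymous", "synonymous", "stopgain", "stopgain", "stoploss"))
})

test_that("non-coding categories are assigned by position and classification is total", {
  m <- toy_models("+")
  g <- m$genes$genes
  sites <- data.frame(chrom = "chrT",
                      pos = c(1L, g$start + 1L, g$end - 1L),
                      ref = c("G", "A", "C"), alt = c("T", "G", "A"),
                      stringsAsFactors = FALSE)
  eff <- classify_variant_effects(sites, m$genes, m$seq)
  expect_equal(eff$category, c("intergenic", "utr", "utr"))
  expect_true(all(!is.na(eff$category)))

  # a two-exon gene gives intronic sites, including the splice dinucleotides
  cfg <- small_config(genes_per_mb = 20, snp_density = 0, rng_seed = 31L)
  gg <- simulate_genome_and_genes(cfg)
  multi <- names(which(table(gg$genes$cds$gene_id) > 1))[1]
  cd <- gg$genes$cds[gg$genes$cds$gene_id == multi, ]
  cd <- cd[order(cd$start), ]
  intron_pos <- cd$end[1] + 1L  # first base of the intron
  seqs <- as.character(gg$sequences)
  ref <- substring(seqs[[cd$chrom[1]]], intron_pos, intron_pos)
  s <- data.frame(chrom = cd$chrom[1], pos = intron_pos, ref = ref,
                  alt = setdiff(c("A", "C", "G", "T"), ref)[1],
                  stringsAsFactors = FALSE)
  expect_equal(classify_variant_effects(s, gg$genes, gg$sequences)$category,
               "intronic")
})

test_that("mismatched reference bases and broken CDS lengths are hard errors", {
  m <- toy_models("+")
  bad <- data.frame(chrom = "chrT", pos = 1L, ref = "T", alt = "A",
                    stringsAsFactors = FALSE)
  expect_error(classify_variant_effects(bad, m$genes, m$seq), "mismatch")
  m2 <- m
  m2$genes$cds$end <- m2$genes$cds$end - 1L
  s <- data.frame(chrom = "chrT", pos = m$genes$cds$start, ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  expect_error(classify_variant_effects(s, m2$genes, m$seq), "divisible")
})

test_that("codon-local calls agree with full-protein retranslation on simulated genomes", {
  cfg <- small_config(genes_per_mb = 25, snp_density = 3e-3, rng_seed = 17L)
  g <- simulate_genome_and_genes(cfg)
  eff <- classify_variant_effects(g$snps, g$genes, g$sequences)
  coding <- eff[eff$category %in% c("synonymous", "nonsynonymous",
                                    "stopgain", "stoploss"), ]
  expect_gt(nrow(coding), 20)
  seqs <- as.character(g$sequences)
  for (i in seq_len(nrow(coding))) {
    gid <- coding$gene_id[i]
    gene <- g$genes$genes[g$genes$genes$gene_id == gid, ]
    cds_segs <- g$genes$cds[g$genes$cds$gene_id == gid, ]
    oracle <- oracle_classify_coding(seqs[[coding$chrom[i]]], coding$pos[i],
                                     coding$alt[i], cds_segs, gene$strand)
    expect_equal(coding$category[i], oracle,
                 info = sprintf("%s:%d in %s", coding$chrom[i], coding$pos[i], gid))
  }
})

test_that("reverse-complementing the genome leaves every category unchanged", {
  cfg <- small_config(genes_per_mb = 20, snp_density = 5e-4, rng_seed = 23L)
  g <- simulate_genome_and_genes(cfg)
  eff <- classify_variant_effects(g$snps, g$genes, g$sequences)

  len <- nchar(as.character(g$sequences)[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip_iv <- function(d) {
    new_start <- len - d$end + 1L
    d$end <- len - d$start + 1L
    d$start <- new_start
    d
  }
  rc_genes <- list(genes = flip_iv(g$genes$genes),
                   exons = flip_iv(g$genes$exons),
                   cds = flip_iv(g$genes$cds))
  rc_genes$genes$strand <- ifelse(g$genes$genes$strand == "+", "-", "+")
  rc_seq <- setNames(oracle_revcomp(as.character(g$sequences)[[1]]),
                     names(g$sequences))
  rc_snps <- g$snps
  rc_snps$pos <- len - g$snps$pos + 1L
  rc_snps$ref <- unname(comp[g$snps$ref])
  rc_snps$alt <- unname(comp[g$snps$alt])
  eff_rc <- classify_variant_effects(rc_snps, rc_genes, rc_seq)
  expect_equal(eff_rc$category, eff$category)
  expect_equal(eff_rc$ref_aa, eff$ref_aa)
  expect_equal(eff_rc$alt_aa, eff$alt_aa)
})

test_that("region gating keeps consequential sites and groups them by gene", {
  effects <- data.frame(
    chrom = "chr1", pos = c(100, 150, 200, 250, 5000),
    ref = "A", alt = "T",
    gene_id = c("G1", "G1", "G1", NA, "G2"),
    category = c("synonymous", "nonsynonymous", "nonsynonymous",
                 "intergenic", "nonsynonymous"),
    stringsAsFactors = FALSE)
  regions <- data.frame(chrom = "chr1", start = 50, end = 300)
  out <- genes_in_regions(effects, regions)
  expect_equal(out$gene_id, "G1")
  expect_equal(out$n_sites, 2L)
  expect_equal(attr(out, "n_sites_kept"), 2L)
  # nonsynonymous site outside every region is excluded (G2 at 5000)
  expect_false("G2" %in% out$gene_id)
  # severity ranking
  effects$category[2] <- "stopgain"
  expect_equal(genes_in_regions(effects, regions)$worst_effect, "stopgain")
})
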