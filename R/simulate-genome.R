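BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

# Wildtype codon engineered at the causal position, by offset of the causal
# base within its codon, so that a single substitution creates a stop codon
# (stop-gain): CAA->TAA, TGG->TAG, TAT->TAA.
CAUSAL_CODON_TABLE <- list(
  `0` = list(codon = "CAA", ref = "C", alt = "T"),
  `1` = list(codon = "TGG", ref = "G", alt = "A"),
  `2` = list(codon = "TAT", ref = "T", alt = "A")
)

# Build one gene in transcription orientation: 5'UTR, CDS (ATG ... stop,
# no internal stop) split across exons by GT..AG introns, 3'UTR.
# Returns local (1-based, transcription-strand) exon/CDS intervals.
build_gene <- function(n_codons, n_exons, utr5_len, utr3_len, intron_lens,
                       cds_codons = NULL) {
  stopifnot(n_codons >= 3, n_exons >= 1, length(intron_lens) == n_exons - 1)
  if (is.null(cds_codons))
    cds_codons <- c("ATG", sample(NONSTOP_CODONS, n_codons - 2, replace = TRUE),
                    sample(STOP_CODONS, 1))
  cds <- paste(cds_codons, collapse = "")
  cds_len <- nchar(cds)
  cuts <- if (n_exons > 1) sort(sample(seq_len(cds_len - 1), n_exons - 1)) else integer()
  chunk_bounds <- cbind(start = c(1L, cuts + 1L), end = c(cuts, cds_len))

  rand_bases <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
  make_intron <- function(n) {
    stopifnot(n >= 4)
    paste0("GT", rand_bases(n - 4), "AG")
  }

  pieces <- character()
  exon_iv <- cds_iv <- NULL
  cursor <- 0L
  add <- function(s) { pieces[[length(pieces) + 1L]] <<- s; cursor <<- cursor + nchar(s) }

  add(rand_bases(utr5_len))
  for (i in seq_len(n_exons)) {
    chunk <- substr(cds, chunk_bounds[i, "start"], chunk_bounds[i, "end"])
    ex_start <- if (i == 1L) 1L else cursor + 1L
    cds_iv <- rbind(cds_iv, c(cursor + 1L, cursor + nchar(chunk)))
    add(chunk)
    if (i == n_exons) add(rand_bases(utr3_len))
    exon_iv <- rbind(exon_iv, c(ex_start, cursor))
    if (i < n_exons) add(make_intron(intron_lens[i]))
  }
  list(seq = paste(pieces, collapse = ""),
       length = cursor,
       exons = exon_iv,
       cds = cds_iv,
       protein_len = n_codons)
}

# Map local (transcription-strand) intervals to genomic coordinates.
local_to_genomic <- function(iv, gene_start, gene_end, strand) {
  if (strand == "+") cbind(gene_start + iv[, 1] - 1L, gene_start + iv[, 2] - 1L)
  else cbind(gene_end - iv[, 2] + 1L, gene_end - iv[, 1] + 1L)
}

#' Simulate reference sequences, gene models and parental SNPs
#'
#' Generates a random reference genome with non-overlapping gene models
#' (ATG-initiated, stop-terminated CDS of length divisible by 3, split by
#' GT..AG introns, on both strands) and a set of parental SNPs that are
#' homozygous-different between the two parents, each labelled with the
#' parent carrying the non-reference allele. A gene is always placed over
#' the causal locus, on the forward strand, with a wildtype codon chosen so
#' that the causal SNP is a stop-gain mutation — the truth downstream
#' stages must recover.
#'
#' @param config a [sim_config()].
#' @return A list with elements `sequences` (a [Biostrings::DNAStringSet]),
#'   `genes` (list of data.frames `genes`, `exons`, `cds` in 1-based
#'   inclusive genomic coordinates), `snps` (data.frame with `chrom`, `pos`,
#'   `ref`, `alt`, `alt_parent`, `causal`), and `truth` (causal gene id and
#'   locus).
#' @export
simulate_genome_and_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed_child(config$rng_seed, "genome"), {
    seqs <- list()
    genes_df <- exons_df <- cds_df <- NULL
    snps <- NULL
    truth <- NULL

    for (chrom in names(config$chromosome_lengths)) {
      len <- as.integer(config$chromosome_lengths[[chrom]])
      chars <- sample(BASES, len, replace = TRUE)

      placed <- NULL  # matrix of occupied [start, end]
      add_gene <- function(g, gstart, strand, gid) {
        gend <- gstart + g$length - 1L
        oriented <- if (strand == "+") g$seq else revcomp_str(g$seq)
        chars[gstart:gend] <<- strsplit(oriented, "", fixed = TRUE)[[1]]
        genes_df <<- rbind(genes_df, data.frame(
          gene_id = gid, chrom = chrom, strand = strand,
          start = gstart, end = gend, protein_len = g$protein_len,
          stringsAsFactors = FALSE))
        ex <- local_to_genomic(g$exons, gstart, gend, strand)
        cd <- local_to_genomic(g$cds, gstart, gend, strand)
        exons_df <<- rbind(exons_df, data.frame(gene_id = gid, chrom = chrom,
          start = ex[, 1], end = ex[, 2], stringsAsFactors = FALSE))
        cds_df <<- rbind(cds_df, data.frame(gene_id = gid, chrom = chrom,
          start = cd[, 1], end = cd[, 2], stringsAsFactors = FALSE))
        placed <<- rbind(placed, c(gstart, gend))
      }

      gi <- 0L
      # Causal gene first: single exon, forward strand, causal base at a
      # known codon offset with an engineered stop-gain substitution.
      if (chrom == config$causal_chrom) {
        offset <- sample(0:2, 1)
        spec <- CAUSAL_CODON_TABLE[[as.character(offset)]]
        k_codon <- 40L
        n_codons <- 100L
        codons <- c("ATG", sample(NONSTOP_CODONS, n_codons - 2, replace = TRUE),
                    sample(STOP_CODONS, 1))
        codons[k_codon] <- spec$codon
        cds_start <- config$causal_pos - (3L * (k_codon - 1L) + offset)
        gstart <- cds_start - 100L
        g <- build_gene(n_codons, 1L, 100L, 100L, integer(), cds_codons = codons)
        if (gstart < 1L || gstart + g$length - 1L > len)
          stopf("chromosome '%s' too short to host a gene at causal_pos %d",
                chrom, config$causal_pos)
        gi <- gi + 1L
        gid <- sprintf("G%s_%03d", chrom, gi)
        add_gene(g, gstart, "+", gid)
        truth <- list(causal_gene = gid, causal_chrom = chrom,
                      causal_pos = config$causal_pos,
                      causal_ref = spec$ref, causal_alt = spec$alt)
      }

      n_genes <- max(0L, round(config$genes_per_mb * len / 1e6))
      if (n_genes > 0) {
        window <- floor(len / n_genes)
        if (window < 2500) stopf("chromosome '%s' too short for %d genes", chrom, n_genes)
        for (w in seq_len(n_genes)) {
          n_codons <- sample(80:300, 1)
          n_exons <- sample(1:3, 1)
          introns <- if (n_exons > 1) sample(80:200, n_exons - 1, replace = TRUE) else integer()
          g <- build_gene(n_codons, n_exons, sample(60:150, 1), sample(60:150, 1), introns)
          lo <- (w - 1L) * window + 1L
          hi <- w * window - g$length - 1L
          if (hi <= lo) next
          gstart <- sample(lo:hi, 1)
          gend <- gstart + g$length - 1L
          if (!is.null(placed) &&
              any(gstart <= placed[, 2] + 50L & gend >= placed[, 1] - 50L)) next
          gi <- gi + 1L
          add_gene(g, gstart, sample(c("+", "-"), 1),
                   sprintf("G%s_%03d", chrom, gi))
        }
      }

      # Parental SNPs: Poisson placement, homozygous-different parents.
      n_snp <- rpois(1, config$snp_density * len)
      pos <- sort(sample.int(len, min(n_snp, len)))
      if (chrom == config$causal_chrom) pos <- setdiff(pos, config$causal_pos)
      if (length(pos)) {
        ref <- chars[pos]
        alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), "")
        snps <- rbind(snps, data.frame(
          chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
          alt_parent = sample(PARENTS, length(pos), replace = TRUE),
          causal = FALSE, stringsAsFactors = FALSE))
      }
      if (chrom == config$causal_chrom) {
        stopifnot(chars[config$causal_pos] == truth$causal_ref)
        snps <- rbind(snps, data.frame(
          chrom = chrom, pos = config$causal_pos,
          ref = truth$causal_ref, alt = truth$causal_alt,
          alt_parent = config$causal_origin, causal = TRUE,
          stringsAsFactors = FALSE))
      }
      seqs[[chrom]] <- paste(chars, collapse = "")
    }

    snps <- snps[order(match(snps$chrom, names(config$chromosome_lengths)), snps$pos), ]
    rownames(snps) <- NULL
    sequences <- Biostrings::DNAStringSet(unlist(seqs))
    list(sequences = sequences,
         genes = list(genes = genes_df, exons = exons_df, cds = cds_df),
         snps = snps,
         truth = truth,
         config = config)
  })
}

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
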