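# On-disk formats. GFF3 and VCF are 1-based inclusive; internal tables are
# 1-based too, so no coordinate shifts happen here except the BED export
# (0-based half-open), which is the only place a -1 appears.

#' Write/read reference sequences as FASTA
#' @param sequences a [Biostrings::DNAStringSet].
#' @param path file path.
#' @export
write_reference_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write gene models as GFF3
#'
#' Emits gene / mRNA / exon / CDS features (one transcript per gene),
#' 1-based inclusive, via rtracklayer.
#'
#' @param genes gene-model list (`genes`, `exons`, `cds` data.frames) from
#'   [simulate_genome_and_genes()].
#' @param path output file.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  g <- genes$genes
  feats <- list(
    data.frame(chrom = g$chrom, start = g$start, end = g$end, strand = g$strand,
               type = "gene", ID = g$gene_id, Parent = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(chrom = g$chrom, start = g$start, end = g$end, strand = g$strand,
               type = "mRNA", ID = paste0(g$gene_id, ".t1"), Parent = g$gene_id,
               stringsAsFactors = FALSE)
  )
  for (ft in c("exons", "cds")) {
    d <- genes[[ft]]
    strand <- g$strand[match(d$gene_id, g$gene_id)]
    feats[[length(feats) + 1L]] <- data.frame(
      chrom = d$chrom, start = d$start, end = d$end, strand = strand,
      type = if (ft == "exons") "exon" else "CDS",
      ID = NA_character_, Parent = paste0(d$gene_id, ".t1"),
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, feats)

  # CDS phase: bases to skip before the first complete codon, accumulated
  # in transcription order within each gene.
  all$phase <- NA_integer_
  is_cds <- all$type == "CDS"
  cds <- all[is_cds, ]
  phase <- integer(nrow(cds))
  for (gid in unique(sub("\\.t1$", "", cds$Parent))) {
    rows <- which(sub("\\.t1$", "", cds$Parent) == gid)
    rows <- rows[order(cds$start[rows],
                       decreasing = g$strand[match(gid, g$gene_id)] == "-")]
    cum <- 0L
    for (r in rows) {
      phase[r] <- (3L - cum %% 3L) %% 3L
      cum <- cum + cds$end[r] - cds$start[r] + 1L
    }
  }
  all$phase[is_cds] <- phase
  gr <- GenomicRanges::GRanges(all$chrom,
                               IRanges::IRanges(all$start, all$end),
                               strand = all$strand)
  S4Vectors::mcols(gr)$type <- all$type
  S4Vectors::mcols(gr)$ID <- all$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(all$Parent, function(p) if (is.na(p)) character() else p))
  S4Vectors::mcols(gr)$phase <- all$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects gene features with ID and exon/CDS features whose Parent
#' resolves to one transcript per gene (`<gene>.t1` or the gene itself).
#'
#' @param path GFF3 file.
#' @return Gene-model list (`genes`, `exons`, `cds`).
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  parent <- vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  strip_tx <- function(x) sub("\\.t1$", "", x)
  genes <- df[df$type == "gene", ]
  genes_df <- data.frame(gene_id = genes$ID, chrom = as.character(genes$seqnames),
                         strand = as.character(genes$strand),
                         start = genes$start, end = genes$end,
                         stringsAsFactors = FALSE)
  pick <- function(type) {
    d <- df[df$type == type, ]
    data.frame(gene_id = strip_tx(parent[df$type == type]),
               chrom = as.character(d$seqnames), start = d$start, end = d$end,
               stringsAsFactors = FALSE)
  }
  list(genes = genes_df, exons = pick("exon"), cds = pick("CDS"))
}

#' Write an allelic-depth SNP table as VCF
#'
#' Minimal VCFv4.2 with GT:AD per sample, samples ordered XAP1, AYP1, BY,
#' KY. Genotypes are emitted as ./. since the pipeline works from allelic
#' depths, not calls.
#'
#' @param sites data.frame from [select_and_sequence_bulks()] (or with the
#'   same `chrom`, `pos`, `ref`, `alt` and `<SAMPLE>_ref`/`_alt` columns).
#' @param path output path.
#' @export
write_snp_vcf <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bulkscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", SAMPLES), collapse = "\t")), con)
  fmt <- vapply(SAMPLES, function(s)
    paste0("./.:", sites[[paste0(s, "_ref")]], ",", sites[[paste0(s, "_alt")]]),
    character(nrow(sites)))
  if (nrow(sites) == 1L) fmt <- matrix(fmt, nrow = 1)
  lines <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                 "PASS", ".", "GT:AD",
                 fmt[, 1], fmt[, 2], fmt[, 3], fmt[, 4], sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read per-sample allelic depths from a VCF
#'
#' Parses a VCF containing the four named samples (XAP1, AYP1, BY, KY) with
#' an AD FORMAT field. Sample columns are resolved by header name, never by
#' position. Multiallelic and non-SNP records are skipped and counted.
#'
#' @param path VCF file (plain or gzipped).
#' @return data.frame of biallelic SNP sites with `<SAMPLE>_ref`/`_alt`
#'   counts; the number of skipped records is in `attr(, "skipped")`.
#' @export
read_allelic_depths <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ok <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% BASES & fix$ALT %in% BASES & !grepl(",", fix$ALT, fixed = TRUE)
  skipped <- sum(!ok)
  if (!all(SAMPLES %in% colnames(v@gt)))
    stopf("VCF is missing required sample(s): %s",
          paste(setdiff(SAMPLES, colnames(v@gt)), collapse = ", "))
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || all(is.na(ad)))
    stopf("VCF has no AD FORMAT field")
  out <- data.frame(chrom = fix$CHROM[ok], pos = as.integer(fix$POS[ok]),
                    ref = fix$REF[ok], alt = fix$ALT[ok],
                    stringsAsFactors = FALSE)
  for (s in SAMPLES) {
    parts <- strsplit(ad[ok, s], ",", fixed = TRUE)
    bad <- vapply(parts, length, 0L) < 2L
    if (any(bad))
      stopf("record %s:%s lacks an AD value for sample %s",
            out$chrom[which(bad)[1]], out$pos[which(bad)[1]], s)
    out[[paste0(s, "_ref")]] <- as.integer(vapply(parts, `[[`, "", 1L))
    out[[paste0(s, "_alt")]] <- as.integer(vapply(parts, `[[`, "", 2L))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write a count matrix as TSV (gene id column + one column per library)
#' @param counts integer matrix from [simulate_expression_counts()].
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write candidate regions as BED (0-based half-open)
#' @param regions data.frame from [call_candidates_and_merge()].
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, regions$start - 1L, regions$end,
                   paste0("region_", seq_len(nrow(regions))), regions$n_sites)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
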