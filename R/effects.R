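# Minimal variant-effect classification against one-transcript gene
# models: intergenic / intronic / utr / synonymous / nonsynonymous /
# stopgain / stoploss. Coding effects are computed by substituting the
# alternate base into the spliced, strand-oriented CDS and translating the
# affected codon with the standard genetic code.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Spliced CDS (transcription orientation) of one gene from its CDS
# segments; segments must be sorted by genomic start.
spliced_cds <- function(cds_segs, chrom_seq, strand) {
  parts <- substring(chrom_seq, cds_segs$start, cds_segs$end)
  if (strand == "-") {
    parts <- rev(vapply(parts, revcomp_str, ""))
  }
  paste(parts, collapse = "")
}

# Position of a genomic coordinate within the spliced CDS (1-based), or NA.
cds_position <- function(pos, cds_segs, strand) {
  hit <- which(pos >= cds_segs$start & pos <= cds_segs$end)
  if (!length(hit)) return(NA_integer_)
  lens <- cds_segs$end - cds_segs$start + 1L
  if (strand == "+") {
    sum(lens[seq_len(hit - 1L)]) + (pos - cds_segs$start[hit] + 1L)
  } else {
    n <- nrow(cds_segs)
    after <- if (hit < n) sum(lens[(hit + 1L):n]) else 0L
    after + (cds_segs$end[hit] - pos + 1L)
  }
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Classify variant effects against gene models
#'
#' Each biallelic SNP gets exactly one category. Sites in the first/last
#' 2 bp of an intron are still "intronic" (splice effects are not
#' modelled); exonic sites outside the CDS are "utr". For CDS sites the
#' alternate base is substituted into the spliced, strand-oriented CDS
#' (minus-strand alleles are complemented) and the affected codon is
#' translated with the standard genetic code.
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param genes gene-model list (`genes`, `exons`, `cds`).
#' @param sequences reference [Biostrings::DNAStringSet] (or named
#'   character vector).
#' @return data.frame: the sites plus `gene_id`, `category`, `ref_aa`,
#'   `alt_aa`, `cds_pos`.
#' @export
classify_variant_effects <- function(sites, genes, sequences) {
  seqs <- if (is.character(sequences)) sequences else as.character(sequences)
  g <- genes$genes
  n <- nrow(sites)
  gene_id <- rep(NA_character_, n)
  category <- rep("intergenic", n)
  ref_aa <- alt_aa <- rep(NA_character_, n)
  cds_pos_out <- rep(NA_integer_, n)

  cds_cache <- new.env(parent = emptyenv())

  for (i in seq_len(n)) {
    chrom <- sites$chrom[i]; pos <- sites$pos[i]
    chrom_seq <- seqs[[chrom]]
    if (substring(chrom_seq, pos, pos) != sites$ref[i])
      stopf("reference mismatch at %s:%d (genome %s, site ref %s)",
            chrom, pos, substring(chrom_seq, pos, pos), sites$ref[i])
    hit <- which(g$chrom == chrom & g$start <= pos & g$end >= pos)
    if (!length(hit)) next
    gid <- g$gene_id[hit[1]]
    strand <- g$strand[hit[1]]
    gene_id[i] <- gid

    ex <- genes$exons[genes$exons$gene_id == gid, , drop = FALSE]
    in_exon <- any(pos >= ex$start & pos <= ex$end)
    if (!in_exon) { category[i] <- "intronic"; next }

    cd <- genes$cds[genes$cds$gene_id == gid, , drop = FALSE]
    cd <- cd[order(cd$start), , drop = FALSE]
    cp <- cds_position(pos, cd, strand)
    if (is.na(cp)) { category[i] <- "utr"; next }

    if (is.null(cds_cache[[gid]]))
      cds_cache[[gid]] <- spliced_cds(cd, chrom_seq, strand)
    cds <- cds_cache[[gid]]
    if (nchar(cds) %% 3L != 0L)
      stopf("CDS length of gene %s is not divisible by 3", gid)

    tx_ref <- if (strand == "+") sites$ref[i] else COMPLEMENT[[sites$ref[i]]]
    tx_alt <- if (strand == "+") sites$alt[i] else COMPLEMENT[[sites$alt[i]]]
    if (substring(cds, cp, cp) != tx_ref)
      stopf("internal inconsistency: CDS base at %s:%d does not match ref", chrom, pos)

    codon_i <- (cp - 1L) %/% 3L
    within <- (cp - 1L) %% 3L
    codon <- substring(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
    alt_codon <- codon
    substr(alt_codon, within + 1L, within + 1L) <- tx_alt

    ra <- translate_codon(codon)
    aa <- translate_codon(alt_codon)
    ref_aa[i] <- ra; alt_aa[i] <- aa
    cds_pos_out[i] <- cp
    category[i] <- if (ra == aa) "synonymous"
      else if (aa == "*" && ra != "*") "stopgain"
      else if (ra == "*" && aa != "*") "stoploss"
      else "nonsynonymous"
  }
  cbind(sites,
        data.frame(gene_id = gene_id, category = category,
                   ref_aa = ref_aa, alt_aa = alt_aa, cds_pos = cds_pos_out,
                   stringsAsFactors = FALSE))
}

#' Candidate genes: consequential variants inside candidate regions
#'
#' Keeps sites lying inside a candidate region whose effect category is in
#' `keep` (by default the consequential classes: nonsynonymous, stopgain,
#' stoploss), groups them by gene, and returns genes sorted by chromosome
#' and position.
#'
#' @param effects output of [classify_variant_effects()].
#' @param regions data.frame from [call_candidates_and_merge()].
#' @param keep effect categories to retain.
#' @return data.frame: `gene_id`, `chrom`, `start`, `end` (span of the
#'   gene's surviving sites), `n_sites`, `categories`, `worst_effect`;
#'   the total surviving-site count is in `attr(, "n_sites_kept")`.
#' @export
genes_in_regions <- function(effects, regions,
                             keep = c("nonsynonymous", "stopgain", "stoploss")) {
  in_region <- rep(FALSE, nrow(effects))
  for (r in seq_len(nrow(regions))) {
    in_region <- in_region |
      (effects$chrom == regions$chrom[r] &
       effects$pos >= regions$start[r] & effects$pos <= regions$end[r])
  }
  kept <- effects[in_region & effects$category %in% keep &
                  !is.na(effects$gene_id), , drop = FALSE]
  if (nrow(kept) == 0) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_sites = integer(),
                      categories = character(), worst_effect = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_sites_kept") <- 0L
    return(out)
  }
  severity <- c(stopgain = 3, stoploss = 2, nonsynonymous = 1)
  rows <- lapply(split(kept, kept$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$pos), end = max(d$pos), n_sites = nrow(d),
               categories = paste(sort(unique(d$category)), collapse = ","),
               worst_effect = names(which.max(severity[unique(d$category)])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sites_kept") <- nrow(kept)
  out
}
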