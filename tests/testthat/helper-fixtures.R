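# Fixture builders: tiny configs and hand-built allelic-depth records.

small_config <- function(...) {
  args <- list(chromosome_lengths = c(chrA = 1e6), snp_density = 2e-4,
               recomb_rate = 3, causal_pos = 5e5, n_f2 = 200, n_bulk = 30,
               rng_seed = 42L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# One allelic-depth site row with the full sample-column layout.
make_site <- function(chrom = "chrA", pos = 100, ref = "A", alt = "T",
                      xap1 = c(10, 0), ayp1 = c(0, 10),
                      by = c(5, 5), ky = c(5, 5)) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             XAP1_ref = xap1[1], XAP1_alt = xap1[2],
             AYP1_ref = ayp1[1], AYP1_alt = ayp1[2],
             BY_ref = by[1], BY_alt = by[2],
             KY_ref = ky[1], KY_alt = ky[2],
             stringsAsFactors = FALSE)
}

# Hand-written VCF text for parser tests.
vcf_header <- function(samples = c("XAP1", "AYP1", "BY", "KY")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
write_vcf_lines <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}
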