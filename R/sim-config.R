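#' Configuration for a synthetic F2 bulked-segregant experiment
#'
#' Bundles every parameter of the simulated study design: genome shape,
#' SNP density, recombination rate, the single recessive sterility locus,
#' F2 population and bulk sizes, and sequencing depths/error. Defaults
#' emulate the study design the pipeline targets: an F2 of 200 plants
#' segregating 3:1 for one fully penetrant recessive locus, extreme bulks
#' of 30 fertile (KY) and 30 sterile (BY) plants, parents at ~10x and
#' bulks at ~30x mean depth.
#'
#' @param chromosome_lengths named numeric vector, bp per chromosome.
#' @param snp_density expected parent-informative SNPs per bp (Poisson).
#' @param recomb_rate recombination rate in cM/Mb (Haldane, no interference).
#' @param causal_chrom,causal_pos location of the recessive sterility locus.
#' @param causal_origin which parent ("XAP1" or "AYP1") carries the recessive
#'   sterile allele. The source study does not identify this parent; it is a
#'   free parameter.
#' @param n_f2 F2 population size.
#' @param n_bulk plants per phenotype-selected bulk.
#' @param parent_depth,bulk_depth mean sequencing depth (Poisson) for parent
#'   and bulk libraries.
#' @param seq_error per-read allele miscall probability, in [0, 0.5).
#' @param genes_per_mb gene models generated per Mb of reference.
#' @param phenotype_error probability a plant's phenotype is misrecorded
#'   (bulk contamination); 0 = full penetrance, the default.
#' @param rng_seed integer seed governing all stages.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(chromosome_lengths = c(chr1 = 1e6), snp_density = 1e-4)
#' cfg
#' @export
sim_config <- function(chromosome_lengths = c(chr07 = 5e6),
                       snp_density = 4e-4,
                       recomb_rate = 3,
                       causal_chrom = names(chromosome_lengths)[1],
                       causal_pos = floor(chromosome_lengths[[1]] / 2),
                       causal_origin = "AYP1",
                       n_f2 = 200,
                       n_bulk = 30,
                       parent_depth = 10,
                       bulk_depth = 30,
                       seq_error = 0.001,
                       genes_per_mb = 10,
                       phenotype_error = 0,
                       rng_seed = 1L) {
  if (is.null(names(chromosome_lengths)) || any(!nzchar(names(chromosome_lengths))))
    stopf("'chromosome_lengths' must be a named vector")
  check_positive(chromosome_lengths, "chromosome_lengths")
  if (snp_density < 0) stopf("'snp_density' must be non-negative")
  if (recomb_rate < 0) stopf("'recomb_rate' must be non-negative")
  check_positive(c(n_f2, n_bulk, parent_depth, bulk_depth), "sizes and depths")
  if (!causal_chrom %in% names(chromosome_lengths))
    stopf("causal_chrom '%s' is not a simulated chromosome", causal_chrom)
  if (causal_pos < 1 || causal_pos > chromosome_lengths[[causal_chrom]])
    stopf("causal_pos %d outside chromosome '%s'", causal_pos, causal_chrom)
  if (seq_error < 0 || seq_error >= 0.5) stopf("'seq_error' must be in [0, 0.5)")
  if (!causal_origin %in% PARENTS) stopf("'causal_origin' must be one of %s", paste(PARENTS, collapse = ", "))
  if (phenotype_error < 0 || phenotype_error >= 0.5) stopf("'phenotype_error' must be in [0, 0.5)")
  if (2 * n_bulk > n_f2) stopf("two bulks of %d cannot be drawn from an F2 of %d", n_bulk, n_f2)

  structure(list(
    chromosome_lengths = chromosome_lengths,
    snp_density = snp_density,
    recomb_rate = recomb_rate,
    causal_chrom = causal_chrom,
    causal_pos = as.integer(causal_pos),
    causal_origin = causal_origin,
    n_f2 = as.integer(n_f2),
    n_bulk = as.integer(n_bulk),
    parent_depth = parent_depth,
    bulk_depth = bulk_depth,
    seq_error = seq_error,
    genes_per_mb = genes_per_mb,
    phenotype_error = phenotype_error,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic F2 bulked-segregant design\n")
  cat(sprintf("  genome: %d chromosome(s), %.3g Mb total, %.3g SNPs/Mb\n",
              length(x$chromosome_lengths), sum(x$chromosome_lengths) / 1e6,
              x$snp_density * 1e6))
  cat(sprintf("  causal locus: %s:%d (recessive allele from %s)\n",
              x$causal_chrom, x$causal_pos, x$causal_origin))
  cat(sprintf("  F2 n = %d; bulks %d + %d; depths parents %gx, bulks %gx; seq error %g\n",
              x$n_f2, x$n_bulk, x$n_bulk, x$parent_depth, x$bulk_depth, x$seq_error))
  cat(sprintf("  recombination %g cM/Mb; seed %d\n", x$recomb_rate, x$rng_seed))
  invisible(x)
}

#' Write/read a simulation configuration as flat key=value text
#'
#' Chromosome lengths are serialized as comma-separated `name:bp` pairs;
#' every other field is one `key=value` line. Reading reconstructs a
#' validated [sim_config()].
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  chrom <- paste(sprintf("%s:%d", names(config$chromosome_lengths),
                         as.integer(config$chromosome_lengths)),
                 collapse = ",")
  scalars <- config[setdiff(names(config), "chromosome_lengths")]
  lines <- c(sprintf("chromosome_lengths=%s", chrom),
             sprintf("%s=%s", names(scalars),
                     vapply(scalars, function(v) format(v, scientific = FALSE), "")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  args <- as.list(setNames(vals, keys))
  pairs <- strsplit(strsplit(args$chromosome_lengths, ",", fixed = TRUE)[[1]],
                    ":", fixed = TRUE)
  args$chromosome_lengths <- setNames(
    as.numeric(vapply(pairs, `[[`, "", 2L)),
    vapply(pairs, `[[`, "", 1L))
  for (num in c("snp_density", "recomb_rate", "causal_pos", "n_f2", "n_bulk",
                "parent_depth", "bulk_depth", "seq_error", "genes_per_mb",
                "phenotype_error", "rng_seed"))
    if (!is.null(args[[num]])) args[[num]] <- as.numeric(args[[num]])
  do.call(sim_config, args)
}
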