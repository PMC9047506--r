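#' Specification of a synthetic bulk RNA-seq experiment
#'
#' Describes the count model for the four sequenced groups (two parents
#' XAP1 and AYP1, and the two bulks KY and BY) with `n_reps` libraries
#' each: per-gene negative-binomial counts with log-normal baseline means
#' and a common dispersion, and a set of differentially expressed genes
#' whose signed log2 fold change multiplies the BY group's mean — the
#' design in which any true DE gene differs from all three normal groups
#' and is therefore recoverable as a shared DEG.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param de_genes subset of `gene_ids` that are differentially expressed
#'   in the sterile (BY) bulk.
#' @param lfc signed log2 fold changes, one per `de_genes`.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   means.
#' @param dispersion negative-binomial dispersion (var = mu + dispersion *
#'   mu^2); scalar or per-gene vector.
#' @param n_reps replicates per group.
#' @param size_factors optional per-library relative depths (length
#'   `4 * n_reps`), default all 1.
#' @return An `expression_spec` list.
#' @export
expression_spec <- function(gene_ids, de_genes = character(), lfc = numeric(),
                            baseline_meanlog = 4, baseline_sdlog = 1,
                            dispersion = 0.1, n_reps = 3,
                            size_factors = NULL) {
  if (length(de_genes) != length(lfc))
    stopf("'de_genes' and 'lfc' must have equal length")
  if (!all(de_genes %in% gene_ids))
    stopf("all 'de_genes' must be in 'gene_ids'")
  check_positive(dispersion, "dispersion")
  if (n_reps < 2) stopf("'n_reps' must be >= 2 for testing")
  n_lib <- 4L * n_reps
  if (is.null(size_factors)) size_factors <- rep(1, n_lib)
  if (length(size_factors) != n_lib) stopf("'size_factors' must have length %d", n_lib)
  check_positive(size_factors, "size_factors")
  structure(list(gene_ids = gene_ids, de_genes = de_genes, lfc = lfc,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion, n_reps = as.integer(n_reps),
                 size_factors = size_factors),
            class = "expression_spec")
}

#' Simulate a gene-level count matrix
#'
#' Draws counts ~ NB(baseline mean x group multiplier x library size
#' factor, dispersion). The BY multiplier is `2^lfc` for DE genes and 1
#' otherwise; all other groups have multiplier 1.
#'
#' @param spec an [expression_spec()].
#' @param seed integer seed.
#' @return Integer matrix genes x libraries with column names like
#'   `BY_1`; the library-to-group map is in `attr(, "groups")` and the
#'   per-gene true baseline means in `attr(, "baseline")`.
#' @export
simulate_expression_counts <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "expression_spec"))
  with_seed(seed_child(seed, "expression"), {
    genes <- spec$gene_ids
    n_g <- length(genes)
    groups <- rep(SAMPLES, each = spec$n_reps)
    libs <- paste0(groups, "_", rep(seq_len(spec$n_reps), times = 4))
    baseline <- rlnorm(n_g, spec$baseline_meanlog, spec$baseline_sdlog)
    mult_by <- rep(1, n_g)
    mult_by[match(spec$de_genes, genes)] <- 2^spec$lfc
    disp <- rep_len(spec$dispersion, n_g)

    counts <- matrix(0L, n_g, length(libs), dimnames = list(genes, libs))
    for (j in seq_along(libs)) {
      mu <- baseline * spec$size_factors[j]
      if (groups[j] == "BY") mu <- mu * mult_by
      counts[, j] <- rnbinom(n_g, mu = mu, size = 1 / disp)
    }
    attr(counts, "groups") <- setNames(groups, libs)
    attr(counts, "baseline") <- setNames(baseline, genes)
    counts
  })
}
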