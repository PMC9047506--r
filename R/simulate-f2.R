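# F2 meiosis under the Haldane model: crossover count per gamete per
# chromosome ~ Poisson(map length in Morgans), positions uniform, no
# interference. A gamete is a mosaic of the two parental origins.

make_gamete <- function(chrom_len, morgans) {
  n_x <- rpois(1, morgans)
  breaks <- if (n_x > 0) sort(runif(n_x, 1, chrom_len)) else numeric()
  list(breaks = breaks, first = sample(PARENTS, 1))
}

# Parental origin of a gamete at position(s) `pos`.
origin_at <- function(gamete, pos) {
  idx <- findInterval(pos, gamete$breaks)
  other <- PARENTS[PARENTS != gamete$first]
  ifelse(idx %% 2L == 0L, gamete$first, other)
}

#' Simulate an F2 population segregating for one recessive locus
#'
#' Each individual is the union of two independent recombinant gametes per
#' chromosome (Haldane map function). Phenotype is fully penetrant
#' recessive: sterile iff both chromosome copies carry the causal-origin
#' allele at the causal position; an optional misclassification rate
#' models bulk contamination.
#'
#' @param config a [sim_config()].
#' @return List of individuals; each has `chromosomes` (per chromosome, a
#'   list of two gametes with `breaks` and `first` origin) and `phenotype`
#'   ("fertile" or "sterile").
#' @export
simulate_f2_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed_child(config$rng_seed, "population"), {
    lens <- config$chromosome_lengths
    morgans <- config$recomb_rate * lens / 1e6 / 100  # cM/Mb * Mb -> cM -> M
    lapply(seq_len(config$n_f2), function(i) {
      chroms <- lapply(names(lens), function(ch) {
        list(make_gamete(lens[[ch]], morgans[[ch]]),
             make_gamete(lens[[ch]], morgans[[ch]]))
      })
      names(chroms) <- names(lens)
      pair <- chroms[[config$causal_chrom]]
      homo <- origin_at(pair[[1]], config$causal_pos) == config$causal_origin &&
              origin_at(pair[[2]], config$causal_pos) == config$causal_origin
      pheno <- if (homo) "sterile" else "fertile"
      if (config$phenotype_error > 0 && runif(1) < config$phenotype_error)
        pheno <- if (pheno == "sterile") "fertile" else "sterile"
      list(chromosomes = chroms, phenotype = pheno)
    })
  })
}

#' Select extreme bulks and simulate pooled sequencing
#'
#' Forms the two bulks (BY = sterile plants, KY = fertile plants, `n_bulk`
#' each, or two disjoint random bulks for a no-QTL control), computes each
#' bulk's true chromosome-level allele frequency at every parental SNP, and
#' draws sequencing reads: per site, depth ~ Poisson(mean depth) and
#' alternate-allele reads ~ Binomial(depth, f') where f' is the true
#' frequency perturbed by the per-read error rate. Parents are sequenced as
#' homozygotes at their own mean depth.
#'
#' @param population from [simulate_f2_population()].
#' @param config the [sim_config()] used to generate it.
#' @param snps parental SNP table from [simulate_genome_and_genes()].
#' @param select `"phenotype"` (default) for extreme bulks, `"random"` for
#'   two disjoint unselected bulks (null control).
#' @return data.frame with one row per SNP: `chrom`, `pos`, `ref`, `alt`,
#'   `alt_parent`, and `<SAMPLE>_ref`/`<SAMPLE>_alt` read counts for
#'   XAP1, AYP1, BY, KY.
#' @export
select_and_sequence_bulks <- function(population, config, snps,
                                      select = c("phenotype", "random")) {
  select <- match.arg(select)
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed_child(config$rng_seed, paste0("bulks-", select)), {
    phenos <- vapply(population, `[[`, "", "phenotype")
    if (select == "phenotype") {
      sterile <- which(phenos == "sterile")
      fertile <- which(phenos == "fertile")
      if (length(sterile) < config$n_bulk)
        stopf("only %d sterile plants available; %d needed per bulk — resample the population",
              length(sterile), config$n_bulk)
      if (length(fertile) < config$n_bulk)
        stopf("only %d fertile plants available; %d needed per bulk — resample the population",
              length(fertile), config$n_bulk)
      by_idx <- sample(sterile, config$n_bulk)
      ky_idx <- sample(fertile, config$n_bulk)
    } else {
      pick <- sample(seq_along(population), 2L * config$n_bulk)
      by_idx <- pick[seq_len(config$n_bulk)]
      ky_idx <- pick[config$n_bulk + seq_len(config$n_bulk)]
    }

    e <- config$seq_error
    n2 <- 2L * config$n_bulk

    # True alternate-allele count per site in a bulk: over each member's two
    # chromosome copies, does the copy's parental origin match the SNP's
    # alt-carrying parent?
    bulk_alt_freq <- function(idx) {
      f <- numeric(nrow(snps))
      for (ch in unique(snps$chrom)) {
        rows <- which(snps$chrom == ch)
        pos <- snps$pos[rows]
        alt_par <- snps$alt_parent[rows]
        count <- integer(length(rows))
        for (i in idx) {
          pair <- population[[i]]$chromosomes[[ch]]
          count <- count + (origin_at(pair[[1]], pos) == alt_par) +
                           (origin_at(pair[[2]], pos) == alt_par)
        }
        f[rows] <- count / n2
      }
      f
    }

    draw_reads <- function(true_f, mean_depth) {
      depth <- rpois(length(true_f), mean_depth)
      p <- true_f * (1 - e) + (1 - true_f) * e
      alt <- rbinom(length(true_f), depth, p)
      cbind(ref = depth - alt, alt = alt)
    }

    out <- snps[, c("chrom", "pos", "ref", "alt", "alt_parent")]
    for (par in PARENTS) {
      rd <- draw_reads(as.numeric(snps$alt_parent == par), config$parent_depth)
      out[[paste0(par, "_ref")]] <- rd[, "ref"]
      out[[paste0(par, "_alt")]] <- rd[, "alt"]
    }
    for (bulk in c("BY", "KY")) {
      idx <- if (bulk == "BY") by_idx else ky_idx
      rd <- draw_reads(bulk_alt_freq(idx), config$bulk_depth)
      out[[paste0(bulk, "_ref")]] <- rd[, "ref"]
      out[[paste0(bulk, "_alt")]] <- rd[, "alt"]
    }
    attr(out, "bulk_members") <- list(BY = by_idx, KY = ky_idx)
    rownames(out) <- NULL
    out
  })
}
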