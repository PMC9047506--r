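# delta(SNP index) scan with a depth-conditional simulated null band.
#
# The null model for one site in an unselected F2 bulk of n plants:
#   allele count k ~ Binomial(2n, 1/2)   (bulk composition)
#   reads r ~ Binomial(depth, k / 2n)    (sequencing)
#   index = r / depth
# delta = index_by - index_ky with the two bulks independent. The band is
# the empirical (1-level)/2 and 1-(1-level)/2 percentiles over n_reps
# replicates, computed per distinct (depth_by, depth_ky) pair and cached,
# so equal-depth sites share one band. Type-1 (inverse-ECDF) quantiles are
# used so the band lands on the discrete support of delta.

.band_cache <- new.env(parent = emptyenv())

null_band_one <- function(n_bulk, depth_by, depth_ky, n_reps, level, seed) {
  s <- seed_child(seed, c(7L, n_bulk, depth_by, depth_ky, n_reps))
  with_seed(s, {
    draw_index <- function(depth) {
      k <- rbinom(n_reps, 2L * n_bulk, 0.5)
      rbinom(n_reps, depth, k / (2 * n_bulk)) / depth
    }
    delta <- draw_index(depth_by) - draw_index(depth_ky)
    unname(quantile(delta, c((1 - level) / 2, 1 - (1 - level) / 2), type = 1))
  })
}

#' Simulated null confidence band for delta(SNP index)
#'
#' Draws `n_reps` replicates of the two-stage binomial null (random bulk
#' composition, then binomial read sampling at the observed depths) and
#' returns the empirical central band at the given level. Bands are cached
#' per (n_bulk, depth_by, depth_ky, n_reps, level, seed), and each depth
#' pair's replicate stream is derived deterministically from the seed, so
#' results do not depend on call order.
#'
#' @param n_bulk plants per bulk.
#' @param depth_by,depth_ky observed total read depth in each bulk.
#' @param n_reps null replicates (default 1000; fewer than 100 warns).
#' @param level central coverage level in (0, 1), default 0.95.
#' @param seed integer seed.
#' @return Numeric `c(ci_low, ci_high)`.
#' @export
simulate_null_band <- function(n_bulk, depth_by, depth_ky, n_reps = 1000,
                               level = 0.95, seed = 1L) {
  check_positive(c(n_bulk, depth_by, depth_ky), "n_bulk and depths")
  if (level <= 0 || level >= 1) stopf("'level' must be in (0, 1)")
  if (n_reps < 100) warning("fewer than 100 null replicates; band will be noisy")
  key <- paste("band", n_bulk, depth_by, depth_ky, n_reps, level, seed, sep = ":")
  if (!is.null(.band_cache[[key]])) return(.band_cache[[key]])
  band <- null_band_one(n_bulk, depth_by, depth_ky, n_reps, level, seed)
  .band_cache[[key]] <- band
  band
}

# Bands for many sites at once (unique depth pairs computed once).
null_band_table <- function(n_bulk, depth_by, depth_ky, n_reps, level, seed) {
  pairs <- paste(depth_by, depth_ky, sep = ":")
  uniq <- !duplicated(pairs)
  bands <- mapply(function(db, dk) {
    if (db <= 0 || dk <= 0) return(c(NA_real_, NA_real_))
    simulate_null_band(n_bulk, db, dk, n_reps, level, seed)
  }, depth_by[uniq], depth_ky[uniq])
  colnames(bands) <- pairs[uniq]
  t(bands[, pairs, drop = FALSE])
}

#' delta(SNP index): difference of the two bulks' SNP indices
#'
#' Fixed orientation: sterile bulk minus fertile bulk (BY minus KY). At a
#' fully penetrant recessive causal locus with 30+30 bulking this tends to
#' 1 - 1/3 = 2/3 when the high parent carries the sterile allele.
#'
#' @param records output of [snp_index_table()].
#' @return Numeric vector of per-site deltas in [-1, 1].
#' @export
delta_snp_index <- function(records) {
  records$index_by - records$index_ky
}

#' Scan filtered sites for QTL signal against the simulated null band
#'
#' Computes delta(SNP index) and, per site, the null band at its observed
#' depth pair; a site is a candidate when its delta falls strictly outside
#' the band.
#'
#' @param records filtered records (the `retained` element of
#'   [apply_filters()]).
#' @param n_bulk plants per bulk (needed by the null model).
#' @param n_reps,level,seed see [simulate_null_band()].
#' @return A `bsa_scan` object: the records with `delta`, `ci_low`,
#'   `ci_high`, `is_candidate` columns, plus scan parameters as
#'   attributes.
#' @export
bsa_scan <- function(records, n_bulk, n_reps = 1000, level = 0.95, seed = 1L) {
  if (nrow(records) == 0) stopf("no records to scan")
  ord <- order(records$chrom, records$pos)
  if (any(ord != seq_len(nrow(records)))) {
    message("scan input not sorted by (chrom, pos); sorting")
    records <- records[ord, , drop = FALSE]
  }
  records$delta <- delta_snp_index(records)
  bands <- null_band_table(n_bulk, records$depth_by, records$depth_ky,
                           n_reps, level, seed)
  records$ci_low <- bands[, 1]
  records$ci_high <- bands[, 2]
  records$is_candidate <- records$delta < records$ci_low |
                          records$delta > records$ci_high
  rownames(records) <- NULL
  structure(records,
            class = c("bsa_scan", "data.frame"),
            n_bulk = n_bulk, n_reps = n_reps, level = level, seed = seed)
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat(sprintf("delta(SNP index) scan: %d sites on %d chromosome(s), %d candidates outside the %.0f%% null band\n",
              nrow(x), length(unique(x$chrom)), sum(x$is_candidate),
              100 * attr(x, "level")))
  print(head(as.data.frame(x)[, c("chrom", "pos", "depth_by", "depth_ky",
                                  "index_by", "index_ky", "delta",
                                  "ci_low", "ci_high", "is_candidate")]), ...)
  if (nrow(x) > 6) cat(sprintf("  ... %d more sites\n", nrow(x) - 6))
  invisible(x)
}

#' @export
summary.bsa_scan <- function(object, ...) {
  cat(sprintf("sites: %d; candidates: %d (%.2f%%); level %.2f; %d null reps; bulks of %d\n",
              nrow(object), sum(object$is_candidate),
              100 * mean(object$is_candidate), attr(object, "level"),
              attr(object, "n_reps"), attr(object, "n_bulk")))
  invisible(object)
}

#' Plot a delta(SNP index) scan
#'
#' One panel per chromosome: per-site delta with the null band and
#' candidate sites highlighted.
#'
#' @param x a `bsa_scan`.
#' @param ... passed to [plot()].
#' @export
plot.bsa_scan <- function(x, ...) {
  chroms <- unique(x$chrom)
  old <- par(mfrow = c(length(chroms), 1), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (ch in chroms) {
    d <- x[x$chrom == ch, ]
    plot(d$pos / 1e6, d$delta, pch = 16, cex = 0.4,
         col = ifelse(d$is_candidate, "red", "grey40"),
         xlab = sprintf("%s position (Mb)", ch), ylab = "delta(SNP index)",
         ylim = c(-1, 1), main = ch, ...)
    o <- order(d$pos)
    graphics::lines(d$pos[o] / 1e6, d$ci_low[o], col = "blue")
    graphics::lines(d$pos[o] / 1e6, d$ci_high[o], col = "blue")
    abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Merge candidate sites into candidate regions
#'
#' Consecutive candidate sites on a chromosome whose gaps are at most
#' `merge_gap` bp form one region; regions carrying fewer than `min_sites`
#' sites are dropped. Region span is the min..max of member positions
#' (1-based inclusive).
#'
#' @param scan a [bsa_scan()] result.
#' @param merge_gap maximum within-region gap in bp (default 1e6).
#' @param min_sites minimum member sites per region (default 3).
#' @return data.frame of regions: `chrom`, `start`, `end`, `n_sites`, and
#'   `sites` (list column of member positions).
#' @export
call_candidates_and_merge <- function(scan, merge_gap = 1e6, min_sites = 3) {
  cand <- as.data.frame(scan)[scan$is_candidate, , drop = FALSE]
  out <- NULL
  for (ch in unique(cand$chrom)) {
    pos <- sort(cand$pos[cand$chrom == ch])
    if (!length(pos)) next
    grp <- cumsum(c(1, diff(pos) > merge_gap))
    for (g in unique(grp)) {
      p <- pos[grp == g]
      if (length(p) < min_sites) next
      out <- rbind(out, data.frame(chrom = ch, start = min(p), end = max(p),
                                   n_sites = length(p),
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
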