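# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written by a different route than the
# package code it checks.

# Exact pmf of the per-bulk SNP index under the two-stage binomial null:
# allele count k ~ Binomial(2n, 1/2), reads r ~ Binomial(depth, k/2n).
enum_index_pmf <- function(n_bulk, depth) {
  ks <- 0:(2 * n_bulk)
  pk <- dbinom(ks, 2 * n_bulk, 0.5)
  rs <- 0:depth
  pr <- sapply(ks, function(k) dbinom(rs, depth, k / (2 * n_bulk)))
  p <- as.vector(pr %*% pk)
  data.frame(value = rs / depth, p = p)
}

# Exact pmf of delta = index_by - index_ky (independent bulks).
enum_delta_pmf <- function(n_bulk, depth_by, depth_ky) {
  a <- enum_index_pmf(n_bulk, depth_by)
  b <- enum_index_pmf(n_bulk, depth_ky)
  d <- round(outer(a$value, b$value, "-"), 10)
  p <- outer(a$p, b$p)
  agg <- tapply(as.vector(p), as.vector(d), sum)
  data.frame(value = as.numeric(names(agg)), p = as.vector(agg))
}

# Type-1 quantiles of a discrete pmf (smallest support value whose CDF
# reaches the probability).
enum_quantile <- function(pmf, probs) {
  o <- order(pmf$value)
  v <- pmf$value[o]
  cdf <- cumsum(pmf$p[o])
  vapply(probs, function(q) v[which(cdf >= q - 1e-12)[1]], numeric(1))
}

enum_null_band <- function(n_bulk, depth_by, depth_ky, level = 0.95) {
  pmf <- enum_delta_pmf(n_bulk, depth_by, depth_ky)
  enum_quantile(pmf, c((1 - level) / 2, 1 - (1 - level) / 2))
}

# Brute-force over-representation p-value: enumerate every possible draw
# of n genes from a universe of N and count draws with >= k term members.
brute_force_hyper_p <- function(N, K, n, k) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)  # term members are genes 1..K
  mean(hits >= k)
}

# Independent full-protein retranslation: splice the CDS out of a (possibly
# mutated) chromosome string and translate it, base R only.
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}
oracle_splice <- function(chrom_seq, cds_segs, strand) {
  cds_segs <- cds_segs[order(cds_segs$start), , drop = FALSE]
  parts <- substring(chrom_seq, cds_segs$start, cds_segs$end)
  if (strand == "-") parts <- rev(vapply(parts, oracle_revcomp, ""))
  paste(parts, collapse = "")
}
oracle_translate <- function(cds) {
  n <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * (seq_len(n) - 1) + 1, 3 * seq_len(n))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}
# Classify a coding variant by diffing the full mutated protein against
# the wildtype protein.
oracle_classify_coding <- function(chrom_seq, pos, alt, cds_segs, strand) {
  mutated <- chrom_seq
  substr(mutated, pos, pos) <- alt
  wt <- oracle_translate(oracle_splice(chrom_seq, cds_segs, strand))
  mt <- oracle_translate(oracle_splice(mutated, cds_segs, strand))
  stopifnot(nchar(wt) == nchar(mt))
  diffs <- which(strsplit(wt, "")[[1]] != strsplit(mt, "")[[1]])
  if (length(diffs) == 0) return("synonymous")
  stopifnot(length(diffs) == 1)
  ra <- substr(wt, diffs, diffs); aa <- substr(mt, diffs, diffs)
  if (aa == "*" && ra != "*") "stopgain"
  else if (ra == "*" && aa != "*") "stoploss"
  else "nonsynonymous"
}
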