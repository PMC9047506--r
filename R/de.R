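# Negative-binomial differential expression, written out in full rather
# than wrapped: median-of-ratios normalization, per-gene method-of-moments
# dispersion, and a Wald test on the normalized mean difference. Simpler
# than shrinkage estimators, adequate at 3 replicates per group, and fully
# checkable against simulation truth.

#' Median-of-ratios library size factors
#'
#' factor_j = median over genes (nonzero in every library) of
#' count_gj / geometric-mean_g, rescaled to geometric mean 1. When no gene
#' is nonzero everywhere, falls back to upper-quartile scaling with a
#' message.
#'
#' @param counts genes x libraries matrix of non-negative counts.
#' @return Positive numeric vector, one factor per library.
#' @export
size_factors <- function(counts) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  pos <- rowSums(counts == 0) == 0
  if (any(pos)) {
    lg <- log(counts[pos, , drop = FALSE])
    ratios <- lg - rowMeans(lg)
    sf <- exp(apply(ratios, 2, median))
  } else {
    message("no gene is nonzero in all libraries; using upper-quartile scaling")
    uq <- apply(counts, 2, function(x) quantile(x[x > 0], 0.75))
    sf <- uq
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Negative-binomial Wald test for one contrast
#'
#' Counts are normalized by [size_factors()] (computed over all supplied
#' libraries). Per gene, dispersion is estimated by method of moments
#' pooled over the two contrast groups (df-weighted average of per-group
#' (s^2 - m)/m^2, floored at 1e-8), the log2 fold change is
#' log2((mean_a + 0.5) / (mean_b + 0.5)) of normalized means, and the
#' two-sided p-value comes from the Wald statistic
#' (m_a - m_b) / sqrt(v_a/n_a + v_b/n_b) with v_g = m_g + phi * m_g^2
#' under a normal approximation. All-zero genes are untestable: p = 1,
#' log2fc = 0.
#'
#' @param counts genes x libraries count matrix with a group map in
#'   `attr(counts, "groups")` (or supply `groups`).
#' @param group_b the comparison group; the contrast is `group_a` minus
#'   `group_b`.
#' @param group_a the group of interest (default "BY", the sterile bulk).
#' @param groups named character vector library -> group, overriding the
#'   attribute.
#' @return data.frame: `gene`, `log2fc`, `p`, `mean_a`, `mean_b`,
#'   `dispersion`, `testable`.
#' @export
nb_test_contrast <- function(counts, group_b, group_a = "BY", groups = NULL) {
  groups <- groups %||% attr(counts, "groups")
  if (is.null(groups)) stopf("no library-to-group map supplied")
  groups <- groups[colnames(counts)]
  for (g in c(group_a, group_b))
    if (sum(groups == g, na.rm = TRUE) < 2)
      stopf("group '%s' needs at least 2 replicates", g)
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  a <- norm[, groups == group_a, drop = FALSE]
  b <- norm[, groups == group_b, drop = FALSE]
  n_a <- ncol(a); n_b <- ncol(b)
  m_a <- rowMeans(a); m_b <- rowMeans(b)
  v_a <- apply(a, 1, var); v_b <- apply(b, 1, var)

  mom <- function(v, m) ifelse(m > 0, (v - m) / m^2, NA_real_)
  phi_a <- mom(v_a, m_a); phi_b <- mom(v_b, m_b)
  w_a <- ifelse(is.na(phi_a), 0, n_a - 1)
  w_b <- ifelse(is.na(phi_b), 0, n_b - 1)
  phi <- (w_a * ifelse(is.na(phi_a), 0, phi_a) +
          w_b * ifelse(is.na(phi_b), 0, phi_b)) /
         pmax(w_a + w_b, 1)
  phi <- pmax(phi, 1e-8)

  se <- sqrt((m_a + phi * m_a^2) / n_a + (m_b + phi * m_b^2) / n_b)
  z <- ifelse(se > 0, (m_a - m_b) / se, 0)
  p <- 2 * pnorm(-abs(z))
  testable <- m_a > 0 | m_b > 0
  p[!testable] <- 1
  log2fc <- log2((m_a + 0.5) / (m_b + 0.5))
  log2fc[!testable] <- 0
  data.frame(gene = rownames(counts), log2fc = log2fc, p = p,
             mean_a = m_a, mean_b = m_b, dispersion = phi,
             testable = testable, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Call DEGs per contrast and intersect the three contrasts
#'
#' Benjamini-Hochberg adjustment is applied within each contrast; a gene
#' is "up" when its adjusted p (or raw p with `adjust = FALSE`) is below
#' `alpha` and log2fc > `lfc`, "down" symmetrically. Shared DEGs are genes
#' called with the same direction in all three contrasts of the sterile
#' bulk against each normal sample.
#'
#' @param results named list of three data.frames from
#'   [nb_test_contrast()] (same gene universe).
#' @param alpha significance threshold (default 0.05).
#' @param lfc absolute log2-fold-change threshold (default 1).
#' @param adjust use BH-adjusted p (default) or raw p.
#' @return A `deg_intersection` list: `calls` (gene x contrast matrix of
#'   "up"/"down"/"ns"), `per_contrast` (up/down counts), `shared_up`,
#'   `shared_down`, and the augmented `results` (with `padj`, `call`).
#' @export
call_and_intersect_degs <- function(results, alpha = 0.05, lfc = 1,
                                    adjust = TRUE) {
  stopifnot(is.list(results), length(results) >= 2)
  universe <- results[[1]]$gene
  for (nm in names(results)) {
    diff <- union(setdiff(results[[nm]]$gene, universe),
                  setdiff(universe, results[[nm]]$gene))
    if (length(diff))
      stopf("contrast '%s' has a different gene universe (e.g. %s)",
            nm, paste(head(diff, 3), collapse = ", "))
  }
  calls <- matrix("ns", length(universe), length(results),
                  dimnames = list(universe, names(results)))
  for (nm in names(results)) {
    r <- results[[nm]]
    r <- r[match(universe, r$gene), ]
    r$padj <- p.adjust(r$p, method = "BH")
    crit <- if (adjust) r$padj else r$p
    r$call <- ifelse(crit < alpha & r$log2fc > lfc, "up",
                     ifelse(crit < alpha & r$log2fc < -lfc, "down", "ns"))
    calls[, nm] <- r$call
    results[[nm]] <- r
  }
  shared_up <- universe[rowSums(calls == "up") == ncol(calls)]
  shared_down <- universe[rowSums(calls == "down") == ncol(calls)]
  per_contrast <- rbind(up = colSums(calls == "up"),
                        down = colSums(calls == "down"))
  structure(list(calls = calls, per_contrast = per_contrast,
                 shared_up = shared_up, shared_down = shared_down,
                 results = results, alpha = alpha, lfc = lfc,
                 adjust = adjust),
            class = "deg_intersection")
}

#' @export
print.deg_intersection <- function(x, ...) {
  cat(sprintf("DEG calls at %s p < %g, |log2FC| > %g\n",
              if (x$adjust) "BH-adjusted" else "raw", x$alpha, x$lfc))
  print(x$per_contrast)
  cat(sprintf("shared up: %d; shared down: %d\n",
              length(x$shared_up), length(x$shared_down)))
  invisible(x)
}

#' FPKM from counts and gene lengths
#'
#' fpkm_gj = count_gj * 1e9 / (length_g * total_j).
#'
#' @param counts genes x libraries count matrix.
#' @param lengths named positive gene lengths in bp (spliced transcript
#'   length).
#' @return Numeric matrix of the same shape.
#' @export
compute_fpkm <- function(counts, lengths) {
  lengths <- as.vector(lengths[rownames(counts)])
  if (any(is.na(lengths) | lengths <= 0))
    stopf("every gene needs a positive length")
  totals <- colSums(counts)
  sweep(counts / lengths, 2, totals, "/") * 1e9
}
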