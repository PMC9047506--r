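#' Chi-square goodness-of-fit test for a Mendelian segregation ratio
#'
#' Pearson chi-square of observed fertile/sterile plant counts against an
#' expected ratio (default 3:1), df = 1, without continuity correction by
#' default (a Yates-corrected variant is available). The trait is judged
#' consistent with the ratio when the statistic is below the df = 1
#' critical value at `alpha`, computed from the chi-square quantile
#' function (about 3.841 at alpha = 0.05).
#'
#' @param n_fertile,n_sterile observed plant counts.
#' @param ratio expected fertile:sterile ratio as a length-2 vector.
#' @param alpha significance level (default 0.05).
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return A `segregation_test` list: counts, `expected`, `chi2`,
#'   `critical`, `p`, `consistent`.
#' @export
chi_square_segregation <- function(n_fertile, n_sterile, ratio = c(3, 1),
                                   alpha = 0.05, correct = FALSE) {
  total <- n_fertile + n_sterile
  if (total <= 0) stopf("total plant count must be positive")
  if (n_fertile < 0 || n_sterile < 0) stopf("counts must be non-negative")
  expected <- total * ratio / sum(ratio)
  obs <- c(n_fertile, n_sterile)
  dev <- abs(obs - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  critical <- qchisq(1 - alpha, df = 1)
  structure(list(n_fertile = n_fertile, n_sterile = n_sterile,
                 ratio = ratio, expected = expected, chi2 = chi2,
                 critical = critical, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 alpha = alpha, consistent = chi2 < critical),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("Segregation %d fertile : %d sterile vs %g:%g\n",
              x$n_fertile, x$n_sterile, x$ratio[1], x$ratio[2]))
  cat(sprintf("  chi2 = %.4g (critical %.3f at alpha %g, df 1) -> %s\n",
              x$chi2, x$critical, x$alpha,
              if (x$consistent) "consistent" else "not consistent"))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' ddCt = (Ct_target - Ct_reference) - (Ct_target_cal - Ct_reference_cal);
#' the calibrator condition maps to 1.0 by construction.
#'
#' @param ct_target,ct_reference Ct values in the condition of interest.
#' @param ct_target_calibrator,ct_reference_calibrator Ct values in the
#'   calibrator condition.
#' @return Fold change 2^-ddCt.
#' @export
relative_expression_ddct <- function(ct_target, ct_reference,
                                     ct_target_calibrator,
                                     ct_reference_calibrator) {
  stopifnot(is.finite(ct_target), is.finite(ct_reference),
            is.finite(ct_target_calibrator), is.finite(ct_reference_calibrator))
  ddct <- (ct_target - ct_reference) -
          (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}

#' Intersect BSA candidate genes with shared DEGs
#'
#' The conjunctive step: genes carrying a consequential variant inside a
#' candidate region that are also shared DEGs (same direction in all
#' three contrasts). Each output row carries the DE direction and, when
#' expression summaries are supplied, the per-group mean expression.
#'
#' @param bsa_genes data.frame from [genes_in_regions()].
#' @param shared_up,shared_down character vectors from
#'   [call_and_intersect_degs()].
#' @param expression_summary optional matrix/data.frame of per-group mean
#'   expression (rows = genes, columns = groups).
#' @return data.frame sorted by chromosome and position: `gene_id`,
#'   `chrom`, `start`, `end`, `worst_effect`, `direction`, and any
#'   expression columns.
#' @export
integrate_bsa_bsr <- function(bsa_genes, shared_up, shared_down,
                              expression_summary = NULL) {
  if (length(intersect(shared_up, shared_down)))
    stopf("a gene cannot be both shared-up and shared-down")
  shared <- c(setNames(rep("up", length(shared_up)), shared_up),
              setNames(rep("down", length(shared_down)), shared_down))
  hit <- bsa_genes$gene_id %in% names(shared)
  if (!any(hit) && nrow(bsa_genes) > 0 && length(shared) > 0) {
    warning(sprintf(
      "no overlap between BSA genes (e.g. %s) and shared DEGs (e.g. %s); check id namespaces",
      paste(head(bsa_genes$gene_id, 2), collapse = ", "),
      paste(head(names(shared), 2), collapse = ", ")))
  }
  out <- bsa_genes[hit, , drop = FALSE]
  out$direction <- unname(shared[out$gene_id])
  if (!is.null(expression_summary) && nrow(out)) {
    es <- as.data.frame(expression_summary)
    idx <- match(out$gene_id, rownames(es))
    for (cn in colnames(es)) out[[paste0("expr_", cn)]] <- es[idx, cn]
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
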