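#' Per-bulk SNP index relative to a designated high parent
#'
#' The SNP index at a site is the fraction of a bulk's reads carrying the
#' designated high parent's allele. The high parent's allele is determined
#' from the parental read counts (its majority allele), not from the
#' ref/alt identity, because the reference genome need not be either
#' parent. Bulks with zero depth get an NA index and a "no-coverage" flag
#' rather than a division by zero.
#'
#' @param sites data.frame of allelic-depth sites
#'   (from [read_allelic_depths()] or [select_and_sequence_bulks()]).
#' @param high_parent "XAP1" or "AYP1".
#' @return The input with columns added: `high_allele` ("ref"/"alt"/NA),
#'   `depth_by`, `depth_ky`, `index_by`, `index_ky`, `no_coverage`.
#' @export
snp_index_table <- function(sites, high_parent = c("AYP1", "XAP1")) {
  high_parent <- match.arg(high_parent)
  hp_ref <- sites[[paste0(high_parent, "_ref")]]
  hp_alt <- sites[[paste0(high_parent, "_alt")]]
  high_allele <- ifelse(hp_ref + hp_alt == 0L, NA_character_,
                        ifelse(hp_alt > hp_ref, "alt", "ref"))
  idx <- function(bulk) {
    ref <- sites[[paste0(bulk, "_ref")]]
    alt <- sites[[paste0(bulk, "_alt")]]
    depth <- ref + alt
    high_reads <- ifelse(high_allele == "alt", alt, ref)
    list(depth = depth, index = ifelse(depth > 0, high_reads / depth, NA_real_))
  }
  by <- idx("BY"); ky <- idx("KY")
  sites$high_parent <- high_parent
  sites$high_allele <- high_allele
  sites$depth_by <- by$depth
  sites$depth_ky <- ky$depth
  sites$index_by <- by$index
  sites$index_ky <- ky$index
  sites$no_coverage <- by$depth == 0L | ky$depth == 0L | is.na(high_allele)
  sites
}

#' Filter SNP-index records on parent informativeness, depth and index
#'
#' Rejection rules, applied in fixed order (a site gets the first reason
#' that fires):
#' \describe{
#'   \item{parent}{a parent is not effectively homozygous (minor-allele
#'     read fraction above `het_tol`), or the two parents' majority
#'     alleles coincide (uninformative).}
#'   \item{depth}{total depth below `min_depth` in either bulk.}
#'   \item{low-index-both}{SNP index below `low_index` in both bulks —
#'     the classic QTL-seq artifact filter.}
#'   \item{missing}{a sample with no reads not already caught above.}
#' }
#' Thresholds are strict (`< min_depth`, `< low_index`). With
#' `homozygous_filter = "bulks"` an additional, aggressive reading of the
#' heterozygosity rule is applied: sites whose index is intermediate (in
#' `(low_index, 1 - low_index)`) in both bulks are also removed. The
#' default applies the parent rule only.
#'
#' @param records output of [snp_index_table()].
#' @param min_depth minimum per-bulk depth (default 7).
#' @param low_index SNP-index floor (default 0.3).
#' @param het_tol maximum parental minor-allele read fraction still called
#'   homozygous (default 0.1).
#' @param homozygous_filter "parents" (default) or "bulks".
#' @return List with `retained` (passing records), `rejected` (with a
#'   `reason` column) and `tally` (named counts per reason, plus
#'   "retained").
#' @export
apply_filters <- function(records, min_depth = 7, low_index = 0.3,
                          het_tol = 0.1,
                          homozygous_filter = c("parents", "bulks")) {
  homozygous_filter <- match.arg(homozygous_filter)
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  par_stats <- lapply(PARENTS, function(p) {
    ref <- records[[paste0(p, "_ref")]]
    alt <- records[[paste0(p, "_alt")]]
    tot <- ref + alt
    list(tot = tot,
         minor = ifelse(tot > 0, pmin(ref, alt) / tot, NA_real_),
         major = ifelse(tot > 0, ifelse(alt > ref, "alt", "ref"), NA_character_))
  })
  names(par_stats) <- PARENTS

  # (a) parent rule: both parents covered, effectively homozygous,
  # and carrying different alleles.
  het <- (par_stats$XAP1$tot > 0 & par_stats$XAP1$minor > het_tol) |
         (par_stats$AYP1$tot > 0 & par_stats$AYP1$minor > het_tol)
  shared <- !is.na(par_stats$XAP1$major) & !is.na(par_stats$AYP1$major) &
            par_stats$XAP1$major == par_stats$AYP1$major
  reason[is.na(reason) & (het | shared)] <- "parent"

  # (b) bulk depth rule.
  low_depth <- records$depth_by < min_depth | records$depth_ky < min_depth
  reason[is.na(reason) & low_depth] <- "depth"

  # (c) low index in BOTH bulks.
  both_low <- !is.na(records$index_by) & !is.na(records$index_ky) &
              records$index_by < low_index & records$index_ky < low_index
  reason[is.na(reason) & both_low] <- "low-index-both"

  # (d) remaining no-coverage samples (parents with zero reads).
  missing <- par_stats$XAP1$tot == 0L | par_stats$AYP1$tot == 0L |
             records$no_coverage
  reason[is.na(reason) & missing] <- "missing"

  if (homozygous_filter == "bulks") {
    bulk_het <- records$index_by > low_index & records$index_by < 1 - low_index &
                records$index_ky > low_index & records$index_ky < 1 - low_index
    reason[is.na(reason) & bulk_het] <- "bulk-het"
  }

  keep <- is.na(reason)
  tally <- table(factor(reason, levels = c("parent", "depth", "low-index-both",
                                           "missing", "bulk-het")))
  tally <- c(as.vector(tally) , sum(keep))
  names(tally) <- c("parent", "depth", "low-index-both", "missing", "bulk-het",
                    "retained")
  retained <- records[keep, , drop = FALSE]
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  rownames(retained) <- rownames(rejected) <- NULL
  list(retained = retained, rejected = rejected, tally = tally)
}
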