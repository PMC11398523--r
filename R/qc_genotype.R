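#' Genotype-level QC thresholds for the deep-exome arm
#'
#' Defaults follow standard exome practice for blended designs: genotypes
#' are removed below 10x depth or genotype quality 20, heterozygotes with
#' allele balance outside `[0.2, 0.8]`, and homozygous-alternate calls with
#' allele balance below 0.8.
#'
#' @param min_dp Minimum read depth.
#' @param min_gq Minimum genotype quality.
#' @param het_ab_range Allowed allele-balance interval for heterozygotes
#'   (inclusive).
#' @param homalt_ab_min Minimum allele balance for homozygous-alternate
#'   calls (inclusive).
#' @return A `bge_gt_thresholds` list.
#' @export
genotype_qc_thresholds <- function(min_dp = 10, min_gq = 20,
                                   het_ab_range = c(0.2, 0.8),
                                   homalt_ab_min = 0.8) {
  stopifnot(min_dp >= 0, min_gq >= 0,
            length(het_ab_range) == 2,
            het_ab_range[1] >= 0, het_ab_range[2] <= 1,
            het_ab_range[1] < het_ab_range[2],
            homalt_ab_min >= 0, homalt_ab_min <= 1)
  structure(list(min_dp = min_dp, min_gq = min_gq,
                 het_ab_range = het_ab_range, homalt_ab_min = homalt_ab_min),
            class = "bge_gt_thresholds")
}

#' Mask low-quality exome genotype calls
#'
#' Applies the per-genotype filters: depth below `min_dp`, genotype quality
#' below `min_gq`, heterozygote allele balance outside `het_ab_range`, and
#' homozygous-alternate allele balance below `homalt_ab_min`. Allele balance
#' is `alt / (ref + alt)` from the AD fields; genotypes whose AD is missing
#' are left unfiltered by the AB rules and counted in the report.
#'
#' @param genotypes Samples x sites integer matrix (0/1/2/NA).
#' @param dp,gq Matching matrices of read depth and genotype quality.
#' @param ad_ref,ad_alt Matching matrices of ref/alt allele depths (may be
#'   NA).
#' @param thresholds A [genotype_qc_thresholds()].
#' @return List with `genotypes` (filtered copy, failures set NA) and
#'   `report` (named counts per rule: `low_dp`, `low_gq`, `het_ab`,
#'   `homalt_ab`, `ab_unavailable`, `removed`).
#' @export
filter_genotypes <- function(genotypes, dp, gq, ad_ref, ad_alt,
                             thresholds = genotype_qc_thresholds()) {
  stopifnot(all(dim(genotypes) == dim(dp)), all(dim(genotypes) == dim(gq)))
  th <- thresholds
  called <- !is.na(genotypes)
  low_dp <- called & !is.na(dp) & dp < th$min_dp
  low_gq <- called & !is.na(gq) & gq < th$min_gq
  ab <- ad_alt / (ad_ref + ad_alt)
  ab_na <- called & (is.na(ad_ref) | is.na(ad_alt)) & genotypes > 0
  het <- called & genotypes == 1L & !is.na(ab)
  het_ab <- het & (ab < th$het_ab_range[1] | ab > th$het_ab_range[2])
  hom <- called & genotypes == 2L & !is.na(ab)
  homalt_ab <- hom & ab < th$homalt_ab_min
  fail <- low_dp | low_gq | het_ab | homalt_ab
  out <- genotypes
  out[fail] <- NA_integer_
  list(genotypes = out,
       report = c(low_dp = sum(low_dp), low_gq = sum(low_gq),
                  het_ab = sum(het_ab), homalt_ab = sum(homalt_ab),
                  ab_unavailable = sum(ab_na), removed = sum(fail)))
}

#' Site-level exome filters
#'
#' Removes a site if any condition holds: more than `max_alleles` alleles,
#' VQSR failure, low-complexity region, or outside the capture target
#' (disjunctive reading of the filter list).
#'
#' @param sites Site table.
#' @param n_alleles Integer vector of allele counts per site.
#' @param vqsr_pass,in_lcr,in_target Logical vectors per site.
#' @param max_alleles Maximum allowed allele count (default 6; strictly more
#'   is removed).
#' @return List with `sites` (retained rows), `keep` (logical), `report`
#'   (counts per reason).
#' @export
filter_sites <- function(sites, n_alleles, vqsr_pass, in_lcr, in_target,
                         max_alleles = 6) {
  r_alleles <- n_alleles > max_alleles
  r_vqsr <- !vqsr_pass
  r_lcr <- in_lcr
  r_target <- !in_target
  drop <- r_alleles | r_vqsr | r_lcr | r_target
  list(sites = sites[!drop, , drop = FALSE], keep = !drop,
       report = c(too_many_alleles = sum(r_alleles), vqsr_fail = sum(r_vqsr),
                  lcr = sum(r_lcr), off_target = sum(r_target),
                  removed = sum(drop)))
}

#' Sample coverage and contamination filters
#'
#' A sample fails if its fraction of exome target at >= 10x is below 0.90,
#' estimated WGS coverage is below 1x, or chimeric/contamination read rates
#' exceed 5% (all boundaries exclusive on the failing side, so 0.90 / 1x /
#' 5% exactly pass).
#'
#' @param records Data frame with columns `sample`, `exome_fraction_10x`,
#'   `wgs_coverage`, `chimera_rate`, `contamination_rate`.
#' @param min_exome_fraction,min_wgs_coverage,max_chimera,max_contamination
#'   Thresholds.
#' @return Data frame with `sample`, `pass`, `reasons` (comma-separated).
#' @export
filter_sample_coverage <- function(records,
                                   min_exome_fraction = 0.90,
                                   min_wgs_coverage = 1,
                                   max_chimera = 0.05,
                                   max_contamination = 0.05) {
  reasons <- cbind(
    exome_fraction = records$exome_fraction_10x < min_exome_fraction,
    wgs_coverage = records$wgs_coverage < min_wgs_coverage,
    chimera = records$chimera_rate > max_chimera,
    contamination = records$contamination_rate > max_contamination
  )
  rs <- apply(reasons, 1, function(r)
    paste(colnames(reasons)[r], collapse = ","))
  data.frame(sample = records$sample, pass = rowSums(reasons) == 0,
             reasons = rs, stringsAsFactors = FALSE)
}

#' Strata-wise MAD outlier filter for sample QC metrics
#'
#' Within each stratum (typically ancestry x cohort) and for each metric,
#' flags samples farther than `k` raw median absolute deviations from the
#' stratum centre. The default centre is the mean with MAD scale
#' (`MAD = median(|x - median(x)|)`, no consistency constant), matching the
#' common "k MADs from the mean" phrasing; `center = "median"` gives the
#' fully robust variant. Strata smaller than `min_stratum` are skipped with
#' a warning, as are metrics with zero MAD in a stratum.
#'
#' @param metrics Numeric matrix, samples x metrics (rownames = sample ids).
#' @param strata Vector of stratum labels, one per sample.
#' @param k Multiplier (default 4).
#' @param center `"mean"` or `"median"`.
#' @param min_stratum Minimum stratum size.
#' @return List with `pass` (logical per sample), `flags` (logical matrix),
#'   `skipped` (data frame of skipped stratum/metric pairs and why).
#' @export
mad_outlier_filter <- function(metrics, strata, k = 4,
                               center = c("mean", "median"),
                               min_stratum = 10) {
  center <- match.arg(center)
  metrics <- as.matrix(metrics)
  stopifnot(nrow(metrics) == length(strata))
  flags <- matrix(FALSE, nrow(metrics), ncol(metrics),
                  dimnames = dimnames(metrics))
  skipped <- list()
  for (st in unique(strata)) {
    idx <- which(strata == st)
    if (length(idx) < min_stratum) {
      warning(sprintf("stratum '%s' has %d < %d samples: skipped", st,
                      length(idx), min_stratum))
      skipped[[length(skipped) + 1]] <-
        data.frame(stratum = st, metric = NA_character_,
                   reason = "small_stratum")
      next
    }
    for (j in seq_len(ncol(metrics))) {
      x <- metrics[idx, j]
      m <- median(x, na.rm = TRUE)
      mad_raw <- median(abs(x - m), na.rm = TRUE)
      if (!is.finite(mad_raw) || mad_raw == 0) {
        skipped[[length(skipped) + 1]] <-
          data.frame(stratum = st,
                     metric = colnames(metrics)[j] %||% as.character(j),
                     reason = "zero_mad")
        next
      }
      c0 <- if (center == "mean") mean(x, na.rm = TRUE) else m
      flags[idx, j] <- !is.na(x) & abs(x - c0) > k * mad_raw
    }
  }
  list(pass = rowSums(flags) == 0, flags = flags,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(stratum = character(), metric = character(),
                    reason = character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
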