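#' Diploid local-ancestry background at one position
#'
#' Returns the unordered pair of the two haplotypes' tract ancestries at a
#' site, canonicalized lexicographically (`"AFR|EUR"`, never `"EUR|AFR"`).
#' A position at a tract boundary belongs to the tract whose half-open
#' interval contains it; a position outside all tracts of either haplotype
#' is `NA`.
#'
#' @param tracts A `bge_tracts` table.
#' @param sample Sample id.
#' @param pos bp position(s).
#' @return Character vector of canonical background labels (or `NA`).
#' @export
background_at <- function(tracts, sample, pos) {
  anc <- attr(tracts, "ancestries")
  c0 <- tract_codes_at(tracts, sample, 0L, pos)
  c1 <- tract_codes_at(tracts, sample, 1L, pos)
  canonical_background(anc[c0 + 1L], anc[c1 + 1L])
}

canonical_background <- function(a, b) {
  out <- ifelse(is.na(a) | is.na(b), NA_character_,
                ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|")))
  out
}

# samples x sites matrix of canonical background labels
background_matrix <- function(tracts, samples, pos) {
  anc <- attr(tracts, "ancestries")
  cm <- ancestry_code_matrices(tracts, samples, pos)
  a <- matrix(anc[cm[[1]] + 1L], nrow = length(samples))
  b <- matrix(anc[cm[[2]] + 1L], nrow = length(samples))
  m <- matrix(canonical_background(a, b), nrow = length(samples),
              dimnames = list(samples, NULL))
  m
}

#' Imputation accuracy stratified by diploid local-ancestry background
#'
#' Assigns every compared genotype (sample x site) to the unordered pair of
#' its two haplotypes' local ancestries and computes, per background and
#' MAF bin, the pooled aggregate R-squared and aggregate non-reference
#' concordance. Stratification is per genotype, not per SNP: one SNP
#' contributes to several backgrounds, which is what keeps rare-variant
#' strata populated. Genotypes not covered by tracts are dropped and
#' counted.
#'
#' @param truth Samples x sites genotype matrix (array truth).
#' @param ds Samples x sites dosage matrix.
#' @param test Samples x sites hard-called test genotypes (for the
#'   concordance metric); defaults to `round(ds)`.
#' @param tracts A `bge_tracts` table covering the samples.
#' @param pos Site bp positions (length = ncol).
#' @param maf Per-site MAFs for binning.
#' @param scheme A [maf_bin_scheme()].
#' @param backgrounds `"all"` or `"homozygous_only"` (only strata whose two
#'   haplotypes agree, the main-figure convention).
#' @return Data frame keyed by (`background`, `bin_lo`, `bin_hi`) with
#'   `n_genotypes`, `r2`, `nonref_concordance`; attribute
#'   `"n_uncovered"` counts genotypes outside tract coverage.
#' @export
stratified_metrics <- function(truth, ds, test = NULL, tracts, pos, maf,
                               scheme = maf_bin_scheme(),
                               backgrounds = c("all", "homozygous_only")) {
  backgrounds <- match.arg(backgrounds)
  stopifnot(all(dim(truth) == dim(ds)), ncol(truth) == length(pos),
            ncol(truth) == length(maf))
  if (is.null(test)) test <- hard_call(ds = ds, rule = "round_ds")
  bg <- background_matrix(tracts, rownames(truth), pos)
  n_uncovered <- sum(is.na(bg))
  levels <- sort(unique(as.vector(bg[!is.na(bg)])))
  if (backgrounds == "homozygous_only") {
    parts <- strsplit(levels, "|", fixed = TRUE)
    levels <- levels[vapply(parts, function(x) x[1] == x[2], TRUE)]
  }
  bins <- assign_maf_bin(maf, scheme)
  bf <- bin_frame(scheme)
  res <- list()
  for (lv in levels) {
    in_bg <- bg == lv & !is.na(bg)
    for (b in bf$bin) {
      js <- which(!is.na(bins) & bins == b)
      if (length(js) == 0) {
        res[[length(res) + 1]] <- data.frame(
          background = lv, bin_lo = bf$bin_lo[b], bin_hi = bf$bin_hi[b],
          n_genotypes = 0L, r2 = NA_real_, nonref_concordance = NA_real_)
        next
      }
      sel <- in_bg[, js, drop = FALSE]
      tv <- truth[, js, drop = FALSE][sel]
      dv <- ds[, js, drop = FALSE][sel]
      xv <- test[, js, drop = FALSE][sel]
      ok <- !is.na(tv) & !is.na(dv)
      r2 <- if (sum(ok) > 1 && sd(tv[ok]) > 0 && sd(dv[ok]) > 0)
        cor(tv[ok], dv[ok])^2 else NA_real_
      nrc <- nonref_concordance(concordance_counts(tv, xv))
      res[[length(res) + 1]] <- data.frame(
        background = lv, bin_lo = bf$bin_lo[b], bin_hi = bf$bin_hi[b],
        n_genotypes = sum(ok), r2 = r2, nonref_concordance = nrc)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(background = character(), bin_lo = numeric(),
               bin_hi = numeric(), n_genotypes = integer(), r2 = numeric(),
               nonref_concordance = numeric())
  rownames(out) <- NULL
  attr(out, "n_uncovered") <- n_uncovered
  out
}

#' Filter a local-ancestry reference panel on global ancestry fraction
#'
#' Reference samples for local-ancestry inference should themselves be
#' non-admixed; samples whose global fraction of the target ancestry is
#' below `min_fraction` are excluded.
#'
#' @param samples Character vector of reference sample ids.
#' @param fractions Per-sample target-ancestry fractions in `[0, 1]`.
#' @param min_fraction Inclusive threshold, default 0.9.
#' @return Character vector of retained sample ids.
#' @export
reference_panel_prefilter <- function(samples, fractions, min_fraction = 0.9) {
  stopifnot(length(samples) == length(fractions))
  samples[!is.na(fractions) & fractions >= min_fraction]
}
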