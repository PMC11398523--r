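#' MAF bin scheme
#'
#' Bins minor allele frequencies into `(lo, hi]` intervals, the first bin
#' closed at zero (`[0, e1]`). Default edges cover `[0, 0.5]` at the
#' resolution used for imputation-accuracy reporting, with the rare end
#' split at 0.005 and 0.01.
#'
#' @param edges Strictly ascending numeric vector starting at 0 and ending
#'   at 0.5.
#' @return A `bge_maf_bins` object.
#' @export
maf_bin_scheme <- function(edges = c(0, 0.005, 0.01, 0.05, 0.1, 0.2, 0.3,
                                     0.4, 0.5)) {
  stopifnot(length(edges) >= 2, !is.unsorted(edges, strictly = TRUE),
            edges[1] == 0, edges[length(edges)] == 0.5)
  structure(list(edges = edges), class = "bge_maf_bins")
}

#' Assign minor allele frequencies to bins
#'
#' @param maf Numeric vector of MAFs in `[0, 0.5]`.
#' @param scheme A [maf_bin_scheme()].
#' @return Integer bin index (1-based); `NA` for missing MAFs.
#' @export
assign_maf_bin <- function(maf, scheme = maf_bin_scheme()) {
  e <- scheme$edges
  idx <- findInterval(maf, e, left.open = TRUE)   # (lo, hi] bins
  idx[!is.na(maf) & maf == 0] <- 1L               # first bin closed at 0
  idx[!is.na(maf) & (maf < 0 | maf > e[length(e)])] <- NA_integer_
  as.integer(idx)
}

bin_frame <- function(scheme) {
  e <- scheme$edges
  data.frame(bin = seq_len(length(e) - 1L), bin_lo = e[-length(e)],
             bin_hi = e[-1])
}

#' Hard-call a genotype from imputation output
#'
#' `argmax_gp` returns the genotype with the largest posterior probability
#' (ties to the smaller genotype); when `gp_threshold` is set, genotypes
#' whose maximum GP falls below it become missing. `round_ds` rounds the
#' dosage to the nearest integer with ties to even.
#'
#' @param ds Dosage matrix/vector (required for `round_ds`).
#' @param gp List of three matrices `g0`,`g1`,`g2` (required for
#'   `argmax_gp`).
#' @param rule `"argmax_gp"` or `"round_ds"`.
#' @param gp_threshold Optional minimum max-GP.
#' @return Integer genotypes in \{0,1,2,NA\}, same shape as the input.
#' @export
hard_call <- function(ds = NULL, gp = NULL, rule = c("argmax_gp", "round_ds"),
                      gp_threshold = NULL) {
  rule <- match.arg(rule)
  if (rule == "argmax_gp") {
    if (is.null(gp)) stop("argmax_gp requires GP", call. = FALSE)
    g <- ifelse(gp$g1 > gp$g0, 1L, 0L)
    top <- pmax(gp$g0, gp$g1)
    g <- ifelse(gp$g2 > top, 2L, g)
    top <- pmax(top, gp$g2)
    g[is.na(gp$g0) | is.na(gp$g1) | is.na(gp$g2)] <- NA_integer_
    if (!is.null(gp_threshold)) g[!is.na(top) & top < gp_threshold] <- NA_integer_
    if (is.matrix(gp$g0)) g <- matrix(g, nrow(gp$g0), ncol(gp$g0),
                                      dimnames = dimnames(gp$g0))
    g
  } else {
    if (is.null(ds)) stop("round_ds requires DS", call. = FALSE)
    g <- as.integer(round(ds))   # banker's rounding: 1.5 -> 2, 0.5 -> 0
    if (is.matrix(ds)) g <- matrix(g, nrow(ds), ncol(ds), dimnames = dimnames(ds))
    g
  }
}

#' Classify a truth/test genotype pair
#'
#' Missing on either side is `MISSING`; a non-reference truth genotype
#' reproduced exactly is `TP`; any other call at a non-reference truth
#' genotype (including the het/hom-alt mismatch) is `FN`; a non-reference
#' call at a reference truth genotype is `FP`; agreement at reference is
#' `TN`. Each compared genotype therefore contributes exactly one count.
#'
#' @param truth,test Integer genotypes (vectors or matrices) in
#'   \{0,1,2,NA\}.
#' @return Character vector of classes.
#' @export
classify_pair <- function(truth, test) {
  t <- as.vector(truth); x <- as.vector(test)
  out <- rep("MISSING", length(t))
  ok <- !is.na(t) & !is.na(x)
  out[ok & t > 0 & x == t] <- "TP"
  out[ok & t > 0 & x != t] <- "FN"
  out[ok & t == 0 & x > 0] <- "FP"
  out[ok & t == 0 & x == 0] <- "TN"
  out
}

#' Tally concordance counts
#'
#' @param truth,test Genotype vectors/matrices.
#' @return Named integer vector `tp`, `fp`, `fn`, `tn`, `missing`.
#' @export
concordance_counts <- function(truth, test) {
  cls <- classify_pair(truth, test)
  c(tp = sum(cls == "TP"), fp = sum(cls == "FP"), fn = sum(cls == "FN"),
    tn = sum(cls == "TN"), missing = sum(cls == "MISSING"))
}

#' Non-reference concordance
#'
#' `TP / (TP + FP + FN)`: credit only for agreeing non-reference genotypes,
#' over all pairs where either side carries the alternate allele.
#'
#' @param counts Output of [concordance_counts()] (or any named vector with
#'   `tp`, `fp`, `fn`).
#' @return The concordance, or `NA` when no pair involves a non-reference
#'   allele.
#' @export
nonref_concordance <- function(counts) {
  den <- counts[["tp"]] + counts[["fp"]] + counts[["fn"]]
  if (den == 0) return(NA_real_)
  counts[["tp"]] / den
}

#' Non-reference concordance per MAF bin
#'
#' In `aggregate` mode (the default, and the mode preferred for rare
#' variants), TP/FP/FN counts are pooled over every genotype of every SNP
#' in a bin before the ratio is taken; SNPs whose truth column is all
#' reference still contribute their genotypes to the pool. In
#' `per_snp_mean` mode the concordance is computed per SNP -- excluding
#' SNPs with missing or only-reference truth genotypes -- and averaged.
#' Averaging deflates rare-variant accuracy whenever a SNP's few minor
#' alleles happen to sit in another stratum, which is why the pooled form
#' exists.
#'
#' @param truth,test Samples x sites genotype matrices.
#' @param maf Per-site minor allele frequencies used for binning.
#' @param scheme A [maf_bin_scheme()].
#' @param mode `"aggregate"` or `"per_snp_mean"`.
#' @return Data frame with `bin_lo`, `bin_hi`, `n_snps`, `n_genotypes`,
#'   `concordance`.
#' @export
nonref_concordance_by_bin <- function(truth, test, maf,
                                      scheme = maf_bin_scheme(),
                                      mode = c("aggregate", "per_snp_mean")) {
  mode <- match.arg(mode)
  stopifnot(all(dim(truth) == dim(test)), ncol(truth) == length(maf))
  bins <- assign_maf_bin(maf, scheme)
  out <- bin_frame(scheme)
  out$n_snps <- 0L; out$n_genotypes <- 0L; out$concordance <- NA_real_
  for (b in out$bin) {
    js <- which(!is.na(bins) & bins == b)
    if (length(js) == 0) next
    tt <- truth[, js, drop = FALSE]; xx <- test[, js, drop = FALSE]
    out$n_snps[b] <- length(js)
    if (mode == "aggregate") {
      cnt <- concordance_counts(tt, xx)
      out$n_genotypes[b] <- sum(cnt[c("tp", "fp", "fn", "tn")])
      out$concordance[b] <- nonref_concordance(cnt)
    } else {
      vals <- vapply(seq_along(js), function(k) {
        t1 <- tt[, k]; x1 <- xx[, k]
        ok <- !is.na(t1) & !is.na(x1)
        if (!any(ok) || all(t1[ok] == 0)) return(NA_real_)
        nonref_concordance(concordance_counts(t1, x1))
      }, numeric(1))
      out$n_genotypes[b] <- sum(!is.na(truth[, js]) & !is.na(test[, js]))
      out$concordance[b] <- mean(vals, na.rm = TRUE)
    }
  }
  out$bin <- NULL
  out
}

#' Aggregate R-squared per MAF bin
#'
#' Stacks the truth genotype calls and imputed dosages of every SNP in a
#' MAF bin into two vectors (dropping pairs with a missing entry) and
#' reports the squared Pearson correlation, together with the number of
#' stacked genotypes.
#'
#' @param truth Samples x sites genotype matrix (array truth).
#' @param ds Samples x sites dosage matrix.
#' @param maf Per-site minor allele frequencies used for binning.
#' @param scheme A [maf_bin_scheme()].
#' @return Data frame with `bin_lo`, `bin_hi`, `n_snps`, `n_genotypes`,
#'   `r2`, `reason` (why a bin is NA: `empty_bin` or `zero_variance`).
#' @export
aggregate_r2 <- function(truth, ds, maf, scheme = maf_bin_scheme()) {
  stopifnot(all(dim(truth) == dim(ds)), ncol(truth) == length(maf))
  bins <- assign_maf_bin(maf, scheme)
  out <- bin_frame(scheme)
  out$n_snps <- 0L; out$n_genotypes <- 0L
  out$r2 <- NA_real_; out$reason <- NA_character_
  for (b in out$bin) {
    js <- which(!is.na(bins) & bins == b)
    if (length(js) == 0) { out$reason[b] <- "empty_bin"; next }
    tv <- as.vector(truth[, js, drop = FALSE])
    dv <- as.vector(ds[, js, drop = FALSE])
    ok <- !is.na(tv) & !is.na(dv)
    out$n_snps[b] <- length(js)
    out$n_genotypes[b] <- sum(ok)
    if (!any(ok) || sd(tv[ok]) == 0 || sd(dv[ok]) == 0) {
      out$reason[b] <- "zero_variance"
      next
    }
    out$r2[b] <- cor(tv[ok], dv[ok])^2
  }
  out$bin <- NULL
  out
}

#' Filter sites on imputation INFO score
#'
#' Keeps sites with `info >= min_info` (inclusive) and reports how many
#' dropped sites fall in each MAF bin (rare variants dominate the removals
#' in practice).
#'
#' @param sites Site table with `info` and either `maf` or `af`.
#' @param min_info Threshold, default 0.8.
#' @param scheme A [maf_bin_scheme()] for the dropped-site histogram.
#' @return List with `keep` (logical; NA INFO never passes), `sites`
#'   (retained rows), `dropped_by_maf` (bin table with `n_dropped`).
#' @export
info_filter <- function(sites, min_info = 0.8, scheme = maf_bin_scheme()) {
  info <- sites$info
  if (all(is.na(info))) warning("all INFO scores missing: every site dropped")
  keep <- !is.na(info) & info >= min_info
  maf <- if (!is.null(sites$maf)) sites$maf else pmin(sites$af, 1 - sites$af)
  bins <- assign_maf_bin(maf[!keep], scheme)
  hist <- bin_frame(scheme)
  hist$n_dropped <- vapply(hist$bin, function(b) sum(bins == b, na.rm = TRUE),
                           1L)
  hist$bin <- NULL
  list(keep = keep, sites = sites[keep, , drop = FALSE],
       dropped_by_maf = hist)
}

#' Sweep a genotype-probability filter and track aggregate R-squared
#'
#' For each threshold, genotypes whose maximum GP falls below it are
#' removed from the stacks before [aggregate_r2()] is recomputed; the
#' overall fraction of genotypes dropped is reported alongside.
#'
#' @param truth Samples x sites genotype matrix.
#' @param ds Dosage matrix.
#' @param gp List of three GP matrices.
#' @param thresholds Numeric vector of max-GP thresholds.
#' @param maf Per-site MAFs.
#' @param scheme A [maf_bin_scheme()].
#' @return Data frame with `threshold`, `bin_lo`, `bin_hi`, `n_genotypes`,
#'   `r2`, `fraction_dropped` (overall, repeated within threshold).
#' @export
gp_filter_sweep <- function(truth, ds, gp, thresholds, maf,
                            scheme = maf_bin_scheme()) {
  maxgp <- pmax(gp$g0, gp$g1, gp$g2)
  n_total <- sum(!is.na(ds))
  res <- list()
  for (th in thresholds) {
    d2 <- ds
    d2[!is.na(maxgp) & maxgp < th] <- NA_real_
    tab <- aggregate_r2(truth, d2, maf, scheme)
    tab$threshold <- th
    tab$fraction_dropped <- 1 - sum(!is.na(d2)) / n_total
    res[[length(res) + 1]] <- tab
  }
  out <- do.call(rbind, res)
  out[c("threshold", "bin_lo", "bin_hi", "n_snps", "n_genotypes", "r2",
        "fraction_dropped")]
}
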