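#' Infer genetic sex from X-chromosome inbreeding
#'
#' Computes, per sample, the X inbreeding coefficient
#' `F = 1 - O_het / E_het`, where `E_het = sum 2 p (1 - p)` over that
#' sample's called sites (non-pseudoautosomal X, common independent markers).
#' Samples with `F < 0.6` are labelled female and `F > 0.6` male; `F`
#' exactly 0.6, or fewer than `min_sites` called sites, yields
#' `undetermined`.
#'
#' @param x_genotypes Samples x sites matrix of diploid-coded X genotypes
#'   (0/1/2/NA); hemizygous males appear as homozygotes.
#' @param afs Optional per-site allele frequencies; defaults to in-sample.
#' @param maf_min Minimum MAF for a site to be used.
#' @param min_sites Minimum called sites per sample.
#' @param f_cut Decision boundary (default 0.6).
#' @return Data frame with `sample`, `f`, `sex`
#'   (`female`/`male`/`undetermined`).
#' @export
infer_sex <- function(x_genotypes, afs = NULL, maf_min = 0.05,
                      min_sites = 20, f_cut = 0.6) {
  if (ncol(x_genotypes) == 0) stop("no X-chromosome sites", call. = FALSE)
  if (is.null(afs)) afs <- colMeans(x_genotypes, na.rm = TRUE) / 2
  use <- !is.na(afs) & pmin(afs, 1 - afs) >= maf_min
  if (!any(use)) stop("no X sites pass the MAF filter", call. = FALSE)
  g <- x_genotypes[, use, drop = FALSE]
  p <- afs[use]
  eh_site <- 2 * p * (1 - p)
  called <- !is.na(g)
  n_called <- rowSums(called)
  o_het <- rowSums(g == 1L, na.rm = TRUE)
  e_het <- called %*% eh_site
  f <- 1 - o_het / as.vector(e_het)
  sex <- ifelse(f < f_cut, "female", ifelse(f > f_cut, "male", "undetermined"))
  sex[n_called < min_sites] <- "undetermined"
  data.frame(sample = rownames(x_genotypes) %||% seq_len(nrow(g)),
             f = f, sex = sex, stringsAsFactors = FALSE, row.names = NULL)
}

#' HWE-normalized principal component analysis of genotypes
#'
#' Centers each site at `2p` and scales by `sqrt(2 p (1 - p))` (the binomial
#' standard deviation under Hardy-Weinberg equilibrium), sets missing
#' entries to 0 after centering, and takes a truncated SVD. Constant or
#' monomorphic sites are dropped with a count. Component signs are fixed by
#' making the largest-magnitude loading of each component positive, so
#' scores are deterministic.
#'
#' @param genotypes Samples x sites matrix (0/1/2/NA).
#' @param n_pcs Number of components (capped at the matrix rank, with a
#'   warning).
#' @return List with `scores` (samples x PCs), `loadings` (sites x PCs),
#'   `d` (singular values), `kept_sites` (logical), `n_dropped`.
#' @export
hwe_normalized_pca <- function(genotypes, n_pcs = 10) {
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  n_dropped <- sum(!keep)
  g <- genotypes[, keep, drop = FALSE]
  p <- p[keep]
  m <- sweep(g, 2, 2 * p)
  m[is.na(m)] <- 0
  m <- sweep(m, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(m)
  rank <- sum(sv$d > max(dim(m)) * .Machine$double.eps * sv$d[1])
  if (n_pcs > rank) {
    warning(sprintf("n_pcs reduced from %d to matrix rank %d", n_pcs, rank))
    n_pcs <- rank
  }
  u <- sv$u[, seq_len(n_pcs), drop = FALSE]
  v <- sv$v[, seq_len(n_pcs), drop = FALSE]
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  scores <- sweep(u, 2, sv$d[seq_len(n_pcs)], "*")
  rownames(scores) <- rownames(genotypes)
  list(scores = scores, loadings = v, d = sv$d[seq_len(n_pcs)],
       kept_sites = keep, n_dropped = n_dropped)
}

#' Probabilistic ancestry assignment by k-nearest-neighbour vote
#'
#' For each query sample, finds the `k` nearest reference samples in the
#' top-`n_pcs` principal-component space (Euclidean distance, ties broken by
#' reference order) and reports the modal reference label together with the
#' fraction of neighbours carrying it. The label is assigned only when that
#' fraction reaches `threshold`; otherwise the sample is `unassigned`. A
#' deterministic stand-in for random-forest classifiers whose
#' hyperparameters vary between sites.
#'
#' @param sample_pcs Query samples x PCs score matrix.
#' @param ref_pcs Reference samples x PCs score matrix (same PC space).
#' @param ref_labels Reference ancestry labels.
#' @param k Neighbourhood size (reduced with a warning if fewer references).
#' @param threshold Minimum vote fraction to assign (default 0.7).
#' @param n_pcs Number of leading PCs used (default 10, capped at available).
#' @return Data frame with `sample`, `label` (`unassigned` if below
#'   threshold), `probability`.
#' @export
assign_ancestry <- function(sample_pcs, ref_pcs, ref_labels, k = 50,
                            threshold = 0.7, n_pcs = 10) {
  sample_pcs <- as.matrix(sample_pcs); ref_pcs <- as.matrix(ref_pcs)
  d <- min(n_pcs, ncol(sample_pcs), ncol(ref_pcs))
  sample_pcs <- sample_pcs[, seq_len(d), drop = FALSE]
  ref_pcs <- ref_pcs[, seq_len(d), drop = FALSE]
  if (k > nrow(ref_pcs)) {
    warning(sprintf("k reduced from %d to %d reference samples", k,
                    nrow(ref_pcs)))
    k <- nrow(ref_pcs)
  }
  ref_labels <- as.character(ref_labels)
  n <- nrow(sample_pcs)
  lab <- character(n); prob <- numeric(n)
  for (i in seq_len(n)) {
    dist2 <- colSums((t(ref_pcs) - sample_pcs[i, ])^2)
    nn <- order(dist2)[seq_len(k)]
    votes <- sort(table(ref_labels[nn]), decreasing = TRUE)
    prob[i] <- votes[1] / k
    lab[i] <- if (prob[i] >= threshold) names(votes)[1] else "unassigned"
  }
  data.frame(sample = rownames(sample_pcs) %||% seq_len(n), label = lab,
             probability = prob, stringsAsFactors = FALSE, row.names = NULL)
}

#' Greedy LD pruning to near-independent markers
#'
#' Left-to-right scan over position-sorted sites: a site is dropped when its
#' genotype correlation with any previously retained site closer than
#' `window_bp` exceeds `sqrt(r2_max)` in magnitude. With `window_bp = 0`
#' every site is retained.
#'
#' @param genotypes Samples x sites matrix (0/1/2/NA).
#' @param pos Site positions (must be sorted ascending).
#' @param window_bp Window in bp.
#' @param r2_max Maximum squared correlation allowed within a window.
#' @return Integer indices of retained sites.
#' @export
ld_prune <- function(genotypes, pos, window_bp = 5e5, r2_max = 0.2) {
  stopifnot(!is.unsorted(pos))
  s <- ncol(genotypes)
  keep <- logical(s)
  kept_idx <- integer(0)
  for (j in seq_len(s)) {
    near <- kept_idx[pos[kept_idx] > pos[j] - window_bp]
    ok <- TRUE
    for (i in rev(near)) {
      r2 <- suppressWarnings(cor(genotypes[, i], genotypes[, j],
                                 use = "pairwise.complete.obs"))^2
      if (!is.na(r2) && r2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) { keep[j] <- TRUE; kept_idx <- c(kept_idx, j) }
  }
  which(keep)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the number of heterozygotes given the minor
#' allele count (Wigginton-style recurrence, no mid-p): the p-value is the
#' total probability of heterozygote counts no more likely than the one
#' observed.
#'
#' @param n_het Observed heterozygote count.
#' @param n_hom_minor,n_hom_major Homozygote counts for the rarer and more
#'   common allele.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_het, n_hom_minor, n_hom_major) {
  stopifnot(n_het >= 0, n_hom_minor >= 0, n_hom_major >= 0)
  n <- n_het + n_hom_minor + n_hom_major
  if (n == 0) return(1)
  n_minor <- 2 * n_hom_minor + n_het
  n_major <- 2 * n_hom_major + n_het
  if (n_minor > n_major) { tmp <- n_minor; n_minor <- n_major; n_major <- tmp }
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  probs <- numeric(length(hets))
  mid <- which.min(abs(hets - n_minor * n_major / (2 * n)))  # start near mode
  probs[mid] <- 1
  if (mid < length(hets)) for (i in mid:(length(hets) - 1)) {
    h <- hets[i]
    hom_r <- (n_minor - h) / 2
    hom_c <- (n_major - h) / 2
    # P(h+2)/P(h) = 4 hom_r hom_c / ((h+1)(h+2))
    probs[i + 1] <- probs[i] * 4 * hom_r * hom_c / ((h + 1) * (h + 2))
  }
  if (mid > 1) for (i in mid:2) {
    h <- hets[i]
    hom_r <- (n_minor - h) / 2
    hom_c <- (n_major - h) / 2
    # P(h-2)/P(h) = h (h-1) / (4 (hom_r+1)(hom_c+1))
    probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) stop("inconsistent genotype counts", call. = FALSE)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Per-sample inbreeding F over autosomal sites (plink --het style):
# F = 1 - O(het) / E(het), E from per-site in-sample AFs.
sample_fhet <- function(genotypes, afs = NULL) {
  if (is.null(afs)) afs <- colMeans(genotypes, na.rm = TRUE) / 2
  use <- !is.na(afs) & afs > 0 & afs < 1
  g <- genotypes[, use, drop = FALSE]
  eh <- 2 * afs[use] * (1 - afs[use])
  called <- !is.na(g)
  1 - rowSums(g == 1L, na.rm = TRUE) / as.vector(called %*% eh)
}

#' Staged QC of array genotype data
#'
#' Applies, in order: (1) SNP call rate >= `snp_call_rate1`; (2) sample
#' filters -- call rate >= `sample_call_rate`, autosomal inbreeding
#' `|FHET| < fhet_max`, and (when both sex vectors are given) concordance of
#' inferred and reported sex; (3) SNP call rate >= `snp_call_rate2`;
#' (4) case/control differential missingness <= `diff_miss_max`; (5) exact
#' HWE with separate thresholds for controls and cases. Stages (4) and (5)
#' use the HWE test within controls and cases when `status` is given;
#' without labels, differential missingness is skipped and HWE runs on all
#' samples at the control threshold.
#'
#' @param genotypes Samples x sites matrix (0/1/2/NA).
#' @param status Optional logical vector, `TRUE` = case.
#' @param reported_sex,inferred_sex Optional label vectors for the sex
#'   concordance check.
#' @param snp_call_rate1,snp_call_rate2 SNP call-rate thresholds.
#' @param sample_call_rate Sample call-rate threshold.
#' @param fhet_max Bound on `|FHET|` (exclusive).
#' @param diff_miss_max Maximum case/control missingness difference.
#' @param hwe_p_controls,hwe_p_cases HWE p-value floors.
#' @return List with `genotypes` (retained block), `kept_samples`,
#'   `kept_sites` (indices into the input), and `report` (stage-wise removal
#'   counts).
#' @export
array_qc <- function(genotypes, status = NULL,
                     reported_sex = NULL, inferred_sex = NULL,
                     snp_call_rate1 = 0.95, snp_call_rate2 = 0.98,
                     sample_call_rate = 0.98, fhet_max = 0.20,
                     diff_miss_max = 0.02,
                     hwe_p_controls = 1e-6, hwe_p_cases = 1e-10) {
  n <- nrow(genotypes)
  samp_idx <- seq_len(n)
  site_idx <- seq_len(ncol(genotypes))
  report <- c()
  g <- genotypes

  cr_site <- colMeans(!is.na(g))
  keep <- cr_site >= snp_call_rate1
  report["snp_call_rate1"] <- sum(!keep)
  g <- g[, keep, drop = FALSE]; site_idx <- site_idx[keep]

  cr_samp <- rowMeans(!is.na(g))
  fhet <- sample_fhet(g)
  keep_s <- cr_samp >= sample_call_rate & abs(fhet) < fhet_max
  report["sample_call_rate"] <- sum(cr_samp < sample_call_rate)
  report["fhet"] <- sum(!(abs(fhet) < fhet_max), na.rm = TRUE)
  if (!is.null(reported_sex) && !is.null(inferred_sex)) {
    disc <- as.character(reported_sex) != as.character(inferred_sex)
    keep_s <- keep_s & !disc
    report["sex_discordant"] <- sum(disc)
  }
  g <- g[keep_s, , drop = FALSE]; samp_idx <- samp_idx[keep_s]
  if (!is.null(status)) status <- status[keep_s]

  cr_site <- colMeans(!is.na(g))
  keep <- cr_site >= snp_call_rate2
  report["snp_call_rate2"] <- sum(!keep)
  g <- g[, keep, drop = FALSE]; site_idx <- site_idx[keep]

  if (!is.null(status) && any(status) && any(!status)) {
    miss_ca <- colMeans(is.na(g[status, , drop = FALSE]))
    miss_co <- colMeans(is.na(g[!status, , drop = FALSE]))
    keep <- abs(miss_ca - miss_co) <= diff_miss_max
    report["diff_missingness"] <- sum(!keep)
    g <- g[, keep, drop = FALSE]; site_idx <- site_idx[keep]
  }

  hwe_p <- function(block) {
    vapply(seq_len(ncol(block)), function(j) {
      x <- block[, j]
      hwe_exact_test(sum(x == 1L, na.rm = TRUE),
                     sum(x == 2L, na.rm = TRUE),
                     sum(x == 0L, na.rm = TRUE))
    }, numeric(1))
  }
  if (!is.null(status) && any(status) && any(!status)) {
    keep <- hwe_p(g[!status, , drop = FALSE]) >= hwe_p_controls &
            hwe_p(g[status, , drop = FALSE]) >= hwe_p_cases
  } else {
    keep <- hwe_p(g) >= hwe_p_controls
  }
  report["hwe"] <- sum(!keep)
  g <- g[, keep, drop = FALSE]; site_idx <- site_idx[keep]

  list(genotypes = g, kept_samples = samp_idx, kept_sites = site_idx,
       report = report)
}
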