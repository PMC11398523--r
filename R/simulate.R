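#' Simulate per-ancestry allele frequencies under Balding-Nichols divergence
#'
#' Ancestral frequencies are drawn uniformly on `ancestral_af_range`; each
#' ancestry's frequency at a site is then an independent
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` draw, so that `E[af] = p` and
#' `Var[af] = F p (1-p)`. This is the simplest standard model producing
#' ancestry-differentiated frequencies.
#'
#' @param config A [cohort_config()].
#' @return A numeric matrix (ancestry x site) of allele frequencies in (0,1),
#'   rownames the ancestry labels, with the ancestral frequencies attached as
#'   attribute `"ancestral"`.
#' @export
simulate_population_afs <- function(config) {
  validate_cohort_config(config)
  .substream(config$seed, 101L)
  s <- config$n_sites
  k <- length(config$ancestries)
  p <- runif(s, config$ancestral_af_range[1], config$ancestral_af_range[2])
  afs <- matrix(NA_real_, k, s, dimnames = list(config$ancestries, NULL))
  for (i in seq_len(k)) {
    f <- config$divergence_fst[i]
    a <- p * (1 - f) / f
    b <- (1 - p) * (1 - f) / f
    x <- rbeta(s, a, b)
    # rbeta can underflow to exactly 0/1 for tiny shapes; keep AFs in (0,1)
    afs[i, ] <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  }
  attr(afs, "ancestral") <- p
  afs
}

#' Simulate local-ancestry tracts for every haplotype
#'
#' Tract breakpoints follow a Poisson process with rate
#' `generations_since_admixture` per Morgan under a uniform 1 cM/Mb map
#' (1 Morgan = 1e8 bp); each tract's ancestry is drawn independently from the
#' admixture proportions. Tracts tile `[1, chrom_length_bp + 1)` as half-open
#' bp intervals, emulating the merged output of a local ancestry caller.
#'
#' @param config A [cohort_config()].
#' @return A `bge_tracts` data frame with columns `sample`, `hap` (0/1),
#'   `chrom`, `spos`, `epos` (1-based half-open) and `anc` (0-based integer
#'   ancestry code); attribute `"ancestries"` maps codes to labels.
#' @export
simulate_tracts <- function(config) {
  validate_cohort_config(config)
  .substream(config$seed, 202L)
  n <- config$n_samples
  len <- config$chrom_length_bp
  g <- config$generations_since_admixture
  morgans <- len / 1e8
  k <- length(config$ancestries)
  ids <- sample_ids(n)
  nhap <- 2L * n
  nbreak <- rpois(nhap, g * morgans)
  total <- sum(nbreak) + nhap
  samp <- character(total); hap <- integer(total)
  spos <- numeric(total); epos <- numeric(total)
  at <- 1L
  for (h in seq_len(nhap)) {
    nb <- nbreak[h]
    if (nb > 0) {
      br <- sort(unique(floor(runif(nb, 2, len + 1))))
      nb <- length(br)
    } else br <- numeric(0)
    nt <- nb + 1L
    idx <- at:(at + nt - 1L)
    samp[idx] <- ids[(h + 1L) %/% 2L]
    hap[idx] <- (h - 1L) %% 2L
    spos[idx] <- c(1, br)
    epos[idx] <- c(br, len + 1)
    at <- at + nt
  }
  samp <- samp[seq_len(at - 1L)]; hap <- hap[seq_len(at - 1L)]
  spos <- spos[seq_len(at - 1L)]; epos <- epos[seq_len(at - 1L)]
  anc <- sample.int(k, at - 1L, replace = TRUE,
                    prob = config$admixture_proportions) - 1L
  tr <- data.frame(sample = samp, hap = hap, chrom = "chr1",
                   spos = spos, epos = epos, anc = anc,
                   stringsAsFactors = FALSE)
  new_tracts(tr, config$ancestries)
}

new_tracts <- function(df, ancestries) {
  stopifnot(all(c("sample", "hap", "chrom", "spos", "epos", "anc") %in% names(df)))
  attr(df, "ancestries") <- ancestries
  class(df) <- c("bge_tracts", "data.frame")
  df
}

sample_ids <- function(n) sprintf("S%05d", seq_len(n))

#' Ancestry codes of one haplotype at query positions
#'
#' @param tracts A `bge_tracts` table.
#' @param sample Sample id.
#' @param hap Haplotype index, 0 or 1.
#' @param pos Vector of bp positions.
#' @return Integer ancestry codes; `NA` where no tract covers the position
#'   (tracts are half-open `[spos, epos)`).
#' @export
tract_codes_at <- function(tracts, sample, hap, pos) {
  t <- tracts[tracts$sample == sample & tracts$hap == hap, , drop = FALSE]
  codes_from_tract_rows(t[order(t$spos), , drop = FALSE], pos)
}

codes_from_tract_rows <- function(t, pos) {
  if (is.null(t) || nrow(t) == 0) return(rep(NA_integer_, length(pos)))
  i <- findInterval(pos, t$spos)
  out <- rep(NA_integer_, length(pos))
  ok <- i >= 1 & pos < t$epos[pmax(i, 1L)]
  out[ok] <- t$anc[i[ok]]
  out
}

# One pass split of a tract table keyed "sample|hap", rows sorted by spos.
split_tracts <- function(tracts) {
  key <- paste(tracts$sample, tracts$hap, sep = "|")
  ord <- order(key, tracts$spos)
  t <- tracts[ord, , drop = FALSE]
  split(t[c("spos", "epos", "anc")], paste(t$sample, t$hap, sep = "|"))
}

# n_samples x n_sites integer code matrices for both haplotypes.
ancestry_code_matrices <- function(tracts, samples, pos) {
  n <- length(samples); s <- length(pos)
  a0 <- matrix(NA_integer_, n, s, dimnames = list(samples, NULL))
  a1 <- a0
  spl <- split_tracts(tracts)
  for (i in seq_len(n)) {
    a0[i, ] <- codes_from_tract_rows(spl[[paste(samples[i], 0L, sep = "|")]], pos)
    a1[i, ] <- codes_from_tract_rows(spl[[paste(samples[i], 1L, sep = "|")]], pos)
  }
  list(a0, a1)
}

#' Simulate ground-truth haplotypes and genotypes for an admixed cohort
#'
#' Draws per-ancestry allele frequencies ([simulate_population_afs()]) and
#' ancestry tracts ([simulate_tracts()]), then sets each haplotype allele to
#' `Bernoulli(af[local ancestry, site])`. Genotype = sum of the two
#' haplotypes.
#'
#' @param config A [cohort_config()].
#' @return A `bge_truth` list: `genotypes` (samples x sites, 0/1/2), `hap0`,
#'   `hap1` (binary matrices), `tracts`, `per_ancestry_afs`, and `sites`
#'   (data frame chrom/pos/ref/alt/af with `af` the expected admixture-weighted
#'   frequency).
#' @export
simulate_truth <- function(config) {
  validate_cohort_config(config)
  afs <- simulate_population_afs(config)
  tracts <- simulate_tracts(config)
  .substream(config$seed, 303L)
  n <- config$n_samples; s <- config$n_sites
  pos <- sort(sample.int(config$chrom_length_bp, s))
  ids <- sample_ids(n)
  site_ids <- sprintf("chr1:%d", pos)
  hap0 <- matrix(0L, n, s, dimnames = list(ids, site_ids))
  hap1 <- hap0
  spl <- split_tracts(tracts)
  for (i in seq_len(n)) {
    c0 <- codes_from_tract_rows(spl[[paste(ids[i], 0L, sep = "|")]], pos)
    c1 <- codes_from_tract_rows(spl[[paste(ids[i], 1L, sep = "|")]], pos)
    hap0[i, ] <- as.integer(runif(s) < afs[cbind(c0 + 1L, seq_len(s))])
    hap1[i, ] <- as.integer(runif(s) < afs[cbind(c1 + 1L, seq_len(s))])
  }
  sites <- data.frame(
    chrom = "chr1", pos = pos, ref = "A", alt = "G",
    af = as.numeric(config$admixture_proportions %*% afs),
    stringsAsFactors = FALSE
  )
  structure(list(genotypes = hap0 + hap1, hap0 = hap0, hap1 = hap1,
                 tracts = tracts, per_ancestry_afs = afs, sites = sites,
                 samples = ids, config = config),
            class = "bge_truth")
}

#' @exportS3Method print bge_truth
print.bge_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d samples x %d sites, ancestries %s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              paste(attr(x$tracts, "ancestries"), collapse = "/")))
  invisible(x)
}

#' Simulate low-pass imputed dosages via read resampling and an HWE prior
#'
#' Emulates the posterior output of low-coverage imputation: each genotype
#' receives `c ~ Poisson(lambda)` reads, of which
#' `Binomial(c, mu_g)` carry the alternate allele with `mu_0 = eps`,
#' `mu_1 = 0.5`, `mu_2 = 1 - eps`. The posterior over \{0,1,2\} combines the
#' binomial read likelihood with a Hardy-Weinberg prior at the site's cohort
#' allele frequency (estimated from the truth genotypes). `GP` is the
#' posterior triple and `DS = GP1 + 2 GP2`; with zero reads the posterior
#' equals the prior, so `DS = 2 AF` exactly.
#'
#' A per-site INFO score is computed as
#' `1 - mean(posterior variance) / (2 p (1-p))` with `p = mean(DS)/2`,
#' clamped to `[0, 1]` (the standard ratio of observed to binomial dosage
#' variance).
#'
#' @param truth A `bge_truth` bundle.
#' @param config A [cohort_config()]; `mean_coverage` may be a scalar or an
#'   n x s matrix of per-genotype lambdas.
#' @return A `bge_dosages` list: `ds` (samples x sites), `gp` (list of three
#'   matrices `g0`,`g1`,`g2`), `sites` (with `af` = mean dosage / 2 and
#'   `info`), `samples`.
#' @export
simulate_lowpass_dosages <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "bge_truth"))
  .substream(config$seed, 404L)
  g <- truth$genotypes
  n <- nrow(g); s <- ncol(g)
  eps <- config$base_error
  lam <- config$mean_coverage
  if (is.matrix(lam)) stopifnot(nrow(lam) == n, ncol(lam) == s)
  p_hat <- colMeans(g) / 2
  degen <- p_hat <= 0 | p_hat >= 1
  if (any(degen))
    warning(sprintf("%d site(s) monomorphic in cohort: prior-only dosages returned",
                    sum(degen)))
  gp0 <- matrix(NA_real_, n, s, dimnames = dimnames(g))
  gp1 <- gp0
  gp2 <- gp0
  # site-chunked so peak memory stays modest at cohort scale
  chunk <- max(1L, min(s, ceiling(4e6 / n)))
  for (j0 in seq(1L, s, by = chunk)) {
    js <- j0:min(s, j0 + chunk - 1L)
    gc_ <- g[, js, drop = FALSE]
    m <- length(gc_)
    lam_c <- if (is.matrix(lam)) lam[, js, drop = FALSE] else lam
    dep <- rpois(m, lam_c)
    mu <- c(eps, 0.5, 1 - eps)[gc_ + 1L]
    alt <- rbinom(m, dep, mu)
    post <- genotype_posterior(alt, dep, rep(p_hat[js], each = n), eps)
    gp0[, js] <- post$g0
    gp1[, js] <- post$g1
    gp2[, js] <- post$g2
  }
  ds <- gp1 + 2 * gp2
  af_est <- colMeans(ds) / 2
  pv <- gp1 + 4 * gp2 - ds^2          # per-genotype posterior variance
  denom <- 2 * af_est * (1 - af_est)
  info <- ifelse(denom > 0, 1 - colMeans(pv) / denom, NA_real_)
  info <- pmin(pmax(info, 0), 1)
  sites <- truth$sites
  sites$af <- af_est
  sites$info <- info
  structure(list(ds = ds, gp = list(g0 = gp0, g1 = gp1, g2 = gp2),
                 sites = sites, samples = truth$samples),
            class = "bge_dosages")
}

#' @exportS3Method print bge_dosages
print.bge_dosages <- function(x, ...) {
  cat(sprintf("Imputed dosages: %d samples x %d sites (median INFO %.3f)\n",
              nrow(x$ds), ncol(x$ds), median(x$sites$info, na.rm = TRUE)))
  invisible(x)
}

#' Posterior genotype probabilities from pileup counts under an HWE prior
#'
#' Combines the binomial read likelihood (`alt ~ Binomial(depth, mu_g)` with
#' `mu_0 = eps`, `mu_1 = 0.5`, `mu_2 = 1 - eps`) with a Hardy-Weinberg prior
#' at allele frequency `af`. With zero depth the posterior equals the prior;
#' if the likelihood annihilates a degenerate prior the prior is returned.
#'
#' @param alt Alternate-allele read counts (vectorized).
#' @param depth Total read depths.
#' @param af Site allele frequencies (prior).
#' @param base_error Per-read base error rate.
#' @return List of numeric vectors `g0`, `g1`, `g2` summing to 1.
#' @examples
#' genotype_posterior(2, 4, 0.5, 0.01) # heterozygote favoured
#' @export
genotype_posterior <- function(alt, depth, af, base_error) {
  eps <- base_error
  af <- rep_len(af, max(length(alt), length(depth), length(af)))
  w0 <- (1 - af)^2 * dbinom(alt, depth, eps)
  w1 <- 2 * af * (1 - af) * dbinom(alt, depth, 0.5)
  w2 <- af^2 * dbinom(alt, depth, 1 - eps)
  tot <- w0 + w1 + w2
  bad <- tot <= 0    # all posterior mass annihilated; fall back to prior
  if (any(bad)) {
    w0[bad] <- (1 - af[bad])^2
    w1[bad] <- 2 * af[bad] * (1 - af[bad])
    w2[bad] <- af[bad]^2
    tot[bad] <- w0[bad] + w1[bad] + w2[bad]
  }
  list(g0 = w0 / tot, g1 = w1 / tot, g2 = w2 / tot)
}

#' Simulate array genotypes with genotyping error and missingness
#'
#' Each truth genotype is independently set missing with
#' `array_missing_rate`; otherwise it is perturbed, with probability
#' `array_error_rate`, to one of the two other genotypes chosen uniformly.
#'
#' @param truth A `bge_truth` bundle.
#' @param config A [cohort_config()].
#' @return Integer matrix (samples x sites) in \{0,1,2,NA\}.
#' @export
simulate_array_genotypes <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "bge_truth"))
  .substream(config$seed, 505L)
  g <- truth$genotypes
  n <- length(g)
  out <- g
  miss <- runif(n) < config$array_missing_rate
  err <- !miss & runif(n) < config$array_error_rate
  if (any(err)) {
    shift <- sample.int(2L, sum(err), replace = TRUE)  # +1 or +2 mod 3
    out[err] <- (g[err] + shift) %% 3L
  }
  out[miss] <- NA_integer_
  out
}

#' Split cohort samples into imputation batches
#'
#' Contiguous blocks in sample order, mirroring randomized batch submission
#' with a fixed batch size.
#'
#' @param samples Character vector of sample ids.
#' @param n_batches Number of batches.
#' @return List of character vectors.
#' @export
split_batches <- function(samples, n_batches) {
  stopifnot(n_batches >= 1, n_batches <= length(samples))
  split(samples, cut(seq_along(samples), n_batches, labels = FALSE))
}
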