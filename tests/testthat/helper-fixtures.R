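# Shared fixtures, built in code at test time.

tiny_config <- function(n_samples = 40, n_sites = 200, seed = 42L, ...) {
  cohort_config(n_samples = n_samples, n_sites = n_sites, seed = seed, ...)
}

# Deterministic two-cluster genotype matrix: two populations fixed for
# opposite alleles at half the sites, HWE at p = 0.5 elsewhere.
two_pop_genotypes <- function(n_per = 30, n_sites = 120, seed = 1) {
  set.seed(seed)
  half <- n_sites %/% 2
  popa <- cbind(matrix(2L, n_per, half),
                matrix(rbinom(n_per * (n_sites - half), 2, 0.5), n_per))
  popb <- cbind(matrix(0L, n_per, half),
                matrix(rbinom(n_per * (n_sites - half), 2, 0.5), n_per))
  g <- rbind(popa, popb)
  rownames(g) <- sprintf("P%03d", seq_len(2 * n_per))
  list(genotypes = g, pop = rep(c("A", "B"), each = n_per))
}

# Hand-built tract table: one sample, hap0 AFR on [1, 5e7), EUR after;
# hap1 all EUR.
toy_tracts <- function(len = 1e8) {
  new_tr <- function(df) {
    attr(df, "ancestries") <- c("AFR", "EUR")
    class(df) <- c("bge_tracts", "data.frame")
    df
  }
  new_tr(data.frame(
    sample = "S1", hap = c(0L, 0L, 1L), chrom = "chr1",
    spos = c(1, 5e7, 1), epos = c(5e7, len + 1, len + 1),
    anc = c(0L, 1L, 1L), stringsAsFactors = FALSE
  ))
}

# Brute-force conditional HWE probability of each heterozygote count given
# the minor allele count; independent oracle for hwe_exact_test.
hwe_enumerate <- function(n_het, n_hom_minor, n_hom_major) {
  n <- n_het + n_hom_minor + n_hom_major
  na <- 2 * n_hom_minor + n_het
  nb <- 2 * n - na
  if (na > nb) { tmp <- na; na <- nb; nb <- tmp }
  hets <- seq(na %% 2, na, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (na - h) / 2
    hc <- (nb - h) / 2
    h * log(2) - lfactorial(hr) - lfactorial(hc) - lfactorial(h)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}
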