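#' Configuration of a synthetic admixed cohort
#'
#' Bundles every parameter of the synthetic-data generator. Defaults describe
#' a two-way admixed cohort sequenced with a low-pass genome arm at 2x mean
#' coverage and genotyped on an array with call rates above 99%.
#'
#' @param n_samples Number of diploid individuals.
#' @param n_sites Number of biallelic SNP sites on the (single) chromosome.
#' @param chrom_length_bp Chromosome length in bp; 1e8 bp corresponds to one
#'   Morgan under the uniform 1 cM/Mb map.
#' @param ancestries Ordered character vector of ancestry labels; their
#'   integer codes (0-based, RFMix2 style) follow this order.
#' @param admixture_proportions Simplex vector, one entry per ancestry.
#' @param generations_since_admixture Positive scalar `g`; ancestry tract
#'   breakpoints arrive as a Poisson process with rate `g` per Morgan.
#' @param divergence_fst Per-ancestry Balding-Nichols F in (0,1) (recycled).
#' @param mean_coverage Mean read depth lambda of the low-pass arm (Poisson).
#' @param base_error Per-read base error rate epsilon in (0, 0.5).
#' @param array_error_rate Probability an array genotype is perturbed to a
#'   uniformly random different genotype.
#' @param array_missing_rate Probability an array genotype is missing.
#' @param n_batches Number of imputation batches the cohort is split into.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param ancestral_af_range Range of the ancestral allele-frequency spectrum
#'   (uniform draw).
#'
#' @return An object of class `bge_cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_samples = 50, n_sites = 200, seed = 1)
#' @export
cohort_config <- function(n_samples = 600,
                          n_sites = 6000,
                          chrom_length_bp = 1e8,
                          ancestries = c("AFR", "EUR"),
                          admixture_proportions = c(0.5, 0.5),
                          generations_since_admixture = 8,
                          divergence_fst = 0.1,
                          mean_coverage = 2,
                          base_error = 0.01,
                          array_error_rate = 1e-3,
                          array_missing_rate = 5e-3,
                          n_batches = max(1L, ceiling(n_samples / 200)),
                          seed = 1L,
                          ancestral_af_range = c(0.01, 0.99)) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_sites = as.integer(n_sites),
    chrom_length_bp = as.integer(chrom_length_bp),
    ancestries = as.character(ancestries),
    admixture_proportions = as.numeric(admixture_proportions),
    generations_since_admixture = as.numeric(generations_since_admixture),
    divergence_fst = rep_len(as.numeric(divergence_fst), length(ancestries)),
    mean_coverage = mean_coverage,
    base_error = as.numeric(base_error),
    array_error_rate = as.numeric(array_error_rate),
    array_missing_rate = as.numeric(array_missing_rate),
    n_batches = as.integer(n_batches),
    seed = as.integer(seed),
    ancestral_af_range = as.numeric(ancestral_af_range)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "bge_cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 1L, cfg$n_sites >= 1L, cfg$chrom_length_bp >= 1L)
  k <- length(cfg$ancestries)
  if (length(cfg$admixture_proportions) != k)
    stop("admixture_proportions must have one entry per ancestry", call. = FALSE)
  if (abs(sum(cfg$admixture_proportions) - 1) > 1e-12)
    stop("admixture_proportions must sum to 1 (tolerance 1e-12)", call. = FALSE)
  if (any(cfg$admixture_proportions < 0))
    stop("admixture_proportions must be nonnegative", call. = FALSE)
  if (any(cfg$divergence_fst <= 0 | cfg$divergence_fst >= 1))
    stop("divergence_fst must lie in (0, 1)", call. = FALSE)
  if (cfg$generations_since_admixture <= 0)
    stop("generations_since_admixture must be > 0", call. = FALSE)
  if (any(cfg$mean_coverage < 0))
    stop("mean_coverage must be >= 0", call. = FALSE)
  if (cfg$base_error <= 0 || cfg$base_error >= 0.5)
    stop("base_error must lie in (0, 0.5)", call. = FALSE)
  if (cfg$array_error_rate < 0 || cfg$array_error_rate >= 1)
    stop("array_error_rate must lie in [0, 1)", call. = FALSE)
  if (cfg$array_missing_rate < 0 || cfg$array_missing_rate > 1)
    stop("array_missing_rate must lie in [0, 1]", call. = FALSE)
  if (cfg$n_batches < 1L) stop("n_batches must be >= 1", call. = FALSE)
  r <- cfg$ancestral_af_range
  if (length(r) != 2 || r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
    stop("ancestral_af_range must be within (0, 1) and ascending", call. = FALSE)
  invisible(cfg)
}

#' @exportS3Method print bge_cohort_config
print.bge_cohort_config <- function(x, ...) {
  cat("Synthetic BGE cohort configuration\n")
  cat(sprintf("  %d samples x %d sites on %s bp (%s)\n",
              x$n_samples, x$n_sites, format(x$chrom_length_bp, big.mark = ","),
              paste(x$ancestries, collapse = "/")))
  cat(sprintf("  admixture: %s; g = %g; Fst = %s\n",
              paste(signif(x$admixture_proportions, 3), collapse = "/"),
              x$generations_since_admixture,
              paste(signif(x$divergence_fst, 3), collapse = "/")))
  cat(sprintf("  coverage lambda = %s, base error = %g, array error/missing = %g/%g\n",
              paste(signif(unique(as.numeric(x$mean_coverage)), 3), collapse = ","),
              x$base_error, x$array_error_rate, x$array_missing_rate))
  cat(sprintf("  %d batches, seed %d\n", x$n_batches, x$seed))
  invisible(x)
}

# Deterministic per-operation RNG substreams: each generator operation seeds
# from config$seed plus a fixed offset so outputs are reproducible both when
# operations run standalone and inside simulate_truth().
.substream <- function(seed, offset) {
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
}
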