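test_that("config validation rejects out-of-range parameters", {
  expect_s3_class(tiny_config(), "bge_cohort_config")
  expect_error(tiny_config(admixture_proportions = c(0.6, 0.5)), "sum to 1")
  expect_error(tiny_config(divergence_fst = 0), "divergence_fst")
  expect_error(tiny_config(divergence_fst = 1), "divergence_fst")
  expect_error(tiny_config(base_error = 0.5), "base_error")
  expect_error(tiny_config(generations_since_admixture = 0), "generations")
})

test_that("Balding-Nichols frequencies match the Beta moments", {
  # closed forms: E[af] = p, Var[af] = F p (1 - p)
  cfg <- cohort_config(n_samples = 2, n_sites = 1e5, seed = 9,
                       ancestries = c("A", "B", "C"),
                       admixture_proportions = rep(1 / 3, 3),
                       divergence_fst = 0.1,
                       ancestral_af_range = c(0.5, 0.5))
  afs <- simulate_population_afs(cfg)
  expect_true(all(afs > 0 & afs < 1))
  for (k in 1:3) {
    expect_equal(mean(afs[k, ]), 0.5, tolerance = 0.01)
    expect_equal(var(afs[k, ]), 0.1 * 0.25, tolerance = 0.05)
  }
  # near-zero divergence collapses each ancestry onto the ancestral AF
  cfg0 <- cohort_config(n_samples = 2, n_sites = 2000, seed = 9,
                        divergence_fst = 1e-6)
  afs0 <- simulate_population_afs(cfg0)
  p <- attr(afs0, "ancestral")
  expect_lt(max(abs(afs0[1, ] - p)), 1e-2)
  expect_lt(max(abs(afs0[2, ] - p)), 1e-2)
})

test_that("tract process has Poisson breakpoint statistics and tiles the chromosome", {
  cfg <- cohort_config(n_samples = 2000, n_sites = 10, seed = 3,
                       generations_since_admixture = 10)
  tr <- simulate_tracts(cfg)
  # mean tracts per haplotype = g * morgans + 1 = 11 on a 1-Morgan chromosome
  per_hap <- table(paste(tr$sample, tr$hap))
  expect_equal(mean(per_hap), 11, tolerance = 0.05)
  # tiling: per haplotype, first tract starts at 1, last ends at L+1,
  # consecutive tracts abut
  one <- tr[tr$sample == tr$sample[1] & tr$hap == 0L, ]
  one <- one[order(one$spos), ]
  expect_equal(one$spos[1], 1)
  expect_equal(one$epos[nrow(one)], cfg$chrom_length_bp + 1)
  if (nrow(one) > 1)
    expect_equal(one$spos[-1], one$epos[-nrow(one)])
  # label marginals follow the admixture proportions (chi-square GOF)
  counts <- table(factor(tr$anc, levels = 0:1))
  expect_gt(chisq.test(counts, p = cfg$admixture_proportions)$p.value, 0.01)
})

test_that("degenerate tract settings behave as limits", {
  cfg <- tiny_config(generations_since_admixture = 1e-9)
  tr <- simulate_tracts(cfg)
  expect_equal(nrow(tr), 2 * cfg$n_samples)  # one tract per haplotype
  cfg1 <- tiny_config(admixture_proportions = c(1, 0))
  expect_true(all(simulate_tracts(cfg1)$anc == 0L))
})

test_that("truth genotypes equal the haplotype sum and follow local AFs", {
  cfg <- tiny_config()
  tr <- simulate_truth(cfg)
  expect_identical(tr$genotypes, tr$hap0 + tr$hap1)
  expect_true(all(tr$genotypes %in% 0:2))
  # single ancestry at negligible divergence: per-site het fraction matches
  # the HWE expectation 2p(1-p)
  cfg1 <- cohort_config(n_samples = 4000, n_sites = 30, seed = 8,
                        ancestries = "AFR", admixture_proportions = 1,
                        divergence_fst = 1e-6)
  t1 <- simulate_truth(cfg1)
  p <- attr(t1$per_ancestry_afs, "ancestral")
  het <- colMeans(t1$genotypes == 1L)
  expect_lt(max(abs(het - 2 * p * (1 - p))), 0.05)
  expect_lt(max(abs(colMeans(t1$genotypes) - 2 * p)), 0.05)
})

test_that("identical configs give bit-identical simulations", {
  cfg <- tiny_config(seed = 77)
  a <- simulate_truth(cfg)
  b <- simulate_truth(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$tracts, b$tracts)
  da <- suppressWarnings(simulate_lowpass_dosages(a))
  db <- suppressWarnings(simulate_lowpass_dosages(b))
  expect_identical(da$ds, db$ds)
  expect_identical(simulate_array_genotypes(a), simulate_array_genotypes(b))
})

test_that("zero coverage returns the HWE prior dosage 2*AF exactly", {
  cfg <- tiny_config(mean_coverage = 0)
  tr <- simulate_truth(cfg)
  d <- suppressWarnings(simulate_lowpass_dosages(tr))
  p <- colMeans(tr$genotypes) / 2
  expect_lt(max(abs(sweep(d$ds, 2, 2 * p))), 1e-12)
})

test_that("the read posterior matches a direct Bayes computation", {
  # truth het, 4 reads with 2 alt, eps = 0.01, AF = 0.5
  post <- genotype_posterior(2, 4, 0.5, 0.01)
  lik <- c(dbinom(2, 4, 0.01), dbinom(2, 4, 0.5), dbinom(2, 4, 0.99))
  prior <- c(0.25, 0.5, 0.25)
  oracle <- prior * lik / sum(prior * lik)
  expect_equal(c(post$g0, post$g1, post$g2), oracle, tolerance = 1e-12)
  expect_gt(post$g1, post$g0)
  expect_gt(post$g1, post$g2)
})

test_that("deep coverage recovers truth and dosage error shrinks with coverage", {
  cfg30 <- cohort_config(n_samples = 200, n_sites = 300, seed = 5,
                         mean_coverage = 30)
  tr <- simulate_truth(cfg30)
  d30 <- suppressWarnings(simulate_lowpass_dosages(tr))
  hc <- hard_call(gp = d30$gp, rule = "argmax_gp")
  expect_gt(mean(hc == tr$genotypes), 0.99)
  errs <- vapply(c(0, 2, 30), function(lam) {
    cfg <- cohort_config(n_samples = 200, n_sites = 300, seed = 5,
                         mean_coverage = lam)
    mean(abs(suppressWarnings(simulate_lowpass_dosages(tr, cfg))$ds -
               tr$genotypes))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("array genotypes reproduce the error and missingness rates", {
  cfg <- tiny_config(array_error_rate = 0, array_missing_rate = 0)
  tr <- simulate_truth(cfg)
  expect_identical(simulate_array_genotypes(tr), tr$genotypes)
  cfg2 <- cohort_config(n_samples = 500, n_sites = 200, seed = 2,
                        array_error_rate = 0.01, array_missing_rate = 0)
  tr2 <- simulate_truth(cfg2)
  arr2 <- simulate_array_genotypes(tr2)
  expect_equal(mean(arr2 != tr2$genotypes), 0.01, tolerance = 0.15)
  cfg3 <- tiny_config(array_missing_rate = 1)
  tr3 <- simulate_truth(cfg3)
  expect_true(all(is.na(simulate_array_genotypes(tr3))))
})

test_that("planted CNV quartets honour the plant specification", {
  exons <- make_exon_intervals(500)
  # no dropout / jitter: test callset equals truth up to qs
  pl <- plant_cnv_quartets(20, exons,
                           plant_spec(n_transmitted = 10, n_de_novo = 3,
                                      dropout = 0, jitter_exons = 0),
                           seed = 4)
  expect_identical(pl$truth[c("sample", "chrom", "start", "end", "type")],
                   pl$test[c("sample", "chrom", "start", "end", "type")])
  expect_equal(nrow(pl$pedigree), 80)
  # de novo events sit in exactly one child and neither parent
  dn_events <- pl$events[pl$events$kind == "de_novo", ]
  expect_equal(dn_events$n_carriers, rep(1L, 3))
  # dropout reproduces ~ (1 - d) of carriers
  pl2 <- plant_cnv_quartets(50, exons,
                            plant_spec(n_transmitted = 25, n_de_novo = 0,
                                       dropout = 0.2, transmit_prob = 1),
                            seed = 6)
  frac <- nrow(pl2$test) / nrow(pl2$truth)
  se <- sqrt(0.2 * 0.8 / nrow(pl2$truth))
  expect_lt(abs(frac - 0.8), 3 * se)
  # asking for more exons than exist is an error
  expect_error(plant_cnv_quartets(5, make_exon_intervals(10),
                                  plant_spec(n_transmitted = 10,
                                             n_de_novo = 0)),
               "exons")
})
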