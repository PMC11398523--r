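test_that("genotype filters apply the depth, quality and allele-balance rules", {
  g <- matrix(c(1L, 1L, 2L, 1L, 0L, 1L), 1)
  dp <- matrix(c(30, 30, 30, 9, 30, 30), 1)
  gq <- matrix(c(99, 99, 99, 99, 19, 99), 1)
  adr <- matrix(c(15, 27, 5, 10, 10, NA), 1)
  ada <- matrix(c(15, 3, 15, 10, 0, NA), 1)
  res <- filter_genotypes(g, dp, gq, adr, ada)
  # kept: balanced het; removed: het AB 0.1, hom-alt AB 0.75, DP 9, GQ 19;
  # AD-less het left alone but counted
  expect_equal(unname(res$genotypes[1, ]), c(1L, NA, NA, NA, NA, 1L))
  expect_equal(res$report[["het_ab"]], 1)
  expect_equal(res$report[["homalt_ab"]], 1)
  expect_equal(res$report[["low_dp"]], 1)
  expect_equal(res$report[["low_gq"]], 1)
  expect_equal(res$report[["ab_unavailable"]], 1)
  # boundaries are inclusive on the keep side: AB 0.2 / 0.8 het and 0.8
  # hom-alt all stay
  g2 <- matrix(c(1L, 1L, 2L), 1)
  res2 <- filter_genotypes(g2, matrix(10, 1, 3), matrix(20, 1, 3),
                           matrix(c(80, 20, 20), 1),
                           matrix(c(20, 80, 80), 1))
  expect_equal(res2$report[["removed"]], 0)
})

test_that("site filters read the removal clause disjunctively", {
  sites <- data.frame(chrom = "chr1", pos = 1:16)
  flags <- expand.grid(n_alleles = c(2, 7), vqsr = c(TRUE, FALSE),
                       lcr = c(FALSE, TRUE), target = c(TRUE, FALSE))
  res <- filter_sites(sites, flags$n_alleles, flags$vqsr, flags$lcr,
                      flags$target)
  expected <- !(flags$n_alleles > 6 | !flags$vqsr | flags$lcr | !flags$target)
  expect_equal(res$keep, expected)
  expect_true(res$keep[1])      # clean biallelic site survives
  expect_equal(sum(res$keep), 1)
})

test_that("coverage filter boundaries follow the stated strict inequalities", {
  rec <- data.frame(
    sample = sprintf("s%d", 1:6),
    exome_fraction_10x = c(0.95, 0.89, 0.90, 0.95, 0.95, 0.95),
    wgs_coverage = c(2.1, 2, 2, 0.99, 2, 2),
    chimera_rate = c(0.01, 0.01, 0.01, 0.01, 0.06, 0.05),
    contamination_rate = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.05)
  )
  res <- filter_sample_coverage(rec)
  expect_equal(res$pass, c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$reasons[2], "exome_fraction")
  expect_equal(res$reasons[4], "wgs_coverage")
  expect_equal(res$reasons[5], "chimera")
})

test_that("MAD outlier filter flags planted outliers and skips degenerate strata", {
  # constant metric: MAD = 0, metric skipped, nobody removed
  m <- matrix(5, 20, 1)
  res <- suppressWarnings(mad_outlier_filter(m, rep("a", 20)))
  expect_true(all(res$pass))
  expect_equal(res$skipped$reason, "zero_mad")
  # median 0, MAD 0 even with one huge value
  m2 <- matrix(c(rep(0, 9), 100), 10, 1)
  res2 <- mad_outlier_filter(m2, rep("a", 10))
  expect_true(all(res2$pass))
  # planted point at 10 sigma flagged; false-flag rate below 2%
  set.seed(31)
  x <- c(rnorm(1000), 10)
  res3 <- mad_outlier_filter(matrix(x, ncol = 1), rep("a", 1001), k = 4)
  expect_false(res3$pass[1001])
  expect_lt(mean(!res3$pass[1:1000]), 0.02)
  # small strata are skipped with a warning
  expect_warning(mad_outlier_filter(matrix(rnorm(5), 5, 1), rep("b", 5)),
                 "skipped")
})

test_that("X inbreeding separates sexes with F = 0.6 undetermined", {
  set.seed(11)
  n <- 60; s <- 2000
  p <- runif(s, 0.1, 0.5)
  females <- t(replicate(n, rbinom(s, 2, p)))
  males <- t(replicate(n, 2L * rbinom(s, 1, p)))   # hemizygous coded diploid
  g <- rbind(females, males)
  rownames(g) <- sprintf("i%03d", 1:(2 * n))
  res <- infer_sex(g, afs = p)
  expect_true(all(abs(res$f[1:n]) < 0.1))
  expect_true(all(res$sex[1:n] == "female"))
  expect_true(all(res$f[(n + 1):(2 * n)] > 0.9))
  expect_true(all(res$sex[(n + 1):(2 * n)] == "male"))
  # a sample with no heterozygotes has F exactly 1
  expect_equal(res$f[n + 1], 1, tolerance = 1e-12)
  # exact boundary: engineer F = 0.6 via o_het = 0.4 * e_het using afs
  g1 <- matrix(c(rep(1L, 2), rep(0L, 8)), 1)
  afs1 <- rep(0.5, 10)           # e_het = 5, o_het = 2 -> F = 0.6
  res1 <- infer_sex(g1, afs = afs1, min_sites = 5)
  expect_equal(res1$f, 0.6)
  expect_equal(res1$sex, "undetermined")
})

test_that("HWE-normalized PCA separates populations deterministically", {
  tp <- two_pop_genotypes()
  pca <- hwe_normalized_pca(tp$genotypes, n_pcs = 4)
  pc1 <- pca$scores[, 1]
  # silhouette of the two clusters on PC1
  a <- pc1[tp$pop == "A"]; b <- pc1[tp$pop == "B"]
  sil_a <- mean(vapply(seq_along(a), function(i) {
    wa <- mean(abs(a[i] - a[-i])); wb <- mean(abs(a[i] - b))
    (wb - wa) / max(wa, wb)
  }, numeric(1)))
  expect_gt(sil_a, 0.9)
  # duplicate samples land on identical scores
  g2 <- rbind(tp$genotypes, tp$genotypes[1, , drop = FALSE])
  p2 <- hwe_normalized_pca(g2, n_pcs = 3)
  expect_equal(p2$scores[1, ], p2$scores[nrow(g2), ], tolerance = 1e-8)
  # repeated runs are identical (fixed sign convention)
  expect_identical(pca$scores, hwe_normalized_pca(tp$genotypes, n_pcs = 4)$scores)
  # n_pcs above rank is capped with a warning
  small <- tp$genotypes[1:5, ]
  expect_warning(res <- hwe_normalized_pca(small, n_pcs = 10), "rank")
  expect_lte(ncol(res$scores), 5)
})

test_that("kNN ancestry vote assigns clear samples and abstains at 50/50", {
  set.seed(21)
  ref <- rbind(matrix(rnorm(60 * 2, mean = 5), ncol = 2),
               matrix(rnorm(60 * 2, mean = -5), ncol = 2))
  labs <- rep(c("AFR", "EUR"), each = 60)
  queries <- rbind(c(5, 5), c(0, 0), c(-5, -5))
  rownames(queries) <- c("q1", "q2", "q3")
  res <- assign_ancestry(queries, ref, labs, k = 50, threshold = 0.7)
  expect_equal(res$label, c("AFR", "unassigned", "EUR"))
  expect_equal(res$probability[1], 1)
  expect_lt(res$probability[2], 0.7)
  # threshold 0 assigns everyone
  res0 <- assign_ancestry(queries, ref, labs, k = 50, threshold = 0)
  expect_false(any(res0$label == "unassigned"))
  expect_warning(assign_ancestry(queries, ref[1:10, ], labs[1:10], k = 50),
                 "reduced")
})

test_that("LD pruning drops duplicated columns and spares independent sites", {
  set.seed(13)
  g <- matrix(rbinom(1000 * 50, 2, 0.4), 1000, 50)
  pos <- sort(sample.int(1e6, 50))
  kept <- ld_prune(g, pos, window_bp = 1e6, r2_max = 0.2)
  expect_gt(length(kept), 49 * 0.99 - 1)  # independent sites survive
  gdup <- cbind(g[, 1, drop = FALSE], g)
  posd <- c(pos[1], pos[1] + 1, pos[-1] + 2)
  keptd <- ld_prune(gdup, posd, window_bp = 1e6, r2_max = 0.99)
  expect_false(2L %in% keptd)             # exact duplicate removed
  expect_equal(ld_prune(g, pos, window_bp = 0, r2_max = 0.01),
               seq_len(50))               # window 0 keeps everything
})

test_that("HWE exact test agrees with brute-force enumeration", {
  cases <- list(c(5, 10, 35), c(0, 2, 48), c(20, 0, 30), c(7, 7, 7),
                c(1, 0, 49), c(12, 3, 10), c(0, 25, 25), c(50, 0, 0))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_enumerate(cs[1], cs[2], cs[3]),
                 tolerance = 1e-9,
                 label = paste("counts", paste(cs, collapse = "/")))
  }
  # equilibrium data is not rejected; a het-free mixture is
  expect_gt(hwe_exact_test(25, 12, 13), 0.05)
  expect_lt(hwe_exact_test(0, 25, 25), 1e-10)
})

test_that("array QC stages remove the planted failures in order", {
  set.seed(17)
  n <- 120; s <- 300
  p <- runif(s, 0.2, 0.5)
  g <- t(replicate(n, rbinom(s, 2, p)))
  status <- rep(c(TRUE, FALSE), n / 2)
  # SNP 1: 94% call rate -> stage-1 removal
  g[1:ceiling(0.06 * n), 1] <- NA
  # SNP 2: differential missingness 5% in cases only
  g[which(status)[1:6], 2] <- NA
  # SNP 3: gross HWE violation in controls (all het)
  g[!status, 3] <- 1L
  g[status, 3] <- 1L
  # sample 1: 90% call rate
  g[1, 5:12] <- NA
  res <- array_qc(g, status = status)
  expect_false(1L %in% res$kept_sites)
  expect_false(2L %in% res$kept_sites)
  expect_false(3L %in% res$kept_sites)
  expect_false(1L %in% res$kept_samples)
  expect_gt(length(res$kept_sites), 60)
  expect_gt(length(res$kept_samples), 100)
  # clean complete data keeps every sample and loses sites only to the
  # HWE lottery
  g0 <- t(replicate(60, rbinom(300, 2, 0.4)))
  res0 <- array_qc(g0)
  expect_equal(length(res0$kept_sites) + res0$report[["hwe"]], 300)
  expect_equal(res0$kept_samples, 1:60)
})

test_that("QC filters are idempotent on their own output", {
  rec <- data.frame(sample = sprintf("s%d", 1:8),
                    exome_fraction_10x = runif(8, 0.92, 0.99),
                    wgs_coverage = runif(8, 1.5, 3),
                    chimera_rate = runif(8, 0, 0.02),
                    contamination_rate = runif(8, 0, 0.02))
  r1 <- filter_sample_coverage(rec)
  r2 <- filter_sample_coverage(rec[r1$pass, ])
  expect_true(all(r2$pass))
  set.seed(3)
  g <- t(replicate(100, rbinom(60, 2, runif(60, 0.2, 0.5))))
  q1 <- array_qc(g)
  q2 <- array_qc(q1$genotypes)
  expect_equal(dim(q2$genotypes), dim(q1$genotypes))
})
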