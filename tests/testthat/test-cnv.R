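test_that("exon annotation counts overlaps under half-open conventions", {
  exons <- make_exon_intervals(10, exon_bp = 100, gap_bp = 900)
  # exons start at 1, 1001, 2001, ...
  calls <- data.frame(
    sample = "s1", chrom = "chr1",
    start = c(150, 2001, 500, 1),
    end = c(160, 6101, 900, 1001),      # half-open
    type = "DEL", qs = 1000
  )
  ann <- annotate_exons(calls, exons)
  expect_equal(ann$exon_count, c(0L, 5L, 0L, 1L))  # exons 3..7 for call 2
  expect_equal(ann$exon_lo[2], 3L)
  expect_equal(ann$exon_hi[2], 7L)
  # a call ending exactly where an exon starts does not touch it
  edge <- annotate_exons(data.frame(sample = "s1", chrom = "chr1",
                                    start = 150, end = 1001, type = "DEL",
                                    qs = 1), exons)
  expect_equal(edge$exon_count, 0L)
})

test_that("site clustering separates types and weak overlaps", {
  calls <- data.frame(
    sample = c("s1", "s2", "s3", "s4", "s5"),
    chrom = "chr1",
    start = c(100, 100, 5000, 100, 104500),
    end = c(1100, 1100, 5500, 1100, 105000),
    type = c("DEL", "DEL", "DEL", "DUP", "DEL"),
    qs = 1000
  )
  cl <- cluster_sites(calls, cohort_size = 100)
  ids <- cl$calls$site_id
  expect_equal(ids[1], ids[2])           # identical calls share a site
  expect_false(ids[1] == ids[3])         # 10% overlap separates
  expect_false(ids[1] == ids[4])         # DEL and DUP never merge
  s1 <- cl$sites[cl$sites$site_id == ids[1], ]
  expect_equal(s1$n_carriers, 2L)
  expect_equal(s1$frequency, 0.02)
})

test_that("call filters enforce QS > 200, rare frequency and the rare-call sample cap", {
  cohort <- data.frame(sample = sprintf("s%03d", 1:300))
  mk <- function(sample, start, qs, n = 1)
    data.frame(sample = sample, chrom = "chr1", start = start,
               end = start + 1000, type = "DEL", qs = qs)
  # 11 distinct rare calls in one sample -> sample removed
  hoarder <- do.call(rbind, lapply(0:10, function(i)
    mk("s001", 1e6 + i * 5e4, qs = 1000)))
  # boundary QS: 200 removed, 201 kept
  qs_edge <- rbind(mk("s002", 1e7, 200), mk("s003", 2e7, 201))
  # a common site carried by 2% of the cohort
  common <- do.call(rbind, lapply(sprintf("s%03d", 101:106), function(s)
    mk(s, 3e7, 1000)))
  res <- filter_cnv_calls(rbind(hoarder, qs_edge, common), cohort)
  expect_equal(res$removed_samples, "s001")
  expect_false("s001" %in% res$calls$sample)
  expect_false("s002" %in% res$calls$sample)   # QS 200 strict
  expect_true("s003" %in% res$calls$sample)
  expect_false(any(res$calls$start == 3e7))    # 2% site filtered
})

test_that("identity callsets give perfect recall and PPV; swap symmetry holds", {
  exons <- make_exon_intervals(800)
  pl <- plant_cnv_quartets(40, exons,
                           plant_spec(n_transmitted = 20, n_de_novo = 5,
                                      span_exons = c(1, 8)), seed = 12)
  sc <- match_and_score(pl$truth, pl$truth, exons, min_exons = c(1, 3, 5))
  expect_true(all(sc$recall == 1))
  expect_true(all(sc$ppv == 1))
  expect_true(all(sc$carrier_recall == 1))
  # swapping truth and test swaps recall and PPV exactly
  ab <- match_and_score(pl$truth, pl$test, exons, min_exons = c(1, 5))
  ba <- match_and_score(pl$test, pl$truth, exons, min_exons = c(1, 5))
  expect_equal(ab$recall, ba$ppv)
  expect_equal(ab$ppv, ba$recall)
  # row order never matters
  shuf <- pl$test[sample(nrow(pl$test)), ]
  ab2 <- match_and_score(pl$truth, shuf, exons, min_exons = c(1, 5))
  expect_equal(ab$recall, ab2$recall)
  expect_equal(ab$ppv, ab2$ppv)
})

test_that("a 2-carrier site with one matched carrier is still recalled (>= 50%)", {
  exons <- make_exon_intervals(50)
  truth <- data.frame(sample = c("s1", "s2"), chrom = "chr1",
                      start = exons$start[10], end = exons$end[14],
                      type = "DEL", qs = 1000)
  test <- truth[1, ]
  sc <- match_and_score(truth, test, exons, min_exons = 1)
  expect_equal(sc$recall, 1)            # 50% of carriers matched, inclusive
  expect_equal(sc$carrier_recall, 0.5)
})

test_that("planted carrier drop-out is recovered by carrier-level recall", {
  exons <- make_exon_intervals(2500)
  pl <- plant_cnv_quartets(60, exons,
                           plant_spec(n_transmitted = 50, n_de_novo = 0,
                                      span_exons = c(5, 8),
                                      transmit_prob = 1, dropout = 0.2),
                           seed = 33)
  sc <- match_and_score(pl$truth, pl$test, exons, min_exons = 5)
  n <- nrow(pl$truth)
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(sc$carrier_recall - 0.8), 2 * se + 1e-9)
  expect_equal(sc$ppv, 1)               # surviving calls all validate
  # larger events tolerate endpoint jitter better, so recall rises with
  # the resolution floor
  exons2 <- make_exon_intervals(4000)
  pl2 <- plant_cnv_quartets(60, exons2,
                            plant_spec(n_transmitted = 100, n_de_novo = 0,
                                       span_exons = c(1, 10), dropout = 0,
                                       jitter_exons = 2, transmit_prob = 1),
                            seed = 34)
  sc2 <- match_and_score(pl2$truth, pl2$test, exons2,
                         min_exons = c(1, 3, 5, 8))
  expect_true(all(diff(sc2$recall) >= -0.05))
  expect_true(all(diff(sc2$carrier_recall) >= -0.02))
  expect_gt(sc2$carrier_recall[4], sc2$carrier_recall[1])
})

test_that("jittered endpoints within half the span still match", {
  exons <- make_exon_intervals(2000)
  pl <- plant_cnv_quartets(30, exons,
                           plant_spec(n_transmitted = 20, n_de_novo = 0,
                                      span_exons = c(6, 10), dropout = 0,
                                      jitter_exons = 1),
                           seed = 35)
  sc <- match_and_score(pl$truth, pl$test, exons, min_exons = 5)
  expect_equal(sc$recall, 1)   # +-1 exon on a >=6-exon call keeps >=50% overlap
})

test_that("de novo detection finds planted events and only those", {
  exons <- make_exon_intervals(2000)
  pl <- plant_cnv_quartets(100, exons,
                           plant_spec(n_transmitted = 40, n_de_novo = 11,
                                      dropout = 0, jitter_exons = 0),
                           seed = 36)
  dn <- de_novo_check(pl$test, pl$pedigree)
  expect_equal(nrow(dn), 11L)
  dn_truth <- pl$events[pl$events$kind == "de_novo", ]
  expect_setequal(dn$start, exons$start[dn_truth$exon_lo])
  # an exact parental match is inherited, an opposite-type one is not
  ped <- data.frame(fam = "f1", id = c("fa", "mo", "kid"),
                    father = c("0", "0", "fa"), mother = c("0", "0", "mo"),
                    sex = c(1, 2, 1), phenotype = 0)
  calls <- data.frame(sample = c("kid", "fa"), chrom = "chr1",
                      start = 100, end = 2000, type = c("DEL", "DEL"),
                      qs = 500)
  expect_equal(nrow(de_novo_check(calls, ped)), 0L)
  calls$type[2] <- "DUP"
  expect_equal(nrow(de_novo_check(calls, ped)), 1L)
  # children without both parents in the table are skipped
  ped2 <- ped[ped$id != "fa", ]
  res <- de_novo_check(calls, ped2)
  expect_equal(attr(res, "n_skipped_children"), 1L)
})
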