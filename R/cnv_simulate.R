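#' Build a synthetic exon interval set
#'
#' Regularly spaced exons on one chromosome, 1-based half-open, already
#' sorted and non-overlapping, for use as the captured-interval set of the
#' CNV benchmark.
#'
#' @param n_exons Number of exons.
#' @param exon_bp Exon width in bp.
#' @param gap_bp Gap between consecutive exons in bp.
#' @param chrom Chromosome label.
#' @return Data frame with `chrom`, `start`, `end` (1-based half-open).
#' @export
make_exon_intervals <- function(n_exons, exon_bp = 150L, gap_bp = 5000L,
                                chrom = "chr1") {
  start <- 1L + (seq_len(n_exons) - 1L) * (exon_bp + gap_bp)
  data.frame(chrom = chrom, start = start, end = start + exon_bp,
             stringsAsFactors = FALSE)
}

#' Specification of planted CNV events for quartet benchmarking
#'
#' @param n_transmitted Number of transmitted CNV sites (parent carrier,
#'   children inherit with `transmit_prob`).
#' @param n_de_novo Number of de novo events (single child, neither parent).
#' @param span_exons Integer range of exons spanned by an event.
#' @param families_per_site Families carrying each transmitted site.
#' @param transmit_prob Per-child transmission probability.
#' @param dropout Probability `d` that a truth carrier's call is absent from
#'   the test callset.
#' @param jitter_exons Maximum endpoint jitter `j` of reproduced test calls,
#'   in exons.
#' @param qs_range Quality-score range for test calls (uniform draw).
#' @return A `bge_plant_spec` list.
#' @export
plant_spec <- function(n_transmitted = 40L, n_de_novo = 11L,
                       span_exons = c(5L, 10L), families_per_site = 2L,
                       transmit_prob = 0.5, dropout = 0, jitter_exons = 0L,
                       qs_range = c(300, 3000)) {
  spec <- list(n_transmitted = as.integer(n_transmitted),
               n_de_novo = as.integer(n_de_novo),
               span_exons = as.integer(rep_len(span_exons, 2)),
               families_per_site = as.integer(families_per_site),
               transmit_prob = transmit_prob,
               dropout = dropout, jitter_exons = as.integer(jitter_exons),
               qs_range = qs_range)
  stopifnot(spec$n_transmitted >= 0, spec$n_de_novo >= 0,
            spec$span_exons[1] >= 1, spec$span_exons[2] >= spec$span_exons[1],
            spec$families_per_site >= 1,
            spec$transmit_prob >= 0, spec$transmit_prob <= 1,
            spec$dropout >= 0, spec$dropout < 1, spec$jitter_exons >= 0)
  class(spec) <- "bge_plant_spec"
  spec
}

#' Plant rare CNVs in quartet families with known truth
#'
#' Creates `n_families` quartets (father, mother, two children) and plants
#' transmitted and de novo DEL/DUP events on the exon grid. Events occupy
#' disjoint exon blocks separated by more than `2 * jitter + 1` exons so
#' jittered calls can never match a neighbouring site. The test callset
#' reproduces each truth carrier's call with probability `1 - dropout`, with
#' both endpoints independently jittered by up to `jitter_exons` exons and
#' the same type; de novo events appear in exactly one child and neither
#' parent.
#'
#' @param n_families Number of quartet families.
#' @param exons Exon interval set (e.g. [make_exon_intervals()]).
#' @param spec A [plant_spec()].
#' @param seed Integer seed.
#' @return List with `truth` and `test` CNV call data frames (`sample`,
#'   `chrom`, `start`, `end`, `type`, `qs`), `pedigree` (6-column PED data
#'   frame), `exons`, and `events` (one row per planted site with its family
#'   assignment and kind).
#' @export
plant_cnv_quartets <- function(n_families, exons, spec = plant_spec(),
                               seed = 1L) {
  stopifnot(inherits(spec, "bge_plant_spec"), n_families >= 1)
  if (spec$n_de_novo > n_families)
    stop("more de novo events than families", call. = FALSE)
  set.seed(as.integer(seed))
  n_events <- spec$n_transmitted + spec$n_de_novo
  gap <- 2L * spec$jitter_exons + 2L
  spans <- if (n_events > 0)
    sample(seq(spec$span_exons[1], spec$span_exons[2]), n_events, replace = TRUE)
  else integer(0)
  need <- sum(spans) + n_events * gap
  if (need > nrow(exons))
    stop(sprintf("plant spec needs %d exons but only %d available", need,
                 nrow(exons)), call. = FALSE)
  # disjoint exon blocks separated by > 2*jitter exons
  exon_lo <- cumsum(c(1L, head(spans + gap, -1L)))
  exon_hi <- exon_lo + spans - 1L

  fams <- sprintf("F%03d", seq_len(n_families))
  members <- c("fa", "mo", "p1", "s1")
  ped <- data.frame(
    fam = rep(fams, each = 4),
    id = paste(rep(fams, each = 4), rep(members, n_families), sep = "."),
    father = rep(c("0", "0", "", ""), n_families),
    mother = rep(c("0", "0", "", ""), n_families),
    sex = rep(c(1L, 2L, 1L, 2L), n_families),
    phenotype = 0L, stringsAsFactors = FALSE
  )
  child <- ped$father == ""
  ped$father[child] <- paste0(rep(fams, each = 4)[child], ".fa")
  ped$mother[child] <- paste0(rep(fams, each = 4)[child], ".mo")

  types <- rep_len(c("DEL", "DUP"), n_events)
  kind <- rep(c("transmitted", "de_novo"),
              c(spec$n_transmitted, spec$n_de_novo))
  carriers <- vector("list", n_events)
  ev_fam <- character(n_events)
  dn_fams <- sample(fams, spec$n_de_novo)
  dn_at <- 0L
  for (e in seq_len(n_events)) {
    if (kind[e] == "transmitted") {
      f <- sample(fams, spec$families_per_site)
      ev_fam[e] <- paste(f, collapse = ",")
      cs <- character(0)
      for (fi in f) {
        par <- paste(fi, sample(c("fa", "mo"), 1L), sep = ".")
        kids <- paste(fi, c("p1", "s1"), sep = ".")
        kids <- kids[runif(2) < spec$transmit_prob]
        cs <- c(cs, par, kids)
      }
      carriers[[e]] <- cs
    } else {
      dn_at <- dn_at + 1L
      fi <- dn_fams[dn_at]
      ev_fam[e] <- fi
      carriers[[e]] <- paste(fi, sample(c("p1", "s1"), 1L), sep = ".")
    }
  }
  events <- data.frame(event = seq_len(n_events), kind = kind, type = types,
                       exon_lo = exon_lo, exon_hi = exon_hi,
                       families = ev_fam,
                       n_carriers = vapply(carriers, length, 1L),
                       stringsAsFactors = FALSE)
  truth <- data.frame(
    sample = unlist(carriers),
    chrom = exons$chrom[1],
    start = rep(exons$start[exon_lo], events$n_carriers),
    end = rep(exons$end[exon_hi], events$n_carriers),
    type = rep(types, events$n_carriers),
    qs = 1000, event = rep(seq_len(n_events), events$n_carriers),
    stringsAsFactors = FALSE
  )
  keep <- runif(nrow(truth)) >= spec$dropout
  test <- truth[keep, , drop = FALSE]
  if (nrow(test) > 0) {
    j <- spec$jitter_exons
    lo <- rep(exon_lo, events$n_carriers)[keep]
    hi <- rep(exon_hi, events$n_carriers)[keep]
    if (j > 0) {
      lo2 <- pmax(1L, lo + sample(seq(-j, j), nrow(test), replace = TRUE))
      hi2 <- pmin(nrow(exons), hi + sample(seq(-j, j), nrow(test), replace = TRUE))
      swap <- lo2 > hi2
      lo2[swap] <- lo[swap]; hi2[swap] <- hi[swap]
      lo <- lo2; hi <- hi2
    }
    test$start <- exons$start[lo]
    test$end <- exons$end[hi]
    test$qs <- runif(nrow(test), spec$qs_range[1], spec$qs_range[2])
  }
  rownames(truth) <- rownames(test) <- NULL
  truth$event <- NULL
  test$event <- NULL
  list(truth = truth, test = test, pedigree = ped, exons = exons,
       events = events)
}
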