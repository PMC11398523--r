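#' Annotate CNV calls with captured-exon counts
#'
#' `exon_count` is the number of exon intervals a call overlaps by at least
#' one bp (half-open coordinates: a call ending where an exon starts does
#' not count it). The first and last overlapped exon indices are attached
#' for exon-space matching.
#'
#' @param calls CNV call data frame (`sample`, `chrom`, `start`, `end`,
#'   `type`, `qs`), 1-based half-open.
#' @param exons Sorted, merged exon intervals (`chrom`, `start`, `end`).
#' @return `calls` with added `exon_count`, `exon_lo`, `exon_hi` columns.
#' @export
annotate_exons <- function(calls, exons) {
  calls$exon_count <- 0L
  calls$exon_lo <- NA_integer_
  calls$exon_hi <- NA_integer_
  if (nrow(calls) == 0) return(calls)
  cg <- intervals_to_gr(calls[c("chrom", "start", "end")])
  eg <- intervals_to_gr(exons)
  ov <- GenomicRanges::findOverlaps(cg, eg)
  if (length(ov) > 0) {
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    lo <- tapply(s, q, min); hi <- tapply(s, q, max)
    cnt <- tapply(s, q, length)
    idx <- as.integer(names(lo))
    calls$exon_lo[idx] <- as.integer(lo)
    calls$exon_hi[idx] <- as.integer(hi)
    calls$exon_count[idx] <- as.integer(cnt)
  }
  calls
}

# bp overlap of two half-open intervals
bp_overlap <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Cluster CNV calls into sites by reciprocal overlap
#'
#' Single-linkage clustering of same-type, same-chromosome calls whose
#' reciprocal bp overlap is at least `min_recip_overlap`; deletions and
#' duplications never share a site. The site interval is the union of its
#' member calls and the carrier frequency uses `cohort_size` as the
#' denominator.
#'
#' @param calls Annotated CNV call data frame.
#' @param cohort_size Number of samples in the cohort (for frequency).
#' @param min_recip_overlap Reciprocal overlap threshold (inclusive),
#'   default 0.5.
#' @return List with `sites` (data frame: `site_id`, `type`, `chrom`,
#'   `start`, `end`, `n_carriers`, `frequency`) and `calls` (input with a
#'   `site_id` column).
#' @export
cluster_sites <- function(calls, cohort_size, min_recip_overlap = 0.5) {
  n <- nrow(calls)
  if (n == 0)
    return(list(sites = data.frame(site_id = integer(), type = character(),
                                   chrom = character(), start = integer(),
                                   end = integer(), n_carriers = integer(),
                                   frequency = numeric()),
                calls = cbind(calls, site_id = integer(0))))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  grp <- split(seq_len(n), paste(calls$chrom, calls$type))
  for (idx in grp) {
    if (length(idx) < 2) next
    o <- idx[order(calls$start[idx])]
    for (a in seq_along(o)) for (b in seq_len(a - 1L)) {
      i <- o[b]; j <- o[a]
      if (calls$start[j] >= calls$end[i]) next
      ov <- bp_overlap(calls$start[i], calls$end[i], calls$start[j], calls$end[j])
      li <- calls$end[i] - calls$start[i]
      lj <- calls$end[j] - calls$start[j]
      if (ov / li >= min_recip_overlap && ov / lj >= min_recip_overlap)
        union2(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  site_id <- match(roots, unique(roots))
  calls$site_id <- site_id
  agg <- lapply(split(seq_len(n), site_id), function(ix) {
    data.frame(type = calls$type[ix[1]], chrom = calls$chrom[ix[1]],
               start = min(calls$start[ix]), end = max(calls$end[ix]),
               n_carriers = length(unique(calls$sample[ix])))
  })
  sites <- do.call(rbind, agg)
  sites <- cbind(site_id = as.integer(names(agg)), sites)
  sites$frequency <- sites$n_carriers / cohort_size
  rownames(sites) <- NULL
  list(sites = sites, calls = calls)
}

#' Sample and call filters for a CNV callset
#'
#' High-quality calls are those with `qs > qs_min` (strict). Samples
#' carrying more than `max_rare_per_sample` rare high-quality calls
#' (site frequency below `freq_max`) are removed; the remaining calls are
#' then kept only when high quality and at a site below `freq_max`
#' frequency within the sample's ancestry group (cohort-wide when no
#' ancestry is given). Frequency denominators use the post-sample-filter
#' cohort size.
#'
#' @param calls CNV call data frame.
#' @param samples Data frame with `sample` and optional `ancestry` columns
#'   describing the full cohort.
#' @param qs_min Quality-score threshold (strictly greater passes).
#' @param freq_max Site-frequency ceiling (strictly below passes).
#' @param max_rare_per_sample Rare-call ceiling per sample (strictly more
#'   fails).
#' @param min_recip_overlap Clustering threshold for site definition.
#' @return List with `calls` (retained), `removed_samples`, `report`.
#' @export
filter_cnv_calls <- function(calls, samples, qs_min = 200, freq_max = 0.01,
                             max_rare_per_sample = 10,
                             min_recip_overlap = 0.5) {
  stopifnot(is.data.frame(samples), "sample" %in% names(samples))
  hq <- calls[calls$qs > qs_min, , drop = FALSE]
  cl <- cluster_sites(hq, cohort_size = nrow(samples), min_recip_overlap)
  freq <- cl$sites$frequency[match(cl$calls$site_id, cl$sites$site_id)]
  rare <- freq < freq_max
  per_sample <- table(cl$calls$sample[rare])
  removed <- names(per_sample)[per_sample > max_rare_per_sample]
  keep_samples <- samples[!samples$sample %in% removed, , drop = FALSE]
  calls2 <- calls[!calls$sample %in% removed, , drop = FALSE]
  hq2 <- calls2[calls2$qs > qs_min, , drop = FALSE]
  out <- list()
  if (is.null(keep_samples$ancestry)) keep_samples$ancestry <- "all"
  anc_of_call <- keep_samples$ancestry[match(hq2$sample, keep_samples$sample)]
  for (a in unique(keep_samples$ancestry)) {
    sub <- hq2[!is.na(anc_of_call) & anc_of_call == a, , drop = FALSE]
    if (nrow(sub) == 0) next
    cls <- cluster_sites(sub, cohort_size = sum(keep_samples$ancestry == a),
                         min_recip_overlap)
    f <- cls$sites$frequency[match(cls$calls$site_id, cls$sites$site_id)]
    out[[length(out) + 1]] <- cls$calls[f < freq_max,
                                        setdiff(names(cls$calls), "site_id"),
                                        drop = FALSE]
  }
  kept <- if (length(out)) do.call(rbind, out) else hq2[0, , drop = FALSE]
  rownames(kept) <- NULL
  list(calls = kept, removed_samples = removed,
       report = c(n_input = nrow(calls), n_removed_samples = length(removed),
                  n_qs_fail = sum(calls2$qs <= qs_min),
                  n_kept = nrow(kept)))
}

# For each call in `a`, TRUE if some call in `b` with same sample, chrom and
# type covers >= frac of a's exons (exon space) or bp (bp space).
match_calls <- function(a, b, frac = 0.5, space = c("exon", "bp")) {
  space <- match.arg(space)
  matched <- logical(nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(matched)
  key_b <- paste(b$sample, b$chrom, b$type)
  idx_b <- split(seq_len(nrow(b)), key_b)
  key_a <- paste(a$sample, a$chrom, a$type)
  for (i in seq_len(nrow(a))) {
    cand <- idx_b[[key_a[i]]]
    if (is.null(cand)) next
    if (space == "exon") {
      if (is.na(a$exon_lo[i]) || a$exon_count[i] == 0) next
      ov <- pmin(a$exon_hi[i], b$exon_hi[cand]) -
            pmax(a$exon_lo[i], b$exon_lo[cand]) + 1L
      ov[is.na(ov)] <- 0L
      matched[i] <- any(ov >= frac * a$exon_count[i], na.rm = TRUE)
    } else {
      ov <- bp_overlap(a$start[i], a$end[i], b$start[cand], b$end[cand])
      matched[i] <- any(ov >= frac * (a$end[i] - a$start[i]))
    }
  }
  matched
}

#' Recall and positive predictive value of a CNV callset
#'
#' A truth call is matched when the same sample has a same-type test call
#' covering at least `interval_fraction` of the truth call's captured exons
#' (exon space by default; `space = "bp"` uses bp overlap). A truth *site*
#' is recalled when at least `carrier_fraction` of its carriers are matched
#' (boundary inclusive). Recall at resolution `m` is computed over truth
#' sites spanning at least `m` exons; PPV applies the identical rule with
#' the roles of truth and test swapped. Carrier-level recall/PPV (the
#' fraction of individual calls matched) is reported alongside, and is the
#' quantity that tracks a planted carrier drop-out rate directly.
#'
#' @param truth,test CNV call data frames.
#' @param exons Exon interval set.
#' @param min_exons Integer vector of resolutions.
#' @param carrier_fraction Minimum matched-carrier fraction per site.
#' @param interval_fraction Minimum captured-interval overlap per call.
#' @param cohort_size Cohort size for site frequencies (defaults to carrier
#'   counts only; frequencies are not used in scoring).
#' @param min_recip_overlap Site-clustering threshold.
#' @param space `"exon"` or `"bp"` matching space.
#' @return Data frame with one row per `min_exons`: `n_truth_sites`,
#'   `recall`, `carrier_recall`, `n_test_sites`, `ppv`, `carrier_ppv`.
#' @export
match_and_score <- function(truth, test, exons,
                            min_exons = c(1, 2, 3, 4, 5, 10),
                            carrier_fraction = 0.5,
                            interval_fraction = 0.5,
                            cohort_size = NULL,
                            min_recip_overlap = 0.5,
                            space = c("exon", "bp")) {
  space <- match.arg(space)
  if (nrow(truth) == 0 || nrow(test) == 0) {
    out <- data.frame(min_exons = min_exons, n_truth_sites = 0L,
                      recall = NA_real_, carrier_recall = NA_real_,
                      n_test_sites = 0L, ppv = NA_real_,
                      carrier_ppv = NA_real_)
    attr(out, "reason") <- "empty callset"
    return(out)
  }
  if (is.null(cohort_size))
    cohort_size <- length(unique(c(truth$sample, test$sample)))
  truth <- annotate_exons(truth, exons)
  test <- annotate_exons(test, exons)

  score_dir <- function(a, b) {
    cl <- cluster_sites(a, cohort_size, min_recip_overlap)
    m <- match_calls(cl$calls, b, interval_fraction, space)
    site_ok <- tapply(m, cl$calls$site_id, mean) >= carrier_fraction
    site_exons <- tapply(
      ifelse(is.na(cl$calls$exon_count), 0L, cl$calls$exon_count),
      cl$calls$site_id, max)
    vapply(min_exons, function(me) {
      use <- site_exons >= me
      call_use <- cl$calls$exon_count >= me & !is.na(cl$calls$exon_count)
      c(n_sites = sum(use),
        site = if (any(use)) mean(site_ok[use]) else NA_real_,
        carrier = if (any(call_use)) mean(m[call_use]) else NA_real_)
    }, numeric(3))
  }
  rec <- score_dir(truth, test)
  ppv <- score_dir(test, truth)
  data.frame(min_exons = min_exons,
             n_truth_sites = as.integer(rec["n_sites", ]),
             recall = rec["site", ], carrier_recall = rec["carrier", ],
             n_test_sites = as.integer(ppv["n_sites", ]),
             ppv = ppv["site", ], carrier_ppv = ppv["carrier", ],
             row.names = NULL)
}

#' Detect de novo CNVs in quartet families
#'
#' A child's call is de novo when neither parent has a same-type call with
#' reciprocal bp overlap of at least `parent_overlap`; an opposite-type
#' parental call at the same locus does not rescue it. Children lacking
#' both parents in the pedigree are skipped and counted.
#'
#' @param calls CNV call data frame.
#' @param pedigree 6-column pedigree data frame ([read_pedigree()]).
#' @param parent_overlap Reciprocal-overlap threshold, default 0.5.
#' @return Data frame of de novo calls with a `fam` column; attribute
#'   `"n_skipped_children"`.
#' @export
de_novo_check <- function(calls, pedigree, parent_overlap = 0.5) {
  kids <- pedigree[pedigree$father != "0" & pedigree$mother != "0", ,
                   drop = FALSE]
  has_both <- kids$father %in% pedigree$id & kids$mother %in% pedigree$id
  skipped <- sum(!has_both)
  if (skipped > 0)
    message(sprintf("%d child(ren) without both parents skipped", skipped))
  kids <- kids[has_both, , drop = FALSE]
  res <- list()
  for (i in seq_len(nrow(kids))) {
    kid <- kids$id[i]
    kc <- calls[calls$sample == kid, , drop = FALSE]
    if (nrow(kc) == 0) next
    pc <- calls[calls$sample %in% c(kids$father[i], kids$mother[i]), ,
                drop = FALSE]
    dn <- vapply(seq_len(nrow(kc)), function(j) {
      cand <- pc[pc$type == kc$type[j] & pc$chrom == kc$chrom[j], ,
                 drop = FALSE]
      if (nrow(cand) == 0) return(TRUE)
      ov <- bp_overlap(kc$start[j], kc$end[j], cand$start, cand$end)
      lk <- kc$end[j] - kc$start[j]
      lp <- cand$end - cand$start
      !any(ov / lk >= parent_overlap & ov / lp >= parent_overlap)
    }, TRUE)
    if (any(dn)) {
      out <- kc[dn, , drop = FALSE]
      out$fam <- kids$fam[i]
      res[[length(res) + 1]] <- out
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    cbind(calls[0, , drop = FALSE], fam = character(0))
  rownames(out) <- NULL
  attr(out, "n_skipped_children") <- skipped
  out
}
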