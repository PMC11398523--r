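#' Merge per-batch allele frequencies into a cohort allele frequency
#'
#' The cohort frequency is the sample-size-weighted mean of batch
#' frequencies: `AFc = sum(AFi * Ni) / sum(Ni)`.
#'
#' @param n Integer vector of batch sample counts `Ni`.
#' @param af Numeric vector of batch allele frequencies `AFi`.
#' @return The cohort allele frequency.
#' @examples
#' merge_af(c(100, 300), c(0.1, 0.3)) # 0.25
#' @export
merge_af <- function(n, af) {
  if (length(n) == 0) stop("at least one batch required", call. = FALSE)
  stopifnot(length(n) == length(af), all(n >= 1),
            all(af >= 0 & af <= 1))
  sum(af * n) / sum(n)
}

#' Merge per-batch INFO scores into a cohort INFO score
#'
#' The INFO score at a site is one minus the ratio of uncaptured imputation
#' variance to the binomial genotype variance `2 N p (1 - p)`. Summing the
#' per-batch uncaptured variances `(1 - Ii) * 2 Ni AFi (1 - AFi)` and
#' re-normalizing by the pooled binomial variance gives
#'
#' `Ic = 1 - sum((1 - Ii) * 2 Ni AFi (1 - AFi)) / (2 sum(Ni) AFc (1 - AFc))`
#'
#' with `AFc` from [merge_af()]. Batches monomorphic at the site
#' (`AFi` 0 or 1) contribute zero to the numerator, so their (undefined)
#' `Ii` may be `NA`; when the cohort itself is monomorphic the result is
#' `NA`. When all batch frequencies are equal this reduces to the
#' `Ni`-weighted mean of the `Ii`.
#'
#' @param n Batch sample counts.
#' @param af Batch allele frequencies.
#' @param info Batch INFO scores (NA allowed only where `af` is 0 or 1).
#' @return The cohort INFO score, or `NA` for a monomorphic cohort.
#' @examples
#' merge_info(c(100, 100), c(0.2, 0.2), c(0.9, 0.7)) # 0.8
#' @export
merge_info <- function(n, af, info) {
  if (length(n) == 0) stop("at least one batch required", call. = FALSE)
  stopifnot(length(n) == length(af), length(n) == length(info))
  mono <- af <= 0 | af >= 1
  bad <- is.na(info) & !mono
  if (any(bad))
    stop("missing INFO score in polymorphic batch ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  afc <- merge_af(n, af)
  if (afc <= 0 || afc >= 1) return(NA_real_)
  num <- ifelse(mono, 0, (1 - info) * 2 * n * af * (1 - af))
  1 - sum(num) / (2 * sum(n) * afc * (1 - afc))
}

#' Merge per-batch imputed VCFs into one cohort callset
#'
#' Concatenates the genotype columns of per-batch imputation VCFs over their
#' shared site list (the intersection, with a message when batches
#' disagree), recomputing each site's allele frequency and INFO score for
#' the full sample size with [merge_af()] and [merge_info()]. Per-batch
#' frequencies are taken from the dosages as read (`mean(DS)/2` over
#' non-missing genotypes) and per-batch INFO scores from the GP posterior
#' variances, so the merged values agree exactly with a pooled computation
#' on the same data; the VCF INFO field is used only when GP is absent.
#' Sample order is batch order, then within-batch order.
#'
#' @param paths Character vector of per-batch VCF paths.
#' @param out Optional path for the merged VCF (DS+GP written when
#'   available).
#' @return List with `summary` (per-site chrom, pos, ref, alt, n_total,
#'   af_cohort, info_cohort, n_batches), `ds`, `gp`, `samples`, `sites`, and
#'   `out` (the path or NULL).
#' @export
merge_callsets <- function(paths, out = NULL) {
  stopifnot(length(paths) >= 1)
  batches <- lapply(paths, function(p) {
    ds <- read_genotype_vcf(p, "DS")
    gp <- tryCatch(read_genotype_vcf(p, "GP")$matrix, error = function(e) NULL)
    key <- with(ds$sites, paste(chrom, pos, ref, alt, sep = ":"))
    list(ds = ds$matrix, gp = gp, sites = ds$sites, samples = ds$samples,
         key = key)
  })
  all_samples <- unlist(lapply(batches, `[[`, "samples"))
  if (anyDuplicated(all_samples))
    stop("duplicate sample ids across batches: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "),
         call. = FALSE)
  shared <- Reduce(intersect, lapply(batches, `[[`, "key"))
  n_union <- length(unique(unlist(lapply(batches, `[[`, "key"))))
  if (length(shared) < n_union)
    message(sprintf("site intersection: %d shared of %d total sites",
                    length(shared), n_union))
  if (length(shared) == 0) {
    warning("no overlapping sites between batches: empty merge")
    return(list(summary = data.frame(), ds = NULL, gp = NULL,
                samples = all_samples, sites = data.frame(), out = NULL))
  }
  batches <- lapply(batches, function(b) {
    idx <- match(shared, b$key)
    b$ds <- b$ds[, idx, drop = FALSE]
    if (!is.null(b$gp)) b$gp <- lapply(b$gp, function(m) m[, idx, drop = FALSE])
    b$sites <- b$sites[idx, , drop = FALSE]
    b
  })
  nb <- length(batches)
  ni <- vapply(batches, function(b) length(b$samples), 1L)
  af_i <- vapply(batches, function(b) colMeans(b$ds, na.rm = TRUE) / 2,
                 numeric(length(shared)))
  af_i <- matrix(af_i, ncol = nb)
  info_i <- matrix(NA_real_, length(shared), nb)
  for (k in seq_len(nb)) {
    b <- batches[[k]]
    if (!is.null(b$gp)) {
      # raw (unclamped) per-batch INFO keeps the merge algebraically exact
      # against a pooled computation; only the cohort value is clamped
      pv <- b$gp$g1 + 4 * b$gp$g2 - (b$gp$g1 + 2 * b$gp$g2)^2
      denom <- 2 * af_i[, k] * (1 - af_i[, k])
      info_i[, k] <- ifelse(denom > 0,
                            1 - colMeans(pv, na.rm = TRUE) / denom,
                            NA_real_)
    } else {
      info_i[, k] <- b$sites$info
    }
  }
  af_c <- vapply(seq_along(shared), function(j) merge_af(ni, af_i[j, ]),
                 numeric(1))
  info_c <- vapply(seq_along(shared), function(j)
    merge_info(ni, af_i[j, ], info_i[j, ]), numeric(1))
  info_c <- pmin(pmax(info_c, 0), 1)
  ds <- do.call(rbind, lapply(batches, `[[`, "ds"))
  gp <- NULL
  if (all(vapply(batches, function(b) !is.null(b$gp), TRUE)))
    gp <- list(g0 = do.call(rbind, lapply(batches, function(b) b$gp$g0)),
               g1 = do.call(rbind, lapply(batches, function(b) b$gp$g1)),
               g2 = do.call(rbind, lapply(batches, function(b) b$gp$g2)))
  sites <- batches[[1]]$sites[c("chrom", "pos", "ref", "alt")]
  sites$af <- af_c
  sites$info <- info_c
  summary <- data.frame(sites[c("chrom", "pos", "ref", "alt")],
                        n_total = sum(ni), af_cohort = af_c,
                        info_cohort = info_c, n_batches = nb)
  if (!is.null(out))
    write_genotype_vcf(out, sites, all_samples, ds = ds, gp = gp)
  list(summary = summary, ds = ds, gp = gp, samples = all_samples,
       sites = sites, out = out)
}
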