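default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "bgeval_demo",
    cohort = list(
      n_samples = 600L, n_sites = 6000L, chrom_length_bp = 1e8,
      ancestries = c("AFR", "EUR"), admixture_proportions = c(0.5, 0.5),
      generations_since_admixture = 8, divergence_fst = 0.1,
      mean_coverage = 6, base_error = 0.01,
      array_error_rate = 1e-3, array_missing_rate = 5e-3,
      n_batches = 3L
    ),
    concord = list(
      min_info = 0.8,
      gp_thresholds = c(0, 0.8, 0.9),
      maf_edges = c(0, 0.005, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
    ),
    qc = list(
      min_dp = 10, min_gq = 20, het_ab_range = c(0.2, 0.8),
      homalt_ab_min = 0.8, min_exome_fraction = 0.90, min_wgs_coverage = 1,
      max_chimera = 0.05, max_contamination = 0.05, mad_k = 4,
      ancestry_threshold = 0.7
    ),
    cnv = list(
      n_families = 100L, n_exons = 3000L, n_transmitted = 40L,
      n_de_novo = 11L, dropout = 0.0, jitter_exons = 0L,
      qs_min = 200, freq_max = 0.01, max_rare_per_sample = 10,
      carrier_fraction = 0.5, interval_fraction = 0.5,
      parent_overlap = 0.5, min_exons = c(1, 2, 3, 4, 5, 10)
    )
  )
}

check_range <- function(value, lo, hi, key) {
  if (!is.numeric(value) || any(is.na(value)) || any(value < lo) ||
      any(value > hi))
    stop(sprintf("config value %s out of range [%g, %g]", key, lo, hi),
         call. = FALSE)
  invisible(value)
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), rejects unknown keys,
#' injects defaults for anything absent, and range-checks the thresholds.
#' An empty file yields the full default configuration.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return The normalized configuration list (class `bge_run_config`).
#' @export
validate_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
    else if (is.list(path)) path
    else yaml::read_yaml(path) %||% list()
  defaults <- default_run_config()
  merge_block <- function(def, usr, prefix) {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste(paste0(prefix, unknown), collapse = ", "), call. = FALSE)
    for (nm in names(usr)) {
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
        def[[nm]] <- merge_block(def[[nm]], usr[[nm]],
                                 paste0(prefix, nm, "."))
      } else def[[nm]] <- usr[[nm]]
    }
    def
  }
  cfg <- merge_block(defaults, user, "")
  check_range(cfg$concord$min_info, 0, 1, "concord.min_info")
  check_range(cfg$concord$gp_thresholds, 0, 1, "concord.gp_thresholds")
  if (is.unsorted(cfg$concord$maf_edges, strictly = TRUE))
    stop("concord.maf_edges must be strictly ascending", call. = FALSE)
  if (length(cfg$qc$het_ab_range) != 2 ||
      cfg$qc$het_ab_range[1] >= cfg$qc$het_ab_range[2])
    stop("qc.het_ab_range must be an ascending pair", call. = FALSE)
  check_range(cfg$qc$het_ab_range, 0, 1, "qc.het_ab_range")
  check_range(cfg$qc$ancestry_threshold, 0, 1, "qc.ancestry_threshold")
  check_range(cfg$cohort$base_error, 1e-9, 0.4999, "cohort.base_error")
  check_range(cfg$cnv$carrier_fraction, 0, 1, "cnv.carrier_fraction")
  check_range(cfg$cnv$interval_fraction, 0, 1, "cnv.interval_fraction")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("bge_run_config", "list")
  cfg
}

#' Run the synthetic end-to-end evaluation demo
#'
#' Simulates an admixed cohort, splits it into imputation batches, writes
#' and re-merges per-batch VCFs with corrected allele frequencies and INFO
#' scores, filters on INFO, computes MAF-binned aggregate R-squared and
#' non-reference concordance against simulated array truth, stratifies both
#' by diploid local ancestry via a written-and-reread msp file, and
#' benchmarks a planted quartet CNV callset including the de novo check.
#' All outputs are plain TSV/VCF/msp files under `out_dir`, plus a
#' `summary.yaml` recording the seed, the effective configuration and its
#' hash; a rerun with the same configuration reproduces every file
#' byte-for-byte.
#'
#' @param config A [validate_config()] result, a YAML path, or NULL for
#'   defaults.
#' @param out_dir Output directory (overrides the config entry).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main result tables (`merge_summary`,
#'   `concordance`, `lai`, `cnv`, `de_novo`, paths).
#' @export
run_demo <- function(config = NULL, out_dir = NULL, quiet = FALSE) {
  cfg <- if (inherits(config, "bge_run_config")) config else
    validate_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("demo stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  co <- cfg$cohort
  cc <- cohort_config(
    n_samples = co$n_samples, n_sites = co$n_sites,
    chrom_length_bp = co$chrom_length_bp, ancestries = co$ancestries,
    admixture_proportions = co$admixture_proportions,
    generations_since_admixture = co$generations_since_admixture,
    divergence_fst = co$divergence_fst, mean_coverage = co$mean_coverage,
    base_error = co$base_error, array_error_rate = co$array_error_rate,
    array_missing_rate = co$array_missing_rate, n_batches = co$n_batches,
    seed = cfg$seed
  )
  say("simulating cohort (%d x %d)", cc$n_samples, cc$n_sites)
  truth <- stage("simulate", simulate_truth(cc))
  dos <- stage("simulate", simulate_lowpass_dosages(truth, cc))
  array <- stage("simulate", simulate_array_genotypes(truth, cc))

  say("writing and merging %d batch VCF(s)", cc$n_batches)
  batches <- split_batches(truth$samples, cc$n_batches)
  paths <- character(0)
  merged <- stage("merge", {
    for (k in seq_along(batches)) {
      ids <- batches[[k]]
      p <- file.path(cfg$out_dir, sprintf("batch%02d.vcf", k))
      idx <- match(ids, truth$samples)
      bs <- dos$sites
      bs$af <- colMeans(dos$ds[idx, , drop = FALSE]) / 2
      bs$info <- NA_real_
      write_genotype_vcf(p, bs, ids, ds = dos$ds[idx, , drop = FALSE],
                         gp = lapply(dos$gp, function(m)
                           m[idx, , drop = FALSE]))
      paths <- c(paths, p)
    }
    merge_callsets(paths, out = file.path(cfg$out_dir, "cohort.vcf"))
  })
  write.table(merged$summary, file.path(cfg$out_dir, "sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  say("concordance vs array truth")
  scheme <- maf_bin_scheme(cfg$concord$maf_edges)
  conc <- stage("concord", {
    flt <- info_filter(merged$sites, cfg$concord$min_info, scheme)
    keep <- flt$keep
    maf <- pmin(merged$sites$af, 1 - merged$sites$af)[keep]
    tr <- array[, keep, drop = FALSE]
    dm <- merged$ds[, keep, drop = FALSE]
    gpk <- lapply(merged$gp, function(m) m[, keep, drop = FALSE])
    r2 <- aggregate_r2(tr, dm, maf, scheme)
    nrc <- nonref_concordance_by_bin(
      tr, hard_call(gp = gpk, rule = "argmax_gp"), maf, scheme)
    sweep <- gp_filter_sweep(tr, dm, gpk, cfg$concord$gp_thresholds, maf,
                             scheme)
    tab <- data.frame(r2[c("bin_lo", "bin_hi", "n_snps", "n_genotypes",
                           "r2")],
                      aggregate_nrc = nrc$concordance)
    list(tab = tab, sweep = sweep, keep = keep, maf = maf)
  })
  write.table(conc$tab, file.path(cfg$out_dir, "concord.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(conc$sweep, file.path(cfg$out_dir, "gp_sweep.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  say("local-ancestry stratified concordance")
  lai <- stage("lai-concord", {
    msp <- file.path(cfg$out_dir, "cohort.msp.tsv")
    write_msp(truth$tracts, msp)
    tracts <- read_msp(msp)
    stratified_metrics(array[, conc$keep, drop = FALSE],
                       merged$ds[, conc$keep, drop = FALSE],
                       tracts = tracts,
                       pos = truth$sites$pos[conc$keep],
                       maf = conc$maf, scheme = scheme)
  })
  write.table(lai, file.path(cfg$out_dir, "lai.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  say("CNV quartet benchmark")
  cv <- cfg$cnv
  cnv <- stage("cnv-bench", {
    exons <- make_exon_intervals(cv$n_exons)
    planted <- plant_cnv_quartets(
      cv$n_families, exons,
      plant_spec(n_transmitted = cv$n_transmitted, n_de_novo = cv$n_de_novo,
                 dropout = cv$dropout, jitter_exons = cv$jitter_exons),
      seed = cfg$seed)
    score <- match_and_score(planted$truth, planted$test, exons,
                             min_exons = cv$min_exons,
                             carrier_fraction = cv$carrier_fraction,
                             interval_fraction = cv$interval_fraction,
                             cohort_size = 4L * cv$n_families)
    dn <- de_novo_check(planted$test, planted$pedigree, cv$parent_overlap)
    write_cnv_calls(planted$truth, file.path(cfg$out_dir, "cnv_truth.tsv"))
    write_cnv_calls(planted$test, file.path(cfg$out_dir, "cnv_test.tsv"))
    write_pedigree(planted$pedigree, file.path(cfg$out_dir, "quartets.ped"))
    list(score = score, de_novo = dn)
  })
  write.table(cnv$score, file.path(cfg$out_dir, "cnv_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cnv$de_novo, file.path(cfg$out_dir, "de_novo.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  eff <- unclass(cfg)
  cfg_yaml <- yaml::as.yaml(eff)
  cfg_path <- file.path(cfg$out_dir, "effective_config.yaml")
  writeLines(cfg_yaml, cfg_path)
  summary <- list(seed = cfg$seed,
                  config_hash = unname(tools::md5sum(cfg_path)),
                  n_samples = cc$n_samples, n_sites = cc$n_sites,
                  n_batches = cc$n_batches,
                  package_version = as.character(utils::packageVersion("bgeval")))
  yaml::write_yaml(summary, file.path(cfg$out_dir, "summary.yaml"))
  say("demo complete: %s", cfg$out_dir)
  invisible(list(merge_summary = merged$summary, concordance = conc$tab,
                 gp_sweep = conc$sweep, lai = lai, cnv = cnv$score,
                 de_novo = cnv$de_novo, out_dir = cfg$out_dir))
}
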