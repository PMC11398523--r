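# File formats and dialects

All internal coordinates are 1-based, half-open `[start, end)`; conversion
happens only at the I/O boundary.

## VCF (read: `read_genotype_vcf`, write: `write_genotype_vcf`)

- FORMAT fields: `GT` (0/1/2 alternate-allele count, phasing ignored),
  `DS` (dosage in [0,2], 3 decimals), `GP` (posterior triple, 3 decimals,
  written so the rounded values sum to 1.000).
- INFO fields: `AF` (allele frequency), `INFO` (imputation INFO score).
- Multi-allelic records are skipped with a message; files must be
  coordinate-sorted; GP triples off the simplex by more than 1e-3 are set
  missing; `DS` is derived as `GP1 + 2*GP2` when only GP is present.

## msp.tsv (read: `read_msp`, write: `write_msp`)

RFMix2-style local-ancestry windows:

    #Subpopulation order/codes: AFR=0<TAB>EUR=1
    #chm  spos  epos  sgpos  egpos  n snps  S1.0  S1.1  S2.0  S2.1 ...
    chr1  1     50000 0.0    0.05   12      0     1     0     0

Two integer-code columns per sample (haplotypes `.0`/`.1`). Consecutive
windows with equal codes merge into maximal tracts on read; positions are
half-open.

## Intervals (read: `read_intervals`, write: `write_bed`)

- BED: 0-based half-open, `chrom start end`.
- Picard interval_list: 1-based closed, `@`-prefixed headers skipped.
- Both normalize to 1-based half-open; overlapping/abutting intervals
  merge.

## CNV calls (`read_cnv_calls` / `write_cnv_calls`)

TSV with header `sample chrom start end type qs`; `type` is `DEL` or
`DUP`; coordinates 1-based half-open; `qs` is the caller's quality score.

## Pedigree (`read_pedigree` / `write_pedigree`)

Headerless 6-column PED: `fam id father mother sex phenotype`; missing
parents are `0`; sex 1 = male, 2 = female.

## Report TSVs (written by `run_demo`)

- `sites.tsv`: chrom, pos, ref, alt, n_total, af_cohort, info_cohort,
  n_batches.
- `concord.tsv`: bin_lo, bin_hi, n_snps, n_genotypes, r2, aggregate_nrc.
- `gp_sweep.tsv`: threshold, bin_lo, bin_hi, n_snps, n_genotypes, r2,
  fraction_dropped.
- `lai.tsv`: background, bin_lo, bin_hi, n_genotypes, r2,
  nonref_concordance.
- `cnv_report.tsv`: min_exons, n_truth_sites, recall, carrier_recall,
  n_test_sites, ppv, carrier_ppv.
- `de_novo.tsv`: the de novo calls with a `fam` column.
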