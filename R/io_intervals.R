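#' Read genomic intervals from BED or Picard interval_list
#'
#' BED is 0-based half-open; interval_list is 1-based closed (its `@`
#' header lines are skipped). Both are normalized to the package-internal
#' convention of 1-based half-open intervals; overlapping or abutting
#' intervals are merged and the result is sorted.
#'
#' @param path Input file.
#' @param dialect `"bed"` or `"interval_list"`.
#' @return Data frame with `chrom`, `start`, `end` (1-based half-open).
#' @export
read_intervals <- function(path, dialect = c("bed", "interval_list")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^(@|#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "[\t ]+")
  chrom <- vapply(parts, `[`, "", 1L)
  a <- as.numeric(vapply(parts, `[`, "", 2L))
  b <- as.numeric(vapply(parts, `[`, "", 3L))
  if (dialect == "bed") {
    bad <- b < a
    start <- a + 1; end <- b + 1
  } else {
    bad <- b < a
    start <- a; end <- b + 1
  }
  if (any(is.na(a) | is.na(b)))
    stop(sprintf("non-numeric interval at line %d of %s",
                 lineno[which(is.na(a) | is.na(b))[1]], path), call. = FALSE)
  if (any(bad))
    stop(sprintf("end < start at line %d of %s", lineno[which(bad)[1]], path),
         call. = FALSE)
  merge_intervals(data.frame(chrom = chrom, start = start, end = end,
                             stringsAsFactors = FALSE))
}

#' Merge and sort 1-based half-open intervals
#'
#' @param intervals Data frame with `chrom`, `start`, `end`.
#' @return Merged, sorted data frame of the same shape.
#' @export
merge_intervals <- function(intervals) {
  gr <- intervals_to_gr(intervals)
  red <- GenomicRanges::reduce(gr)   # merges overlapping and abutting
  red <- GenomicRanges::sort(red)
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red),
             end = GenomicRanges::end(red) + 1L,
             stringsAsFactors = FALSE)
}

# internal half-open [start, end) -> closed IRanges [start, end-1]
intervals_to_gr <- function(intervals) {
  GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start, intervals$end - 1L)
  )
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (1-based
#'   half-open).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  write.table(data.frame(intervals$chrom, intervals$start - 1L,
                         intervals$end - 1L),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write CNV call tables
#'
#' Plain TSV with header `sample chrom start end type qs`; coordinates are
#' 1-based half-open, `type` is `DEL` or `DUP`.
#'
#' @param path File path.
#' @return Data frame of calls.
#' @export
read_cnv_calls <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "type", "qs")
  if (!all(need %in% names(d)))
    stop("CNV table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(d$end <= d$start)) stop("CNV calls must satisfy end > start",
                                  call. = FALSE)
  if (!all(d$type %in% c("DEL", "DUP")))
    stop("CNV type must be DEL or DUP", call. = FALSE)
  d[need]
}

#' @rdname read_cnv_calls
#' @param calls CNV call data frame.
#' @export
write_cnv_calls <- function(calls, path) {
  write.table(calls[c("sample", "chrom", "start", "end", "type", "qs")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write 6-column PED pedigree files
#'
#' Columns: family, id, father, mother, sex (1 = male, 2 = female),
#' phenotype. Missing parents are coded `"0"`.
#'
#' @param path File path.
#' @return Data frame with columns `fam`, `id`, `father`, `mother`, `sex`,
#'   `phenotype`.
#' @export
read_pedigree <- function(path) {
  d <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("fam", "id", "father", "mother", "sex",
                                "phenotype"))
  d$father <- as.character(d$father)
  d$mother <- as.character(d$mother)
  d
}

#' @rdname read_pedigree
#' @param pedigree Pedigree data frame.
#' @export
write_pedigree <- function(pedigree, path) {
  write.table(pedigree[c("fam", "id", "father", "mother", "sex", "phenotype")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
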