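#' Read RFMix2-style msp.tsv local-ancestry windows into tracts
#'
#' Expects the msp dialect: a first comment line carrying the subpopulation
#' code map (`#Subpopulation order/codes: AFR=0 EUR=1`), a header line
#' `#chm spos epos sgpos egpos n snps` followed by two integer code columns
#' per sample (`<id>.0`, `<id>.1`). Consecutive windows with identical codes
#' are merged into maximal tracts; positions are treated as 1-based
#' half-open.
#'
#' @param path msp.tsv file.
#' @return A `bge_tracts` data frame (see [simulate_tracts()]).
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("msp file too short: ", path, call. = FALSE)
  codes_line <- sub("^#[^:]*:\\s*", "", lines[1])
  kv <- strsplit(strsplit(trimws(codes_line), "[\t ]+")[[1]], "=", fixed = TRUE)
  code_map <- vapply(kv, function(x) as.integer(x[2]), 1L)
  names(code_map) <- vapply(kv, `[`, "", 1L)
  ancestries <- names(sort(code_map))
  header <- strsplit(sub("^#", "", lines[2]), "\t", fixed = TRUE)[[1]]
  hap_cols <- header[-(1:6)]
  if (length(hap_cols) %% 2 != 0)
    stop(sprintf("msp file has %d haplotype columns (odd count): %s",
                 length(hap_cols), path), call. = FALSE)
  d <- read.table(text = lines[-(1:2)], sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE)
  colnames(d) <- header
  samples <- unique(sub("\\.[01]$", "", hap_cols))
  out <- vector("list", length(hap_cols))
  for (k in seq_along(hap_cols)) {
    code <- d[[hap_cols[k]]]
    brk <- c(TRUE, code[-1] != code[-length(code)] |
                   d$spos[-1] != d$epos[-nrow(d)] |
                   d$chm[-1] != d$chm[-nrow(d)])
    starts <- which(brk)
    ends <- c(starts[-1] - 1L, nrow(d))
    out[[k]] <- data.frame(
      sample = sub("\\.[01]$", "", hap_cols[k]),
      hap = as.integer(sub("^.*\\.", "", hap_cols[k])),
      chrom = d$chm[starts],
      spos = as.numeric(d$spos[starts]),
      epos = as.numeric(d$epos[ends]),
      anc = as.integer(code[starts]),
      stringsAsFactors = FALSE
    )
  }
  tr <- do.call(rbind, out)
  rownames(tr) <- NULL
  new_tracts(tr, ancestries)
}

#' Write tracts as an RFMix2-style msp.tsv
#'
#' Windows are the union of all tract breakpoints across haplotypes, so a
#' write/read round trip reproduces the tracts exactly. Genetic positions use
#' the uniform 1 cM/Mb map.
#'
#' @param tracts A `bge_tracts` table (single chromosome).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_msp <- function(tracts, path) {
  stopifnot(inherits(tracts, "bge_tracts"))
  anc <- attr(tracts, "ancestries")
  if (length(unique(tracts$chrom)) != 1)
    stop("write_msp handles a single chromosome", call. = FALSE)
  bp <- sort(unique(c(tracts$spos, tracts$epos)))
  spos <- bp[-length(bp)]
  epos <- bp[-1]
  mid <- spos
  samples <- unique(tracts$sample)
  spl <- split_tracts(tracts)
  cols <- list()
  for (s in samples) for (h in 0:1) {
    cols[[paste(s, h, sep = ".")]] <-
      codes_from_tract_rows(spl[[paste(s, h, sep = "|")]], mid)
  }
  code_line <- paste0("#Subpopulation order/codes: ",
                      paste(sprintf("%s=%d", anc, seq_along(anc) - 1L),
                            collapse = "\t"))
  header <- paste(c("#chm", "spos", "epos", "sgpos", "egpos", "n snps",
                    names(cols)), collapse = "\t")
  body <- data.frame(chm = tracts$chrom[1], spos = spos, epos = epos,
                     sgpos = round(spos / 1e6, 4),
                     egpos = round(epos / 1e6, 4),
                     nsnps = 1L, stringsAsFactors = FALSE)
  for (nm in names(cols)) body[[nm]] <- cols[[nm]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(code_line, header), con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
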