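#' Read a genotype matrix from a VCF
#'
#' Loads one FORMAT field from a VCF into a samples x sites matrix together
#' with the site table. Internal conventions: genotypes coded 0/1/2/NA
#' (count of alternate alleles, phasing ignored); dosages clipped to
#' `[0, 2]`; GP triples renormalized when `|sum - 1| <= 1e-3` (the slack a
#' 3-decimal VCF needs) and set missing otherwise. Multi-allelic records are
#' skipped with a message; an unsorted file is an error.
#'
#' When `field = "DS"` and the file carries only GP, dosages are derived as
#' `GP1 + 2 GP2`.
#'
#' @param path VCF file.
#' @param field One of `"GT"`, `"DS"`, `"GP"`.
#' @return A list: `matrix` (samples x sites; for GP a list of three
#'   matrices `g0`,`g1`,`g2`), `sites` (chrom, pos, ref, alt, af, info, maf),
#'   `samples`, and `n_multiallelic_skipped`.
#' @export
read_genotype_vcf <- function(path, field = c("GT", "DS", "GP")) {
  field <- match.arg(field)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) stop("empty VCF: ", path, call. = FALSE)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    message(sprintf("skipping %d multi-allelic record(s)", n_multi))
    v <- v[!multi, ]
    fix <- v@fix
  }
  pos <- as.integer(fix[, "POS"])
  chrom <- fix[, "CHROM"]
  if (is.unsorted(order(match(chrom, unique(chrom)), pos)))
    stop("VCF is not coordinate-sorted: ", path, call. = FALSE)
  fmt <- v@gt[, 1]
  have <- function(f) all(vapply(strsplit(fmt, ":", fixed = TRUE),
                                 function(x) f %in% x, TRUE))
  af <- suppressWarnings(vcfR::extract.info(v, "AF", as.numeric = TRUE))
  info <- suppressWarnings(vcfR::extract.info(v, "INFO", as.numeric = TRUE))
  if (is.null(af)) af <- rep(NA_real_, nrow(fix))
  if (is.null(info)) info <- rep(NA_real_, nrow(fix))
  sites <- data.frame(chrom = chrom, pos = pos, ref = fix[, "REF"],
                      alt = fix[, "ALT"], af = af, info = info,
                      maf = pmin(af, 1 - af), stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  samples <- colnames(v@gt)[-1]

  read_gp <- function() {
    raw <- vcfR::extract.gt(v, "GP")
    parts <- strsplit(as.vector(raw), ",", fixed = TRUE)
    num <- vapply(parts, function(x)
      if (length(x) == 3) suppressWarnings(as.numeric(x)) else rep(NA_real_, 3),
      numeric(3))
    tot <- colSums(num)
    bad <- !is.na(tot) & abs(tot - 1) > 1e-3
    if (any(bad)) {
      warning(sprintf("%d GP triple(s) off-simplex by > 1e-3 set missing",
                      sum(bad)))
      num[, bad] <- NA_real_
    }
    ok <- !is.na(tot) & !bad
    num[, ok] <- sweep(num[, ok, drop = FALSE], 2, tot[ok], "/")
    dm <- list(rownames(raw), colnames(raw))
    shape <- function(k) t(matrix(num[k, ], nrow(raw), ncol(raw),
                                  dimnames = dm))
    list(g0 = shape(1), g1 = shape(2), g2 = shape(3))
  }

  mat <- switch(field,
    GT = {
      if (!have("GT")) stop("FORMAT field GT absent from ", path, call. = FALSE)
      raw <- vcfR::extract.gt(v, "GT")
      g <- matrix(NA_integer_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
      clean <- gsub("|", "/", raw, fixed = TRUE)
      g[clean == "0/0"] <- 0L
      g[clean == "0/1" | clean == "1/0"] <- 1L
      g[clean == "1/1"] <- 2L
      t(g)
    },
    DS = {
      if (have("DS")) {
        raw <- vcfR::extract.gt(v, "DS", as.numeric = TRUE)
        t(pmin(pmax(raw, 0), 2))
      } else if (have("GP")) {
        gp <- read_gp()
        gp$g1 + 2 * gp$g2
      } else stop("FORMAT field DS absent (and no GP to derive it) in ",
                  path, call. = FALSE)
    },
    GP = {
      if (!have("GP")) stop("FORMAT field GP absent from ", path, call. = FALSE)
      read_gp()
    }
  )
  list(matrix = mat, sites = sites, samples = samples,
       n_multiallelic_skipped = n_multi)
}

#' Write a genotype/dosage VCF
#'
#' Emits a minimal VCFv4.2 with any combination of GT, DS and GP FORMAT
#' fields (DS and GP rounded to 3 decimals) and per-site `AF`/`INFO` INFO
#' fields.
#'
#' @param path Output file.
#' @param sites Site table with `chrom`, `pos`, `ref`, `alt` and optionally
#'   `af`, `info`.
#' @param samples Character vector of sample ids.
#' @param gt Optional samples x sites integer matrix (0/1/2/NA).
#' @param ds Optional samples x sites dosage matrix.
#' @param gp Optional list of three samples x sites matrices.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(path, sites, samples, gt = NULL, ds = NULL,
                               gp = NULL) {
  stopifnot(!is.null(gt) || !is.null(ds) || !is.null(gp))
  ns <- nrow(sites)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bgeval",
           sprintf("##contig=<ID=%s>", unique(sites$chrom)),
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
           "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation INFO score\">")
  fields <- c(if (!is.null(gt)) "GT", if (!is.null(ds)) "DS",
              if (!is.null(gp)) "GP")
  if ("GT" %in% fields)
    hdr <- c(hdr, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if ("DS" %in% fields)
    hdr <- c(hdr, "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">")
  if ("GP" %in% fields)
    hdr <- c(hdr, "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype probabilities\">")
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", samples), collapse = "\t"))
  info_col <- rep(".", ns)
  if (!is.null(sites$af)) {
    info_col <- sprintf("AF=%.10g", sites$af)
    if (!is.null(sites$info))
      info_col <- paste0(info_col, ifelse(is.na(sites$info), "",
                                          sprintf(";INFO=%.10g", sites$info)))
  }
  per <- vector("list", length(fields))
  names(per) <- fields
  if (!is.null(gt)) {
    m <- matrix("./.", nrow(gt), ncol(gt))
    m[!is.na(gt) & gt == 0L] <- "0/0"
    m[!is.na(gt) & gt == 1L] <- "0/1"
    m[!is.na(gt) & gt == 2L] <- "1/1"
    per$GT <- m
  }
  fmt3 <- function(x) ifelse(is.na(x), ".", sprintf("%.3f", x))
  if (!is.null(ds)) per$DS <- matrix(fmt3(ds), nrow(ds), ncol(ds))
  if (!is.null(gp)) {
    # round so the written triple still sums to 1.000: the largest
    # component absorbs the rounding remainder of the other two
    r0 <- round(gp$g0, 3); r1 <- round(gp$g1, 3); r2 <- round(gp$g2, 3)
    imax <- pmax(gp$g0, gp$g1, gp$g2)
    fix0 <- gp$g0 == imax
    fix1 <- !fix0 & gp$g1 == imax
    fix2 <- !fix0 & !fix1
    r0[fix0] <- 1 - r1[fix0] - r2[fix0]
    r1[fix1] <- 1 - r0[fix1] - r2[fix1]
    r2[fix2] <- 1 - r0[fix2] - r1[fix2]
    per$GP <- matrix(paste(fmt3(r0), fmt3(r1), fmt3(r2), sep = ","),
                     nrow(gp$g0), ncol(gp$g0))
  }
  cells <- per[[1]]
  if (length(per) > 1)
    for (k in 2:length(per)) cells <- matrix(paste(cells, per[[k]], sep = ":"),
                                             nrow(cells), ncol(cells))
  # cells is samples x sites; VCF rows are sites
  body <- vapply(seq_len(ns), function(j)
    paste(c(sites$chrom[j], sites$pos[j], ".", sites$ref[j], sites$alt[j],
            ".", "PASS", info_col[j], paste(fields, collapse = ":"),
            cells[, j]), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
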