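#' Read panel genotypes from VCF or the tabular dialect
#'
#' Two formats are supported. VCF 4.x is parsed with
#' [VariantAnnotation::readVcf()]; diploid genotypes map as 0/0 -> -1,
#' 0/1 -> 0, 1/1 -> +1, ./. -> NA; non-biallelic or non-SNP records are
#' skipped with a warning giving their count. The tabular dialect is a TSV
#' with a header row of marker ids (`SNP-<chrom>.<pos>`), one row per line
#' (first column the line id), and cells in \{A, H, B, N\} or
#' \{-1, 0, 1, NA\}; optional `#ref_alleles` / `#alt_alleles` comment lines
#' (tab-separated, aligned with the marker columns) carry alleles, which
#' otherwise default to A/T.
#'
#' @param path input file
#' @param format `"auto"` (by extension), `"vcf"` or `"tabular"`
#' @return a [GenotypePanel-class]
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tabular")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) "vcf" else "tabular"
  switch(format, vcf = .readVcfPanel(path), tabular = .readTabularPanel(path))
}

.readVcfPanel <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(altL)
  alt1 <- rep(NA_character_, length(nalt))
  alt1[nalt == 1L] <- as.character(unlist(altL[nalt == 1L]))
  ok <- nalt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L
  if (any(!ok))
    warning(sum(!ok), " non-biallelic-SNP record(s) skipped")
  vcf <- vcf[ok, ]
  gt <- VariantAnnotation::geno(vcf)$GT
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gt2 <- gsub("\\|", "/", gt)
  code[gt2 == "0/0"] <- -1L
  code[gt2 %in% c("0/1", "1/0")] <- 0L
  code[gt2 == "1/1"] <- 1L
  rr <- SummarizedExperiment::rowRanges(vcf)
  markers <- data.frame(
    chromosome = as.character(GenomeInfoDb::seqnames(rr)),
    position = GenomicRanges::start(rr),
    ref_allele = ref[ok], alt_allele = alt1[ok])
  markers$id <- makeMarkerIds(markers$chromosome, markers$position)
  GenotypePanel(code, markers, data.frame(id = colnames(gt)))
}

.readTabularPanel <- function(path) {
  all_lines <- readLines(path)
  meta <- grep("^#", all_lines)
  refA <- altA <- NULL
  for (i in meta) {
    f <- strsplit(all_lines[i], "\t", fixed = TRUE)[[1]]
    if (f[1] == "#ref_alleles") refA <- f[-1]
    if (f[1] == "#alt_alleles") altA <- f[-1]
  }
  body <- all_lines[setdiff(seq_along(all_lines), meta)]
  if (!length(body)) stop("tabular parse error at line 1: no header row")
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2)
    stop("tabular parse error at line 1: header must name at least one marker")
  ids <- hdr[-1]
  parsed <- regmatches(ids, regexec("^SNP-(.+)\\.([0-9]+)$", ids))
  bad <- which(vapply(parsed, length, 1L) != 3L)
  if (length(bad))
    stop("tabular parse error at line 1: malformed marker id '", ids[bad[1]], "'")
  chrom <- vapply(parsed, `[`, "", 2L)
  pos <- as.integer(vapply(parsed, `[`, "", 3L))
  nm <- length(ids)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  nf <- vapply(rows, length, 1L)
  if (any(nf != nm + 1L)) {
    j <- which(nf != nm + 1L)[1]
    stop("tabular parse error at line ", meta_offset(meta, j + 1L),
         ": expected ", nm + 1L, " fields, found ", nf[j])
  }
  lid <- vapply(rows, `[`, "", 1L)
  cells <- t(vapply(rows, function(r) r[-1], character(nm)))
  code <- matrix(NA_integer_, nrow = nm, ncol = length(lid))
  tr <- c(A = -1L, H = 0L, B = 1L, `-1` = -1L, `0` = 0L, `1` = 1L)
  flat <- t(cells)                      # markers x lines
  known <- flat %in% names(tr) | flat %in% c("N", "NA", "")
  if (any(!known))
    stop("tabular parse error: unknown genotype code '", flat[!known][1], "'")
  idx <- match(flat, names(tr))
  code[] <- tr[idx]
  if (is.null(refA)) refA <- rep("A", nm)
  if (is.null(altA)) altA <- rep("T", nm)
  markers <- data.frame(id = ids, chromosome = chrom, position = pos,
                        ref_allele = refA, alt_allele = altA)
  GenotypePanel(code, markers, data.frame(id = lid))
}

meta_offset <- function(meta, bodyLine) {
  # physical line number of the bodyLine-th non-comment line
  n <- bodyLine
  for (m in sort(meta)) if (m <= n) n <- n + 1L
  n
}

#' Write panel genotypes
#'
#' Writes either a minimal VCFv4.2 (GT field only) or the tabular TSV
#' dialect described in [readGenotypes()]. Both round-trip losslessly
#' through the corresponding reader.
#'
#' @param panel a [GenotypePanel-class]
#' @param path output file
#' @param format `"vcf"` or `"tabular"`
#' @return `path`, invisibly
#' @export
writeGenotypes <- function(panel, path, format = c("vcf", "tabular")) {
  format <- match.arg(format)
  g <- genotypes(panel)
  mi <- markerInfo(panel)
  if (format == "vcf") {
    gt <- matrix("./.", nrow(g), ncol(g))
    gt[!is.na(g) & g == -1L] <- "0/0"
    gt[!is.na(g) & g == 0L] <- "0/1"
    gt[!is.na(g) & g == 1L] <- "1/1"
    hdr <- c("##fileformat=VCFv4.2",
             "##source=panelGWAS",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", lineIds(panel)), collapse = "\t"))
    recs <- cbind(mi$chromosome, mi$position, mi$id, mi$ref_allele,
                  mi$alt_allele, ".", ".", ".", "GT", gt)
    writeLines(c(hdr, apply(recs, 1, paste, collapse = "\t")), path)
  } else {
    tr <- c("A", "H", "B")
    cells <- matrix("N", nrow(g), ncol(g))
    nz <- !is.na(g)
    cells[nz] <- tr[g[nz] + 2L]
    out <- c(paste(c("#ref_alleles", mi$ref_allele), collapse = "\t"),
             paste(c("#alt_alleles", mi$alt_allele), collapse = "\t"),
             paste(c("line_id", mi$id), collapse = "\t"),
             vapply(seq_len(ncol(g)), function(j)
               paste(c(lineIds(panel)[j], cells[, j]), collapse = "\t"), ""))
    writeLines(out, path)
  }
  invisible(path)
}

#' Read/write line metadata
#'
#' CSV with columns `id`, one `ancestry.<subpop>` column per subpopulation
#' and optionally `assigned_group`.
#'
#' @param path CSV file
#' @return data.frame with `id`, matrix column `ancestry`, `assigned_group`
#' @export
readLineInfo <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  acol <- grep("^ancestry\\.", names(df), value = TRUE)
  out <- data.frame(id = df$id)
  if (length(acol)) {
    anc <- as.matrix(df[acol])
    colnames(anc) <- sub("^ancestry\\.", "", acol)
    out$ancestry <- I(anc)
  }
  if ("assigned_group" %in% names(df)) out$assigned_group <- df$assigned_group
  out
}

#' @rdname readLineInfo
#' @param info line metadata as returned by [lineInfo()]
#' @export
writeLineInfo <- function(info, path) {
  df <- data.frame(id = info$id)
  if (!is.null(info$ancestry)) {
    anc <- as.matrix(info$ancestry)
    for (s in colnames(anc)) df[[paste0("ancestry.", s)]] <- anc[, s]
  }
  if (!is.null(info$assigned_group)) df$assigned_group <- info$assigned_group
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a replicated multi-environment phenotype table
#'
#' CSV with columns `line_id`, `environment`, `replicate`, `value` (trait
#' units, e.g. mm). (line, environment, replicate) combinations must be
#' unique and values finite.
#'
#' @param path CSV file
#' @return validated data.frame
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.csv(path)
  validatePhenotypes(df)
}

#' @rdname readPhenotypes
#' @param pheno a phenotype data.frame
#' @export
validatePhenotypes <- function(pheno) {
  need <- c("line_id", "environment", "replicate", "value")
  if (!all(need %in% names(pheno)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  key <- paste(pheno$line_id, pheno$environment, pheno$replicate)
  if (anyDuplicated(key))
    stop("duplicate (line, environment, replicate) combinations")
  if (any(!is.finite(pheno$value)))
    stop("phenotype values must be finite")
  pheno
}

#' Per-line phenotype means
#'
#' Collapses a replicated phenotype table to one mean per line (the scale
#' on which association scans are run).
#'
#' @param pheno phenotype data.frame (see [readPhenotypes()])
#' @return named numeric vector of line means
#' @export
lineMeans <- function(pheno) {
  ids <- unique(as.character(pheno$line_id))
  m <- tapply(pheno$value, as.character(pheno$line_id), mean)
  setNames(as.numeric(m[ids]), ids)
}
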