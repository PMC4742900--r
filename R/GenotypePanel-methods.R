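#' Build a GenotypePanel
#'
#' @param genotypes integer matrix, markers in rows, lines in columns, values
#'   in \{-1, 0, +1, NA\} (AA = -1, AB = 0, BB = +1).
#' @param markers data.frame with columns `id`, `chromosome`, `position`
#'   (1-based), `ref_allele`, `alt_allele`. If `id` is absent, ids of the
#'   form `SNP-<chrom>.<position>` are generated.
#' @param lines data.frame with column `id`; optionally an `ancestry` matrix
#'   column (fractions over named subpopulations, each row summing to 1) and
#'   `assigned_group`.
#' @return a [GenotypePanel-class]. Markers are sorted by (chromosome,
#'   position).
#' @examples
#' g <- matrix(c(-1L, 1L, 0L, NA), nrow = 2,
#'             dimnames = list(NULL, c("L1", "L2")))
#' mk <- data.frame(chromosome = "1", position = c(100L, 200L),
#'                  ref_allele = "A", alt_allele = c("T", "G"))
#' gp <- GenotypePanel(g, mk, data.frame(id = c("L1", "L2")))
#' @export
GenotypePanel <- function(genotypes, markers, lines = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  markers <- as.data.frame(markers)
  stopifnot(nrow(markers) == nrow(genotypes))
  if (is.null(markers$id))
    markers$id <- makeMarkerIds(markers$chromosome, markers$position)
  if (is.null(lines)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- sprintf("L%03d", seq_len(ncol(genotypes)))
    lines <- data.frame(id = ids)
  }
  lines <- as.data.frame(lines)
  stopifnot(nrow(lines) == ncol(genotypes))
  if (anyDuplicated(lines$id)) stop("line ids must be unique")
  o <- order(markers$chromosome, markers$position)
  markers <- markers[o, , drop = FALSE]
  genotypes <- genotypes[o, , drop = FALSE]
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(markers$chromosome),
    ranges = IRanges::IRanges(start = as.integer(markers$position), width = 1L))
  names(rr) <- markers$id
  rd <- S4Vectors::DataFrame(
    ref_allele = as.character(markers$ref_allele),
    alt_allele = as.character(markers$alt_allele))
  S4Vectors::mcols(rr) <- rd
  cd <- S4Vectors::DataFrame(row.names = lines$id)
  if (!is.null(lines$ancestry)) {
    anc <- as.matrix(lines$ancestry)
    if (any(anc < -1e-9 | anc > 1 + 1e-9))
      stop("ancestry fractions must lie in [0, 1]")
    if (any(abs(rowSums(anc) - 1) > 1e-9))
      stop("ancestry fractions must sum to 1 per line")
    cd$ancestry <- anc
  }
  if (!is.null(lines$assigned_group)) cd$assigned_group <- lines$assigned_group
  dimnames(genotypes) <- list(markers$id, lines$id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotype = genotypes), rowRanges = rr, colData = cd)
  methods::new("GenotypePanel", se)
}

#' Marker id dialect
#'
#' Ids take the form `SNP-<chromosome>.<position>`.
#' @param chromosome,position vectors of equal length
#' @return character vector of marker ids
#' @export
makeMarkerIds <- function(chromosome, position) {
  sprintf("SNP-%s.%d", as.character(chromosome), as.integer(position))
}

#' @rdname genotypes
#' @export
setGeneric("genotypes", function(x, ...) standardGeneric("genotypes"))

#' Accessors for GenotypePanel
#'
#' `genotypes()` returns the markers-by-lines genotype matrix;
#' `markerInfo()` a data.frame of marker metadata; `lineInfo()` a data.frame
#' of line metadata (with an `ancestry` matrix column when present);
#' `nMarkers()`/`nLines()` the dimensions; `markerIds()`/`lineIds()` the
#' identifiers.
#'
#' @param x a [GenotypePanel-class]
#' @param ... unused
#' @return see description
#' @export
setMethod("genotypes", "GenotypePanel", function(x, ...) {
  SummarizedExperiment::assay(x, "genotype")
})

#' @rdname genotypes
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname genotypes
#' @export
setMethod("markerInfo", "GenotypePanel", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(
    id = names(rr),
    chromosome = as.character(GenomeInfoDb::seqnames(rr)),
    position = GenomicRanges::start(rr),
    ref_allele = S4Vectors::mcols(rr)$ref_allele,
    alt_allele = S4Vectors::mcols(rr)$alt_allele,
    row.names = NULL)
})

#' @rdname genotypes
#' @export
setGeneric("lineInfo", function(x) standardGeneric("lineInfo"))

#' @rdname genotypes
#' @export
setMethod("lineInfo", "GenotypePanel", function(x) {
  cd <- SummarizedExperiment::colData(x)
  out <- data.frame(id = rownames(cd), row.names = NULL)
  if ("ancestry" %in% colnames(cd)) out$ancestry <- I(as.matrix(cd$ancestry))
  if ("assigned_group" %in% colnames(cd)) out$assigned_group <- cd$assigned_group
  out
})

#' @rdname genotypes
#' @export
nMarkers <- function(x) nrow(x)

#' @rdname genotypes
#' @export
nLines <- function(x) ncol(x)

#' @rdname genotypes
#' @export
markerIds <- function(x) rownames(x)

#' @rdname genotypes
#' @export
lineIds <- function(x) colnames(x)

#' Subset a panel to a genomic region
#'
#' @param x a [GenotypePanel-class]
#' @param chromosome chromosome label
#' @param start,end 1-based closed interval bounds
#' @return the panel restricted to markers within the region
#' @export
subsetRegion <- function(x, chromosome, start, end) {
  stopifnot(start <= end)
  mi <- markerInfo(x)
  keep <- mi$chromosome == as.character(chromosome) &
    mi$position >= start & mi$position <= end
  x[keep, ]
}

setMethod("show", "GenotypePanel", function(object) {
  cat(sprintf("GenotypePanel: %d markers x %d lines\n",
              nrow(object), ncol(object)))
  chr <- as.character(GenomeInfoDb::seqnames(SummarizedExperiment::rowRanges(object)))
  if (length(chr))
    cat("chromosomes:", paste(unique(chr), collapse = ", "), "\n")
  g <- genotypes(object)
  cat(sprintf("missing: %.2f%%  heterozygous: %.2f%%\n",
              100 * mean(is.na(g)), 100 * mean(g == 0L, na.rm = TRUE)))
  cd <- SummarizedExperiment::colData(object)
  if ("assigned_group" %in% colnames(cd)) {
    tb <- table(cd$assigned_group)
    cat("groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
})
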