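#' @import methods
#' @importFrom stats var cor sd median quantile rnorm runif rbeta rbinom
#'   pt qchisq qbeta setNames aov anova p.adjust fisher.test chisq.test
#'   t.test optimize complete.cases prcomp qnorm pchisq ks.test rmultinom
#'   ppoints
#' @importFrom utils head tail read.csv write.csv
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData rowRanges
#' @importFrom GenomicRanges GRanges start end strand granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame mcols queryHits
#' @importFrom GenomeInfoDb seqnames
#' @importFrom Rcpp evalCpp
#' @useDynLib panelGWAS, .registration = TRUE
NULL

#' Container for inbred-panel genotypes
#'
#' `GenotypePanel` holds a lines-by-markers genotype table in the additive
#' coding AA = -1, AB = 0, BB = +1 (NA = missing), together with marker
#' metadata (chromosome, 1-based position, ref/alt alleles) and line
#' metadata (subpopulation ancestry fractions and assigned group). It
#' extends [SummarizedExperiment::RangedSummarizedExperiment-class]: markers
#' are rows (with genomic coordinates in `rowRanges`), lines are columns.
#'
#' Markers are kept sorted by (chromosome, position). Because the panels
#' this package targets are purified inbred lines, heterozygous calls are
#' expected to be rare but are fully supported.
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment-class];
#'   the single assay is named `"genotype"`.
#' @seealso [GenotypePanel()], [genotypes()], [markerInfo()], [lineInfo()]
#' @export
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'genotype' is required")
  else {
    g <- SummarizedExperiment::assay(object, "genotype")
    bad <- !(g %in% c(-1L, 0L, 1L)) & !is.na(g)
    if (any(bad))
      msg <- c(msg, "genotype values must be in {-1, 0, +1} or NA")
  }
  rd <- SummarizedExperiment::rowData(object)
  for (fld in c("ref_allele", "alt_allele"))
    if (!fld %in% colnames(rd)) msg <- c(msg, sprintf("rowData lacks '%s'", fld))
  if (all(c("ref_allele", "alt_allele") %in% colnames(rd)) && nrow(rd) > 0 &&
      any(rd$ref_allele == rd$alt_allele))
    msg <- c(msg, "ref and alt alleles must differ")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "line ids must be unique")
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(object))
  if (length(pos) && any(pos < 1L))
    msg <- c(msg, "marker positions must be 1-based (>= 1)")
  # sorted by (chromosome, position)
  chr <- as.character(GenomeInfoDb::seqnames(SummarizedExperiment::rowRanges(object)))
  if (length(pos) > 1) {
    o <- order(chr, pos)
    if (!identical(o, seq_along(pos)))
      msg <- c(msg, "markers must be sorted by (chromosome, position)")
  }
  if (length(msg)) msg else TRUE
})
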