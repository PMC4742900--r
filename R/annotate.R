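#' Load gene models from GFF3
#'
#' Reads a GFF3 annotation (e.g. the MSU7 rice gene models) and extracts
#' per-transcript exon, CDS, 5'/3' UTR intervals, derived introns (gaps
#' between exons) and the putative promoter/regulatory region (PPR), the
#' 2 kb immediately upstream of the transcription start site,
#' strand-aware: `[TSS-2000, TSS-1]` on +, `[end+1, end+2000]` on -.
#'
#' @param path GFF3 file
#' @param pprBp PPR width upstream of the TSS (default 2000)
#' @return a `GRanges` of features with metadata columns `type` (exon,
#'   intron, utr5, utr3, ppr, transcript) and `transcript`
#' @export
readGeneModels <- function(path, pprBp = 2000) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  txId <- function(x) {
    id <- as.character(x$ID)
    if (all(is.na(id)) || is.null(id)) id <- rep(NA_character_, length(x))
    id
  }
  parentOf <- function(x) {
    p <- x$Parent
    vapply(as.list(p), function(v) if (length(v)) as.character(v[1]) else NA_character_, "")
  }
  tx <- gff[type %in% c("mRNA", "transcript")]
  if (!length(tx)) tx <- gff[type == "gene"]
  txIds <- txId(tx)
  bad <- is.na(txIds)
  if (any(bad)) {
    warning(sum(bad), " malformed transcript record(s) skipped")
    tx <- tx[!bad]; txIds <- txIds[!bad]
  }
  pieces <- list()
  add <- function(gr, typ, parent) {
    if (!length(gr)) return()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(type = typ, transcript = parent)
    pieces[[length(pieces) + 1]] <<- gr
  }
  typeMap <- c(exon = "exon", five_prime_UTR = "utr5", three_prime_UTR = "utr3",
               CDS = "cds")
  for (t in names(typeMap)) {
    sub <- gff[type == t]
    if (!length(sub)) next
    add(GenomicRanges::granges(sub), typeMap[[t]], parentOf(sub))
  }
  # introns: per transcript, gaps between its exons
  exons <- gff[type == "exon"]
  if (length(exons)) {
    par <- parentOf(exons)
    for (p in unique(par[!is.na(par)])) {
      ex <- IRanges::reduce(GenomicRanges::granges(exons[par == p]))
      if (length(ex) < 2) next
      o <- order(GenomicRanges::start(ex))
      ex <- ex[o]
      intr <- GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(ex)[-1],
        IRanges::IRanges(start = GenomicRanges::end(ex)[-length(ex)] + 1L,
                         end = GenomicRanges::start(ex)[-1] - 1L),
        strand = GenomicRanges::strand(ex)[-1])
      intr <- intr[GenomicRanges::width(intr) > 0]
      add(intr, "intron", p)
    }
  }
  # transcript bodies + PPR
  add(GenomicRanges::granges(tx), "transcript", txIds)
  plus <- as.character(GenomicRanges::strand(tx)) != "-"
  pprStart <- ifelse(plus, pmax(GenomicRanges::start(tx) - pprBp, 1L),
                     GenomicRanges::end(tx) + 1L)
  pprEnd <- ifelse(plus, pmax(GenomicRanges::start(tx) - 1L, 1L),
                   GenomicRanges::end(tx) + pprBp)
  ok <- pprEnd >= pprStart & (plus & GenomicRanges::start(tx) > 1L | !plus)
  ppr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(tx)[ok],
                                IRanges::IRanges(pprStart[ok], pprEnd[ok]),
                                strand = GenomicRanges::strand(tx)[ok])
  add(ppr, "ppr", txIds[ok])
  out <- suppressWarnings(do.call(c, pieces))
  out
}

#' Classify SNPs into functional categories
#'
#' Collects every category a SNP overlaps across all gene models (exonic,
#' intronic, utr5, utr3, ppr), then assigns the primary category by the
#' priority order exonic > intronic > UTR (5'/3') > PPR; SNPs touching
#' nothing are intergenic. The exonic category is taken from exon
#' intervals; positions inside a transcript but in no exon/UTR are
#' intronic.
#'
#' @param positions data.frame with `chromosome` and `position` (or a
#'   [GenotypePanel-class], whose markers are used)
#' @param models gene-model `GRanges` from [readGeneModels()]
#' @return data.frame: `chromosome`, `position`, `categories`
#'   (comma-separated), `primary`
#' @export
classifySnps <- function(positions, models) {
  if (methods::is(positions, "GenotypePanel")) positions <- markerInfo(positions)
  snps <- GenomicRanges::GRanges(as.character(positions$chromosome),
                                 IRanges::IRanges(positions$position, width = 1L))
  typ <- as.character(models$type)
  cats <- matrix(FALSE, length(snps), 5,
                 dimnames = list(NULL, c("exonic", "intronic", "utr5",
                                         "utr3", "ppr")))
  mark <- function(sel, col) {
    if (!any(sel)) return()
    hits <- GenomicRanges::findOverlaps(snps, models[sel], ignore.strand = TRUE)
    cats[unique(S4Vectors::queryHits(hits)), col] <<- TRUE
  }
  # coding exon intervals define the exonic category when CDS features are
  # present (UTRs sit inside exon intervals, so raw exons would shadow
  # them under the priority rule); exon intervals are the fallback for
  # annotations without CDS records
  if (any(typ == "cds")) mark(typ == "cds", "exonic")
  else mark(typ == "exon", "exonic")
  mark(typ == "intron", "intronic")
  mark(typ == "utr5", "utr5")
  mark(typ == "utr3", "utr3")
  mark(typ == "ppr", "ppr")
  prio <- c("exonic", "intronic", "utr5", "utr3", "ppr")
  primary <- apply(cats, 1, function(r) {
    hit <- prio[r[prio]]
    if (length(hit)) hit[1] else "intergenic"
  })
  data.frame(chromosome = as.character(positions$chromosome),
             position = positions$position,
             categories = apply(cats, 1, function(r)
               paste(colnames(cats)[r], collapse = ",")),
             primary = primary)
}

#' Coding consequence of a SNP within a codon
#'
#' Translates the reference codon and the mutated codon with the standard
#' genetic code (codons supplied in coding orientation; minus-strand
#' handling is the caller's responsibility) and classifies the change.
#'
#' @param codonRef 3-base reference codon (coding strand)
#' @param posInCodon position of the SNP within the codon (1, 2 or 3)
#' @param altBase substituted base (coding strand)
#' @return one of "synonymous", "non-synonymous", "stop_gain",
#'   "stop_loss", or "unknown" for ambiguous bases
#' @examples
#' codingEffect("GCT", 3, "C")   # synonymous (Ala -> Ala)
#' codingEffect("TAC", 3, "A")   # stop_gain
#' @export
codingEffect <- function(codonRef, posInCodon, altBase) {
  codonRef <- toupper(codonRef)
  altBase <- toupper(altBase)
  stopifnot(nchar(codonRef) == 3, posInCodon %in% 1:3, nchar(altBase) == 1)
  bases <- strsplit(codonRef, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")) || !altBase %in% c("A", "C", "G", "T"))
    return("unknown")
  gc <- Biostrings::GENETIC_CODE
  aaRef <- gc[[codonRef]]
  bases[posInCodon] <- altBase
  aaAlt <- gc[[paste(bases, collapse = "")]]
  if (aaRef == "*" && aaAlt != "*") return("stop_loss")
  if (aaRef != "*" && aaAlt == "*") return("stop_gain")
  if (aaRef == aaAlt) "synonymous" else "non-synonymous"
}

#' Category frequency table for a set of SNP annotations
#'
#' @param annotations data.frame from [classifySnps()]
#' @return list: `byPrimary` (count and fraction per primary category),
#'   `genicSplit` (fractions of genic SNPs in exon/intron/UTR5/UTR3, by
#'   primary category), `pprFractionOfIntergenic`
#' @export
annotationSummary <- function(annotations) {
  lev <- c("exonic", "intronic", "utr5", "utr3", "ppr", "intergenic")
  if (!nrow(annotations)) {
    tb <- setNames(integer(length(lev)), lev)
    return(list(byPrimary = data.frame(category = lev, count = 0L, fraction = 0),
                genicSplit = setNames(rep(NA_real_, 4),
                                      c("exonic", "intronic", "utr5", "utr3")),
                pprFractionOfIntergenic = NA_real_))
  }
  tb <- table(factor(annotations$primary, levels = lev))
  byPrimary <- data.frame(category = lev, count = as.integer(tb),
                          fraction = as.integer(tb) / nrow(annotations))
  genic <- sum(tb[c("exonic", "intronic", "utr5", "utr3")])
  genicSplit <- if (genic > 0)
    setNames(as.numeric(tb[c("exonic", "intronic", "utr5", "utr3")]) / genic,
             c("exonic", "intronic", "utr5", "utr3"))
  else setNames(rep(NA_real_, 4), c("exonic", "intronic", "utr5", "utr3"))
  nonGenic <- sum(tb[c("ppr", "intergenic")])
  list(byPrimary = byPrimary, genicSplit = genicSplit,
       pprFractionOfIntergenic = if (nonGenic > 0) as.numeric(tb["ppr"]) / nonGenic
                                 else NA_real_)
}
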