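#' Call QTL peaks from a scan
#'
#' A region qualifies as a peak when it contains at least one SNP with
#' P < `pMs` supported by at least `minSupport` additional SNPs with
#' P < `pSupport` within `windowBp` on either side. Overlapping qualified
#' windows on a chromosome are merged into a single peak whose MS-SNP
#' (most significant SNP) is the smallest-P marker (ties broken by smaller
#' position). Input ordering does not matter; an empty result is valid.
#'
#' @param assoc an `assocResult` (or any data.frame with `marker_id`,
#'   `chromosome`, `position`, `p`; `beta` and `pve_marker` are carried
#'   through when present)
#' @param pMs MS-SNP threshold (default 1e-5)
#' @param pSupport support-SNP threshold (default 1e-4)
#' @param windowBp half-window in bp (default 100000)
#' @param minSupport minimum number of additional support SNPs (default 2)
#' @return data.frame of class `peakTable`, one row per peak:
#'   `chromosome`, `ms_snp`, `ms_position`, `ms_p`, `ms_beta`, `ms_pve`,
#'   `window_start`, `window_end`, `n_support`, and a list column
#'   `support_snps`
#' @export
callPeaks <- function(assoc, pMs = 1e-5, pSupport = 1e-4, windowBp = 100000,
                      minSupport = 2) {
  df <- as.data.frame(assoc)[, intersect(c("marker_id", "chromosome",
                                           "position", "p", "beta",
                                           "pve_marker"), colnames(assoc))]
  df <- df[!is.na(df$p), , drop = FALSE]
  df <- df[order(df$chromosome, df$position), , drop = FALSE]
  peaks <- list()
  for (chr in unique(df$chromosome)) {
    d <- df[df$chromosome == chr, , drop = FALSE]
    cand <- which(d$p < pMs)
    if (!length(cand)) next
    qualified <- cand[vapply(cand, function(i) {
      sup <- d$p < pSupport & abs(d$position - d$position[i]) <= windowBp
      sup[i] <- FALSE
      sum(sup) >= minSupport
    }, TRUE)]
    if (!length(qualified)) next
    win <- IRanges::IRanges(start = pmax(d$position[qualified] - windowBp, 1),
                            end = d$position[qualified] + windowBp)
    merged <- IRanges::reduce(win)
    for (k in seq_along(merged)) {
      lo <- IRanges::start(merged)[k]
      hi <- IRanges::end(merged)[k]
      inR <- which(d$position >= lo & d$position <= hi)
      inQ <- intersect(inR, qualified)
      ms <- inQ[order(d$p[inQ], d$position[inQ])][1]
      supp <- which(d$p < pSupport &
                      abs(d$position - d$position[ms]) <= windowBp)
      supp <- setdiff(supp, ms)
      peaks[[length(peaks) + 1]] <- data.frame(
        chromosome = chr,
        ms_snp = d$marker_id[ms],
        ms_position = d$position[ms],
        ms_p = d$p[ms],
        ms_beta = if ("beta" %in% names(d)) d$beta[ms] else NA_real_,
        ms_pve = if ("pve_marker" %in% names(d)) d$pve_marker[ms] else NA_real_,
        window_start = max(d$position[ms] - windowBp, 1),
        window_end = d$position[ms] + windowBp,
        n_support = length(supp),
        support_snps = I(list(d$marker_id[supp])))
    }
  }
  out <- if (length(peaks)) do.call(rbind, peaks)
    else data.frame(chromosome = character(), ms_snp = character(),
                    ms_position = integer(), ms_p = numeric(),
                    ms_beta = numeric(), ms_pve = numeric(),
                    window_start = integer(), window_end = integer(),
                    n_support = integer(),
                    support_snps = I(list()))
  class(out) <- c("peakTable", "data.frame")
  attr(out, "params") <- list(pMs = pMs, pSupport = pSupport,
                              windowBp = windowBp, minSupport = minSupport)
  out
}

#' Read candidate genes from BED or a name/chrom/interval TSV
#'
#' BED input (0-based half-open) is converted to 1-based closed
#' coordinates. The TSV alternative has columns name, chrom, start-end.
#'
#' @param path input file
#' @param format `"bed"` or `"tsv"` (auto by extension)
#' @return data.frame `name`, `chromosome`, `start`, `end` (1-based closed)
#' @export
readCandidateGenes <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.bed$", path)) "bed" else "tsv"
  if (format == "bed") {
    bed <- rtracklayer::import(path, format = "BED")
    data.frame(name = if (!is.null(bed$name)) bed$name
                      else paste0("cand", seq_along(bed)),
               chromosome = as.character(GenomeInfoDb::seqnames(bed)),
               start = GenomicRanges::start(bed),  # rtracklayer converts to 1-based
               end = GenomicRanges::end(bed))
  } else {
    df <- utils::read.delim(path, header = TRUE)
    se <- do.call(rbind, strsplit(as.character(df[[3]]), "-"))
    data.frame(name = df[[1]], chromosome = as.character(df[[2]]),
               start = as.integer(se[, 1]), end = as.integer(se[, 2]))
  }
}

#' Attach candidate genes to peaks
#'
#' A candidate is attached to a peak when its interval, extended by
#' `flankBp` on both sides, intersects (closed intervals) the position of
#' any significant SNP of the peak (the MS-SNP or one of its support
#' SNPs).
#'
#' @param peaks a `peakTable` from [callPeaks()]
#' @param candidates data.frame `name`, `chromosome`, `start`, `end`
#'   (1-based closed), e.g. from [readCandidateGenes()]
#' @param assoc the scan the peaks came from (needed to locate support
#'   SNPs); when NULL only MS-SNP positions are used
#' @param flankBp flank in bp (default 24000)
#' @return the peak table with a `candidates` list column added
#' @export
overlapCandidates <- function(peaks, candidates, assoc = NULL,
                              flankBp = 24000) {
  if (!nrow(peaks)) {
    peaks$candidates <- I(list())
    return(peaks)
  }
  if (is.null(candidates) || !nrow(candidates)) {
    peaks$candidates <- I(rep(list(character(0)), nrow(peaks)))
    return(peaks)
  }
  posOf <- function(ids) {
    if (is.null(assoc)) return(integer(0))
    m <- match(ids, assoc$marker_id)
    assoc$position[m[!is.na(m)]]
  }
  chromOk <- candidates$chromosome %in% unique(peaks$chromosome)
  if (any(!chromOk))
    warning("candidate(s) on unknown chromosome skipped: ",
            paste(candidates$name[!chromOk], collapse = ", "))
  res <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    sig <- c(peaks$ms_position[i], posOf(peaks$support_snps[[i]]))
    cand <- candidates[candidates$chromosome == peaks$chromosome[i], ,
                       drop = FALSE]
    hit <- vapply(seq_len(nrow(cand)), function(j)
      any(sig >= cand$start[j] - flankBp & sig <= cand$end[j] + flankBp),
      TRUE)
    res[[i]] <- cand$name[hit]
  }
  peaks$candidates <- I(res)
  peaks
}

#' Re-validate a peak table against its own rule
#'
#' Audit pass: checks every reported peak satisfies the MS-SNP threshold,
#' minimum support and window containment it was called with.
#'
#' @param peaks a `peakTable`
#' @param assoc the source scan
#' @return TRUE invisibly; stops with a message on violation
#' @export
auditPeaks <- function(peaks, assoc) {
  par <- attr(peaks, "params")
  for (i in seq_len(nrow(peaks))) {
    if (!(peaks$ms_p[i] < par$pMs)) stop("peak ", i, ": MS-SNP P above threshold")
    if (peaks$n_support[i] < par$minSupport)
      stop("peak ", i, ": insufficient support")
    sup <- peaks$support_snps[[i]]
    pos <- assoc$position[match(sup, assoc$marker_id)]
    if (any(abs(pos - peaks$ms_position[i]) > par$windowBp))
      stop("peak ", i, ": support SNP outside window")
  }
  invisible(TRUE)
}
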