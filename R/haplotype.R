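#' Three-stage regional SNP filter for haplotype analysis
#'
#' Applied in order (each stage is marker-local so the final set is
#' order-invariant): (1) folded MAF > `mafGt` on the analysis lines;
#' (2) missing rate < `maxMissing`; (3) a two-sided allele-frequency test
#' between the two named groups with P < `pCutoff` (Fisher exact on the
#' 2x2 allele-count table by default; chi-square selectable). Survivor
#' counts per stage are recorded.
#'
#' @param panel a [GenotypePanel-class]
#' @param chromosome,start,end region (1-based closed)
#' @param groupA,groupB line-id vectors of the two contrasted groups
#'   (e.g. INDICA vs JAPONICA)
#' @param lines lines on which MAF/missingness are evaluated (default:
#'   union of the two groups)
#' @param mafGt exclusive MAF bound (default 0.05)
#' @param maxMissing exclusive missing-rate bound (default 0.03)
#' @param pCutoff frequency-test P cutoff (default 1e-6)
#' @param test `"fisher"` or `"chisq"`
#' @return character vector of surviving marker ids with attribute
#'   `stageCounts` (named: region, maf, missing, freqtest)
#' @export
filterRegionSnps <- function(panel, chromosome, start, end, groupA, groupB,
                             lines = NULL, mafGt = 0.05, maxMissing = 0.03,
                             pCutoff = 1e-6, test = c("fisher", "chisq")) {
  test <- match.arg(test)
  if (!length(groupA) || !length(groupB))
    stop("both groups must contain at least one line")
  reg <- subsetRegion(panel, chromosome, start, end)
  if (!nMarkers(reg)) stop("region contains no markers")
  if (is.null(lines)) lines <- union(groupA, groupB)
  st <- markerStats(reg, lines)
  counts <- c(region = nMarkers(reg))
  pass <- st$defined & !is.na(st$maf) & st$maf > mafGt
  counts["maf"] <- sum(pass)
  pass <- pass & st$missing_rate < maxMissing
  counts["missing"] <- sum(pass)
  alleleCounts <- function(gv) {
    nA <- sum(gv == -1L, na.rm = TRUE) * 2 + sum(gv == 0L, na.rm = TRUE)
    nB <- sum(gv == 1L, na.rm = TRUE) * 2 + sum(gv == 0L, na.rm = TRUE)
    c(nA, nB)
  }
  g <- genotypes(reg)
  pFreq <- rep(NA_real_, nMarkers(reg))
  for (i in which(pass)) {
    tab <- rbind(alleleCounts(g[i, groupA]), alleleCounts(g[i, groupB]))
    if (any(rowSums(tab) == 0)) next
    pFreq[i] <- if (test == "fisher") fisher.test(tab)$p.value
                else suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
  pass <- pass & !is.na(pFreq) & pFreq < pCutoff
  counts["freqtest"] <- sum(pass)
  message(sprintf("filterRegionSnps: %d in region, %d pass MAF, %d pass missing, %d pass frequency test",
                  counts["region"], counts["maf"], counts["missing"],
                  counts["freqtest"]))
  structure(markerIds(reg)[pass], stageCounts = counts,
            freqTestP = pFreq[pass])
}

# distance of a line's genotype string to a consensus: differing
# homozygotes count 1, any comparison involving a heterozygote 1/2,
# missing cells are wildcards
.hapDistance <- function(lineG, consensus) {
  ok <- !is.na(lineG) & !is.na(consensus)
  if (!any(ok)) return(0)
  a <- lineG[ok]; b <- consensus[ok]
  het <- a == 0L | b == 0L
  sum(het & (a != b)) * 0.5 + sum(!het & a != b)
}

# exact-string match with missing wildcarded
.hapMatches <- function(lineG, template) {
  ok <- !is.na(lineG) & !is.na(template)
  all(lineG[ok] == template[ok])
}

.hapConsensus <- function(gg) {
  # per-site majority; ties broken towards the smaller code (ref first)
  apply(gg, 1, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_integer_)
    tb <- table(factor(col, levels = c(-1L, 0L, 1L)))
    as.integer(names(tb)[which.max(tb)])
  })
}

#' Group lines into extended haplotypes over a filtered region
#'
#' Greedy frequency-seeded agglomeration: the most frequent exact allele
#' string (missing cells wildcarded; ties broken by lexicographically
#' smallest string) seeds a group; lines within `maxMismatch` of the
#' group's per-site majority consensus are absorbed and the consensus
#' recomputed until stable; the group's members are removed and the
#' procedure repeats. Heterozygous cells are retained in the consensus
#' but count only 1/2 towards mismatch distance. Groups smaller than
#' `minGroupSize` form a residual "rare recombinant" pool. The result is
#' invariant to the input line order.
#'
#' @param panel a [GenotypePanel-class] (already region-restricted, or
#'   pass `markers`)
#' @param markers marker ids to use (e.g. from [filterRegionSnps()])
#' @param lines line ids to group (default: all panel lines)
#' @param maxMismatch mismatch budget for absorption (default 2)
#' @param minGroupSize minimum reported group size (default 2)
#' @return list of class `ehGroups`: `groups` (each with `consensus`,
#'   `members`, `size`, `subpopCounts`), `residual` (line ids), `markers`
#' @export
buildExtendedHaplotypes <- function(panel, markers = NULL, lines = NULL,
                                    maxMismatch = 2, minGroupSize = 2) {
  g <- genotypes(panel)
  if (!is.null(markers)) {
    if (!length(markers)) stop("no markers to build haplotypes from")
    g <- g[markers, , drop = FALSE]
  }
  if (!is.null(lines)) g <- g[, lines, drop = FALSE]
  if (all(is.na(g))) stop("all genotypes missing in region")
  g <- g[, order(colnames(g)), drop = FALSE]   # order-invariance
  remaining <- colnames(g)
  groups <- list()
  while (length(remaining)) {
    gg <- g[, remaining, drop = FALSE]
    nmatch <- vapply(seq_along(remaining), function(j)
      sum(vapply(seq_along(remaining), function(k)
        .hapMatches(gg[, k], gg[, j]), TRUE)), 0L)
    key <- apply(gg, 2, function(col)
      paste(ifelse(is.na(col), "9", as.character(col + 1L)), collapse = ""))
    seedIdx <- order(-nmatch, key)[1]
    members <- remaining[vapply(seq_along(remaining), function(k)
      .hapMatches(gg[, k], gg[, seedIdx]), TRUE)]
    consensus <- .hapConsensus(g[, members, drop = FALSE])
    for (iter in 1:10) {
      absorb <- remaining[vapply(remaining, function(l)
        .hapDistance(g[, l], consensus) <= maxMismatch, TRUE)]
      newCons <- .hapConsensus(g[, absorb, drop = FALSE])
      if (identical(absorb, members) && identical(newCons, consensus)) break
      members <- absorb
      consensus <- newCons
    }
    groups[[length(groups) + 1]] <- list(consensus = consensus,
                                         members = members,
                                         size = length(members))
    remaining <- setdiff(remaining, members)
  }
  big <- vapply(groups, function(x) x$size >= minGroupSize, TRUE)
  residual <- unlist(lapply(groups[!big], `[[`, "members"))
  groups <- groups[big]
  o <- order(-vapply(groups, `[[`, 0L, "size"),
             vapply(groups, function(x) paste(x$consensus, collapse = ","), ""))
  groups <- groups[o]
  li <- lineInfo(panel)
  for (i in seq_along(groups)) {
    names(groups)[i] <- paste0("EH", i)
    if (!is.null(li$assigned_group)) {
      m <- match(groups[[i]]$members, li$id)
      groups[[i]]$subpopCounts <- table(as.character(li$assigned_group[m]))
    }
  }
  structure(list(groups = groups, residual = if (is.null(residual)) character(0) else residual,
                 markers = rownames(g)),
            class = "ehGroups")
}

#' @export
print.ehGroups <- function(x, ...) {
  cat(sprintf("%d extended haplotype group(s) over %d SNPs; %d line(s) in residual pool\n",
              length(x$groups), length(x$markers), length(x$residual)))
  for (nm in names(x$groups))
    cat(sprintf("  %s: n=%d\n", nm, x$groups[[nm]]$size))
  invisible(x)
}

#' Phenotype summaries per extended haplotype group
#'
#' @param groups an `ehGroups` from [buildExtendedHaplotypes()]
#' @param phenotype named vector of per-line means, or a phenotype table
#' @return data.frame: group, n (phenotyped members), mean, median, q25,
#'   q75 (NA rows for groups with no phenotyped member)
#' @export
haplotypePhenotypeSummary <- function(groups, phenotype) {
  if (is.data.frame(phenotype)) phenotype <- lineMeans(phenotype)
  rows <- lapply(names(groups$groups), function(nm) {
    v <- phenotype[intersect(groups$groups[[nm]]$members, names(phenotype))]
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(group = nm, n = 0L, mean = NA_real_,
                        median = NA_real_, q25 = NA_real_, q75 = NA_real_))
    q <- quantile(v, c(0.25, 0.75), names = FALSE)
    data.frame(group = nm, n = length(v), mean = mean(v), median = median(v),
               q25 = q[1], q75 = q[2])
  })
  do.call(rbind, rows)
}

#' Welch t comparison between two sets of haplotype groups
#'
#' @param groups an `ehGroups`
#' @param phenotype named vector or phenotype table
#' @param setA,setB character vectors of group names (e.g. c("EH15","EH16"))
#' @return htest object from [stats::t.test()] (Welch)
#' @export
compareHaplotypeGroups <- function(groups, phenotype, setA, setB) {
  if (is.data.frame(phenotype)) phenotype <- lineMeans(phenotype)
  mem <- function(s) unlist(lapply(groups$groups[s], `[[`, "members"))
  a <- phenotype[intersect(mem(setA), names(phenotype))]
  b <- phenotype[intersect(mem(setB), names(phenotype))]
  t.test(a, b)
}
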