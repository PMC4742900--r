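#' Per-marker allele statistics
#'
#' Allele counts are taken over non-missing lines: a homozygote contributes
#' two copies of its allele, a heterozygote one of each. The minor allele
#' frequency is folded (`maf = 0.5 - |0.5 - alt frequency|`, so `maf <= 0.5`).
#'
#' @param panel a [GenotypePanel-class]
#' @param lines optional character vector of line ids to evaluate on
#' @return data.frame with one row per marker: `id`, `maf`, `mac`,
#'   `missing_rate`, `n_called`, `alt_freq` and `defined` (FALSE when the
#'   marker is missing in every evaluated line, in which case `maf`,
#'   `alt_freq` are NA rather than NaN).
#' @export
markerStats <- function(panel, lines = NULL) {
  g <- genotypes(panel)
  if (!is.null(lines)) {
    if (!length(lines)) stop("'lines' must be non-empty")
    miss <- setdiff(lines, colnames(g))
    if (length(miss)) stop("unknown line id(s): ", paste(head(miss, 3), collapse = ", "))
    g <- g[, lines, drop = FALSE]
  }
  # single-pass counts: with codes in {-1, 0, 1}, sum(g) = nB - nA and
  # sum(g^2) = nA + nB over non-missing cells
  miss <- is.na(g)
  g0 <- g
  g0[miss] <- 0L
  s1 <- rowSums(g0)
  s2 <- rowSums(g0 * g0)
  nA <- (s2 - s1) / 2
  nB <- (s2 + s1) / 2
  nH <- (ncol(g) - rowSums(miss)) - s2
  refCount <- 2 * nA + nH
  altCount <- 2 * nB + nH
  tot <- refCount + altCount
  altFreq <- ifelse(tot > 0, altCount / tot, NA_real_)
  maf <- 0.5 - abs(0.5 - altFreq)
  mac <- pmin(refCount, altCount)
  data.frame(id = markerIds(panel),
             maf = maf,
             mac = as.integer(mac),
             missing_rate = rowMeans(miss),
             n_called = as.integer(nA + nH + nB),
             alt_freq = altFreq,
             defined = tot > 0,
             row.names = NULL)
}

#' Filter markers on frequency, count and missingness
#'
#' Retains markers with folded MAF strictly greater than `mafGt`, minor
#' allele count at least `macGe`, and missing rate at most `maxMissing`,
#' all evaluated on `lines` (default: all lines). A marker missing in every
#' evaluated line fails. Marker order is preserved; the filter is
#' idempotent.
#'
#' @inheritParams markerStats
#' @param mafGt exclusive lower MAF bound (default 0.05)
#' @param macGe inclusive lower minor-allele-count bound (default 3)
#' @param maxMissing inclusive upper missing-rate bound (default 0.30)
#' @return the filtered [GenotypePanel-class] (all lines retained)
#' @export
filterMarkers <- function(panel, mafGt = 0.05, macGe = 3, maxMissing = 0.30,
                          lines = NULL) {
  stopifnot(mafGt >= 0, mafGt <= 0.5, macGe >= 0, maxMissing >= 0, maxMissing <= 1)
  st <- markerStats(panel, lines)
  keep <- st$defined & !is.na(st$maf) & st$maf > mafGt & st$mac >= macGe &
    st$missing_rate <= maxMissing
  if (!any(keep)) message("filterMarkers: no markers pass; returning empty panel")
  panel[keep, ]
}

#' Union-of-subpopulation marker filter for joint scans
#'
#' For scans across the whole panel, the marker set is the union of markers
#' passing the MAF filter within each individual subpopulation (markers
#' common at moderate frequency in any one group are retained even if rare
#' panel-wide). MAC and missingness are then evaluated on the joint line
#' set.
#'
#' @inheritParams filterMarkers
#' @param groups named list of character vectors of line ids (one per
#'   subpopulation)
#' @return the filtered [GenotypePanel-class]
#' @export
subpopUnionFilter <- function(panel, groups, mafGt = 0.05, macGe = 3,
                              maxMissing = 0.30) {
  stopifnot(is.list(groups), length(groups) >= 1)
  pass <- rep(FALSE, nMarkers(panel))
  for (gl in groups) {
    st <- markerStats(panel, gl)
    pass <- pass | (st$defined & !is.na(st$maf) & st$maf > mafGt)
  }
  allLines <- unique(unlist(groups))
  st <- markerStats(panel, allLines)
  keep <- pass & st$mac >= macGe & st$missing_rate <= maxMissing
  panel[keep, ]
}

#' Classify a line from its ancestry fractions
#'
#' Applies the 70%-ancestry rule used for structured rice panels: a line is
#' assigned to a subpopulation when a single ancestry fraction reaches the
#' cutoff; otherwise to `admixed-INDICA` when the combined INDICA-side
#' (aus + indica) ancestry reaches it, `admixed-JAPONICA` when the combined
#' JAPONICA-side (temperate/tropical japonica + aromatic) ancestry does,
#' and `admixed-INDICA-JAPONICA` otherwise.
#'
#' @param ancestry named numeric vector (or matrix, lines in rows) of
#'   ancestry fractions summing to 1
#' @param cutoff ancestry cutoff (default 0.70)
#' @param indicaSide,japonicaSide subpopulation names forming the two
#'   varietal groups
#' @return character vector of assigned groups
#' @examples
#' assignGroup(c(indica = 0.95, aus = 0.05))
#' assignGroup(c(aus = 0.40, indica = 0.45, temperate_japonica = 0.15))
#' @export
assignGroup <- function(ancestry, cutoff = 0.70,
                        indicaSide = c("aus", "indica"),
                        japonicaSide = c("temperate_japonica",
                                         "tropical_japonica", "aromatic")) {
  if (is.null(dim(ancestry))) ancestry <- matrix(ancestry, nrow = 1,
                                                 dimnames = list(NULL, names(ancestry)))
  ancestry <- as.matrix(ancestry)
  if (is.null(colnames(ancestry))) stop("ancestry fractions must be named")
  if (any(abs(rowSums(ancestry) - 1) > 1e-9))
    stop("ancestry fractions must sum to 1")
  pops <- colnames(ancestry)
  ind <- intersect(indicaSide, pops)
  jap <- intersect(japonicaSide, pops)
  apply(ancestry, 1, function(a) {
    if (max(a) >= cutoff) return(pops[which.max(a)])
    if (length(ind) && sum(a[ind]) >= cutoff) return("admixed-INDICA")
    if (length(jap) && sum(a[jap]) >= cutoff) return("admixed-JAPONICA")
    "admixed-INDICA-JAPONICA"
  })
}

#' Line ids belonging to a group or varietal group
#'
#' Convenience lookup against `assigned_group` in [lineInfo()]. The
#' varietal groups `"INDICA"` and `"JAPONICA"` expand to their member
#' subpopulations plus the corresponding admixed class.
#'
#' @param panel a [GenotypePanel-class]
#' @param group a subpopulation name, `"INDICA"`, `"JAPONICA"`, `"ALL"`, or
#'   an admixed class
#' @inheritParams assignGroup
#' @return character vector of line ids
#' @export
groupLines <- function(panel, group,
                       indicaSide = c("aus", "indica"),
                       japonicaSide = c("temperate_japonica",
                                        "tropical_japonica", "aromatic")) {
  li <- lineInfo(panel)
  if (group == "ALL") return(li$id)
  if (is.null(li$assigned_group)) stop("panel has no assigned_group metadata")
  ag <- as.character(li$assigned_group)
  sel <- switch(group,
    INDICA = ag %in% c(indicaSide, "admixed-INDICA"),
    JAPONICA = ag %in% c(japonicaSide, "admixed-JAPONICA"),
    ag == group)
  li$id[sel]
}
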