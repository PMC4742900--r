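#' Principal components of the genetic correlation matrix
#'
#' Uses only markers with no missing call across the included lines. Each
#' marker is centred on its panel mean, the line-by-line Pearson
#' correlation matrix of the centred genotype vectors is formed and
#' eigendecomposed. Marker centring removes the shared-ancestry common
#' mode so that the leading components describe population structure (the
#' first axis separates the deepest split). Component k's variance
#' fraction is lambda_k / sum(lambda); fractions sum to 1 over all
#' components.
#'
#' @param panel a [GenotypePanel-class]
#' @param lines optional subset of line ids (>= 2)
#' @return list of class `pcaResult`: `scores` (lines x components,
#'   eigenvectors scaled by sqrt(lambda)), `varianceFraction`, `values`,
#'   `nMarkersUsed`
#' @export
computePCA <- function(panel, lines = NULL) {
  g <- genotypes(panel)
  if (!is.null(lines)) g <- g[, lines, drop = FALSE]
  if (ncol(g) < 2) stop("PCA requires at least 2 lines")
  complete <- rowSums(is.na(g)) == 0
  if (sum(complete) < 2)
    stop("too few markers complete in all lines; impute or subset first")
  x <- g[complete, , drop = FALSE] * 1.0
  x <- x - rowMeans(x)             # centre each marker
  sds <- sqrt(colSums(x^2))
  if (any(!is.finite(sds) | sds == 0))
    stop("line(s) with degenerate genotype vector: ",
         paste(colnames(x)[!is.finite(sds) | sds == 0], collapse = ", "))
  z <- scale(x)                    # correlation = crossprod of z-scores
  C <- crossprod(z) / (nrow(z) - 1)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  scores <- e$vectors %*% diag(sqrt(vals), nrow = length(vals))
  dimnames(scores) <- list(colnames(g), paste0("PC", seq_along(vals)))
  structure(list(scores = scores, varianceFraction = vals / sum(vals),
                 values = vals, nMarkersUsed = sum(complete)),
            class = "pcaResult")
}

#' @export
print.pcaResult <- function(x, ...) {
  cat(sprintf("PCA of genetic correlation matrix: %d lines, %d complete markers\n",
              nrow(x$scores), x$nMarkersUsed))
  k <- min(5, length(x$varianceFraction))
  cat("variance fractions:",
      paste(sprintf("PC%d=%.1f%%", seq_len(k), 100 * x$varianceFraction[seq_len(k)]),
            collapse = " "), "\n")
  invisible(x)
}

#' Folded 1D site-frequency spectrum
#'
#' Bins folded minor-allele frequencies into `nBins` equal-width intervals
#' over [0, 0.5]. Bins are left-closed, right-open except the last, so
#' cumulative counts at shared edges agree across refinements (e.g. 50 vs
#' 500 bins).
#'
#' @param freqs folded frequencies, all in [0, 0.5]
#' @param nBins number of intervals (default 100)
#' @return data.frame `lower`, `upper`, `count`
#' @export
sfs1d <- function(freqs, nBins = 100) {
  freqs <- freqs[!is.na(freqs)]
  if (any(freqs < 0 | freqs > 0.5))
    stop("frequencies must be folded into [0, 0.5]")
  width <- 0.5 / nBins
  idx <- pmin(floor(freqs / width) + 1L, nBins)
  data.frame(lower = (seq_len(nBins) - 1) * width,
             upper = seq_len(nBins) * width,
             count = tabulate(idx, nBins))
}

#' Two-dimensional site-frequency spectrum
#'
#' For each SNP the minor allele is determined panel-wide (folded over
#' `allLines`); its frequency is then computed separately within groups A
#' and B, where it may exceed 0.5 or reach fixation. Frequencies are
#' binned on a `nBins` x `nBins` grid over [0,1] x [0,1]. SNPs
#' monomorphic (or all-missing) in `allLines` are excluded and counted.
#'
#' @param panel a [GenotypePanel-class]
#' @param linesA,linesB disjoint line-id groups
#' @param allLines lines defining the panel-wide minor allele (default:
#'   all panel lines); both groups must be subsets
#' @param nBins bins per axis (default 250)
#' @return list of class `sfs2d`: `counts` (A bins x B bins), `freqs`
#'   per-SNP data.frame, `nExcluded`
#' @export
sfs2d <- function(panel, linesA, linesB, allLines = NULL, nBins = 250) {
  if (is.null(allLines)) allLines <- lineIds(panel)
  stopifnot(all(linesA %in% allLines), all(linesB %in% allLines))
  if (length(intersect(linesA, linesB)))
    stop("groups must be disjoint")
  all_st <- markerStats(panel, allLines)
  poly <- all_st$defined & !is.na(all_st$alt_freq) &
    all_st$alt_freq > 0 & all_st$alt_freq < 1
  nExcluded <- sum(!poly)
  minorIsAlt <- all_st$alt_freq[poly] <= 0.5
  fr <- function(lns) {
    st <- markerStats(panel, lns)
    af <- st$alt_freq[poly]
    ifelse(minorIsAlt, af, 1 - af)
  }
  fA <- fr(linesA)
  fB <- fr(linesB)
  ok <- !is.na(fA) & !is.na(fB)
  nExcluded <- nExcluded + sum(!ok)
  width <- 1 / nBins
  bin <- function(f) pmin(floor(f / width) + 1L, nBins)
  counts <- matrix(0L, nBins, nBins)
  tb <- table(factor(bin(fA[ok]), levels = seq_len(nBins)),
              factor(bin(fB[ok]), levels = seq_len(nBins)))
  counts[] <- as.integer(tb)
  structure(list(counts = counts,
                 freqs = data.frame(id = all_st$id[poly][ok],
                                    freqA = fA[ok], freqB = fB[ok]),
                 nExcluded = nExcluded, nBins = nBins),
            class = "sfs2d")
}

#' Linkage disequilibrium between two markers
#'
#' r^2 is the squared Pearson correlation of genotype codes over
#' pairwise-complete lines. |D'| treats homozygous inbred lines as
#' haplotypes (heterozygotes are dropped for the haplotype counts; no
#' phasing is needed) and normalises D by Lewontin's bound.
#'
#' @param x1,x2 genotype vectors in \{-1, 0, +1, NA\}
#' @return list `r2`, `dprime`, `n` (pairwise-complete lines),
#'   `nHaplotypes`; fields are NA with attribute `reason` when undefined
#'   (monomorphic after completeness restriction)
#' @export
ldPair <- function(x1, x2) {
  cc <- !is.na(x1) & !is.na(x2)
  n <- sum(cc)
  und <- function(reason) structure(list(r2 = NA_real_, dprime = NA_real_,
                                         n = n, nHaplotypes = 0L),
                                    reason = reason)
  if (n < 2) return(und("fewer than 2 pairwise-complete lines"))
  a <- x1[cc]; b <- x2[cc]
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    return(und("monomorphic after completeness restriction"))
  r2 <- suppressWarnings(cor(a, b))^2
  hom <- a != 0 & b != 0
  dprime <- NA_real_
  nh <- sum(hom)
  if (nh >= 2) {
    ha <- (a[hom] + 1) / 2                 # 1 = alt allele
    hb <- (b[hom] + 1) / 2
    pA <- mean(ha); pB <- mean(hb)
    if (pA > 0 && pA < 1 && pB > 0 && pB < 1) {
      D <- mean(ha * hb) - pA * pB
      dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
              else min(pA * pB, (1 - pA) * (1 - pB))
      if (dmax > 0) dprime <- abs(D) / dmax
    }
  }
  list(r2 = r2, dprime = dprime, n = n, nHaplotypes = nh)
}

# vectorised per-window LD: r2 by pairwise-complete correlation, |D'| from
# homozygote-haplotype counts via indicator cross-products
.windowLD <- function(gw) {
  r2 <- suppressWarnings(cor(t(gw), use = "pairwise.complete.obs"))^2
  A <- (!is.na(gw) & gw == -1L) * 1
  B <- (!is.na(gw) & gw == 1L) * 1
  nAA <- tcrossprod(A); nBB <- tcrossprod(B)
  nAB <- tcrossprod(A, B); nBA <- tcrossprod(B, A)
  tot <- nAA + nAB + nBA + nBB
  fi <- (nBA + nBB) / tot                 # alt freq at row marker
  fj <- (nAB + nBB) / tot                 # alt freq at col marker
  p11 <- nBB / tot
  D <- p11 - fi * fj
  dmaxPos <- pmin(fi * (1 - fj), (1 - fi) * fj)
  dmaxNeg <- pmin(fi * fj, (1 - fi) * (1 - fj))
  dmax <- ifelse(D >= 0, dmaxPos, dmaxNeg)
  dp <- ifelse(tot >= 2 & fi > 0 & fi < 1 & fj > 0 & fj < 1 & dmax > 0,
               abs(D) / dmax, NA_real_)
  list(r2 = r2, dprime = dp)
}

#' Linkage disequilibrium decay
#'
#' Markers with missing rate above `maxMissing` or with fewer than
#' `minCarriers` lines carrying the minor allele are discarded. Windows of
#' `windowSnps` consecutive markers are moved non-overlapping along each
#' chromosome; all within-window pairs are scored (r^2 over
#' pairwise-complete lines, |D'| from homozygote haplotypes) and their
#' distances pooled into `nBins` equal-width bins over the observed
#' distance range.
#'
#' @param panel a [GenotypePanel-class]
#' @param lines optional subset of line ids
#' @param windowSnps window size in markers (default 4000)
#' @param nBins number of distance bins (default 500)
#' @param maxMissing per-marker missing-rate cutoff (default 1/3)
#' @param minCarriers minimum minor-allele carriers (default 3)
#' @return data.frame of class `ldDecay`: `bin`, `meanDistance`,
#'   `meanR2`, `meanDprime`, `nPairs`; attributes `nPairsTotal`,
#'   `nSkipped` (pairs undefined for r^2), `nMarkersUsed`
#' @export
ldDecay <- function(panel, lines = NULL, windowSnps = 4000, nBins = 500,
                    maxMissing = 1/3, minCarriers = 3) {
  g <- genotypes(panel)
  if (!is.null(lines)) g <- g[, lines, drop = FALSE]
  st <- markerStats(panel, if (is.null(lines)) lineIds(panel) else lines)
  carriers <- .minorCarriers(g)
  keep <- st$missing_rate <= maxMissing & carriers >= minCarriers
  mi <- markerInfo(panel)
  dist <- r2v <- dpv <- numeric(0)
  for (chr in unique(mi$chromosome)) {
    sel <- which(keep & mi$chromosome == chr)
    if (length(sel) < 2) {
      message("ldDecay: chromosome ", chr, " skipped (<2 usable markers)")
      next
    }
    starts <- seq(1, length(sel), by = windowSnps)
    for (s in starts) {
      w <- sel[s:min(s + windowSnps - 1, length(sel))]
      if (length(w) < 2) next
      ld <- .windowLD(g[w, , drop = FALSE])
      ut <- upper.tri(ld$r2)
      d <- abs(outer(mi$position[w], mi$position[w], "-"))[ut]
      dist <- c(dist, d)
      r2v <- c(r2v, ld$r2[ut])
      dpv <- c(dpv, ld$dprime[ut])
    }
  }
  if (!length(dist)) stop("no marker pairs to evaluate")
  ok <- !is.na(r2v)
  rng <- range(dist[ok])
  width <- max(diff(rng), 1) / nBins
  bin <- pmin(floor((dist - rng[1]) / width) + 1L, nBins)
  agg <- function(v, b) tapply(v, factor(b, levels = seq_len(nBins)),
                               mean, na.rm = TRUE)
  out <- data.frame(bin = seq_len(nBins),
                    meanDistance = as.numeric(agg(dist[ok], bin[ok])),
                    meanR2 = as.numeric(agg(r2v[ok], bin[ok])),
                    meanDprime = as.numeric(agg(dpv[ok], bin[ok])),
                    nPairs = as.integer(tabulate(bin[ok], nBins)))
  class(out) <- c("ldDecay", "data.frame")
  attr(out, "nPairsTotal") <- sum(ok)
  attr(out, "nSkipped") <- sum(!ok)
  attr(out, "nMarkersUsed") <- sum(keep)
  out
}

# lines carrying at least one copy of the per-marker minor allele
.minorCarriers <- function(g) {
  nA <- rowSums(g == -1L, na.rm = TRUE)
  nH <- rowSums(g == 0L, na.rm = TRUE)
  nB <- rowSums(g == 1L, na.rm = TRUE)
  altMinor <- (2 * nB + nH) <= (2 * nA + nH)
  ifelse(altMinor, nB + nH, nA + nH)
}

#' Private and shared SNP accounting across subpopulations
#'
#' For each subpopulation: the number of polymorphic markers, of
#' polymorphic non-synonymous markers (when `codingEffects` is supplied),
#' counts at folded MAF > 0.05 and > 0.10, and the private count (markers
#' segregating only in that subpopulation). Also reports the panel-wide
#' polymorphic total and the common set segregating in every
#' subpopulation.
#'
#' @param panel a [GenotypePanel-class]
#' @param groups named list of line-id vectors, one per subpopulation
#' @param codingEffects optional character vector (per marker, aligned
#'   with the panel) of coding effects as from [codingEffect()]
#' @return list of class `snpSharing`: `perGroup` data.frame,
#'   `totalPolymorphic`, `sharedAll`
#' @export
privateSharedSnps <- function(panel, groups, codingEffects = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  nm <- nMarkers(panel)
  poly <- matrix(FALSE, nm, length(groups),
                 dimnames = list(NULL, names(groups)))
  rows <- list()
  for (i in seq_along(groups)) {
    gname <- names(groups)[i]
    lns <- groups[[i]]
    if (!length(lns)) {
      warning("empty subpopulation: ", gname)
      rows[[gname]] <- data.frame(group = gname, nLines = 0L,
                                  polymorphic = 0L, nonSynPolymorphic = 0L,
                                  mafGt05 = 0L, mafGt10 = 0L, private = 0L)
      next
    }
    st <- markerStats(panel, lns)
    isPoly <- st$defined & !is.na(st$maf) & st$maf > 0
    poly[, i] <- isPoly
    nonSyn <- if (is.null(codingEffects)) NA_integer_
              else sum(isPoly & codingEffects == "non-synonymous", na.rm = TRUE)
    rows[[gname]] <- data.frame(group = gname, nLines = length(lns),
                                polymorphic = sum(isPoly),
                                nonSynPolymorphic = nonSyn,
                                mafGt05 = sum(isPoly & st$maf > 0.05),
                                mafGt10 = sum(isPoly & st$maf > 0.10),
                                private = NA_integer_)
  }
  perGroup <- do.call(rbind, rows)
  npop <- rowSums(poly)
  for (i in seq_along(groups))
    if (length(groups[[i]]))
      perGroup$private[perGroup$group == names(groups)[i]] <-
        sum(poly[, i] & npop == 1)
  structure(list(perGroup = perGroup,
                 totalPolymorphic = sum(npop >= 1),
                 sharedAll = sum(npop == length(groups))),
            class = "snpSharing")
}

#' @export
print.snpSharing <- function(x, ...) {
  print(x$perGroup, row.names = FALSE)
  cat(sprintf("polymorphic in >=1 subpopulation: %d; segregating in all: %d\n",
              x$totalPolymorphic, x$sharedAll))
  invisible(x)
}
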