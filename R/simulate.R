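#' Configuration for the structured-panel simulator
#'
#' The generator emulates a deeply structured, near-homozygous diversity
#' panel: `nSubpops` subpopulations diverge from shared ancestral allele
#' frequencies under the Balding-Nichols model with per-subpopulation Fst,
#' lines are inbred draws from their subpopulation frequencies, and a
#' fraction of lines are two-way admixed. Defaults mirror a rice-like
#' panel: five subpopulations, twelve chromosomes, strong differentiation.
#'
#' @param nSubpops number of subpopulations (default 5)
#' @param linesPerSubpop pure lines per subpopulation
#' @param admixedFraction fraction of the final panel that is admixed
#'   between two subpopulations
#' @param nMarkers total marker count
#' @param chromLengths named vector of chromosome lengths in bp
#' @param fst per-subpopulation Balding-Nichols Fst, recycled to
#'   `nSubpops`; each in (0, 1)
#' @param residualHetRate probability a genotype call is heterozygous
#'   (residual heterozygosity of purified inbred lines)
#' @param missingRate probability a call is missing
#' @param subpopNames subpopulation labels
#' @param ancestralFreqRange range of the uniform ancestral allele
#'   frequency draw
#' @return a list of class `simConfig`
#' @export
simPanelConfig <- function(nSubpops = 5, linesPerSubpop = 80,
                           admixedFraction = 0.15, nMarkers = 10000,
                           chromLengths = setNames(rep(30e6, 12),
                                                   as.character(1:12)),
                           fst = rep(0.30, nSubpops),
                           residualHetRate = 0.005, missingRate = 0.065,
                           subpopNames = c("indica", "aus",
                                           "temperate_japonica",
                                           "tropical_japonica", "aromatic"),
                           ancestralFreqRange = c(0.05, 0.95)) {
  fst <- rep_len(fst, nSubpops)
  chromLengths <- unlist(chromLengths)       # tolerate YAML list input
  stopifnot(nSubpops >= 1, linesPerSubpop >= 1, nMarkers >= 1,
            all(fst > 0), all(fst < 1),
            admixedFraction >= 0, admixedFraction < 1,
            residualHetRate >= 0, residualHetRate < 1,
            missingRate >= 0, missingRate < 1,
            all(chromLengths > 0))
  if (length(subpopNames) < nSubpops)
    subpopNames <- c(subpopNames,
                     paste0("pop", seq_len(nSubpops - length(subpopNames)) +
                              length(subpopNames)))
  structure(list(nSubpops = nSubpops, linesPerSubpop = linesPerSubpop,
                 admixedFraction = admixedFraction, nMarkers = nMarkers,
                 chromLengths = chromLengths, fst = fst,
                 residualHetRate = residualHetRate,
                 missingRate = missingRate,
                 subpopNames = subpopNames[seq_len(nSubpops)],
                 ancestralFreqRange = ancestralFreqRange),
            class = "simConfig")
}

#' Simulate a structured inbred genotype panel
#'
#' Per marker, an ancestral alternate-allele frequency p is drawn uniformly
#' over `ancestralFreqRange`; each subpopulation frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) (Balding-Nichols, variance F p(1-p)).
#' Each pure line is a homozygous draw: BB with its subpopulation
#' frequency, AA otherwise; calls are flipped to heterozygous at
#' `residualHetRate` and masked at `missingRate`. Admixed lines draw from a
#' mixture of two subpopulation frequency vectors with a random ancestry
#' weight. Marker positions are uniform over chromosomes, then sorted.
#'
#' @param cfg a [simPanelConfig()] object
#' @param seed integer seed; the same (cfg, seed) reproduces the panel
#'   exactly
#' @return list with `panel` (a [GenotypePanel-class]) and `truth`, a
#'   `panelTruth` list holding ancestral frequencies (`ancestralFreq`),
#'   per-subpopulation frequencies (`subpopFreq`, markers x subpops), the
#'   true ancestry matrix, config and seed.
#' @export
simulateGenotypes <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(seed)
  nm <- cfg$nMarkers
  chroms <- names(cfg$chromLengths)
  cnt <- as.vector(stats::rmultinom(1, nm, cfg$chromLengths / sum(cfg$chromLengths)))
  chrom <- rep(chroms, cnt)
  pos <- unlist(lapply(seq_along(chroms), function(i) {
    if (cnt[i] == 0) return(integer())
    sort(sample.int(cfg$chromLengths[i], cnt[i]))
  }))
  p <- runif(nm, cfg$ancestralFreqRange[1], cfg$ancestralFreqRange[2])
  q <- matrix(0, nm, cfg$nSubpops, dimnames = list(NULL, cfg$subpopNames))
  for (s in seq_len(cfg$nSubpops)) {
    f <- cfg$fst[s]
    q[, s] <- rbeta(nm, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  nPure <- cfg$nSubpops * cfg$linesPerSubpop
  nAdm <- round(cfg$admixedFraction * nPure / max(1 - cfg$admixedFraction, 1e-9))
  nL <- nPure + nAdm
  anc <- matrix(0, nL, cfg$nSubpops, dimnames = list(NULL, cfg$subpopNames))
  lineFreq <- matrix(0, nm, nL)
  ids <- character(nL)
  k <- 0L
  for (s in seq_len(cfg$nSubpops)) {
    for (i in seq_len(cfg$linesPerSubpop)) {
      k <- k + 1L
      anc[k, s] <- 1
      lineFreq[, k] <- q[, s]
      ids[k] <- sprintf("%s_%03d", toupper(substr(cfg$subpopNames[s], 1, 3)), i)
    }
  }
  if (nAdm > 0) {
    for (i in seq_len(nAdm)) {
      k <- k + 1L
      pr <- sample.int(cfg$nSubpops, 2)
      w <- runif(1)
      anc[k, pr[1]] <- w
      anc[k, pr[2]] <- 1 - w
      lineFreq[, k] <- w * q[, pr[1]] + (1 - w) * q[, pr[2]]
      ids[k] <- sprintf("ADM_%03d", i)
    }
  }
  g <- matrix(-1L, nm, nL)
  g[matrix(runif(nm * nL), nm, nL) < lineFreq] <- 1L
  if (cfg$residualHetRate > 0)
    g[matrix(runif(nm * nL), nm, nL) < cfg$residualHetRate] <- 0L
  if (cfg$missingRate > 0) {
    # array-like missingness: concentrated in a subset of markers (half the
    # markers fully called), overall mean equal to missingRate
    rate <- ifelse(runif(nm) < 0.5, 0,
                   pmin(runif(nm, 0, 4 * cfg$missingRate), 0.9))
    g[matrix(runif(nm * nL), nm, nL) < rate] <- NA_integer_
  }
  markers <- data.frame(chromosome = chrom, position = pos,
                        ref_allele = "A", alt_allele = "T")
  markers$id <- makeMarkerIds(chrom, pos)
  dup <- duplicated(markers$id)
  if (any(dup)) {          # collided positions: nudge
    markers$position[dup] <- markers$position[dup] + 1L
    markers$id <- makeMarkerIds(markers$chromosome, markers$position)
  }
  lines <- data.frame(id = ids)
  lines$ancestry <- I(anc)
  lines$assigned_group <- assignGroup(anc,
                                      indicaSide = intersect(c("aus", "indica"), cfg$subpopNames),
                                      japonicaSide = intersect(c("temperate_japonica",
                                                                 "tropical_japonica", "aromatic"),
                                                               cfg$subpopNames))
  panel <- GenotypePanel(g, markers, lines)
  # panel construction sorts markers; carry the same order into the truth
  o <- order(markers$chromosome, markers$position)
  truth <- structure(list(ancestralFreq = p[o], subpopFreq = q[o, , drop = FALSE],
                          ancestry = anc, markerIds = markers$id[o],
                          config = cfg, seed = seed),
                     class = "panelTruth")
  list(panel = panel, truth = truth)
}

#' Describe a planted trait architecture
#'
#' Additive QTLs (in the -1/0/+1 coding, so the BB-AA homozygote contrast
#' is 2a), an optional marginal-free epistatic pair (see
#' [plantPureEpistasis()]), a polygenic background with covariance
#' `sigma2Bg * K`, and the variance components of a replicated
#' multi-environment trial.
#'
#' @param additiveQtls data.frame with columns `marker` (id), `effect`
#'   (trait units per alternate allele) and optionally `restricted_to`
#'   (subpopulation in which the minor allele segregates, informational)
#' @param epistaticPair an `epistasisFragment` from [plantPureEpistasis()],
#'   or NULL
#' @param sigma2Bg polygenic background variance
#' @param sigma2Gxe genotype-by-environment variance
#' @param sigma2Err experimental error variance
#' @param sigma2Env environment main-effect variance
#' @param environments,replicates trial dimensions
#' @param traitMean trait mean (e.g. mm grain length)
#' @return list of class `traitArchitecture`
#' @export
traitArchitecture <- function(additiveQtls = NULL, epistaticPair = NULL,
                              sigma2Bg = 0, sigma2Gxe = 0, sigma2Err = 0,
                              sigma2Env = 0, environments = 2, replicates = 3,
                              traitMean = 5.7) {
  stopifnot(sigma2Bg >= 0, sigma2Gxe >= 0, sigma2Err >= 0, sigma2Env >= 0,
            environments >= 1, replicates >= 1)
  if (!is.null(additiveQtls)) {
    stopifnot(all(c("marker", "effect") %in% names(additiveQtls)))
    if (is.null(additiveQtls$restricted_to))
      additiveQtls$restricted_to <- NA_character_
  }
  structure(list(additiveQtls = additiveQtls, epistaticPair = epistaticPair,
                 sigma2Bg = sigma2Bg, sigma2Gxe = sigma2Gxe,
                 sigma2Err = sigma2Err, sigma2Env = sigma2Env,
                 environments = environments, replicates = replicates,
                 traitMean = traitMean),
            class = "traitArchitecture")
}

# QTL genotype columns with missing cells imputed by the line's
# subpopulation mean genotype (falling back to the panel mean)
.qtlGenotypes <- function(panel, markers) {
  g <- genotypes(panel)
  miss <- setdiff(markers, rownames(g))
  if (length(miss)) stop("architecture marker(s) not in panel: ",
                         paste(miss, collapse = ", "))
  x <- t(g[markers, , drop = FALSE]) * 1.0    # lines x markers
  if (anyNA(x)) {
    li <- lineInfo(panel)
    grp <- if (!is.null(li$assigned_group)) as.character(li$assigned_group)
           else rep("all", nrow(li))
    nimp <- 0L
    for (j in seq_len(ncol(x))) {
      na <- which(is.na(x[, j]))
      if (!length(na)) next
      for (i in na) {
        same <- grp == grp[i]
        m <- mean(x[same, j], na.rm = TRUE)
        if (!is.finite(m)) m <- mean(x[, j], na.rm = TRUE)
        if (!is.finite(m)) m <- 0
        x[i, j] <- m
      }
      nimp <- nimp + length(na)
    }
    message("simulatePhenotypes: ", nimp,
            " missing QTL genotype(s) imputed by subpopulation mean")
  }
  x
}

#' Simulate replicated multi-environment phenotypes
#'
#' Genetic value = sum of additive QTL effects + the marginal-centred
#' epistatic contribution + a polygenic deviate drawn from
#' N(0, sigma2Bg * K) with K the IBS kinship of the panel. Observed values
#' add an environment main effect, a G-by-E deviate and experimental error
#' for each of `replicates` x `environments` records.
#'
#' @param panel a [GenotypePanel-class]
#' @param arch a [traitArchitecture()]
#' @param seed integer seed
#' @param kinship optional precomputed kinship matrix (saves recomputation)
#' @return phenotype data.frame (`line_id`, `environment`, `replicate`,
#'   `value`) with attributes `geneticValues` (named vector) and
#'   `components`
#' @export
simulatePhenotypes <- function(panel, arch, seed = 1, kinship = NULL) {
  stopifnot(inherits(arch, "traitArchitecture"))
  set.seed(seed)
  n <- nLines(panel)
  ids <- lineIds(panel)
  gv <- rep(0, n)
  if (!is.null(arch$additiveQtls) && nrow(arch$additiveQtls)) {
    x <- .qtlGenotypes(panel, arch$additiveQtls$marker)
    gv <- gv + drop(x %*% arch$additiveQtls$effect)
  }
  if (!is.null(arch$epistaticPair))
    gv <- gv + epistasisContribution(panel, arch$epistaticPair)
  if (arch$sigma2Bg > 0) {
    K <- if (is.null(kinship)) computeKinship(panel) else kinship
    U <- chol(K + diag(1e-6, n))
    gv <- gv + sqrt(arch$sigma2Bg) * drop(crossprod(U, rnorm(n)))
  }
  e <- arch$environments
  r <- arch$replicates
  envEff <- rnorm(e, 0, sqrt(arch$sigma2Env))
  gxe <- matrix(rnorm(n * e, 0, sqrt(arch$sigma2Gxe)), n, e)
  rec <- expand.grid(replicate = seq_len(r), environment = seq_len(e),
                     line = seq_len(n))
  value <- arch$traitMean + gv[rec$line] + envEff[rec$environment] +
    gxe[cbind(rec$line, rec$environment)] +
    rnorm(nrow(rec), 0, sqrt(arch$sigma2Err))
  out <- data.frame(line_id = ids[rec$line],
                    environment = paste0("E", rec$environment),
                    replicate = rec$replicate,
                    value = value)
  attr(out, "geneticValues") <- setNames(gv, ids)
  attr(out, "components") <- list(sigma2Bg = arch$sigma2Bg,
                                  sigma2Gxe = arch$sigma2Gxe,
                                  sigma2Err = arch$sigma2Err,
                                  sigma2Env = arch$sigma2Env)
  out
}

#' Plant a purely epistatic pair
#'
#' Builds a two-locus interaction whose single-marker (marginal) effects
#' are ~0 across the panel: the raw contribution `w * I(x1, x2)` (with `I`
#' the double-homozygote interaction coding of [encodeInteraction()]) is
#' regressed on an intercept and both single-marker codes, and the fitted
#' single-marker components are subtracted. Such a pair is invisible to a
#' single-marker scan yet detectable by an interaction scan.
#'
#' @param panel a [GenotypePanel-class]
#' @param marker1,marker2 marker ids (must not be in perfect LD)
#' @param w interaction effect (trait units)
#' @return list of class `epistasisFragment` with the markers, `w` and the
#'   fitted centring coefficients
#' @export
plantPureEpistasis <- function(panel, marker1, marker2, w) {
  g <- genotypes(panel)
  stopifnot(marker1 %in% rownames(g), marker2 %in% rownames(g))
  x1 <- g[marker1, ]
  x2 <- g[marker2, ]
  cc <- complete.cases(x1, x2)
  if (length(unique(x1[cc])) < 2 || length(unique(x2[cc])) < 2)
    stop("both markers must be polymorphic")
  if (abs(cor(x1[cc], x2[cc])) > 1 - 1e-12)
    stop("markers in perfect LD: interaction unidentifiable")
  I <- encodeInteraction(x1, x2)
  X <- cbind(1, x1, x2)[cc & !is.na(I), ]
  yI <- (w * I)[cc & !is.na(I)]
  b <- qr.coef(qr(X), yI)
  b[is.na(b)] <- 0
  # on purely homozygous lines I = (x1 + x2)/2 exactly; the interaction is
  # identifiable only through heterozygous cells
  res <- yI - drop(X %*% b)
  if (w != 0 && var(res) < 1e-12 * max(var(yI), 1e-12))
    warning("interaction collinear with the main effects (no heterozygous ",
            "cells among complete lines): the centred contribution is zero ",
            "and the pair is unidentifiable to an interaction scan")
  structure(list(marker1 = marker1, marker2 = marker2, w = w, centre = b),
            class = "epistasisFragment")
}

#' Phenotypic contribution of a planted epistatic pair
#'
#' @param panel a [GenotypePanel-class]
#' @param fragment an `epistasisFragment`
#' @return numeric vector over lines (missing genotypes imputed as in
#'   [simulatePhenotypes()])
#' @export
epistasisContribution <- function(panel, fragment) {
  x <- .qtlGenotypes(panel, c(fragment$marker1, fragment$marker2))
  I <- encodeInteraction(round(x[, 1]), round(x[, 2]))
  I[is.na(I)] <- 0
  drop(fragment$w * I - cbind(1, x[, 1], x[, 2]) %*% fragment$centre)
}

#' Additive effect size for a target variance share
#'
#' Returns the additive effect a such that a QTL at `marker` explains a
#' `pve` fraction of a phenotype whose remaining variance is
#' `otherVariance`: a = sqrt(pve/(1-pve) * otherVariance / Var(x)).
#'
#' @param panel a [GenotypePanel-class]
#' @param marker marker id
#' @param pve target variance fraction in (0, 1)
#' @param otherVariance total phenotypic variance from all other sources
#' @export
effectForTargetPve <- function(panel, marker, pve, otherVariance) {
  stopifnot(pve > 0, pve < 1, otherVariance > 0)
  x <- genotypes(panel)[marker, ]
  vx <- var(x[!is.na(x)])
  if (!is.finite(vx) || vx <= 0) stop("marker is monomorphic")
  sqrt(pve / (1 - pve) * otherVariance / vx)
}

#' Induce local linkage disequilibrium around a focal marker
#'
#' The base generator draws markers independently, so a planted QTL has no
#' linked neighbours and can never satisfy a support-SNP peak rule. This
#' helper rewrites the genotypes of every other marker within `windowBp`
#' of the focal marker as noisy copies of the focal genotypes (each
#' non-missing call flipped to the opposite homozygote with probability
#' `flipProb`, original missing patterns retained), emulating a tight LD
#' block such as a haplotype carrying a causal variant.
#'
#' @param panel a [GenotypePanel-class]
#' @param focal focal marker id
#' @param windowBp half-width of the LD block in bp (default 100000)
#' @param flipProb per-call flip probability controlling the r^2 with the
#'   focal marker (default 0.05)
#' @param seed integer seed
#' @return the modified panel; attribute `linked` lists the rewritten
#'   marker ids
#' @export
induceLocalLD <- function(panel, focal, windowBp = 100000, flipProb = 0.05,
                          seed = 1) {
  set.seed(seed)
  mi <- markerInfo(panel)
  i <- match(focal, mi$id)
  if (is.na(i)) stop("unknown focal marker: ", focal)
  sel <- which(mi$chromosome == mi$chromosome[i] &
                 abs(mi$position - mi$position[i]) <= windowBp & mi$id != focal)
  g <- genotypes(panel)
  base <- g[focal, ]
  for (j in sel) {
    x <- base
    flip <- runif(length(x)) < flipProb
    x[flip & !is.na(x)] <- -x[flip & !is.na(x)]
    x[is.na(g[j, ])] <- NA_integer_
    g[j, ] <- x
  }
  SummarizedExperiment::assay(panel, "genotype") <- g
  attr(panel, "linked") <- mi$id[sel]
  panel
}

#' Markers whose minor allele is confined to one subpopulation
#'
#' Uses simulator truth frequencies: markers where the panel-wide minor
#' allele segregates at usable frequency in `subpop` but is (nearly) absent
#' from all other subpopulations, emulating subpopulation-restricted
#' alleles.
#'
#' @param truth `panelTruth` from [simulateGenotypes()]
#' @param subpop subpopulation name
#' @param minIn minimum minor-allele frequency within `subpop`
#' @param maxOut maximum minor-allele frequency in every other subpop
#' @return character vector of marker ids
#' @export
findRestrictedMarkers <- function(truth, subpop, minIn = 0.15, maxOut = 0.02) {
  q <- truth$subpopFreq
  stopifnot(subpop %in% colnames(q))
  w <- rowMeans(q)                         # panel-scale alt frequency
  minorIsAlt <- w <= 0.5
  fmin <- q                                # per-subpop minor-allele freq
  fmin[!minorIsAlt, ] <- 1 - q[!minorIsAlt, , drop = FALSE]
  tgt <- fmin[, subpop]
  oth <- fmin[, setdiff(colnames(q), subpop), drop = FALSE]
  truth$markerIds[tgt >= minIn & apply(oth, 1, max) <= maxOut]
}
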