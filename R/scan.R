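#' Benjamini-Hochberg significance threshold
#'
#' Step-up rule at FDR level `q`: with ordered p(1) <= ... <= p(m), the
#' cutoff is p(k) for the largest k with p(k) <= q k / m (computed through
#' [stats::p.adjust()]).
#'
#' @param p vector of P values in (0, 1]
#' @param q FDR level (default 0.10)
#' @return list with `cutoff` (NA when nothing passes), logical
#'   `significant`, and `nSignificant`
#' @examples
#' bhThreshold(c(0.001, 0.01, 0.02, 0.9), q = 0.1)
#' @export
bhThreshold <- function(p, q = 0.10) {
  ok <- !is.na(p)
  if (!any(ok)) {
    message("bhThreshold: no p values")
    return(list(cutoff = NA_real_, significant = rep(FALSE, length(p)),
                nSignificant = 0L))
  }
  adj <- rep(NA_real_, length(p))
  adj[ok] <- p.adjust(p[ok], method = "BH")
  sig <- !is.na(adj) & adj <= q
  list(cutoff = if (any(sig)) max(p[sig]) else NA_real_,
       significant = sig, nSignificant = sum(sig))
}

#' Epistatic interaction coding
#'
#' The double-homozygote interaction regressor: -1 for AA/AA, +1 for
#' BB/BB, 0 for AA/BB and BB/AA and for any combination including a
#' heterozygote; missing if either genotype is missing. Symmetric in its
#' arguments.
#'
#' @param x1,x2 genotype vectors in \{-1, 0, +1, NA\}
#' @return integer vector in \{-1, 0, +1, NA\}
#' @export
encodeInteraction <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  chk <- function(x) all(x %in% c(-1L, 0L, 1L) | is.na(x))
  if (!chk(x1) || !chk(x2)) stop("genotypes must be in {-1, 0, +1, NA}")
  out <- integer(length(x1))
  out[x1 == -1L & x2 == -1L] <- -1L
  out[x1 == 1L & x2 == 1L] <- 1L
  out[is.na(x1) | is.na(x2)] <- NA_integer_
  out
}

# dummy genotype column: random biallelic inbred genotypes, used for the
# degrees-of-freedom-matched PVE baseline
.dummyGenotype <- function(n) {
  f <- runif(1, 0.1, 0.9)
  x <- ifelse(runif(n) < f, 1, -1)
  if (length(unique(x)) < 2) x[1] <- -x[1]
  x
}

# variance-explained of one fitted GLS system: 1 - Var(resid incl BLUP)/Var(y)
# res: a .glsFit result; pre: .emmaxPre; K: kinship
.pveModel <- function(res, pre, K) {
  vz <- res$Vinvr
  u <- pre$sigma_g * drop(K %*% vz)
  kept <- setdiff(seq_len(pre$n), res$dropped)
  e <- res$resid0[kept] - u[kept]
  1 - var(e) / var(pre$y[kept])
}

# additive variance share of one fitted term: Var(beta * x) / Var(y),
# both over the lines used in the fit
.termShare <- function(beta, x, y, kept) {
  v <- var(x[kept]) * beta^2 / var(y[kept])
  min(max(v, 0), 1)
}

#' Variance decomposition of a marker model
#'
#' Decomposes phenotypic variance for the mixed model containing
#' `xMarker` (plus any SNP-covariate columns already present in the fit's
#' design). `pve_marker` is the marker's additive share
#' Var(beta x)/Var(y) (the term variance underlying its t test);
#' `pve_model` = 1 - Var(model residuals, including the kinship
#' BLUP)/Var(y) is the total model share; `pve_random` comes from a
#' baseline fit in which every marker fixed term is replaced by a random
#' genotype vector of identical degrees of freedom, so that
#' `pve_fixed_total` = `pve_model` - `pve_random` attributes the jointly
#' explained fixed genetic share. With several SNP covariates, per-term
#' shares are also attributed by leave-one-term-out differencing of
#' `pve_model`.
#'
#' @param fit an `lmmFit`; its `markerCols` field marks which design
#'   columns are SNP covariates
#' @param xMarker genotype vector of the tested marker (or NULL to
#'   decompose the covariate-only model)
#' @param nDummy number of random-baseline draws to average (default 1)
#' @param seed seed for the dummy draws
#' @return list with `pve_marker`, `pve_model`, `pve_random`,
#'   `pve_fixed_total`, per-covariate additive shares `perTermShare` and,
#'   when SNP covariates are present, `perTermLOO` leave-one-out shares
#' @export
pveDecomposition <- function(fit, xMarker = NULL, nDummy = 1, seed = 1) {
  stopifnot(inherits(fit, "lmmFit"))
  if (var(fit$y) == 0) stop("Var(y) is zero")
  pre <- .emmaxPre(fit)
  q <- if (is.null(xMarker)) 0L else 1L
  E <- if (q) matrix(as.numeric(xMarker), ncol = 1) else
    matrix(numeric(0), nrow = fit$n, ncol = 0)
  full <- if (q || length(fit$markerCols)) .glsFit(pre, E) else NULL
  baseCols <- setdiff(seq_len(fit$p), fit$markerCols)
  pve_model <- if (!is.null(full)) .pveModel(full, pre, fit$K) else NA_real_
  kept <- if (!is.null(full)) setdiff(seq_len(fit$n), full$dropped)
          else seq_len(fit$n)
  nMarkerTerms <- length(fit$markerCols) + q
  set.seed(seed)
  pr <- numeric(nDummy)
  for (d in seq_len(nDummy)) {
    D <- vapply(seq_len(max(nMarkerTerms, 1L)), function(i) .dummyGenotype(fit$n),
                numeric(fit$n))
    Xb <- cbind(fit$X[, baseCols, drop = FALSE],
                D[, seq_len(max(nMarkerTerms - 1L, 0L)), drop = FALSE])
    f2 <- fitRefitDesign(fit, Xb)
    p2 <- .emmaxPre(f2)
    r2 <- .glsFit(p2, D[, max(nMarkerTerms, 1L), drop = FALSE])
    pr[d] <- .pveModel(r2, p2, fit$K)
  }
  pve_random <- mean(pr)
  out <- list(pve_marker = NA_real_, pve_model = pve_model,
              pve_random = pve_random,
              pve_fixed_total = min(max(pve_model - pve_random, 0), 1))
  if (q)
    out$pve_marker <- .termShare(full$beta[fit$p + 1L], E[, 1], fit$y, kept)
  if (length(fit$markerCols)) {
    share <- loo <- numeric(length(fit$markerCols))
    names(share) <- names(loo) <- colnames(fit$X)[fit$markerCols]
    for (i in seq_along(fit$markerCols)) {
      ci <- fit$markerCols[i]
      share[i] <- .termShare(full$beta[ci], fit$X[, ci], fit$y, kept)
      Xi <- fit$X[, -ci, drop = FALSE]
      f2 <- fitRefitDesign(fit, Xi)
      p2 <- .emmaxPre(f2)
      ri <- .glsFit(p2, E)
      loo[i] <- pve_model - .pveModel(ri, p2, fit$K)
    }
    out$perTermShare <- share
    out$perTermLOO <- pmin(pmax(loo, 0), 1)
  }
  out
}

# reuse the variance components of `fit` with a different fixed design
fitRefitDesign <- function(fit, X) {
  f <- fit
  f$X <- as.matrix(X)
  f$p <- ncol(f$X)
  f$markerCols <- integer()
  f
}

# shared scan driver: tests each marker (optionally plus an interaction
# column) against the fitted null model. Complete markers go through a
# fully vectorised rotated-space regression in chunks; markers with
# missing genotypes go through the exact covariance-downdate GLS.
.scanDriver <- function(fit, G, interactionWith = NULL, computePve = TRUE,
                        nDummy = 1, seed = 1, covNames = character(),
                        chunkSize = 4000) {
  L <- ncol(G)
  n <- fit$n
  p <- fit$p
  nterm <- if (is.null(interactionWith)) 1L else 2L
  tgt <- p + nterm           # index of the reported (marker or interaction) term
  beta <- se <- tstat <- pval <- rep(NA_real_, L)
  mainBeta <- mainP <- rep(NA_real_, L)
  n_used <- rep(NA_integer_, L)
  dfv <- rep(NA_integer_, L)
  flag <- character(L)
  covBeta <- matrix(NA_real_, L, length(fit$markerCols))
  covP <- matrix(NA_real_, L, length(fit$markerCols))
  pveMarker <- pveModel <- rep(NA_real_, L)
  vary <- var(fit$y)
  # marker classification (sum and sum-of-squares passes, see markerStats)
  Gna <- is.na(G)
  nmiss <- colSums(Gna)
  G0cls <- G
  G0cls[Gna] <- 0
  s1c <- colSums(G0cls)
  s2c <- colSums(G0cls * G0cls)
  nA <- (s2c - s1c) / 2
  nB <- (s2c + s1c) / 2
  nH <- (n - nmiss) - s2c
  poly <- ((nA > 0) + (nH > 0) + (nB > 0)) >= 2
  flag[!poly] <- "monomorphic"
  Imat <- NULL
  if (nterm == 2L) {
    xc <- interactionWith
    Imat <- ((G == 1) & (xc == 1)) * 1 - ((G == -1) & (xc == -1)) * 1
    Imat[is.na(G)] <- NA_real_
    I0cls <- Imat
    I0cls[is.na(Imat)] <- 0
    t1c <- colSums(I0cls)
    t2c <- colSums(I0cls * I0cls)
    iA <- (t2c - t1c) / 2
    iB <- (t2c + t1c) / 2
    iH <- (n - colSums(is.na(Imat))) - t2c
    constI <- ((iA > 0) + (iH > 0) + (iB > 0)) < 2
    rm(I0cls)
    flag[poly & constI] <- "constant_interaction"
  }
  testable <- flag == ""
  completeIdx <- which(testable & nmiss == 0)
  missingIdx <- which(testable & nmiss > 0)
  # rotated system for the complete-marker batch
  sw <- sqrt(1 / (fit$sigma_g * fit$eigK$values + fit$sigma_e))
  Ut <- t(fit$eigK$vectors)
  Ty <- drop(sw * (Ut %*% fit$y))
  TX <- sw * (Ut %*% fit$X)
  XtX <- crossprod(TX)
  XtXinv <- chol2inv(chol(XtX))
  Xty <- drop(crossprod(TX, Ty))
  RSS0 <- sum(Ty^2) - drop(t(Xty) %*% XtXinv %*% Xty)
  Bx0 <- drop(XtXinv %*% Xty)
  yty <- sum(Ty^2)
  colVar <- function(M) (colSums(M^2) - colSums(M)^2 / n) / (n - 1)
  for (s in seq(1, length(completeIdx), by = chunkSize)) {
    idx <- completeIdx[s:min(s + chunkSize - 1, length(completeIdx))]
    Gc <- G[, idx, drop = FALSE]
    TG <- sw * (Ut %*% Gc)
    cXg <- XtXinv %*% crossprod(TX, TG)       # p x k
    Gr <- TG - TX %*% cXg
    s11 <- colSums(Gr^2)
    b1 <- colSums(Gr * Ty)
    if (nterm == 1L) {
      bad <- s11 <= 1e-10 * colSums(TG^2)
      betaG <- ifelse(bad, NA, b1 / s11)
      RSS <- pmax(RSS0 - b1^2 / s11, 0)
      dfk <- n - p - 1L
      sig2 <- RSS / dfk
      seG <- sqrt(sig2 / s11)
      BX <- Bx0 - t(t(cXg) * betaG)           # p x k
      beta[idx] <- betaG; se[idx] <- seG
      tstat[idx] <- betaG / seG
      pval[idx] <- 2 * pt(-abs(tstat[idx]), dfk)
      n_used[idx] <- n; dfv[idx] <- dfk
      flag[idx[bad]] <- "singular"
      beta[idx[bad]] <- se[idx[bad]] <- tstat[idx[bad]] <- pval[idx[bad]] <- NA
      if (length(fit$markerCols)) {
        for (ci in seq_along(fit$markerCols)) {
          cc <- fit$markerCols[ci]
          vb <- sig2 * (XtXinv[cc, cc] + cXg[cc, ]^2 / s11)
          covBeta[idx, ci] <- BX[cc, ]
          covP[idx, ci] <- ifelse(vb > 0,
                                  2 * pt(-abs(BX[cc, ] / sqrt(pmax(vb, 0))),
                                         dfk),
                                  NA_real_)
        }
      }
      if (computePve) {
        Rt <- Ty - TX %*% BX - t(t(TG) * betaG)
        R0 <- fit$y - fit$X %*% BX - t(t(Gc) * betaG)
        VRc <- fit$eigK$vectors %*% (sw * Rt)
        Ub <- fit$sigma_g * (fit$K %*% VRc)
        pveModel[idx] <- 1 - colVar(R0 - Ub) / vary
        pveMarker[idx] <- pmin(pmax(betaG^2 * colVar(Gc) / vary, 0), 1)
      }
    } else {
      Ic <- Imat[, idx, drop = FALSE]
      TI <- sw * (Ut %*% Ic)
      cXi <- XtXinv %*% crossprod(TX, TI)
      Ir <- TI - TX %*% cXi
      s22 <- colSums(Ir^2)
      s12 <- colSums(Gr * Ir)
      b2 <- colSums(Ir * Ty)
      det <- s11 * s22 - s12^2
      bad <- det <= 1e-10 * pmax(s11 * s22, 1e-300)
      betaG <- (s22 * b1 - s12 * b2) / det
      betaI <- (s11 * b2 - s12 * b1) / det
      RSS <- pmax(RSS0 - (betaG * b1 + betaI * b2), 0)
      dfk <- n - p - 2L
      sig2 <- RSS / dfk
      seG <- sqrt(pmax(sig2 * s22 / det, 0))
      seI <- sqrt(pmax(sig2 * s11 / det, 0))
      beta[idx] <- betaI; se[idx] <- seI
      tstat[idx] <- betaI / seI
      pval[idx] <- 2 * pt(-abs(tstat[idx]), dfk)
      mainBeta[idx] <- betaG
      mainP[idx] <- 2 * pt(-abs(betaG / seG), dfk)
      n_used[idx] <- n; dfv[idx] <- dfk
      flag[idx[bad]] <- "singular"
      beta[idx[bad]] <- se[idx[bad]] <- tstat[idx[bad]] <- pval[idx[bad]] <- NA
      mainBeta[idx[bad]] <- mainP[idx[bad]] <- NA
      BX <- Bx0 - t(t(cXg) * betaG) - t(t(cXi) * betaI)
      if (length(fit$markerCols)) {
        for (ci in seq_along(fit$markerCols)) {
          cc <- fit$markerCols[ci]
          vb <- sig2 * (XtXinv[cc, cc] +
                          (s22 * cXg[cc, ]^2 - 2 * s12 * cXg[cc, ] * cXi[cc, ] +
                             s11 * cXi[cc, ]^2) / det)
          covBeta[idx, ci] <- BX[cc, ]
          covP[idx, ci] <- ifelse(vb > 0,
                                  2 * pt(-abs(BX[cc, ] / sqrt(pmax(vb, 0))),
                                         dfk),
                                  NA_real_)
        }
      }
      if (computePve) {
        Rt <- Ty - TX %*% BX - t(t(TG) * betaG) - t(t(TI) * betaI)
        R0 <- fit$y - fit$X %*% BX - t(t(Gc) * betaG) - t(t(Ic) * betaI)
        VRc <- fit$eigK$vectors %*% (sw * Rt)
        Ub <- fit$sigma_g * (fit$K %*% VRc)
        pveModel[idx] <- 1 - colVar(R0 - Ub) / vary
        pveMarker[idx] <- pmin(pmax(betaI^2 * colVar(Ic) / vary, 0), 1)
      }
    }
  }
  # markers with missing genotypes: exact downdated GLS in compiled code,
  # with P %*% G batched up front
  if (length(missingIdx)) {
    pre <- .emmaxPre(fit)
    G0m <- G[, missingIdx, drop = FALSE]
    G0m[is.na(G0m)] <- 0
    PGm <- pre$P %*% G0m
    if (nterm == 2L) {
      I0m <- Imat[, missingIdx, drop = FALSE]
      I0m[is.na(I0m)] <- 0
      PIm <- pre$P %*% I0m
    } else {
      I0m <- PIm <- matrix(0, 0, 0)
    }
    naIdx <- lapply(missingIdx, function(j) which(is.na(G[, j])))
    bat <- .glsMissingBatch(pre$P, fit$X, fit$y, pre$Py, pre$PX, pre$XtPX,
                            pre$XtPy, pre$yPy, G0m, PGm, I0m, PIm,
                            nterm == 2L, naIdx, computePve)
    ok <- bat$singular == 0L
    flag[missingIdx[!ok]] <- "singular"
    okIdx <- missingIdx[ok]
    beta[okIdx] <- bat$coef[tgt, ok]
    se[okIdx] <- bat$se[tgt, ok]
    tstat[okIdx] <- bat$coef[tgt, ok] / bat$se[tgt, ok]
    dfv[okIdx] <- bat$df[ok]
    n_used[okIdx] <- bat$n_used[ok]
    pval[okIdx] <- 2 * pt(-abs(tstat[okIdx]), dfv[okIdx])
    if (nterm == 2L) {
      mainBeta[okIdx] <- bat$coef[p + 1L, ok]
      mainP[okIdx] <- 2 * pt(-abs(bat$coef[p + 1L, ok] / bat$se[p + 1L, ok]),
                             dfv[okIdx])
    }
    if (length(fit$markerCols)) {
      for (ci in seq_along(fit$markerCols)) {
        cc <- fit$markerCols[ci]
        covBeta[okIdx, ci] <- bat$coef[cc, ok]
        covP[okIdx, ci] <- 2 * pt(-abs(bat$coef[cc, ok] / bat$se[cc, ok]),
                                  dfv[okIdx])
      }
    }
    if (computePve) {
      Ubm <- fit$sigma_g * (fit$K %*% bat$VR)
      for (jj in which(ok)) {
        j <- missingIdx[jj]
        kept <- setdiff(seq_len(n), naIdx[[jj]])
        e <- bat$R0[kept, jj] - Ubm[kept, jj]
        pveModel[j] <- 1 - var(e) / var(fit$y[kept])
        xE <- if (nterm == 2L) Imat[, j] else G[, j]
        pveMarker[j] <- .termShare(bat$coef[tgt, jj], xE, fit$y, kept)
      }
    }
  }
  out <- data.frame(beta = beta, se = se, t = tstat, p = pval,
                    n_used = n_used, df = dfv, flag = flag)
  if (nterm == 2L) { out$main_beta <- mainBeta; out$main_p <- mainP }
  if (length(fit$markerCols)) {
    colnames(covBeta) <- paste0("cov_beta.", covNames)
    colnames(covP) <- paste0("cov_p.", covNames)
    out <- cbind(out, covBeta, covP)
  }
  if (computePve) {
    out$pve_model <- pveModel
    # baseline with df-matched random marker terms (shared across markers)
    set.seed(seed)
    pr <- numeric(nDummy)
    baseCols <- setdiff(seq_len(fit$p), fit$markerCols)
    nMarkerTerms <- length(fit$markerCols) + nterm
    for (d in seq_len(nDummy)) {
      D <- vapply(seq_len(nMarkerTerms), function(i) .dummyGenotype(n), numeric(n))
      Xb <- cbind(fit$X[, baseCols, drop = FALSE],
                  D[, seq_len(nMarkerTerms - 1L), drop = FALSE])
      f2 <- fitRefitDesign(fit, Xb)
      p2 <- .emmaxPre(f2)
      r2 <- .glsFit(p2, D[, nMarkerTerms, drop = FALSE])
      pr[d] <- .pveModel(r2, p2, fit$K)
    }
    out$pve_random <- mean(pr)
    out$pve_fixed_total <- pmin(pmax(out$pve_model - out$pve_random, 0), 1)
    out$pve_marker <- pveMarker
  }
  out
}

# assemble design matrix (intercept + PCs + SNP covariates) and kinship,
# returning everything runScan/interactionScan share
.scanSetup <- function(panel, phenotype, lines = NULL, nPcs = 3,
                       snpCovariates = character(), mafGt = 0.05, macGe = 3,
                       maxMissing = 0.30, subpopGroups = NULL,
                       kinshipMethod = "ibs", kinship = NULL, filter = TRUE) {
  if (is.data.frame(phenotype)) phenotype <- lineMeans(phenotype)
  ph <- phenotype[!is.na(phenotype)]
  lines <- if (is.null(lines)) lineIds(panel) else lines
  lines <- intersect(lines, names(ph))
  if (!length(lines)) stop("no lines with both genotype and phenotype")
  stats <- NULL
  if (!filter) {
    fp <- panel
  } else if (is.null(subpopGroups)) {
    stf <- markerStats(panel, lines)
    keep <- stf$defined & !is.na(stf$maf) & stf$maf > mafGt &
      stf$mac >= macGe & stf$missing_rate <= maxMissing
    fp <- panel[keep, ]
    stats <- stf[keep, , drop = FALSE]
  } else {
    fp <- subpopUnionFilter(panel, subpopGroups, mafGt, macGe, maxMissing)
  }
  if (is.null(stats)) stats <- markerStats(fp, lines)
  missingCov <- setdiff(snpCovariates, markerIds(fp))
  if (length(missingCov))
    stop("SNP covariate(s) absent after filtering: ",
         paste(missingCov, collapse = ", "))
  g <- genotypes(fp)[, lines, drop = FALSE]
  y <- as.numeric(ph[lines])
  X <- matrix(1, length(lines), 1, dimnames = list(lines, "intercept"))
  if (nPcs > 0) {
    pca <- computePCA(fp, lines = lines)
    X <- cbind(X, pca$scores[lines, seq_len(nPcs), drop = FALSE])
    colnames(X)[1 + seq_len(nPcs)] <- paste0("PC", seq_len(nPcs))
  }
  markerCols <- integer()
  if (length(snpCovariates)) {
    cg <- t(g[snpCovariates, , drop = FALSE]) * 1.0
    dropL <- rowSums(is.na(cg)) > 0
    if (any(dropL)) {
      message("dropping ", sum(dropL), " line(s) with missing covariate genotype")
      lines <- lines[!dropL]
      g <- g[, lines, drop = FALSE]
      y <- y[!dropL]
      X <- X[lines, , drop = FALSE]
      cg <- cg[lines, , drop = FALSE]
    }
    for (a in seq_along(snpCovariates)) for (b in seq_along(snpCovariates)) {
      if (a < b && abs(cor(cg[, a], cg[, b])) > 1 - 1e-12)
        stop("collinear SNP covariates: ", snpCovariates[a], " and ",
             snpCovariates[b])
    }
    markerCols <- ncol(X) + seq_along(snpCovariates)
    X <- cbind(X, cg)
    colnames(X)[markerCols] <- snpCovariates
  }
  K <- if (!is.null(kinship)) kinship[lines, lines]
       else if (kinshipMethod == "identity")
         diag(length(lines))  # no structure correction (diagnostic use)
       else computeKinship(fp, method = kinshipMethod, lines = lines)
  list(panel = fp, lines = lines, y = y, X = X, K = K, g = g,
       markerCols = markerCols, snpCovariates = snpCovariates,
       stats = stats)
}

#' Genome-wide kinship mixed-model association scan
#'
#' EMMAX-style scan: markers are filtered (MAF/MAC/missingness on the scan
#' lines, or the union of per-subpopulation MAF-passing markers when
#' `subpopGroups` is given); kinship is computed from the filtered
#' markers; the null model (intercept + `nPcs` principal components +
#' `snpCovariates` fixed genotype terms) is fitted once by REML; every
#' marker is then tested by generalized least squares under the frozen
#' covariance. Benjamini-Hochberg significance at `fdrQ` and the marker /
#' model / kinship variance shares are appended.
#'
#' @param panel a [GenotypePanel-class]
#' @param phenotype named vector of per-line means, or a replicated
#'   phenotype table (collapsed with [lineMeans()])
#' @param lines line ids to scan (default: all phenotyped panel lines)
#' @param nPcs number of PC covariates (3 for whole-panel scans, 0 within
#'   subpopulations)
#' @param snpCovariates marker ids to condition on as fixed terms
#' @param fdrQ FDR level for the significance flag (default 0.10)
#' @param mafGt,macGe,maxMissing marker filters (see [filterMarkers()])
#' @param subpopGroups optional named list of line-id vectors; when given,
#'   the marker set is the union of per-subpopulation MAF-passing markers
#' @param kinshipMethod,kinship kinship estimator, or a precomputed matrix
#' @param computePve whether to decompose variance per marker
#' @param nDummy,seed random-baseline draws for the PVE decomposition
#' @return data.frame (class `assocResult`) with one row per tested
#'   marker: `marker_id`, `chromosome`, `position`, `maf`, `beta`, `se`,
#'   `t`, `p`, `n_used`, `df`, `flag`, covariate effect columns, PVE
#'   columns and `significant`; attributes `vc` (variance components),
#'   `threshold` (BH cutoff), `lambda` (genomic inflation), `fit`.
#' @export
runScan <- function(panel, phenotype, lines = NULL, nPcs = 3,
                    snpCovariates = character(), fdrQ = 0.10, mafGt = 0.05,
                    macGe = 3, maxMissing = 0.30, subpopGroups = NULL,
                    kinshipMethod = "ibs", kinship = NULL, computePve = TRUE,
                    nDummy = 1, seed = 1) {
  st <- .scanSetup(panel, phenotype, lines, nPcs, snpCovariates, mafGt,
                   macGe, maxMissing, subpopGroups, kinshipMethod, kinship)
  fit <- fitNullLMM(st$y, st$X, st$K)
  fit$markerCols <- st$markerCols
  G <- t(st$g) * 1.0
  res <- .scanDriver(fit, G, computePve = computePve, nDummy = nDummy,
                     seed = seed, covNames = st$snpCovariates)
  mi <- markerInfo(st$panel)
  out <- cbind(data.frame(marker_id = mi$id, chromosome = mi$chromosome,
                          position = mi$position, maf = st$stats$maf), res)
  bh <- bhThreshold(out$p, fdrQ)
  out$significant <- bh$significant
  class(out) <- c("assocResult", "data.frame")
  attr(out, "vc") <- list(sigma_g = fit$sigma_g, sigma_e = fit$sigma_e,
                          delta = fit$delta, logLik = fit$logLik)
  attr(out, "threshold") <- bh$cutoff
  attr(out, "lambda") <- genomicInflation(out$p)
  attr(out, "config") <- list(nPcs = nPcs, snpCovariates = snpCovariates,
                              fdrQ = fdrQ, mafGt = mafGt, macGe = macGe,
                              maxMissing = maxMissing, lines = st$lines)
  attr(out, "fit") <- fit
  out
}

#' Covariate-by-marker epistatic interaction scan
#'
#' For each scan marker, fits intercept + PCs + the covariate SNP main
#' effect + the scan-marker main effect + the double-homozygote
#' interaction regressor of [encodeInteraction()], and reports the
#' interaction term's effect, P value and variance share along with the
#' scan-marker main effect.
#'
#' @inheritParams runScan
#' @param covariateSnp marker id of the conditioning SNP
#' @param markers optional explicit scan-marker ids (default: all filtered
#'   markers); requesting the covariate itself is an error
#' @return data.frame (class `assocResult`) keyed on the interaction term:
#'   `beta`/`se`/`t`/`p` refer to the interaction; `main_beta`/`main_p` to
#'   the scan-marker main effect; BH significance is computed on the
#'   interaction P values.
#' @export
interactionScan <- function(panel, phenotype, covariateSnp, lines = NULL,
                            nPcs = 3, fdrQ = 0.10, mafGt = 0.05, macGe = 3,
                            maxMissing = 0.30, subpopGroups = NULL,
                            kinshipMethod = "ibs", kinship = NULL,
                            computePve = FALSE, nDummy = 1, seed = 1,
                            markers = NULL) {
  stopifnot(length(covariateSnp) == 1)
  if (!is.null(markers) && all(markers == covariateSnp))
    stop("covariate paired with itself: perfect collinearity")
  st <- .scanSetup(panel, phenotype, lines, nPcs, snpCovariates = covariateSnp,
                   mafGt, macGe, maxMissing, subpopGroups, kinshipMethod,
                   kinship)
  fit <- fitNullLMM(st$y, st$X, st$K)
  fit$markerCols <- st$markerCols
  xcov <- st$X[, ncol(st$X)]
  ids <- if (is.null(markers)) markerIds(st$panel)
         else intersect(markers, markerIds(st$panel))
  G <- t(st$g[ids, , drop = FALSE]) * 1.0
  res <- .scanDriver(fit, G, interactionWith = xcov, computePve = computePve,
                     nDummy = nDummy, seed = seed, covNames = covariateSnp)
  mi <- markerInfo(st$panel)
  mi <- mi[match(ids, mi$id), ]
  out <- cbind(data.frame(marker_id = mi$id, chromosome = mi$chromosome,
                          position = mi$position), res)
  out$flag[out$marker_id == covariateSnp] <- "covariate"
  out$p[out$marker_id == covariateSnp] <- NA
  bh <- bhThreshold(out$p, fdrQ)
  out$significant <- bh$significant
  class(out) <- c("assocResult", "data.frame")
  attr(out, "vc") <- list(sigma_g = fit$sigma_g, sigma_e = fit$sigma_e,
                          delta = fit$delta)
  attr(out, "threshold") <- bh$cutoff
  attr(out, "lambda") <- genomicInflation(out$p)
  attr(out, "config") <- list(nPcs = nPcs, covariateSnp = covariateSnp,
                              fdrQ = fdrQ, lines = st$lines)
  out
}
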