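#' Fit the null kinship mixed model by REML
#'
#' Model: y = X b + u + e with u ~ N(0, sigma2_g K), e ~ N(0, sigma2_e I).
#' The restricted likelihood is profiled over the variance ratio
#' delta = sigma2_e / sigma2_g using the eigendecomposition of S K S
#' (S the projection off the column space of X), evaluated on a dense grid
#' of log(delta) and refined around every grid local maximum with a
#' derivative-free optimiser. The grid guards against the multimodality of
#' the REML surface at small n.
#'
#' @param y numeric response (no NAs)
#' @param X fixed-effect design matrix including the intercept; must be
#'   full column rank
#' @param K kinship matrix aligned with `y`; slightly negative eigenvalues
#'   are clamped to zero with a warning
#' @param gridPoints grid size for log(delta) (default 100)
#' @param bounds log(delta) search interval (default c(-10, 10))
#' @return object of class `lmmFit`: variance components `sigma_g`,
#'   `sigma_e`, `delta`, REML `logLik`, the data, and cached
#'   eigendecompositions used by [glsTest()] and the scan functions.
#' @export
fitNullLMM <- function(y, X, K, gridPoints = 100, bounds = c(-10, 10)) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (anyNA(y) || anyNA(X)) stop("y and X must be complete")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    if (is.null(bad)) bad <- qx$pivot[(qx$rank + 1):p]
    stop("X is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eK$values) < -1e-8) {
    warning("kinship matrix not PSD; clamping negative eigenvalues to 0")
    eK$values[eK$values < 0] <- 0
    K <- eK$vectors %*% (eK$values * t(eK$vectors))
  } else eK$values[eK$values < 0] <- 0
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  eS <- eigen(S %*% K %*% S, symmetric = TRUE)
  np <- n - p
  lam <- pmax(eS$values[seq_len(np)], 0)
  U <- eS$vectors[, seq_len(np), drop = FALSE]
  eta2 <- drop(crossprod(U, y))^2
  restLL <- function(logd) {
    d <- exp(logd)
    R <- sum(eta2 / (lam + d))
    0.5 * (np * log(np / (2 * pi)) - np - np * log(R) - sum(log(lam + d)))
  }
  grid <- seq(bounds[1], bounds[2], length.out = gridPoints)
  ll <- vapply(grid, restLL, 0)
  # refine around every grid local maximum
  isMax <- vapply(seq_along(grid), function(i) {
    (i == 1 || ll[i] >= ll[i - 1]) && (i == length(grid) || ll[i] >= ll[i + 1])
  }, TRUE)
  best <- list(objective = -Inf)
  for (i in which(isMax)) {
    lo <- grid[max(i - 1, 1)]
    hi <- grid[min(i + 1, length(grid))]
    o <- if (hi > lo) optimize(restLL, c(lo, hi), maximum = TRUE)
         else list(maximum = grid[i], objective = ll[i])
    if (o$objective > best$objective)
      best <- list(objective = o$objective, maximum = o$maximum)
  }
  delta <- exp(best$maximum)
  sigma_g <- sum(eta2 / (lam + delta)) / np
  sigma_e <- delta * sigma_g
  structure(list(delta = delta, sigma_g = sigma_g, sigma_e = sigma_e,
                 logLik = best$objective, y = y, X = X, K = K,
                 eigK = eK, n = n, p = p, markerCols = integer()),
            class = "lmmFit")
}

#' @export
print.lmmFit <- function(x, ...) {
  cat(sprintf("kinship LMM fit (REML): n = %d, p = %d\n", x$n, x$p))
  cat(sprintf("  sigma2_g = %.5g  sigma2_e = %.5g  delta = %.5g  logLik = %.4f\n",
              x$sigma_g, x$sigma_e, x$delta, x$logLik))
  invisible(x)
}

# Precompute V^-1 machinery shared by all per-marker tests.
# V = sigma_g K + sigma_e I; P = V^-1 via the cached eigendecomposition.
.emmaxPre <- function(fit) {
  w <- 1 / (fit$sigma_g * fit$eigK$values + fit$sigma_e)
  P <- fit$eigK$vectors %*% (w * t(fit$eigK$vectors))
  P <- (P + t(P)) / 2
  Py <- drop(P %*% fit$y)
  PX <- P %*% fit$X
  list(P = P, Py = Py, PX = PX,
       XtPX = crossprod(fit$X, PX), XtPy = drop(crossprod(fit$X, Py)),
       yPy = sum(fit$y * Py), X = fit$X, y = fit$y,
       n = fit$n, p = fit$p, sigma_g = fit$sigma_g)
}

# Exact GLS of y on [X, E] under fixed V, dropping lines where any column
# of E is missing. Uses a block-downdate of V^-1 so no per-marker
# refactorisation is needed. Returns NULL when the system is singular
# (e.g. a monomorphic or collinear extra column). PE = P %*% E (with NAs
# zeroed) may be passed in when precomputed in batch.
.glsFit <- function(pre, E, PE = NULL, Mi = NULL, needResid = TRUE) {
  if (!is.matrix(E)) E <- as.matrix(E)
  q <- ncol(E)
  if (is.null(Mi)) Mi <- which(is.na(E[, 1]) | (q > 1 & is.na(E[, q])))
  g0 <- E
  if (length(Mi)) g0[Mi, ] <- 0
  g0[is.na(g0)] <- 0
  if (is.null(PE)) PE <- pre$P %*% g0
  C_XE <- crossprod(pre$PX, g0)
  C_EE <- crossprod(g0, PE)
  c_E <- drop(crossprod(g0, pre$Py))
  if (length(Mi)) {
    m <- length(Mi)
    Q <- pre$P[, Mi, drop = FALSE]
    Pmm <- pre$P[Mi, Mi, drop = FALSE]
    XM <- pre$X[Mi, , drop = FALSE]
    yM <- pre$y[Mi]
    XtQ <- crossprod(pre$X, Q)
    PyM <- pre$Py[Mi]
    PEM <- PE[Mi, , drop = FALSE]
    cho <- chol(Pmm)                      # P is PD, so Pmm is PD
    PmmyM <- drop(Pmm %*% yM)
    t1 <- XtQ %*% XM
    C_XX <- pre$XtPX - t1 - t(t1) + crossprod(XM, Pmm %*% XM)
    C_XE <- C_XE - crossprod(XM, PEM)
    c_X <- pre$XtPy - drop(XtQ %*% yM) - drop(crossprod(XM, PyM)) +
      drop(crossprod(XM, PmmyM))
    c_E <- c_E - drop(crossprod(PEM, yM))
    yPy <- pre$yPy - 2 * sum(PyM * yM) + sum(yM * PmmyM)
    G <- rbind(XtQ - crossprod(XM, Pmm), t(PEM))
    h <- PyM - PmmyM
    # G Pmm^-1 G', G Pmm^-1 h, h' Pmm^-1 h via one triangular factor
    A1 <- backsolve(cho, t(G), transpose = TRUE)
    bh <- backsolve(cho, h, transpose = TRUE)
    C <- rbind(cbind(C_XX, C_XE), cbind(t(C_XE), C_EE)) - crossprod(A1)
    cc <- c(c_X, c_E) - drop(crossprod(A1, bh))
    ytVy <- yPy - sum(bh^2)
  } else {
    C <- rbind(cbind(pre$XtPX, C_XE), cbind(t(C_XE), C_EE))
    cc <- c(pre$XtPy, c_E)
    ytVy <- pre$yPy
  }
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e) NULL)
  if (is.null(Cinv)) return(NULL)
  beta <- drop(Cinv %*% cc)
  n_used <- pre$n - length(Mi)
  df <- n_used - (pre$p + q)
  if (df <= 0) return(NULL)
  rss <- max(ytVy - sum(beta * cc), 0)
  sigma2 <- rss / df
  se <- sqrt(pmax(diag(Cinv) * sigma2, 0))
  tstat <- ifelse(se > 0, beta / se, NA_real_)
  pval <- 2 * pt(-abs(tstat), df)
  if (!needResid)
    return(list(beta = beta, se = se, t = tstat, p = pval, df = df,
                n_used = n_used, sigma2 = sigma2, rss = rss, dropped = Mi))
  # V_kk^-1 r_k on the kept lines (zeroed at dropped lines), for the
  # model-variance (PVE) bookkeeping: r = y - [X, E] beta
  bx <- beta[seq_len(pre$p)]
  bE <- beta[pre$p + seq_len(q)]
  if (length(Mi)) {
    s <- (pre$Py - drop(Q %*% yM)) -
      (pre$PX %*% bx - drop(Q %*% (XM %*% bx))) - drop(PE %*% bE)
    s <- drop(s)
    corr <- backsolve(cho, backsolve(cho, s[Mi], transpose = TRUE))
    vr <- s - drop(Q %*% corr)
    vr[Mi] <- 0
  } else {
    vr <- drop(pre$Py - pre$PX %*% bx - PE %*% bE)
  }
  r <- pre$y - drop(pre$X %*% bx) - drop(g0 %*% bE)
  if (length(Mi)) r[Mi] <- 0
  list(beta = beta, se = se, t = tstat, p = pval, df = df, n_used = n_used,
       sigma2 = sigma2, rss = rss, Vinvr = vr, resid0 = r, dropped = Mi)
}

#' Generalized least squares test of one marker (EMMAX step)
#'
#' Tests `xMarker` as a fixed term added to the null-model design, under
#' the covariance sigma2_g K + sigma2_e I frozen at the null-model REML
#' estimates (the EMMAX approximation). Lines with a missing marker
#' genotype are dropped from the test exactly (block-downdate of the
#' covariance inverse); the marker effect is the expected trait change per
#' alternate (B) allele; the P value is a two-sided t test on
#' `n_used - p` df.
#'
#' @param fit an `lmmFit` from [fitNullLMM()]
#' @param xMarker numeric genotype vector in \{-1, 0, +1, NA\} aligned with
#'   the fit
#' @param refit if TRUE, re-estimate the variance components with the
#'   marker's missing lines removed before testing (exact per-marker LMM
#'   rather than the EMMAX approximation)
#' @return one-row data.frame: `beta`, `se`, `t`, `p`, `n_used`, `df`;
#'   attribute `"coefficients"` holds the full fixed-effect vector. NULL
#'   fields (all NA) with attribute `"flag"` when the marker is monomorphic
#'   among tested lines.
#' @export
glsTest <- function(fit, xMarker, refit = FALSE) {
  stopifnot(inherits(fit, "lmmFit"), length(xMarker) == fit$n)
  keep <- !is.na(xMarker)
  if (length(unique(xMarker[keep])) < 2) {
    out <- data.frame(beta = NA_real_, se = NA_real_, t = NA_real_,
                      p = NA_real_, n_used = sum(keep), df = NA_integer_)
    attr(out, "flag") <- "monomorphic"
    return(out)
  }
  if (refit && any(!keep)) {
    sub <- fitNullLMM(fit$y[keep], fit$X[keep, , drop = FALSE],
                      fit$K[keep, keep])
    return(glsTest(sub, xMarker[keep]))
  }
  pre <- .emmaxPre(fit)
  res <- .glsFit(pre, matrix(as.numeric(xMarker), ncol = 1))
  if (is.null(res)) {
    out <- data.frame(beta = NA_real_, se = NA_real_, t = NA_real_,
                      p = NA_real_, n_used = sum(keep), df = NA_integer_)
    attr(out, "flag") <- "singular"
    return(out)
  }
  j <- fit$p + 1L
  out <- data.frame(beta = res$beta[j], se = res$se[j], t = res$t[j],
                    p = res$p[j], n_used = res$n_used, df = res$df)
  attr(out, "coefficients") <- res$beta
  attr(out, "se.all") <- res$se
  out
}

#' Genomic inflation factor
#'
#' Lambda_GC: the median association chi-square divided by its null median.
#' Values near 1 indicate calibrated tests; values above ~1.2 indicate
#' confounding by uncorrected structure.
#'
#' @param p vector of P values
#' @export
genomicInflation <- function(p) {
  p <- p[!is.na(p)]
  median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)
}
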