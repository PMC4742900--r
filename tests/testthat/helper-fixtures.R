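# Shared fixtures and independent oracles used across the suite.

# quick panel from a raw genotype matrix (markers x lines)
toyPanel <- function(g, chromosome = "1", position = NULL, lineIds = NULL,
                     ref = "A", alt = "T", lines = NULL) {
  g <- as.matrix(g)
  if (is.null(position)) position <- seq_len(nrow(g)) * 1000L
  if (is.null(lines)) {
    if (is.null(lineIds)) lineIds <- sprintf("L%02d", seq_len(ncol(g)))
    lines <- data.frame(id = lineIds)
  }
  mk <- data.frame(chromosome = rep_len(chromosome, nrow(g)),
                   position = position, ref_allele = ref, alt_allele = alt)
  GenotypePanel(g, mk, lines)
}

# medium structured panel shared by module tests (built once)
.fixtureCache <- new.env(parent = emptyenv())
testPanel <- function() {
  if (is.null(.fixtureCache$panel)) {
    cfg <- simPanelConfig(linesPerSubpop = 30, nMarkers = 1200,
                          admixedFraction = 0.1,
                          chromLengths = setNames(rep(20e6, 4),
                                                  as.character(1:4)))
    sim <- simulateGenotypes(cfg, seed = 99)
    .fixtureCache$panel <- sim$panel
    .fixtureCache$truth <- sim$truth
    .fixtureCache$filtered <- filterMarkers(sim$panel)
    .fixtureCache$K <- computeKinship(.fixtureCache$filtered)
  }
  .fixtureCache
}

# dense GLS oracle: explicit covariance inverse, lines with missing marker
# genotype dropped
denseGlsOracle <- function(y, X, x, K, sigma_g, sigma_e) {
  k <- which(!is.na(x))
  V <- sigma_g * K + sigma_e * diag(length(y))
  Vik <- solve(V[k, k])
  B <- cbind(X[k, , drop = FALSE], x[k])
  C <- t(B) %*% Vik %*% B
  cc <- drop(t(B) %*% Vik %*% y[k])
  beta <- solve(C, cc)
  df <- length(k) - ncol(B)
  rss <- drop(t(y[k]) %*% Vik %*% y[k]) - sum(beta * cc)
  sig2 <- rss / df
  se <- sqrt(diag(solve(C)) * sig2)
  j <- ncol(B)
  tst <- beta[j] / se[j]
  list(beta = beta[j], se = se[j], p = 2 * pt(-abs(tst), df),
       coefficients = beta)
}

# dense REML log-likelihood (EMMA parameterisation, profiled over sigma_g)
denseRemlLL <- function(y, X, K, logDelta) {
  n <- length(y)
  p <- ncol(X)
  d <- exp(logDelta)
  V1 <- K + d * diag(n)
  Vi <- solve(V1)
  XtViX <- t(X) %*% Vi %*% X
  P1 <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  yPy <- drop(t(y) %*% P1 %*% y)
  np <- n - p
  as.numeric(0.5 * (np * log(np / (2 * pi)) - np - np * log(yPy) -
                      determinant(V1)$modulus - determinant(XtViX)$modulus +
                      determinant(crossprod(X))$modulus))
}

# eigenvalues by characteristic polynomial (Faddeev-LeVerrier + polyroot)
charPolyEigenvalues <- function(M) {
  n <- nrow(M)
  cs <- numeric(n)
  Mk <- M
  cs[1] <- -sum(diag(Mk))
  for (k in 2:n) {
    Mk <- M %*% (Mk + cs[k - 1] * diag(n))
    cs[k] <- -sum(diag(Mk)) / k
  }
  r <- polyroot(rev(c(1, cs)))
  sort(Re(r), decreasing = TRUE)
}

# balanced replicated trial with known variance components
simTrial <- function(nGeno, e = 2, r = 3, s2g = 1, s2gxe = 0.2, s2 = 0.4,
                     mean = 5, seed = 1) {
  set.seed(seed)
  gv <- rnorm(nGeno, 0, sqrt(s2g))
  gxe <- matrix(rnorm(nGeno * e, 0, sqrt(s2gxe)), nGeno, e)
  rec <- expand.grid(replicate = seq_len(r), environment = seq_len(e),
                     geno = seq_len(nGeno))
  data.frame(line_id = sprintf("G%04d", rec$geno),
             environment = paste0("E", rec$environment),
             replicate = rec$replicate,
             value = mean + gv[rec$geno] +
               gxe[cbind(rec$geno, rec$environment)] +
               rnorm(nrow(rec), 0, sqrt(s2)))
}

identityKinship <- function(ids) {
  K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  K
}
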