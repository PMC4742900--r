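test_that("Benjamini-Hochberg step-up matches hand computation", {
  r <- bhThreshold(c(0.001, 0.01, 0.02, 0.9), q = 0.1)
  expect_equal(r$cutoff, 0.02)
  expect_equal(r$nSignificant, 3L)
  expect_identical(r$significant, c(TRUE, TRUE, TRUE, FALSE))
  r1 <- bhThreshold(0.05, q = 0.1)
  expect_equal(r1$nSignificant, 1L)
  r0 <- bhThreshold(rep(1, 5), q = 0.1)
  expect_true(is.na(r0$cutoff))
  expect_equal(r0$nSignificant, 0L)
  expect_message(bhThreshold(numeric(0)), "no p values")
})

test_that("interaction coding enumerates the double-homozygote contrast", {
  vals <- c(-1L, 0L, 1L, NA)
  for (a in vals) for (b in vals) {
    got <- encodeInteraction(a, b)
    want <- if (is.na(a) || is.na(b)) NA_integer_
            else if (a == -1L && b == -1L) -1L
            else if (a == 1L && b == 1L) 1L
            else 0L
    expect_identical(got, want, label = sprintf("(%s,%s)", a, b))
    expect_identical(got, encodeInteraction(b, a),
                     label = sprintf("symmetry (%s,%s)", a, b))
  }
  expect_error(encodeInteraction(2L, 1L), "-1, 0")
})

test_that("variance decomposition recognises a marker that is the phenotype", {
  set.seed(20)
  n <- 200
  y <- rnorm(n)
  x <- drop(scale(y))
  fit <- fitNullLMM(y, matrix(1, n, 1), diag(n))
  d <- pveDecomposition(fit, x, seed = 1)
  expect_gt(d$pve_marker, 0.99)
  # independent marker explains nothing
  set.seed(21)
  x2 <- sample(c(-1, 1), 500, TRUE)
  y2 <- rnorm(500)
  fit2 <- fitNullLMM(y2, matrix(1, 500, 1), diag(500))
  d2 <- pveDecomposition(fit2, x2, seed = 1)
  expect_lt(abs(d2$pve_marker), 0.01)
})

test_that("a QTL constructed to explain 20% of variance is attributed ~20%", {
  set.seed(22)
  n <- 500
  pves <- vapply(1:20, function(s) {
    set.seed(400 + s)
    x <- sample(c(-1, 1), n, TRUE)
    noise <- rnorm(n)
    a <- sqrt(0.2 / 0.8 * var(noise) / var(x))
    y <- a * x + noise
    fit <- fitNullLMM(y, matrix(1, n, 1), diag(n))
    pveDecomposition(fit, x, seed = s)$pve_marker
  }, 0)
  expect_gte(mean(pves), 0.15)
  expect_lte(mean(pves), 0.25)
})

test_that("scan results are deterministic and bookkeep degrees of freedom", {
  fx <- testPanel()
  arch <- traitArchitecture(sigma2Bg = 0.5, sigma2Err = 0.1)
  y <- lineMeans(simulatePhenotypes(fx$filtered, arch, seed = 51,
                                    kinship = fx$K))
  r1 <- runScan(fx$filtered, y, nPcs = 3, seed = 7, kinship = fx$K)
  r2 <- runScan(fx$filtered, y, nPcs = 3, seed = 7, kinship = fx$K)
  expect_identical(r1, r2)
  ok <- r1$flag == ""
  # df = n_used - p exactly, p = intercept + 3 PCs + marker
  expect_true(all(r1$df[ok] == r1$n_used[ok] - 5L))
  expect_true(all(r1$p[ok] > 0 & r1$p[ok] <= 1))
})

test_that("variance shares are coherent on a scanned panel", {
  fx <- testPanel()
  st <- markerStats(fx$filtered)
  mk <- st$id[st$missing_rate == 0 & st$maf > 0.3][1]
  arch <- traitArchitecture(
    additiveQtls = data.frame(marker = mk, effect = 0.4),
    sigma2Bg = 0.3, sigma2Err = 0.05)
  y <- lineMeans(simulatePhenotypes(fx$filtered, arch, seed = 52,
                                    kinship = fx$K))
  res <- runScan(fx$filtered, y, nPcs = 0, seed = 3, kinship = fx$K)
  ok <- res$flag == ""
  expect_true(all(res$pve_model[ok] >= res$pve_random[ok] - 1e-6))
  expect_true(all(res$pve_marker[ok] >= 0 & res$pve_marker[ok] <= 1))
  expect_true(all(res$pve_fixed_total[ok] + res$pve_random[ok] <=
                    res$pve_model[ok] + 1e-6))
  # the planted QTL tops the scan
  expect_equal(res$marker_id[which.min(res$p)], mk)
})

test_that("SNP-covariate conditioning validates its inputs", {
  fx <- testPanel()
  arch <- traitArchitecture(sigma2Bg = 0.5, sigma2Err = 0.1)
  y <- lineMeans(simulatePhenotypes(fx$filtered, arch, seed = 53,
                                    kinship = fx$K))
  expect_error(runScan(fx$filtered, y, snpCovariates = "SNP-9.999",
                       kinship = fx$K),
               "absent after filtering")
  # duplicating a covariate column is collinear
  g <- genotypes(fx$filtered)
  st <- markerStats(fx$filtered)
  dup <- st$id[st$missing_rate == 0 & st$maf > 0.3]
  g2 <- rbind(g, dup2 = g[dup[1], ])
  mi <- markerInfo(fx$filtered)
  mi2 <- rbind(mi, data.frame(id = "SNP-4.19999999", chromosome = "4",
                              position = 19999999L, ref_allele = "A",
                              alt_allele = "T"))
  rownames(g2)[nrow(g2)] <- "SNP-4.19999999"
  p2 <- GenotypePanel(g2, mi2, lineInfo(fx$filtered))
  expect_error(runScan(p2, y, snpCovariates = c(dup[1], "SNP-4.19999999")),
               "collinear")
  expect_error(interactionScan(fx$filtered, y, dup[1], markers = dup[1]),
               "itself")
})

test_that("conditioning on a planted QTL removes its signal", {
  fx <- testPanel()
  st <- markerStats(fx$filtered)
  mk <- st$id[st$missing_rate == 0 & st$maf > 0.3][1]
  arch <- traitArchitecture(
    additiveQtls = data.frame(marker = mk, effect = 0.5),
    sigma2Bg = 0.3, sigma2Err = 0.05)
  y <- lineMeans(simulatePhenotypes(fx$filtered, arch, seed = 54,
                                    kinship = fx$K))
  plain <- runScan(fx$filtered, y, nPcs = 0, computePve = FALSE,
                   kinship = fx$K)
  expect_lt(plain$p[plain$marker_id == mk], 1e-8)
  cond <- runScan(fx$filtered, y, nPcs = 0, snpCovariates = mk,
                  computePve = FALSE, kinship = fx$K)
  expect_true(cond$flag[cond$marker_id == mk] != "")
  # covariate effect is reported and close to the planted effect
  cb <- cond[[paste0("cov_beta.", mk)]]
  expect_equal(median(cb, na.rm = TRUE), 0.5, tolerance = 0.15)
})

test_that("interaction scans expose planted epistasis and flag degenerate terms", {
  fx <- testPanel()
  st <- markerStats(fx$filtered)
  mi <- markerInfo(fx$filtered)
  hets <- rowSums(genotypes(fx$filtered) == 0L, na.rm = TRUE)
  cand <- st$id[st$missing_rate == 0 & st$maf > 0.35 & hets >= 1]
  chr <- mi$chromosome[match(cand, mi$id)]
  m1 <- cand[chr == chr[1]][1]
  m2 <- cand[chr != chr[1]][1]
  # size the interaction for ~30% of phenotypic variance
  unit <- epistasisContribution(fx$filtered,
                                plantPureEpistasis(fx$filtered, m1, m2, 1))
  baseVar <- 0.2 * (1 - mean(fx$K[upper.tri(fx$K)])) + 0.05
  w <- sqrt(0.3 / 0.7 * baseVar / var(unit))
  frag <- plantPureEpistasis(fx$filtered, m1, m2, w = w)
  arch <- traitArchitecture(epistaticPair = frag, sigma2Bg = 0.2,
                            sigma2Err = 0.05)
  y <- lineMeans(simulatePhenotypes(fx$filtered, arch, seed = 55,
                                    kinship = fx$K))
  single <- runScan(fx$filtered, y, nPcs = 0, computePve = FALSE,
                    kinship = fx$K)
  expect_gt(single$p[single$marker_id == m1], 1e-3)
  expect_gt(single$p[single$marker_id == m2], 1e-3)
  inter <- interactionScan(fx$filtered, y, m1, nPcs = 0, kinship = fx$K)
  expect_lt(inter$p[inter$marker_id == m2], 1e-4)
  expect_equal(inter$flag[inter$marker_id == m1], "covariate")
})

test_that("null interaction scans are calibrated across phenotype draws", {
  # within one scan, interaction P values share the covariate and the single
  # phenotype realisation and are therefore dependent; calibration is
  # assessed with one randomly chosen interaction P per independent seed
  # (iid uniform under the null) plus the per-scan inflation factor
  fx <- testPanel()
  st <- markerStats(fx$filtered)
  cov1 <- st$id[st$missing_rate == 0 & st$maf > 0.35][1]
  arch <- traitArchitecture(sigma2Bg = 0.5, sigma2Err = 0.1)
  set.seed(90)
  pick <- numeric(12)
  lam <- numeric(12)
  for (s in 1:12) {
    y <- lineMeans(simulatePhenotypes(fx$filtered, arch, seed = 600 + s,
                                      kinship = fx$K))
    inter <- interactionScan(fx$filtered, y, cov1, nPcs = 0,
                             kinship = fx$K)
    p <- inter$p[!is.na(inter$p)]
    pick[s] <- sample(p, 1)
    lam[s] <- genomicInflation(p)
  }
  expect_gt(ks.test(pick, "punif")$p.value, 0.01)
  expect_gt(mean(lam), 0.6)
  expect_lt(mean(lam), 1.4)
})

test_that("genomic inflation is computed from the chi-square median", {
  set.seed(30)
  p <- runif(50000)
  expect_equal(genomicInflation(p), 1, tolerance = 0.05)
})
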