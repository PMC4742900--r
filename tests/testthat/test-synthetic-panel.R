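test_that("the generator is deterministic given (config, seed)", {
  cfg <- simPanelConfig(linesPerSubpop = 10, nMarkers = 200,
                        chromLengths = c(`1` = 1e6))
  a <- simulateGenotypes(cfg, seed = 5)
  b <- simulateGenotypes(cfg, seed = 5)
  expect_identical(genotypes(a$panel), genotypes(b$panel))
  expect_identical(a$truth$subpopFreq, b$truth$subpopFreq)
  c <- simulateGenotypes(cfg, seed = 6)
  expect_false(identical(genotypes(a$panel), genotypes(c$panel)))
})

test_that("residual heterozygosity is bounded by its configured rate", {
  cfg0 <- simPanelConfig(linesPerSubpop = 10, nMarkers = 300,
                         residualHetRate = 0, missingRate = 0,
                         chromLengths = c(`1` = 1e6))
  g0 <- genotypes(simulateGenotypes(cfg0, seed = 3)$panel)
  expect_false(any(g0 == 0L, na.rm = TRUE))
  rate <- 0.01
  cfg1 <- simPanelConfig(linesPerSubpop = 20, nMarkers = 2000,
                         residualHetRate = rate, missingRate = 0,
                         chromLengths = c(`1` = 1e6))
  g1 <- genotypes(simulateGenotypes(cfg1, seed = 3)$panel)
  n <- length(g1)
  expect_lte(mean(g1 == 0L), rate + 3 * sqrt(rate * (1 - rate) / n))
})

test_that("subpopulation frequencies follow the Balding-Nichols variance", {
  # F -> 0: per-subpop frequencies collapse onto the ancestral values
  cfg <- simPanelConfig(nSubpops = 2, linesPerSubpop = 2, nMarkers = 10000,
                        fst = 1e-6, chromLengths = c(`1` = 1e8))
  tr <- simulateGenotypes(cfg, seed = 4)$truth
  dev <- abs(tr$subpopFreq - tr$ancestralFreq)
  expect_lt(mean(dev), 0.05)
  # moderate F: sd of (q - p) across markers ~ sqrt(F p (1-p))
  cfgF <- simPanelConfig(nSubpops = 1, linesPerSubpop = 2, nMarkers = 20000,
                         fst = 0.2, chromLengths = c(`1` = 1e8),
                         ancestralFreqRange = c(0.5, 0.5))
  trF <- simulateGenotypes(cfgF, seed = 4)$truth
  expect_equal(sd(trF$subpopFreq[, 1]), sqrt(0.2 * 0.25), tolerance = 0.05)
})

test_that("missingness and marker ordering invariants hold", {
  fx <- testPanel()
  mi <- markerInfo(fx$panel)
  expect_true(all(diff(order(mi$chromosome, mi$position)) == 1))
  expect_true(all(mi$position >= 1))
  g <- genotypes(fx$panel)
  expect_equal(mean(is.na(g)), fx$truth$config$missingRate, tolerance = 0.35)
})

test_that("phenotypes with no QTLs and zero variances are constant at the trait mean", {
  fx <- testPanel()
  arch <- traitArchitecture(traitMean = 6.1, environments = 2, replicates = 2)
  ph <- simulatePhenotypes(fx$filtered, arch, seed = 1)
  expect_true(all(ph$value == 6.1))
  expect_equal(nrow(ph), nLines(fx$filtered) * 4)
})

test_that("a noise-free additive QTL separates homozygotes by twice its effect", {
  fx <- testPanel()
  st <- markerStats(fx$filtered)
  mk <- st$id[st$missing_rate == 0 & st$maf > 0.3][1]
  arch <- traitArchitecture(additiveQtls = data.frame(marker = mk,
                                                      effect = 0.5),
                            environments = 1, replicates = 1)
  ph <- simulatePhenotypes(fx$filtered, arch, seed = 1)
  y <- lineMeans(ph)
  x <- genotypes(fx$filtered)[mk, names(y)]
  expect_equal(unname(mean(y[x == 1]) - mean(y[x == -1])), 1.0)
})

test_that("heritability is recovered from simulated replicated trials", {
  # iid genetic values (identity kinship), sigma2_g = 1, gxe = 0.2, err = 0.4
  fx <- testPanel()
  ids <- lineIds(fx$filtered)
  Ki <- identityKinship(ids)
  target <- broadSenseH2(1, 0.2, 0.4, r = 3, e = 2)
  h2s <- vapply(1:20, function(s) {
    arch <- traitArchitecture(sigma2Bg = 1, sigma2Gxe = 0.2, sigma2Err = 0.4,
                              environments = 2, replicates = 3)
    ph <- simulatePhenotypes(fx$filtered, arch, seed = 100 + s, kinship = Ki)
    estimateComponents(ph)$H2
  }, 0)
  expect_lt(abs(mean(h2s) - target), 0.05)
})

test_that("realized genetic variance matches the variance of planted genetic values", {
  fx <- testPanel()
  arch <- traitArchitecture(sigma2Bg = 0.5, sigma2Err = 1e-8,
                            environments = 2, replicates = 3)
  ph <- simulatePhenotypes(fx$filtered, arch, seed = 12, kinship = fx$K)
  gv <- attr(ph, "geneticValues")
  y <- lineMeans(ph)
  expect_equal(var(unname(y)), var(unname(gv)), tolerance = 0.02)
})

test_that("pure epistasis construction zeroes the marginal effects", {
  # balanced 2x2 homozygote table
  g <- rbind(rep(c(-1L, 1L), each = 10),
             rep(rep(c(-1L, 1L), each = 5), 2))
  p <- toyPanel(g, position = c(1000L, 500000L))
  # on an all-homozygote table the interaction is fully absorbed by the
  # mains (I = (x1+x2)/2) and the constructor says so
  expect_warning(
    frag <- plantPureEpistasis(p, markerIds(p)[1], markerIds(p)[2], w = 1),
    "collinear")
  contrib <- epistasisContribution(p, frag)
  x1 <- genotypes(p)[1, ]
  x2 <- genotypes(p)[2, ]
  expect_lt(abs(coef(lm(contrib ~ x1))[2]), 1e-10)
  expect_lt(abs(coef(lm(contrib ~ x2))[2]), 1e-10)
  # w = 0: no contribution at all
  frag0 <- plantPureEpistasis(p, markerIds(p)[1], markerIds(p)[2], w = 0)
  expect_true(all(abs(epistasisContribution(p, frag0)) < 1e-12))
})

test_that("pure epistasis refuses markers in perfect LD and requires polymorphism", {
  g <- rbind(rep(c(-1L, 1L), each = 10),
             rep(c(-1L, 1L), each = 10),
             rep(-1L, 20))
  p <- toyPanel(g)
  ids <- markerIds(p)
  expect_error(plantPureEpistasis(p, ids[1], ids[2], 1), "perfect LD")
  expect_error(plantPureEpistasis(p, ids[1], ids[3], 1), "polymorphic")
})

test_that("marginal-centred epistasis on real panels keeps marginals small", {
  fx <- testPanel()
  st <- markerStats(fx$filtered)
  mi <- markerInfo(fx$filtered)
  hets <- rowSums(genotypes(fx$filtered) == 0L, na.rm = TRUE)
  cand <- st$id[st$missing_rate == 0 & st$maf > 0.35 & hets >= 1]
  chr <- mi$chromosome[match(cand, mi$id)]
  m1 <- cand[chr == chr[1]][1]
  m2 <- cand[chr != chr[1]][1]
  frag <- plantPureEpistasis(fx$filtered, m1, m2, w = 1)
  contrib <- epistasisContribution(fx$filtered, frag)
  x1 <- genotypes(fx$filtered)[m1, ]
  r <- summary(lm(contrib ~ x1))$r.squared
  expect_lt(r, 0.02)
})

test_that("subpopulation-restricted markers segregate only where intended", {
  cfg <- simPanelConfig(linesPerSubpop = 40, nMarkers = 3000,
                        admixedFraction = 0, fst = 0.5,
                        chromLengths = setNames(rep(1e7, 3),
                                                as.character(1:3)))
  sim <- simulateGenotypes(cfg, seed = 21)
  mk <- findRestrictedMarkers(sim$truth, "aus", minIn = 0.2, maxOut = 0.01)
  expect_gt(length(mk), 0)
  st_aus <- markerStats(sim$panel, groupLines(sim$panel, "aus"))
  st_oth <- markerStats(sim$panel, setdiff(lineIds(sim$panel),
                                           groupLines(sim$panel, "aus")))
  i <- match(mk, st_aus$id)
  expect_gt(mean(st_aus$maf[i] > 0.1, na.rm = TRUE), 0.8)
  expect_lt(mean(st_oth$maf[i], na.rm = TRUE), 0.05)
})

test_that("local LD induction creates a support cluster around the focal marker", {
  fx <- testPanel()
  st <- markerStats(fx$filtered)
  mk <- st$id[st$missing_rate == 0 & st$maf > 0.3][2]
  p2 <- induceLocalLD(fx$filtered, mk, windowBp = 200000, flipProb = 0.05,
                      seed = 3)
  linked <- attr(p2, "linked")
  expect_gt(length(linked), 0)
  x0 <- genotypes(p2)[mk, ]
  for (l in linked) {
    r <- ldPair(x0, genotypes(p2)[l, ])
    expect_gt(r$r2, 0.5)
  }
})
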