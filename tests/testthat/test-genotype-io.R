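test_that("tabular dialect maps A/H/B/N to -1/0/1/NA", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("line_id\tSNP-1.100\tSNP-1.200",
               "L1\tA\tB",
               "L2\tH\tN"), f)
  p <- readGenotypes(f, "tabular")
  expect_identical(genotypes(p)["SNP-1.100", ], c(L1 = -1L, L2 = 0L))
  expect_identical(genotypes(p)["SNP-1.200", ], c(L1 = 1L, L2 = NA_integer_))
})

test_that("VCF genotypes map to additive codes and non-biallelic records are skipped", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "L1", "L2", "L3", sep = "\t"),
               "1\t100\ts1\tA\tG\t.\t.\t.\tGT\t0/0\t0/0\t0/0",
               "1\t200\ts2\tA\tG,T\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
               "1\t300\ts3\tA\tG\t.\t.\t.\tGT\t0/1\t1/1\t./."), f)
  expect_warning(p <- readGenotypes(f, "vcf"), "skipped")
  expect_equal(nMarkers(p), 2)
  expect_identical(unname(genotypes(p)[1, ]), c(-1L, -1L, -1L))
  expect_identical(unname(genotypes(p)[2, ]), c(0L, 1L, NA))
})

test_that("write/read round trips are identity for both formats", {
  cfg <- simPanelConfig(nSubpops = 2, linesPerSubpop = 5, nMarkers = 50,
                        admixedFraction = 0,
                        chromLengths = c(`1` = 1e6, `2` = 1e6))
  p <- simulateGenotypes(cfg, seed = 11)$panel
  for (fmt in c("vcf", "tabular")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeGenotypes(p, f, fmt)
    p2 <- readGenotypes(f)
    expect_identical(genotypes(p2), genotypes(p), label = fmt)
    expect_identical(markerInfo(p2), markerInfo(p), label = fmt)
    expect_identical(lineIds(p2), lineIds(p), label = fmt)
  }
})

test_that("malformed tabular input fails with a line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("line_id\tbadid\tSNP-1.200", "L1\tA\tB"), f)
  expect_error(readGenotypes(f, "tabular"), "line 1.*badid")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("line_id\tSNP-1.100", "L1\tA\tB"), f2)
  expect_error(readGenotypes(f2, "tabular"), "expected 2 fields")
})

test_that("marker statistics count alleles with het contributing one of each", {
  p <- toyPanel(matrix(c(-1L, -1L, 1L), 1, 3))
  st <- markerStats(p)
  expect_equal(st$maf, 1 / 3)
  expect_equal(st$mac, 2L)
  p2 <- toyPanel(matrix(c(-1L, 0L, 1L), 1, 3))
  expect_equal(markerStats(p2)$maf, 0.5)
})

test_that("marker statistics match a brute-force allele tally on random data", {
  set.seed(42)
  g <- matrix(sample(c(-1L, 0L, 1L, NA), 100 * 10, TRUE,
                     prob = c(0.4, 0.1, 0.4, 0.1)), 100, 10)
  p <- toyPanel(g)
  st <- markerStats(p)
  for (i in seq_len(nrow(g))) {
    v <- g[i, ]
    nA <- sum(v == -1L, na.rm = TRUE) * 2 + sum(v == 0L, na.rm = TRUE)
    nB <- sum(v == 1L, na.rm = TRUE) * 2 + sum(v == 0L, na.rm = TRUE)
    if (nA + nB == 0) {
      expect_false(st$defined[i])
    } else {
      expect_equal(st$maf[i], min(nA, nB) / (nA + nB))
      expect_equal(st$mac[i], min(nA, nB))
      # folded-MAF identity
      expect_equal(st$maf[i], 0.5 - abs(0.5 - st$alt_freq[i]))
    }
    expect_equal(st$missing_rate[i], mean(is.na(v)))
  }
})

test_that("marker filter applies strict MAF, inclusive MAC and missingness bounds", {
  # maf exactly 0.05: one het among 10 lines = 1 alt allele in 20
  g <- matrix(-1L, 1, 10)
  g[1, 1] <- 0L
  p <- toyPanel(g)
  expect_equal(markerStats(p)$maf, 0.05)
  expect_equal(nMarkers(filterMarkers(p, mafGt = 0.05, macGe = 0)), 0)
  expect_equal(nMarkers(filterMarkers(p, mafGt = 0.049, macGe = 0)), 1)

  # 5-marker toy where exactly markers 2 and 4 pass the default thresholds
  n <- 20
  g5 <- rbind(rep(-1L, n),                                  # monomorphic
              c(rep(1L, 8), rep(-1L, n - 8)),               # passes
              c(1L, rep(-1L, n - 1)),                       # mac 2 < 3
              c(rep(1L, 6), rep(-1L, n - 6)),               # passes
              c(rep(1L, 8), rep(-1L, 5), rep(NA, 7)))       # 35% missing
  p5 <- toyPanel(g5)
  kept <- markerIds(filterMarkers(p5))
  expect_identical(kept, makeMarkerIds("1", c(2000L, 4000L)))
})

test_that("marker filter is idempotent and becomes the identity at open thresholds", {
  fx <- testPanel()
  f1 <- filterMarkers(fx$panel)
  f2 <- filterMarkers(f1)
  expect_identical(genotypes(f1), genotypes(f2))
  # all-polymorphic toy: open thresholds keep everything
  set.seed(7)
  g <- matrix(sample(c(-1L, 1L), 60, TRUE), 6, 10)
  g[1, 1:5] <- -1L; g[1, 6:10] <- 1L
  p <- toyPanel(g)
  poly <- markerStats(p)$maf > 0
  expect_equal(nMarkers(filterMarkers(p[poly, ], mafGt = 0, macGe = 0,
                                      maxMissing = 1)),
               sum(poly))
})

test_that("ancestry classification follows the 70% cutoff rule", {
  expect_equal(assignGroup(c(indica = 0.95, aus = 0.05)), "indica")
  expect_equal(assignGroup(c(aus = 0.40, indica = 0.45,
                             temperate_japonica = 0.15)),
               "admixed-INDICA")
  expect_equal(assignGroup(c(indica = 0.5, temperate_japonica = 0.5)),
               "admixed-INDICA-JAPONICA")
  expect_equal(assignGroup(c(tropical_japonica = 0.5, aromatic = 0.3,
                             indica = 0.2)),
               "admixed-JAPONICA")
  expect_error(assignGroup(c(indica = 0.5, aus = 0.2)), "sum to 1")
  # matrix input vectorises
  anc <- rbind(c(0.8, 0.1, 0.1), c(0.3, 0.4, 0.3))
  colnames(anc) <- c("indica", "aus", "aromatic")
  expect_equal(assignGroup(anc), c("indica", "admixed-INDICA"))
})

test_that("phenotype tables validate uniqueness and finiteness", {
  ph <- data.frame(line_id = c("A", "A", "B"), environment = "E1",
                   replicate = c(1, 2, 1), value = c(5, 6, 7))
  expect_silent(validatePhenotypes(ph))
  expect_equal(unname(lineMeans(ph)), c(5.5, 7))
  ph2 <- ph; ph2$replicate <- c(1, 1, 1)
  expect_error(validatePhenotypes(ph2), "duplicate")
  ph3 <- ph; ph3$value[1] <- Inf
  expect_error(validatePhenotypes(ph3), "finite")
})

test_that("line metadata round trips through CSV", {
  li <- data.frame(id = c("L1", "L2"))
  anc <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  colnames(anc) <- c("indica", "aus")
  li$ancestry <- I(anc)
  li$assigned_group <- c("indica", "aus")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLineInfo(li, f)
  li2 <- readLineInfo(f)
  expect_equal(li2$id, li$id)
  expect_equal(as.matrix(li2$ancestry), anc, ignore_attr = TRUE)
  expect_equal(li2$assigned_group, li$assigned_group)
})
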