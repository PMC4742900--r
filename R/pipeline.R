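#' Run the full panel analysis pipeline from a config
#'
#' Orchestrates: simulate (or load) genotypes and phenotypes -> marker
#' filters -> PCA -> association scans (with optional SNP covariates and
#' epistasis covariates, 3 PCs for whole-panel scans and 0 within
#' subpopulations unless overridden) -> peak calling -> optional haplotype
#' analysis and heritability. Writes per-scan TSVs, a peak JSON, and a
#' machine-readable manifest (package version, seed, MD5 digests of every
#' output) so a rerun with the same config and seed is byte-identical.
#'
#' @param config a list or path to a YAML file. Recognised top-level keys:
#'   `simulate` (arguments to [simPanelConfig()] plus an `architecture`
#'   block), or `genotypes`/`phenotypes` file paths; `scans`: list of
#'   blocks with `name`, `group` (default ALL), `n_pcs` (default 3 for
#'   ALL, 0 otherwise), `covariates`, `epistasis_covariate`; `peaks`:
#'   `p_ms`, `p_support`, `window_bp`, `min_support`; `haplotype`:
#'   `region` ("chrom:start-end"), `group_a`, `group_b`; `h2`: logical.
#' @param outDir output directory (created if needed)
#' @param seed integer master seed; every stochastic stage derives its
#'   substream from it
#' @return invisible list with the in-memory results and the manifest
#' @export
runPipeline <- function(config, outDir, seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  # ---- inputs -------------------------------------------------------
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    arch <- sc$architecture
    sc$architecture <- NULL
    cfgArgs <- sc[intersect(names(sc), names(formals(simPanelConfig)))]
    cfg <- do.call(simPanelConfig, cfgArgs)
    sim <- simulateGenotypes(cfg, seed = seed)
    panel <- sim$panel
    truth <- sim$truth
    if (is.null(arch)) {
      pheno <- NULL
    } else {
      aq <- if (!is.null(arch$additive_qtls))
        do.call(rbind, lapply(arch$additive_qtls, as.data.frame)) else NULL
      ta <- traitArchitecture(
        additiveQtls = aq,
        sigma2Bg = arch$sigma2_bg %||% 0,
        sigma2Gxe = arch$sigma2_gxe %||% 0,
        sigma2Err = arch$sigma2_err %||% 0,
        sigma2Env = arch$sigma2_env %||% 0,
        environments = arch$environments %||% 2,
        replicates = arch$replicates %||% 3,
        traitMean = arch$trait_mean %||% 5.7)
      pheno <- simulatePhenotypes(panel, ta, seed = seed + 1L)
    }
  } else {
    if (is.null(config$genotypes)) stop("config needs 'simulate' or 'genotypes'")
    panel <- readGenotypes(config$genotypes)
    truth <- NULL
    pheno <- if (!is.null(config$phenotypes)) readPhenotypes(config$phenotypes)
             else NULL
  }
  # validate scan covariates before any compute
  for (scn in config$scans)
    for (cv in c(scn$covariates, scn$epistasis_covariate))
      if (!is.null(cv) && !cv %in% markerIds(panel))
        stop("config names unknown covariate marker: ", cv)
  results <- list(panel = panel, truth = truth, phenotypes = pheno)
  # ---- popgen summaries --------------------------------------------
  pca <- tryCatch(computePCA(panel), error = function(e) NULL)
  if (!is.null(pca)) {
    emit(data.frame(line_id = rownames(pca$scores),
                    pca$scores[, seq_len(min(10, ncol(pca$scores)))]),
         "pca_scores.tsv")
    results$pca <- pca
  }
  # ---- scans --------------------------------------------------------
  scanSeed <- seed + 100L
  ph <- if (!is.null(pheno)) lineMeans(pheno) else NULL
  results$scans <- list()
  results$peaks <- list()
  pk <- config$peaks %||% list()
  for (scn in config$scans) {
    if (is.null(ph)) break
    name <- scn$name %||% paste0("scan", length(results$scans) + 1)
    group <- scn$group %||% "ALL"
    lines <- groupLines(panel, group)
    npcs <- scn$n_pcs %||% (if (group == "ALL") 3 else 0)
    scanSeed <- scanSeed + 1L
    if (!is.null(scn$epistasis_covariate)) {
      res <- interactionScan(panel, ph, scn$epistasis_covariate,
                             lines = lines, nPcs = npcs, seed = scanSeed)
    } else {
      res <- runScan(panel, ph, lines = lines, nPcs = npcs,
                     snpCovariates = as.character(scn$covariates %||% character()),
                     seed = scanSeed)
    }
    emit(as.data.frame(res)[, setdiff(colnames(res), "support_snps")],
         paste0(name, "_assoc.tsv"))
    qq <- data.frame(observed = sort(-log10(res$p[!is.na(res$p)])),
                     expected = sort(-log10(stats::ppoints(sum(!is.na(res$p))))))
    emit(qq, paste0(name, "_qq.tsv"))
    peaks <- callPeaks(res, pMs = pk$p_ms %||% 1e-5,
                       pSupport = pk$p_support %||% 1e-4,
                       windowBp = pk$window_bp %||% 1e5,
                       minSupport = pk$min_support %||% 2)
    results$scans[[name]] <- res
    results$peaks[[name]] <- peaks
  }
  if (length(results$peaks)) {
    pj <- lapply(results$peaks, function(p) {
      d <- as.data.frame(p)
      d$support_snps <- vapply(p$support_snps, paste, "", collapse = ",")
      d
    })
    path <- file.path(outDir, "peaks.json")
    jsonlite::write_json(pj, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    outputs <- c(outputs, path)
  }
  # ---- haplotypes ---------------------------------------------------
  if (!is.null(config$haplotype)) {
    hp <- config$haplotype
    reg <- strsplit(hp$region, "[:-]")[[1]]
    mk <- filterRegionSnps(panel, reg[1], as.integer(reg[2]), as.integer(reg[3]),
                           groupLines(panel, hp$group_a),
                           groupLines(panel, hp$group_b),
                           mafGt = hp$maf_gt %||% 0.05,
                           maxMissing = hp$max_missing %||% 0.03,
                           pCutoff = hp$p_cutoff %||% 1e-6)
    if (length(mk)) {
      eh <- buildExtendedHaplotypes(panel, markers = mk,
                                    maxMismatch = hp$max_mismatch %||% 2)
      results$haplotypes <- eh
      if (!is.null(ph))
        emit(haplotypePhenotypeSummary(eh, ph), "haplotype_phenotypes.tsv")
    }
  }
  # ---- heritability -------------------------------------------------
  if (isTRUE(config$h2) && !is.null(pheno) &&
      length(unique(pheno$environment)) >= 2) {
    h2 <- estimateComponents(pheno)
    results$h2 <- h2
    path <- file.path(outDir, "h2.json")
    jsonlite::write_json(list(sigma2_g = h2$sigma2_g,
                              sigma2_gxe = h2$sigma2_gxe,
                              sigma2 = h2$sigma2, r = h2$r, e = h2$e,
                              H2 = h2$H2),
                         path, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, path)
  }
  # ---- manifest -----------------------------------------------------
  manifest <- list(
    package = "panelGWAS",
    version = as.character(utils::packageVersion("panelGWAS")),
    seed = seed,
    outputs = lapply(outputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
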