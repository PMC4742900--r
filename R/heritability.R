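#' Variance components of a replicated multi-environment trial
#'
#' Two-way ANOVA (genotype, environment, their interaction, residual) with
#' method-of-moments estimators from the expected mean squares of a
#' balanced design: sigma2 = MS_error; sigma2_gxe = (MS_GxE - MS_error)/r;
#' sigma2_g = (MS_G - MS_GxE)/(r e). Negative estimates are clamped to
#' zero and flagged. With a single environment the G-by-E component is
#' inseparable from the genotypic term and the single-environment variant
#' sigma2_g = (MS_G - MS_error)/r is returned with a warning.
#'
#' @param pheno phenotype data.frame (`line_id`, `environment`,
#'   `replicate`, `value`); the design must be balanced (same replicate
#'   count in every genotype-by-environment cell)
#' @return list of class `h2Components`: `sigma2_g`, `sigma2_gxe`,
#'   `sigma2`, `r`, `e`, `H2`, `clamped` (which components were clamped),
#'   `anova` (the aov table)
#' @export
estimateComponents <- function(pheno) {
  pheno <- validatePhenotypes(pheno)
  G <- factor(pheno$line_id)
  E <- factor(pheno$environment)
  ng <- nlevels(G); ne <- nlevels(E)
  if (ng < 2) stop("need at least 2 genotypes")
  cell <- table(G, E)
  if (length(unique(as.vector(cell))) != 1)
    stop("unbalanced design: equalise replicates per genotype x environment ",
         "cell (e.g. by cell-mean imputation) before estimating components")
  r <- unique(as.vector(cell))
  if (r < 2) stop("need at least 2 replicates")
  if (ne < 2) {
    warning("single environment: G-by-E variance inseparable; ",
            "returning single-environment estimates")
    fit <- aov(value ~ G, data = data.frame(value = pheno$value, G = G))
    ms <- anova(fit)[["Mean Sq"]]
    s2 <- ms[2]
    s2g <- (ms[1] - ms[2]) / r
    clamped <- character()
    if (s2g < 0) { s2g <- 0; clamped <- "sigma2_g" }
    h2 <- if (s2g + s2 > 0) s2g / (s2g + s2 / r) else NA_real_
    return(structure(list(sigma2_g = s2g, sigma2_gxe = NA_real_, sigma2 = s2,
                          r = r, e = 1L, H2 = h2, clamped = clamped,
                          anova = anova(fit)),
                     class = "h2Components"))
  }
  fit <- aov(value ~ G + E + G:E,
             data = data.frame(value = pheno$value, G = G, E = E))
  tab <- suppressWarnings(anova(fit))  # F tests unused; mean squares only
  ms <- setNames(tab[["Mean Sq"]], rownames(tab))
  s2 <- ms[["Residuals"]]
  s2gxe <- (ms[["G:E"]] - s2) / r
  s2g <- (ms[["G"]] - ms[["G:E"]]) / (r * ne)
  clamped <- character()
  if (s2gxe < 0) { s2gxe <- 0; clamped <- c(clamped, "sigma2_gxe") }
  if (s2g < 0) { s2g <- 0; clamped <- c(clamped, "sigma2_g") }
  h2 <- broadSenseH2(s2g, s2gxe, s2, r, ne)
  structure(list(sigma2_g = s2g, sigma2_gxe = s2gxe, sigma2 = s2,
                 r = r, e = ne, H2 = h2, clamped = clamped, anova = tab),
            class = "h2Components")
}

#' @export
print.h2Components <- function(x, ...) {
  cat(sprintf("variance components (r = %d replicates, e = %d environments)\n",
              x$r, x$e))
  cat(sprintf("  sigma2_g = %.5g  sigma2_gxe = %s  sigma2 = %.5g\n",
              x$sigma2_g,
              if (is.na(x$sigma2_gxe)) "NA" else sprintf("%.5g", x$sigma2_gxe),
              x$sigma2))
  cat(sprintf("  broad-sense H2 = %.4f\n", x$H2))
  if (length(x$clamped))
    cat("  (clamped to 0:", paste(x$clamped, collapse = ", "), ")\n")
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' H2 = sigma2_g / (sigma2_g + sigma2_gxe / e + sigma2 / (r e)): the
#' fraction of the variance of genotype means (over e environments and r
#' replicates) attributable to genotypic variance.
#'
#' @param sigma2_g genotypic variance
#' @param sigma2_gxe genotype-by-environment interaction variance
#' @param sigma2 experimental error variance
#' @param r replicates per environment
#' @param e environments
#' @return H2 in [0, 1]
#' @examples
#' broadSenseH2(1, 0.2, 0.4, r = 3, e = 2)   # 0.857
#' @export
broadSenseH2 <- function(sigma2_g, sigma2_gxe, sigma2, r, e) {
  stopifnot(r >= 1, e >= 1, sigma2_g >= 0, sigma2_gxe >= 0, sigma2 >= 0)
  den <- sigma2_g + sigma2_gxe / e + sigma2 / (r * e)
  if (den == 0) stop("all variance components are zero: H2 undefined")
  sigma2_g / den
}
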