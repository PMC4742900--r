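#' Kinship matrix of a panel
#'
#' Default is pairwise identity-by-state: K_ij is the mean over
#' pairwise-complete markers of (2 - |x_i - x_j|)/2 with x in \{-1, 0, +1\},
#' i.e. 1 for matching homozygotes, 1/2 for homozygote-vs-heterozygote, 0
#' for opposite homozygotes. The `"centered"` alternative mean-imputes
#' missing calls, centres each marker and returns the cross-product scaled
#' by the marker count (a realized-relationship style estimator).
#'
#' @param panel a [GenotypePanel-class]
#' @param method `"ibs"` (default) or `"centered"`
#' @param lines optional subset of line ids
#' @return symmetric n x n matrix with line ids as dimnames and attribute
#'   `method`
#' @export
computeKinship <- function(panel, method = c("ibs", "centered"), lines = NULL) {
  method <- match.arg(method)
  g <- genotypes(panel)
  if (!is.null(lines)) g <- g[, lines, drop = FALSE]
  n <- ncol(g)
  if (n < 2) stop("kinship requires at least 2 lines")
  if (method == "ibs") {
    # mean over complete pairs of 1 - |x_i - x_j|/2, using
    # sum |x_i - x_j| = sum (x_i - x_j)^2 - 2 * #(opposite homozygotes)
    A <- (!is.na(g) & g == -1L) * 1
    B <- (!is.na(g) & g == 1L) * 1
    C <- (!is.na(g)) * 1
    X0 <- g * 1.0
    X0[is.na(X0)] <- 0
    sq <- A + B                           # x^2 with NA -> 0
    sqC <- crossprod(sq, C)
    D2 <- sqC + t(sqC) - 2 * crossprod(X0)
    nOpp <- crossprod(A, B)
    nOpp <- nOpp + t(nOpp)
    den <- crossprod(C)
    if (any(den == 0)) {
      ij <- which(den == 0, arr.ind = TRUE)[1, ]
      stop("no shared non-missing markers for line pair ",
           colnames(g)[ij[1]], " / ", colnames(g)[ij[2]])
    }
    K <- (den - 0.5 * (D2 - 2 * nOpp)) / den
  } else {
    x <- g * 1.0
    mu <- rowMeans(x, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    na <- which(is.na(x))
    if (length(na)) x[na] <- mu[row(x)[na]]
    x <- x - mu
    K <- crossprod(x) / nrow(x)
  }
  K <- (K + t(K)) / 2
  dimnames(K) <- list(colnames(g), colnames(g))
  attr(K, "method") <- method
  K
}
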