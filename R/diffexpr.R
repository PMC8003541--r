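#' Bundle a count matrix and condition labels into a SummarizedExperiment
#'
#' @param counts Nonnegative integer matrix, genes in rows (unique
#'   rownames), samples in columns.
#' @param condition Per-sample labels; coerced to a factor with exactly two
#'   levels for testing. The first factor level is the reference of the
#'   contrast (fold changes are level2 over level1).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{"counts"} and \code{colData$condition}.
#' @export
makeCountExperiment <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and nonnegative")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique rownames (gene identifiers)")
  if (length(condition) != ncol(counts))
    stop("one condition label per sample required")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = factor(condition)))
}

.countsAndCondition <- function(counts, condition = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    cond <- SummarizedExperiment::colData(counts)$condition
    counts <- SummarizedExperiment::assay(counts, "counts")
    list(counts = as.matrix(counts), condition = factor(cond))
  } else {
    list(counts = as.matrix(counts),
         condition = if (is.null(condition)) NULL else factor(condition))
  }
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors in the median-of-ratios convention: the
#' per-gene reference is the geometric mean across samples (genes with any
#' zero excluded); a sample's factor is the median over genes of its count
#' divided by the reference. Factors are rescaled to geometric mean 1. When
#' no gene is nonzero in every sample, the function falls back to
#' upper-quartile normalization with a warning.
#'
#' @param counts Count matrix (genes x samples) or a SummarizedExperiment
#'   with a \code{"counts"} assay.
#' @return Named numeric vector of positive per-sample size factors.
#' @export
computeSizeFactors <- function(counts) {
  counts <- .countsAndCondition(counts)$counts
  if (ncol(counts) < 2L) stop("need at least two samples")
  allPos <- rowSums(counts == 0) == 0
  if (any(allPos)) {
    lref <- rowMeans(log(counts[allPos, , drop = FALSE]))
    sf <- apply(counts[allPos, , drop = FALSE], 2L,
                function(cc) median(exp(log(cc) - lref)))
  } else {
    warning("no gene with nonzero counts in all samples; ",
            "falling back to upper-quartile normalization")
    sf <- apply(counts, 2L, function(cc) quantile(cc[cc > 0], 0.75))
    if (any(!is.finite(sf) | sf <= 0))
      stop("upper-quartile fallback failed: a sample has no nonzero counts")
  }
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Method-of-moments dispersion with trend shrinkage
#'
#' Per-gene negative-binomial dispersion (Var = mu + phi * mu^2) estimated
#' by moments on normalized counts within each condition:
#' \code{phi = max(0, (s^2 - m) / m^2)} averaged across the two conditions,
#' then shrunk 50/50 toward the running median dispersion of the 50 genes
#' nearest in base mean (a simple mean-dispersion trend). Genes with all
#' zero counts get \code{NA} and are excluded from testing.
#'
#' @inheritParams nbWaldTest
#' @return Named numeric vector of per-gene dispersions (NA when
#'   undefined).
#' @export
estimateDispersionsMoM <- function(counts, condition = NULL,
                                   sizeFactors = NULL) {
  cc <- .countsAndCondition(counts, condition)
  counts <- cc$counts; condition <- cc$condition
  if (is.null(condition)) stop("condition labels required")
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  norm <- sweep(counts, 2L, sizeFactors, "/")
  lev <- levels(condition)
  phiByCond <- vapply(lev, function(l) {
    sub <- norm[, condition == l, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1L, var)
    ifelse(m > 0, pmax(0, (v - m) / m^2), NA_real_)
  }, numeric(nrow(counts)))
  phi <- rowMeans(phiByCond, na.rm = TRUE)
  phi[rowSums(counts) == 0] <- NA_real_
  baseMean <- rowMeans(norm)
  ok <- !is.na(phi)
  if (sum(ok) >= 3L) {
    o <- order(baseMean[ok])
    k <- min(51L, sum(ok) - (1L - sum(ok) %% 2L))  # odd, <= n
    if (k >= 3L) {
      tr <- runmed(phi[ok][o], k, endrule = "median")
      trend <- numeric(sum(ok)); trend[o] <- tr
      phi[ok] <- 0.5 * phi[ok] + 0.5 * trend
    }
  }
  names(phi) <- rownames(counts)
  phi
}

#' Negative-binomial Wald test for a two-level contrast
#'
#' Per gene, the log2 fold change is
#' \code{log2((mean2 + c) / (mean1 + c))} on normalized counts with
#' pseudocount \code{c} (default 0.5); its standard error comes from the
#' delta method under NB variance \code{mu + phi * mu^2} summed over
#' samples; the two-sided p-value is normal on \code{log2fc / se}, and FDR
#' is Benjamini-Hochberg within the tested genes. Genes with base mean
#' below \code{minBaseMean} are excluded from testing (NA statistics,
#' reported but never candidates).
#'
#' @param counts Count matrix (genes x samples) or SummarizedExperiment
#'   with assay \code{"counts"} and \code{colData$condition}.
#' @param condition Per-sample two-level factor (ignored when `counts` is a
#'   SummarizedExperiment). Fold changes are level 2 over level 1.
#' @param sizeFactors Optional per-sample size factors; computed by
#'   [computeSizeFactors()] when `NULL`.
#' @param dispersions Optional per-gene dispersions; estimated by
#'   [estimateDispersionsMoM()] when `NULL`.
#' @param pseudocount Added to group means before the log ratio (default
#'   0.5).
#' @param minBaseMean Minimum mean normalized count for a gene to be tested
#'   (default 5).
#' @return A data.frame with one row per input gene: \code{gene_id},
#'   \code{base_mean}, \code{log2fc}, \code{se}, \code{stat},
#'   \code{pvalue}, \code{fdr}.
#' @export
nbWaldTest <- function(counts, condition = NULL, sizeFactors = NULL,
                       dispersions = NULL, pseudocount = 0.5,
                       minBaseMean = 5) {
  cc <- .countsAndCondition(counts, condition)
  counts <- cc$counts; condition <- cc$condition
  if (is.null(condition)) stop("condition labels required")
  condition <- droplevels(condition)
  lev <- levels(condition)
  if (length(lev) != 2L)
    stop("exactly two condition levels required, got: ",
         paste(lev, collapse = ", "))
  for (l in lev) {
    if (sum(condition == l) < 2L)
      stop(sprintf("condition level '%s' has fewer than 2 samples", l))
  }
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  if (is.null(dispersions))
    dispersions <- estimateDispersionsMoM(counts, condition, sizeFactors)
  norm <- sweep(counts, 2L, sizeFactors, "/")
  i1 <- condition == lev[1L]; i2 <- condition == lev[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  baseMean <- rowMeans(norm)
  lfc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  phi <- ifelse(is.na(dispersions), 0, dispersions)
  # Var(mean of normalized counts) with mu_s = sf_s * q: per group
  v1 <- (m1 * sum(1 / sizeFactors[i1]) + n1 * phi * m1^2) / n1^2
  v2 <- (m2 * sum(1 / sizeFactors[i2]) + n2 * phi * m2^2) / n2^2
  se <- sqrt(v1 / (m1 + pseudocount)^2 + v2 / (m2 + pseudocount)^2) / log(2)
  tested <- baseMean >= minBaseMean & !is.na(dispersions) & se > 0
  stat <- ifelse(tested, lfc / se, NA_real_)
  p <- ifelse(tested, 2 * pnorm(-abs(stat)), NA_real_)
  fdr <- bhAdjust(p)
  data.frame(gene_id = rownames(counts), base_mean = baseMean,
             log2fc = lfc, se = se, stat = stat, pvalue = p, fdr = fdr,
             row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \code{q_(i) = min over j >= i of (m / j) * p_(j)}, capped at 1 and mapped
#' back to input order; \code{m} is the number of non-missing p-values and
#' \code{NA}s propagate.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Numeric vector of BH-adjusted values (FDR), same length/order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0L) return(out)
  ps <- p[ok]
  o <- order(ps)
  q <- pmin(1, rev(cummin(rev(ps[o] * m / seq_len(m)))))
  tmp <- rep(NA_real_, m); tmp[o] <- q
  out[ok] <- tmp
  out
}
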