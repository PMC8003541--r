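#' Correlation between a gene and pri-miR-29b2~c on log2 normalized values
#'
#' Pearson (default) or Spearman correlation computed on
#' \code{log2(x + 1)}-transformed normalized expression values, the scale
#' on which miRNA-mRNA anti-correlation is screened.
#'
#' @param expr Per-sample normalized expression of one gene (nonnegative).
#' @param mir Per-sample normalized pri-miR-29b2~c expression, same
#'   length.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param log2p1 Apply the \code{log2(. + 1)} transform first (default
#'   TRUE); set FALSE when the inputs are already on a log-like scale.
#' @return Correlation coefficient; \code{NA} when either transformed
#'   vector is constant.
#' @export
corLog2 <- function(expr, mir, method = c("pearson", "spearman"),
                    log2p1 = TRUE) {
  method <- match.arg(method)
  if (length(expr) != length(mir)) stop("length mismatch")
  if (length(expr) < 3L) stop("need at least 3 samples")
  if (log2p1) {
    x <- log2(expr + 1); y <- log2(mir + 1)
  } else {
    x <- expr; y <- mir
  }
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = method)
}

#' Selection thresholds for the four-criterion cascade
#'
#' Defaults encode the published selection: mimic downregulation with
#' log2FC < -0.5 and FDR < 0.05 (both strict), cohort upregulation with
#' log2FC >= 0.3 and FDR <= 0.05 (non-strict), conserved sites predicted by
#' at least 8 algorithms, and anti-correlation r <= -0.3 (non-strict).
#'
#' @param mimicLfcMax Strict upper bound on the mimic-contrast log2 fold
#'   change (negative; default -0.5).
#' @param mimicFdrMax Strict upper bound on the mimic-contrast FDR
#'   (default 0.05).
#' @param cohortLfcMin Non-strict lower bound on the cohort log2 fold
#'   change (positive; default 0.3).
#' @param cohortFdrMax Non-strict upper bound on the cohort FDR
#'   (default 0.05).
#' @param minAlgorithms Non-strict minimum number of supporting prediction
#'   algorithms (default 8).
#' @param corrMax Non-strict upper bound on the anti-correlation
#'   coefficient (negative; default -0.3).
#' @return A named list of validated thresholds.
#' @export
cascadeThresholds <- function(mimicLfcMax = -0.5, mimicFdrMax = 0.05,
                              cohortLfcMin = 0.3, cohortFdrMax = 0.05,
                              minAlgorithms = 8L, corrMax = -0.3) {
  stopifnot(mimicLfcMax < 0, cohortLfcMin > 0, corrMax < 0,
            minAlgorithms >= 1, mimicFdrMax > 0, cohortFdrMax > 0)
  list(mimicLfcMax = mimicLfcMax, mimicFdrMax = mimicFdrMax,
       cohortLfcMin = cohortLfcMin, cohortFdrMax = cohortFdrMax,
       minAlgorithms = as.integer(minAlgorithms), corrMax = corrMax)
}

#' Candidate set produced by the selection cascade
#'
#' Holds the ranked candidate table, the complete per-gene stage ledger
#' (every input gene with its four stage booleans), and the thresholds
#' applied.
#'
#' @slot candidates data.frame of genes passing all four stages, ranked.
#' @slot ledger data.frame with one row per input gene and the four stage
#'   booleans.
#' @slot thresholds Named list from [cascadeThresholds()].
#' @seealso [runCascade()], [candidates()], [stageLedger()]
#' @export
setClass("CascadeResult", slots = c(candidates = "data.frame",
                                    ledger = "data.frame",
                                    thresholds = "list"))

setValidity("CascadeResult", function(object) {
  need <- c("gene_id", "pass_mimic", "pass_cohort", "pass_sites",
            "pass_anticorr", "candidate")
  if (!all(need %in% names(object@ledger)))
    return("ledger must carry gene_id, the four stage booleans and 'candidate'")
  if (anyDuplicated(object@ledger$gene_id))
    return("ledger must have one row per gene")
  TRUE
})

#' @describeIn CascadeResult Compact display.
#' @param object A `CascadeResult`.
#' @export
setMethod("show", "CascadeResult", function(object) {
  th <- object@thresholds
  cat("CascadeResult:", nrow(object@candidates), "candidate(s) from",
      nrow(object@ledger), "genes\n")
  cat(sprintf("  stage 1 (mimic down):  log2FC < %g & FDR < %g  [%d genes]\n",
      th$mimicLfcMax, th$mimicFdrMax, sum(object@ledger$pass_mimic)))
  cat(sprintf("  stage 2 (cohort up):   log2FC >= %g & FDR <= %g [%d genes]\n",
      th$cohortLfcMin, th$cohortFdrMax, sum(object@ledger$pass_cohort)))
  cat(sprintf("  stage 3 (sites):       >= %d algorithms & conserved [%d genes]\n",
      th$minAlgorithms, sum(object@ledger$pass_sites)))
  cat(sprintf("  stage 4 (anticorr):    r <= %g            [%d genes]\n",
      th$corrMax, sum(object@ledger$pass_anticorr)))
  if (nrow(object@candidates))
    cat("  candidates:", paste(head(object@candidates$gene_id, 20),
                               collapse = ", "), "\n")
})

#' Extract the ranked candidate table
#' @param x A [CascadeResult-class] object.
#' @return data.frame of candidate genes with all per-stage evidence.
#' @export
candidates <- function(x) {
  stopifnot(is(x, "CascadeResult"))
  x@candidates
}

#' Extract the complete per-gene stage ledger
#' @param x A [CascadeResult-class] object.
#' @return data.frame with one row per input gene, per-stage evidence and
#'   the four stage booleans.
#' @export
stageLedger <- function(x) {
  stopifnot(is(x, "CascadeResult"))
  x@ledger
}

.dedupCheck <- function(ids, what) {
  if (anyDuplicated(ids))
    stop("duplicate gene_ids in ", what)
}

#' Run the four-criterion target-selection cascade
#'
#' Intersects the four evidence streams into a ranked candidate table. A
#' gene is a candidate iff it passes all four stage predicates:
#' \enumerate{
#'   \item \code{mimic log2FC < mimicLfcMax} and
#'     \code{mimic FDR < mimicFdrMax} (strict),
#'   \item \code{cohort log2FC >= cohortLfcMin} and
#'     \code{cohort FDR <= cohortFdrMax},
#'   \item \code{n_algorithms >= minAlgorithms} and \code{conserved},
#'   \item \code{r <= corrMax}.
#' }
#' Genes missing from a stream (or with NA evidence) fail that stage but
#' stay in the ledger. Candidates are sorted by \code{r} ascending, ties by
#' mimic log2FC ascending, then gene_id, so output is byte-stable.
#'
#' @param mimicDE data.frame from [nbWaldTest()] for the mimic-vs-control
#'   contrast (columns \code{gene_id}, \code{log2fc}, \code{fdr}).
#' @param cohortDE Same, for the melanoma-vs-nevus contrast.
#' @param summaries data.frame from [summarizeGeneSites()].
#' @param correlations Named numeric vector of per-gene correlation with
#'   pri-miR-29b2~c, or a data.frame with columns \code{gene_id}, \code{r}.
#' @param thresholds From [cascadeThresholds()].
#' @return A [CascadeResult-class] object.
#' @export
runCascade <- function(mimicDE, cohortDE, summaries, correlations,
                       thresholds = cascadeThresholds()) {
  .dedupCheck(mimicDE$gene_id, "mimic DE table")
  .dedupCheck(cohortDE$gene_id, "cohort DE table")
  .dedupCheck(summaries$gene_id, "site summary table")
  if (is.data.frame(correlations)) {
    .dedupCheck(correlations$gene_id, "correlation table")
    correlations <- setNames(correlations$r, correlations$gene_id)
  } else if (!is.null(names(correlations))) {
    .dedupCheck(names(correlations), "correlation vector")
  } else stop("correlations must be a named vector or a gene_id/r data.frame")

  genes <- sort(unique(c(mimicDE$gene_id, cohortDE$gene_id,
                         summaries$gene_id, names(correlations))))
  im <- match(genes, mimicDE$gene_id)
  ic <- match(genes, cohortDE$gene_id)
  is_ <- match(genes, summaries$gene_id)
  led <- data.frame(
    gene_id = genes,
    mimic_lfc = mimicDE$log2fc[im], mimic_fdr = mimicDE$fdr[im],
    cohort_lfc = cohortDE$log2fc[ic], cohort_fdr = cohortDE$fdr[ic],
    n_algorithms = ifelse(is.na(is_), 0L, summaries$n_algorithms[is_]),
    conserved = ifelse(is.na(is_), FALSE, summaries$conserved[is_]),
    best_type = if (length(genes)) as.character(summaries$best_type[is_])
                else character(0),
    r = unname(correlations[genes]),
    stringsAsFactors = FALSE)

  th <- thresholds
  pass <- function(x) !is.na(x) & x
  led$pass_mimic <- pass(led$mimic_lfc < th$mimicLfcMax &
                         led$mimic_fdr < th$mimicFdrMax)
  led$pass_cohort <- pass(led$cohort_lfc >= th$cohortLfcMin &
                          led$cohort_fdr <= th$cohortFdrMax)
  led$pass_sites <- pass(led$n_algorithms >= th$minAlgorithms & led$conserved)
  led$pass_anticorr <- pass(led$r <= th$corrMax)
  led$candidate <- led$pass_mimic & led$pass_cohort & led$pass_sites &
    led$pass_anticorr

  cand <- led[led$candidate, , drop = FALSE]
  if (nrow(cand))
    cand <- cand[order(cand$r, cand$mimic_lfc, cand$gene_id), , drop = FALSE]
  rownames(cand) <- NULL; rownames(led) <- NULL
  new("CascadeResult", candidates = cand, ledger = led, thresholds = th)
}
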