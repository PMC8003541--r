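#' Relative quantification by the 2^-ddCt convention
#'
#' Technical replicates are averaged per sample first; each sample's
#' dCt = Ct(target) - Ct(reference); per condition, ddCt is the mean dCt
#' minus the calibrator's mean dCt and the relative quantity is
#' \code{base^-ddCt} (amplification efficiency fixed at a doubling per
#' cycle by default). The per-condition SEM of dCt is propagated into an
#' RQ interval \code{base^-(ddCt +/- SEM)}. A constant shift of every Ct
#' cancels in the reference subtraction, so RQ is shift-invariant.
#'
#' @param records data.frame with columns \code{sample_id},
#'   \code{gene_id}, \code{condition}, \code{ct} (and optionally
#'   \code{replicate}).
#' @param target Gene identifier quantified.
#' @param reference Endogenous control gene identifier (e.g. GAPDH,
#'   beta-actin for mRNAs; snoU6 for mature miRNAs).
#' @param calibrator Condition used as calibrator (RQ = 1).
#' @param base Amplification base (default 2).
#' @return data.frame with one row per condition: \code{condition},
#'   \code{n} (samples), \code{delta_ct}, \code{sem_delta_ct},
#'   \code{ddct}, \code{rq}, \code{rq_lo}, \code{rq_hi}.
#' @export
ddctQuantify <- function(records, target, reference, calibrator, base = 2) {
  need <- c("sample_id", "gene_id", "condition", "ct")
  if (!all(need %in% names(records)))
    stop("records need columns sample_id, gene_id, condition, ct")
  if (any(!is.finite(records$ct))) stop("non-finite Ct value")
  tg <- records[records$gene_id == target, , drop = FALSE]
  rf <- records[records$gene_id == reference, , drop = FALSE]
  if (!nrow(tg)) stop("no rows for target gene")
  ctT <- aggregate(ct ~ sample_id + condition, tg, mean)
  ctR <- aggregate(ct ~ sample_id + condition, rf, mean)
  m <- merge(ctT, ctR, by = c("sample_id", "condition"),
             suffixes = c("_t", "_r"), all.x = TRUE)
  drop <- is.na(m$ct_r)
  if (any(drop)) {
    warning(sum(drop), " sample(s) without reference measurement dropped")
    m <- m[!drop, , drop = FALSE]
  }
  if (!nrow(m)) stop("no sample with both target and reference Ct")
  m$dct <- m$ct_t - m$ct_r
  agg <- aggregate(dct ~ condition, m, function(v)
    c(n = length(v), mean = mean(v),
      sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0))
  out <- data.frame(condition = agg$condition,
                    n = agg$dct[, "n"],
                    delta_ct = agg$dct[, "mean"],
                    sem_delta_ct = agg$dct[, "sem"])
  if (!calibrator %in% out$condition)
    stop("calibrator condition absent: ", calibrator)
  cal <- out$delta_ct[out$condition == calibrator]
  out$ddct <- out$delta_ct - cal
  out$rq <- base^(-out$ddct)
  out$rq_lo <- base^(-(out$ddct + out$sem_delta_ct))
  out$rq_hi <- base^(-(out$ddct - out$sem_delta_ct))
  rownames(out) <- NULL
  out
}

#' Dual-luciferase normalization and seed-mutant rescue index
#'
#' Per sample, the UTR-bearing reporter signal is divided by the
#' co-expressed control normalizer; per (condition, reporter) cell, the
#' mean ratio is divided by the baseline condition's mean ratio within the
#' same reporter, giving the fold change of reporter activity under
#' treatment. With a wildtype-UTR and a seed-mutant-UTR reporter, the
#' rescue index is (mutant fold change under treatment) - (wildtype fold
#' change under treatment): positive when mutating the miR-29 binding site
#' rescues repression.
#'
#' @param records data.frame with columns \code{condition} (e.g. control /
#'   mimic), \code{experimental} (UTR reporter signal, nonnegative),
#'   \code{control} (normalizer signal, positive), and optionally
#'   \code{reporter} (e.g. wildtype / mutant).
#' @param baseline Condition used as baseline (activity = 1).
#' @param treatment Condition whose fold changes enter the rescue index;
#'   default: the single non-baseline condition.
#' @param wildtype,mutant Reporter labels used for the rescue index
#'   (defaults \code{"wildtype"}, \code{"mutant"}).
#' @return List with \code{activity}: a data.frame of per-(condition,
#'   reporter) mean normalized ratio, fold change vs baseline, SEM and n;
#'   and \code{rescue_index} (NA when the two reporters are not both
#'   present).
#' @export
luciferaseNormalize <- function(records, baseline,
                                treatment = NULL,
                                wildtype = "wildtype", mutant = "mutant") {
  need <- c("condition", "experimental", "control")
  if (!all(need %in% names(records)))
    stop("records need columns condition, experimental, control")
  if (any(records$control <= 0)) stop("control signal must be positive")
  if (any(records$experimental < 0)) stop("negative experimental signal")
  if (!"reporter" %in% names(records)) records$reporter <- "reporter"
  if (!baseline %in% records$condition)
    stop("baseline condition absent: ", baseline)
  records$ratio <- records$experimental / records$control
  agg <- aggregate(ratio ~ condition + reporter, records, function(v)
    c(n = length(v), mean = mean(v),
      sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0))
  act <- data.frame(condition = agg$condition, reporter = agg$reporter,
                    n = agg$ratio[, "n"], mean_ratio = agg$ratio[, "mean"],
                    sem_ratio = agg$ratio[, "sem"])
  base_ <- act[act$condition == baseline, c("reporter", "mean_ratio")]
  act$fold_change <- act$mean_ratio /
    base_$mean_ratio[match(act$reporter, base_$reporter)]
  conds <- setdiff(unique(act$condition), baseline)
  if (is.null(treatment))
    treatment <- if (length(conds) == 1L) conds else NA_character_
  fc <- function(rep_) {
    v <- act$fold_change[act$condition %in% treatment & act$reporter == rep_]
    if (length(v) == 1L) v else NA_real_
  }
  rescue <- fc(mutant) - fc(wildtype)
  list(activity = act, rescue_index = rescue)
}

#' Two-group t test or one-way ANOVA
#'
#' Unpaired two-tailed t test with pooled variance, or ordinary one-way
#' ANOVA, as used for non-survival group comparisons. For two groups the
#' squared pooled t statistic equals the ANOVA F statistic.
#'
#' @param values List of numeric vectors, one per group (each n >= 2;
#'   exactly 2 groups for \code{"ttest"}, >= 2 for \code{"anova"}).
#' @param mode \code{"ttest"} or \code{"anova"}.
#' @return List with \code{statistic} (t or F), \code{df}, \code{p.value},
#'   \code{method}. Zero within-group variance in every group yields NA
#'   with a warning.
#' @export
groupCompare <- function(values, mode = c("ttest", "anova")) {
  mode <- match.arg(mode)
  if (!is.list(values) || length(values) < 2L)
    stop("values must be a list of >= 2 group vectors")
  if (any(vapply(values, length, integer(1L)) < 2L))
    stop("each group needs n >= 2")
  if (all(vapply(values, function(v) var(v) == 0, logical(1L)))) {
    warning("zero within-group variance in all groups; test undefined")
    return(list(statistic = NA_real_, df = NA_real_, p.value = NA_real_,
                method = mode))
  }
  if (mode == "ttest") {
    if (length(values) != 2L) stop("ttest requires exactly 2 groups")
    ht <- t.test(values[[1L]], values[[2L]], var.equal = TRUE)
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value, method = "unpaired two-tailed t (pooled)")
  } else {
    y <- unlist(values)
    g <- factor(rep(seq_along(values), lengths(values)))
    ht <- oneway.test(y ~ g, var.equal = TRUE)
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value, method = "one-way ANOVA")
  }
}
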