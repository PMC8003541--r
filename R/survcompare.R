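#' Kaplan-Meier product-limit estimate
#'
#' Survival curve at each distinct event time; at tied times events precede
#' censorings (the standard convention). Censored-only inputs yield a curve
#' constant at 1.
#'
#' @param time Positive event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @return data.frame with columns \code{time} (distinct event times,
#'   ascending), \code{n_risk}, \code{n_event}, \code{survival}
#'   (\code{S(t) = prod(1 - d_j / n_j)}).
#' @examples
#' kmEstimate(c(1, 2), c(1, 0))  # S(1) = 0.5
#' @export
kmEstimate <- function(time, event) {
  if (!length(time)) stop("empty sample")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive and finite")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  evT <- sort(unique(time[event == 1]))
  if (!length(evT))
    return(data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0)))
  nRisk <- vapply(evT, function(t) sum(time >= t), integer(1L))
  nEvent <- vapply(evT, function(t) sum(time == t & event == 1), integer(1L))
  data.frame(time = evT, n_risk = nRisk, n_event = nEvent,
             survival = cumprod(1 - nEvent / nRisk))
}

# weighted log-rank machinery shared by the asymptotic and permutation paths:
# returns U = sum_j w_j (d1j - e1j), V = sum_j w_j^2 v_j, chi2
.wlrStat <- function(time, event, inGroup1, weight = c("gehan", "logrank")) {
  weight <- match.arg(weight)
  evT <- sort(unique(time[event == 1]))
  if (!length(evT)) return(c(U = NA_real_, V = NA_real_, chi2 = NA_real_))
  U <- 0; V <- 0
  for (t in evT) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & inGroup1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & inGroup1)
    e1 <- d * n1 / n
    v <- if (n > 1L) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
    w <- if (weight == "gehan") n else 1
    U <- U + w * (d1 - e1)
    V <- V + w^2 * v
  }
  chi2 <- if (V > 0) U^2 / V else 0
  c(U = U, V = V, chi2 = chi2)
}

#' Gehan-Breslow-Wilcoxon two-group survival comparison
#'
#' Weighted log-rank test with weight \code{w_j = n_j} (the total number at
#' risk) at each event time, emphasizing early differences; ties use the
#' standard hypergeometric variance. The statistic is
#' \code{chi2 = U^2 / Var(U)} with
#' \code{U = sum_j n_j (d_1j - e_1j)}. The p-value is chi-square with 1 df
#' by default; with \code{pMethod = "auto"} (the default) small studies
#' (total n <= 10) instead get an exact p-value by complete enumeration of
#' group-label assignments, where the asymptotic reference is unreliable.
#' Plain log-rank weights are available via \code{weight = "logrank"}.
#'
#' @param time Positive times.
#' @param event 1 = event, 0 = censored.
#' @param group Two-level grouping factor/vector.
#' @param weight \code{"gehan"} (default, w = n at risk) or
#'   \code{"logrank"} (w = 1).
#' @param pMethod \code{"auto"} (exact for total n <= 10, else asymptotic),
#'   \code{"asymptotic"}, \code{"exact"} (complete enumeration), or
#'   \code{"permutation"} (`nPerm` random label permutations).
#' @param nPerm Number of permutations when \code{pMethod = "permutation"}.
#' @return An object of class \code{"htest"}: \code{statistic} (chi2),
#'   \code{parameter} (df = 1), \code{p.value}, and \code{estimate} holding
#'   per-group sizes. Returns NA statistic with a warning when there are no
#'   events.
#' @export
gbwTest <- function(time, event, group, weight = c("gehan", "logrank"),
                    pMethod = c("auto", "asymptotic", "exact", "permutation"),
                    nPerm = 50000L) {
  weight <- match.arg(weight)
  pMethod <- match.arg(pMethod)
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop("exactly two group levels required")
  if (any(table(group) == 0L)) stop("a group level is empty")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive and finite")
  g1 <- group == levels(group)[1L]
  dname <- paste(deparse(substitute(time)), "by", deparse(substitute(group)))
  obs <- .wlrStat(time, event, g1, weight)
  method <- if (weight == "gehan")
    "Gehan-Breslow-Wilcoxon weighted log-rank test" else "log-rank test"
  if (is.na(obs["chi2"])) {
    warning("no events observed; test undefined")
    p <- NA_real_
  } else {
    n <- length(time); n1 <- sum(g1)
    if (pMethod == "auto")
      pMethod <- if (n <= 10L) "exact" else "asymptotic"
    if (pMethod == "asymptotic") {
      p <- pchisq(obs["chi2"], df = 1L, lower.tail = FALSE)
    } else if (pMethod == "exact") {
      if (choose(n, n1) > 2e5)
        stop("too many label assignments for exact enumeration")
      idx <- utils::combn(n, n1)
      stats <- apply(idx, 2L, function(ii) {
        m <- rep(FALSE, n); m[ii] <- TRUE
        .wlrStat(time, event, m, weight)["chi2"]
      })
      p <- mean(stats >= obs["chi2"] - 1e-12)
      method <- paste(method, "(exact enumeration)")
    } else {
      stats <- vapply(seq_len(nPerm), function(b) {
        m <- rep(FALSE, n); m[sample.int(n, n1)] <- TRUE
        .wlrStat(time, event, m, weight)["chi2"]
      }, numeric(1L))
      p <- (1 + sum(stats >= obs["chi2"] - 1e-12)) / (nPerm + 1)
      method <- paste(method, "(permutation)")
    }
  }
  structure(list(
    statistic = c(chi2 = unname(obs["chi2"])),
    parameter = c(df = 1L),
    p.value = unname(p),
    estimate = c(n1 = sum(g1), n2 = sum(!g1)),
    method = method, data.name = dname,
    U = unname(obs["U"]), V = unname(obs["V"])),
    class = "htest")
}

#' Stratify subjects into high/low groups by a gene-set score
#'
#' The per-subject score is the mean of per-gene z-scores over the gene
#' set; subjects are split at the median score, with subjects exactly at
#' the median assigned \code{"low"} (documented tie rule), so group sizes
#' differ by at most 1. A \code{"tertile"} split labels the top third
#' \code{"high"}, the bottom third \code{"low"} and the middle \code{NA}.
#'
#' @param expr Numeric matrix, genes in rows (rownames required), subjects
#'   in columns.
#' @param geneSet Character vector of gene identifiers (non-empty, present
#'   in `expr`); defaults to all rows.
#' @param split \code{"median"} (default) or \code{"tertile"}.
#' @return Factor with levels \code{c("low", "high")}, one per subject;
#'   the numeric scores are attached as attribute \code{"score"}. All-equal
#'   scores yield all \code{"low"} with a warning.
#' @export
stratifyByScore <- function(expr, geneSet = rownames(expr),
                            split = c("median", "tertile")) {
  split <- match.arg(split)
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("need at least 2 subjects")
  if (!length(geneSet)) stop("empty gene set")
  miss <- setdiff(geneSet, rownames(expr))
  if (length(miss))
    stop("gene(s) absent from expression matrix: ",
         paste(head(miss, 5), collapse = ", "))
  sub <- expr[geneSet, , drop = FALSE]
  sds <- apply(sub, 1L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped from the score")
    sub <- sub[sds > 0, , drop = FALSE]
    if (!nrow(sub)) stop("no non-constant gene in the set")
  }
  z <- (sub - rowMeans(sub)) / apply(sub, 1L, sd)
  score <- colMeans(z)
  if (max(score) == min(score)) {
    warning("all scores equal; every subject assigned 'low'")
    grp <- factor(rep("low", length(score)), levels = c("low", "high"))
  } else if (split == "median") {
    grp <- factor(ifelse(score > median(score), "high", "low"),
                  levels = c("low", "high"))
  } else {
    qs <- quantile(score, c(1 / 3, 2 / 3))
    grp <- factor(ifelse(score <= qs[1L], "low",
                  ifelse(score > qs[2L], "high", NA)),
                  levels = c("low", "high"))
  }
  names(grp) <- colnames(expr)
  attr(grp, "score") <- score
  grp
}
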