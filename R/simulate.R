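#' Parameters of the synthetic miR-29 study
#'
#' Holds every knob of the synthetic-data generators: the mimic
#' transfection arm sizes, the nevus/melanoma cohort sizes, planted effect
#' sizes, the negative-binomial dispersion, the strength of the latent
#' pri-miR-29b2~c coupling, the algorithm-vote means, and the hazard model
#' of the survival scenario. Defaults emulate the published study designs:
#' a 3-vs-3 mimic transfection with nine planted targets repressed 2-fold
#' (log2FC -1), a 23-nevus / 57-melanoma cohort with planted +0.6 log2FC
#' upregulation of targets, vote means 10 vs 2 of a nominal 12 algorithms,
#' and a log hazard ratio of 0.8 per unit of standardized target score.
#'
#' @slot nGenes,nTargets Number of genes and planted true targets
#'   (targets are the first `nTargets` gene identifiers).
#' @slot mimicEffectLog2 Planted log2 fold change of targets under mimic
#'   (negative).
#' @slot cohortEffectLog2 Planted melanoma-vs-nevus log2 fold change of
#'   targets (positive).
#' @slot nMimic,nControl,nNevus,nMelanoma Per-arm sample counts (>= 2).
#' @slot dispersion Shared NB dispersion phi, Var = mu + phi mu^2.
#' @slot anticorrBeta Coupling of target means to the latent standard
#'   normal pri-miR-29b2~c factor (target mean multiplied by
#'   \code{2^(-anticorrBeta * m_s)}).
#' @slot voteHigh,voteLow Mean algorithm votes (of 12) for targets and
#'   non-targets.
#' @slot hazardLogHR Log hazard ratio per unit standardized score.
#' @slot baselineLogMean,baselineLogSd Log-normal baseline expression of
#'   background genes.
#' @slot targetLogMean,targetLogSd Log-normal baseline of planted targets
#'   (kept at quantifiable expression, as nominated targets must be).
#' @slot seed Integer RNG seed; identical parameters imply identical
#'   outputs of every generator.
#' @seealso [simParams()]
#' @export
setClass("SimParams", slots = c(
  nGenes = "integer", nTargets = "integer",
  mimicEffectLog2 = "numeric", cohortEffectLog2 = "numeric",
  nMimic = "integer", nControl = "integer",
  nNevus = "integer", nMelanoma = "integer",
  dispersion = "numeric", anticorrBeta = "numeric",
  voteHigh = "integer", voteLow = "integer",
  hazardLogHR = "numeric",
  baselineLogMean = "numeric", baselineLogSd = "numeric",
  targetLogMean = "numeric", targetLogSd = "numeric",
  seed = "integer"))

setValidity("SimParams", function(object) {
  msg <- character(0)
  num1 <- c("mimicEffectLog2", "cohortEffectLog2", "dispersion",
            "anticorrBeta", "hazardLogHR", "baselineLogMean",
            "baselineLogSd", "targetLogMean", "targetLogSd")
  for (s in c(num1, "nGenes", "nTargets", "nMimic", "nControl", "nNevus",
              "nMelanoma", "voteHigh", "voteLow", "seed"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, paste0(s, " must be a single finite value"))
  if (length(msg)) return(msg)
  if (object@nTargets >= object@nGenes)
    msg <- c(msg, "nTargets must be smaller than nGenes")
  if (object@nTargets < 0L) msg <- c(msg, "nTargets must be >= 0")
  if (any(c(object@nMimic, object@nControl, object@nNevus,
            object@nMelanoma) < 2L))
    msg <- c(msg, "all arms need at least 2 samples")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@voteHigh < 0L || object@voteHigh > 12L ||
      object@voteLow < 0L || object@voteLow > 12L)
    msg <- c(msg, "vote means must lie in [0, 12]")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimParams Compact display.
#' @param object A `SimParams`.
#' @export
setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@nGenes, "genes,", object@nTargets,
      "planted targets, seed", object@seed, "\n")
  cat(sprintf("  mimic %dv%d (log2FC %g), cohort %d nevi / %d melanomas (log2FC %+g)\n",
      object@nControl, object@nMimic, object@mimicEffectLog2,
      object@nNevus, object@nMelanoma, object@cohortEffectLog2))
  cat(sprintf("  dispersion %g, anticorr beta %g, votes %d/%d, log HR %g\n",
      object@dispersion, object@anticorrBeta, object@voteHigh,
      object@voteLow, object@hazardLogHR))
})

#' Construct synthetic-study parameters
#'
#' @param nGenes,nTargets,mimicEffectLog2,cohortEffectLog2 See
#'   [SimParams-class].
#' @param nMimic,nControl,nNevus,nMelanoma Arm sizes.
#' @param dispersion NB dispersion phi (Var = mu + phi mu^2); the default
#'   0.02 is replicate-level variability typical of isogenic cell-line
#'   transfection experiments.
#' @param anticorrBeta,voteHigh,voteLow,hazardLogHR See
#'   [SimParams-class].
#' @param baselineLogMean,baselineLogSd,targetLogMean,targetLogSd
#'   Log-normal baseline expression parameters.
#' @param seed RNG seed.
#' @return A validated [SimParams-class] object.
#' @export
simParams <- function(nGenes = 2000L, nTargets = 9L,
                      mimicEffectLog2 = -1.0, cohortEffectLog2 = 0.6,
                      nMimic = 3L, nControl = 3L,
                      nNevus = 23L, nMelanoma = 57L,
                      dispersion = 0.02, anticorrBeta = 0.5,
                      voteHigh = 10L, voteLow = 2L,
                      hazardLogHR = 0.8,
                      baselineLogMean = log(300), baselineLogSd = 1.2,
                      targetLogMean = log(500), targetLogSd = 0.5,
                      seed = 1L) {
  new("SimParams",
      nGenes = as.integer(nGenes), nTargets = as.integer(nTargets),
      mimicEffectLog2 = as.numeric(mimicEffectLog2),
      cohortEffectLog2 = as.numeric(cohortEffectLog2),
      nMimic = as.integer(nMimic), nControl = as.integer(nControl),
      nNevus = as.integer(nNevus), nMelanoma = as.integer(nMelanoma),
      dispersion = as.numeric(dispersion),
      anticorrBeta = as.numeric(anticorrBeta),
      voteHigh = as.integer(voteHigh), voteLow = as.integer(voteLow),
      hazardLogHR = as.numeric(hazardLogHR),
      baselineLogMean = as.numeric(baselineLogMean),
      baselineLogSd = as.numeric(baselineLogSd),
      targetLogMean = as.numeric(targetLogMean),
      targetLogSd = as.numeric(targetLogSd),
      seed = as.integer(seed))
}

.geneIds <- function(params) sprintf("g%04d", seq_len(params@nGenes))
.targetIds <- function(params) {
  if (params@nTargets > 0L) .geneIds(params)[seq_len(params@nTargets)]
  else character(0)
}

.rnbOrPois <- function(n, mu, phi) {
  if (phi > 0) rnbinom(n, mu = mu, size = 1 / phi) else rpois(n, mu)
}

#' Simulate a gene x sample count matrix with planted targets
#'
#' Counts follow \code{NB(mu_gs, phi)} with
#' \code{mu_gs = s_s * q_g * 2^(x_s * beta_g)}: \code{s_s} a per-sample
#' depth factor log-uniform in \[0.5, 2\], \code{q_g} a log-normal
#' baseline, \code{x_s} the condition indicator and \code{beta_g} the
#' planted log2 fold change (0 for non-targets). For the cohort contrast a
#' latent standard-normal per-sample factor \code{m_s} — standing for
#' normalized pri-miR-29b2~c expression — additionally multiplies target
#' means by \code{2^(-anticorrBeta * m_s)}, inducing anti-correlation; the
#' pri-miR-29b2~c expression vector \code{100 * 2^(m_s)} is emitted
#' alongside. Identical parameters (including the seed) give identical
#' output.
#'
#' @param params A [SimParams-class] object.
#' @param contrast \code{"mimic"} (control vs mimic, `nControl` +
#'   `nMimic` samples) or \code{"cohort"} (nevus vs melanoma).
#' @return List with \code{se}: a
#'   [SummarizedExperiment::SummarizedExperiment] (assay \code{"counts"},
#'   \code{colData$condition} with the reference level first,
#'   \code{colData$depth} the true depth factors); \code{truth}: list with
#'   \code{target_ids}, per-gene \code{log2fc}, and for the cohort
#'   contrast \code{m} (the latent factor); and, for the cohort,
#'   \code{mirExpr}: the emitted pri-miR-29b2~c normalized expression.
#' @export
simulateCounts <- function(params, contrast = c("mimic", "cohort")) {
  contrast <- match.arg(contrast)
  stopifnot(is(params, "SimParams"))
  validObject(params)
  withr::local_preserve_seed()
  set.seed(params@seed + if (contrast == "cohort") 1L else 0L)
  G <- params@nGenes
  ids <- .geneIds(params)
  tIds <- .targetIds(params)
  q <- exp(rnorm(G, params@baselineLogMean, params@baselineLogSd))
  if (length(tIds))
    q[seq_along(tIds)] <- exp(rnorm(length(tIds), params@targetLogMean,
                                    params@targetLogSd))
  if (contrast == "mimic") {
    n0 <- params@nControl; n1 <- params@nMimic
    condLev <- c("control", "mimic")
    effect <- params@mimicEffectLog2
  } else {
    n0 <- params@nNevus; n1 <- params@nMelanoma
    condLev <- c("nevus", "melanoma")
    effect <- params@cohortEffectLog2
  }
  n <- n0 + n1
  cond <- factor(rep(condLev, c(n0, n1)), levels = condLev)
  x <- as.integer(cond == condLev[2L])
  s <- exp(runif(n, log(0.5), log(2)))
  beta <- numeric(G)
  beta[seq_len(params@nTargets)] <- effect
  mu <- outer(q, s) * 2^outer(beta, x)
  m <- NULL
  if (contrast == "cohort") {
    m <- rnorm(n)
    if (params@nTargets > 0L)
      mu[seq_len(params@nTargets), ] <- mu[seq_len(params@nTargets), ] *
        rep(2^(-params@anticorrBeta * m), each = params@nTargets)
  }
  counts <- matrix(.rnbOrPois(length(mu), mu, params@dispersion), nrow = G,
                   dimnames = list(ids, sprintf("%s_%02d", cond, seq_len(n))))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = cond, depth = s,
                                   row.names = colnames(counts)))
  truth <- list(target_ids = tIds,
                log2fc = setNames(beta, ids),
                contrast = contrast)
  out <- list(se = se, truth = truth)
  if (contrast == "cohort") {
    truth$m <- setNames(m, colnames(counts))
    out$truth <- truth
    out$mirExpr <- setNames(100 * 2^m, colnames(counts))
  }
  out
}

# one clean random UTR free of the 6-nt core match (sense strand)
.cleanUtr <- function(len, core6, maxIter = 50L) {
  for (i in seq_len(maxIter)) {
    s <- paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
               collapse = "")
    hit <- gregexpr(core6, s, fixed = TRUE)[[1L]]
    if (hit[1L] == -1L) return(s)
    # mutate one base inside each accidental core instead of resampling
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (h in hit) ch[h] <- setdiff(c("A", "C", "G", "U"), ch[h])[1L]
    s <- paste(ch, collapse = "")
    if (gregexpr(core6, s, fixed = TRUE)[[1L]][1L] == -1L) return(s)
  }
  stop("failed to generate a clean background UTR")
}

#' Simulate 3'UTR sequences with planted seed sites and algorithm votes
#'
#' Background UTRs (lengths uniform in \[200, 2000\], uniform base
#' composition) are screened so they contain no accidental seed-core match
#' to the given miRNA; each planted target receives one 8mer site at a
#' recorded position (re-drawn if the insertion junction would create an
#' extra match, so ground truth stays exact). Algorithm votes are binomial
#' with 12 trials around \code{voteHigh / 12} for targets and
#' \code{voteLow / 12} for non-targets; targets are flagged conserved,
#' non-targets conserved with probability 0.5. With \code{decoys = TRUE}
#' background sequences are left unscreened (accidental sites allowed),
#' for stress tests.
#'
#' @param params A [SimParams-class] object.
#' @param mirna Mature miRNA whose sites are planted (default
#'   miR-29a-3p).
#' @param decoys Allow accidental background sites (default FALSE).
#' @return List with \code{utrs}: a named [Biostrings::RNAStringSet];
#'   \code{support}: data.frame (\code{gene_id}, \code{n_algorithms},
#'   \code{conserved}); \code{truth}: data.frame of planted sites
#'   (\code{gene_id}, \code{start} 0-based, \code{end} half-open,
#'   \code{site_type}).
#' @export
simulateUtrVotes <- function(params, mirna = mir29Family()[1],
                             decoys = FALSE) {
  stopifnot(is(params, "SimParams"))
  withr::local_preserve_seed()
  set.seed(params@seed + 2L)
  seed7 <- seedSequence(mirna)
  core6 <- revComp(substr(seed7, 1L, 6L), as = "RNA")
  site8 <- paste0(revComp(seed7, as = "RNA"), "A")   # rc(seed 2-8) + A1
  ids <- .geneIds(params)
  isTarget <- seq_along(ids) <= params@nTargets
  lens <- sample(200:2000, length(ids), replace = TRUE)
  utrs <- character(length(ids))
  plant <- data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), site_type = character(0))
  for (i in seq_along(ids)) {
    if (!isTarget[i] && decoys) {
      utrs[i] <- paste(sample(c("A", "C", "G", "U"), lens[i], replace = TRUE),
                       collapse = "")
      next
    }
    s <- .cleanUtr(lens[i], core6)
    if (isTarget[i]) {
      if (lens[i] < nchar(site8) + 2L)
        stop("planted site longer than UTR")
      ok <- FALSE
      for (try in 1:20) {
        pos0 <- sample.int(lens[i] - nchar(site8) - 1L, 1L)  # 0-based start
        cand <- paste0(substr(s, 1L, pos0),
                       site8,
                       substr(s, pos0 + nchar(site8) + 1L, lens[i]))
        hits <- gregexpr(core6, cand, fixed = TRUE)[[1L]]
        if (length(hits) == 1L && hits[1L] == pos0 + 2L) { ok <- TRUE; break }
      }
      if (!ok) stop("could not plant a junction-clean site for ", ids[i])
      s <- cand
      plant <- rbind(plant, data.frame(gene_id = ids[i], start = pos0,
                                       end = pos0 + nchar(site8),
                                       site_type = "8mer"))
    }
    utrs[i] <- s
  }
  votes <- rbinom(length(ids), 12L,
                  ifelse(isTarget, params@voteHigh, params@voteLow) / 12)
  conserved <- ifelse(isTarget, TRUE, runif(length(ids)) < 0.5)
  list(utrs = Biostrings::RNAStringSet(setNames(utrs, ids)),
       support = data.frame(gene_id = ids, n_algorithms = votes,
                            conserved = conserved),
       truth = plant)
}

#' Simulate survival records coupled to a subject score
#'
#' Exponential event times with hazard
#' \code{h_i = h0 * exp(hazardLogHR * z_i)}, where \code{z_i} is the
#' standardized score (or a 0/1 indicator when `scores` is a two-level
#' factor, the mouse-genotype scenario), with independent
#' Uniform(0, 3 / h0) censoring (roughly 20-40 percent censored at
#' defaults). The emitted group label is the median split of the score
#' (ties to "low") or the factor itself.
#'
#' @param params A [SimParams-class] object (supplies `hazardLogHR` and
#'   the seed).
#' @param scores Per-subject numeric scores, or a two-level factor.
#' @param h0 Baseline hazard (default 0.1 per time unit).
#' @param seedOffset Added to the seed so several cohorts can be drawn
#'   from one parameter set.
#' @return data.frame with \code{subject_id}, \code{time}, \code{event}
#'   (1 = event, 0 = censored), \code{group}, \code{score}.
#' @export
simulateSurvival <- function(params, scores, h0 = 0.1, seedOffset = 0L) {
  stopifnot(is(params, "SimParams"))
  if (!length(scores)) stop("empty score vector")
  withr::local_preserve_seed()
  set.seed(params@seed + 3L + seedOffset)
  n <- length(scores)
  if (is.factor(scores) || is.character(scores)) {
    grp <- factor(scores)
    if (nlevels(grp) != 2L) stop("group scenario needs two levels")
    z <- as.numeric(grp == levels(grp)[2L])
    scoreNum <- z
  } else {
    scoreNum <- as.numeric(scores)
    z <- if (sd(scoreNum) > 0) as.numeric(scale(scoreNum)) else rep(0, n)
    grp <- factor(ifelse(scoreNum > median(scoreNum), "high", "low"),
                  levels = c("low", "high"))
  }
  h <- h0 * exp(params@hazardLogHR * z)
  tEvent <- rexp(n, rate = h)
  cens <- runif(n, 0, 3 / h0)
  data.frame(subject_id = sprintf("s%03d", seq_len(n)),
             time = pmin(tEvent, cens),
             event = as.integer(tEvent <= cens),
             group = grp,
             score = scoreNum)
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' For each gene with planted fold change F, treated-well target Ct values
#' are shifted by \code{-log2(F)} relative to control wells, reference-gene
#' Ct values are constant across conditions, and Gaussian well noise of sd
#' `noiseSd` is added everywhere, so [ddctQuantify()] recovers
#' \code{RQ = F} (exactly when `noiseSd = 0`).
#'
#' @param params A [SimParams-class] object (seed source).
#' @param foldChanges Named numeric vector of planted fold changes
#'   (treated / control) per target gene.
#' @param reference Reference gene name (default "GAPDH").
#' @param nRep Technical replicates per well (default 3).
#' @param noiseSd Gaussian Ct noise sd (default 0.05 cycles).
#' @param baseCt,refCt Baseline Ct of targets and of the reference gene.
#' @return data.frame with \code{sample_id}, \code{gene_id},
#'   \code{condition}, \code{replicate}, \code{ct}.
#' @export
simulateCtTable <- function(params, foldChanges, reference = "GAPDH",
                            nRep = 3L, noiseSd = 0.05,
                            baseCt = 24, refCt = 18) {
  stopifnot(is(params, "SimParams"))
  if (is.null(names(foldChanges)) || !length(foldChanges))
    stop("foldChanges must be a non-empty named vector")
  withr::local_preserve_seed()
  set.seed(params@seed + 4L)
  rows <- list()
  for (cond in c("control", "treated")) {
    for (r in seq_len(nRep)) {
      sid <- sprintf("%s_%d", cond, r)
      for (g in names(foldChanges)) {
        shift <- if (cond == "treated") -log2(foldChanges[[g]]) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, gene_id = g, condition = cond, replicate = r,
          ct = baseCt + shift + rnorm(1L, 0, noiseSd))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, gene_id = reference, condition = cond,
        replicate = r, ct = refCt + rnorm(1L, 0, noiseSd))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate dual-luciferase records with planted repression and rescue
#'
#' The wildtype-UTR reporter's normalized signal is multiplied by
#' `repression` under mimic; the seed-mutant reporter is repressed by the
#' residual \code{1 - rescue * (1 - repression)}, so with full rescue
#' (default) the mutant is untouched and the planted rescue index is
#' \code{1 - repression}.
#'
#' @param params A [SimParams-class] object (seed source).
#' @param repression Fold change of the wildtype reporter under mimic
#'   (default 0.6).
#' @param rescue Fraction of the repression removed by mutating the seed
#'   site (default 1, full rescue).
#' @param nRep Replicate wells per condition (default 4).
#' @param noiseSd Multiplicative log-normal noise sd (default 0.02).
#' @return data.frame with \code{sample_id}, \code{condition},
#'   \code{reporter}, \code{experimental}, \code{control}.
#' @export
simulateLuciferase <- function(params, repression = 0.6, rescue = 1,
                               nRep = 4L, noiseSd = 0.02) {
  stopifnot(is(params, "SimParams"))
  withr::local_preserve_seed()
  set.seed(params@seed + 5L)
  mutFc <- 1 - (1 - rescue) * (1 - repression)
  grid <- expand.grid(condition = c("control", "mimic"),
                      reporter = c("wildtype", "mutant"),
                      rep = seq_len(nRep), stringsAsFactors = FALSE)
  fc <- ifelse(grid$condition == "control", 1,
        ifelse(grid$reporter == "wildtype", repression, mutFc))
  ctrl <- exp(rnorm(nrow(grid), log(1000), 0.1))
  expr <- 0.8 * ctrl * fc * exp(rnorm(nrow(grid), 0, noiseSd))
  data.frame(sample_id = sprintf("%s_%s_%d", grid$condition, grid$reporter,
                                 grid$rep),
             condition = grid$condition, reporter = grid$reporter,
             experimental = expr, control = ctrl)
}
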