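test_that("parameter validation catches inconsistent designs", {
  expect_error(simParams(nTargets = 2000, nGenes = 2000), "smaller")
  expect_error(simParams(nMimic = 1), "at least 2")
  expect_error(simParams(dispersion = -0.1), ">= 0")
  expect_error(simParams(voteHigh = 13), "\\[0, 12\\]")
  expect_error(simParams(mimicEffectLog2 = NaN), "finite")
})

test_that("identical parameters give byte-identical outputs", {
  p <- simParams(nGenes = 200, nTargets = 3, seed = 77)
  a <- simulateCounts(p, "mimic"); b <- simulateCounts(p, "mimic")
  expect_identical(SummarizedExperiment::assay(a$se),
                   SummarizedExperiment::assay(b$se))
  ca <- simulateCounts(p, "cohort"); cb <- simulateCounts(p, "cohort")
  expect_identical(SummarizedExperiment::assay(ca$se),
                   SummarizedExperiment::assay(cb$se))
  expect_identical(ca$mirExpr, cb$mirExpr)
  ua <- simulateUtrVotes(p); ub <- simulateUtrVotes(p)
  expect_identical(as.character(ua$utrs), as.character(ub$utrs))
  expect_identical(ua$support, ub$support)
  sa <- simulateSurvival(p, rep(c(-1, 1), 10))
  sb <- simulateSurvival(p, rep(c(-1, 1), 10))
  expect_identical(sa, sb)
  # and the generators do not disturb the global RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(simulateCounts(p, "mimic")); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("a null mimic effect yields near-zero average fold change", {
  p <- simParams(nGenes = 2000, nTargets = 0, mimicEffectLog2 = 0,
                 dispersion = 0.1, seed = 13)
  sim <- simulateCounts(p, "mimic")
  cnt <- SummarizedExperiment::assay(sim$se)
  sf <- computeSizeFactors(cnt)
  norm <- sweep(cnt, 2, sf, "/")
  cond <- SummarizedExperiment::colData(sim$se)$condition
  lfc <- log2((rowMeans(norm[, cond == "mimic"]) + 0.5) /
              (rowMeans(norm[, cond == "control"]) + 0.5))
  expect_lt(abs(mean(lfc)), 0.05)
})

test_that("planted mimic fold changes are recovered per target", {
  # at the default cell-line dispersion the per-target empirical log2FC
  # concentrates tightly around the planted -1
  p <- simParams(seed = 7)
  sim <- simulateCounts(p, "mimic")
  cnt <- SummarizedExperiment::assay(sim$se)
  norm <- sweep(cnt, 2, computeSizeFactors(cnt), "/")
  cond <- SummarizedExperiment::colData(sim$se)$condition
  lfc <- log2((rowMeans(norm[, cond == "mimic", drop = FALSE]) + 0.5) /
              (rowMeans(norm[, cond == "control", drop = FALSE]) + 0.5))
  tg <- sim$truth$target_ids
  expect_gte(sum(abs(lfc[tg] + 1) < 0.5), 8)
  # convergence: wider arms tighten the recovery (two sample sizes)
  p2 <- simParams(nMimic = 12, nControl = 12, seed = 7)
  sim2 <- simulateCounts(p2, "mimic")
  cnt2 <- SummarizedExperiment::assay(sim2$se)
  norm2 <- sweep(cnt2, 2, computeSizeFactors(cnt2), "/")
  cond2 <- SummarizedExperiment::colData(sim2$se)$condition
  lfc2 <- log2((rowMeans(norm2[, cond2 == "mimic"]) + 0.5) /
               (rowMeans(norm2[, cond2 == "control"]) + 0.5))
  expect_lt(mean(abs(lfc2[tg] + 1)), mean(abs(lfc[tg] + 1)) + 0.05)
  expect_true(all(abs(lfc2[tg] + 1) < 0.5))
})

test_that("cohort targets anti-correlate with the emitted pri-miR-29b2~c", {
  p <- simParams(seed = 19)
  sim <- simulateCounts(p, "cohort")
  cnt <- SummarizedExperiment::assay(sim$se)
  norm <- sweep(cnt, 2, computeSizeFactors(cnt), "/")
  r <- apply(norm[sim$truth$target_ids, ], 1,
             function(v) corLog2(v, sim$mirExpr))
  expect_true(all(r <= -0.3))
  set.seed(1)
  bg <- apply(norm[sample(setdiff(rownames(norm), sim$truth$target_ids), 50), ],
              1, function(v) corLog2(v, sim$mirExpr))
  expect_lt(mean(abs(bg)), 0.2)
})

test_that("UTRs carry exactly the planted sites at recorded coordinates", {
  p <- simParams(nGenes = 120, nTargets = 10, seed = 23)
  u <- simulateUtrVotes(p)
  sites <- findSeedSites(mir29Family()[1], u$utrs)
  df <- sitesToDf(sites)
  expect_identical(nrow(df), nrow(u$truth))      # nothing accidental
  df <- df[match(u$truth$gene_id, df$gene), ]
  expect_identical(df$start - 1L, u$truth$start) # 0-based truth
  expect_identical(df$end, u$truth$end)
  expect_true(all(df$site_type == "8mer"))
  # no planted targets, decoys off -> scan is empty
  p0 <- simParams(nGenes = 50, nTargets = 0, seed = 29)
  u0 <- simulateUtrVotes(p0)
  expect_length(findSeedSites(mir29Family()[1], u0$utrs), 0L)
})

test_that("vote distributions separate targets from background as designed", {
  p <- simParams(nGenes = 1000, nTargets = 200, seed = 31)
  u <- simulateUtrVotes(p)
  isT <- u$support$gene_id %in% sprintf("g%04d", 1:200)
  passT <- mean(u$support$n_algorithms[isT] >= 8)
  passB <- mean(u$support$n_algorithms[!isT] >= 8)
  expect_gte(passT, 0.95)                  # binomial tail at 10/12
  expect_lte(passB, 0.01)                  # binomial tail at 2/12
  expect_true(all(u$support$conserved[isT]))
})

test_that("survival generator respects its contracts", {
  p <- simParams(seed = 37)
  expect_error(simulateSurvival(p, numeric(0)), "empty")
  sv <- simulateSurvival(p, rnorm(100))
  expect_true(all(sv$time > 0))
  expect_true(all(sv$event %in% 0:1))
  # censoring fraction in the designed range at defaults
  frac <- 1 - mean(sv$event)
  expect_gt(frac, 0.1); expect_lt(frac, 0.5)
  # two-level factor scenario (mouse genotypes)
  svg <- simulateSurvival(p, factor(rep(c("gfp", "sponge"), each = 10)))
  expect_identical(levels(svg$group), c("gfp", "sponge"))
})

test_that("null survival p-values are uniform and all-censored data degenerate cleanly", {
  p <- simParams(hazardLogHR = 0, seed = 41)
  pv <- sapply(1:200, function(i) {
    sv <- simulateSurvival(p, rnorm(40), seedOffset = i)
    gbwTest(sv$time, sv$event, sv$group, pMethod = "asymptotic")$p.value
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
  sv <- simulateSurvival(p, rnorm(10))
  sv$event <- 0L
  expect_identical(nrow(kmEstimate(sv$time, sv$event)), 0L)  # S stays 1
})

test_that("the end-to-end demo recovers the planted targets deterministically", {
  p <- simParams(seed = 7)
  d1 <- runDemo(p)
  expect_gte(d1$report$recall, 8 / 9)
  expect_lte(length(d1$report$false_positives), 1L)
  d2 <- runDemo(p)
  expect_identical(d1$report, d2$report)
  # file outputs round-trip
  out <- withr::local_tempdir()
  runDemo(simParams(nGenes = 150, nTargets = 3, seed = 3), outDir = out)
  expect_true(file.exists(file.path(out, "report.json")))
  se <- readCountExperiment(file.path(out, "mimic_counts.tsv"),
                            file.path(out, "mimic_meta.tsv"))
  expect_identical(dim(se), c(150L, 6L))
  sup <- readSupportTsv(file.path(out, "support.tsv"))
  expect_identical(nrow(sup), 150L)
  expect_type(sup$conserved, "logical")
})
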