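mkDE <- function(ids, lfc, fdr) {
  data.frame(gene_id = ids, base_mean = 100, log2fc = lfc, se = 0.1,
             stat = lfc / 0.1, pvalue = fdr, fdr = fdr)
}
mkSum <- function(ids, votes, cons) {
  data.frame(gene_id = ids, n_8mer = 1L, n_7mer_m8 = 0L, n_7mer_A1 = 0L,
             n_6mer = 0L, n_sites = 1L,
             best_type = factor("8mer",
               levels = c("8mer", "7mer-m8", "7mer-A1", "6mer", "none")),
             n_algorithms = votes, conserved = cons)
}

test_that("correlation on log2 values matches the covariance formula", {
  x <- c(1, 2, 3, 4); y <- c(4, 3, 2, 1)
  lx <- log2(x + 1); ly <- log2(y + 1)
  want <- sum((lx - mean(lx)) * (ly - mean(ly))) /
    sqrt(sum((lx - mean(lx))^2) * sum((ly - mean(ly))^2))
  expect_equal(corLog2(x, y), want, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    a <- rexp(10, 0.01); b <- rexp(10, 0.01)
    la <- log2(a + 1); lb <- log2(b + 1)
    manual <- mean((la - mean(la)) * (lb - mean(lb))) /
      (sd(la) * sd(lb)) * 10 / 9
    expect_equal(corLog2(a, b), manual, tolerance = 1e-12)
  }
})

test_that("perfect anti-correlation and degenerate inputs", {
  x <- c(1, 2, 3, 4)
  # on the raw scale a reversed sequence is exactly anti-correlated
  expect_equal(corLog2(x, rev(x), log2p1 = FALSE), -1, tolerance = 1e-12)
  y <- 2^(-log2(x + 1)) - 1          # y = -x on the log2(.+1) scale
  expect_equal(corLog2(x, y), -1, tolerance = 1e-12)
  expect_true(is.na(corLog2(c(1, 1, 1), c(1, 2, 3))))
  expect_error(corLog2(1:4, 1:3), "length mismatch")
  expect_error(corLog2(1:2, 1:2), "at least 3")
})

test_that("a record meeting all four criteria is a candidate", {
  res <- runCascade(mkDE("g1", -0.6, 0.01), mkDE("g1", 0.4, 0.04),
                    mkSum("g1", 9L, TRUE), c(g1 = -0.35))
  led <- stageLedger(res)
  expect_true(all(led[, c("pass_mimic", "pass_cohort", "pass_sites",
                          "pass_anticorr", "candidate")] == TRUE))
  expect_identical(candidates(res)$gene_id, "g1")
})

test_that("boundary semantics: stage 1 strict, stages 2-4 non-strict", {
  # exactly at the mimic threshold: fails (strict <)
  r1 <- runCascade(mkDE("g1", -0.5, 0.01), mkDE("g1", 0.4, 0.04),
                   mkSum("g1", 9L, TRUE), c(g1 = -0.35))
  expect_false(stageLedger(r1)$pass_mimic)
  r1b <- runCascade(mkDE("g1", -0.6, 0.05), mkDE("g1", 0.4, 0.04),
                    mkSum("g1", 9L, TRUE), c(g1 = -0.35))
  expect_false(stageLedger(r1b)$pass_mimic)
  # exactly at the cohort/sites/correlation thresholds: passes (non-strict)
  r2 <- runCascade(mkDE("g1", -0.6, 0.01), mkDE("g1", 0.3, 0.05),
                   mkSum("g1", 8L, TRUE), c(g1 = -0.3))
  led <- stageLedger(r2)
  expect_true(led$pass_cohort)
  expect_true(led$pass_sites)
  expect_true(led$pass_anticorr)
  expect_true(led$candidate)
})

test_that("genes missing from a stream fail that stage but stay in the ledger", {
  res <- runCascade(mkDE(c("g1", "g2"), c(-1, -1), c(0.01, 0.01)),
                    mkDE("g1", 0.5, 0.01),
                    mkSum("g1", 9L, TRUE), c(g1 = -0.5))
  led <- stageLedger(res)
  expect_identical(nrow(led), 2L)
  g2 <- led[led$gene_id == "g2", ]
  expect_true(g2$pass_mimic)
  expect_false(g2$pass_cohort)
  expect_false(g2$pass_sites)
  expect_false(g2$pass_anticorr)
})

test_that("duplicate gene ids in a stream are rejected; empty result is valid", {
  expect_error(runCascade(mkDE(c("g1", "g1"), c(-1, -1), c(0.01, 0.01)),
                          mkDE("g1", 0.5, 0.01), mkSum("g1", 9L, TRUE),
                          c(g1 = -0.5)), "duplicate")
  res <- runCascade(mkDE("g1", 0.2, 0.8), mkDE("g1", 0, 0.9),
                    mkSum("g1", 1L, FALSE), c(g1 = 0.1))
  expect_identical(nrow(candidates(res)), 0L)
})

test_that("filters commute and loosening a threshold never drops a candidate", {
  set.seed(12)
  n <- 300L
  ids <- sprintf("g%03d", 1:n)
  mimic <- mkDE(ids, rnorm(n, -0.4, 0.5), runif(n, 0, 0.2))
  cohort <- mkDE(ids, rnorm(n, 0.3, 0.3), runif(n, 0, 0.2))
  summ <- mkSum(ids, sample(0:12, n, TRUE), sample(c(TRUE, FALSE), n, TRUE))
  r <- setNames(runif(n, -1, 0.5), ids)
  th <- cascadeThresholds()
  res <- runCascade(mimic, cohort, summ, r, th)
  led <- stageLedger(res)
  # order independence: the candidate set is the intersection of the four
  # independently evaluated predicates, whatever order they are applied in
  byHand <- Reduce(intersect, list(
    ids[!is.na(mimic$log2fc) & mimic$log2fc < th$mimicLfcMax &
          mimic$fdr < th$mimicFdrMax],
    ids[cohort$log2fc >= th$cohortLfcMin & cohort$fdr <= th$cohortFdrMax],
    ids[summ$n_algorithms >= th$minAlgorithms & summ$conserved],
    ids[r <= th$corrMax]))
  expect_setequal(candidates(res)$gene_id, byHand)
  # ledger completeness
  expect_identical(nrow(led), n)
  expect_false(anyDuplicated(led$gene_id) > 0)
  # monotonicity under loosening
  loose <- cascadeThresholds(mimicLfcMax = -0.3, mimicFdrMax = 0.1,
                             cohortLfcMin = 0.1, cohortFdrMax = 0.1,
                             minAlgorithms = 5L, corrMax = -0.1)
  res2 <- runCascade(mimic, cohort, summ, r, loose)
  expect_true(all(candidates(res)$gene_id %in% candidates(res2)$gene_id))
})

test_that("candidate ordering is deterministic: r, then mimic lfc, then id", {
  ids <- c("gB", "gA", "gC")
  res <- runCascade(mkDE(ids, c(-1, -2, -1), c(0.01, 0.01, 0.01)),
                    mkDE(ids, c(1, 1, 1), c(0.01, 0.01, 0.01)),
                    mkSum(ids, 9L, TRUE),
                    setNames(c(-0.5, -0.5, -0.9), ids))
  expect_identical(candidates(res)$gene_id, c("gC", "gA", "gB"))
})

test_that("threshold constructor enforces sign conventions", {
  expect_error(cascadeThresholds(mimicLfcMax = 0.5))
  expect_error(cascadeThresholds(cohortLfcMin = -0.3))
  expect_error(cascadeThresholds(corrMax = 0.3))
  expect_error(cascadeThresholds(minAlgorithms = 0))
})
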