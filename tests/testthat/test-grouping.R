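# Spearman correlation of binary indicators and collinearity merging.

test_that("phi equals the rank-based Spearman for binary vectors", {
  # worked 6-patient vectors
  x <- c(1, 1, 0, 0, 1, 0)
  y <- c(1, 1, 0, 0, 0, 0)
  m <- cbind(a = x, b = y)
  corr <- pairwiseSpearman(m, dili = c(1, 0, 0, 1, 0, 0))
  expect_equal(corr@rho["a", "b"], spearmanRankOracle(x, y))
  expect_equal(corr@rho["a", "b"], cor(x, y, method = "spearman"))

  # identical and complementary columns
  m2 <- cbind(p = x, q = x, r = 1 - x)
  corr2 <- pairwiseSpearman(m2, dili = y)
  expect_equal(corr2@rho["p", "q"], 1)
  expect_equal(corr2@rho["p", "r"], -1)

  # random binary matrices against the rank oracle
  set.seed(41)
  for (i in 1:5) {
    mm <- matrix(runif(200) < runif(1, 0.2, 0.8), 50, 4,
                 dimnames = list(NULL, letters[1:4]))
    if (any(apply(mm, 2, function(v) length(unique(v))) == 1)) next
    got <- pairwiseSpearman(mm, dili = runif(50) < 0.5)@rho
    for (p in 1:3) for (q in (p + 1):4)
      expect_equal(got[p, q], spearmanRankOracle(mm[, p], mm[, q]))
  }
})

test_that("constant indicators are flagged and excluded from merging", {
  m <- cbind(a = c(1, 0, 1, 0), b = c(0, 0, 0, 0), c = c(1, 0, 1, 0))
  expect_warning(corr <- pairwiseSpearman(m, dili = c(1, 0, 0, 0)),
                 "constant")
  expect_equal(corr@constant, "b")
  groups <- mergeCollinear(corr)
  expect_equal(sort(unname(unlist(groupMembers(groups)))), c("a", "c"))
  expect_equal(groups@excluded, "b")
})

test_that("no pair above the threshold yields all singletons", {
  set.seed(43)
  m <- matrix(runif(500) < 0.4, 100, 5,
              dimnames = list(NULL, paste0("d", 1:5)))
  corr <- pairwiseSpearman(m, dili = runif(100) < 0.3)
  stopifnot(max(corr@rho[upper.tri(corr@rho)]) < 0.9)  # fixture sanity
  groups <- mergeCollinear(corr, 0.9)
  expect_equal(nGroups(groups), 5)
  expect_equal(lengths(groupMembers(groups)), setNames(rep(1L, 5),
                                                       paste0("d", 1:5)))
})

test_that("a planted trio merges with outcome-ordered label A > B > C", {
  set.seed(47)
  n <- 400
  base <- runif(n) < 0.3
  dili <- runif(n) < plogis(qlogis(0.2) + 2 * base)
  # A, B, C identical exposure columns; outcome correlation tweaked by
  # flipping a few entries of B and C away from the outcome
  A <- base
  B <- base; B[which(dili & B)[1:3]] <- FALSE
  C <- base; C[which(dili & C)[1:8]] <- FALSE
  m <- cbind(C = C, A = A, B = B)   # shuffled input order
  corr <- pairwiseSpearman(m, dili = dili)
  stopifnot(min(corr@rho[upper.tri(corr@rho)]) > 0.9)  # fixture sanity
  stopifnot(corr@outcomeRho["A"] > corr@outcomeRho["B"],
            corr@outcomeRho["B"] > corr@outcomeRho["C"])
  groups <- mergeCollinear(corr, 0.9)
  expect_equal(nGroups(groups), 1)
  expect_equal(groupLabels(groups), "A > B > C")
  expect_equal(groupRepresentatives(groups), "A")
})

test_that("exactly tied outcome correlations use '=' and name order", {
  x <- c(1, 1, 0, 0, 1, 0, 0, 0)
  m <- cbind(zeta = x, alpha = x)
  corr <- pairwiseSpearman(m, dili = c(1, 0, 0, 1, 0, 0, 1, 0))
  groups <- mergeCollinear(corr, 0.9)
  expect_equal(groupLabels(groups), "alpha = zeta")
  expect_equal(groupRepresentatives(groups), "alpha")
})

test_that("grouping is a partition and threshold-monotone", {
  cfg <- simulationConfig(nPatients = 4000, seed = 13,
                          collinearClusters = list(c("Safflower",
                                                     "Sappan Wood")))
  cohort <- simulateCohort(cfg)
  corr <- pairwiseSpearman(cohort)
  non_constant <- setdiff(colnames(corr@rho), corr@constant)
  sizes <- integer(0)
  for (th in c(0.5, 0.7, 0.9, 0.99)) {
    g <- mergeCollinear(corr, th)
    members <- unname(unlist(groupMembers(g)))
    expect_equal(sort(members), sort(non_constant))  # partition, no overlap
    sizes <- c(sizes, nGroups(g))
  }
  expect_true(all(diff(sizes) >= 0))  # raising the threshold never merges more
})

test_that("group flags are ORs: group counts dominate member counts", {
  cfg <- simulationConfig(nPatients = 3000, seed = 17)
  cohort <- simulateCohort(cfg)
  groups <- mergeCollinear(pairwiseSpearman(cohort), 0.9)
  gf <- groupFlags(cohort, groups)
  e <- t(exposureMatrix(cohort)) > 0
  for (i in seq_len(nGroups(groups))) {
    mem <- groupMembers(groups)[[i]]
    expect_true(all(colSums(e[, mem, drop = FALSE]) <= sum(gf[, i])))
    expect_equal(unname(gf[, i]),
                 unname(rowSums(e[, mem, drop = FALSE]) > 0))
  }
  # representative mode uses the representative's own column
  gfr <- groupFlags(cohort, groups, mode = "representative")
  expect_equal(unname(gfr[, 1]),
               unname(e[, groupRepresentatives(groups)[1]]))
})
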