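# 2x2 tables, corrected ROR, Fisher's exact test and the signal criterion.

test_that("contingency tables count the joint classification", {
  t0 <- buildContingency(rep(FALSE, 7), c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                          TRUE, FALSE))
  expect_equal(unlist(t0[c("a", "b", "c", "d")]),
               c(a = 0, b = 0, c = 3, d = 4))

  t1 <- buildContingency(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                         c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0))
  expect_equal(unlist(t1[c("a", "b", "c", "d")]), c(a = 3, b = 2, c = 1,
                                                    d = 4))
  expect_error(buildContingency(c(1, 0), c(1, 0, 1)), "lengths differ")

  # nested-loop pair-counting oracle on a random fixture, several groups
  set.seed(51)
  g <- matrix(runif(300) < 0.4, 100, 3, dimnames = list(NULL, letters[1:3]))
  y <- runif(100) < 0.3
  tab <- buildContingency(g, y)
  for (j in 1:3) {
    a <- b <- cc <- d <- 0
    for (i in 1:100) {
      if (g[i, j] && y[i]) a <- a + 1
      else if (g[i, j]) b <- b + 1
      else if (y[i]) cc <- cc + 1
      else d <- d + 1
    }
    expect_equal(unlist(tab[j, c("a", "b", "c", "d")]),
                 c(a = a, b = b, c = cc, d = d))
  }
  expect_equal(tab$a + tab$b + tab$c + tab$d, rep(100L, 3))
})

test_that("corrected ROR follows the half-added cross-product formula", {
  expect_equal(rorCorrected(5, 5, 9, 9)$ror, 1)        # a=b, c=d
  expect_equal(rorCorrected(0, 0, 7, 7)$ror, 1)        # zero-exposure table
  got <- rorCorrected(10, 90, 100, 9800)
  expect_equal(got$ror, (10.5 * 9800.5) / (90.5 * 100.5))
  se <- sqrt(1 / 10.5 + 1 / 90.5 + 1 / 100.5 + 1 / 9800.5)
  expect_equal(got$ci_low, exp(log(got$ror) - qnorm(0.975) * se))
  expect_equal(got$ci_high, exp(log(got$ror) + qnorm(0.975) * se))
  # correction keeps everything finite even for the all-zero table
  z <- rorCorrected(0, 0, 0, 0)
  expect_true(is.finite(z$ror) && is.finite(z$ci_low) && z$ror == 1)
})

test_that("corrected ROR converges to the raw odds ratio as cells grow", {
  a <- 3; b <- 7; c <- 5; d <- 25
  raw <- (a * d) / (b * c)
  devs <- vapply(c(1, 10, 100), function(m)
    abs(log(rorCorrected(m * a, m * b, m * c, m * d)$ror) - log(raw)), 0)
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 0.01)
})

test_that("Fisher p matches hand enumeration on the worked examples", {
  expect_equal(fisherExact2x2(0, 0, 4, 9), 1)          # empty margin
  expect_equal(fisherExact2x2(5, 0, 0, 5), 1 / 126)    # 2 / choose(10, 5)
  expect_equal(fisherExact2x2(3, 2, 1, 4), fisherOracle(3, 2, 1, 4))
  expect_equal(fisherExact2x2(3, 2, 1, 4),
               fisher.test(matrix(c(3, 1, 2, 4), 2))$p.value)
})

test_that("Fisher p agrees with stats::fisher.test across random tables", {
  set.seed(53)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(5:60, 1), runif(4, 0.05, 1)))
    got <- fisherExact2x2(cells[1], cells[2], cells[3], cells[4])
    ref <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("Fisher p is invariant under transposing the 2x2 axes", {
  set.seed(57)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, 40, runif(4, 0.05, 1)))
    expect_equal(fisherExact2x2(cells[1], cells[2], cells[3], cells[4]),
                 fisherExact2x2(cells[1], cells[3], cells[2], cells[4]))
  }
})

test_that("CI always brackets the ROR and volcano inputs stay finite", {
  set.seed(59)
  cells <- matrix(rpois(400, 4), ncol = 4)
  est <- rorCorrected(cells[, 1], cells[, 2], cells[, 3], cells[, 4])
  expect_true(all(est$ci_low <= est$ror & est$ror <= est$ci_high))
  expect_true(all(is.finite(log(est$ror))))
  p <- fisherExact2x2(cells[, 1], cells[, 2], cells[, 3], cells[, 4])
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(is.finite(-log10(pmax(p, 1e-300)))))
})

test_that("the three-part criterion and reason codes behave as defined", {
  got <- classifySignal(ror = c(8.63, 50, 0.9, 1.2),
                        p = c(1e-30, 0.001, 0.001, 0.2),
                        n_reports = c(5000, 4, 100, 50))
  expect_equal(got$is_signal, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(got$reasons[2], "reports<10")
  expect_equal(got$reasons[3], "ror<=1")
  expect_equal(got$reasons[4], "p>=0.05")
})

test_that("signalTest ties the stages together on a known cohort", {
  cohort <- simulateIndependentExposures(
    nPatients = 5000, nCrude = 8, exposureProb = 0.1,
    baselineDiliProb = 0.08, plantedEffects = c(drug_001 = 6), seed = 61)
  res <- signalTest(cohort)
  expect_s4_class(res, "SignalResults")
  expect_equal(nrow(res), 8)
  expect_equal(res$a + res$b + res$c + res$d, rep(5000L, 8))
  expect_equal(res$n_reports, res$a + res$b)
  i <- match("drug_001", res$label)
  expect_true(res$is_signal[i])
  expect_gt(res$ror[i], 3)
  # coordinates consistent with the statistics
  expect_equal(res$ln_ror, log(res$ror))
  expect_equal(res$neg_log10_p, -log10(pmax(res$p_value, 1e-300)))
  # debug switch adds raw-count estimates
  res2 <- signalTest(cohort, debugRawCI = TRUE)
  expect_true(all(c("ror_raw", "ci_low_raw") %in% colnames(res2)))
})
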