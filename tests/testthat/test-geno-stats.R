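test_that("HWE exact test matches enumeration oracle for all tables with n <= 20", {
  for (n in c(2, 5, 9, 14, 20)) {
    for (n0 in 0:n) for (n1 in 0:(n - n0)) {
      n2 <- n - n0 - n1
      expect_equal(hweExactTest(n0, n1, n2), oracleHweP(n0, n1, n2),
                   tolerance = 1e-9,
                   info = sprintf("table (%d,%d,%d)", n0, n1, n2))
    }
  }
})

test_that("HWE exact test handles boundary configurations", {
  # all minor alleles heterozygous at tiny frequency: only feasible
  # configurations are h in {0, 2}, observed is the likelier one
  expect_equal(hweExactTest(9998, 2, 0), 1)
  # extreme heterozygote deficit
  expect_lt(hweExactTest(10, 0, 10), 1e-5)
  # monomorphic convention
  expect_equal(hweExactTest(50, 0, 0), 1)
  expect_equal(hweExactTest(0, 0, 50), 1)
  expect_error(hweExactTest(-1, 0, 0), "non-negative")
})

test_that("HWE p-values are valid (sub-uniform) under the null", {
  set.seed(11)
  n <- 200
  p <- replicate(2000, {
    g <- rbinom(n, 2, 0.3)
    hweExactTest(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  grid <- seq(0.05, 0.95, by = 0.05)
  emp <- vapply(grid, function(a) mean(p <= a), numeric(1))
  expect_true(all(emp <= grid + 0.03))
})

test_that("HWE filter removes planted violations and calibrates near alpha on null loci", {
  set.seed(5)
  n <- 1000
  nullCodes <- lapply(1:200, function(i) rbinom(n, 2, 0.3))
  gd <- makeTinyGd(nullCodes)
  res <- hweFilter(gd, alpha = 0.05)
  rate <- mean(res$report$removed)
  # exact test is conservative: removal rate near but not above alpha
  expect_lte(rate, 0.05 + 0.02)
  expect_gt(rate, 0)

  # heterozygote-free loci at q = 0.5 are always removed
  bad <- lapply(1:20, function(i) 2L * rbinom(200, 1, 0.5))
  gdBad <- makeTinyGd(bad)
  resBad <- hweFilter(gdBad, alpha = 0.05)
  expect_equal(nrow(resBad$genotypes), 0)

  # alpha = 0 removes nothing; filters never touch subjects
  expect_equal(nrow(hweFilter(gdBad, alpha = 0)$genotypes), 20)
  expect_equal(ncol(res$genotypes), n)
})

test_that("Shannon information matches the closed form", {
  expect_equal(shannonInfo(5, 3, 2), log(2))            # p1 = 0.5
  expect_equal(shannonInfo(10, 0, 0), 0)                # p1 = 0
  expect_equal(shannonInfo(8, 1, 1),
               -0.8 * log(0.8) - 0.2 * log(0.2))        # p1 = 0.2
  # allele basis: p1 = (n1 + 2 n2) / 2n
  expect_equal(shannonInfo(2, 0, 2, basis = "allele"), log(2))
  # bounded by ln 2
  set.seed(3)
  for (i in 1:20) {
    cnt <- rmultinom(1, 30, runif(3))
    expect_lte(shannonInfo(cnt[1], cnt[2], cnt[3]), log(2) + 1e-12)
  }
})

test_that("informative filter keeps common loci in A and drops rare ones to C", {
  set.seed(9)
  n <- 67
  common <- lapply(1:10, function(i) rbinom(n, 2, 0.4))
  rare <- lapply(1:30, function(i) { g <- integer(n); g[sample(n, 1)] <- 1L; g })
  gd <- makeTinyGd(c(common, rare))
  res <- informativeFilter(gd)
  kept <- which(res$report$kept)
  expect_true(all(1:10 %in% kept))
  expect_false(any(11:40 %in% kept))
  expect_error(informativeFilter(gd[0, ]), "empty")
})

test_that("chi-squared effect sizes match the contingency oracle", {
  # (20,10) vs (10,20) allele table
  g <- c(rep(2L, 10), rep(0L, 5), rep(0L, 10), rep(2L, 5))
  gd <- makeTinyGd(list(g))
  labels <- rep(1:2, each = 15)
  expect_equal(unname(chi2Effect(gd, labels)),
               oracleChi2(matrix(c(20, 10, 10, 20), 2)))
  expect_equal(unname(chi2Effect(gd, labels)), 20 / 3, tolerance = 1e-9)

  # equal frequencies -> 0; monomorphic -> 0
  gd0 <- makeTinyGd(list(rep(c(0L, 1L), 10), rep(0L, 20)))
  expect_equal(unname(chi2Effect(gd0, rep(1:2, each = 10))), c(0, 0))

  # random instances against the oracle
  set.seed(21)
  for (i in 1:20) {
    g <- rbinom(40, 2, runif(1, 0.1, 0.9))
    lab <- rep(1:2, each = 20)
    a <- sum(g[1:20]); b <- sum(g[21:40])
    tab <- matrix(c(a, 40 - a, b, 40 - b), 2)
    expected <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 0
                else oracleChi2(tab)
    expect_equal(unname(chi2Effect(makeTinyGd(list(g)), lab)), expected,
                 tolerance = 1e-9)
  }
})

test_that("effect-size filter recovers planted associated loci and stays null under permutation", {
  set.seed(31)
  n <- 67
  labels <- rep(1:2, c(42, 25))
  hits <- 0; planted_total <- 0
  enrichP <- numeric(20)
  for (s in 1:20) {
    assoc <- lapply(1:8, function(i) {
      q <- c(runif(1, 0.15, 0.35), 0)
      q[2] <- min(q[1] + runif(1, 0.25, 0.35), 0.95)
      rbinom(n, 2, q[labels])
    })
    nulls <- lapply(1:72, function(i) rbinom(n, 2, runif(1, 0.05, 0.5)))
    gd <- makeTinyGd(c(assoc, nulls))
    res <- effectSizeFilter(gd, labels)
    kept <- which(res$report$kept)
    hits <- hits + sum(1:8 %in% kept)
    planted_total <- planted_total + 8

    # permuted labels: retained set should not be enriched for planted loci
    resP <- effectSizeFilter(gd, sample(labels))
    keptP <- resP$report$locus[resP$report$kept]
    inA <- rownames(dosage(gd)) %in% keptP
    planted <- seq_len(80) <= 8
    enrichP[s] <- fisher.test(table(inA, planted))$p.value
  }
  expect_gte(hits / planted_total, 0.8)
  expect_gte(mean(enrichP > 0.05), 0.9)

  # single locus input: A non-empty
  single <- effectSizeFilter(makeTinyGd(list(rbinom(n, 2, 0.4))), labels)
  expect_equal(nrow(single$genotypes), 1)
})

test_that("cluster allele frequencies count variant alleles per cluster in percent", {
  gd <- makeTinyGd(list(c(0L, 1L, 2L, 2L, 0L, 0L)))
  f <- clusterAlleleFrequencies(gd, rep(1:2, c(4, 2)))
  expect_equal(unname(f[1, "1"]), 100 * 5 / 8)
  expect_equal(unname(f[1, "2"]), 0)

  # synthetic locus at the (39, 66) design frequencies lands within 10 points
  set.seed(2)
  labels <- rep(1:2, c(42, 25))
  est <- replicate(20, {
    g <- rbinom(67, 2, c(0.39, 0.66)[labels])
    clusterAlleleFrequencies(makeTinyGd(list(g)), labels)[1, ]
  })
  # per-draw sampling noise at these cluster sizes is ~5 points; the
  # average estimate must sit well within 10 points of the design values
  expect_lt(abs(mean(est["1", ]) - 39), 10)
  expect_lt(abs(mean(est["2", ]) - 66), 10)
  expect_lt(abs(mean(est["1", ]) - 39), 3)
  expect_lt(abs(mean(est["2", ]) - 66), 3)
})

test_that("variant class proportions sum to 100 and mirror the class mix", {
  info <- data.frame(class = rep(c("SNV", "Del", "Ins", "MIX"),
                                 c(787, 109, 86, 18)))
  pr <- variantClassSummary(info)
  expect_equal(sum(pr), 100)
  expect_equal(unname(pr["SNV"]), 78.7)
  expect_equal(unname(pr["Del"]), 10.9)
  expect_equal(unname(pr["Ins"]), 8.6)
  expect_equal(unname(pr["MIX"]), 1.8)
  expect_equal(variantClassSummary(info[sample(nrow(info)), , drop = FALSE]),
               pr)
  one <- variantClassSummary(data.frame(class = "Del"))
  expect_equal(unname(one["Del"]), 100)
})
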