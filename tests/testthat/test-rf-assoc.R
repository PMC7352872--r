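test_that("Monte-Carlo splits are stratified, exhaustive and reproducible", {
  labels <- rep(1:2, c(42, 25))
  s <- mcSplit(labels, 2 / 3, seed = 1)
  expect_length(s$train, 45)                  # round(2/3 * 67)
  expect_length(s$test, 22)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), 1:67)
  # both classes on both sides
  expect_setequal(unique(labels[s$train]), 1:2)
  expect_setequal(unique(labels[s$test]), 1:2)
  expect_identical(mcSplit(labels, seed = 7), mcSplit(labels, seed = 7))
  expect_false(identical(mcSplit(labels, seed = 7),
                         mcSplit(labels, seed = 8)))
  expect_error(mcSplit(rep(1:2, 2)), "at least 6")
})

test_that("the per-split feature count follows ceil(0.2 sqrt(d))", {
  expect_equal(ThermoPainAssoc:::.mtry(80), 2L)   # ceil(0.2 * 8.94) = 2
  expect_equal(ThermoPainAssoc:::.mtry(25), 1L)
  expect_equal(ThermoPainAssoc:::.mtry(400), 4L)
  expect_equal(ThermoPainAssoc:::.mtry(1), 1L)
})

test_that("balanced accuracy and AUC behave as defined", {
  truth <- factor(rep(c("a", "b"), c(8, 2)))
  pred <- factor(rep("a", 10), levels = c("a", "b"))
  expect_equal(balancedAccuracy(truth, pred), 0.5)
  # invariant to relabeling
  expect_equal(balancedAccuracy(truth, pred),
               balancedAccuracy(factor(rep(c("b", "a"), c(8, 2))),
                                factor(rep("b", 10), levels = c("a", "b"))))
  # AUC equals the Mann-Whitney U statistic over n1*n0 (pROC reference)
  set.seed(3)
  for (i in 1:10) {
    y <- factor(sample(c("x", "z"), 30, replace = TRUE))
    if (length(unique(y)) < 2) next
    sc <- rnorm(30)
    ref <- as.numeric(suppressMessages(pROC::auc(y, sc,
                                                 levels = c("x", "z"),
                                                 direction = "<")))
    expect_equal(aucFromScores(y, sc), ref, tolerance = 1e-12)
  }
})

test_that("a perfectly separating locus is classified and ranked first", {
  set.seed(5)
  n <- 60
  labels <- factor(rep(1:2, each = 30))
  x <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
  x[, 4] <- ifelse(labels == 1, 0L, 2L)       # perfect separator
  colnames(x) <- sprintf("L%d", 1:10)
  split <- mcSplit(labels, seed = 2)
  rr <- fitAndEvaluate(x, labels, split, assocConfig(n_trees = 300), seed = 2)
  expect_equal(rr$balancedAccuracy, 1)
  expect_equal(rr$auc, 1)
  expect_equal(names(which.max(rr$importance)), "L4")
})

test_that("chance-level data gives chance-level metrics", {
  set.seed(19)
  bas <- replicate(20, {
    n <- 100
    labels <- factor(rep(1:2, each = 50))
    x <- matrix(rbinom(n * 50, 2, 0.3), n, 50)
    split <- mcSplit(labels, seed = sample.int(1e6, 1))
    fitAndEvaluate(x, labels, split, assocConfig(n_trees = 200),
                   seed = sample.int(1e6, 1))$balancedAccuracy
  })
  expect_lt(abs(mean(bas) - 0.5), 0.05)
})

test_that("the identity permutation reproduces the unpermuted fit exactly", {
  set.seed(8)
  n <- 40
  labels <- factor(rep(1:2, each = 20))
  x <- matrix(rbinom(n * 12, 2, 0.4), n, 12)
  split <- mcSplit(labels, seed = 3)
  cfg <- assocConfig(n_trees = 150)
  a <- fitAndEvaluate(x, labels, split, cfg, seed = 10)
  b <- permutationControl(x, labels, split, cfg, seed = 10,
                          permutation = seq_along(split$train))
  expect_identical(a$balancedAccuracy, b$balancedAccuracy)
  expect_identical(a$auc, b$auc)
  expect_identical(a$importance, b$importance)
})

test_that("permuting training genotypes drops association to chance", {
  spec <- cohortSpec(n_subjects = 67, cluster_sizes = c(42, 25),
                     n_null_loci = 72, n_rare_loci = 0,
                     n_hwe_violating_loci = 0, n_control_loci = 0,
                     seed = 13)
  labels <- rep(1:2, c(42, 25))
  gd <- generateGenotypes(spec, labels)
  x <- t(dosage(gd))
  cfg <- assocConfig(n_trees = 500, n_repetitions = 10, seed = 13)
  bas <- auc <- numeric(10)
  for (r in 1:10) {
    split <- mcSplit(labels, seed = 13 + r)
    ctrl <- permutationControl(x, labels, split, cfg, seed = 13 + r)
    bas[r] <- ctrl$balancedAccuracy
    auc[r] <- ctrl$auc
  }
  expect_lt(abs(mean(bas) - 0.5), 0.05)
  expect_lt(abs(mean(auc) - 0.5), 0.1)
})

test_that("the full association harness summarizes runs and selects planted loci", {
  spec <- cohortSpec(n_subjects = 67, cluster_sizes = c(42, 25),
                     n_null_loci = 72, n_rare_loci = 0,
                     n_hwe_violating_loci = 0, n_control_loci = 0,
                     seed = 7)
  labels <- rep(1:2, c(42, 25))
  gd <- generateGenotypes(spec, labels)
  rep1 <- runAssociation(gd, labels,
                         assocConfig(n_trees = 500, n_repetitions = 5,
                                     seed = 7))
  expect_equal(nrow(rep1$runs), 5)
  expect_true(all(rep1$runs$balancedAccuracy >= 0 &
                  rep1$runs$balancedAccuracy <= 1))
  planted <- rownames(gd)[locusInfo(gd)$role == "associated"]
  expect_gte(sum(planted %in% rep1$finalSet), 5)
  # true-data AUC clearly exceeds its permutation control
  expect_gt(mean(rep1$runs$auc) - mean(rep1$runs$aucPermuted), 0.15)
  # reproducibility of the whole harness
  rep2 <- runAssociation(gd, labels,
                         assocConfig(n_trees = 500, n_repetitions = 5,
                                     seed = 7))
  expect_identical(rep1$runs, rep2$runs)
  expect_identical(rep1$finalSet, rep2$finalSet)
  # single repetition: degenerate percentile interval
  rep3 <- runAssociation(gd, labels,
                         assocConfig(n_trees = 200, n_repetitions = 1,
                                     seed = 3))
  s <- rep3$summary$balancedAccuracy
  expect_equal(unname(s["lo"]), unname(s["mean"]))
  expect_equal(unname(s["hi"]), unname(s["mean"]))
})

test_that("negative-control audit flags control loci in the final set", {
  info <- data.frame(gene = c("CYP2J2", "TRPV3"), control = c(TRUE, FALSE),
                     row.names = c("c1", "t1"))
  expect_true(negativeControlAudit(c("t1"), info)$pass)
  expect_false(negativeControlAudit(c("t1", "c1"), info)$pass)
  # vacuous pass without control loci
  info2 <- data.frame(gene = "TRPV3", control = FALSE, row.names = "t1")
  expect_true(negativeControlAudit("t1", info2)$pass)
})

test_that("gene tallies count initial and final sets and correlate them", {
  tab <- finalVariantTable()
  info <- data.frame(gene = tab$gene, control = FALSE,
                     row.names = tab$locus)
  gt <- geneTally(tab$locus, tab$locus, info)
  expect_equal(sum(gt$table$final), 38)
  expect_equal(gt$table$final[gt$table$gene == "TRPV3"], 10)
  expect_equal(gt$table$final[gt$table$gene == "TRPM3"], 6)
  # empty final set: all-zero tallies
  gt0 <- geneTally(character(), tab$locus, info)
  expect_true(all(gt0$table$final == 0))
  # correlation against the direct formula
  set.seed(1)
  genes <- sprintf("G%d", 1:8)
  info2 <- data.frame(gene = rep(genes, times = c(1, 2, 3, 4, 2, 5, 3, 4)),
                      control = FALSE,
                      row.names = sprintf("v%d", 1:24))
  fin <- sample(rownames(info2), 9)
  gt2 <- geneTally(fin, rownames(info2), info2)
  expect_equal(unname(gt2$correlation["r"]),
               cor(gt2$table$initial, gt2$table$final))
  # fewer than 3 genes: correlation undefined
  info3 <- data.frame(gene = rep(c("A", "B"), 2), control = FALSE,
                      row.names = sprintf("w%d", 1:4))
  expect_true(is.na(geneTally("w1", rownames(info3), info3)$correlation["r"]))
})
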