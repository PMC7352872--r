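#' Configuration of the random-forest association harness
#'
#' Defaults follow the reference analysis settings: 1500 trees, number of
#' candidate features per split ceil(0.2 * sqrt(d)), training on a
#' Monte-Carlo-resampled 2/3 of the subjects, 10 repetitions, and a
#' permuted-genotype control fitted alongside every run.
#'
#' @param n_trees trees per forest.
#' @param mtry_factor candidate features per split = ceiling of
#'   \code{mtry_factor * sqrt(d)}.
#' @param train_fraction fraction of subjects in the training split.
#' @param n_repetitions Monte-Carlo repetitions.
#' @param seed master seed.
#' @param permutation_control fit the permuted-training control each run.
#' @param importance \code{"permutation"}: out-of-bag mean decrease in
#'   accuracy when a locus is permuted (standard mean-decrease-accuracy);
#'   \code{"refit"}: slow literal exclusion-refit variant measuring the
#'   test-set accuracy drop when the locus is left out.
#' @param tune_trees optional integer vector; when given, the tree count
#'   is picked per run from this grid by smallest out-of-bag error.
#' @return list of class \code{"AssocConfig"}.
#' @export
assocConfig <- function(n_trees = 1500L, mtry_factor = 0.2,
                        train_fraction = 2 / 3, n_repetitions = 10L,
                        seed = 42L, permutation_control = TRUE,
                        importance = c("permutation", "refit"),
                        tune_trees = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (n_trees < 1 || n_repetitions < 1 || mtry_factor <= 0)
    stop("counts and mtry_factor must be positive")
  structure(list(n_trees = as.integer(n_trees),
                 mtry_factor = mtry_factor,
                 train_fraction = train_fraction,
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed),
                 permutation_control = isTRUE(permutation_control),
                 importance = match.arg(importance),
                 tune_trees = tune_trees),
            class = "AssocConfig")
}

.mtry <- function(d, factor = 0.2) max(1L, as.integer(ceiling(factor * sqrt(d))))

#' Stratified Monte-Carlo train/test split
#'
#' Splits \code{n} subjects into disjoint, exhaustive train and test sets
#' with train size \code{round(fraction * n)}, stratified by class
#' (largest-remainder allocation) so that both classes appear on both
#' sides.
#'
#' @param labels class labels (length n >= 6).
#' @param fraction training fraction (default 2/3).
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @examples
#' s <- mcSplit(rep(1:2, c(42, 25)), seed = 1)
#' length(s$train)   # 45 = round(2/3 * 67)
#' @export
mcSplit <- function(labels, fraction = 2 / 3, seed = 42L) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (n < 6) stop("at least 6 subjects are required for a stratified split")
  target <- round(fraction * n)
  cls <- levels(labels)
  sizes <- table(labels)
  exact <- fraction * as.numeric(sizes)
  base <- floor(exact)
  rem <- target - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(exact - base)
    base[ord[seq_len(-rem)]] <- base[ord[seq_len(-rem)]] - 1
  }
  # both classes must appear in train and test
  base <- pmax(1, pmin(as.numeric(sizes) - 1, base))
  if (sum(base) != target)
    target <- sum(base)
  set.seed(as.integer(seed))
  train <- unlist(lapply(seq_along(cls), function(k) {
    idx <- which(labels == cls[k])
    sample(idx, base[k])
  }))
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Balanced accuracy
#'
#' Mean of per-class recalls; equals plain accuracy on a balanced test set
#' and is invariant to class relabeling.
#'
#' @param truth,predicted factors of equal length.
#' @return value in [0, 1].
#' @export
balancedAccuracy <- function(truth, predicted) {
  truth <- as.factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  mean(vapply(levels(truth), function(lv)
    mean(predicted[truth == lv] == lv), numeric(1)))
}

#' Area under the ROC curve from scores
#'
#' Rank-based AUC (equivalent to the Mann-Whitney U statistic divided by
#' n1*n0), with average ranks for ties.
#'
#' @param truth binary factor; the second level is taken as positive.
#' @param score numeric score for the positive class (e.g. forest vote
#'   fraction).
#' @return AUC in [0, 1].
#' @export
aucFromScores <- function(truth, score) {
  truth <- as.factor(truth)
  pos <- truth == levels(truth)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.fitForest <- function(xtr, ytr, config) {
  d <- ncol(xtr)
  ntree <- config$n_trees
  if (!is.null(config$tune_trees)) {
    oob <- vapply(config$tune_trees, function(nt) {
      f <- randomForest::randomForest(xtr, ytr, ntree = nt,
                                      mtry = .mtry(d, config$mtry_factor))
      f$err.rate[nt, "OOB"]
    }, numeric(1))
    ntree <- config$tune_trees[which.min(oob)]
  }
  randomForest::randomForest(
    xtr, ytr, ntree = ntree, mtry = .mtry(d, config$mtry_factor),
    importance = TRUE)
}

#' Fit a random forest and evaluate one Monte-Carlo run
#'
#' Trains a forest (majority vote over \code{n_trees} trees, candidate
#' features per split ceil(mtry_factor * sqrt(d))) on the training
#' subjects and evaluates balanced accuracy and vote-fraction AUC-ROC on
#' the test subjects. Per-locus importance is the out-of-bag mean decrease
#' in accuracy under permutation of that locus (or the exclusion-refit
#' variant when configured).
#'
#' @param x subjects x loci numeric matrix (dosages).
#' @param labels binary class factor per subject.
#' @param split list with \code{train}/\code{test} indices (see
#'   \code{\link{mcSplit}}).
#' @param config an \code{\link{assocConfig}}.
#' @param permute_train optional permutation of the training rows of
#'   \code{x} applied before fitting (genotype-link destruction); the
#'   identity permutation reproduces the unpermuted fit.
#' @param seed seed for this run.
#' @return list of class \code{"RunResult"}: \code{balancedAccuracy},
#'   \code{auc}, \code{importance} (named, length d).
#' @export
fitAndEvaluate <- function(x, labels, split, config = assocConfig(),
                           permute_train = NULL, seed = 42L) {
  labels <- as.factor(labels)
  xtr <- x[split$train, , drop = FALSE]
  ytr <- droplevels(labels[split$train])
  if (nlevels(ytr) < 2) stop("training set must contain both classes")
  if (!is.null(permute_train))
    xtr <- xtr[permute_train, , drop = FALSE]
  set.seed(as.integer(seed))
  fit <- .fitForest(xtr, ytr, config)
  xte <- x[split$test, , drop = FALSE]
  yte <- labels[split$test]
  pred <- predict(fit, xte)
  votes <- predict(fit, xte, type = "vote")[, levels(labels)[2]]
  imp <- fit$importance[, "MeanDecreaseAccuracy"]
  if (config$importance == "refit") {
    full <- mean(predict(fit, xte) == yte)
    imp <- vapply(seq_len(ncol(x)), function(j) {
      f <- randomForest::randomForest(
        xtr[, -j, drop = FALSE], ytr, ntree = config$n_trees,
        mtry = .mtry(ncol(x) - 1, config$mtry_factor))
      full - mean(predict(f, xte[, -j, drop = FALSE]) == yte)
    }, numeric(1))
    names(imp) <- colnames(x)
  }
  structure(list(balancedAccuracy = balancedAccuracy(yte, pred),
                 auc = aucFromScores(yte, votes),
                 importance = imp),
            class = "RunResult")
}

#' Permuted-genotype control run
#'
#' Destroys the genotype-phenotype link by shuffling the subject-to-
#' genotype assignment within the training data (phenotype labels stay
#' fixed), then fits and evaluates exactly as \code{\link{fitAndEvaluate}}
#' on the untouched test data. A classifier trained this way should
#' perform at chance; systematically better performance indicates
#' overfitting of the harness.
#'
#' @inheritParams fitAndEvaluate
#' @param permutation optional explicit permutation of the training rows
#'   (test hook); default: a random shuffle drawn under \code{seed}.
#' @return A \code{"RunResult"}.
#' @export
permutationControl <- function(x, labels, split, config = assocConfig(),
                               seed = 42L, permutation = NULL) {
  if (is.null(permutation)) {
    set.seed(as.integer(seed) + 1L)
    permutation <- sample.int(length(split$train))
  }
  fitAndEvaluate(x, labels, split, config,
                 permute_train = permutation, seed = seed)
}

.summarize <- function(v) {
  c(mean = mean(v), lo = unname(quantile(v, 0.025)),
    hi = unname(quantile(v, 0.975)))
}

#' Monte-Carlo resampled random-forest association analysis
#'
#' Runs \code{n_repetitions} cycles of stratified 2/3-1/3 splitting,
#' forest fitting/evaluation and (optionally) the permuted-training
#' control; averages per-locus importances across runs (negative means are
#' clamped to zero, as negative mean-decrease-accuracy carries no yield);
#' selects the final most informative loci as the computed-ABC set "A" of
#' the mean importances; tallies genes in the initial versus final sets;
#' and audits the negative-control loci.
#'
#' @param gd a \linkS4class{GenotypeData} (post feature-selection filters).
#' @param labels binary phenotype cluster labels per subject.
#' @param config an \code{\link{assocConfig}}.
#' @return list of class \code{"AssociationReport"}: per-run metric table
#'   \code{runs}, metric \code{summary} (mean and 2.5-97.5 percentile
#'   interval), \code{importance} (mean per locus), \code{finalSet}
#'   (locus names of set "A"), \code{partition}, \code{geneTally},
#'   \code{controlAudit}, \code{chanceLevel} (TRUE when the true-data
#'   accuracy interval covers 0.5), \code{seeds}.
#' @export
runAssociation <- function(gd, labels, config = assocConfig()) {
  x <- t(dosage(gd))
  if (anyNA(x)) stop("association analysis requires complete genotypes")
  labels <- as.factor(labels)
  nrep <- config$n_repetitions
  seeds <- config$seed + seq_len(nrep)
  runs <- vector("list", nrep)
  ctrl <- vector("list", nrep)
  impMat <- matrix(0, nrep, ncol(x))
  for (r in seq_len(nrep)) {
    split <- mcSplit(labels, config$train_fraction, seed = seeds[r])
    rr <- fitAndEvaluate(x, labels, split, config, seed = seeds[r])
    runs[[r]] <- rr
    impMat[r, ] <- rr$importance
    if (config$permutation_control)
      ctrl[[r]] <- permutationControl(x, labels, split, config,
                                      seed = seeds[r])
  }
  runTab <- data.frame(
    repetition = seq_len(nrep),
    balancedAccuracy = vapply(runs, `[[`, numeric(1), "balancedAccuracy"),
    auc = vapply(runs, `[[`, numeric(1), "auc"))
  if (config$permutation_control) {
    runTab$balancedAccuracyPermuted <-
      vapply(ctrl, `[[`, numeric(1), "balancedAccuracy")
    runTab$aucPermuted <- vapply(ctrl, `[[`, numeric(1), "auc")
  }
  summary <- lapply(runTab[, -1, drop = FALSE], .summarize)
  meanImp <- pmax(colMeans(impMat), 0)
  names(meanImp) <- colnames(x)
  part <- abcPartition(meanImp)
  finalSet <- colnames(x)[part@setA]
  tally <- geneTally(finalSet, rownames(gd), locusInfo(gd))
  audit <- negativeControlAudit(finalSet, locusInfo(gd))
  chance <- summary$balancedAccuracy["lo"] <= 0.5 &&
    summary$balancedAccuracy["hi"] >= 0.5
  structure(list(runs = runTab, summary = summary, importance = meanImp,
                 finalSet = finalSet, partition = part, geneTally = tally,
                 controlAudit = audit, chanceLevel = unname(chance),
                 seeds = seeds, config = config),
            class = "AssociationReport")
}

#' @export
print.AssociationReport <- function(x, ...) {
  s <- x$summary
  cat(sprintf("AssociationReport: %d repetitions\n", nrow(x$runs)))
  cat(sprintf("  balanced accuracy %.3f [%.3f, %.3f]\n",
              s$balancedAccuracy["mean"], s$balancedAccuracy["lo"],
              s$balancedAccuracy["hi"]))
  cat(sprintf("  AUC-ROC           %.3f [%.3f, %.3f]\n",
              s$auc["mean"], s$auc["lo"], s$auc["hi"]))
  if (!is.null(s$balancedAccuracyPermuted))
    cat(sprintf("  permuted control  %.3f [%.3f, %.3f] (accuracy)\n",
                s$balancedAccuracyPermuted["mean"],
                s$balancedAccuracyPermuted["lo"],
                s$balancedAccuracyPermuted["hi"]))
  cat(sprintf("  final set 'A': %d loci; control audit: %s%s\n",
              length(x$finalSet),
              if (x$controlAudit$pass) "pass" else "FAIL",
              if (x$chanceLevel) " (performance at chance level)" else ""))
  invisible(x)
}

#' Audit the negative-control loci
#'
#' Passes if and only if no negative-control-flagged locus was selected
#' into the final set; vacuously passes when no control loci are present.
#'
#' @param finalSet character vector of selected locus ids (or an
#'   \code{"AssociationReport"}).
#' @param info locus metadata data.frame with a logical \code{control}
#'   column, row names = locus ids.
#' @return list with \code{pass}, \code{nControl}, \code{selectedControls}.
#' @export
negativeControlAudit <- function(finalSet, info) {
  if (inherits(finalSet, "AssociationReport"))
    finalSet <- finalSet$finalSet
  controls <- rownames(info)[info$control]
  bad <- intersect(finalSet, controls)
  list(pass = length(bad) == 0, nControl = length(controls),
       selectedControls = bad)
}

#' Per-gene variant tallies of the initial and final sets
#'
#' Counts variants per gene in the initial (pre-selection) and final
#' (selected) locus sets and reports the Pearson correlation between the
#' two per-gene count vectors (undefined, and reported as NA, with fewer
#' than 3 genes).
#'
#' @param finalSet,initialSet character vectors of locus ids.
#' @param info locus metadata with \code{gene}, row names = locus ids.
#' @return list with \code{table} (gene, initial, final),
#'   \code{correlation} (r, p or NA).
#' @export
geneTally <- function(finalSet, initialSet, info) {
  genes <- info[initialSet, "gene"]
  tab <- data.frame(gene = sort(unique(genes)))
  tab$initial <- vapply(tab$gene, function(g)
    sum(genes == g, na.rm = TRUE), numeric(1))
  finGenes <- info[finalSet, "gene"]
  tab$final <- vapply(tab$gene, function(g)
    sum(finGenes == g, na.rm = TRUE), numeric(1))
  corr <- if (nrow(tab) >= 3 && sd(tab$initial) > 0 && sd(tab$final) > 0) {
    ct <- cor.test(tab$initial, tab$final)
    c(r = unname(ct$estimate), p = ct$p.value)
  } else c(r = NA_real_, p = NA_real_)
  list(table = tab, correlation = corr)
}
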