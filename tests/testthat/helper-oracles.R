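# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity from first principles and do
# not share code with the package internals.

# Silhouette by direct O(n^2) looping over the definition.
oracleSilhouette <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    dmat[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(dmat[i, own])
    b <- Inf
    for (lv in unique(labels)) {
      if (lv == labels[i]) next
      b <- min(b, mean(dmat[i, labels == lv]))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Exhaustive evaluation of both ABC limit criteria over all candidate
# indices, on the sorted values.
oracleAbcLimits <- function(values) {
  v <- sort(values, decreasing = TRUE)
  n <- length(v)
  tot <- sum(v)
  bestD <- Inf; limAB <- NA_integer_
  for (i in seq_len(n)) {
    xi <- i / n
    yi <- sum(v[seq_len(i)]) / tot
    d <- sqrt(xi^2 + (1 - yi)^2)
    if (d < bestD) { bestD <- d; limAB <- i }
  }
  limBC <- n
  for (i in seq_len(n)) {
    if (i < limAB) next
    marginal <- v[i] / tot
    if (n * marginal < 1) { limBC <- i; break }
  }
  list(limitAB = limAB, limitBC = max(limBC, limAB))
}

# Exact HWE p-value by enumeration of all genotype configurations with the
# observed subject and allele counts, probabilities from the conditioned
# multinomial (any HWE allele frequency gives the same conditional law).
oracleHweP <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- n1 + 2 * n2             # alt allele count
  q <- max(min(na / (2 * n), 0.9), 0.1)  # arbitrary interior frequency
  probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  configs <- list()
  for (h in 0:n) {
    n2c <- (na - h) / 2
    if (n2c < 0 || n2c != round(n2c)) next
    n0c <- n - h - n2c
    if (n0c < 0) next
    configs[[length(configs) + 1L]] <- c(n0c, h, n2c)
  }
  pr <- vapply(configs, function(cf) dmultinom(cf, prob = probs), numeric(1))
  pr <- pr / sum(pr)
  obs <- which(vapply(configs, function(cf) cf[2] == n1, logical(1)))
  sum(pr[pr <= pr[obs] * (1 + 1e-9)])
}

# Repeated-measures ANOVA sums of squares computed directly from the
# textbook decomposition for a between x within design.
oracleRmAnova <- function(values, cluster, subject, test) {
  grand <- mean(values)
  n <- length(unique(subject))
  t <- length(unique(test))
  ssTotal <- sum((values - grand)^2)
  subjMean <- tapply(values, subject, mean)
  ssSubj <- t * sum((subjMean - grand)^2)
  clMeanBySubj <- tapply(cluster, subject, function(z) z[1])
  clMean <- tapply(values, cluster, mean)
  nPerCl <- table(clMeanBySubj)
  ssCluster <- t * sum(nPerCl * (clMean[names(nPerCl)] - grand)^2)
  ssSubjErr <- ssSubj - ssCluster
  testMean <- tapply(values, test, mean)
  ssTest <- n * sum((testMean - grand)^2)
  cellMean <- tapply(values, list(cluster, test), mean)
  ssCells <- 0
  for (g in rownames(cellMean)) for (v in colnames(cellMean))
    ssCells <- ssCells + nPerCl[g] * (cellMean[g, v] - grand)^2
  ssInter <- ssCells - ssCluster - ssTest
  ssErr <- ssTotal - ssSubj - ssTest - ssInter
  dfCl <- length(clMean) - 1
  dfSubjErr <- n - length(clMean)
  dfTest <- t - 1
  dfInter <- dfCl * dfTest
  dfErr <- dfSubjErr * dfTest
  list(
    Fcluster = (ssCluster / dfCl) / (ssSubjErr / dfSubjErr),
    Ftest = (ssTest / dfTest) / (ssErr / dfErr),
    Finter = (ssInter / dfInter) / (ssErr / dfErr))
}

# Pearson chi-squared on a 2x2 table, textbook formula.
oracleChi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small labelled cohort for genotype-stage tests
makeTinyGd <- function(codes, labels = NULL, control = NULL) {
  d <- matrix(as.integer(unlist(codes)), nrow = length(codes), byrow = TRUE)
  rownames(d) <- sprintf("L%d", seq_len(nrow(d)))
  info <- data.frame(gene = sprintf("G%d", seq_len(nrow(d))),
                     control = if (is.null(control)) FALSE else control,
                     row.names = rownames(d))
  GenotypeData(d, info)
}
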