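#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test for deviation from Hardy-Weinberg proportions at a
#' biallelic locus. Given \code{n} genotyped subjects and the minor-allele
#' count, all feasible heterozygote counts (same parity as the minor-allele
#' count) are enumerated; each configuration's probability conditional on
#' the allele counts is
#' \deqn{P(n_{het} = h) = \frac{n!\,2^h}{n_{hom.maj}!\,h!\,n_{hom.min}!}
#'   \cdot \frac{n_a!\,n_b!}{(2n)!}}
#' and the p-value is the total probability of configurations no more
#' probable than the observed one.
#'
#' @param n0,n1,n2 counts of subjects with 0, 1 and 2 non-reference alleles.
#' @return Two-sided exact p-value. A monomorphic locus returns 1 by
#'   convention.
#' @examples
#' hweExactTest(10, 0, 10)   # extreme heterozygote deficit, p ~ 1e-6
#' @export
hweExactTest <- function(n0, n1, n2) {
  if (any(c(n0, n1, n2) < 0) || n0 + n1 + n2 < 1)
    stop("genotype counts must be non-negative with at least one subject")
  n <- n0 + n1 + n2
  nAlt <- n1 + 2 * n2
  nMinor <- min(nAlt, 2 * n - nAlt)
  if (nMinor == 0) return(1)
  h <- seq(nMinor %% 2, nMinor, by = 2)        # feasible het counts
  homMin <- (nMinor - h) / 2
  homMaj <- n - h - homMin
  logp <- lfactorial(n) + h * log(2) -
    (lfactorial(homMaj) + lfactorial(h) + lfactorial(homMin))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  pObs <- prob[match(n1, h)]
  sum(prob[prob <= pObs * (1 + 1e-10)])
}

#' Shannon information content of a gene locus
#'
#' Binary entropy (in nats) of observing versus not observing a variant
#' allele at a locus:
#' \deqn{Info = -p_0 \ln p_0 - p_1 \ln p_1}
#' with the \eqn{0 \ln 0 = 0} convention. By default \eqn{p_1} is the
#' carrier fraction (subjects with at least one variant allele); the
#' allele-based reading (\eqn{p_1} = variant-allele frequency) is available
#' via \code{basis = "allele"}.
#'
#' @inheritParams hweExactTest
#' @param basis \code{"carrier"} (default) or \code{"allele"}.
#' @return Information in nats, in \eqn{[0, \ln 2]}.
#' @examples
#' shannonInfo(5, 3, 2)           # p1 = 0.5 -> ln 2
#' shannonInfo(8, 1, 1)           # p1 = 0.2 -> 0.5004
#' @export
shannonInfo <- function(n0, n1, n2, basis = c("carrier", "allele")) {
  basis <- match.arg(basis)
  n <- n0 + n1 + n2
  if (n < 1) stop("at least one genotyped subject is required")
  p1 <- if (basis == "carrier") (n1 + n2) / n else (n1 + 2 * n2) / (2 * n)
  p0 <- 1 - p1
  xlx <- function(p) ifelse(p > 0, p * log(p), 0)
  -xlx(p0) - xlx(p1)
}

.locusCounts <- function(dosage) {
  # per-locus genotype counts over non-missing subjects
  t(apply(dosage, 1L, function(g) {
    g <- g[!is.na(g)]
    c(n0 = sum(g == 0L), n1 = sum(g == 1L), n2 = sum(g == 2L))
  }))
}

#' Per-locus summary statistics
#'
#' Computes, for every locus of a \linkS4class{GenotypeData}, the genotype
#' counts, carrier fraction, variant-allele frequency, exact Hardy-Weinberg
#' p-value and Shannon information.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param basis entropy basis, see \code{\link{shannonInfo}}.
#' @return data.frame with one row per locus.
#' @export
locusStats <- function(gd, basis = c("carrier", "allele")) {
  basis <- match.arg(basis)
  cnt <- .locusCounts(dosage(gd))
  n <- rowSums(cnt)
  data.frame(
    locus = rownames(gd),
    n0 = cnt[, 1], n1 = cnt[, 2], n2 = cnt[, 3],
    carrierFraction = (cnt[, 2] + cnt[, 3]) / n,
    alleleFrequency = (cnt[, 2] + 2 * cnt[, 3]) / (2 * n),
    hweP = vapply(seq_len(nrow(cnt)), function(i)
      hweExactTest(cnt[i, 1], cnt[i, 2], cnt[i, 3]), numeric(1)),
    info = vapply(seq_len(nrow(cnt)), function(i)
      shannonInfo(cnt[i, 1], cnt[i, 2], cnt[i, 3], basis), numeric(1)),
    row.names = NULL)
}

#' Hardy-Weinberg equilibrium filter
#'
#' Removes loci whose exact Hardy-Weinberg p-value falls below
#' \code{alpha}, flagging likely genotyping artifacts.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param alpha exclusion level (default 0.05).
#' @return list with \code{genotypes} (filtered \code{GenotypeData}) and
#'   \code{report} (data.frame: locus, hweP, removed).
#' @export
hweFilter <- function(gd, alpha = 0.05) {
  st <- locusStats(gd)
  removed <- st$hweP < alpha
  list(genotypes = gd[!removed, ],
       report = data.frame(locus = st$locus, hweP = st$hweP,
                           removed = removed))
}

#' Shannon-information filter with computed ABC cutoff
#'
#' Scores every locus by its Shannon information content and retains the
#' loci falling into the ABC set chosen by \code{retain} (default "A", the
#' most informative loci); the cutoff is computed from the data by
#' \code{\link{abcPartition}}, not fixed a priori.
#'
#' @inheritParams locusStats
#' @param retain \code{"A"} (default) or \code{"AB"}.
#' @return list with \code{genotypes}, \code{report} (locus, info, kept) and
#'   the \code{partition}.
#' @export
informativeFilter <- function(gd, basis = c("carrier", "allele"),
                              retain = c("A", "AB")) {
  retain <- match.arg(retain)
  if (!nrow(gd)) stop("empty genotype matrix")
  st <- locusStats(gd, basis = match.arg(basis))
  part <- abcPartition(setNames(st$info, st$locus))
  keep <- if (retain == "A") part@setA else c(part@setA, part@setB)
  kept <- seq_len(nrow(gd)) %in% keep
  list(genotypes = gd[kept, ],
       report = data.frame(locus = st$locus, info = st$info, kept = kept),
       partition = part)
}

#' Per-locus chi-squared effect size versus phenotype clusters
#'
#' For each locus, builds the 2x2 contingency table of allele counts
#' (variant versus reference, two alleles per subject) by cluster and
#' returns the Pearson chi-squared statistic without continuity correction.
#' Subjects with a missing call at a locus are dropped for that locus; a
#' locus monomorphic in the combined sample yields 0.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param labels cluster labels (2 levels) aligned with subjects.
#' @return named numeric vector of chi-squared statistics, one per locus.
#' @export
chi2Effect <- function(gd, labels) {
  d <- dosage(gd)
  labels <- as.factor(labels)
  if (length(labels) != ncol(d))
    stop("labels must align with subjects")
  if (nlevels(labels) != 2) stop("exactly two cluster labels are required")
  g1 <- labels == levels(labels)[1]
  vapply(seq_len(nrow(d)), function(i) {
    g <- d[i, ]
    ok <- !is.na(g)
    a <- sum(g[ok & g1]); n1s <- sum(ok & g1)      # variant alleles, cluster 1
    b <- sum(g[ok & !g1]); n2s <- sum(ok & !g1)
    tab <- matrix(c(a, 2 * n1s - a, b, 2 * n2s - b), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(0)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }, numeric(1), USE.NAMES = FALSE) |> setNames(rownames(d))
}

#' Chi-squared effect-size filter with computed ABC cutoff
#'
#' Retains the loci whose cluster-association chi-squared statistic falls
#' into the ABC set chosen by \code{retain} (default "A").
#'
#' @inheritParams chi2Effect
#' @param retain \code{"A"} (default) or \code{"AB"}.
#' @return list with \code{genotypes}, \code{report} (locus, chi2, kept) and
#'   the \code{partition}.
#' @export
effectSizeFilter <- function(gd, labels, retain = c("A", "AB")) {
  retain <- match.arg(retain)
  chi2 <- chi2Effect(gd, labels)
  part <- abcPartition(chi2)
  keep <- if (retain == "A") part@setA else c(part@setA, part@setB)
  kept <- seq_len(nrow(gd)) %in% keep
  list(genotypes = gd[kept, ],
       report = data.frame(locus = names(chi2), chi2 = unname(chi2),
                           kept = kept),
       partition = part)
}

#' Per-cluster variant-allele frequencies
#'
#' Variant-allele count divided by twice the number of non-missing subjects,
#' per locus and cluster, in percent (the convention used for reporting
#' cluster-wise allelic frequencies).
#'
#' @inheritParams chi2Effect
#' @return matrix loci x clusters of frequencies in percent.
#' @export
clusterAlleleFrequencies <- function(gd, labels) {
  d <- dosage(gd)
  labels <- as.factor(labels)
  if (length(labels) != ncol(d)) stop("labels must align with subjects")
  out <- sapply(levels(labels), function(lv) {
    sel <- labels == lv
    apply(d[, sel, drop = FALSE], 1L, function(g) {
      g <- g[!is.na(g)]
      if (!length(g)) return(NA_real_)
      100 * sum(g) / (2 * length(g))
    })
  })
  out <- matrix(out, nrow = nrow(d),
                dimnames = list(rownames(d), levels(labels)))
  out
}

#' Variant class proportions
#'
#' @param info a locus metadata data.frame with a \code{class} column (or a
#'   \linkS4class{GenotypeData}).
#' @return named numeric vector of percentages per variant class, summing
#'   to 100.
#' @export
variantClassSummary <- function(info) {
  if (is(info, "GenotypeData")) info <- locusInfo(info)
  if (!nrow(info)) stop("empty locus table")
  cls <- factor(info$class, levels = .VARIANT_CLASSES)
  100 * table(cls) / nrow(info)
}
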