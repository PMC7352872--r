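.PHENO_VARS <- c("zHPT_baseline", "zHPT_UVB", "zCPT_baseline", "zCPT_UVB")
.ION_GENES <- c("ASIC1", "ASIC2", "ASIC3", "ASIC4", "TRPA1", "TRPC1",
                "TRPM2", "TRPM3", "TRPM4", "TRPM5", "TRPM8", "TRPV1",
                "TRPV2", "TRPV3", "TRPV4")
.CONTROL_GENES <- c("CYP2J2", "CYP2C9", "CYP2C19")

.deriveSeed <- function(seed, stream) {
  # independent per-component streams from one master seed; keep < 2^31
  as.integer((as.numeric(seed) * 1103L + stream * 7919) %% 2147483629)
}

#' Specification of a synthetic thermal-pain cohort
#'
#' Bundles the design parameters of the synthetic cohort generator: two
#' phenotype clusters differing mainly in baseline heat/cold pain
#' sensitivity, a strongly correlated cold-threshold pair, and a genotype
#' panel of cluster-associated, Hardy-Weinberg-conforming null, rare
#' near-monomorphic, deliberately HWE-violating, and negative-control-gene
#' loci.
#'
#' Defaults emulate the study conditions: 82 phenotyped subjects in
#' clusters of 51 and 31, a cold-pair correlation of 0.812, cluster mean
#' separations derived from the reported between-cluster Welch statistics
#' (about 3.6 z-units for baseline cold, 2.1 for post-UV-B cold, 1.4/1.2
#' for heat), and eight associated loci with cluster allele-frequency
#' pairs patterned on the published final-selection table (differentials
#' 0.25-0.35).
#'
#' @param n_subjects total subjects.
#' @param cluster_sizes integer pair summing to \code{n_subjects}.
#' @param phenotype_effects named numeric: mean shift (cluster 1 minus
#'   cluster 2, z-units) per threshold variable.
#' @param cold_correlation Pearson correlation imposed on the bivariate
#'   normal draw of the two cold thresholds, in (-1, 1).
#' @param uvb_shift named numeric: overall right-shift of the post-UV-B
#'   columns (hypersensitization), heat and cold.
#' @param heat_uvb_coupling correlation of the post-UV-B heat threshold
#'   with its baseline, so derived UV-B effects are non-degenerate.
#' @param n_assoc_loci,n_null_loci,n_rare_loci,n_hwe_violating_loci,n_control_loci
#'   locus panel composition.
#' @param assoc_freqs 2-column matrix (or coercible) of per-cluster variant
#'   allele frequencies for the associated loci, values in [0, 1].
#' @param seed master integer seed; one derived stream per component.
#' @return A validated list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(n_subjects = 82L,
                       cluster_sizes = c(51L, 31L),
                       phenotype_effects = c(zHPT_baseline = 1.4,
                                             zHPT_UVB = 1.2,
                                             zCPT_baseline = 3.6,
                                             zCPT_UVB = 2.1),
                       cold_correlation = 0.812,
                       uvb_shift = c(heat = 1.0, cold = 0.3),
                       heat_uvb_coupling = 0.6,
                       n_assoc_loci = 8L,
                       n_null_loci = 72L,
                       n_rare_loci = 40L,
                       n_hwe_violating_loci = 10L,
                       n_control_loci = 51L,
                       assoc_freqs = cbind(
                         c(0.39, 0.20, 0.45, 0.30, 0.25, 0.50, 0.35, 0.16),
                         c(0.66, 0.50, 0.15, 0.60, 0.55, 0.22, 0.65, 0.44)),
                       seed = 42L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               cluster_sizes = as.integer(cluster_sizes),
               phenotype_effects = phenotype_effects,
               cold_correlation = cold_correlation,
               uvb_shift = uvb_shift,
               heat_uvb_coupling = heat_uvb_coupling,
               n_assoc_loci = as.integer(n_assoc_loci),
               n_null_loci = as.integer(n_null_loci),
               n_rare_loci = as.integer(n_rare_loci),
               n_hwe_violating_loci = as.integer(n_hwe_violating_loci),
               n_control_loci = as.integer(n_control_loci),
               assoc_freqs = as.matrix(assoc_freqs),
               seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  validateCohortSpec(spec)
  spec
}

#' @rdname cohortSpec
#' @param spec an object to validate.
#' @export
validateCohortSpec <- function(spec) {
  if (length(spec$cluster_sizes) != 2 || any(spec$cluster_sizes < 0))
    stop("cluster_sizes must be two non-negative counts")
  if (sum(spec$cluster_sizes) != spec$n_subjects)
    stop("cluster sizes must sum to n_subjects")
  if (!is.finite(spec$cold_correlation) ||
      abs(spec$cold_correlation) >= 1)
    stop("cold_correlation must lie strictly inside (-1, 1)")
  if (spec$n_assoc_loci > 0) {
    if (nrow(spec$assoc_freqs) < spec$n_assoc_loci)
      stop("assoc_freqs must provide one frequency pair per associated locus")
    if (any(spec$assoc_freqs < 0 | spec$assoc_freqs > 1))
      stop("allele frequencies must lie in [0, 1]")
  }
  counts <- c(spec$n_assoc_loci, spec$n_null_loci, spec$n_rare_loci,
              spec$n_hwe_violating_loci, spec$n_control_loci)
  if (any(counts < 0)) stop("locus counts must be non-negative")
  invisible(spec)
}

#' Generate synthetic thermal-pain phenotypes
#'
#' Draws z-scored heat/cold pain thresholds for two subject clusters. The
#' two cold thresholds come from a bivariate normal with the requested
#' correlation; the post-UV-B heat threshold is the baseline plus a shifted
#' correlated component, so that derived UV-B effects are non-degenerate.
#' Within-cluster noise is unit-variance Gaussian (the inputs are z-scores
#' by construction); clusters are shifted by \code{phenotype_effects}.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return list with \code{phenotypes} (data.frame: subject plus the four
#'   threshold columns) and \code{labels} (true cluster of each subject,
#'   for validation only).
#' @export
generatePhenotypes <- function(spec) {
  validateCohortSpec(spec)
  n <- spec$n_subjects
  if (n == 0)
    return(list(phenotypes = data.frame(
      subject = character(), zHPT_baseline = numeric(),
      zHPT_UVB = numeric(), zCPT_baseline = numeric(),
      zCPT_UVB = numeric()), labels = integer()))
  set.seed(.deriveSeed(spec$seed, 1L))
  labels <- rep(1:2, spec$cluster_sizes)
  eff <- spec$phenotype_effects[.PHENO_VARS]
  eff[is.na(eff)] <- 0
  # cluster means: cluster 1 sits +eff/2, cluster 2 -eff/2
  mu <- outer(ifelse(labels == 1, 0.5, -0.5), eff)
  colnames(mu) <- .PHENO_VARS
  mu[, "zHPT_UVB"] <- mu[, "zHPT_UVB"] + spec$uvb_shift[["heat"]]
  mu[, "zCPT_UVB"] <- mu[, "zCPT_UVB"] + spec$uvb_shift[["cold"]]
  rho <- spec$cold_correlation
  a <- spec$heat_uvb_coupling
  hb <- rnorm(n)
  hu <- a * hb + sqrt(1 - a^2) * rnorm(n)
  cb <- rnorm(n)
  cu <- rho * cb + sqrt(1 - rho^2) * rnorm(n)
  tab <- data.frame(subject = sprintf("S%03d", seq_len(n)),
                    zHPT_baseline = mu[, 1] + hb,
                    zHPT_UVB = mu[, 2] + hu,
                    zCPT_baseline = mu[, 3] + cb,
                    zCPT_UVB = mu[, 4] + cu)
  list(phenotypes = tab, labels = labels)
}

#' Generate synthetic genotype data for a labelled cohort
#'
#' Builds the locus panel declared in the cohort specification: associated loci draw
#' per-subject allele dosages Binomial(2, q) with cluster-specific variant
#' frequencies; null and negative-control loci are in Hardy-Weinberg
#' proportions with q ~ U(0.05, 0.5); rare loci carry at most two
#' heterozygous carriers; HWE-violating loci are generated without
#' heterozygotes (all variant alleles homozygous), a strong equilibrium
#' distortion. Control loci are flagged and assigned cytochrome P450 gene
#' names; all other loci cycle through the ion-channel gene panel. The
#' per-locus \code{role} column records the planted truth for validation.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param labels cluster labels of length \code{n_subjects}.
#' @return A \linkS4class{GenotypeData}.
#' @export
generateGenotypes <- function(spec, labels) {
  validateCohortSpec(spec)
  n <- spec$n_subjects
  if (length(labels) != n) stop("labels length must equal n_subjects")
  set.seed(.deriveSeed(spec$seed, 2L))
  rows <- list(); role <- character(); gene <- character()
  ctrl <- logical()
  drawHwe <- function(q) rbinom(n, 2L, q)
  for (i in seq_len(spec$n_assoc_loci)) {
    q <- spec$assoc_freqs[i, ]
    rows[[length(rows) + 1L]] <- rbinom(n, 2L, q[labels])
    role <- c(role, "associated"); ctrl <- c(ctrl, FALSE)
  }
  for (i in seq_len(spec$n_null_loci)) {
    rows[[length(rows) + 1L]] <- drawHwe(runif(1, 0.05, 0.5))
    role <- c(role, "null"); ctrl <- c(ctrl, FALSE)
  }
  for (i in seq_len(spec$n_rare_loci)) {
    g <- integer(n)
    if (n > 0) g[sample.int(n, min(n, sample(1:2, 1)))] <- 1L
    rows[[length(rows) + 1L]] <- g
    role <- c(role, "rare"); ctrl <- c(ctrl, FALSE)
  }
  for (i in seq_len(spec$n_hwe_violating_loci)) {
    q <- runif(1, 0.3, 0.5)
    rows[[length(rows) + 1L]] <- 2L * rbinom(n, 1L, q)  # no heterozygotes
    role <- c(role, "hwe_violating"); ctrl <- c(ctrl, FALSE)
  }
  for (i in seq_len(spec$n_control_loci)) {
    rows[[length(rows) + 1L]] <- drawHwe(runif(1, 0.05, 0.5))
    role <- c(role, "control"); ctrl <- c(ctrl, TRUE)
  }
  nl <- length(rows)
  d <- if (nl) do.call(rbind, rows) else matrix(integer(), 0, n)
  gene <- character(nl)
  gene[!ctrl] <- rep_len(.ION_GENES, sum(!ctrl))
  gene[ctrl] <- rep_len(.CONTROL_GENES, sum(ctrl))
  chrom <- match(gene, c(.ION_GENES, .CONTROL_GENES))
  pos <- 1e6L + seq_len(nl) * 1000L
  ids <- sprintf("X%d.%d.SNV", chrom, pos)
  colnames(d) <- sprintf("S%03d", seq_len(n))
  rownames(d) <- ids
  GenotypeData(d, data.frame(gene = gene, chrom = chrom, pos = pos,
                             class = "SNV", dbsnp = NA_character_,
                             control = ctrl, role = role,
                             row.names = ids))
}

#' Generate synthetic functional-score sets
#'
#' Draws Gaussian stand-ins for variant functional-impact score sets (e.g.
#' the selected-set / positive-control / negative-control comparison) at
#' the requested moments.
#'
#' @param means,sds,sizes equal-length vectors of set means, standard
#'   deviations (> 0) and sizes (>= 1).
#' @param seed integer seed.
#' @param labels optional set names.
#' @return named list of numeric vectors.
#' @export
generateScoreSets <- function(means, sds, sizes, seed = 42L,
                              labels = NULL) {
  k <- length(means)
  if (length(sds) != k || length(sizes) != k)
    stop("means, sds and sizes must have equal length")
  if (any(sds <= 0)) stop("standard deviations must be positive")
  if (any(sizes < 1)) stop("set sizes must be at least 1")
  set.seed(.deriveSeed(seed, 3L))
  out <- lapply(seq_len(k), function(i) rnorm(sizes[i], means[i], sds[i]))
  names(out) <- if (!is.null(labels)) labels else
    sprintf("set%d", seq_len(k))
  out
}

#' Read/write a phenotype table as CSV
#'
#' @param file path of the CSV (columns: subject id plus named z-score
#'   columns).
#' @return \code{readPhenotypeCsv}: the phenotype data.frame.
#' @export
readPhenotypeCsv <- function(file) {
  read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname readPhenotypeCsv
#' @param table phenotype data.frame.
#' @export
writePhenotypeCsv <- function(table, file) {
  write.csv(table, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
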