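#' Pipeline configuration
#'
#' Assembles all stage parameters with defaults equal to the reference
#' analysis settings: 50 x 80 ESOM grid trained for 20 epochs, two
#' clusters, correlation screen at |r| > 0.8, Hardy-Weinberg exclusion at
#' alpha = 0.05, ABC retention of set "A" at both filter stages, and a
#' 1500-tree forest harness with mtry = ceil(0.2 sqrt(d)), 2/3 training
#' fraction and 10 Monte-Carlo repetitions. A YAML file with any subset of
#' these keys can override them.
#'
#' @param file optional YAML configuration file.
#' @param ... named overrides applied after the file.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(file = NULL, ...) {
  cfg <- list(
    phenotype_csv = NULL,        # input paths; NULL -> simulate
    genotype_vcf = NULL,
    genotype_tsv = NULL,
    locus_info_tsv = NULL,
    score_tsv = NULL,
    simulate = list(),           # cohortSpec() overrides
    esom = list(rows = 50L, cols = 80L, epochs = 20L),
    k_clusters = 2L,
    correlation_threshold = 0.8,
    hwe_alpha = 0.05,
    abc_retain = "A",
    assoc = list(n_trees = 1500L, mtry_factor = 0.2,
                 train_fraction = 2 / 3, n_repetitions = 10L),
    seed = 42L,
    outdir = NULL)
  if (!is.null(file)) {
    over <- yaml::read_yaml(file)
    cfg <- utils::modifyList(cfg, over)
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  class(cfg) <- "PipelineConfig"
  cfg
}

.writeStage <- function(outdir, name, writer) {
  if (is.null(outdir)) return(invisible(NULL))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  path <- file.path(outdir, name)
  if (file.exists(path))
    stop("refusing to overwrite existing output: ", path)
  writer(path)
  invisible(path)
}

#' Phenotype construction stage
#'
#' Derives UV-B effects, screens for strongly correlated variables,
#' decorrelates each block by PCA (eigenvalue > 1 retention), projects the
#' post-decorrelation feature set with an ESOM, extracts \code{k} U-matrix
#' watershed clusters, validates them with the silhouette index, explains
#' them with induced rules over the original six variables and compares
#' the clusters statistically.
#'
#' @param table phenotype data.frame (four threshold columns and subject
#'   ids).
#' @param config a \code{\link{pipelineConfig}}.
#' @param sex optional per-subject sex labels.
#' @return list: \code{table} (with UV-B effects), \code{screen},
#'   \code{pca} (per block), \code{features} (matrix used for
#'   projection), \code{model}, \code{umatrix}, \code{labels},
#'   \code{silhouette}, \code{rules}, \code{stats}.
#' @export
phenotypeStage <- function(table, config = pipelineConfig(), sex = NULL) {
  table <- deriveUvbEffects(table)
  vars6 <- c(.PHENO_VARS, "UVBEff_Heat", "UVBEff_Cold")
  screen <- correlationScreen(table, config$correlation_threshold,
                              vars = .PHENO_VARS)
  feats <- table[, setdiff(vars6, unlist(screen$blocks)), drop = FALSE]
  pca <- list()
  for (b in seq_along(screen$blocks)) {
    blk <- screen$blocks[[b]]
    pb <- pcaDecorrelate(table, blk, prefix = sprintf("PC%d_", b))
    pca[[b]] <- pb
    feats <- cbind(feats, as.data.frame(pb$scores))
  }
  x <- scale(as.matrix(feats))
  model <- trainEsom(x, rows = config$esom$rows, cols = config$esom$cols,
                     epochs = config$esom$epochs, seed = config$seed)
  um <- computeUMatrix(model, x)
  labels <- extractClusters(um, k = config$k_clusters, data = x)
  sil <- silhouetteIndex(x, labels)
  rules <- induceRules(table, labels, vars = vars6, seed = config$seed)
  stats <- clusterStats(table, labels, sex = sex, vars = vars6)
  list(table = table, screen = screen, pca = pca, features = x,
       model = model, umatrix = um, labels = labels, silhouette = sil,
       rules = rules, stats = stats)
}

#' Genotype preprocessing stage
#'
#' Applies the fixed filter funnel to an encoded genotype matrix: exact
#' Hardy-Weinberg exclusion, Shannon-information/ABC retention, then
#' chi-squared effect-size/ABC retention against the phenotype clusters.
#' The per-stage locus counts are recorded.
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param labels binary phenotype cluster labels aligned with the
#'   genotyped subjects.
#' @param config a \code{\link{pipelineConfig}}.
#' @return list: \code{genotypes} (filtered), \code{funnel} (stage,
#'   loci), \code{hwe}, \code{shannon}, \code{chi2} stage reports.
#' @export
prepareStage <- function(gd, labels, config = pipelineConfig()) {
  funnel <- data.frame(stage = "initial", loci = nrow(gd))
  hwe <- hweFilter(gd, alpha = config$hwe_alpha)
  funnel <- rbind(funnel, data.frame(stage = "post_hwe",
                                     loci = nrow(hwe$genotypes)))
  shan <- informativeFilter(hwe$genotypes, retain = config$abc_retain)
  funnel <- rbind(funnel, data.frame(stage = "post_shannon",
                                     loci = nrow(shan$genotypes)))
  chi2 <- effectSizeFilter(shan$genotypes, labels,
                           retain = config$abc_retain)
  funnel <- rbind(funnel, data.frame(stage = "post_chi2",
                                     loci = nrow(chi2$genotypes)))
  list(genotypes = chi2$genotypes, funnel = funnel,
       hwe = hwe$report, shannon = shan$report, chi2 = chi2$report)
}

#' Run the full genotype-phenotype association pipeline
#'
#' Executes phenotype construction, cluster discovery, genotype
#' preprocessing, the Monte-Carlo random-forest association with
#' permutation control and negative-control audit, and (when scores are
#' supplied) the functional-score comparison. Inputs are read from the
#' paths in the configuration or, when none are given, simulated with
#' \code{\link{cohortSpec}} under the configured seed. When
#' \code{config$outdir} is set, every stage's outputs are written as
#' TSV/JSON (existing files are never silently overwritten).
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list of class \code{"PipelineReport"} with elements
#'   \code{phenotype}, \code{prepare}, \code{association},
#'   \code{scoreComparison} (or NULL), \code{funnel}, \code{config}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  simulated <- is.null(config$phenotype_csv)
  truth <- NULL
  if (simulated) {
    spec <- do.call(cohortSpec,
                    c(config$simulate, list(seed = config$seed)))
    ph <- generatePhenotypes(spec)
    pheno <- ph$phenotypes
    truth <- ph$labels
    gd <- generateGenotypes(spec, ph$labels)
  } else {
    pheno <- readPhenotypeCsv(config$phenotype_csv)
    gd <- if (!is.null(config$genotype_vcf))
      readGenotypesVcf(config$genotype_vcf, config$locus_info_tsv)
    else if (!is.null(config$genotype_tsv))
      readGenotypesTsv(config$genotype_tsv, config$locus_info_tsv)
    else stop("no genotype input configured")
  }
  phen <- phenotypeStage(pheno, config)
  # align genotyped subjects with phenotyped subjects by id
  common <- intersect(colnames(gd), pheno$subject)
  if (!length(common)) stop("no overlap between genotyped and phenotyped subjects")
  gd <- gd[, common]
  labels <- phen$labels[match(common, pheno$subject)]
  prep <- prepareStage(gd, labels, config)
  assoc <- runAssociation(prep$genotypes, labels,
                          do.call(assocConfig,
                                  c(config$assoc, list(seed = config$seed))))
  funnel <- rbind(prep$funnel,
                  data.frame(stage = "set_A",
                             loci = length(assoc$finalSet)))
  scores <- NULL
  if (!is.null(config$score_tsv)) {
    sc <- readScoreTsv(config$score_tsv)
    inA <- names(sc) %in% assoc$finalSet
    if (any(inA) && any(!inA))
      scores <- compareScoreSets(list(setA = sc[inA], rest = sc[!inA]))
  }
  report <- structure(list(phenotype = phen, prepare = prep,
                           association = assoc, scoreComparison = scores,
                           funnel = funnel, truth = truth,
                           config = config),
                      class = "PipelineReport")
  if (!is.null(config$outdir)) writePipelineReport(report, config$outdir)
  report
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("Genotype-phenotype association pipeline\n")
  cat(sprintf("  subjects clustered: %d (silhouette %.3f)\n",
              length(x$phenotype$labels), x$phenotype$silhouette))
  cat("  locus funnel: ",
      paste(sprintf("%s=%d", x$funnel$stage, x$funnel$loci),
            collapse = " -> "), "\n", sep = "")
  print(x$association)
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' Serializes every stage of a \code{\link{runPipeline}} result to plain
#' text under \code{outdir}: cluster labels, U-matrix grid, rules (text
#' and JSON), cluster statistics, filter reports, the locus funnel,
#' per-run association metrics, importances with set membership, gene
#' tallies and a JSON summary (seeds and package version included).
#'
#' @param report a \code{"PipelineReport"}.
#' @param outdir output directory (created if needed).
#' @return Invisibly, \code{outdir}.
#' @export
writePipelineReport <- function(report, outdir) {
  w <- function(name, writer) .writeStage(outdir, name, writer)
  phen <- report$phenotype
  w("cluster_labels.tsv", function(p)
    write.table(data.frame(subject = phen$table$subject,
                           cluster = phen$labels),
                p, sep = "\t", quote = FALSE, row.names = FALSE))
  w("umatrix.tsv", function(p) writeUMatrixTsv(phen$umatrix, p))
  w("rules.txt", function(p) writeLines(format(phen$rules), p))
  w("rules.json", function(p) ruleSetToJson(phen$rules, p))
  w("funnel.tsv", function(p)
    write.table(report$funnel, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
  w("hwe_report.tsv", function(p)
    write.table(report$prepare$hwe, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
  w("shannon_report.tsv", function(p)
    write.table(report$prepare$shannon, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
  w("chi2_report.tsv", function(p)
    write.table(report$prepare$chi2, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
  w("association_runs.tsv", function(p)
    write.table(report$association$runs, p, sep = "\t", quote = FALSE,
                row.names = FALSE))
  w("importance.tsv", function(p) {
    imp <- report$association$importance
    write.table(data.frame(locus = names(imp), importance = imp,
                           setA = names(imp) %in% report$association$finalSet),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  w("gene_tally.tsv", function(p)
    write.table(report$association$geneTally$table, p, sep = "\t",
                quote = FALSE, row.names = FALSE))
  w("summary.json", function(p) {
    s <- report$association$summary
    jsonlite::write_json(list(
      package = as.character(utils::packageVersion("ThermoPainAssoc")),
      seed = report$config$seed,
      seeds = report$association$seeds,
      silhouette = phen$silhouette,
      clusterSizes = as.integer(table(phen$labels)),
      funnel = report$funnel,
      metrics = lapply(s, as.list),
      controlAudit = report$association$controlAudit,
      chanceLevel = report$association$chanceLevel),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(outdir)
}
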