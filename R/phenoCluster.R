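#' Derive UV-B hypersensitization effects
#'
#' Appends the UV-B effect columns, each the difference between the
#' post-irradiation and baseline z-scored threshold:
#' \code{UVBEff_Heat = zHPT_UVB - zHPT_baseline} and
#' \code{UVBEff_Cold = zCPT_UVB - zCPT_baseline}. Input columns are left
#' unchanged.
#'
#' @param table phenotype data.frame containing the four threshold columns
#'   \code{zHPT_baseline}, \code{zHPT_UVB}, \code{zCPT_baseline},
#'   \code{zCPT_UVB}.
#' @return The table with \code{UVBEff_Heat} and \code{UVBEff_Cold}
#'   appended.
#' @export
deriveUvbEffects <- function(table) {
  miss <- setdiff(.PHENO_VARS, colnames(table))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  table$UVBEff_Heat <- table$zHPT_UVB - table$zHPT_baseline
  table$UVBEff_Cold <- table$zCPT_UVB - table$zCPT_baseline
  table
}

#' Screen for strongly correlated variable blocks
#'
#' Computes the pairwise Pearson correlation of the numeric phenotype
#' variables and returns the blocks of variables linked by
#' \code{|r| > threshold} (connected components of the correlation graph).
#' Constant columns, whose correlation is undefined, are reported and
#' excluded. Variables not in any block pass through unaltered.
#'
#' @param table data.frame with at least two complete numeric columns.
#' @param threshold absolute correlation above which variables are grouped
#'   (default 0.8).
#' @param vars columns to screen; defaults to all numeric columns.
#' @return list with \code{blocks} (list of character vectors, size >= 2),
#'   \code{ungrouped}, \code{excluded} (constant columns) and \code{r}
#'   (the correlation matrix).
#' @export
correlationScreen <- function(table, threshold = 0.8, vars = NULL) {
  if (is.null(vars))
    vars <- colnames(table)[vapply(table, is.numeric, logical(1))]
  if (length(vars) < 2) stop("need at least two numeric variables")
  x <- as.matrix(table[, vars, drop = FALSE])
  if (any(!complete.cases(x)))
    stop("rows admitted to the correlation screen must be complete")
  constant <- vars[apply(x, 2, function(v) var(v) == 0)]
  use <- setdiff(vars, constant)
  r <- cor(x[, use, drop = FALSE])
  adj <- abs(r) > threshold
  diag(adj) <- FALSE
  # connected components by repeated expansion
  remaining <- use
  blocks <- list()
  while (length(remaining)) {
    comp <- remaining[1]
    repeat {
      nb <- use[rowSums(adj[, comp, drop = FALSE]) > 0]
      nxt <- union(comp, nb)
      if (length(nxt) == length(comp)) break
      comp <- nxt
    }
    if (length(comp) > 1) blocks[[length(blocks) + 1L]] <- comp
    remaining <- setdiff(remaining, comp)
  }
  list(blocks = blocks,
       ungrouped = setdiff(use, unlist(blocks)),
       excluded = constant, r = r)
}

#' Decorrelate a variable block by principal component analysis
#'
#' Standardizes the block variables, eigendecomposes their correlation
#' matrix and retains the components with eigenvalue strictly greater than
#' 1 (Kaiser criterion; a tie at exactly 1.0 is not retained). For a
#' 2-variable standardized block the eigenvalues are exactly \eqn{1 \pm r}.
#'
#' @param table phenotype data.frame.
#' @param block character vector of >= 2 column names.
#' @param prefix name stem for the retained component scores (default
#'   \code{"PC"}).
#' @return list of class \code{"PcaBlock"} with \code{variables},
#'   \code{eigenvalues} (descending), \code{loadings}, \code{scores}
#'   (retained components only) and \code{retained}.
#' @examples
#' # two standardized variables at r = 0.812 have eigenvalues 1.812, 0.188
#' @export
pcaDecorrelate <- function(table, block, prefix = "PC") {
  if (length(block) < 2) stop("a PCA block needs at least two variables")
  x <- scale(as.matrix(table[, block, drop = FALSE]))
  R <- cor(x)
  e <- eigen(R, symmetric = TRUE)
  keep <- which(e$values > 1)
  scores <- x %*% e$vectors[, keep, drop = FALSE]
  colnames(scores) <- sprintf("%s%d", prefix, seq_along(keep))
  structure(list(variables = block,
                 eigenvalues = e$values,
                 loadings = e$vectors,
                 scores = scores,
                 retained = keep),
            class = "PcaBlock")
}

#' @export
print.PcaBlock <- function(x, ...) {
  cat(sprintf("PcaBlock over {%s}: eigenvalues %s; %d component(s) retained\n",
              paste(x$variables, collapse = ", "),
              paste(signif(x$eigenvalues, 3), collapse = ", "),
              length(x$retained)))
  invisible(x)
}

#' Silhouette index of a clustering
#'
#' Mean over subjects of \eqn{(b - a) / \max(a, b)}, with \eqn{a} the mean
#' Euclidean distance to the subject's own cluster and \eqn{b} the smallest
#' mean distance to another cluster. Members of singleton clusters, and
#' points for which \eqn{\max(a, b) = 0} (coincident clusters), contribute
#' 0.
#'
#' @param data numeric matrix/data.frame, subjects in rows.
#' @param labels cluster labels, at least two non-empty clusters.
#' @return Mean silhouette width in [-1, 1].
#' @export
silhouetteIndex <- function(data, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("silhouette requires at least two non-empty clusters")
  labels <- droplevels(labels)
  D <- as.matrix(dist(as.matrix(data)))
  n <- nrow(D)
  s <- vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)   # singleton convention
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(levels(labels), as.character(labels[i])),
                    function(lv) mean(D[i, labels == lv]), numeric(1)))
    if (max(a, b) == 0) return(0)     # 0/0 convention
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Between-cluster phenotype statistics
#'
#' Statistical characterization of a two-cluster phenotype solution over
#' the six thermal-pain variables: a repeated-measures ANOVA with the
#' variable ("test") as within-subject factor, cluster as between-subject
#' factor and their interaction; per-variable Welch two-sample t-tests with
#' a Bonferroni-corrected alpha (0.05 divided by the number of post-hoc
#' tests); and, when subject sex is supplied, a 2x2 chi-squared test of
#' sex by cluster (without continuity correction). No sphericity correction
#' is applied to the rm-ANOVA.
#'
#' @param table phenotype data.frame containing \code{vars}.
#' @param labels binary cluster labels (each cluster >= 2 subjects).
#' @param sex optional per-subject sex labels.
#' @param vars the phenotype variables (default: four thresholds plus both
#'   UV-B effects).
#' @param alpha nominal significance level (default 0.05).
#' @return list of class \code{"ClusterStats"}: \code{anova} (data.frame
#'   with F, df and p for test, cluster and interaction), \code{ttests}
#'   (per-variable Welch t, df, p), \code{alphaCorrected}, \code{sexTest}
#'   (or NULL).
#' @export
clusterStats <- function(table, labels, sex = NULL,
                         vars = c(.PHENO_VARS, "UVBEff_Heat", "UVBEff_Cold"),
                         alpha = 0.05) {
  miss <- setdiff(vars, colnames(table))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("two cluster labels are required")
  if (any(table(labels) < 2)) stop("each cluster needs at least 2 subjects")
  n <- nrow(table)
  long <- data.frame(
    subject = factor(rep(seq_len(n), times = length(vars))),
    cluster = factor(rep(labels, times = length(vars))),
    test = factor(rep(vars, each = n), levels = vars),
    value = unlist(table[, vars], use.names = FALSE))
  fit <- aov(value ~ cluster * test + Error(subject), data = long)
  sm <- summary(fit)
  betw <- sm[["Error: subject"]][[1]]
  wth <- sm[["Error: Within"]][[1]]
  rn <- function(tab) trimws(rownames(tab))
  anova <- data.frame(
    effect = c("cluster", "test", "cluster:test"),
    df = c(betw[rn(betw) == "cluster", "Df"],
           wth[rn(wth) == "test", "Df"],
           wth[rn(wth) == "cluster:test", "Df"]),
    F = c(betw[rn(betw) == "cluster", "F value"],
          wth[rn(wth) == "test", "F value"],
          wth[rn(wth) == "cluster:test", "F value"]),
    p = c(betw[rn(betw) == "cluster", "Pr(>F)"],
          wth[rn(wth) == "test", "Pr(>F)"],
          wth[rn(wth) == "cluster:test", "Pr(>F)"]))
  tt <- do.call(rbind, lapply(vars, function(v) {
    ht <- t.test(table[[v]] ~ labels)        # Welch by default
    data.frame(variable = v, t = unname(ht$statistic),
               df = unname(ht$parameter), p = ht$p.value)
  }))
  sexTest <- NULL
  if (!is.null(sex)) {
    ht <- suppressWarnings(chisq.test(table(sex, labels), correct = FALSE))
    sexTest <- data.frame(chi2 = unname(ht$statistic),
                          df = unname(ht$parameter), p = ht$p.value)
  }
  structure(list(anova = anova, ttests = tt,
                 alphaCorrected = alpha / length(vars),
                 sexTest = sexTest),
            class = "ClusterStats")
}

#' @export
print.ClusterStats <- function(x, ...) {
  cat("Repeated-measures ANOVA:\n"); print(x$anova, row.names = FALSE)
  cat(sprintf("\nWelch t-tests (Bonferroni-corrected alpha = %.5f):\n",
              x$alphaCorrected))
  print(x$ttests, row.names = FALSE)
  if (!is.null(x$sexTest)) {
    cat("\nSex by cluster:\n"); print(x$sexTest, row.names = FALSE)
  }
  invisible(x)
}
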