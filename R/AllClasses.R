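#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats aov chisq.test coef complete.cases cor cor.test dist
#'   ecdf p.adjust pchisq prcomp quantile rbinom rnorm runif sd setNames
#'   t.test var wilcox.test
#' @importFrom utils head read.csv read.delim write.csv write.table
NULL

#' Genotype matrix with locus metadata
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding a loci x
#' subjects dosage matrix (assay \code{"dosage"}, integer codes 0/1/2 =
#' number of non-reference alleles, \code{NA} = missing call) with per-locus
#' metadata in \code{rowData}: \code{gene}, \code{chrom}, \code{pos},
#' \code{class} (one of SNV/Del/Ins/MIX), \code{dbsnp} and a logical
#' \code{control} flag marking negative-control-gene loci.
#'
#' @slot .. inherited from \code{SummarizedExperiment}.
#' @seealso \code{\link{GenotypeData}}, \code{\link{dosage}},
#'   \code{\link{locusInfo}}
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

.VARIANT_CLASSES <- c("SNV", "Del", "Ins", "MIX")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- !is.na(d) & !(d %in% c(0L, 1L, 2L))
    if (any(bad))
      msg <- c(msg, "dosage codes must be 0, 1, 2 or NA")
  }
  rd <- SummarizedExperiment::rowData(object)
  need <- c("gene", "class", "control")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if ("class" %in% colnames(rd) &&
      !all(rd$class %in% .VARIANT_CLASSES))
    msg <- c(msg, "variant class must be one of SNV, Del, Ins, MIX")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "locus ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage integer matrix, loci in rows and subjects in columns,
#'   entries in \{0, 1, 2\} or \code{NA}.
#' @param locusInfo data.frame of per-locus metadata aligned with the rows of
#'   \code{dosage}. Recognized columns: \code{gene}, \code{chrom},
#'   \code{pos}, \code{class}, \code{dbsnp}, \code{control}. Missing columns
#'   are filled with defaults (gene \code{NA}, class \code{"SNV"}, control
#'   \code{FALSE}).
#'
#' @return A \linkS4class{GenotypeData} object.
#' @examples
#' gd <- GenotypeData(matrix(c(0L, 1L, 2L, 0L), 2,
#'                    dimnames = list(c("l1", "l2"), c("s1", "s2"))))
#' dosage(gd)
#' @export
GenotypeData <- function(dosage, locusInfo = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (anyDuplicated(rownames(dosage)))
    stop("locus ids must be unique")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("locus%d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("S%d", seq_len(ncol(dosage)))
  if (is.null(locusInfo))
    locusInfo <- data.frame(row.names = rownames(dosage))
  locusInfo <- as.data.frame(locusInfo)
  if (!nrow(locusInfo)) locusInfo <- data.frame(row.names = rownames(dosage))
  if (is.null(locusInfo$gene)) locusInfo$gene <- NA_character_
  if (is.null(locusInfo$class)) locusInfo$class <- "SNV"
  if (is.null(locusInfo$control)) locusInfo$control <- FALSE
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = S4Vectors::DataFrame(locusInfo, row.names = rownames(dosage)))
  new("GenotypeData", se)
}

#' @describeIn GenotypeData accessor for the dosage matrix.
#' @param x a \code{GenotypeData} object.
#' @export
dosage <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeData accessor for the per-locus metadata as a
#'   data.frame.
#' @export
locusInfo <- function(x)
  as.data.frame(SummarizedExperiment::rowData(x))

#' @describeIn GenotypeData indices of negative-control-gene loci.
#' @export
controlLoci <- function(x) which(locusInfo(x)$control)

setMethod("show", "GenotypeData", function(object) {
  d <- dosage(object)
  cat(sprintf("GenotypeData: %d loci x %d subjects\n", nrow(d), ncol(d)))
  rd <- locusInfo(object)
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(table(rd$class)),
                            as.integer(table(rd$class))), collapse = " ")))
  cat(sprintf("  control loci: %d; missing calls: %d\n",
              sum(rd$control), sum(is.na(d))))
})

#' Trained emergent self-organizing map
#'
#' Holds the neuron weight grid of an ESOM trained by
#' \code{\link{trainEsom}}: a toroidal \code{rows} x \code{cols} lattice of
#' neurons, each carrying a weight vector in the input feature space.
#'
#' @slot weights numeric matrix, (rows*cols) x d; neuron (r, c) is row
#'   (r-1)*cols + c.
#' @slot rows,cols grid dimensions.
#' @slot toroidal logical; opposite grid edges are connected.
#' @slot epochs training epochs used.
#' @slot seed integer seed the training was run under.
#' @slot varnames names of the input features.
#' @export
setClass("EsomModel",
         representation(weights = "matrix", rows = "integer",
                        cols = "integer", toroidal = "logical",
                        epochs = "integer", seed = "integer",
                        varnames = "character"))

setValidity("EsomModel", function(object) {
  if (nrow(object@weights) != object@rows * object@cols)
    return("weight matrix must have rows*cols rows")
  TRUE
})

setMethod("show", "EsomModel", function(object) {
  cat(sprintf("EsomModel: %d x %d toroidal grid (%d neurons), d = %d, %d epochs\n",
              object@rows, object@cols, nrow(object@weights),
              ncol(object@weights), object@epochs))
})

#' Computed ABC partition of a set of item values
#'
#' Result of \code{\link{abcPartition}}: items ordered by decreasing value,
#' the cumulative yield-versus-effort curve, and the data-driven limits
#' dividing the items into the most profitable set "A", intermediate "B" and
#' trivial "C".
#'
#' @slot values input values in original order.
#' @slot order permutation sorting values decreasingly (stable).
#' @slot curve data.frame with columns \code{x} (effort fraction i/n) and
#'   \code{y} (cumulative value share), including the origin (0, 0).
#' @slot limitAB,limitBC item indices (positions in the sorted order) of the
#'   A/B and B/C boundaries.
#' @slot setA,setB,setC integer vectors of original item indices per set.
#' @export
setClass("AbcPartition",
         representation(values = "numeric", order = "integer",
                        curve = "data.frame", limitAB = "integer",
                        limitBC = "integer", setA = "integer", setB = "integer",
                        setC = "integer"))

setMethod("show", "AbcPartition", function(object) {
  n <- length(object@values)
  shareA <- sum(object@values[object@setA]) / sum(object@values)
  cat(sprintf("AbcPartition: n = %d | A = %d, B = %d, C = %d | A yield share = %.3f\n",
              n, length(object@setA), length(object@setB), length(object@setC),
              shareA))
})
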