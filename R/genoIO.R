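#' Read genotypes from a VCF file
#'
#' Parses a VCF (v4.x, GT field) into a \linkS4class{GenotypeData}: each
#' record/alternate-allele combination becomes one locus whose dosage is the
#' per-subject count of that alternate allele. Multi-allelic records are
#' split per alternate allele. The variant class is inferred from the
#' REF/ALT lengths (both length 1: SNV; ALT shorter: Del; ALT longer: Ins;
#' otherwise MIX) and locus ids follow the \code{X<chrom>.<pos>.<class>}
#' dialect. Missing GT fields become missing calls.
#'
#' @param file path to a VCF file.
#' @param locusInfoFile optional TSV of extra locus metadata (columns
#'   \code{locus}, \code{gene}, \code{dbsnp}, \code{control}) merged by
#'   locus id.
#' @return A \linkS4class{GenotypeData}.
#' @export
readGenotypesVcf <- function(file, locusInfoFile = NULL) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  rows <- list(); ids <- character(); meta <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      cls <- .inferVariantClass(fix$REF[i], alts[k])
      id <- sprintf("X%s.%s.%s", fix$CHROM[i], fix$POS[i], cls)
      # split GT on / or |, count occurrences of allele index k
      codes <- vapply(gt[i, ], function(s) {
        if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
        al <- strsplit(s, "[/|]")[[1]]
        if (any(al == ".")) return(NA_integer_)
        sum(al == as.character(k))
      }, integer(1))
      rows[[length(rows) + 1L]] <- codes
      ids <- c(ids, id)
      meta[[length(meta) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), class = cls,
        dbsnp = ifelse(is.na(fix$ID[i]) | fix$ID[i] == ".",
                       NA_character_, fix$ID[i]),
        gene = .infoField(fix$INFO[i], "GENE"),
        control = identical(.infoField(fix$INFO[i], "CTRL"), "1"))
    }
  }
  d <- do.call(rbind, rows)
  rownames(d) <- make.unique(ids)
  info <- do.call(rbind, meta)
  rownames(info) <- rownames(d)
  if (!is.null(locusInfoFile)) {
    extra <- read.delim(locusInfoFile, stringsAsFactors = FALSE)
    m <- match(rownames(info), extra$locus)
    for (col in setdiff(colnames(extra), "locus"))
      info[[col]] <- ifelse(is.na(m), info[[col]], extra[[col]][m])
  }
  GenotypeData(d, info)
}

.infoField <- function(info, key) {
  if (is.na(info)) return(NA_character_)
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info, perl = TRUE))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

.inferVariantClass <- function(ref, alt) {
  if (nchar(ref) == 1 && nchar(alt) == 1) "SNV"
  else if (nchar(alt) < nchar(ref)) "Del"
  else if (nchar(alt) > nchar(ref)) "Ins"
  else "MIX"
}

#' Write genotypes as a minimal VCF
#'
#' Emits a plain-text VCF v4.2 with a GT FORMAT field and one sample column
#' per subject. REF/ALT alleles are synthesized from the variant class when
#' no real alleles are available (SNV: A>G; Del: AT>A; Ins: A>AT; MIX:
#' AT>GC), sufficient for round-tripping dosage codes and class labels.
#' Gene symbols and control flags are carried in INFO (\code{GENE=},
#' \code{CTRL=1}).
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param file output path.
#' @return Invisibly, \code{file}.
#' @export
writeGenotypesVcf <- function(gd, file) {
  d <- dosage(gd)
  info <- locusInfo(gd)
  alleles <- list(SNV = c("A", "G"), Del = c("AT", "A"),
                  Ins = c("A", "AT"), MIX = c("AT", "GC"))
  chrom <- if (!is.null(info$chrom)) info$chrom else rep(1L, nrow(d))
  pos <- if (!is.null(info$pos)) info$pos else seq_len(nrow(d))
  id <- if (!is.null(info$dbsnp)) ifelse(is.na(info$dbsnp), ".", info$dbsnp)
        else rep(".", nrow(d))
  gtmap <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
             "##INFO=<ID=CTRL,Number=1,Type=Integer,Description=\"Negative control gene\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(d)), collapse = "\t"))
  body <- vapply(seq_len(nrow(d)), function(i) {
    al <- alleles[[info$class[i]]]
    gt <- ifelse(is.na(d[i, ]), "./.", gtmap[d[i, ] + 1L])
    inf <- character()
    if (!is.na(info$gene[i])) inf <- c(inf, paste0("GENE=", info$gene[i]))
    if (isTRUE(info$control[i])) inf <- c(inf, "CTRL=1")
    paste(c(chrom[i], pos[i], id[i], al[1], al[2], ".", "PASS",
            if (length(inf)) paste(inf, collapse = ";") else ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), file)
  invisible(file)
}

#' Read/write genotype codes as a tab-separated table
#'
#' Tabular alternative to VCF: loci in rows, subjects in columns, first
#' column \code{locus}, entries 0/1/2 or NA.
#'
#' @param file path to the TSV.
#' @param locusInfoFile optional metadata TSV as in
#'   \code{\link{readGenotypesVcf}}.
#' @return \code{readGenotypesTsv}: a \linkS4class{GenotypeData}.
#' @export
readGenotypesTsv <- function(file, locusInfoFile = NULL) {
  tab <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  d <- as.matrix(tab[, -1, drop = FALSE])
  rownames(d) <- tab[[1]]
  info <- NULL
  if (!is.null(locusInfoFile)) {
    extra <- read.delim(locusInfoFile, stringsAsFactors = FALSE)
    info <- extra[match(rownames(d), extra$locus),
                  setdiff(colnames(extra), "locus"), drop = FALSE]
    rownames(info) <- rownames(d)
  }
  GenotypeData(d, info)
}

#' @rdname readGenotypesTsv
#' @param gd a \linkS4class{GenotypeData}.
#' @return \code{writeGenotypesTsv}: invisibly, \code{file}.
#' @export
writeGenotypesTsv <- function(gd, file) {
  d <- dosage(gd)
  tab <- data.frame(locus = rownames(d), d, check.names = FALSE)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write the locus metadata table
#'
#' @param gd a \linkS4class{GenotypeData}.
#' @param file output TSV path.
#' @return Invisibly, \code{file}.
#' @export
writeLocusInfoTsv <- function(gd, file) {
  info <- locusInfo(gd)
  tab <- data.frame(locus = rownames(info), info, check.names = FALSE)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Final-selection variant table (packaged fixture)
#'
#' The packaged table of the 38 ion-channel gene variants selected into the
#' final ABC set "A" of the published analysis: gene symbol, importance
#' rank, locus id (\code{X<chrom>.<pos>.<class>}), DNA change, molecular
#' consequence, dbSNP id and the variant-allele frequencies (percent) in
#' the two pain-phenotype clusters.
#'
#' @return data.frame with 38 rows.
#' @examples
#' tab <- finalVariantTable()
#' table(tab$gene)["TRPV3"]   # 10
#' @export
finalVariantTable <- function() {
  f <- system.file("extdata", "final_set_A_variants.tsv",
                   package = "ThermoPainAssoc", mustWork = TRUE)
  read.delim(f, stringsAsFactors = FALSE, na.strings = c("NA", "-"))
}
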