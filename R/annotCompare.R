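#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum test between two sets of functional annotation
#' scores. The statistic follows the first-sample convention,
#' \eqn{W = (\mathrm{rank\ sum\ of\ } x) - n_x(n_x+1)/2}, so
#' \eqn{W(x, y) + W(y, x) = n_x n_y}. The p-value is computed by exact
#' enumeration when \eqn{n_x + n_y \le 20} and no ties are present, and
#' otherwise by the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y non-empty numeric vectors of scores.
#' @return list with \code{W}, \code{p}, \code{nx}, \code{ny},
#'   \code{exact}.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))   # W = 0, p = 1/3
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both score sets must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("scores must be finite")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 20) && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE,
                alternative = "two.sided"))
  list(W = unname(ht$statistic), p = ht$p.value,
       nx = length(x), ny = length(y), exact = exact)
}

#' Compare several score sets pairwise
#'
#' Pairwise Wilcoxon-Mann-Whitney tests between all sets of variant
#' functional scores, with per-set summary moments. Rank-based, hence
#' invariant under any common monotone transform of the scores.
#'
#' @param sets named list of >= 2 numeric score vectors.
#' @return list of class \code{"ScoreComparison"} with \code{moments}
#'   (set, n, mean, sd) and \code{tests} (setX, setY, W, p, exact).
#' @export
compareScoreSets <- function(sets) {
  if (length(sets) < 2) stop("at least two score sets are required")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- sprintf("set%d", seq_along(sets))
  moments <- data.frame(
    set = names(sets),
    n = vapply(sets, length, integer(1)),
    mean = vapply(sets, mean, numeric(1)),
    sd = vapply(sets, sd, numeric(1)),
    row.names = NULL)
  pairs <- utils::combn(names(sets), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    w <- wilcoxonRankSum(sets[[a]], sets[[b]])
    data.frame(setX = a, setY = b, W = w$W, p = w$p, exact = w$exact)
  }))
  structure(list(moments = moments, tests = tests),
            class = "ScoreComparison")
}

#' @export
print.ScoreComparison <- function(x, ...) {
  cat("Score set moments:\n"); print(x$moments, row.names = FALSE)
  cat("\nPairwise Wilcoxon-Mann-Whitney tests:\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Read a variant score table
#'
#' TSV with columns \code{variant} and \code{score} (e.g. precomputed
#' functional-impact scores); scores are taken as given, never computed.
#'
#' @param file path to the TSV.
#' @return named numeric vector of scores.
#' @export
readScoreTsv <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  setNames(tab$score, tab$variant)
}
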