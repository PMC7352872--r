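#' Cumulative yield-versus-effort (ABC) curve
#'
#' Sorts non-negative item values decreasingly and computes the cumulative
#' contribution curve used by the computed ABC analysis: after the top
#' \eqn{i} of \eqn{n} items (effort fraction \eqn{x_i = i/n}) the yield
#' fraction is \eqn{y_i = \sum_{j \le i} v_{(j)} / \sum_j v_j}. For sorted
#' input the curve is non-decreasing and concave, starting at (0, 0) and
#' ending at (1, 1).
#'
#' @param values numeric vector of non-negative item values, at least one
#'   positive. Names are preserved in the partition functions.
#' @return data.frame with columns \code{x}, \code{y}; the first row is the
#'   origin (0, 0), followed by one row per item in decreasing value order.
#' @examples
#' abcCurve(c(3, 1))   # points (0.5, 0.75) and (1, 1)
#' @export
abcCurve <- function(values) {
  .checkAbcInput(values)
  v <- sort(values, decreasing = TRUE)
  n <- length(v)
  data.frame(x = c(0, seq_len(n) / n),
             y = c(0, cumsum(v) / sum(v)))
}

.checkAbcInput <- function(values) {
  if (!length(values) || !is.numeric(values))
    stop("ABC analysis requires a non-empty numeric vector")
  if (any(is.na(values)))
    stop("ABC analysis does not accept missing values")
  if (any(values < 0))
    stop("ABC item values must be non-negative")
  if (all(values == 0))
    stop("ABC analysis requires at least one positive item value")
  invisible(TRUE)
}

#' Computed ABC analysis: partition items into sets A, B and C
#'
#' Data-driven categorization of a set of positive item values into the most
#' profitable set "A", an intermediate set "B" and a trivial set "C", from
#' the shape of the cumulative yield curve alone (no fixed percentage
#' thresholds). Two limits are computed on the empirical curve:
#' \itemize{
#'   \item \emph{A/B limit (Pareto point)}: the item index whose curve point
#'     \eqn{(x_i, y_i)} lies closest (Euclidean) to the ideal point (0, 1) of
#'     maximal yield at no effort.
#'   \item \emph{B/C limit (break-even point)}: the smallest index at or
#'     after the A/B limit whose marginal yield per item falls below the
#'     uniform rate, i.e. \eqn{n \, \Delta y_i < 1}; if no such index exists
#'     the limit is \eqn{n} and C is empty.
#' }
#' Set A comprises sorted items \code{1..limitAB}, B the items
#' \code{(limitAB, limitBC]}, C the rest. Ties in the sort are broken by
#' original position (stable), so the partition is deterministic; it is
#' invariant to input order and to rescaling all values by a positive
#' constant.
#'
#' @inheritParams abcCurve
#' @return An \linkS4class{AbcPartition} object.
#' @examples
#' p <- abcPartition(c(10, 8, 1, 0.5, 0.2))
#' abcSet(p, "A")
#' @export
abcPartition <- function(values) {
  .checkAbcInput(values)
  n <- length(values)
  ord <- order(values, decreasing = TRUE)   # stable: ties keep input order
  v <- values[ord]
  x <- seq_len(n) / n
  y <- cumsum(v) / sum(v)
  limitAB <- which.min(x^2 + (1 - y)^2)
  dy <- v / sum(v)                          # marginal yield of item i
  below <- which(seq_len(n) >= limitAB & n * dy < 1)
  limitBC <- if (length(below)) min(below) else n
  limitBC <- max(limitBC, limitAB)          # enforce A <= B <= C ordering
  idx <- seq_len(n)
  vals <- as.numeric(values)
  names(vals) <- names(values)
  new("AbcPartition",
      values = vals, order = as.integer(ord),
      curve = data.frame(x = c(0, x), y = c(0, y)),
      limitAB = as.integer(limitAB), limitBC = as.integer(limitBC),
      setA = as.integer(ord[idx <= limitAB]),
      setB = as.integer(ord[idx > limitAB & idx <= limitBC]),
      setC = as.integer(ord[idx > limitBC]))
}

#' Extract one set from an ABC partition
#'
#' @param partition an \linkS4class{AbcPartition}.
#' @param set \code{"A"}, \code{"B"} or \code{"C"}.
#' @return Integer vector of original item indices (named if the input
#'   values were named).
#' @export
abcSet <- function(partition, set = c("A", "B", "C")) {
  set <- match.arg(set)
  idx <- slot(partition, paste0("set", set))
  nm <- names(partition@values)
  if (!is.null(nm)) names(idx) <- nm[idx]
  idx
}

#' Write an ABC partition to TSV files
#'
#' Emits the item table (item, value, set) and optionally the curve, both as
#' plain tab-separated text for external plotting.
#'
#' @param partition an \linkS4class{AbcPartition}.
#' @param file path of the item table.
#' @param curveFile optional path for the curve table.
#' @return Invisibly, the item table data.frame.
#' @export
writeAbcTsv <- function(partition, file, curveFile = NULL) {
  nm <- names(partition@values)
  if (is.null(nm)) nm <- sprintf("item%d", seq_along(partition@values))
  set <- character(length(nm))
  set[partition@setA] <- "A"; set[partition@setB] <- "B"; set[partition@setC] <- "C"
  tab <- data.frame(item = nm, value = partition@values, set = set)
  tab <- tab[order(-tab$value), ]
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(curveFile))
    write.table(partition@curve, curveFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(tab)
}
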