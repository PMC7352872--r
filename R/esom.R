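#' Train an emergent self-organizing map
#'
#' Competitive online learning of a large toroidal neuron grid used as a
#' distance-preserving projection surface (thousands of neurons, not a
#' k-means surrogate). Each presented sample pulls the weight vectors of
#' all neurons toward it, weighted by a Gaussian neighborhood kernel over
#' the toroidal grid distance to the sample's best-matching unit. The
#' neighborhood radius anneals linearly from half the smaller grid
#' dimension down to 1 and the learning rate from 0.5 to 0.05 over the
#' epochs; weights are initialized uniformly within the per-dimension data
#' range. Training is deterministic given \code{seed}.
#'
#' @param data numeric matrix/data.frame, subjects in rows, complete.
#' @param rows,cols grid dimensions (default 50 x 80 = 4000 neurons).
#' @param epochs training epochs (default 20).
#' @param seed integer seed for initialization and sample order.
#' @param toroidal connect opposite grid edges (default TRUE).
#' @return An \linkS4class{EsomModel}.
#' @export
trainEsom <- function(data, rows = 50L, cols = 80L, epochs = 20L,
                      seed = 42L, toroidal = TRUE) {
  x <- as.matrix(data)
  if (nrow(x) < 2) stop("ESOM training requires at least 2 subjects")
  if (any(!is.finite(x))) stop("training data must be complete")
  if (rows < 1 || cols < 1 || epochs < 1)
    stop("grid dimensions and epochs must be positive")
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- nrow(x); d <- ncol(x); m <- rows * cols
  set.seed(as.integer(seed))
  rng <- apply(x, 2, range)
  W <- sapply(seq_len(d), function(j) runif(m, rng[1, j], rng[2, j]))
  W <- matrix(W, nrow = m)
  # neuron grid coordinates, row-major: neuron i -> (r, c)
  gr <- (seq_len(m) - 1L) %/% cols
  gc <- (seq_len(m) - 1L) %% cols
  radius0 <- max(min(rows, cols) / 2, 1)
  steps <- epochs
  for (e in seq_len(epochs)) {
    frac <- if (steps > 1) (e - 1) / (steps - 1) else 0
    sigma <- radius0 + frac * (1 - radius0)        # radius0 -> 1
    lr <- 0.5 + frac * (0.05 - 0.5)                # 0.5 -> 0.05
    for (i in sample.int(n)) {
      xi <- x[i, ]
      diffs <- sweep(W, 2, xi)
      bmu <- which.min(rowSums(diffs * diffs))
      dr <- abs(gr - gr[bmu]); dc <- abs(gc - gc[bmu])
      if (toroidal) {
        dr <- pmin(dr, rows - dr)
        dc <- pmin(dc, cols - dc)
      }
      h <- exp(-(dr * dr + dc * dc) / (2 * sigma * sigma))
      W <- W - (lr * h) * diffs
    }
  }
  colnames(W) <- colnames(x)
  new("EsomModel", weights = W, rows = rows, cols = cols,
      toroidal = isTRUE(toroidal), epochs = as.integer(epochs),
      seed = as.integer(seed),
      varnames = if (is.null(colnames(x))) character() else colnames(x))
}

.gridNeighbors <- function(rows, cols, toroidal = TRUE) {
  # list of 8-neighborhood neuron indices per neuron (row-major)
  m <- rows * cols
  gr <- (seq_len(m) - 1L) %/% cols
  gc <- (seq_len(m) - 1L) %% cols
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  lapply(seq_len(m), function(i) {
    rr <- gr[i] + offs$dr; cc <- gc[i] + offs$dc
    if (toroidal) {
      rr <- rr %% rows; cc <- cc %% cols
    }
    ok <- rr >= 0 & rr < rows & cc >= 0 & cc < cols
    unique(rr[ok] * cols + cc[ok] + 1L)
  })
}

#' Compute the U-matrix and best-matching units
#'
#' Per-neuron height = mean Euclidean distance between the neuron's weight
#' vector and those of its grid neighbors (8-neighborhood, toroidal when
#' the model is). High "ridges" mark large feature-space distances that
#' separate data clusters. Each subject is mapped to its best-matching
#' unit, the neuron nearest in feature space.
#'
#' @param model a trained \linkS4class{EsomModel}.
#' @param data the data to map (same feature space as training).
#' @return list of class \code{"UMatrix"}: \code{heights} (rows x cols
#'   matrix), \code{bmu} (neuron index per subject), \code{rows},
#'   \code{cols}, \code{toroidal}.
#' @export
computeUMatrix <- function(model, data) {
  W <- model@weights
  nb <- .gridNeighbors(model@rows, model@cols, model@toroidal)
  heights <- vapply(seq_len(nrow(W)), function(i) {
    dif <- sweep(W[nb[[i]], , drop = FALSE], 2, W[i, ])
    mean(sqrt(rowSums(dif * dif)))
  }, numeric(1))
  x <- as.matrix(data)
  bmu <- vapply(seq_len(nrow(x)), function(i) {
    dif <- sweep(W, 2, x[i, ])
    which.min(rowSums(dif * dif))
  }, integer(1))
  structure(list(heights = matrix(heights, model@rows, model@cols,
                                  byrow = TRUE),
                 bmu = bmu, rows = model@rows, cols = model@cols,
                 toroidal = model@toroidal),
            class = "UMatrix")
}

#' Extract clusters from a U-matrix by watershed flooding
#'
#' Automated replacement for visual inspection of the topographic map:
#' neurons are flooded in order of increasing U-matrix height; a neuron
#' with no previously flooded neighbor opens a new basin (a local valley),
#' otherwise it joins a neighboring basin, and when it touches several
#' basins they are recorded as merging at that height. Merges are then
#' applied in increasing height order until exactly \code{k} basins
#' containing best-matching units remain; subjects inherit their BMU's
#' basin label.
#'
#' @param umatrix result of \code{\link{computeUMatrix}}.
#' @param k requested number of clusters.
#' @param minSize minimum number of mapped subjects for a basin to count
#'   as a cluster (default: 5 percent of the cohort, at least 2); smaller
#'   basins (isolated outlier pockets) keep being absorbed by the flood
#'   instead of blocking the threshold scan, and their subjects join the
#'   nearest retained basin on the grid.
#' @param data optional subjects x features matrix (the data the map was
#'   trained on). When supplied, the flooding threshold is chosen among
#'   all candidate k-basin states as the one whose induced subject
#'   partition has the highest silhouette index - the same validity
#'   criterion the analysis reports - instead of simply the deepest
#'   (last) k-basin state.
#' @return integer vector of cluster labels (1..k) per subject, with an
#'   attribute \code{"neuronBasin"} giving the basin id of every neuron.
#' @export
extractClusters <- function(umatrix, k = 2L,
                            minSize = max(2L, ceiling(0.05 * length(umatrix$bmu))),
                            data = NULL) {
  h <- as.vector(t(umatrix$heights))          # back to row-major
  m <- length(h)
  nb <- .gridNeighbors(umatrix$rows, umatrix$cols, umatrix$toroidal)
  ord <- order(h)
  basin <- integer(m)                         # 0 = not yet flooded
  parent <- integer(0)                        # union-find over basins
  findRoot <- function(b) {
    while (parent[b] != b) b <- parent[b]
    b
  }
  merges <- list()
  for (i in ord) {
    roots <- unique(vapply(basin[nb[[i]]][basin[nb[[i]]] > 0],
                           findRoot, integer(1)))
    if (!length(roots)) {
      parent <- c(parent, length(parent) + 1L)
      basin[i] <- length(parent)
    } else {
      basin[i] <- roots[1]
      if (length(roots) > 1)
        for (r in roots[-1])
          merges[[length(merges) + 1L]] <- c(h[i], roots[1], r)
    }
  }
  # BMU count per root under the current union state
  bmuBasin <- basin[umatrix$bmu]
  countMajor <- function() {
    rt <- vapply(bmuBasin, findRoot, integer(1))
    sum(table(rt) >= minSize)
  }
  # scan the merge threshold: apply merges in increasing ridge height and
  # keep the last state in which exactly k substantial basins remain (the
  # deepest k-way valley structure before it collapses to k-1)
  ms <- if (length(merges)) {
    tmp <- do.call(rbind, merges)
    tmp[order(tmp[, 1]), , drop = FALSE]
  } else matrix(numeric(), 0, 3)
  snapshots <- vector("list", nrow(ms) + 1L)
  snapshots[[1L]] <- parent
  for (j in seq_len(nrow(ms))) {
    a <- findRoot(as.integer(ms[j, 2]))
    b <- findRoot(as.integer(ms[j, 3]))
    if (a != b) parent[b] <- a
    snapshots[[j + 1L]] <- parent
  }
  rootOf <- function(pr, b) {
    while (pr[b] != b) b <- pr[b]
    b
  }
  nMajAt <- vapply(snapshots, function(pr) {
    rt <- vapply(bmuBasin, function(b) rootOf(pr, b), integer(1))
    sum(table(rt) >= minSize)
  }, integer(1))
  hit <- which(nMajAt == k)
  if (!length(hit))
    stop(sprintf(
      "no flooding threshold yields k = %d basins holding >= %d subjects (max %d)",
      k, minSize, max(nMajAt)))
  pick <- max(hit)
  if (!is.null(data) && k >= 2) {
    # among candidate thresholds, keep the partition with the best
    # silhouette over the subjects inside substantial basins; evaluate
    # each distinct major-partition only once
    xd <- as.matrix(data)
    best <- -Inf
    seen <- character()
    for (j in rev(hit)) {
      pr <- snapshots[[j]]
      rtj <- vapply(bmuBasin, function(b) rootOf(pr, b), integer(1))
      cntj <- table(rtj)
      majorj <- as.integer(names(cntj)[cntj >= minSize])
      inMaj <- rtj %in% majorj
      key <- paste(ifelse(inMaj, rtj, 0L), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      sil <- silhouetteIndex(xd[inMaj, , drop = FALSE], rtj[inMaj])
      if (sil > best) {
        best <- sil
        pick <- j
      }
    }
  }
  parent <- snapshots[[pick]]
  rt <- vapply(bmuBasin, findRoot, integer(1))
  cnt <- table(rt)
  major <- as.integer(names(cnt)[cnt >= minSize])
  # any subject still in a minor basin joins the nearest flooded major
  # basin (smallest height at which its basin would have merged)
  if (any(!rt %in% major)) {
    root <- vapply(seq_along(parent), findRoot, integer(1))
    neuron <- root[basin]
    for (s in which(!rt %in% major)) {
      ds <- .toroidalGridDist(umatrix, umatrix$bmu[s],
                              which(neuron %in% major))
      tgt <- which(neuron %in% major)[which.min(ds)]
      rt[s] <- root[basin[tgt]]
    }
  }
  labels <- as.integer(factor(rt, levels = unique(rt)))
  root <- vapply(seq_along(parent), findRoot, integer(1))
  attr(labels, "neuronBasin") <- root[basin]
  labels
}

.toroidalGridDist <- function(umatrix, from, to) {
  cols <- umatrix$cols; rows <- umatrix$rows
  r0 <- (from - 1L) %/% cols; c0 <- (from - 1L) %% cols
  r1 <- (to - 1L) %/% cols; c1 <- (to - 1L) %% cols
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  if (umatrix$toroidal) {
    dr <- pmin(dr, rows - dr); dc <- pmin(dc, cols - dc)
  }
  sqrt(dr^2 + dc^2)
}

#' Export a U-matrix height grid as TSV
#'
#' @param umatrix result of \code{\link{computeUMatrix}}.
#' @param file output path.
#' @return Invisibly, \code{file}.
#' @export
writeUMatrixTsv <- function(umatrix, file) {
  write.table(umatrix$heights, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}
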