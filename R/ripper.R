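#' Induce classification rules (RIPPER-style separate-and-conquer)
#'
#' Learns an ordered set of conjunctive threshold rules describing a
#' two-class clustering in terms of the original variables. Rules are grown
#' for the minority class by a separate-and-conquer strategy: predicates
#' of the form (variable <= t) or (variable > t), with candidate
#' thresholds at the midpoints of consecutive sorted values, are added
#' greedily by FOIL information gain on a growing set (two thirds of the
#' training data); each rule is then simplified by reduced-error pruning on
#' the held-out third. A rule is kept only if it improves whole-set
#' training accuracy; learning stops when no positive examples remain or no
#' rule improves. Prediction applies rules in order, falling back to the
#' default (majority) class.
#'
#' @param table data.frame of numeric features.
#' @param labels binary class labels.
#' @param vars feature columns (default: all numeric).
#' @param seed seed for the grow/prune split.
#' @return list of class \code{"RuleSet"}: \code{rules} (each a data.frame
#'   of predicates plus a class), \code{defaultClass}, \code{classes},
#'   \code{trainAccuracy}.
#' @export
induceRules <- function(table, labels, vars = NULL, seed = 42L) {
  if (is.null(vars))
    vars <- colnames(table)[vapply(table, is.numeric, logical(1))]
  x <- as.matrix(table[, vars, drop = FALSE])
  y <- as.factor(labels)
  classes <- levels(droplevels(y))
  if (length(classes) < 2) {
    rs <- structure(list(rules = list(), defaultClass = classes[1],
                         classes = classes, trainAccuracy = 1),
                    class = "RuleSet")
    return(rs)
  }
  tabY <- table(y)
  minority <- names(tabY)[which.min(tabY)]
  majority <- setdiff(names(tabY), minority)[1]
  pos <- y == minority
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(x))
  growIdx <- idx[seq_len(ceiling(2 * length(idx) / 3))]
  pruneIdx <- setdiff(idx, growIdx)

  applyRule <- function(rule, xm) {
    hit <- rep(TRUE, nrow(xm))
    for (j in seq_len(nrow(rule))) {
      v <- xm[, rule$variable[j]]
      hit <- hit & if (rule$op[j] == "<=") v <= rule$threshold[j]
                   else v > rule$threshold[j]
    }
    hit
  }
  predictWith <- function(rules, xm) {
    out <- rep(majority, nrow(xm))
    covered <- rep(FALSE, nrow(xm))
    for (r in rules) {
      hit <- applyRule(r, xm) & !covered
      out[hit] <- attr(r, "ruleClass")
      covered <- covered | hit
    }
    factor(out, levels = classes)
  }
  foilGain <- function(p, np, P, NP) {
    if (p == 0) return(-Inf)
    p * (log2(p / (p + np)) - log2(P / (P + NP)))
  }
  growRule <- function(xm, posv) {
    rule <- data.frame(variable = character(), op = character(),
                       threshold = numeric(), stringsAsFactors = FALSE)
    cov <- rep(TRUE, nrow(xm))
    repeat {
      P <- sum(posv & cov); NP <- sum(!posv & cov)
      if (NP == 0 || P == 0) break
      best <- NULL; bestGain <- 0
      for (v in vars) {
        vals <- sort(unique(xm[cov, v]))
        if (length(vals) < 2) next
        thr <- (head(vals, -1) + vals[-1]) / 2
        for (t in thr) for (op in c("<=", ">")) {
          sel <- if (op == "<=") xm[, v] <= t else xm[, v] > t
          g <- foilGain(sum(posv & cov & sel), sum(!posv & cov & sel), P, NP)
          if (g > bestGain + 1e-12) {
            bestGain <- g
            best <- list(v = v, op = op, t = t)
          }
        }
      }
      if (is.null(best)) break
      rule <- rbind(rule, data.frame(variable = best$v, op = best$op,
                                     threshold = best$t))
      cov <- cov & applyRule(rule[nrow(rule), , drop = FALSE], xm)
    }
    rule
  }
  pruneRule <- function(rule, xm, posv) {
    if (!nrow(rule) || !length(posv)) return(rule)
    score <- function(r) {
      if (!nrow(r)) return(-Inf)
      hit <- applyRule(r, xm)
      p <- sum(posv & hit); np <- sum(!posv & hit)
      if (p + np == 0) return(-Inf)
      (p - np) / (p + np)
    }
    repeat {
      if (nrow(rule) <= 1) break
      scores <- vapply(seq_len(nrow(rule) - 1), function(kk)
        score(rule[seq_len(kk), , drop = FALSE]), numeric(1))
      full <- score(rule)
      k <- which.max(scores)
      if (scores[k] > full) rule <- rule[seq_len(k), , drop = FALSE]
      else break
    }
    rule
  }

  rules <- list()
  remaining <- rep(TRUE, nrow(x))
  baseAcc <- max(tabY) / length(y)
  bestAcc <- baseAcc
  repeat {
    gIdx <- intersect(growIdx, which(remaining))
    pIdx <- intersect(pruneIdx, which(remaining))
    if (!sum(pos & remaining)) break
    if (length(gIdx) < 2) break
    rule <- growRule(x[gIdx, , drop = FALSE], pos[gIdx])
    if (!nrow(rule)) break
    rule <- pruneRule(rule, x[pIdx, , drop = FALSE], pos[pIdx])
    attr(rule, "ruleClass") <- minority
    cand <- c(rules, list(rule))
    acc <- mean(predictWith(cand, x) == y)
    if (acc <= bestAcc + 1e-12) break
    rules <- cand
    bestAcc <- acc
    remaining <- remaining & !applyRule(rule, x)
  }
  structure(list(rules = rules, defaultClass = majority,
                 classes = classes, trainAccuracy = bestAcc),
            class = "RuleSet")
}

#' Predict classes from a rule set
#'
#' @param object a \code{"RuleSet"} from \code{\link{induceRules}}.
#' @param newdata data.frame with the rule variables.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.RuleSet <- function(object, newdata, ...) {
  xm <- as.matrix(newdata[, unique(unlist(lapply(object$rules, function(r)
    r$variable))), drop = FALSE])
  out <- rep(object$defaultClass, nrow(newdata))
  covered <- rep(FALSE, nrow(newdata))
  for (r in object$rules) {
    hit <- rep(TRUE, nrow(newdata))
    for (j in seq_len(nrow(r))) {
      v <- newdata[[r$variable[j]]]
      hit <- hit & if (r$op[j] == "<=") v <= r$threshold[j]
                   else v > r$threshold[j]
    }
    hit <- hit & !covered
    out[hit] <- attr(r, "ruleClass")
    covered <- covered | hit
  }
  factor(out, levels = object$classes)
}

#' @export
print.RuleSet <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.RuleSet <- function(x, ...) {
  lines <- character()
  for (r in x$rules) {
    conj <- paste(sprintf("%s %s %.4g", r$variable, r$op, r$threshold),
                  collapse = " AND ")
    lines <- c(lines, sprintf("IF %s THEN class = %s", conj,
                              attr(r, "ruleClass")))
  }
  c(lines, sprintf("ELSE class = %s", x$defaultClass),
    sprintf("(training accuracy %.3f)", x$trainAccuracy))
}

#' Serialize a rule set to JSON
#'
#' @param x a \code{"RuleSet"}.
#' @param file optional path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
ruleSetToJson <- function(x, file = NULL) {
  obj <- list(rules = lapply(x$rules, function(r)
    list(class = attr(r, "ruleClass"),
         predicates = as.data.frame(r))),
    defaultClass = x$defaultClass,
    trainAccuracy = x$trainAccuracy)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}
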