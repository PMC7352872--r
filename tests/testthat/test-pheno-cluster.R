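test_that("UV-B effects are the post-minus-baseline differences", {
  tab <- data.frame(zHPT_baseline = c(-1, 0.3), zHPT_UVB = c(0.5, 0.3),
                    zCPT_baseline = c(0.2, 1), zCPT_UVB = c(0.2, 1.4))
  out <- deriveUvbEffects(tab)
  expect_equal(out$UVBEff_Heat, c(1.5, 0))
  expect_equal(out$UVBEff_Cold, c(0, 0.4))
  expect_equal(out[, 1:4], tab)                       # inputs untouched
  expect_error(deriveUvbEffects(tab[, -2]), "lacks")

  # identical measurements -> identically zero effect
  same <- data.frame(zHPT_baseline = rnorm(5), zCPT_baseline = rnorm(5))
  same$zHPT_UVB <- same$zHPT_baseline
  same$zCPT_UVB <- same$zCPT_baseline
  out2 <- deriveUvbEffects(same)
  expect_true(all(out2$UVBEff_Heat == 0 & out2$UVBEff_Cold == 0))
})

test_that("correlation screen groups the strongly correlated pair and nothing else", {
  set.seed(4)
  n <- 1000
  z <- rnorm(n)
  tab <- data.frame(a = z, b = 0.812 * z + sqrt(1 - 0.812^2) * rnorm(n),
                    c = rnorm(n), d = rnorm(n))
  sc <- correlationScreen(tab, threshold = 0.8)
  expect_length(sc$blocks, 1)
  expect_setequal(sc$blocks[[1]], c("a", "b"))
  expect_setequal(sc$ungrouped, c("c", "d"))

  # a variable is perfectly correlated with itself
  expect_equal(unname(diag(sc$r)), rep(1, 4))

  # six independent standard normals: no blocks at n = 1000
  null <- as.data.frame(matrix(rnorm(6 * n), ncol = 6))
  expect_length(correlationScreen(null, 0.8)$blocks, 0)

  # constant columns are reported and excluded
  tab$e <- 1
  sc2 <- correlationScreen(tab, 0.8)
  expect_equal(sc2$excluded, "e")
})

test_that("PCA of a 2-variable standardized block has eigenvalues 1 +/- r", {
  mkpair <- function(r, n = 100) {
    # exact sample correlation r via orthonormal construction
    u <- rep(c(1, -1), length.out = n)
    v <- rep(c(1, 1, -1, -1), length.out = n)
    data.frame(x = u, y = r * u + sqrt(1 - r^2) * v)
  }
  pb <- pcaDecorrelate(mkpair(0.812), c("x", "y"))
  expect_equal(pb$eigenvalues, c(1.812, 0.188), tolerance = 1e-12)
  expect_length(pb$retained, 1)
  expect_equal(ncol(pb$scores), 1)

  pb0 <- pcaDecorrelate(mkpair(0), c("x", "y"))
  expect_equal(pb0$eigenvalues, c(1, 1))
  expect_length(pb0$retained, 0)     # strict > 1: ties not retained

  pb5 <- pcaDecorrelate(mkpair(0.5), c("x", "y"))
  expect_equal(pb5$eigenvalues, c(1.5, 0.5), tolerance = 1e-12)

  expect_error(pcaDecorrelate(mkpair(0.5), "x"), "two variables")
})

test_that("silhouette matches the brute-force oracle and its conventions", {
  # two tight, well separated pairs
  x <- matrix(c(0, 0, 0.1, 0, 10, 0, 10.1, 0), ncol = 2, byrow = TRUE)
  s <- silhouetteIndex(x, c(1, 1, 2, 2))
  expect_gt(s, 0.95)

  # coincident points in 2 clusters: 0/0 convention gives 0
  xx <- matrix(1, 6, 2)
  expect_equal(silhouetteIndex(xx, rep(1:2, 3)), 0)

  expect_error(silhouetteIndex(x, rep(1, 4)), "two non-empty")

  # random instances up to n = 50 against the O(n^2) oracle and, as an
  # independent reference, cluster::silhouette
  set.seed(12)
  for (i in 1:10) {
    n <- sample(6:50, 1)
    k <- sample(2:4, 1)
    xm <- matrix(rnorm(n * 3), ncol = 3)
    lab <- sample(k, n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- 1:2
    expect_equal(silhouetteIndex(xm, lab), oracleSilhouette(xm, lab),
                 tolerance = 1e-12)
    if (requireNamespace("cluster", quietly = TRUE) &&
        all(table(lab) > 1)) {
      ref <- mean(cluster::silhouette(lab, dist(xm))[, "sil_width"])
      expect_equal(silhouetteIndex(xm, lab), ref, tolerance = 1e-12)
    }
  }
})

test_that("cluster statistics match a hand-computed repeated-measures decomposition", {
  # 4 subjects x 2 variables toy with a known decomposition
  tab <- data.frame(v1 = c(1, 2, 5, 6), v2 = c(2, 3, 7, 9))
  labels <- c(1, 1, 2, 2)
  cs <- clusterStats(tab, labels, vars = c("v1", "v2"))
  long <- data.frame(values = c(tab$v1, tab$v2),
                     cluster = rep(labels, 2),
                     subject = rep(1:4, 2),
                     test = rep(c("v1", "v2"), each = 4))
  o <- oracleRmAnova(long$values, long$cluster, long$subject, long$test)
  a <- cs$anova
  expect_equal(a$F[a$effect == "cluster"], unname(o$Fcluster),
               tolerance = 1e-10)
  expect_equal(a$F[a$effect == "test"], unname(o$Ftest), tolerance = 1e-10)
  expect_equal(a$F[a$effect == "cluster:test"], unname(o$Finter),
               tolerance = 1e-10)

  # Welch t-tests agree with stats::t.test var.equal = FALSE
  ref <- t.test(tab$v1 ~ labels)
  tt <- cs$ttests[cs$ttests$variable == "v1", ]
  expect_equal(tt$t, unname(ref$statistic))
  expect_equal(tt$df, unname(ref$parameter))
})

test_that("cluster statistics report the Bonferroni alpha and a null sex test", {
  spec <- cohortSpec(seed = 6)
  ph <- generatePhenotypes(spec)
  tab <- deriveUvbEffects(ph$phenotypes)
  sex <- rep(c("f", "m"), length.out = 82)     # sex independent of cluster
  cs <- clusterStats(tab, ph$labels, sex = sex)
  expect_equal(cs$alphaCorrected, 0.05 / 6)
  expect_equal(round(cs$alphaCorrected, 5), 0.00833)
  expect_equal(cs$sexTest$df, 1)
  expect_gt(cs$sexTest$p, 0.001)

  # identical cluster distributions: F_cluster ~ 0, p ~ 1
  tab2 <- rbind(tab[, -1], tab[, -1])
  cs2 <- clusterStats(cbind(subject = 1, tab2),
                      rep(1:2, each = nrow(tab)))
  expect_lt(cs2$anova$F[cs2$anova$effect == "cluster"], 1e-20)
  expect_gt(cs2$anova$p[cs2$anova$effect == "cluster"], 0.999)

  expect_error(clusterStats(tab, c(1, rep(2, 81))), "at least 2")
})
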