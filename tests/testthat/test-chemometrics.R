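test_that("standardize yields exact zero means and unit sds, idempotently", {
  set.seed(5)
  tab <- matrix(rnorm(6 * 4, mean = 3, sd = 2), 6, 4,
                dimnames = list(NULL, paste0("v", 1:4)))
  z <- standardize(tab)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(standardize(z)), unname(z), tolerance = 1e-12)
  expect_error(standardize(cbind(tab, k = 2)), "k")
  expect_error(standardize(tab[1, , drop = FALSE]), ">= 2")
})

test_that("single linkage reproduces hand-computed merges on a line", {
  pts <- matrix(c(0, 1, 3, 7), ncol = 1,
                dimnames = list(c("a", "b", "c", "d"), "x"))
  tree <- single_linkage(pts)
  expect_equal(tree$height, c(1, 2, 4))
  expect_equal(tree$members[[1]], list(a = "a", b = "b"))
  expect_equal(tree$members[[2]], list(a = c("a", "b"), b = "c"))
  expect_equal(tree$members[[3]], list(a = c("a", "b", "c"), b = "d"))
})

test_that("identical rows merge first at height zero and ties break lexicographically", {
  pts <- matrix(c(0, 5, 5, 9), ncol = 1,
                dimnames = list(c("w", "x", "y", "z"), "v"))
  tree <- single_linkage(pts)
  expect_equal(tree$height[1], 0)
  expect_equal(tree$members[[1]], list(a = "x", b = "y"))
  # equidistant ties: four points with two merges at distance 1 pick the
  # lexicographically smallest pair first
  tie <- matrix(c(0, 1, 10, 11), ncol = 1,
                dimnames = list(c("d", "c", "b", "a"), "v"))
  ttree <- single_linkage(tie)
  expect_equal(ttree$members[[1]], list(a = "a", b = "b"))
  expect_equal(ttree$members[[2]], list(a = "c", b = "d"))
})

test_that("single linkage agrees with stats::hclust through cophenetic distances", {
  set.seed(17)
  for (i in 1:5) {
    n <- sample(5:9, 1)
    tab <- matrix(rnorm(n * 3), n, 3,
                  dimnames = list(paste0("s", seq_len(n)), c("a", "b", "c")))
    tree <- single_linkage(tab)
    expect_true(all(diff(tree$height) >= -1e-12))  # no inversions
    hc <- hclust(dist(tab), method = "single")
    coph <- as.matrix(cophenetic(hc))
    labs <- sort(rownames(tab))
    expect_equal(tree_cophenetic(tree)[labs, labs], coph[labs, labs],
                 tolerance = 1e-12)
  }
})

test_that("the published lipophilicity block clusters into the structural pairs", {
  tab <- lipophilicity_table()   # R_M0, logP_TLC + ten calculator columns
  d <- as.matrix(dist(tab))
  expect_lt(abs(d["EB365", "EB366"] - 0.35), 0.01)
  expect_lt(abs(d["EB355A", "EB367"] - 0.89), 0.01)
  expect_true(all(d["Betulin", c("EB355A", "EB365", "EB366", "EB367")] >
                  d["EB355A", "EB367"]))
  tree <- single_linkage(tab)
  expect_equal(tree$members[[1]], list(a = "EB365", b = "EB366"))
  expect_equal(tree$members[[2]], list(a = "EB355A", b = "EB367"))
  # betulin joins only at the final merge
  expect_equal(tree$members[[4]]$a, "Betulin")
})

test_that("to_newick renders ultrametric branch lengths and round-trips", {
  pts <- matrix(c(0, 4), ncol = 1, dimnames = list(c("A", "B"), "x"))
  expect_equal(to_newick(single_linkage(pts)), "(A:2,B:2);")

  skip_if_not_installed("ape")
  tree <- single_linkage(lipophilicity_table())
  phy <- ape::read.tree(text = to_newick(tree))
  expect_equal(sort(phy$tip.label), sort(tree$labels))
  # path lengths through the phylogeny equal the merge heights
  pd <- ape::cophenetic.phylo(phy)
  labs <- sort(tree$labels)
  expect_equal(pd[labs, labs], tree_cophenetic(tree)[labs, labs],
               tolerance = 1e-8)
  # topology: the two structural pairs are sister clades
  expect_true(ape::is.monophyletic(phy, c("EB365", "EB366")))
  expect_true(ape::is.monophyletic(phy, c("EB355A", "EB367")))
})

test_that("descriptor_pca matches prcomp up to component sign", {
  set.seed(29)
  tab <- matrix(rnorm(7 * 5), 7, 5, dimnames = list(NULL, paste0("v", 1:5)))
  res <- descriptor_pca(tab, standardize = TRUE)
  ref <- prcomp(tab, center = TRUE, scale. = TRUE)
  expect_equal(res$eigenvalues, ref$sdev^2, tolerance = 1e-9)
  expect_equal(abs(res$loadings), abs(unclass(ref$rotation)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # deterministic orientation: the largest-magnitude loading is positive
  for (k in seq_len(ncol(res$loadings))) {
    expect_gt(res$loadings[which.max(abs(res$loadings[, k])), k], 0)
  }
})

test_that("PCA invariants hold: trace, scores, reconstruction", {
  set.seed(37)
  tab <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(NULL, paste0("v", 1:4)))
  res <- descriptor_pca(tab, standardize = TRUE)
  expect_equal(sum(res$eigenvalues), ncol(tab), tolerance = 1e-9)
  expect_equal(crossprod(res$loadings), diag(ncol(tab)),
               tolerance = 1e-9, ignore_attr = TRUE)
  z <- standardize(tab)
  expect_equal(unname(res$scores), unname(z %*% res$loadings),
               tolerance = 1e-12)
  expect_equal(unname(res$scores %*% t(res$loadings)), unname(z),
               tolerance = 1e-9)
  # standardize = FALSE on pre-standardized data is the same analysis
  res2 <- descriptor_pca(standardize(tab), standardize = FALSE)
  expect_equal(res2$eigenvalues, res$eigenvalues, tolerance = 1e-9)
  expect_equal(res2$loadings, res$loadings, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a single varying direction gives one nonzero eigenvalue at 100%", {
  t_lat <- c(-2, -1, 0, 1, 2)
  tab <- cbind(a = 2 * t_lat + 1, b = -t_lat, c = 0.5 * t_lat)
  rownames(tab) <- paste0("s", 1:5)
  res <- descriptor_pca(tab, standardize = TRUE)
  expect_equal(sum(res$eigenvalues > 0), 1L)
  expect_equal(res$explained[1], 100, tolerance = 1e-9)
  sc <- scree(res)
  expect_equal(sc$cumulative_pct[1], 100, tolerance = 1e-9)
  expect_true(all(diff(sc$eigenvalue) <= 1e-12))
})

test_that("the published descriptor matrix has rank 4 with a dominant first component", {
  tab <- lipophilicity_table(c("experimental", "theoretical", "properties"))
  res <- descriptor_pca(tab, standardize = TRUE)
  expect_equal(sum(res$eigenvalues > 0), 4L)   # rank <= n - 1
  expect_gt(res$explained[1], 90)
  expect_equal(sum(res$explained), 100, tolerance = 1e-9)
  # the hydrogen-bond-donor count dominates the second component
  expect_equal(rownames(res$loadings)[which.max(abs(res$loadings[, 2]))],
               "nHBD")
})
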