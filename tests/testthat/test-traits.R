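test_that("OU simulation honours its transition moments and seeding", {
  tr <- ape::rcoal(12)

  # vanishing diffusion pins every tip to the optimum
  x <- simulate_ou(tr, alpha = 0.5, theta = 2, sigma = 1e-12, seed = 1)
  expect_lt(max(abs(x - 2)), 1e-10)

  expect_identical(simulate_ou(tr, 0.4, seed = 9), simulate_ou(tr, 0.4, seed = 9))
  expect_error(simulate_ou(tr, alpha = 0), "simulate_bm")
  expect_error(simulate_ou(tr, alpha = 0.5, sigma = -1), "sigma")

  # deep star tree: tips are independent draws from the stationary
  # distribution with variance sigma^2 / (2 alpha)
  star <- parse_newick(paste0(
    "(", paste(sprintf("s%d:40", 1:10000), collapse = ","), ");"))
  y <- simulate_ou(star, alpha = 0.5, sigma = 0.1, seed = 4)
  expect_lt(abs(var(y) / 0.01 - 1), 0.15)
})

test_that("Brownian simulation accumulates variance with branch length", {
  star <- parse_newick(paste0(
    "(", paste(sprintf("s%d:2.5", 1:8000), collapse = ","), ");"))
  y <- simulate_bm(star, sigma = 0.4, seed = 8)
  expect_lt(abs(var(y) / (0.4^2 * 2.5) - 1), 0.15)
  expect_identical(simulate_bm(star, seed = 3), simulate_bm(star, seed = 3))
})

test_that("Blomberg's K is 1 on a star tree and ranks clade alignment", {
  star <- parse_newick(paste0(
    "(", paste(sprintf("s%d:3", 1:8), collapse = ","), ");"))
  set.seed(5)
  x <- stats::setNames(rnorm(8), star$tip.label)
  expect_equal(blomberg_k(star, x), 1, tolerance = 1e-10)

  # 4-tip balanced unit tree: dense hand-built V oracle
  tr4 <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
  V <- matrix(c(2, 1, 0, 0,
                1, 2, 0, 0,
                0, 0, 2, 1,
                0, 0, 1, 2), 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  k_oracle <- function(xv) {
    Vi <- solve(V)
    ah <- sum(Vi %*% xv) / sum(Vi)
    obs <- sum((xv - ah)^2) / drop(t(xv - ah) %*% Vi %*% (xv - ah))
    obs / ((sum(diag(V)) - 4 / sum(Vi)) / 3)
  }
  aligned <- c(a = 0, b = 0, c = 1, d = 1)
  anti <- c(a = 0, b = 1, c = 0, d = 1)
  expect_equal(blomberg_k(tr4, aligned), k_oracle(aligned), tolerance = 1e-12)
  expect_equal(blomberg_k(tr4, anti), k_oracle(anti), tolerance = 1e-12)
  expect_gt(blomberg_k(tr4, aligned), blomberg_k(tr4, anti))

  expect_error(blomberg_k(tr4, c(a = 1, b = 2, c = 3, e = 4)), "every tip")
})

test_that("Blomberg's K matches the picante implementation", {
  set.seed(17)
  for (i in 1:5) {
    tr <- ape::rcoal(20)
    x <- simulate_bm(tr)
    expect_equal(blomberg_k(tr, x),
                 as.numeric(picante::Kcalc(x[tr$tip.label], tr)),
                 tolerance = 1e-8)
  }
})

test_that("trait dendrograms are ultrametric UPGMA trees on trait distances", {
  # two species: single merge at height 4, tips at depth 2
  d2 <- trait_dendrogram(c(a = 1, b = 5))
  expect_equal(tree_depth(d2), 2)
  expect_equal(unname(unclass(patristic_matrix(d2))["a", "b"]), 4)

  # closest pair merges first
  d3 <- trait_dendrogram(c(a = 0, b = 1, c = 10))
  D3 <- unclass(patristic_matrix(d3))
  expect_equal(unname(D3["a", "b"]), 1)
  expect_true(all(D3["c", c("a", "b")] > 1))

  # cophenetic distances equal a naive O(n^3) agglomeration
  set.seed(23)
  for (i in 1:5) {
    x <- stats::setNames(runif(6, 0, 10), paste0("s", 1:6))
    dend <- trait_dendrogram(x)
    expect_true(is_ultrametric_tree(dend, tol = 1e-8))
    lab <- names(x)
    expect_equal(unclass(patristic_matrix(dend))[lab, lab],
                 oracle_upgma_cophenetic(x), tolerance = 1e-10)
  }

  expect_error(trait_dendrogram(c(a = 1)), "at least 2")
  expect_error(trait_dendrogram(stats::setNames(1:3, c("a", "a", "b"))),
               "duplicate")
})

test_that("alternative linkages mirror hclust's merge heights", {
  set.seed(29)
  x <- stats::setNames(runif(8), paste0("s", 1:8))
  for (link in c("complete", "single")) {
    dend <- trait_dendrogram(x, linkage = link)
    hc <- stats::hclust(dist(x), method = link)
    coph <- as.matrix(stats::cophenetic(hc))[names(x), names(x)]
    expect_equal(unclass(patristic_matrix(dend))[names(x), names(x)],
                 coph, tolerance = 1e-10)
  }
})

test_that("the signal sweep is seeded, sized, and bounded", {
  g <- simulate_gradient(n_plots = 6, n_species = 16,
                         total_individuals = 1200, seed = 31)
  sw <- signal_sweep(g$tree, g$comm, n_datasets = 8, oversample = 4,
                     metrics = c("phylosor", "dpw"), seed = 13)
  expect_s3_class(sw, "signal_sweep")
  expect_equal(nrow(sw$datasets), 8L)
  expect_equal(nrow(sw$r2), 8L * 2L)
  expect_true(all(sw$datasets$K > 0))
  expect_true(all(sw$r2$r2 >= 0 & sw$r2$r2 <= 1, na.rm = TRUE))
  # K values of the retained datasets are ordered draws spanning the
  # candidates' realized range
  expect_true(all(diff(sort(sw$datasets$K)) >= 0))

  sw2 <- signal_sweep(g$tree, g$comm, n_datasets = 8, oversample = 4,
                      metrics = c("phylosor", "dpw"), seed = 13)
  expect_identical(sw$r2, sw2$r2)
})

test_that("functional beta computed on the phylogeny itself correlates perfectly", {
  # if the trait dendrogram coincided with the phylogeny the regression of
  # functional on phylogenetic beta would be exact for every metric
  g <- simulate_gradient(n_plots = 5, n_species = 12,
                         total_individuals = 800, seed = 37)
  phy <- all_pairs(g$tree, g$comm, metrics = phylo_metric_names())
  fun <- all_pairs(g$tree, g$comm, metrics = phylo_metric_names())
  for (m in phylo_metric_names()) {
    r2 <- cor(phy$value[phy$metric == m], fun$value[fun$metric == m])^2
    expect_equal(r2, 1, tolerance = 1e-12)
  }
})
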