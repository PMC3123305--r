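fx <- fig1_fixture()

test_that("worked-example spot values reproduce the published arithmetic", {
  expect_equal(phylosor(fx$tree, fx$comm, "B_blue", "B_orange"), 0.125)
  expect_equal(phylosor(fx$tree, fx$comm, "C_blue", "C_orange"), 2 / 3)
  expect_equal(unifrac(fx$tree, fx$comm, "B_blue", "B_orange"), 14 / 15)
  expect_equal(unifrac(fx$tree, fx$comm, "D_blue", "D_orange"), 8 / 15)
  expect_equal(dnn(fx$tree, fx$comm, "B_blue", "B_orange"), 6)
  expect_equal(dpw(fx$tree, fx$comm, "A_blue", "A_orange"), 8)
  expect_equal(rao_d(fx$tree, fx$comm, "B_blue", "B_orange", mode = "presence"), 3)
  expect_equal(rao_h(fx$tree, fx$comm, "A_blue", "A_orange", mode = "presence"), 2.75)
  expect_equal(rao_h(fx$tree, fx$comm, "C_blue", "C_orange", mode = "presence"), 0.25)
})

test_that("self-comparison gives the identity value of each metric", {
  comm <- rbind(fx$comm, X_blue = fx$comm["A_blue", ])
  expect_equal(phylosor(fx$tree, comm, "A_blue", "X_blue"), 1)
  expect_equal(unifrac(fx$tree, comm, "A_blue", "X_blue"), 0)
  expect_equal(dnn(fx$tree, comm, "A_blue", "X_blue"), 0)
  expect_equal(rao_h(fx$tree, comm, "A_blue", "X_blue"), 0)
  expect_equal(jaccard(comm, "A_blue", "X_blue"), 0)
  expect_equal(bray_curtis(comm, "A_blue", "X_blue"), 0)
})

test_that("every metric is symmetric in its two plots", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    ab <- all_pairs(inst$tree, inst$comm)
    comm_rev <- inst$comm[c("p2", "p1"), ]
    ba <- all_pairs(inst$tree, comm_rev)
    expect_equal(ab$value, ba$value, tolerance = 1e-12)
  }
})

test_that("on a star phylogeny PhyloSor is Sorensen and distances hit 2T", {
  star <- parse_newick(paste0("(", paste(sprintf("s%d:3", 1:8), collapse = ","), ");"))
  comm <- matrix(0, 2, 8, dimnames = list(c("p1", "p2"), sprintf("s%d", 1:8)))
  comm["p1", 1:5] <- 1      # n1 = 5
  comm["p2", 4:8] <- 1      # n2 = 5, a = 2 shared
  expect_identical(phylosor(star, comm, "p1", "p2"), 2 * 2 / (5 + 5))

  comm2 <- comm
  comm2["p2", ] <- c(0, 0, 0, 0, 0, 1, 1, 1)  # disjoint
  expect_equal(dnn(star, comm2, "p1", "p2"), 6)
  expect_equal(dpw(star, comm2, "p1", "p2"), 6)
})

test_that("Rao's D is exactly half of abundance-weighted Dpw", {
  for (seed in 11:20) {
    inst <- random_instance(seed)
    d <- dpw(inst$tree, inst$comm, "p1", "p2", mode = "abundance")
    r <- rao_d(inst$tree, inst$comm, "p1", "p2", mode = "abundance")
    expect_identical(r, d / 2)
  }
})

test_that("Jaccard and Bray-Curtis behave as their formulas dictate", {
  comm <- matrix(c(3, 1, 0, 1, 1, 2), 2, 3, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), c("a", "b", "c")))
  expect_equal(bray_curtis(comm, "p1", "p2"), 0.5)  # (2+0+2)/(4+2+2)
  expect_equal(jaccard(comm, "p1", "p2"), 1 - 2 / 3)
  disj <- matrix(c(1, 1, 0, 0, 0, 0, 2, 3), 2, 4, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), letters[1:4]))
  expect_equal(jaccard(disj, "p1", "p2"), 1)
  expect_equal(bray_curtis(disj, "p1", "p2"), 1)
})

test_that("all_pairs enumerates each unordered pair once per metric", {
  g <- simulate_gradient(n_plots = 6, n_species = 15,
                         total_individuals = 900, seed = 7)
  res <- all_pairs(g$tree, g$comm)
  expect_equal(nrow(res), choose(6, 2) * length(beta_metric_names()))
  expect_false(any(duplicated(res[c("plot1", "plot2", "metric")])))

  two <- all_pairs(g$tree, g$comm[1:2, colSums(g$comm[1:2, ]) > 0],
                   metrics = "phylosor")
  expect_equal(nrow(two), 1L)

  expect_error(all_pairs(g$tree, g$comm, metrics = "nosuch"), "unknown metric")

  # the bulk path agrees with the single-pair functions
  one <- res[res$metric == "unifrac" & res$plot1 == "plot001" &
               res$plot2 == "plot004", "value"]
  expect_equal(one, unifrac(g$tree, g$comm, "plot001", "plot004"))
  oneh <- res[res$metric == "raoh" & res$plot1 == "plot002" &
                res$plot2 == "plot003", "value"]
  expect_equal(oneh, rao_h(g$tree, g$comm, "plot002", "plot003"))
})

test_that("the scenario/lambda grid has one row per cell of the published table", {
  tab <- scenario_metric_table()
  expect_equal(nrow(tab), 4 * 6 * 5)
  expect_false(any(duplicated(tab[c("metric", "scenario", "lambda")])))
})

test_that("metrics at lambda = 0.001 converge on their star-tree values", {
  star <- lambda_transform(fx$tree, 0)
  near <- scenario_metric_table(lambdas = 0.001)
  at_star <- scenario_metric_table(lambdas = 0, fixture = {
    f <- fx
    f$tree <- star
    f
  })
  expect_true(all(abs(near$value - at_star$value) < 0.01))
})

test_that("species absent from the tree are a hard error", {
  comm <- matrix(1, 2, 2, dimnames = list(c("p1", "p2"), c("t1", "zz")))
  expect_error(phylosor(fx$tree, comm, "p1", "p2"), "absent from the tree")
})

test_that("beta_matrix reshapes the long table symmetrically", {
  g <- simulate_gradient(n_plots = 5, n_species = 12,
                         total_individuals = 600, seed = 3)
  res <- all_pairs(g$tree, g$comm, metrics = c("phylosor", "dpww"))
  ps <- beta_matrix(res, "phylosor")
  expect_equal(attr(ps, "orientation"), "similarity")
  expect_equal(unname(diag(unclass(ps))), rep(1, 5))
  expect_equal(unname(unclass(ps)["plot001", "plot003"]),
               phylosor(g$tree, g$comm, "plot001", "plot003"))
  dp <- beta_matrix(res, "dpww")
  expect_equal(unname(diag(unclass(dp))), rep(0, 5))
  expect_equal(unclass(dp), t(unclass(dp)))
})
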