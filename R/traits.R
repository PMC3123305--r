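# Trait evolution and phylogenetic signal: exact Ornstein-Uhlenbeck and
# Brownian simulation along a tree, Blomberg's K, trait dendrograms, and the
# signal-vs-functional-beta sweep.

#' Simulate a trait under an Ornstein-Uhlenbeck process
#'
#' Mean-reverting trait evolution with selective constraint \code{alpha},
#' optimum \code{theta} and diffusion standard deviation \code{sigma}.  The
#' root starts at the optimum and each branch of length \eqn{t} applies the
#' exact OU transition
#' \deqn{x_{child} = x_{parent} e^{-\alpha t} + \theta (1 - e^{-\alpha t}) +
#'       \epsilon, \quad
#'       \epsilon \sim N\!\left(0, \frac{\sigma^2 (1 - e^{-2\alpha t})}{2\alpha}\right).}
#' Large \code{alpha} erases phylogenetic signal (tips approach independent
#' draws from the stationary distribution with variance
#' \eqn{\sigma^2 / 2\alpha}); for drift without constraint use
#' [simulate_bm()], not a small-\code{alpha} limit.
#'
#' @param tree a \code{"phylo"} tree with branch lengths.
#' @param alpha selective constraint, strictly positive.
#' @param theta trait optimum (default 0).
#' @param sigma diffusion standard deviation, strictly positive (default 0.1).
#' @param seed optional integer for a deterministic draw.
#' @return named numeric vector of tip trait values.
#' @examples
#' x <- simulate_ou(ape::rcoal(8), alpha = 0.5, seed = 1)
#' @export
simulate_ou <- function(tree, alpha, theta = 0, sigma = 0.1, seed = NULL) {
  tree <- validate_tree(tree)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be > 0; use simulate_bm() for pure drift")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be > 0")
  .with_seed(seed, {
    .evolve(tree, root_state = theta,
            step = function(parent_value, t)
              parent_value * exp(-alpha * t) + theta * (1 - exp(-alpha * t)) +
                stats::rnorm(1L, 0, sigma * sqrt((1 - exp(-2 * alpha * t)) / (2 * alpha))))
  })
}

#' Simulate a trait under Brownian motion
#'
#' Pure drift: along a branch of length \eqn{t} the trait changes by
#' \eqn{N(0, \sigma^2 t)}.  The expected Blomberg's K of a Brownian trait on
#' the generating tree is approximately 1.
#'
#' @inheritParams simulate_ou
#' @param root root trait value (default 0).
#' @param sigma diffusion standard deviation per unit branch length.
#' @return named numeric vector of tip trait values.
#' @export
simulate_bm <- function(tree, sigma = 1, root = 0, seed = NULL) {
  tree <- validate_tree(tree)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be > 0")
  .with_seed(seed, {
    .evolve(tree, root_state = root,
            step = function(parent_value, t)
              parent_value + stats::rnorm(1L, 0, sigma * sqrt(t)))
  })
}

# walk edges root-to-tips applying `step(parent_value, branch_length)`
.evolve <- function(tree, root_state, step) {
  nt <- ape::Ntip(tree)
  po <- stats::reorder(tree, "postorder")
  x <- numeric(nt + tree$Nnode)
  x[nt + 1L] <- root_state
  for (k in rev(seq_len(nrow(po$edge)))) {
    x[po$edge[k, 2L]] <- step(x[po$edge[k, 1L]], po$edge.length[k])
  }
  stats::setNames(x[seq_len(nt)], tree$tip.label)
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' Ratio of the observed mean squared error of tip values around the
#' phylogenetically (GLS) estimated mean to the GLS mean squared error,
#' scaled by its Brownian-motion expectation on the same tree:
#' \deqn{K = \frac{MSE_0 / MSE}
#'            {\left[\mathrm{tr}(V) - n / \sum (V^{-1})\right] / (n - 1)}}
#' with \eqn{V} the tips' shared branch-length matrix.  K near 1 indicates
#' Brownian-like signal, K above 1 stronger-than-Brownian clustering of
#' trait values on the tree, K near 0 no signal.  On an exact star phylogeny
#' K equals 1 for any trait vector.
#'
#' @param tree a \code{"phylo"} tree with at least 4 tips.
#' @param x named numeric trait vector covering every tip exactly once.
#' @return K, a positive real.
#' @examples
#' tr <- ape::rcoal(16)
#' blomberg_k(tr, simulate_bm(tr, seed = 1))
#' @export
blomberg_k <- function(tree, x) {
  tree <- validate_tree(tree)
  nt <- ape::Ntip(tree)
  if (nt < 4L) stop("Blomberg's K needs at least 4 tips")
  if (is.null(names(x)) || !setequal(names(x), tree$tip.label) ||
      length(x) != nt)
    stop("'x' must be named and cover every tip exactly once")
  if (any(!is.finite(x))) stop("trait values must be finite")
  V <- ape::vcv(tree)
  x <- x[rownames(V)]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular phylogenetic covariance matrix"))
  ahat <- sum(Vi %*% x) / sum(Vi)
  dev <- x - ahat
  mse0 <- sum(dev^2)
  mse <- drop(t(dev) %*% Vi %*% dev)
  observed <- mse0 / mse
  expected <- (sum(diag(V)) - nt / sum(Vi)) / (nt - 1)
  observed / expected
}

#' Trait dendrogram by hierarchical clustering
#'
#' Clusters species on absolute trait differences (Euclidean distance in one
#' dimension) and returns the dendrogram as an ultrametric \code{"phylo"}
#' tree, so the whole beta-diversity toolkit applies to functional as well as
#' phylogenetic turnover.  Tip depth is half the merge height, making
#' cophenetic distances equal merge heights.
#'
#' @param x named numeric trait vector (one value per species), or a numeric
#'   matrix with species as rows for multivariate traits.
#' @param linkage agglomeration rule: \code{"average"} (UPGMA, default),
#'   \code{"complete"} or \code{"single"}.
#' @return an ultrametric \code{"phylo"} dendrogram over the same labels.
#' @examples
#' trait_dendrogram(c(a = 0, b = 1, c = 10))
#' @export
trait_dendrogram <- function(x, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) stop("trait matrix must have species row names")
    labs <- rownames(x)
  } else {
    if (is.null(names(x))) stop("trait vector must be named by species")
    labs <- names(x)
  }
  if (anyDuplicated(labs)) stop("duplicate species labels in traits")
  if (length(labs) < 2L) stop("need at least 2 species")
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = linkage)
  hc$labels <- labs
  validate_tree(ape::as.phylo(hc))
}

#' Sweep of phylogenetic signal versus functional-beta recovery
#'
#' Generates OU trait datasets across a grid of selective constraints,
#' retains \code{n_datasets} of them spread evenly across the realized range
#' of Blomberg's K (one per quantile bin of the K order statistics, from
#' \code{oversample} times as many candidates), and for each retained
#' dataset: builds a trait dendrogram, computes functional beta diversity
#' between all plot pairs with every requested metric, and regresses the
#' functional on the phylogenetic beta diversity.  The per-metric
#' coefficient of determination \eqn{R^2} against K shows how much signal a
#' metric needs before phylogenetic turnover mirrors functional turnover.
#'
#' @param tree phylogeny covering the community's species.
#' @param comm plots-by-species community matrix (at least 3 plot pairs).
#' @param alpha_grid OU selective constraints cycled over candidate datasets
#'   (default 12 values spanning 0.2 to 0.99).
#' @param n_datasets number of retained trait datasets (default 60).
#' @param metrics phylogenetic metrics to evaluate.
#' @param mode weighting for the Rao metrics, as in [all_pairs()].
#' @param sigma,theta OU diffusion standard deviation and optimum.
#' @param oversample candidate-to-retained ratio (default 10).
#' @param linkage dendrogram linkage, see [trait_dendrogram()].
#' @param seed optional integer; the whole sweep is deterministic given the
#'   seed.
#' @return object of class \code{"signal_sweep"}: a list with
#'   \code{datasets} (data frame: dataset, alpha, K) and \code{r2}
#'   (data frame: dataset, K, metric, r2).
#' @export
signal_sweep <- function(tree, comm,
                         alpha_grid = seq(0.2, 0.99, length.out = 12),
                         n_datasets = 60,
                         metrics = phylo_metric_names(),
                         mode = c("abundance", "presence"),
                         sigma = 0.1, theta = 0,
                         oversample = 10,
                         linkage = "average",
                         seed = NULL) {
  mode <- match.arg(mode)
  tree <- validate_tree(tree)
  comm <- validate_community(comm, tree)
  if (choose(nrow(comm), 2L) < 3L) stop("need at least 3 plot pairs")
  if (any(alpha_grid <= 0)) stop("'alpha_grid' must be positive")

  .with_seed(seed, {
    n_cand <- oversample * n_datasets
    alphas <- rep_len(alpha_grid, n_cand)
    traits <- lapply(alphas, function(a)
      simulate_ou(tree, alpha = a, theta = theta, sigma = sigma))
    K <- vapply(traits, function(x) blomberg_k(tree, x), numeric(1L))

    # one dataset per quantile bin of the realized K distribution
    keep <- sort(order(K)[unique(round(seq(1, n_cand, length.out = n_datasets)))])
    if (length(keep) < n_datasets)
      keep <- sort(order(K)[seq_len(n_datasets)])  # degenerate tiny-n fallback

    phylo_pairs <- all_pairs(tree, comm, metrics, mode)
    phylo_by_metric <- lapply(metrics, function(m)
      phylo_pairs$value[phylo_pairs$metric == m])
    names(phylo_by_metric) <- metrics

    rows <- lapply(seq_along(keep), function(i) {
      idx <- keep[i]
      dend <- trait_dendrogram(traits[[idx]], linkage = linkage)
      func_pairs <- all_pairs(dend, comm, metrics, mode)
      r2 <- vapply(metrics, function(m) {
        fv <- func_pairs$value[func_pairs$metric == m]
        pv <- phylo_by_metric[[m]]
        if (stats::sd(fv) == 0 || stats::sd(pv) == 0) return(NA_real_)
        stats::cor(fv, pv)^2
      }, numeric(1L))
      data.frame(dataset = i, K = K[idx], metric = metrics, r2 = unname(r2),
                 stringsAsFactors = FALSE, row.names = NULL)
    })

    structure(list(
      datasets = data.frame(dataset = seq_along(keep),
                            alpha = alphas[keep], K = K[keep],
                            row.names = NULL),
      r2 = do.call(rbind, rows)),
      class = "signal_sweep")
  })
}

#' @export
print.signal_sweep <- function(x, ...) {
  cat(sprintf("signal_sweep: %d trait datasets, K in [%.3g, %.3g]\n",
              nrow(x$datasets), min(x$datasets$K), max(x$datasets$K)))
  rho <- vapply(split(x$r2, x$r2$metric), function(d)
    suppressWarnings(stats::cor(d$K, d$r2, method = "spearman")), numeric(1L))
  cat("Spearman rho(K, R^2) by metric:\n")
  print(round(rho, 3))
  invisible(x)
}
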