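# Comparing beta-diversity surfaces: Mantel tests against environmental
# distances, metric-by-metric correlations, PCA of metric outputs, and
# confidence intervals over random polytomy resolutions.

# Pearson r between the lower triangles of two conformable matrices
.mantel_r <- function(m1, m2) stats::cor(.lower_tri(m1), .lower_tri(m2))

.as_conformable <- function(m1, m2) {
  m1 <- .pm_values(if (inherits(m1, "dist")) as.matrix(m1) else m1)
  m2 <- .pm_values(if (inherits(m2, "dist")) as.matrix(m2) else m2)
  if (!.is_square_numeric(m1) || !.is_square_numeric(m2))
    stop("inputs must be square numeric matrices")
  if (nrow(m1) != nrow(m2)) stop("matrix sizes differ")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2)))
      stop("matrix labels differ")
    if (!identical(rownames(m1), rownames(m2)))
      stop("matrix labels are ordered differently; reorder before testing")
  }
  list(m1 = m1, m2 = m2)
}

#' Mantel test between two distance (or similarity) matrices
#'
#' Pearson correlation of the lower-triangle elements, with a permutation
#' null obtained by simultaneously permuting the rows and columns of the
#' second matrix.  P-values carry the add-one correction
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})} (one-sided
#' greater; analogous for the other alternatives), so the smallest
#' attainable p is \eqn{1/(1 + n_{perm})}.
#'
#' @param m1,m2 square symmetric matrices (or \code{pairwise_matrix} /
#'   \code{dist}) with identical label ordering.
#' @param n_perm number of permutations (at least 99; default 999).
#' @param seed optional integer for a deterministic permutation stream.
#' @param alternative \code{"greater"} (default), \code{"two.sided"} or
#'   \code{"less"}.
#' @return object of class \code{"mantel_result"}: list with \code{r},
#'   \code{p}, \code{n_perm}, \code{alternative}, \code{perm_r}.
#' @examples
#' m <- as.matrix(dist(runif(8))); dimnames(m) <- list(letters[1:8], letters[1:8])
#' mantel_test(m, m, n_perm = 99, seed = 1)$r  # 1
#' @export
mantel_test <- function(m1, m2, n_perm = 999, seed = NULL,
                        alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  if (n_perm < 99) stop("'n_perm' must be at least 99")
  mm <- .as_conformable(m1, m2)
  v1 <- .lower_tri(mm$m1)
  v2 <- .lower_tri(mm$m2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero-variance matrix: Mantel r is undefined")
  r_obs <- stats::cor(v1, v2)
  n <- nrow(mm$m1)
  lt <- lower.tri(mm$m2)
  perm_r <- .with_seed(seed, vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    stats::cor(v1, mm$m2[p, p][lt])
  }, numeric(1L)))
  p <- switch(alternative,
    greater = (1 + sum(perm_r >= r_obs)) / (1 + n_perm),
    less = (1 + sum(perm_r <= r_obs)) / (1 + n_perm),
    two.sided = (1 + sum(abs(perm_r) >= abs(r_obs))) / (1 + n_perm))
  structure(list(r = r_obs, p = p, n_perm = n_perm,
                 alternative = alternative, perm_r = perm_r),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, x$alternative, x$n_perm))
  invisible(x)
}

# long all_pairs() table -> pairs-by-metrics value matrix
.pairs_wide <- function(pairs) {
  metrics <- unique(pairs$metric)
  key <- paste(pairs$plot1, pairs$plot2, sep = "\r")
  keys <- unique(key)
  wide <- matrix(NA_real_, length(keys), length(metrics),
                 dimnames = list(keys, metrics))
  wide[cbind(match(key, keys), match(pairs$metric, metrics))] <- pairs$value
  if (anyNA(wide)) stop("all metrics must be computed on the identical pair set")
  wide
}

#' Pearson correlations between metric outputs
#'
#' Correlates the per-pair value vectors of every metric in a long
#' [all_pairs()] table against every other, mirroring how redundancy among
#' beta-diversity metrics is assessed.
#'
#' @param pairs long data frame from [all_pairs()] (at least 3 plot pairs).
#' @return symmetric correlation matrix over metrics.
#' @export
metric_correlations <- function(pairs) {
  wide <- .pairs_wide(pairs)
  if (nrow(wide) < 3L) stop("need at least 3 plot pairs")
  sds <- apply(wide, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant metric vector(s): ",
         paste(colnames(wide)[sds == 0], collapse = ", "))
  stats::cor(wide)
}

#' Principal components analysis of metric outputs
#'
#' Similarity-oriented metrics bounded in \eqn{[0, 1]} (PhyloSor) are
#' converted to dissimilarities as \eqn{1 - s}; every metric vector is then
#' z-scored and the PCA performed on the resulting correlation structure.
#' For readability the largest-magnitude loading of each component is given
#' a negative sign (component signs are arbitrary).
#'
#' @param pairs long data frame from [all_pairs()] with at least 2 metrics
#'   and 3 plot pairs.
#' @return object of class \code{"pca_metrics"}: list with \code{loadings}
#'   (metrics by components), \code{proportion} and \code{cumulative}
#'   variance explained, and \code{scores}.
#' @export
pca_metrics <- function(pairs) {
  wide <- .pairs_wide(pairs)
  if (ncol(wide) < 2L) stop("need at least 2 metrics")
  if (nrow(wide) < 3L) stop("need at least 3 plot pairs")
  sim <- colnames(wide)[metric_orientation(colnames(wide)) == "similarity"]
  for (m in sim) wide[, m] <- 1 - wide[, m]
  sds <- apply(wide, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant metric vector(s): ",
         paste(colnames(wide)[sds == 0], collapse = ", "))
  z <- scale(wide)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  pc$rotation <- sweep(pc$rotation, 2L, flip, "/") * -1
  pc$x <- sweep(pc$x, 2L, flip, "/") * -1
  vr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation,
                 proportion = vr,
                 cumulative = cumsum(vr),
                 scores = pc$x),
            class = "pca_metrics")
}

#' @export
print.pca_metrics <- function(x, digits = 3, ...) {
  k <- min(3L, ncol(x$loadings))
  tab <- rbind(x$loadings[, seq_len(k), drop = FALSE],
               `Proportion of Variance` = x$proportion[seq_len(k)],
               `Cumulative Variance` = x$cumulative[seq_len(k)])
  print(round(tab, digits), ...)
  invisible(x)
}

#' Mantel correlations across random polytomy resolutions
#'
#' Repeats the metric-versus-environment Mantel correlation on
#' \code{n_resolutions} independently resolved copies of the tree and
#' summarizes each metric's r by its 2.5/97.5 percentile interval.  Because
#' inserted branches have length zero, metrics that depend only on patristic
#' distances (Dnn, Dpw, Rao) are invariant across replicates; only the
#' branch-sharing metrics can vary.
#'
#' @param tree a rooted tree, possibly with polytomies.
#' @param comm plots-by-species community matrix.
#' @param env_dist a plot-by-plot \code{\link{pairwise_matrix}} of an
#'   environmental distance (see [env_distances()]).
#' @param metrics phylogenetic metrics to evaluate.
#' @param n_resolutions number of random resolutions (default 100).
#' @param mode weighting for the Rao metrics.
#' @param seed optional integer for determinism.
#' @return data frame with columns \code{metric}, \code{r} (point estimate on
#'   the input tree), \code{lo}, \code{hi} (95\% interval across
#'   resolutions); the replicate r values are attached as attribute
#'   \code{"replicates"} (resolutions by metrics).
#' @export
resolution_ci <- function(tree, comm, env_dist,
                          metrics = phylo_metric_names(),
                          n_resolutions = 100,
                          mode = c("abundance", "presence"),
                          seed = NULL) {
  mode <- match.arg(mode)
  tree <- validate_tree(tree)
  comm <- validate_community(comm, tree)
  env_m <- .pm_values(env_dist)
  plots <- rownames(comm)
  if (!setequal(rownames(env_m), plots))
    stop("environment matrix labels do not match the community plots")
  env_m <- env_m[plots, plots]

  r_for_tree <- function(tr) {
    pairs <- all_pairs(tr, comm, metrics, mode)
    vapply(metrics, function(m)
      .mantel_r(.pm_values(beta_matrix(pairs, m))[plots, plots], env_m),
      numeric(1L))
  }

  point <- r_for_tree(tree)
  reps <- .with_seed(seed, t(vapply(seq_len(n_resolutions), function(b)
    r_for_tree(resolve_polytomies(tree)), numeric(length(metrics)))))
  colnames(reps) <- metrics
  ci <- apply(reps, 2L, stats::quantile, probs = c(0.025, 0.975))
  out <- data.frame(metric = metrics, r = unname(point),
                    lo = unname(ci[1L, ]), hi = unname(ci[2L, ]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "replicates") <- reps
  out
}
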