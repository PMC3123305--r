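# The eight phylogenetic beta-diversity metrics plus classical Jaccard and
# Bray-Curtis, per plot pair and in bulk.
#
# Branch-sharing metrics (PhyloSor, UniFrac): a branch "belongs to" a
# community iff at least one member tip descends through it, i.e. the branch
# lies on a root path of a member.  Distance metrics (Dnn, Dpw, Rao) work on
# the patristic matrix; species shared between the two plots contribute a
# distance of zero rather than being excluded.

#' Names of the supported beta-diversity metrics
#'
#' \code{phylo_metric_names()} lists the eight phylogeny-based metrics;
#' \code{beta_metric_names()} adds the species-level Jaccard and Bray-Curtis
#' dissimilarities.  The trailing \code{w} marks abundance weighting
#' (\code{dnnw} is Dnn', \code{dpww} is Dpw').
#'
#' @return character vector of metric names.
#' @export
beta_metric_names <- function() {
  c(phylo_metric_names(), "jaccard", "braycurtis")
}

#' @rdname beta_metric_names
#' @export
phylo_metric_names <- function() {
  c("phylosor", "unifrac", "dnn", "dnnw", "dpw", "dpww", "raod", "raoh")
}

#' Orientation of a metric
#' @param metric metric name as in [beta_metric_names()].
#' @return \code{"similarity"} (PhyloSor) or \code{"dissimilarity"}.
#' @export
metric_orientation <- function(metric) {
  metric <- match.arg(metric, beta_metric_names(), several.ok = TRUE)
  ifelse(metric == "phylosor", "similarity", "dissimilarity")
}

# shared precomputation for one (tree, community) pairing
.beta_context <- function(tree, comm) {
  tree <- validate_tree(tree)
  comm <- validate_community(comm, tree)
  eti <- .edge_tip_incidence(tree)
  inc <- eti$inc[, colnames(comm), drop = FALSE]
  D <- .pm_values(patristic_matrix(tree))[colnames(comm), colnames(comm), drop = FALSE]
  list(comm = comm, inc = inc, len = eti$len, D = D)
}

.plot_index <- function(ctx, plot) {
  if (!plot %in% rownames(ctx$comm)) stop("unknown plot: ", plot)
  which(ctx$comm[plot, ] > 0)
}

# relative-abundance weights over the species indices `sp`
.plot_weights <- function(ctx, plot, sp, mode) {
  if (mode == "presence") return(rep(1 / length(sp), length(sp)))
  x <- ctx$comm[plot, sp]
  x / sum(x)
}

.branch_member <- function(ctx, sp) rowSums(ctx$inc[, sp, drop = FALSE]) > 0

.phylosor_pair <- function(ctx, p1, p2) {
  m1 <- .branch_member(ctx, .plot_index(ctx, p1))
  m2 <- .branch_member(ctx, .plot_index(ctx, p2))
  2 * sum(ctx$len[m1 & m2]) / (sum(ctx$len[m1]) + sum(ctx$len[m2]))
}

.unifrac_pair <- function(ctx, p1, p2) {
  m1 <- .branch_member(ctx, .plot_index(ctx, p1))
  m2 <- .branch_member(ctx, .plot_index(ctx, p2))
  sum(ctx$len[xor(m1, m2)]) / sum(ctx$len[m1 | m2])
}

.dnn_pair <- function(ctx, p1, p2, mode) {
  s1 <- .plot_index(ctx, p1)
  s2 <- .plot_index(ctx, p2)
  Dsub <- ctx$D[s1, s2, drop = FALSE]
  mi <- apply(Dsub, 1L, min)
  mj <- apply(Dsub, 2L, min)
  if (mode == "presence")
    return((sum(mi) + sum(mj)) / (length(s1) + length(s2)))
  f1 <- .plot_weights(ctx, p1, s1, "abundance")
  f2 <- .plot_weights(ctx, p2, s2, "abundance")
  (sum(f1 * mi) + sum(f2 * mj)) / 2
}

.dpw_pair <- function(ctx, p1, p2, mode) {
  s1 <- .plot_index(ctx, p1)
  s2 <- .plot_index(ctx, p2)
  f1 <- .plot_weights(ctx, p1, s1, mode)
  f2 <- .plot_weights(ctx, p2, s2, mode)
  drop(f1 %*% ctx$D[s1, s2, drop = FALSE] %*% f2)
}

.raod_pair <- function(ctx, p1, p2, mode) {
  .dpw_pair(ctx, p1, p2, mode) / 2
}

# within-plot Rao diversity, ordered pairs including self (d_ii = 0)
.rao_within <- function(ctx, p, mode) {
  s <- .plot_index(ctx, p)
  f <- .plot_weights(ctx, p, s, mode)
  drop(f %*% ctx$D[s, s, drop = FALSE] %*% f) / 2
}

.raoh_pair <- function(ctx, p1, p2, mode) {
  .raod_pair(ctx, p1, p2, mode) -
    (.rao_within(ctx, p1, mode) + .rao_within(ctx, p2, mode)) / 2
}

#' PhyloSor similarity between two plots
#'
#' Phylogenetic analogue of Sorensen's index:
#' \eqn{2 BL_{k_1 k_2} / (BL_{k_1} + BL_{k_2})}, where \eqn{BL_k} is the
#' summed length of all branches on root paths of the species in community
#' \eqn{k} and \eqn{BL_{k_1 k_2}} the summed length of branches shared by
#' both.  1 for identical communities; on a star phylogeny it reduces to the
#' classical Sorensen similarity.
#'
#' @param tree a \code{"phylo"} tree covering all species.
#' @param comm plots-by-species community matrix.
#' @param plot1,plot2 plot ids.
#' @return similarity in \eqn{[0, 1]}.
#' @examples
#' f <- fig1_fixture()
#' phylosor(f$tree, f$comm, "C_blue", "C_orange")  # 2/3
#' @export
phylosor <- function(tree, comm, plot1, plot2) {
  ctx <- .beta_context(tree, comm)
  .phylosor_pair(ctx, plot1, plot2)
}

#' UniFrac dissimilarity between two plots
#'
#' Unique fraction of the phylogeny: summed length of branches belonging to
#' exactly one of the two communities divided by the summed length of
#' branches belonging to at least one.  0 for identical communities, 1 when
#' the communities share no branches.
#'
#' @inheritParams phylosor
#' @return dissimilarity in \eqn{[0, 1]}.
#' @export
unifrac <- function(tree, comm, plot1, plot2) {
  ctx <- .beta_context(tree, comm)
  .unifrac_pair(ctx, plot1, plot2)
}

#' Mean nearest phylogenetic neighbour distance (Dnn / Dnn')
#'
#' For each species the patristic distance to its nearest neighbour in the
#' other community.  Presence mode pools the minima over both communities and
#' divides by \eqn{n_1 + n_2}; abundance mode (Dnn') weights each minimum by
#' the species' relative abundance \eqn{f_i} within its own community and
#' halves the sum of the two community totals.  Species occurring in both
#' plots contribute a distance of zero.
#'
#' @inheritParams phylosor
#' @param mode \code{"presence"} or \code{"abundance"}.
#' @return non-negative distance in branch-length units.
#' @export
dnn <- function(tree, comm, plot1, plot2, mode = c("presence", "abundance")) {
  mode <- match.arg(mode)
  ctx <- .beta_context(tree, comm)
  .dnn_pair(ctx, plot1, plot2, mode)
}

#' Mean pairwise phylogenetic distance (Dpw / Dpw')
#'
#' Presence mode: mean patristic distance over all \eqn{n_1 n_2}
#' cross-community species pairs.  Abundance mode (Dpw'):
#' \eqn{\sum_i \sum_j f_i f_j d_{ij}} with relative abundances taken within
#' each community, which reduces to the presence value under equal
#' abundances.
#'
#' @inheritParams dnn
#' @return non-negative distance in branch-length units.
#' @export
dpw <- function(tree, comm, plot1, plot2, mode = c("presence", "abundance")) {
  mode <- match.arg(mode)
  ctx <- .beta_context(tree, comm)
  .dpw_pair(ctx, plot1, plot2, mode)
}

#' Rao's quadratic entropy between plots (D)
#'
#' \eqn{D_{12} = \frac{1}{2} \sum_i \sum_j f_i f_j d_{ij}} over
#' cross-community pairs; exactly half of Dpw', so the two metrics are
#' perfectly collinear across plot pairs.  Presence mode uses
#' \eqn{f_i = 1/n}.
#'
#' @inheritParams dnn
#' @param mode \code{"abundance"} (default) or \code{"presence"}.
#' @return non-negative value in branch-length units.
#' @export
rao_d <- function(tree, comm, plot1, plot2, mode = c("abundance", "presence")) {
  mode <- match.arg(mode)
  ctx <- .beta_context(tree, comm)
  .raod_pair(ctx, plot1, plot2, mode)
}

#' Rao's H: quadratic entropy standardized by alpha diversity
#'
#' \eqn{H = D_{12} - (D_{11} + D_{22})/2}, where \eqn{D_{kk}} is the
#' within-plot quadratic entropy over all ordered species pairs including
#' self pairs (\eqn{d_{ii} = 0}).  Zero for identical plots; non-negative on
#' ultrametric trees for disjoint communities.
#'
#' @inheritParams rao_d
#' @return real value in branch-length units.
#' @export
rao_h <- function(tree, comm, plot1, plot2, mode = c("abundance", "presence")) {
  mode <- match.arg(mode)
  ctx <- .beta_context(tree, comm)
  .raoh_pair(ctx, plot1, plot2, mode)
}

#' Jaccard dissimilarity between two plots
#'
#' \eqn{1 - |A \cap B| / |A \cup B|} on presence sets (via
#' \code{vegan::vegdist}).
#'
#' @param comm plots-by-species community matrix.
#' @param plot1,plot2 plot ids.
#' @return dissimilarity in \eqn{[0, 1]}.
#' @export
jaccard <- function(comm, plot1, plot2) {
  comm <- validate_community(comm)
  as.numeric(vegan::vegdist(comm[c(plot1, plot2), , drop = FALSE],
                            method = "jaccard", binary = TRUE))
}

#' Bray-Curtis dissimilarity between two plots
#'
#' \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)} on abundances (via
#' \code{vegan::vegdist}).
#'
#' @inheritParams jaccard
#' @return dissimilarity in \eqn{[0, 1]}.
#' @export
bray_curtis <- function(comm, plot1, plot2) {
  comm <- validate_community(comm)
  as.numeric(vegan::vegdist(comm[c(plot1, plot2), , drop = FALSE],
                            method = "bray"))
}

## ---- bulk computation -----------------------------------------------------

# vectorized PhyloSor / UniFrac over all plot pairs:
# S[a, b] = total length of branches belonging to both a and b,
# S[a, a] = BL_a, via one cross product of the edge membership matrix.
.branch_share_matrix <- function(ctx) {
  M <- (ctx$inc %*% t(ctx$comm > 0)) > 0
  storage.mode(M) <- "double"
  crossprod(M, M * ctx$len)
}

#' All pairwise beta-diversity values
#'
#' Computes the requested metrics for every unordered plot pair, returning a
#' long table with one row per pair and metric.  \code{dnn}/\code{dpw} are
#' presence-weighted, \code{dnnw}/\code{dpww} abundance-weighted;
#' \code{mode} selects the weighting of the Rao metrics (and is recorded per
#' row for all metrics).
#'
#' @param tree a \code{"phylo"} tree; may be \code{NULL} if only
#'   \code{jaccard}/\code{braycurtis} are requested.
#' @param comm plots-by-species community matrix with at least two plots.
#' @param metrics character vector from [beta_metric_names()].
#' @param mode weighting for \code{raod}/\code{raoh}: \code{"abundance"}
#'   (default) or \code{"presence"}.
#' @return data frame with columns \code{plot1}, \code{plot2}, \code{metric},
#'   \code{mode}, \code{value}; pairs ordered as \code{combn} of the row
#'   order, metrics in the order requested.
#' @examples
#' f <- fig1_fixture()
#' head(all_pairs(f$tree, f$comm, metrics = c("phylosor", "dpw")))
#' @export
all_pairs <- function(tree, comm, metrics = beta_metric_names(),
                      mode = c("abundance", "presence")) {
  mode <- match.arg(mode)
  unknown <- setdiff(metrics, beta_metric_names())
  if (length(unknown)) stop("unknown metric(s): ", paste(unknown, collapse = ", "))
  comm <- validate_community(comm)
  if (nrow(comm) < 2L) stop("need at least two plots")
  need_tree <- intersect(metrics, phylo_metric_names())
  ctx <- if (length(need_tree)) .beta_context(tree, comm) else NULL

  plots <- rownames(comm)
  pr <- utils::combn(plots, 2L)
  n_pair <- ncol(pr)
  i1 <- match(pr[1L, ], plots)
  i2 <- match(pr[2L, ], plots)

  value_of <- function(metric) {
    switch(metric,
      phylosor = ,
      unifrac = {
        S <- .branch_share_matrix(ctx)
        bl <- diag(S)
        if (metric == "phylosor") {
          2 * S[cbind(i1, i2)] / (bl[i1] + bl[i2])
        } else {
          sh <- S[cbind(i1, i2)]
          (bl[i1] + bl[i2] - 2 * sh) / (bl[i1] + bl[i2] - sh)
        }
      },
      dnn = vapply(seq_len(n_pair), function(k)
        .dnn_pair(ctx, pr[1L, k], pr[2L, k], "presence"), numeric(1L)),
      dnnw = vapply(seq_len(n_pair), function(k)
        .dnn_pair(ctx, pr[1L, k], pr[2L, k], "abundance"), numeric(1L)),
      dpw = ,
      dpww = ,
      raod = ,
      raoh = {
        w_mode <- if (metric == "dpw") "presence"
                  else if (metric == "dpww") "abundance"
                  else mode
        W <- t(apply(ctx$comm, 1L, function(x) {
          w <- if (w_mode == "presence") as.numeric(x > 0) else x
          w / sum(w)
        }))
        Q <- W %*% ctx$D %*% t(W)
        v <- Q[cbind(i1, i2)]
        switch(metric,
          dpw = ,
          dpww = v,
          raod = v / 2,
          raoh = v / 2 - (diag(Q)[i1] / 2 + diag(Q)[i2] / 2) / 2)
      },
      jaccard = {
        dm <- as.matrix(vegan::vegdist(comm, method = "jaccard", binary = TRUE))
        dm[cbind(i1, i2)]
      },
      braycurtis = {
        dm <- as.matrix(vegan::vegdist(comm, method = "bray"))
        dm[cbind(i1, i2)]
      })
  }

  mode_of <- function(metric) {
    switch(metric,
      dnnw = , dpww = , braycurtis = "abundance",
      raod = , raoh = mode,
      "presence")
  }

  do.call(rbind, lapply(metrics, function(m) {
    data.frame(plot1 = pr[1L, ], plot2 = pr[2L, ], metric = m,
               mode = mode_of(m), value = value_of(m),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Plot-by-plot matrix for one metric
#'
#' Reshapes rows of an [all_pairs()] table into a symmetric
#' \code{\link{pairwise_matrix}}; the diagonal is 1 for similarities
#' (PhyloSor) and 0 otherwise.
#'
#' @param pairs data frame as returned by [all_pairs()].
#' @param metric one metric name present in \code{pairs}.
#' @return a \code{\link{pairwise_matrix}}.
#' @export
beta_matrix <- function(pairs, metric) {
  rows <- pairs[pairs$metric == metric, , drop = FALSE]
  if (!nrow(rows)) stop("metric not present in table: ", metric)
  plots <- unique(c(rows$plot1, rows$plot2))
  m <- matrix(NA_real_, length(plots), length(plots),
              dimnames = list(plots, plots))
  m[cbind(rows$plot1, rows$plot2)] <- rows$value
  m[cbind(rows$plot2, rows$plot1)] <- rows$value
  orient <- unname(metric_orientation(metric))
  diag(m) <- if (orient == "similarity") 1 else 0
  if (anyNA(m)) stop("incomplete pair set for metric ", metric)
  pairwise_matrix(m, orient, metric)
}
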