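# Synthetic data: the 16-tip worked-example fixture with its four community
# pairs, and a gradient-community simulator emulating a tropical forest plot
# network along a steep rainfall gradient.

#' Worked-example fixture: 16-tip tree and four community pairs
#'
#' A balanced binary ultrametric 16-tip tree with every branch length set to
#' one (depth 4), tips \code{t1..t16} in cherries \code{(t1,t2)} through
#' \code{(t15,t16)}, plus four presence-absence community pairs illustrating
#' contrasting kinds of phylogenetic turnover.  Every scenario has complete
#' species turnover (species Jaccard = 1) while the phylogenetic turnover
#' ranges from maximally basal to maximally terminal:
#' \describe{
#'   \item{A}{blue = \code{t1..t4}, orange = \code{t9..t12}: clades in
#'     opposite halves of the root -- extreme basal turnover.}
#'   \item{B}{blue = \code{t1..t4}, orange = \code{t5..t8}: sister
#'     four-species clades -- moderate basal turnover.}
#'   \item{C}{blue = \code{t1,t3,t9,t11}, orange = \code{t2,t4,t10,t12}:
#'     cherry mates split between communities in both root halves --
#'     terminal turnover.}
#'   \item{D}{blue = \code{t1,t3,t5,t7}, orange = \code{t2,t4,t6,t8}:
#'     cherry mates split within one root half.}
#' }
#'
#' @return list of class \code{"fig1_fixture"} with elements \code{tree}
#'   (\code{"phylo"}), \code{comm} (8 plots by 16 species presence matrix,
#'   plots named \code{A_blue}, \code{A_orange}, ...) and \code{scenarios}
#'   (named list of plot-id pairs).
#' @examples
#' f <- fig1_fixture()
#' dpw(f$tree, f$comm, "A_blue", "A_orange")  # 8
#' @export
fig1_fixture <- function() {
  cherry <- function(i) sprintf("(t%d:1,t%d:1):1", i, i + 1L)
  quartet <- function(i) sprintf("(%s,%s):1", cherry(i), cherry(i + 2L))
  half <- function(i) sprintf("(%s,%s):1", quartet(i), quartet(i + 4L))
  nw <- sprintf("(%s,%s);", half(1L), half(9L))
  tree <- parse_newick(nw)

  scen <- list(
    A = list(blue = paste0("t", 1:4),           orange = paste0("t", 9:12)),
    B = list(blue = paste0("t", 1:4),           orange = paste0("t", 5:8)),
    C = list(blue = paste0("t", c(1, 3, 9, 11)), orange = paste0("t", c(2, 4, 10, 12))),
    D = list(blue = paste0("t", c(1, 3, 5, 7)),  orange = paste0("t", c(2, 4, 6, 8))))

  plots <- unlist(lapply(names(scen), function(s)
    paste(s, c("blue", "orange"), sep = "_")))
  comm <- matrix(0, length(plots), 16L,
                 dimnames = list(plots, paste0("t", 1:16)))
  for (s in names(scen)) {
    comm[paste0(s, "_blue"), scen[[s]]$blue] <- 1
    comm[paste0(s, "_orange"), scen[[s]]$orange] <- 1
  }
  scenarios <- lapply(names(scen), function(s)
    c(paste0(s, "_blue"), paste0(s, "_orange")))
  names(scenarios) <- names(scen)

  structure(list(tree = tree, comm = comm, scenarios = scenarios),
            class = "fig1_fixture")
}

#' Presence-weighted metric table over scenarios and lambda values
#'
#' Computes the six presence-weighted metrics (Dpw, Dnn, PhyloSor, UniFrac,
#' Rao's D, Rao's H) for each community pair of the worked-example fixture on
#' lambda-transformed versions of its tree.
#'
#' @param lambdas lambda values (default \code{c(1, 0.75, 0.5, 0.25, 0.001)},
#'   the last being effectively a star phylogeny).
#' @param fixture a [fig1_fixture()] (built fresh by default).
#' @return data frame with columns \code{metric}, \code{scenario},
#'   \code{lambda}, \code{value}.
#' @export
scenario_metric_table <- function(lambdas = c(1, 0.75, 0.5, 0.25, 0.001),
                                  fixture = fig1_fixture()) {
  metrics <- c("dpw", "dnn", "phylosor", "unifrac", "raod", "raoh")
  rows <- list()
  for (lam in lambdas) {
    tr <- lambda_transform(fixture$tree, lam)
    ctx <- .beta_context(tr, fixture$comm)
    for (s in names(fixture$scenarios)) {
      p <- fixture$scenarios[[s]]
      vals <- c(
        dpw = .dpw_pair(ctx, p[1L], p[2L], "presence"),
        dnn = .dnn_pair(ctx, p[1L], p[2L], "presence"),
        phylosor = .phylosor_pair(ctx, p[1L], p[2L]),
        unifrac = .unifrac_pair(ctx, p[1L], p[2L]),
        raod = .raod_pair(ctx, p[1L], p[2L], "presence"),
        raoh = .raoh_pair(ctx, p[1L], p[2L], "presence"))
      rows[[length(rows) + 1L]] <-
        data.frame(metric = metrics, scenario = s, lambda = lam,
                   value = unname(vals[metrics]),
                   stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a plot network along a rainfall gradient
#'
#' Generates a random ultrametric phylogeny, evolves a precipitation optimum
#' for every species on it, lays plots out on a latitudinal transect whose
#' annual rainfall rises monotonically between the range endpoints, and fills
#' each plot by multinomial sampling with species weights given by a Gaussian
#' niche kernel of the distance between the plot's rainfall and the species'
#' optimum.  The rainfall profile is a gentle linear ramp plus one sharp
#' escarpment step at a random position in the middle of the transect, the
#' signature of orographic rainfall on mountain gradients; the step makes
#' rainfall difference informative about community turnover beyond what
#' geographic distance alone carries.  Altitude is drawn independently of
#' community assembly and so serves as a negative control in Mantel
#' analyses.
#'
#' In \code{"conserved"} mode the optima are Brownian tip values, so
#' habitat preference carries phylogenetic signal and clades turn over along
#' the gradient; in \code{"labile"} mode the same optima are shuffled across
#' species, destroying the phylogenetic structure of turnover while leaving
#' the species-level gradient intact.
#'
#' @param n_plots number of plots (default 96).
#' @param n_species number of species (default 446).
#' @param total_individuals target summed abundance over all plots
#'   (default 61965); realized totals match to rounding.
#' @param precip_range annual rainfall endpoints in mm (default
#'   \code{c(776, 8340)}).
#' @param alt_range altitude range in m (default \code{c(55, 1060)}).
#' @param lat_range latitude range in degrees (default \code{c(13.2, 15.2)}).
#' @param lon longitude of the (constant-longitude) transect, degrees.
#' @param mode \code{"conserved"} or \code{"labile"} niche evolution.
#' @param niche_breadth Gaussian niche kernel standard deviation in mm of
#'   annual rainfall (default 600).
#' @param tree_age root-to-tip depth of the simulated phylogeny in
#'   normalized time units (default 1).
#' @param seed optional integer for a fully deterministic world.
#' @return list of class \code{"gradient_sim"} with elements \code{tree},
#'   \code{comm} (plots by species counts), \code{env} (environment data
#'   frame) and \code{optima} (per-species rainfall optima, mm).
#' @examples
#' g <- simulate_gradient(n_plots = 6, n_species = 12,
#'                        total_individuals = 600, seed = 1)
#' rowSums(g$comm)
#' @export
simulate_gradient <- function(n_plots = 96, n_species = 446,
                              total_individuals = 61965,
                              precip_range = c(776, 8340),
                              alt_range = c(55, 1060),
                              lat_range = c(13.2, 15.2),
                              lon = 74.8,
                              mode = c("conserved", "labile"),
                              niche_breadth = 600,
                              tree_age = 1,
                              seed = NULL) {
  mode <- match.arg(mode)
  if (n_plots < 2L) stop("'n_plots' must be at least 2")
  if (n_species < 2L) stop("'n_species' must be at least 2")
  rng_ok <- function(r) length(r) == 2L && all(is.finite(r)) && r[1L] < r[2L] && r[1L] > 0
  if (!rng_ok(precip_range)) stop("'precip_range' must be positive and increasing")
  if (!rng_ok(alt_range)) stop("'alt_range' must be positive and increasing")
  if (diff(lat_range) <= 0) stop("'lat_range' must be increasing")
  if (niche_breadth <= 0) stop("'niche_breadth' must be positive")
  if (total_individuals < n_plots)
    stop("'total_individuals' must allow at least one individual per plot")

  .with_seed(seed, {
    tree <- ape::rcoal(n_species, tip.label = sprintf("sp%04d", seq_len(n_species)))
    tree$edge.length <- tree$edge.length / tree_depth(tree) * tree_age

    bm <- simulate_bm(tree, sigma = 1)
    # rank-preserving affine map of Brownian tip values onto the rainfall range
    optima <- precip_range[1L] +
      (bm - min(bm)) / (max(bm) - min(bm)) * diff(precip_range)
    if (mode == "labile") optima <- stats::setNames(sample(optima), names(optima))

    plots <- sprintf("plot%03d", seq_len(n_plots))
    u <- seq(0, 1, length.out = n_plots)
    # monotone rainfall: linear ramp (35% of the range) plus an escarpment
    # step (65%) at a random crest position in the middle of the transect
    crest <- stats::runif(1L, 0.3, 0.7)
    shape <- 0.35 * u + 0.65 * (u > crest)
    precip <- precip_range[1L] + diff(precip_range) * shape
    env <- data.frame(plot = plots,
                      lat = lat_range[1L] + u * diff(lat_range),
                      lon = lon,
                      alt_m = stats::runif(n_plots, alt_range[1L], alt_range[2L]),
                      precip_mm = precip,
                      stringsAsFactors = FALSE)

    sizes <- rep(total_individuals %/% n_plots, n_plots)
    extra <- total_individuals - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L

    comm <- matrix(0, n_plots, n_species,
                   dimnames = list(plots, tree$tip.label))
    for (k in seq_len(n_plots)) {
      w <- exp(-((precip[k] - optima[tree$tip.label])^2) / (2 * niche_breadth^2))
      if (sum(w) <= 0 || !any(is.finite(w)))
        stop("infeasible configuration: niche kernel vanished at plot ", plots[k],
             " (niche_breadth too small for the optima spread)")
      comm[k, ] <- stats::rmultinom(1L, sizes[k], w)
    }

    structure(list(tree = tree, comm = comm, env = env, optima = optima),
              class = "gradient_sim")
  })
}

#' @export
print.gradient_sim <- function(x, ...) {
  cat(sprintf(paste0("gradient_sim: %d plots x %d species, %d individuals,\n",
                     "  rainfall %.0f-%.0f mm along %.1f-%.1f deg latitude\n"),
              nrow(x$comm), ncol(x$comm), sum(x$comm),
              min(x$env$precip_mm), max(x$env$precip_mm),
              min(x$env$lat), max(x$env$lat)))
  invisible(x)
}
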