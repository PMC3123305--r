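# Site-by-species tables and per-plot environment tables: CSV I/O,
# validation, relative abundances, and environmental distance matrices.

#' Validate a site-by-species community table
#'
#' A community table is a numeric matrix with plots as rows and species as
#' columns; entries are non-negative abundances (or 0/1 presences).  Every
#' plot must contain at least one individual.  When a tree is supplied every
#' species must be one of its tips: species missing from the phylogeny are a
#' hard error, since silently dropping them would bias every metric.
#'
#' @param comm matrix or data frame, plots as rows.
#' @param tree optional \code{"phylo"} tree to check species coverage against.
#' @return the table as a numeric matrix.
#' @export
validate_community <- function(comm, tree = NULL) {
  if (is.data.frame(comm)) comm <- as.matrix(comm)
  if (!is.matrix(comm) || !is.numeric(comm))
    stop("'comm' must be a numeric matrix (plots x species)")
  if (is.null(rownames(comm)) || is.null(colnames(comm)))
    stop("'comm' must have plot row names and species column names")
  if (anyDuplicated(rownames(comm))) stop("duplicate plot ids")
  if (anyDuplicated(colnames(comm))) stop("duplicate species ids")
  if (anyNA(comm)) stop("missing abundances; use 0 for absences")
  if (any(comm < 0)) stop("negative abundances are not allowed")
  if (any(rowSums(comm) == 0))
    stop("empty plots: ", paste(rownames(comm)[rowSums(comm) == 0], collapse = ", "))
  if (!is.null(tree)) {
    missing_sp <- setdiff(colnames(comm), tree$tip.label)
    if (length(missing_sp))
      stop("species absent from the tree: ", paste(missing_sp, collapse = ", "))
  }
  comm
}

#' Read a community table from CSV
#'
#' Expects a wide CSV with plot ids in the first column and one column per
#' species.  Missing abundance cells are treated as zeros.
#'
#' @param path CSV file path.
#' @param tree optional tree for species validation.
#' @return numeric plots-by-species matrix.
#' @export
read_community <- function(path, tree = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("community CSV needs a plot id column plus species columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate plot ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path)
  m[is.na(m)] <- 0
  rownames(m) <- ids
  validate_community(m, tree)
}

#' Write a community table to CSV
#' @param comm plots-by-species matrix.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_community <- function(comm, path) {
  comm <- validate_community(comm)
  df <- data.frame(plot = rownames(comm), comm, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a plot environment table from CSV
#'
#' Columns: \code{plot}, \code{lat} (degrees), \code{lon} (degrees),
#' \code{alt_m} (metres) and \code{precip_mm} (mm/yr).  Missing values are an
#' error, as is any latitude outside \eqn{[-90, 90]}.
#'
#' @param path CSV file path.
#' @return data frame with one row per plot.
#' @export
read_env <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_env(df)
}

#' Validate a plot environment table
#' @param env data frame with columns plot, lat, lon, alt_m, precip_mm.
#' @return the validated data frame.
#' @export
validate_env <- function(env) {
  needed <- c("plot", "lat", "lon", "alt_m", "precip_mm")
  miss <- setdiff(needed, names(env))
  if (length(miss)) stop("environment table lacks columns: ", paste(miss, collapse = ", "))
  env$plot <- as.character(env$plot)
  if (anyDuplicated(env$plot)) stop("duplicate plot ids in environment table")
  num <- c("lat", "lon", "alt_m", "precip_mm")
  for (v in num) {
    if (anyNA(env[[v]])) stop("missing values in environment column '", v, "'")
    if (!is.numeric(env[[v]])) stop("column '", v, "' must be numeric")
  }
  if (any(env$lat < -90 | env$lat > 90)) stop("latitude outside [-90, 90]")
  if (any(env$lon < -180 | env$lon > 360)) stop("longitude outside [-180, 360]")
  env
}

#' Write a plot environment table to CSV
#' @param env environment data frame.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_env <- function(env, path) {
  env <- validate_env(env)
  utils::write.csv(env, path, row.names = FALSE)
  invisible(path)
}

#' Relative abundances within one plot
#'
#' Returns \eqn{f_i}, the relative abundance of each species present in the
#' plot, summing to one.  In presence mode every present species gets
#' \eqn{1/n}; the presence-weighted metrics are the equal-abundance special
#' case of their abundance-weighted versions.
#'
#' @param comm community matrix.
#' @param plot plot id (row name).
#' @param mode \code{"abundance"} or \code{"presence"}.
#' @return named numeric vector over the species present in the plot.
#' @examples
#' comm <- matrix(c(3, 1), 1, dimnames = list("p1", c("a", "b")))
#' relative_abundance(comm, "p1")
#' @export
relative_abundance <- function(comm, plot, mode = c("abundance", "presence")) {
  mode <- match.arg(mode)
  comm <- validate_community(comm)
  if (!plot %in% rownames(comm)) stop("unknown plot: ", plot)
  x <- comm[plot, ]
  x <- x[x > 0]
  if (!length(x)) stop("plot ", plot, " is empty")
  if (mode == "presence") x[] <- 1
  x / sum(x)
}

#' Environmental distance matrices
#'
#' Great-circle (haversine, 6371 km sphere) geographic distances in km, and
#' absolute altitude (m) and annual precipitation (mm) differences between
#' all plot pairs.
#'
#' @param env validated environment table.
#' @return named list of three \code{\link{pairwise_matrix}} objects:
#'   \code{geographic_km}, \code{altitude_m}, \code{precipitation_mm}.
#' @export
env_distances <- function(env) {
  env <- validate_env(env)
  pts <- cbind(env$lon, env$lat)
  geo <- geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(geo) <- list(env$plot, env$plot)
  alt <- abs(outer(env$alt_m, env$alt_m, "-"))
  dimnames(alt) <- dimnames(geo)
  pre <- abs(outer(env$precip_mm, env$precip_mm, "-"))
  dimnames(pre) <- dimnames(geo)
  list(geographic_km = pairwise_matrix(geo, "dissimilarity", "geographic_km"),
       altitude_m = pairwise_matrix(alt, "dissimilarity", "altitude_m"),
       precipitation_mm = pairwise_matrix(pre, "dissimilarity", "precipitation_mm"))
}
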