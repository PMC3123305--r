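# Tree handling: newick I/O and validation, patristic distances, Pagel's
# lambda branch-length transformation, uniform random polytomy resolution.
# Trees are ape "phylo" objects throughout; branch lengths live on the child
# end of each edge and the root carries no branch.

#' Validate a phylogenetic tree
#'
#' Checks the invariants assumed by every other function in the package:
#' at least two tips, unique non-empty tip labels, and a finite non-negative
#' branch length on every edge.  Trees without branch lengths get unit
#' lengths.
#'
#' @param tree an object of class \code{"phylo"}.
#' @return the validated (possibly unit-branch-length) tree, invisibly usable.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a \"phylo\" object")
  nt <- ape::Ntip(tree)
  if (nt < 2L) stop("tree must have at least 2 tips")
  lab <- tree$tip.label
  if (any(is.na(lab) | !nzchar(lab))) stop("empty tip labels are not allowed")
  if (anyDuplicated(lab))
    stop("duplicate tip labels: ", paste(unique(lab[duplicated(lab)]), collapse = ", "))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 1
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  tree
}

# quick structural scan so malformed strings fail with a position, which
# ape::read.tree does not report
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error: unmatched ')' at position %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("newick parse error: %d unclosed '(' at end of string", depth))
  if (!grepl(";", text, fixed = TRUE))
    stop("newick parse error: missing terminating ';'")
  invisible(TRUE)
}

#' Parse a newick string
#'
#' Accepts the plain newick dialect: unquoted labels, branch lengths after
#' colons, unlabeled internal nodes, polytomies, trailing semicolon.  Edges
#' without a stated length default to length 1.
#'
#' @param text a single newick string.
#' @return a validated \code{"phylo"} tree.
#' @examples
#' tr <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
#' ape::Ntip(tr)
#' @seealso [read_newick()] for files, [write_newick()] for the inverse.
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single newick string")
  .check_newick_syntax(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error: unreadable tree string")
  validate_tree(tree)
}

#' Read a newick tree from a file
#' @param path path to a newick file (first tree used).
#' @return a validated \code{"phylo"} tree.
#' @export
read_newick <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Serialize a tree to newick
#' @param tree a \code{"phylo"} tree.
#' @param path optional file path; if \code{NULL} the string is returned.
#' @return the newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  tree <- validate_tree(tree)
  s <- ape::write.tree(tree, digits = 17)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

# distance from the root to every node, in branch-length units
.node_heights <- function(tree) ape::node.depth.edgelength(tree)

#' Root-to-tip depth of a tree
#' @param tree a \code{"phylo"} tree.
#' @return maximum root-to-tip path length.
#' @export
tree_depth <- function(tree) {
  tree <- validate_tree(tree)
  max(.node_heights(tree)[seq_len(ape::Ntip(tree))])
}

#' Is a tree ultrametric?
#'
#' All root-to-tip path lengths equal within a relative tolerance.
#'
#' @param tree a \code{"phylo"} tree.
#' @param tol relative tolerance (default \code{1e-9}).
#' @return logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-9) {
  tree <- validate_tree(tree)
  h <- .node_heights(tree)[seq_len(ape::Ntip(tree))]
  T <- max(h)
  if (T == 0) return(TRUE)
  (max(h) - min(h)) / T <= tol
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips
#' (\eqn{d_{ij}}), the substrate of the pairwise and nearest-neighbour
#' beta-diversity metrics.
#'
#' @param tree a \code{"phylo"} tree.
#' @return a \code{\link{pairwise_matrix}} (dissimilarity) over tip labels,
#'   rows ordered as \code{tree$tip.label}.
#' @examples
#' patristic_matrix(parse_newick("((a:1,b:1):1,c:2);"))
#' @export
patristic_matrix <- function(tree) {
  tree <- validate_tree(tree)
  m <- as.matrix(stats::cophenetic(tree))
  m <- m[tree$tip.label, tree$tip.label]
  pairwise_matrix(m, "dissimilarity", "patristic")
}

#' Pagel's lambda branch-length transformation
#'
#' Compresses every internal node's height (distance from the root) by the
#' factor \code{lam} while holding all tips at the original depth
#' \eqn{T}: terminal branches stretch to \eqn{T - \lambda h_{parent}}.
#' \code{lam = 1} is the identity; \code{lam -> 0} approaches a star
#' phylogeny in which all species are equally related.  Defined for
#' ultrametric trees only.
#'
#' @param tree an ultrametric \code{"phylo"} tree.
#' @param lam lambda in \eqn{[0, 1]}.
#' @return the transformed tree (same topology, same depth).
#' @examples
#' tr <- fig1_fixture()$tree
#' tree_depth(lambda_transform(tr, 0.5))  # depth preserved
#' @export
lambda_transform <- function(tree, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0 || lam > 1)
    stop("'lam' must be a single number in [0, 1]")
  tree <- validate_tree(tree)
  if (!is_ultrametric_tree(tree))
    stop("lambda transformation requires an ultrametric tree")
  nt <- ape::Ntip(tree)
  h <- .node_heights(tree)
  T <- max(h[seq_len(nt)])
  h_new <- h
  h_new[(nt + 1L):length(h)] <- lam * h[(nt + 1L):length(h)]
  h_new[seq_len(nt)] <- T
  tree$edge.length <- h_new[tree$edge[, 2L]] - h_new[tree$edge[, 1L]]
  tree
}

## ---- uniform random polytomy resolution -----------------------------------

# Uniform rooted binary shape on k labelled leaves by sequential edge
# addition: leaf j+1 attaches to one of the 2j-1 positions (any subtree,
# including above the current root) of the j-leaf tree, giving each of the
# (2k-3)!! labelled rooted shapes equal probability.
.uniform_binary_shape <- function(k) {
  insert_at <- function(node, path, leaf) {
    if (length(path) == 0L) return(list(node, leaf))
    node[[path[1L]]] <- insert_at(node[[path[1L]]], path[-1L], leaf)
    node
  }
  all_paths <- function(node, prefix = integer(0)) {
    out <- list(prefix)
    if (is.list(node))
      out <- c(out, all_paths(node[[1L]], c(prefix, 1L)),
               all_paths(node[[2L]], c(prefix, 2L)))
    out
  }
  tr <- list(1L, 2L)
  if (k > 2L) {
    for (j in 3L:k) {
      paths <- all_paths(tr)
      tr <- insert_at(tr, paths[[sample.int(length(paths), 1L)]], j)
    }
  }
  tr
}

#' Resolve polytomies uniformly at random
#'
#' Replaces every multifurcation by a binary expansion drawn uniformly from
#' all rooted binary shapes on its children.  Inserted branches have length
#' zero, so the total tree length and every tip-to-tip patristic distance are
#' conserved; only branch-sharing quantities (PhyloSor, UniFrac) can change.
#'
#' @param tree a rooted \code{"phylo"} tree, possibly with polytomies.
#' @param seed optional integer; when given the resolution is deterministic
#'   and the caller's RNG state is untouched.
#' @return a strictly binary \code{"phylo"} tree.
#' @examples
#' tr <- parse_newick("(a:1,b:1,c:1,d:1);")
#' ape::is.binary(resolve_polytomies(tr, seed = 1))
#' @export
resolve_polytomies <- function(tree, seed = NULL) {
  tree <- validate_tree(tree)
  if (ape::is.binary(tree)) return(tree)
  .with_seed(seed, .resolve_all(tree))
}

.resolve_all <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  kids <- vector("list", nn)
  len <- numeric(nn)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]
    ch <- tree$edge[k, 2L]
    kids[[p]] <- c(kids[[p]], ch)
    len[ch] <- tree$edge.length[k]
  }
  root <- nt + 1L
  env <- new.env(parent = emptyenv())
  env$kids <- kids
  env$len <- len
  env$nxt <- nn

  realize <- function(struct, members, parent_id) {
    if (!is.list(struct)) return(members[struct])
    env$nxt <- env$nxt + 1L
    id <- env$nxt
    env$len[id] <- 0
    env$kids[[id]] <- c(realize(struct[[1L]], members, id),
                        realize(struct[[2L]], members, id))
    id
  }

  todo <- root
  while (length(todo)) {
    nd <- todo[1L]
    todo <- todo[-1L]
    ch <- env$kids[[nd]]
    if (length(ch) > 2L) {
      shape <- .uniform_binary_shape(length(ch))
      env$kids[[nd]] <- c(realize(shape[[1L]], ch, nd),
                          realize(shape[[2L]], ch, nd))
    }
    todo <- c(todo, env$kids[[nd]][env$kids[[nd]] > nt])
  }

  rec <- function(nd) {
    ch <- if (nd <= length(env$kids)) env$kids[[nd]] else NULL
    if (is.null(ch) || length(ch) == 0L)
      return(sprintf("%s:%.17g", tree$tip.label[nd], env$len[nd]))
    sprintf("(%s):%.17g", paste(vapply(ch, rec, character(1L)), collapse = ","), env$len[nd])
  }
  nw <- paste0("(", paste(vapply(env$kids[[root]], rec, character(1L)), collapse = ","), ");")
  parse_newick(nw)
}

## ---- edge/tip incidence (internal, used by the beta metrics) --------------

# For every edge of the tree, which tips descend through it.  Returned as a
# logical edges-by-tips matrix (postorder edge order) plus the matching
# branch lengths.
.edge_tip_incidence <- function(tree) {
  nt <- ape::Ntip(tree)
  po <- stats::reorder(tree, "postorder")
  E <- nrow(po$edge)
  inc_node <- matrix(FALSE, nt + tree$Nnode, nt)
  inc_node[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (k in seq_len(E)) {
    p <- po$edge[k, 1L]
    ch <- po$edge[k, 2L]
    inc_node[p, ] <- inc_node[p, ] | inc_node[ch, ]
  }
  inc <- inc_node[po$edge[, 2L], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  list(inc = inc, len = po$edge.length)
}
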