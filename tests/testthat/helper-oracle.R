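# Independent brute-force reference implementations.  Everything works from
# enumerated root paths on the raw edge matrix and explicit loops; none of it
# reuses the package's incidence/crossprod machinery.

# per tip, the indices of the edges on its path to the root
oracle_root_paths <- function(tree) {
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ape::Ntip(tree) + 1L
  paths <- lapply(seq_len(ape::Ntip(tree)), function(tip) {
    path <- integer(0)
    nd <- tip
    while (nd != root) {
      e <- parent_edge[nd]
      path <- c(path, e)
      nd <- tree$edge[e, 1]
    }
    path
  })
  names(paths) <- tree$tip.label
  paths
}

# patristic distances as branch sums over the symmetric difference of root paths
oracle_patristic <- function(tree) {
  paths <- oracle_root_paths(tree)
  nt <- ape::Ntip(tree)
  D <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i != j) {
        sym <- c(setdiff(paths[[i]], paths[[j]]), setdiff(paths[[j]], paths[[i]]))
        D[i, j] <- sum(tree$edge.length[sym])
      }
    }
  }
  D
}

# second independent route: d_ij = depth_i + depth_j - 2 * depth_mrca
oracle_patristic_mrca <- function(tree) {
  h <- ape::node.depth.edgelength(tree)
  nt <- ape::Ntip(tree)
  M <- ape::mrca(tree)
  D <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i != j) D[i, j] <- h[i] + h[j] - 2 * h[M[i, j]]
    }
  }
  D
}

oracle_branch_set <- function(tree, species) {
  paths <- oracle_root_paths(tree)
  sort(unique(unlist(paths[species])))
}

oracle_phylosor <- function(tree, sp1, sp2) {
  b1 <- oracle_branch_set(tree, sp1)
  b2 <- oracle_branch_set(tree, sp2)
  2 * sum(tree$edge.length[intersect(b1, b2)]) /
    (sum(tree$edge.length[b1]) + sum(tree$edge.length[b2]))
}

oracle_unifrac <- function(tree, sp1, sp2) {
  b1 <- oracle_branch_set(tree, sp1)
  b2 <- oracle_branch_set(tree, sp2)
  uniq <- c(setdiff(b1, b2), setdiff(b2, b1))
  sum(tree$edge.length[uniq]) / sum(tree$edge.length[union(b1, b2)])
}

# relative abundances for a named count vector restricted to species present
oracle_relabund <- function(counts, presence_mode) {
  x <- counts[counts > 0]
  if (presence_mode) x[] <- 1
  x / sum(x)
}

oracle_dnn <- function(tree, x1, x2, mode) {
  D <- oracle_patristic(tree)
  sp1 <- names(x1)[x1 > 0]
  sp2 <- names(x2)[x2 > 0]
  mins1 <- sapply(sp1, function(i) min(sapply(sp2, function(j) D[i, j])))
  mins2 <- sapply(sp2, function(j) min(sapply(sp1, function(i) D[i, j])))
  if (mode == "presence")
    return((sum(mins1) + sum(mins2)) / (length(sp1) + length(sp2)))
  f1 <- oracle_relabund(x1, FALSE)
  f2 <- oracle_relabund(x2, FALSE)
  (sum(f1[sp1] * mins1) + sum(f2[sp2] * mins2)) / 2
}

oracle_dpw <- function(tree, x1, x2, mode) {
  D <- oracle_patristic(tree)
  sp1 <- names(x1)[x1 > 0]
  sp2 <- names(x2)[x2 > 0]
  f1 <- oracle_relabund(x1, mode == "presence")
  f2 <- oracle_relabund(x2, mode == "presence")
  total <- 0
  for (i in sp1) for (j in sp2) total <- total + f1[[i]] * f2[[j]] * D[i, j]
  total
}

oracle_raod <- function(tree, x1, x2, mode) oracle_dpw(tree, x1, x2, mode) / 2

oracle_raoh <- function(tree, x1, x2, mode) {
  D <- oracle_patristic(tree)
  within <- function(x) {
    sp <- names(x)[x > 0]
    f <- oracle_relabund(x, mode == "presence")
    total <- 0
    for (i in sp) for (j in sp) total <- total + f[[i]] * f[[j]] * D[i, j]
    total / 2
  }
  oracle_raod(tree, x1, x2, mode) - (within(x1) + within(x2)) / 2
}

# naive O(n^3) UPGMA returning the cophenetic matrix of merge heights
oracle_upgma_cophenetic <- function(x) {
  labs <- names(x)
  n <- length(x)
  D0 <- abs(outer(x, x, "-"))
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a < b) {
          d <- mean(D0[clusters[[a]], clusters[[b]]])
          if (d < best_d) {
            best_d <- d
            best <- c(a, b)
          }
        }
      }
    }
    coph[clusters[[best[1]]], clusters[[best[2]]]] <- best_d
    coph[clusters[[best[2]]], clusters[[best[1]]]] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  coph
}

# random (tree, community pair) instance on <= 8 tips; communities may
# overlap and may be abundance-weighted
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  tree <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
  repeat {
    x1 <- stats::setNames(rpois(n, 1.2), tree$tip.label)
    x2 <- stats::setNames(rpois(n, 1.2), tree$tip.label)
    if (sum(x1) > 0 && sum(x2) > 0) break
  }
  comm <- rbind(p1 = x1, p2 = x2)
  list(tree = tree, comm = comm, x1 = x1, x2 = x2)
}

# labelled Euclidean distance matrix on random points
make_dist <- function(n, seed, dim = 3) {
  set.seed(seed)
  m <- as.matrix(dist(matrix(runif(n * dim), n)))
  dimnames(m) <- list(paste0("p", seq_len(n)), paste0("p", seq_len(n)))
  m
}

# exhaustive list of all permutations of 1..n (tiny n only)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}
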