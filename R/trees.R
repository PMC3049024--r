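#' Simulate a birth-death species tree
#'
#' Fixed-size birth-death tree with branch lengths in expected
#' substitutions per site; seeded runs are deterministic.
#'
#' @param n_taxa number of tips (`>= 3`).
#' @param birth_rate,death_rate birth-death rates (`>= 0`).
#' @param seed integer seed or `NULL`.
#' @param unrooted return the unrooted tree (default).
#' @return an `ape::phylo` tree with tip labels `t1..tn`.
#' @export
simulate_species_tree <- function(n_taxa, birth_rate = 1, death_rate = 0,
                                  seed = NULL, unrooted = TRUE) {
  if (n_taxa < 3) stop("n_taxa must be at least 3")
  stopifnot(birth_rate >= 0, death_rate >= 0)
  with_seed(seed, {
    tr <- ape::rphylo(n_taxa, birth_rate, death_rate)
    if (unrooted) tr <- ape::unroot(tr)
    tr$edge.length <- pmax(tr$edge.length, 1e-8)
    tr
  })
}

#' Rescale a tree to a target mean root-to-tip depth
#'
#' Multiplies all branch lengths by a common factor so the mean
#' root-to-tip path length equals `depth` (expected substitutions per
#' site). Used to set family divergence to a controlled level.
#'
#' @param tree a `phylo`.
#' @param depth target mean root-to-tip depth.
#' @return the rescaled tree.
#' @export
rescale_tree_depth <- function(tree, depth) {
  rt <- if (ape::is.rooted(tree)) tree else
    ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  d <- ape::node.depth.edgelength(rt)
  cur <- mean(d[seq_along(rt$tip.label)])
  tree$edge.length <- tree$edge.length * depth / cur
  tree
}

# Deterministic internal-edge enumeration: edges of the postorder-reordered
# tree whose child is an internal node, in postorder position.
internal_edges <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  which(tree$edge[, 2] > length(tree$tip.label))
}

# Identify an edge by the tip set on its child side (stable across
# reorderings and grafts).
edge_split <- function(tree, edge_row) {
  ntip <- length(tree$tip.label)
  child <- tree$edge[edge_row, 2]
  if (child <= ntip) return(tree$tip.label[child])
  pp <- ape::prop.part(tree)
  sort(tree$tip.label[pp[[child - ntip]]])
}

# tips descending from each node (1..ntip+Nnode), as a list of tip labels
node_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  out <- vector("list", nn)
  for (i in seq_len(ntip)) out[[i]] <- tree$tip.label[i]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; c <- tr$edge[e, 2]
    out[[p]] <- c(out[[p]], out[[c]])
  }
  lapply(out, sort)
}

#' Graft an outgroup subtree onto a host-tree edge
#'
#' Attaches `outgroup` (kept monophyletic) to the midpoint of a host edge
#' via a stem branch, producing the joint constrained topology used by the
#' intersection tests. Pruning the outgroup taxa from the result restores
#' the host tree exactly.
#'
#' @param host unrooted host `phylo`.
#' @param outgroup `phylo` subtree; taxa must be disjoint from the host's.
#' @param edge row index into `host$edge` naming the attachment edge.
#' @param stem_length stem branch length (`>= 0`).
#' @param position attachment point along the edge, as a fraction of the
#'   edge length measured from the child end (default midpoint).
#' @return the joint `phylo` tree.
#' @export
graft_outgroup <- function(host, outgroup, edge, stem_length = 0.1,
                           position = 0.5) {
  if (edge < 1 || edge > nrow(host$edge)) stop("edge not in host tree")
  if (length(intersect(host$tip.label, outgroup$tip.label)))
    stop("outgroup taxa overlap host taxa")
  og <- outgroup
  og$root.edge <- stem_length
  child <- host$edge[edge, 2]
  pos <- host$edge.length[edge] * position
  joint <- ape::bind.tree(host, og, where = child, position = pos)
  joint
}

# prune outgroup taxa; returns host-comparable tree
prune_to_host <- function(joint, outgroup_taxa) {
  ape::drop.tip(joint, outgroup_taxa)
}

# unrooted topological identity
same_topology <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) return(FALSE)
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# LogDet / paralinear distance for amino-acid alignments, with a
# Jukes-Cantor-style fallback when the divergence matrix is singular.
logdet_dist <- function(aln) {
  taxa <- rownames(aln)
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  idx <- lapply(seq_len(n), function(i) match(aln[i, ], AA))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(idx[[i]]) & !is.na(idx[[j]])
    if (sum(ok) < 10) { d[i, j] <- d[j, i] <- 3; next }
    F <- unclass(table(factor(idx[[i]][ok], levels = 1:20),
                       factor(idx[[j]][ok], levels = 1:20)))
    F <- matrix(as.numeric(F + 0.1), 20, 20)
    F <- F / sum(F)
    fa <- rowSums(F); fb <- colSums(F)
    dt <- determinant(F, logarithm = TRUE)$modulus
    val <- -(as.numeric(dt) - 0.5 * (sum(log(fa)) + sum(log(fb)))) / 20
    if (!is.finite(val) || val <= 0) {
      p <- mean(idx[[i]][ok] != idx[[j]][ok])
      val <- -19 / 20 * log(max(1 - 20 / 19 * p, 1e-6))
    }
    d[i, j] <- d[j, i] <- val
  }
  as.dist(d)
}

#' Maximum-likelihood tree search with bootstrap support
#'
#' Starts from a LogDet-distance neighbour-joining tree and hill-climbs by
#' nearest-neighbour interchange, accepting moves that improve the
#' branch-length-optimized log-likelihood, until the NNI neighbourhood
#' contains no better tree. Bootstrap support is computed by resampling
#' alignment columns and re-running the full search per replicate.
#'
#' @inheritParams log_likelihood
#' @param n_bootstrap number of bootstrap replicates (0 = none).
#' @param max_rounds cap on NNI improvement rounds.
#' @return list with `tree` (ML tree; node labels carry bootstrap
#'   proportions when requested), `loglik` and `bootstrap_trees`.
#' @export
ml_search <- function(patterns, model, rates = rate_model(ncat = 1),
                      n_bootstrap = 0, max_rounds = 20,
                      condition = model$kind == "binary") {
  if (length(patterns$taxa) < 4) stop("need at least 4 taxa")
  search_one <- function(pat) {
    aln <- expand_patterns_matrix(pat)
    start <- if (pat$nsym == 20) ape::nj(logdet_dist(aln))
             else ape::nj(binary_dist(aln))
    start <- ape::unroot(start)
    start$edge.length <- pmax(start$edge.length, 1e-6)
    opt <- function(...) suppressWarnings(optimize_branch_lengths(...))
    cur <- opt(start, pat, model, rates,
               max_sweeps = 20, condition = condition)
    for (round in seq_len(max_rounds)) {
      nb <- phangorn::nni(cur$tree)
      improved <- FALSE
      for (ci in seq_along(nb)) {
        cand <- nb[[ci]]   # [[ restores tip labels on compressed multiPhylo
        cand$edge.length <- rep(0.1, nrow(cand$edge))
        fit <- opt(cand, pat, model, rates, max_sweeps = 10,
                   condition = condition)
        if (fit$loglik > cur$loglik + 1e-6) { cur <- fit; improved <- TRUE }
      }
      if (!improved) break
    }
    cur
  }
  best <- search_one(patterns)
  boots <- NULL
  if (n_bootstrap > 0) {
    boots <- vector("list", n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      pb <- resample_patterns(patterns)
      boots[[b]] <- search_one(pb)$tree
    }
    class(boots) <- "multiPhylo"
    pp <- ape::prop.part(boots)
    sup <- ape::prop.clades(best$tree, part = pp, rooted = FALSE) /
      n_bootstrap
    sup[is.na(sup)] <- 0
    best$tree$node.label <- formatC(sup, digits = 2, format = "f")
  }
  list(tree = best$tree, loglik = best$loglik, bootstrap_trees = boots)
}

# mean mismatch distance for binary patterns
binary_dist <- function(aln) {
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- mean(aln[i, ] != aln[j, ], na.rm = TRUE)
    d[i, j] <- d[j, i] <- -log(max(1 - 2 * p, 0.02)) / 2
  }
  as.dist(d)
}

# reconstruct a full character matrix from patterns (for distance starts)
expand_patterns_matrix <- function(pat) {
  m <- pat$states[, pat$site_index, drop = FALSE] + 1L
  sym <- c(pat$alphabet, NA)
  out <- matrix(sym[m], nrow(m), ncol(m))
  rownames(out) <- pat$taxa
  out
}

# multinomial column resampling expressed as new pattern weights
resample_patterns <- function(pat) {
  pick <- sample(rep.int(seq_along(pat$weights), pat$weights),
                 pat$nsites, replace = TRUE)
  w <- tabulate(pick, nbins = length(pat$weights))
  out <- pat
  keep <- w > 0
  out$states <- pat$states[, keep, drop = FALSE]
  out$weights <- as.numeric(w[keep])
  out$site_index <- match(pick, which(keep))
  out
}
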