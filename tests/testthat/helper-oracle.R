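# Independent likelihood oracle: exhaustive enumeration over internal-node
# state assignments, with transition probabilities from Matrix::expm (not
# the package's eigendecomposition path), and category rates from direct
# numerical integration of the gamma density (not the package's formula).

oracle_gamma_rates <- function(shape, k) {
  if (k == 1) return(1)
  qb <- qgamma((0:k) / k, shape, rate = shape)
  sapply(seq_len(k), function(j) {
    f <- function(x) x * dgamma(x, shape, rate = shape)
    k * integrate(f, qb[j], qb[j + 1], rel.tol = 1e-10)$value
  })
}

# Q: rate matrix; pi: root frequencies; tip_states: matrix ntip x nsites of
# 1-based states (NA = missing); tree: rooted/unrooted ape phylo.
oracle_loglik_onecat <- function(tree, tip_states, Q, root_freq, rate = 1) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  ns <- nrow(Q)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * rate * tree$edge.length[e])))
  internals <- (ntip + 1):nn
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  nsites <- ncol(tip_states)
  combos <- as.matrix(expand.grid(rep(list(seq_len(ns)),
                                      length(internals))))
  lik <- numeric(nsites)
  for (ci in seq_len(nrow(combos))) {
    st <- combos[ci, ]
    names(st) <- internals
    pr <- rep(root_freq[st[as.character(root)]], nsites)
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
      sa <- st[as.character(a)]
      if (b <= ntip) {
        sb <- tip_states[b, ]
        pe <- ifelse(is.na(sb), 1, P[[e]][sa, ifelse(is.na(sb), 1, sb)])
      } else {
        pe <- rep(P[[e]][sa, st[as.character(b)]], nsites)
      }
      pr <- pr * pe
    }
    lik <- lik + pr
  }
  lik
}

# full oracle with gamma mixture and optional restriction conditioning
oracle_loglik <- function(tree, tip_states, Q, root_freq, shape = NULL,
                          k = 1, condition = FALSE) {
  rates <- if (k == 1) 1 else oracle_gamma_rates(shape, k)
  lik <- 0
  for (r in rates)
    lik <- lik + oracle_loglik_onecat(tree, tip_states, Q, root_freq, r) / k
  if (condition) {
    absent <- matrix(1L, nrow(tip_states), 1)
    p0 <- 0
    for (r in rates)
      p0 <- p0 + oracle_loglik_onecat(tree, absent, Q, root_freq, r) / k
    lik <- lik / (1 - p0)
  }
  sum(log(lik))
}

# all unrooted binary topologies over the given tip labels (3 for 4 taxa,
# 15 for 5)
all_unrooted_topologies <- function(tips) {
  tl <- phangorn::allTrees(length(tips), rooted = FALSE, tip.label = tips)
  lapply(tl, identity)
}

random_blens <- function(tree, seed) {
  with_seed_local(seed, {
    tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.8)
    tree
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# character-state tip matrix from an alignment (1-based indices, NA = gap)
tips_to_states <- function(aln, alphabet) {
  m <- matrix(match(aln, alphabet), nrow(aln), ncol(aln))
  rownames(m) <- rownames(aln)
  m
}

# brute-force quartet oracle: prune both trees to each 4-subset
oracle_quartet_support <- function(reference, gene_trees) {
  ref <- ape::unroot(reference)
  ntip <- length(ref$tip.label)
  refP <- ape::reorder.phylo(ref, "postorder")
  ie <- which(refP$edge[, 2] > ntip)
  splits <- lapply(ie, function(e) dogphy:::edge_split(refP, e))
  inform <- agree <- numeric(length(ie))
  for (gt in gene_trees) {
    if (length(gt$tip.label) < 4) next
    for (q in utils::combn(gt$tip.label, 4, simplify = FALSE)) {
      sub_g <- ape::unroot(ape::keep.tip(gt, q))
      sub_r <- ape::unroot(ape::keep.tip(refP, q))
      if (sub_g$Nnode < 2) next                  # unresolved
      for (k in seq_along(ie)) {
        if (sum(q %in% splits[[k]]) != 2) next
        # reference quartet induced by this edge is the 2|2 split itself
        pair <- q[q %in% splits[[k]]]
        want <- ape::read.tree(text = sprintf("((%s,%s),(%s,%s));",
                                              pair[1], pair[2],
                                              setdiff(q, pair)[1],
                                              setdiff(q, pair)[2]))
        inform[k] <- inform[k] + 1
        if (ape::dist.topo(sub_g, ape::unroot(want)) == 0)
          agree[k] <- agree[k] + 1
      }
    }
  }
  data.frame(edge = ie, informative = inform, agreeing = agree,
             support = ifelse(inform > 0, 100 * agree / inform, NA))
}
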