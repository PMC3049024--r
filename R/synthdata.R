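#' Simulate gene presence/absence along a tree
#'
#' Evolves one binary character per gene family along the tree under a
#' two-state continuous-time Markov chain with gain and loss rates,
#' starting from a root state drawn with probability `root_prob` of
#' presence. Families absent in every taxon are unobservable and are
#' discarded and re-simulated until the requested number of observable
#' families is reached.
#'
#' @param tree `phylo` with branch lengths.
#' @param n_families number of observable families to produce.
#' @param gain,loss gain (0 to 1) and loss (1 to 0) rates per unit branch
#'   length.
#' @param root_prob probability the root carries a family.
#' @param lgt_rate optional lateral-transfer rate: expected number of
#'   transfer events per family per unit total tree length; each event
#'   copies presence from a random carrier to a random taxon.
#' @param seed integer seed.
#' @return list with `presence` (a `presence_matrix`: taxa x families) and
#'   `truth` (per-family root states and transfer counts).
#' @export
simulate_gene_content <- function(tree, n_families, gain = 0.5, loss = 0.5,
                                  root_prob = 0.8, lgt_rate = 0,
                                  seed = NULL) {
  stopifnot(gain >= 0, loss >= 0, root_prob >= 0, root_prob <= 1)
  if (gain == 0 && root_prob == 0)
    stop("no observable families possible with zero gain rate and zero ",
         "root presence probability")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  with_seed(seed, {
    tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    ntip <- length(tr$tip.label)
    nn <- ntip + tr$Nnode
    root <- ntip + 1L
    s <- gain + loss
    p01 <- function(t) if (s == 0) 0 else gain / s * (1 - exp(-s * t))
    p11 <- function(t) if (s == 0) 1 else gain / s + loss / s * exp(-s * t)
    simulate_block <- function(nf) {
      st <- matrix(0L, nn, nf)
      st[root, ] <- rbinom(nf, 1, root_prob)
      for (e in seq_len(nrow(tr$edge))) {
        p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; t <- tr$edge.length[e]
        pr <- ifelse(st[p, ] == 1L, p11(t), p01(t))
        st[ch, ] <- rbinom(nf, 1, pr)
      }
      list(tips = st[seq_len(ntip), , drop = FALSE],
           root = st[root, ])
    }
    tips <- matrix(0L, ntip, 0); roots <- integer(0)
    tries <- 0
    while (ncol(tips) < n_families) {
      tries <- tries + 1
      if (tries > 1000)
        stop("could not produce observable families; gain/root ",
             "probability too small")
      blk <- simulate_block(max(n_families - ncol(tips), 8))
      keep <- colSums(blk$tips) > 0
      tips <- cbind(tips, blk$tips[, keep, drop = FALSE])
      roots <- c(roots, blk$root[keep])
    }
    tips <- tips[, seq_len(n_families), drop = FALSE]
    roots <- roots[seq_len(n_families)]
    transfers <- integer(n_families)
    if (lgt_rate > 0) {
      tot <- sum(tr$edge.length)
      for (f in seq_len(n_families)) {
        nev <- stats::rpois(1, lgt_rate * tot)
        transfers[f] <- nev
        for (ev in seq_len(nev)) {
          carriers <- which(tips[, f] == 1L)
          if (!length(carriers)) next
          tips[sample.int(ntip, 1), f] <- 1L
        }
      }
    }
    rownames(tips) <- tr$tip.label
    colnames(tips) <- sprintf("F%04d", seq_len(n_families))
    presence <- structure(tips, class = "presence_matrix")
    list(presence = presence,
         truth = data.frame(family = colnames(tips), root_state = roots,
                            n_transfers = transfers))
  })
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d taxa x %d families, fill %.2f\n",
              nrow(x), ncol(x), mean(x == 1)))
  invisible(x)
}

#' Simulate an amino-acid (or binary) alignment on a tree
#'
#' Sites are iid given a per-site discrete-gamma rate category; with
#' covarion switch rates the process runs on the doubled hidden state
#' space and the observable residue is emitted. Optional crude indels
#' (per-site Bernoulli deletion on a random subtree) exist only to
#' exercise gap handling.
#'
#' @param tree `phylo` with branch lengths.
#' @param length number of sites.
#' @param model a `subst_model` or model name (`"WAG"`, `"Dayhoff"`,
#'   `"BLOSUM62"`).
#' @param rates a [rate_model()].
#' @param indel_prob per-site probability of a deletion event.
#' @param seed integer seed.
#' @return character matrix (taxa x sites); attribute `site_category`
#'   records each site's true rate category.
#' @export
simulate_alignment <- function(tree, length, model = "WAG",
                               rates = rate_model(ncat = 1),
                               indel_prob = 0, seed = NULL) {
  stopifnot(length >= 1)
  if (is.character(model)) model <- aa_model(model)
  with_seed(seed, {
    tr <- ape::reorder.phylo(tree, "cladewise")
    ntip <- base::length(tr$tip.label)
    nn <- ntip + tr$Nnode
    root <- ntip + 1L
    k <- rates$ncat
    catr <- if (k == 1) 1 else discretize_gamma(rates$shape, k)
    zcat <- sample.int(k, length, replace = TRUE)
    nsym <- model$nsym
    cov <- rates$covarion
    nstate <- if (cov) 2L * nsym else nsym
    root_freq <- if (!cov) model$pi else {
      p_on <- rates$s_on / (rates$s_on + rates$s_off)
      if (isTRUE(rates$root_on_only)) c(model$pi, rep(0, nsym))
      else c(model$pi * p_on, model$pi * (1 - p_on))
    }
    states <- matrix(0L, nn, length)
    states[root, ] <- sample.int(nstate, length, replace = TRUE,
                                 prob = root_freq)
    eig <- lapply(seq_len(k), function(j) {
      Q <- if (!cov) model$Q * catr[j]
           else covarion_Q(model$Q * catr[j], rates$s_on, rates$s_off)
      pi_full <- if (!cov) model$pi else {
        p_on <- rates$s_on / (rates$s_on + rates$s_off)
        c(model$pi * p_on, model$pi * (1 - p_on))
      }
      reversible_eigen(Q, pi_full)
    })
    Plist <- vector("list", k)
    for (e in seq_len(nrow(tr$edge))) {
      t <- tr$edge.length[e]
      for (j in seq_len(k)) {
        e_ <- eig[[j]]
        P <- e_$U %*% diag(exp(e_$lambda * t)) %*% e_$Uinv
        P[P < 0] <- 0
        Plist[[j]] <- P / rowSums(P)
      }
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      for (j in seq_len(k)) {
        sel <- which(zcat == j)
        if (!base::length(sel)) next
        ps <- states[p, sel]
        for (s in unique(ps)) {
          ii <- sel[ps == s]
          states[ch, ii] <- sample.int(nstate, base::length(ii),
                                       replace = TRUE,
                                       prob = Plist[[j]][s, ])
        }
      }
    }
    obs <- states[seq_len(ntip), , drop = FALSE]
    if (cov) obs <- ((obs - 1L) %% nsym) + 1L
    aln <- matrix(model$states[obs], ntip, length)
    rownames(aln) <- tr$tip.label
    if (indel_prob > 0) {
      tipsets <- node_tipsets(tr)
      for (site in which(runif(length) < indel_prob)) {
        nd <- sample(seq_len(nn)[-root], 1)
        aln[match(tipsets[[nd]], rownames(aln)), site] <- "-"
      }
    }
    attr(aln, "site_category") <- zcat
    aln
  })
}

#' Simulate per-taxon proteomes with known family membership
#'
#' Generates one sequence family per requested family: an ungapped
#' amino-acid "gene" evolved along the species tree, present exactly in
#' the taxa given by the presence matrix. Optional paralogous copies are
#' simulated as additional diverged branches within a taxon.
#'
#' @param tree species tree.
#' @param presence `presence_matrix` (taxa x families), or `NULL` for all
#'   present.
#' @param n_families number of families when `presence` is `NULL`.
#' @param seq_length sequence length per family.
#' @param scale branch-length multiplier controlling family divergence.
#' @param model substitution model (name or `subst_model`).
#' @param paralogs optional data frame with columns `family` (index or
#'   name), `taxon`, `copies` (extra copies to add).
#' @param paralog_divergence branch length separating paralogous copies.
#' @param seed integer seed.
#' @return list with `proteomes` (named list: taxon -> named character
#'   vector of sequences) and `truth` (data frame seq_id, taxon, family,
#'   is_paralog).
#' @export
simulate_proteomes <- function(tree, presence = NULL, n_families = NULL,
                               seq_length = 80, scale = 1, model = "WAG",
                               paralogs = NULL, paralog_divergence = 0.6,
                               seed = NULL) {
  if (is.character(model)) model <- aa_model(model)
  if (is.null(presence)) {
    stopifnot(!is.null(n_families))
    presence <- matrix(1L, length(tree$tip.label), n_families,
                       dimnames = list(tree$tip.label,
                                       sprintf("F%04d", seq_len(n_families))))
  }
  fams <- colnames(presence)
  taxa <- tree$tip.label
  with_seed(seed, {
    proteomes <- setNames(lapply(taxa, function(t) character(0)), taxa)
    truth <- list()
    sc_tree <- tree
    sc_tree$edge.length <- tree$edge.length * scale
    for (fi in seq_along(fams)) {
      f <- fams[fi]
      aln <- simulate_alignment(sc_tree, seq_length, model)
      for (t in taxa[presence[taxa, f] == 1L]) {
        id <- paste0(t, "|", f)
        sq <- paste(aln[t, ], collapse = "")
        proteomes[[t]][id] <- sq
        truth[[length(truth) + 1]] <-
          data.frame(seq_id = id, taxon = t, family = f,
                     is_paralog = FALSE)
        pr <- paralogs
        if (!is.null(pr)) {
          hit <- pr[(pr$family == f | pr$family == fi) & pr$taxon == t, ]
          if (nrow(hit)) {
            for (cp in seq_len(hit$copies[1])) {
              id2 <- paste0(t, "|", f, ".p", cp + 1)
              sq2 <- mutate_sequence(aln[t, ], model, paralog_divergence)
              proteomes[[t]][id2] <- paste(sq2, collapse = "")
              truth[[length(truth) + 1]] <-
                data.frame(seq_id = id2, taxon = t, family = f,
                           is_paralog = TRUE)
            }
          }
        }
      }
    }
    truth <- do.call(rbind, truth)
    if (anyDuplicated(truth$seq_id)) stop("duplicate sequence IDs")
    list(proteomes = proteomes, truth = truth)
  })
}

# evolve a residue vector along one branch of length t
mutate_sequence <- function(res, model, t) {
  e <- reversible_eigen(model$Q, model$pi)
  P <- e$U %*% diag(exp(e$lambda * t)) %*% e$Uinv
  P[P < 0] <- 0
  P <- P / rowSums(P)
  idx <- match(res, model$states)
  out <- idx
  for (s in unique(idx[!is.na(idx)])) {
    ii <- which(idx == s)
    out[ii] <- sample.int(model$nsym, length(ii), replace = TRUE,
                          prob = P[s, ])
  }
  ifelse(is.na(idx), res, model$states[out])
}

#' Simulate a constrained-intersection dataset with known attachment
#'
#' Grafts a monophyletic outgroup subtree onto a known host-tree edge and
#' simulates an amino-acid alignment on the joint tree; the true
#' attachment edge is recorded so placement-recovery experiments can be
#' scored.
#'
#' @param host_tree unrooted host `phylo`.
#' @param outgroup_tree outgroup `phylo`, taxa disjoint from the host.
#' @param attach_edge row of `host_tree$edge` to graft onto.
#' @param stem_length stem branch length.
#' @param length alignment length.
#' @param model substitution model name or object.
#' @param rates a [rate_model()].
#' @param seed integer seed.
#' @return list with `alignment`, `joint_tree` and `truth` (attachment
#'   edge index and its child-side tip set in the host tree).
#' @export
simulate_intersection_dataset <- function(host_tree, outgroup_tree,
                                          attach_edge, stem_length = 0.2,
                                          length = 10000, model = "WAG",
                                          rates = rate_model(shape = 1,
                                                             ncat = 4),
                                          seed = NULL) {
  joint <- graft_outgroup(host_tree, outgroup_tree, attach_edge,
                          stem_length)
  aln <- simulate_alignment(joint, length, model, rates, seed = seed)
  list(alignment = aln, joint_tree = joint,
       truth = list(attach_edge = attach_edge,
                    attach_split = edge_split(host_tree, attach_edge),
                    outgroup_taxa = outgroup_tree$tip.label))
}
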