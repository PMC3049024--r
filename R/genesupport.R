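#' Per-gene maximum-likelihood trees
#'
#' Infers one ML tree per family alignment via [ml_search()], restricted
#' to the taxa present in that family; families with fewer than four
#' taxa are skipped and logged.
#'
#' @param alignments named list of character-matrix alignments.
#' @param model substitution model.
#' @param rates a [rate_model()].
#' @return list with `trees` (named list of `phylo`) and `skipped`
#'   (family names with < 4 taxa).
#' @export
per_gene_trees <- function(alignments, model = aa_model("WAG"),
                           rates = rate_model(ncat = 1)) {
  trees <- list(); skipped <- character(0)
  for (f in names(alignments)) {
    a <- alignments[[f]]
    if (nrow(a) < 4) { skipped <- c(skipped, f); next }
    pat <- make_patterns(a)
    trees[[f]] <- ml_search(pat, model, rates)$tree
  }
  list(trees = trees, skipped = skipped)
}

# induced quartet topology from a topological distance matrix; returns
# 0 for unresolved, else the index (1..3) of the pairing:
# 1: (a,b)|(c,d)  2: (a,c)|(b,d)  3: (a,d)|(b,c)
quartet_top <- function(D, q) {
  s1 <- D[q[1], q[2]] + D[q[3], q[4]]
  s2 <- D[q[1], q[3]] + D[q[2], q[4]]
  s3 <- D[q[1], q[4]] + D[q[2], q[3]]
  s <- c(s1, s2, s3)
  if (sum(s == min(s)) > 1) return(0L)
  which.min(s)
}

topo_dist_matrix <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  D <- ape::cophenetic.phylo(t2)
  D[tree$tip.label, tree$tip.label]
}

#' Quartet support for a reference topology from gene trees
#'
#' Every four-taxon subset of each gene tree induces one quartet
#' topology there and one in the reference tree. A quartet is
#' informative for a reference edge when that edge separates its four
#' taxa two-against-two; support is the percentage of informative
#' quartets whose gene-tree topology agrees with the reference.
#'
#' @param reference_tree reference `phylo` (unrooted).
#' @param gene_trees list of `phylo` over subsets of the reference taxa.
#' @return object of class `quartet_support`: data frame with one row
#'   per internal reference edge: `edge`, `split`, `informative`,
#'   `agreeing`, `support` (percent).
#' @export
quartet_support <- function(reference_tree, gene_trees) {
  ref <- ape::reorder.phylo(ape::unroot(reference_tree), "postorder")
  ntip <- length(ref$tip.label)
  Dref <- topo_dist_matrix(ref)
  ie <- which(ref$edge[, 2] > ntip)
  splits <- lapply(ie, function(e) edge_split(ref, e))
  inform <- agree <- setNames(numeric(length(ie)),
                              vapply(ie, function(e) as.character(e), ""))
  for (gt in gene_trees) {
    if (!all(gt$tip.label %in% ref$tip.label))
      stop("gene tree taxa outside reference taxa")
    taxa <- gt$tip.label
    if (length(taxa) < 4) next
    Dg <- topo_dist_matrix(gt)
    quads <- utils::combn(taxa, 4, simplify = FALSE)
    for (q in quads) {
      tg <- quartet_top(Dg, q)
      if (tg == 0L) next                     # star quartet: uninformative
      for (k in seq_along(ie)) {
        inA <- q %in% splits[[k]]
        if (sum(inA) != 2) next              # edge must split 2|2
        # reference pairing induced by the edge
        pairing <- if (all(inA == c(TRUE, TRUE, FALSE, FALSE)) ||
                       all(inA == c(FALSE, FALSE, TRUE, TRUE))) 1L
                   else if (all(inA == c(TRUE, FALSE, TRUE, FALSE)) ||
                            all(inA == c(FALSE, TRUE, FALSE, TRUE))) 2L
                   else 3L
        inform[k] <- inform[k] + 1
        if (tg == pairing) agree[k] <- agree[k] + 1
      }
    }
  }
  out <- data.frame(edge = ie,
                    split = vapply(splits, paste, "", collapse = "+"),
                    informative = as.numeric(inform),
                    agreeing = as.numeric(agree),
                    support = ifelse(inform > 0, 100 * agree / inform,
                                     NA_real_))
  class(out) <- c("quartet_support", "data.frame")
  attr(out, "reference") <- ref
  out
}

#' Write the reference tree with quartet-support labels
#'
#' @param qs a [quartet_support()] table.
#' @param path output Newick path.
#' @export
write_support_tree <- function(qs, path) {
  ref <- attr(qs, "reference")
  ntip <- length(ref$tip.label)
  lab <- rep("", ref$Nnode)
  for (i in seq_len(nrow(qs))) {
    nd <- ref$edge[qs$edge[i], 2]
    lab[nd - ntip] <- formatC(qs$support[i], format = "f", digits = 1)
  }
  ref$node.label <- lab
  ape::write.tree(ref, path)
  invisible(path)
}

#' Pooled amino-acid composition profile
#'
#' @param sequences character vector of sequences, or a character-matrix
#'   alignment; gaps are excluded.
#' @param label group label.
#' @return object of class `composition_profile`: list with `freq`
#'   (named length-20 vector summing to 1), `n` residues, `label`.
#' @export
composition_profile <- function(sequences, label = "group") {
  ch <- if (is.matrix(sequences)) as.vector(sequences)
        else unlist(strsplit(sequences, ""))
  ch <- toupper(ch)
  counts <- tabulate(match(ch, AA), 20)
  if (sum(counts) == 0) stop("no residues in input")
  structure(list(freq = setNames(counts / sum(counts), AA),
                 n = sum(counts), label = label),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> %s: %d residues\n", x$label, x$n))
  invisible(x)
}

#' Correlation between compositional similarity and Bayes factors
#'
#' Tests whether intersection support merely tracks amino-acid
#' composition: computes the distance between each candidate node's
#' composition profile and the target (outgroup) profile, and the OLS
#' r-squared between those distances and the per-hypothesis average
#' log10 Bayes factors.
#'
#' @param node_profiles named list of `composition_profile` (names =
#'   hypothesis IDs).
#' @param target_profile a `composition_profile`.
#' @param bf_table a [run_intersection()] result.
#' @param metric `"euclidean"` or `"chisq"`.
#' @return list with `r2`, `p`, `table`.
#' @export
composition_correlation <- function(node_profiles, target_profile, bf_table,
                                    metric = c("euclidean", "chisq")) {
  metric <- match.arg(metric)
  avg <- attr(bf_table, "average")
  ids <- names(node_profiles)
  if (length(ids) < 3) stop("need at least 3 nodes")
  if (!all(ids %in% names(avg))) stop("node IDs must match BF hypotheses")
  dist1 <- vapply(node_profiles, function(p) {
    d <- p$freq - target_profile$freq
    if (metric == "euclidean") sqrt(sum(d^2))
    else sum(d^2 / pmax(target_profile$freq, 1e-9))
  }, 0)
  x <- avg[ids]; y <- dist1
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate variance: correlation undefined")
  r <- cor(x, y)
  n <- length(x)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- max(2 * pt(-abs(tval), n - 2), 1e-5)
  list(r2 = r^2, p = p,
       table = data.frame(hypothesis = ids, distance = unname(y),
                          avg_bf = unname(x)))
}
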