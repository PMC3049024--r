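#' Enumerate attachment hypotheses for a monophyletic outgroup
#'
#' Builds one constrained joint topology per internal edge of the host
#' tree (plus any explicitly listed terminal edges): the outgroup subtree
#' is grafted onto the midpoint of the edge via a stem branch. Hypotheses
#' are ordered deterministically by postorder edge index.
#'
#' @param host_tree unrooted binary host `phylo`.
#' @param outgroup_tree outgroup `phylo` (taxa disjoint from host).
#' @param extra_terminal_edges tip labels whose terminal edges should
#'   also be tested (e.g. conspicuously long terminal branches).
#' @param stem_length stem branch length used to initialize the graft.
#' @return list of `attachment_hypothesis` objects: `id`, `edge` (row in
#'   the postorder-reordered host edge matrix), `split` (child-side tip
#'   set), `tree` (joint topology).
#' @export
enumerate_attachments <- function(host_tree, outgroup_tree,
                                  extra_terminal_edges = character(0),
                                  stem_length = 0.1) {
  host <- ape::reorder.phylo(host_tree, "postorder")
  ntip <- length(host$tip.label)
  ie <- which(host$edge[, 2] > ntip)
  te <- which(host$tip.label[host$edge[, 2]] %in% extra_terminal_edges &
                host$edge[, 2] <= ntip)
  if (anyDuplicated(c(ie, te))) stop("duplicate edges in hypothesis list")
  missing_t <- setdiff(extra_terminal_edges, host$tip.label)
  if (length(missing_t)) stop("terminal edges not in host tree: ",
                              paste(missing_t, collapse = ", "))
  edges <- c(ie, te)
  out <- lapply(seq_along(edges), function(k) {
    e <- edges[k]
    structure(list(id = sprintf("H%02d", k), edge = e,
                   split = edge_split(host, e),
                   tree = graft_outgroup(host, outgroup_tree, e,
                                         stem_length)),
              class = "attachment_hypothesis")
  })
  attr(out, "host") <- host
  out
}

#' Estimate a log marginal likelihood from a chain trace
#'
#' Default estimator: stabilized harmonic mean of the sampled
#' log-likelihoods computed in log space, with a standard error from a
#' block bootstrap of the (autocorrelated) lnL series. Alternative:
#' stepping-stone sampling over a ladder of power posteriors
#' (`Beta(0.3, 1)`-spaced), for cross-checking; this re-runs the sampler
#' at each rung and needs `refit` arguments.
#'
#' @param trace a `chain_trace` (post-burn-in samples).
#' @param method `"harmonic"` or `"stepping"`.
#' @param n_boot bootstrap pseudo-replicates for the SE.
#' @param refit for `"stepping"`: a function `function(beta)` returning a
#'   `chain_trace` sampled under the likelihood raised to `beta`.
#' @param K number of stepping-stone rungs.
#' @return list with `logml`, `se`, `method`, `n`.
#' @export
estimate_log_marginal <- function(trace, method = c("harmonic", "stepping"),
                                  n_boot = 1000, refit = NULL, K = 8) {
  method <- match.arg(method)
  lnl <- trace$samples$lnl
  if (length(lnl) < 100 && method == "harmonic")
    stop("need at least 100 post-burn-in samples")
  if (method == "harmonic") {
    hm <- function(x) -logmeanexp(-x)
    est <- hm(lnl)
    n <- length(lnl)
    bl <- max(1, floor(sqrt(n)))
    nb <- ceiling(n / bl)
    boots <- vapply(seq_len(n_boot), function(b) {
      st <- sample.int(n - bl + 1, nb, replace = TRUE)
      idx <- as.vector(outer(0:(bl - 1), st, "+"))[seq_len(n)]
      hm(lnl[idx])
    }, 0)
    list(logml = est, se = sd(boots), method = "harmonic", n = n)
  } else {
    if (is.null(refit)) stop("stepping-stone needs a refit function")
    beta <- (seq(0, K) / K)^(1 / 0.3)  # Beta(0.3, 1) quantile schedule
    logr <- numeric(K)
    for (k in seq_len(K)) {
      tr_k <- refit(beta[k])           # power-posterior at lower rung
      x <- tr_k$samples$lnl
      logr[k] <- logmeanexp((beta[k + 1] - beta[k]) * x)
    }
    list(logml = sum(logr), se = NA_real_, method = "stepping", n = K)
  }
}

#' Log10 Bayes factors against the best hypothesis
#'
#' @param logml named numeric vector of log marginal likelihoods (natural
#'   log).
#' @return named vector: `(max(logml) - logml) / ln(10)`; the best
#'   hypothesis has 0, all others are positive.
#' @export
log10_bayes_factors <- function(logml) {
  stopifnot(length(logml) >= 2)
  (max(logml) - logml) / log(10)
}

#' Run the constrained-intersection analysis
#'
#' For every attachment hypothesis and every substitution model, runs a
#' fixed-topology MCMC over branch lengths (and gamma shape), estimates
#' the log marginal likelihood by the stabilized harmonic mean, and
#' tabulates log10 Bayes factors against each model's best hypothesis
#' plus the across-model average.
#'
#' @param patterns site patterns of the intersection alignment (host +
#'   outgroup taxa).
#' @param hypotheses from [enumerate_attachments()].
#' @param models character vector of amino-acid model names.
#' @param rates a [rate_model()].
#' @param config an [mcmc_config()]; a distinct child seed is derived per
#'   hypothesis x model.
#' @param sample_shape sample the gamma shape in each run.
#' @return a `bf_table`: data frame with one row per hypothesis x model
#'   (`hypothesis`, `split`, `model`, `logml`, `se`, `bf`) plus
#'   attributes `average` (per-hypothesis mean BF) and `best`.
#' @export
run_intersection <- function(patterns, hypotheses,
                             models = c("WAG", "Dayhoff"),
                             rates = rate_model(shape = 1, ncat = 4),
                             config = mcmc_config(n_generations = 5000,
                                                  sample_interval = 10,
                                                  burnin = 2000, seed = 1),
                             sample_shape = TRUE) {
  rows <- list()
  for (mi in seq_along(models)) {
    model <- aa_model(models[mi])
    logml <- se <- numeric(length(hypotheses))
    for (hi in seq_along(hypotheses)) {
      h <- hypotheses[[hi]]
      cfg <- config
      cfg$seed <- child_seed(config$seed, 1000 * mi + hi)
      tr <- mcmc_sample(patterns, model, rates, cfg, topology = h$tree,
                        sample_shape = sample_shape)
      est <- with_seed(cfg$seed, estimate_log_marginal(tr, "harmonic"))
      logml[hi] <- est$logml; se[hi] <- est$se
    }
    bf <- log10_bayes_factors(logml)
    rows[[mi]] <- data.frame(
      hypothesis = vapply(hypotheses, `[[`, "", "id"),
      split = vapply(hypotheses, function(h) paste(h$split, collapse = "+"),
                     ""),
      model = models[mi], logml = logml, se = se, bf = bf)
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("bf_table", "data.frame")
  avg <- aggregate(bf ~ hypothesis, tab, mean)
  attr(tab, "average") <- setNames(avg$bf, avg$hypothesis)
  attr(tab, "best") <- avg$hypothesis[which.min(avg$bf)]
  tab
}

#' @export
print.bf_table <- function(x, ...) {
  cat("<bf_table>", length(unique(x$hypothesis)), "hypotheses x",
      length(unique(x$model)), "models; best:", attr(x, "best"), "\n")
  print.data.frame(head(x[order(x$model, x$bf), ], 12))
  invisible(x)
}

#' Average Bayes factors over models and annotate the host tree
#'
#' @param bf_table a [run_intersection()] table (all models must share
#'   the hypothesis set).
#' @param hypotheses the hypothesis list the table was built from.
#' @param flag_threshold Bayes factors above this value are flagged
#'   (mirrors asterisk annotation of extreme values; default 1000).
#' @return list with `tree` (host tree, edge-annotated via node labels
#'   where applicable), `report` (per-hypothesis average BF, rank, flag)
#'   and `best`.
#' @export
average_and_map <- function(bf_table, hypotheses, flag_threshold = 1000) {
  hyps <- unique(bf_table$hypothesis)
  by_model <- split(bf_table, bf_table$model)
  for (m in by_model)
    if (!identical(sort(unique(m$hypothesis)), sort(hyps)))
      stop("hypothesis sets differ between models")
  avg <- aggregate(bf ~ hypothesis + split, bf_table, mean)
  avg <- avg[order(match(avg$hypothesis, vapply(hypotheses, `[[`, "", "id"))), ]
  report <- data.frame(hypothesis = avg$hypothesis, split = avg$split,
                       avg_bf = avg$bf, rank = rank(avg$bf,
                                                    ties.method = "min"),
                       flagged = avg$bf > flag_threshold)
  host <- attr(hypotheses, "host")
  lab <- rep(NA_character_, nrow(host$edge))
  for (k in seq_along(hypotheses))
    lab[hypotheses[[k]]$edge] <- formatC(report$avg_bf[k], format = "f",
                                         digits = 2)
  host$edge.label <- lab
  structure(list(tree = host, report = report,
                 best = report$hypothesis[which.min(report$avg_bf)]),
            class = "attachment_map")
}

#' @export
print.attachment_map <- function(x, ...) {
  cat("<attachment_map> best attachment:", x$best, "\n")
  print(x$report)
  invisible(x)
}

#' Heat-map plot of average Bayes factors on the host tree
#'
#' Colours each tested edge by its average log10 Bayes factor (best =
#' green through blue to red = worst, scaled between the observed
#' extremes) and prints the value above the branch; flagged extreme
#' values are marked with an asterisk.
#'
#' @param x an `attachment_map` from [average_and_map()].
#' @param ... passed to `ape::plot.phylo`.
#' @export
plot.attachment_map <- function(x, ...) {
  host <- x$tree
  bf <- rep(NA_real_, nrow(host$edge))
  bf[!is.na(host$edge.label)] <- as.numeric(stats::na.omit(host$edge.label))
  pal <- grDevices::colorRampPalette(c("forestgreen", "steelblue", "red"))(101)
  rng <- range(bf, na.rm = TRUE)
  sc <- if (diff(rng) > 0) (bf - rng[1]) / diff(rng) else rep(0, length(bf))
  col <- ifelse(is.na(bf), "grey40", pal[1 + round(100 * sc)])
  ape::plot.phylo(host, edge.color = col, ...)
  lab <- ifelse(is.na(bf), "",
                paste0(formatC(bf, format = "f", digits = 1),
                       ifelse(!is.na(bf) & bf > 1000, "*", "")))
  ape::edgelabels(lab, frame = "none", adj = c(0.5, -0.3), cex = 0.7)
  invisible(x)
}

#' Model independence of the Bayes-factor profile
#'
#' Ordinary least-squares r-squared (with slope and p-value from the t
#' transform of the correlation) between the per-hypothesis log10
#' Bayes-factor vectors obtained under each pair of substitution models.
#'
#' @param bf_table a [run_intersection()] table with >= 2 models.
#' @return data frame with one row per model pair: `model1`, `model2`,
#'   `r2`, `slope`, `p` (p-values floored at 1e-5).
#' @export
model_independence <- function(bf_table) {
  ms <- unique(bf_table$model)
  stopifnot(length(ms) >= 2)
  wide <- split(bf_table, bf_table$model)
  hyp <- sort(unique(bf_table$hypothesis))
  if (length(hyp) < 3) stop("need at least 3 hypotheses for r-squared")
  out <- list()
  for (i in seq_len(length(ms) - 1)) for (j in (i + 1):length(ms)) {
    a <- wide[[ms[i]]]; b <- wide[[ms[j]]]
    x <- a$bf[match(hyp, a$hypothesis)]
    y <- b$bf[match(hyp, b$hypothesis)]
    r <- cor(x, y)
    n <- length(x)
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- max(2 * pt(-abs(tval), n - 2), 1e-5)
    out[[length(out) + 1]] <-
      data.frame(model1 = ms[i], model2 = ms[j], r2 = r^2,
                 slope = coef(lm(y ~ x))[2], p = p)
  }
  do.call(rbind, out)
}

#' Remove clade-restricted families shared with the outgroup
#'
#' Drops DOGs whose host-side presence is confined to a focal clade
#' *and* that are detected in the outgroup — the families most plausibly
#' explained by lateral transfer between the clade and the outgroup.
#'
#' @param presence a `presence_matrix` (host taxa x families).
#' @param focal_clade_taxa host taxa forming the focal clade.
#' @param outgroup_detected character vector of family IDs detected in
#'   the outgroup.
#' @return list with `presence` (reduced matrix), `removed` (family
#'   IDs), `n_removed`.
#' @export
filter_shared_dogs <- function(presence, focal_clade_taxa,
                               outgroup_detected) {
  stopifnot(all(focal_clade_taxa %in% rownames(presence)))
  other <- setdiff(rownames(presence), focal_clade_taxa)
  confined <- colSums(presence[other, , drop = FALSE] == 1L) == 0
  remove <- confined & colnames(presence) %in% outgroup_detected
  out <- presence[, !remove, drop = FALSE]
  class(out) <- "presence_matrix"
  list(presence = out, removed = colnames(presence)[remove],
       n_removed = sum(remove))
}
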