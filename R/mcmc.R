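#' MCMC configuration
#'
#' Settings for the Metropolis samplers. Defaults mirror a typical
#' long-run configuration (300,000 generations, sampling every 500, four
#' Metropolis-coupled chains with incremental heating 0.2); analyses in
#' this package usually override them with much smaller desk-scale values.
#'
#' @param n_generations total generations.
#' @param sample_interval generations between recorded samples.
#' @param burnin generations discarded before sampling begins (burn-in is
#'   configuration here, not auto-detected; inspect traces with
#'   [plot.chain_trace()]).
#' @param n_chains number of Metropolis-coupled chains (free-topology
#'   sampler only; chain `i` runs at heat `1/(1 + temperature * (i-1))`).
#' @param temperature incremental heating parameter.
#' @param p_shape_move probability of proposing a gamma-shape update.
#' @param p_topology_move probability of proposing an NNI topology move
#'   (free-topology sampler only).
#' @param mult_lambda scale of the branch-length multiplier proposal.
#' @param shape_window width of the reflected sliding window on the shape.
#' @param bl_prior_rate rate of the exponential branch-length prior.
#' @param moves_per_edge consecutive multiplier proposals per edge visit
#'   in the fixed-topology sweep sampler.
#' @param seed integer seed; recorded and applied before sampling.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_generations = 300000, sample_interval = 500,
                        burnin = floor(n_generations / 3), n_chains = 4,
                        temperature = 0.2, p_shape_move = 0.15,
                        p_topology_move = 0.2, mult_lambda = 1.0,
                        shape_window = 0.35, bl_prior_rate = 10,
                        moves_per_edge = 4, seed = NULL) {
  stopifnot(burnin < n_generations, temperature > 0, n_chains >= 1)
  structure(list(n_generations = n_generations,
                 sample_interval = sample_interval, burnin = burnin,
                 n_chains = n_chains, temperature = temperature,
                 p_shape_move = p_shape_move,
                 p_topology_move = p_topology_move,
                 mult_lambda = mult_lambda, shape_window = shape_window,
                 bl_prior_rate = bl_prior_rate,
                 moves_per_edge = moves_per_edge, seed = seed),
            class = "mcmc_config")
}

new_chain_trace <- function(samples, trees = NULL, acc = NULL, config = NULL,
                            topology = NULL) {
  stopifnot(!is.unsorted(samples$gen, strictly = TRUE))
  structure(list(samples = samples, trees = trees, acc = acc,
                 config = config, topology = topology),
            class = "chain_trace")
}

#' @export
print.chain_trace <- function(x, ...) {
  cat(sprintf("<chain_trace> %d samples, lnL range [%.2f, %.2f]%s\n",
              nrow(x$samples), min(x$samples$lnl), max(x$samples$lnl),
              if (!is.null(x$trees)) sprintf(", %d trees", length(x$trees))
              else ""))
  invisible(x)
}

#' Sample branch lengths (and optionally topology) by MCMC
#'
#' Metropolis-Hastings sampling of branch lengths (multiplier proposal),
#' discrete-gamma shape (reflected sliding window) and, when the topology
#' is free, NNI topology moves with Metropolis-coupled chains. Priors are
#' iid exponential branch lengths and a uniform shape. With a fixed
#' topology a fast C++ sampler with cached partial likelihoods is used;
#' `beta_power` tempers the likelihood (used by stepping-stone marginal
#' likelihood estimation).
#'
#' @inheritParams log_likelihood
#' @param config an [mcmc_config()].
#' @param topology either a fixed `phylo` tree (fixed-topology run) or
#'   `"free"` to sample topology as well.
#' @param sample_shape sample the gamma shape (requires a plain,
#'   non-covarion rate model on the fixed-topology path).
#' @param beta_power power applied to the likelihood (1 = posterior).
#' @return a `chain_trace`: `samples` is a data frame with columns `gen`,
#'   `lnl`, `shape` and one column per branch; `trees` holds sampled
#'   topologies for free-topology runs.
#' @export
mcmc_sample <- function(patterns, model, rates = rate_model(ncat = 1),
                        config = mcmc_config(), topology,
                        sample_shape = FALSE, beta_power = 1,
                        condition = model$kind == "binary") {
  if (inherits(topology, "phylo"))
    mcmc_fixed(patterns, model, rates, config, topology, sample_shape,
               beta_power, condition)
  else if (identical(topology, "free"))
    mcmc_free(patterns, model, rates, config, sample_shape, condition)
  else stop("topology must be a phylo tree or \"free\"")
}

mcmc_fixed <- function(patterns, model, rates, config, tree, sample_shape,
                       beta_power, condition) {
  if (sample_shape && rates$covarion)
    stop("shape sampling is not supported with covarion rates on the ",
         "fixed-topology path")
  a <- engine_args(tree, patterns, model, rates, condition)
  r <- with_seed(config$seed,
    cpp_mcmc(a$edge, a$blen, a$ntip, a$st, a$wt, a$me$tipmap,
             a$me$U, a$me$Uinv, a$me$lambda, a$me$lambda_base, a$me$catw,
             a$me$root_freq, a$cond_pat, a$me$shape, sample_shape,
             as.integer(config$n_generations),
             as.integer(config$sample_interval),
             as.integer(config$burnin), config$p_shape_move,
             config$mult_lambda, config$shape_window, config$bl_prior_rate,
             0.05, 50, 1e-8, 20, beta_power,
             as.integer(config$moves_per_edge %||% 4)))
  bl <- r$blens
  colnames(bl) <- paste0("bl", seq_len(ncol(bl)))
  samples <- data.frame(gen = as.numeric(r$gen), lnl = as.numeric(r$lnl),
                        shape = as.numeric(r$shape), bl)
  new_chain_trace(samples, acc = c(branch = r$acc_bl, shape = r$acc_shape),
                  config = config, topology = tree)
}

# Free-topology sampler in R: full likelihood recomputation per proposal,
# NNI moves, optional Metropolis coupling. Meant for small alignments.
mcmc_free <- function(patterns, model, rates, config, sample_shape,
                      condition) {
  with_seed(config$seed, {
    nchain <- config$n_chains
    heats <- 1 / (1 + config$temperature * (seq_len(nchain) - 1))
    start_tree <- function() {
      tr <- ape::rtree(length(patterns$taxa), tip.label = sample(patterns$taxa))
      tr <- ape::unroot(tr)
      tr$edge.length <- rexp(nrow(tr$edge), 10)
      tr
    }
    lnl_of <- function(tree, shape) {
      rt <- rates
      if (!is.null(rt$shape)) rt$shape <- shape
      as.numeric(log_likelihood(tree, patterns, model, rt, condition))
    }
    chains <- lapply(seq_len(nchain), function(i) {
      tr <- start_tree()
      sh <- if (is.null(rates$shape)) 1 else rates$shape
      list(tree = tr, shape = sh, lnl = lnl_of(tr, sh))
    })
    logprior <- function(tree) -config$bl_prior_rate * sum(tree$edge.length)
    kept <- list(); gens <- lnls <- shapes <- numeric(0)
    acc <- c(prop = 0, acc = 0)
    for (g in seq_len(config$n_generations)) {
      for (ci in seq_len(nchain)) {
        st <- chains[[ci]]; heat <- heats[ci]
        u <- runif(1)
        if (u < config$p_topology_move && length(patterns$taxa) >= 4) {
          cand <- phangorn::rNNI(st$tree, 1)
          lnl1 <- lnl_of(cand, st$shape)
          logr <- heat * (lnl1 - st$lnl) + logprior(cand) - logprior(st$tree)
          if (log(runif(1)) < logr)
            st <- list(tree = cand, shape = st$shape, lnl = lnl1)
        } else if (sample_shape &&
                   u < config$p_topology_move + config$p_shape_move) {
          s1 <- st$shape + (runif(1) - 0.5) * config$shape_window
          while (s1 < 0.05 || s1 > 50) {
            if (s1 < 0.05) s1 <- 0.1 - s1
            if (s1 > 50) s1 <- 100 - s1
          }
          lnl1 <- lnl_of(st$tree, s1)
          if (log(runif(1)) < heat * (lnl1 - st$lnl))
            st <- list(tree = st$tree, shape = s1, lnl = lnl1)
        } else {
          e <- sample.int(nrow(st$tree$edge), 1)
          t0 <- st$tree$edge.length[e]
          t1 <- t0 * exp(config$mult_lambda * (runif(1) - 0.5))
          if (t1 >= 1e-8 && t1 <= 20) {
            cand <- st$tree; cand$edge.length[e] <- t1
            lnl1 <- lnl_of(cand, st$shape)
            logr <- heat * (lnl1 - st$lnl) +
              config$bl_prior_rate * (t0 - t1) + log(t1 / t0)
            acc["prop"] <- acc["prop"] + 1
            if (log(runif(1)) < logr) {
              st <- list(tree = cand, shape = st$shape, lnl = lnl1)
              acc["acc"] <- acc["acc"] + 1
            }
          }
        }
        chains[[ci]] <- st
      }
      if (nchain > 1 && g %% 10 == 0) { # propose a chain swap
        ij <- sample.int(nchain, 2)
        d <- (heats[ij[1]] - heats[ij[2]]) *
          (chains[[ij[2]]]$lnl - chains[[ij[1]]]$lnl)
        if (log(runif(1)) < d) chains[ij] <- chains[rev(ij)]
      }
      if (g > config$burnin &&
          (g - config$burnin) %% config$sample_interval == 0) {
        cold <- chains[[1]]
        kept[[length(kept) + 1]] <- cold$tree
        gens <- c(gens, g); lnls <- c(lnls, cold$lnl)
        shapes <- c(shapes, cold$shape)
      }
    }
    samples <- data.frame(gen = gens, lnl = lnls, shape = shapes)
    trees <- kept
    class(trees) <- "multiPhylo"
    new_chain_trace(samples, trees = trees,
                    acc = c(branch = unname(acc["acc"] / max(acc["prop"], 1))),
                    config = config)
  })
}

#' Majority-rule consensus with posterior bipartition support
#'
#' @param trees a list / `multiPhylo` of sampled trees over the same taxa.
#' @return list with `tree` (majority-rule consensus, node labels carry
#'   support) and `support` (bipartition frequencies in `[0, 1]`).
#' @export
consensus_tree <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  taxa <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(taxa, paste, "", collapse = "|"))) != 1)
    stop("trees have incompatible taxon sets")
  cons <- ape::consensus(trees, p = 0.5)
  pp <- ape::prop.part(trees)
  freq <- attr(pp, "number") / length(trees)
  sup <- ape::prop.clades(cons, part = pp, rooted = FALSE) / length(trees)
  sup[is.na(sup)] <- 0
  cons$node.label <- formatC(sup, digits = 3, format = "f")
  list(tree = cons, support = sup, part_freq = freq)
}

#' Write a chain trace as a tab-separated ".p"-style file
#'
#' @param trace a `chain_trace`.
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  write.table(trace$samples, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Trace plot of sampled log-likelihoods
#'
#' Utility for eyeballing stationarity when choosing a burn-in.
#' @param x a `chain_trace`.
#' @param ... passed to `plot`.
#' @export
plot.chain_trace <- function(x, ...) {
  plot(x$samples$gen, x$samples$lnl, type = "l", xlab = "generation",
       ylab = "log-likelihood", ...)
  invisible(x)
}
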