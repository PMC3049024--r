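test_that("discrete-gamma category rates are sorted, mean-1, and match quadrature", {
  expect_equal(discretize_gamma(0.7, 1), 1)
  for (shape in c(0.3, 0.5, 1, 2.7)) {
    r <- discretize_gamma(shape, 4)
    expect_false(is.unsorted(r))
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_equal(r, oracle_gamma_rates(shape, 4), tolerance = 1e-6)
  }
  r8 <- discretize_gamma(0.5, 8)
  expect_equal(r8, oracle_gamma_rates(0.5, 8), tolerance = 1e-6)
})

test_that("pruning likelihood equals exhaustive enumeration on 4-taxon AA trees", {
  m <- aa_model("WAG")
  for (tr in all_unrooted_topologies(paste0("t", 1:4))) {
    tr <- random_blens(tr, 42)
    aln <- simulate_alignment(tr, 15, m, seed = 7)
    pat <- make_patterns(aln)
    got <- as.numeric(log_likelihood(tr, pat, m))
    want <- oracle_loglik(tr, tips_to_states(aln[tr$tip.label, ], AA),
                          m$Q, m$pi)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("likelihood handles gaps as missing data (sums over states)", {
  m <- aa_model("WAG")
  tr <- random_blens(all_unrooted_topologies(paste0("t", 1:4))[[2]], 3)
  aln <- simulate_alignment(tr, 12, m, seed = 9)
  aln[1, 3] <- "-"; aln[3, 7] <- "-"
  pat <- make_patterns(aln)
  got <- as.numeric(log_likelihood(tr, pat, m))
  want <- oracle_loglik(tr, tips_to_states(aln[tr$tip.label, ], AA),
                        m$Q, m$pi)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("gamma-mixture likelihood matches the enumeration oracle", {
  m <- aa_model("Dayhoff")
  tr <- random_blens(all_unrooted_topologies(paste0("t", 1:5))[[4]], 11)
  aln <- simulate_alignment(tr, 10, m, rate_model(shape = 0.6, ncat = 4),
                            seed = 13)
  pat <- make_patterns(aln)
  got <- as.numeric(log_likelihood(tr, pat, m,
                                   rate_model(shape = 0.6, ncat = 4)))
  want <- oracle_loglik(tr, tips_to_states(aln[tr$tip.label, ], AA),
                        m$Q, m$pi, shape = 0.6, k = 4)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("restriction-model likelihood is conditioned on observability", {
  bm <- binary_model(0.4, 0.6)
  tr <- random_blens(all_unrooted_topologies(paste0("t", 1:4))[[1]], 5)
  x <- matrix(c(1L, 0L, 1L, 1L,
                0L, 1L, 1L, 0L,
                1L, 1L, 1L, 1L), 4, 3)
  rownames(x) <- paste0("t", 1:4)
  pat <- make_patterns(x, type = "binary")
  got <- as.numeric(log_likelihood(tr, pat, bm))
  st <- x + 1L
  want <- oracle_loglik(tr, st[tr$tip.label, , drop = FALSE], bm$Q, bm$pi,
                        condition = TRUE)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("conditioned observable-pattern probabilities sum to one (n <= 4)", {
  bm <- binary_model()
  for (n in 3:4) {
    tr <- random_blens(all_unrooted_topologies(paste0("t", 1:n))[[1]], n)
    pats <- as.matrix(expand.grid(rep(list(0:1), n)))
    pats <- pats[rowSums(pats) > 0, , drop = FALSE]   # observable only
    tot <- 0
    for (i in seq_len(nrow(pats))) {
      x <- matrix(as.integer(pats[i, ]), n, 1)
      rownames(x) <- paste0("t", 1:n)
      tot <- tot + exp(as.numeric(log_likelihood(
        tr, make_patterns(x, type = "binary"), bm,
        rate_model(shape = 0.7, ncat = 8))))
    }
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant under re-rooting (time-reversible model)", {
  m <- aa_model("WAG")
  tr <- random_blens(all_unrooted_topologies(paste0("t", 1:5))[[7]], 17)
  aln <- simulate_alignment(tr, 40, m, seed = 19)
  pat <- make_patterns(aln)
  base <- as.numeric(log_likelihood(tr, pat, m))
  for (og in c("t2", "t4")) {
    rr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(as.numeric(log_likelihood(rr, pat, m)), base,
                 tolerance = 1e-9)
  }
})

test_that("covarion likelihood reduces to the plain model as switch rates vanish", {
  m <- aa_model("WAG")
  tr <- random_blens(all_unrooted_topologies(paste0("t", 1:4))[[3]], 23)
  aln <- simulate_alignment(tr, 30, m, seed = 29)
  pat <- make_patterns(aln)
  plain <- as.numeric(log_likelihood(tr, pat, m))
  cov0 <- as.numeric(log_likelihood(
    tr, pat, m, rate_model(ncat = 1, s_on = 1e-7, s_off = 1e-7,
                           root_on_only = TRUE)))
  expect_equal(cov0, plain, tolerance = 1e-6)
})

test_that("covarion collapses to a single averaged rate at fast switching", {
  # at very fast switching every site sees the average of ON (rate 1) and
  # OFF (rate 0) weighted by the stationary hidden-state frequencies
  m <- binary_model()
  tr <- random_blens(all_unrooted_topologies(paste0("t", 1:4))[[1]], 31)
  x <- matrix(c(1L, 0L, 1L, 0L, 1L, 1L, 0L, 1L), 4, 2)
  rownames(x) <- paste0("t", 1:4)
  pat <- make_patterns(x, type = "binary")
  s <- 5e3
  fast <- as.numeric(log_likelihood(
    tr, pat, m, rate_model(ncat = 1, s_on = s, s_off = s),
    condition = FALSE))
  half <- tr
  half$edge.length <- tr$edge.length * 0.5   # p_on = 1/2
  avg <- as.numeric(log_likelihood(half, pat, m, condition = FALSE))
  expect_equal(fast, avg, tolerance = 1e-4)
})

test_that("covarion likelihood on the doubled state space matches enumeration", {
  m <- binary_model()
  tr <- random_blens(all_unrooted_topologies(paste0("t", 1:4))[[2]], 37)
  x <- matrix(c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L), 4, 2)
  rownames(x) <- paste0("t", 1:4)
  pat <- make_patterns(x, type = "binary")
  rm <- rate_model(ncat = 1, s_on = 0.7, s_off = 0.4)
  got <- as.numeric(log_likelihood(tr, pat, m, rm, condition = FALSE))
  Qc <- dogphy:::covarion_Q(m$Q, 0.7, 0.4)
  p_on <- 0.7 / 1.1
  pic <- c(m$pi * p_on, m$pi * (1 - p_on))
  # observed state s maps to hidden states {s_on, s_off}: enumerate both
  st <- x + 1L
  lik <- 0
  combos <- as.matrix(expand.grid(rep(list(0:1), nrow(x))))
  for (ci in seq_len(nrow(combos))) {
    sth <- st + 2L * matrix(combos[ci, ], nrow(x), ncol(x))
    lik <- lik + exp(sapply(seq_len(ncol(x)), function(j)
      oracle_loglik(tr, sth[tr$tip.label, j, drop = FALSE], Qc, pic)))
  }
  expect_equal(got, sum(log(lik)), tolerance = 1e-8)
})

test_that("branch-length optimization is monotone and stable at the optimum", {
  m <- aa_model("WAG")
  tr <- rescale_tree_depth(simulate_species_tree(6, 1, 0, seed = 41), 0.5)
  aln <- simulate_alignment(tr, 500, m, seed = 43)
  pat <- make_patterns(aln)
  fit <- optimize_branch_lengths(tr, pat, m)
  expect_true(all(diff(fit$trace) > -1e-9))
  expect_true(fit$converged)
  # restarting at the optimum changes nothing beyond tolerance
  fit2 <- optimize_branch_lengths(fit$tree, pat, m)
  expect_lt(abs(fit2$loglik - fit$loglik), 1e-4)
  expect_lt(fit2$sweeps, 3)
})

test_that("fixed-topology MCMC on degenerate constant data shrinks branches", {
  m <- aa_model("WAG")
  tr <- random_blens(all_unrooted_topologies(paste0("t", 1:4))[[1]], 47)
  aln <- matrix("A", 4, 50, dimnames = list(paste0("t", 1:4), NULL))
  pat <- make_patterns(aln)
  trc <- mcmc_sample(pat, m, config = mcmc_config(
    n_generations = 4000, sample_interval = 10, burnin = 1000, seed = 3),
    topology = tr)
  post <- colMeans(trc$samples[, grep("^bl", names(trc$samples))])
  expect_true(all(post < 0.05))
})

test_that("MCMC branch proposals are tuned into a sane acceptance band", {
  m <- aa_model("WAG")
  tr <- rescale_tree_depth(simulate_species_tree(8, 1, 0, seed = 53), 0.5)
  aln <- simulate_alignment(tr, 2000, m, rate_model(shape = 1, ncat = 4),
                            seed = 59)
  pat <- make_patterns(aln)
  trc <- mcmc_sample(pat, m, rate_model(shape = 1, ncat = 4),
                     mcmc_config(n_generations = 3000, sample_interval = 10,
                                 burnin = 1000, seed = 4),
                     topology = tr, sample_shape = TRUE)
  expect_gte(trc$acc["branch"], 0.1)
  expect_lte(trc$acc["branch"], 0.7)
  expect_gte(trc$acc["shape"], 0.1)
  expect_lte(trc$acc["shape"], 0.7)
})

test_that("posterior of a single free branch matches 1-D quadrature", {
  bm <- binary_model()
  # two-tip tree: likelihood depends on the total path length T, whose
  # prior (sum of two iid Exp(10) lengths) is Gamma(2, 10)
  tr <- ape::read.tree(text = "(a:0.2,b:0.2);")
  x <- matrix(c(rep(c(1L, 1L), 30), rep(c(1L, 0L), 12), rep(c(0L, 1L), 8)),
              nrow = 2)
  rownames(x) <- c("a", "b")
  pat <- make_patterns(x, type = "binary")
  lik_T <- function(T) {
    vapply(T, function(tt) {
      t2 <- tr; t2$edge.length <- c(tt / 2, tt / 2)
      exp(as.numeric(log_likelihood(t2, pat, bm)))
    }, 0)
  }
  prior <- function(T) dgamma(T, 2, 10)
  Z <- integrate(function(T) lik_T(T) * prior(T), 0, 20)$value
  post_mean <- integrate(function(T) T * lik_T(T) * prior(T), 0, 20)$value / Z
  trc <- mcmc_sample(pat, bm, config = mcmc_config(
    n_generations = 30000, sample_interval = 10, burnin = 5000, seed = 11),
    topology = tr)
  Tsamp <- rowSums(trc$samples[, c("bl1", "bl2")])
  mcse <- sd(Tsamp) / sqrt(length(Tsamp) / 10)  # crude ESS deflation
  expect_lt(abs(mean(Tsamp) - post_mean), 4 * mcse + 0.01)
})

test_that("free-topology MCMC consensus recovers a 5-taxon tree", {
  m <- aa_model("WAG")
  tr <- rescale_tree_depth(simulate_species_tree(5, 1, 0, seed = 61), 0.6)
  wins <- 0; runs <- 10
  for (r in seq_len(runs)) {
    aln <- simulate_alignment(tr, 300, m, seed = 70 + r)
    pat <- make_patterns(aln)
    trc <- mcmc_sample(pat, m, config = mcmc_config(
      n_generations = 1500, sample_interval = 10, burnin = 500,
      n_chains = 1, seed = 80 + r), topology = "free")
    cons <- consensus_tree(trc$trees)
    wins <- wins + dogphy:::same_topology(cons$tree, tr)
  }
  expect_gte(wins, 0.9 * runs)
})

test_that("majority-rule consensus matches hand-counted bipartition frequencies", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,b),(c,e),d);")
  trees <- c(rep(list(t1), 3), rep(list(t2), 2))
  cons <- consensus_tree(trees)
  # ab appears in 5/5 samples; cd in 3/5; ce in 2/5
  expect_true(dogphy:::same_topology(cons$tree, t1))
  expect_true(any(abs(cons$support - 1.0) < 1e-12))
  expect_true(any(abs(cons$support - 0.6) < 1e-12))
  # identical samples give supports of exactly 1
  cons2 <- consensus_tree(rep(list(t1), 4))
  expect_true(all(cons2$support[cons2$support > 0] == 1))
  expect_error(consensus_tree(list(t1, ape::read.tree(text = "((a,b),(c,f),e);"))),
               "incompatible")
})

test_that("two equally frequent conflicting bipartitions drop from the majority consensus", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,b),(c,e),d);")
  cons <- consensus_tree(list(t1, t2))
  # cd and ce conflict at 50/50: neither is in the strict majority tree
  expect_equal(cons$tree$Nnode, 2)
})

test_that("ML search recovers a clean 6-taxon topology with strong bootstrap support", {
  m <- aa_model("WAG")
  tr <- rescale_tree_depth(simulate_species_tree(6, 1, 0, seed = 91), 0.5)
  aln <- simulate_alignment(tr, 800, m, seed = 93)
  pat <- make_patterns(aln)
  fit <- with_seed_local(95, ml_search(pat, m, n_bootstrap = 20))
  expect_true(dogphy:::same_topology(fit$tree, tr))
  sup <- as.numeric(fit$tree$node.label)
  sup <- sup[!is.na(sup) & sup > 0]
  expect_true(all(sup >= 0.95))
  # local-optimum certificate: no NNI neighbour improves the likelihood
  nb <- phangorn::nni(fit$tree)
  for (ci in seq_along(nb)) {
    cand <- nb[[ci]]
    cand$edge.length <- rep(0.1, nrow(cand$edge))
    f <- suppressWarnings(optimize_branch_lengths(cand, pat, m,
                                                  max_sweeps = 15))
    expect_lte(f$loglik, fit$loglik + 0.01)
  }
})

test_that("branch recovery: optimized lengths track the generating values", {
  m <- aa_model("WAG")
  tr <- rescale_tree_depth(simulate_species_tree(6, 1, 0, seed = 97), 0.6)
  aln <- simulate_alignment(tr, 5000, m, seed = 99)
  pat <- make_patterns(aln)
  start <- tr
  start$edge.length <- rep(0.2, nrow(tr$edge))
  fit <- optimize_branch_lengths(start, pat, m)
  rel <- abs(fit$tree$edge.length - tr$edge.length) / tr$edge.length
  expect_lt(median(rel), 0.1)
})
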