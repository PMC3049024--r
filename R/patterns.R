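#' Compress an alignment into site patterns
#'
#' Collapses identical alignment columns into weighted site patterns, the
#' unit the likelihood engine works on. Gaps and ambiguity characters are
#' treated as missing data (summed over states).
#'
#' @param x a character matrix (taxa in rows) for amino-acid data, or an
#'   integer/numeric matrix of 0/1 (NA = missing) for binary
#'   detection/non-detection data. A `presence_matrix` is accepted.
#' @param type `"aa"` or `"binary"`; guessed from `x` when missing.
#' @return an object of class `site_patterns` with elements `states`
#'   (taxa x patterns, 0-based symbol codes, `nsym` = missing), `weights`,
#'   `taxa`, `nsym`, `alphabet` and `site_index` mapping original sites to
#'   patterns.
#' @export
make_patterns <- function(x, type = NULL) {
  if (inherits(x, "presence_matrix")) { x <- unclass(x); type <- "binary" }
  if (is.null(type)) type <- if (is.character(x)) "aa" else "binary"
  if (type == "aa") {
    alphabet <- AA
    m <- matrix(match(toupper(x), AA), nrow(x), ncol(x))
    m[is.na(m)] <- length(AA) + 1L  # gaps / unknowns -> missing
  } else {
    alphabet <- c("0", "1")
    m <- matrix(as.integer(x) + 1L, nrow(x), ncol(x))
    m[is.na(m) | !(m %in% c(1L, 2L))] <- 3L
  }
  if (is.null(rownames(x))) stop("alignment must have taxon rownames")
  key <- apply(m, 2, paste, collapse = ",")
  ft <- factor(key, levels = unique(key))
  idx <- as.integer(ft)
  first <- match(levels(ft), key)
  states <- m[, first, drop = FALSE] - 1L  # 0-based; nsym = missing
  structure(list(states = states, weights = as.numeric(tabulate(idx)),
                 taxa = rownames(x), nsym = length(alphabet),
                 alphabet = alphabet, site_index = idx,
                 nsites = ncol(x)),
            class = "site_patterns")
}

#' @export
print.site_patterns <- function(x, ...) {
  cat(sprintf("<site_patterns> %d taxa, %d sites, %d patterns (%s)\n",
              length(x$taxa), x$nsites, length(x$weights),
              if (x$nsym == 2) "binary" else "amino acid"))
  invisible(x)
}

# Reorder pattern rows to match tree tip order, append the ascertainment
# conditioning pattern when asked, and bundle engine arguments.
engine_args <- function(tree, patterns, model, rates, condition) {
  if (is.null(tree$tip.label) || length(tree$tip.label) < 2)
    stop("tree has no tip labels")
  ord <- match(tree$tip.label, patterns$taxa)
  if (anyNA(ord)) stop("tree taxa missing from patterns: ",
                       paste(setdiff(tree$tip.label, patterns$taxa),
                             collapse = ", "))
  st <- patterns$states[ord, , drop = FALSE]
  wt <- patterns$weights
  cond_pat <- -1L
  if (condition) {
    if (is.null(model$cond_state))
      stop("model has no conditioning state")
    st <- cbind(st, rep(as.integer(model$cond_state), nrow(st)))
    wt <- c(wt, 0)
    cond_pat <- ncol(st) - 1L  # 0-based for C++
  }
  me <- model_engine(model, rates)
  list(edge = tree$edge, blen = tree$edge.length, ntip = length(tree$tip.label),
       st = st, wt = wt, me = me, cond_pat = cond_pat)
}

#' Phylogenetic log-likelihood
#'
#' Felsenstein-pruning log-likelihood of site patterns on a tree under a
#' substitution model with discrete-gamma (and optionally covarion) rate
#' variation. Binary restriction-model likelihoods are conditioned on
#' characters being observable (not absent in every taxon), matching how
#' detection/non-detection data arise.
#'
#' @param tree an `ape::phylo` tree with branch lengths; taxa must cover
#'   the pattern taxa.
#' @param patterns a [make_patterns()] object.
#' @param model a [aa_model()] or [binary_model()].
#' @param rates a [rate_model()].
#' @param condition condition on observability (default: `TRUE` for the
#'   binary restriction model).
#' @return the total log-likelihood, with attribute `site_lnl` giving the
#'   per-pattern log-likelihoods.
#' @export
log_likelihood <- function(tree, patterns, model,
                           rates = rate_model(ncat = 1),
                           condition = model$kind == "binary") {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  a <- engine_args(tree, patterns, model, rates, condition)
  r <- cpp_loglik(a$edge, a$blen, a$ntip, a$st, a$wt, a$me$tipmap,
                  a$me$U, a$me$Uinv, a$me$lambda, a$me$lambda_base,
                  a$me$catw, a$me$root_freq, a$cond_pat, a$me$shape)
  sl <- as.numeric(r$site_lnl)
  if (a$cond_pat >= 0) sl <- sl[-(a$cond_pat + 1)]
  structure(r$loglik, site_lnl = sl)
}

#' Per-site log-likelihoods on the original site grid
#'
#' @inheritParams log_likelihood
#' @return numeric vector of length `patterns$nsites`.
#' @export
site_loglik <- function(tree, patterns, model, rates = rate_model(ncat = 1),
                        condition = model$kind == "binary") {
  ll <- log_likelihood(tree, patterns, model, rates, condition)
  attr(ll, "site_lnl")[patterns$site_index]
}

#' Optimize branch lengths (and optionally the gamma shape)
#'
#' Sequential coordinate ascent: each branch is optimized in turn by
#' bounded scalar (Brent) search on `[1e-8, 20]` with all cached partial
#' likelihoods updated exactly, so the log-likelihood never decreases
#' across sweeps. Sweeps repeat until the improvement falls below `tol`.
#'
#' @inheritParams log_likelihood
#' @param optimize_shape also optimize the discrete-gamma shape.
#' @param max_sweeps hard cap on coordinate-ascent sweeps.
#' @param tol convergence tolerance on the log-likelihood.
#' @return list with elements `tree` (optimized branch lengths), `loglik`,
#'   `shape`, `converged`, `sweeps`, `trace` (lnL per sweep) and
#'   `site_lnl`.
#' @export
optimize_branch_lengths <- function(tree, patterns, model,
                                    rates = rate_model(ncat = 1),
                                    optimize_shape = FALSE,
                                    max_sweeps = 100, tol = 1e-6,
                                    condition = model$kind == "binary") {
  if (optimize_shape && rates$covarion)
    stop("shape optimization is not supported together with covarion rates")
  a <- engine_args(tree, patterns, model, rates, condition)
  r <- cpp_optimize(a$edge, a$blen, a$ntip, a$st, a$wt, a$me$tipmap,
                    a$me$U, a$me$Uinv, a$me$lambda, a$me$lambda_base,
                    a$me$catw, a$me$root_freq, a$cond_pat, a$me$shape,
                    optimize_shape, 1e-8, 20, tol, max_sweeps)
  if (!r$converged)
    warning("branch-length optimization did not converge in ",
            max_sweeps, " sweeps")
  tree$edge.length <- as.numeric(r$blens)
  sl <- as.numeric(r$site_lnl)
  if (a$cond_pat >= 0) sl <- sl[-(a$cond_pat + 1)]
  list(tree = tree, loglik = r$loglik, shape = r$shape,
       converged = r$converged, sweeps = r$sweeps,
       trace = as.numeric(r$trace), site_lnl = sl)
}
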