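#' Per-site log-likelihoods for a set of topology hypotheses
#'
#' Optimizes branch lengths (and optionally the gamma shape) for every
#' hypothesis and records per-site log-likelihoods on the pattern grid
#' together with pattern weights; the matrix feeds the SH and AU tests.
#'
#' @param hypotheses list of `phylo` trees (or `attachment_hypothesis`
#'   objects) over the same taxon set.
#' @param patterns site patterns.
#' @param model substitution model.
#' @param rates a [rate_model()].
#' @param optimize_shape optimize the gamma shape per hypothesis.
#' @param tol,max_sweeps optimizer settings (branch-length differences of
#'   interest here are large, so a loose tolerance is adequate).
#' @return object of class `site_lnl_matrix`: list with `lnl` (hypotheses
#'   x patterns), `weights`, `total` (per-hypothesis lnL), `delta`
#'   (lnL difference to the best hypothesis), `ids`.
#' @export
per_site_lnl <- function(hypotheses, patterns, model,
                         rates = rate_model(ncat = 1),
                         optimize_shape = FALSE, tol = 1e-3,
                         max_sweeps = 30) {
  trees <- lapply(hypotheses, function(h)
    if (inherits(h, "attachment_hypothesis")) h$tree else h)
  ids <- vapply(seq_along(hypotheses), function(i) {
    h <- hypotheses[[i]]
    if (inherits(h, "attachment_hypothesis")) h$id else sprintf("T%02d", i)
  }, "")
  npat <- length(patterns$weights)
  lnl <- matrix(NA_real_, length(trees), npat)
  warns <- logical(length(trees))
  for (i in seq_along(trees)) {
    fit <- withCallingHandlers(
      optimize_branch_lengths(trees[[i]], patterns, model, rates,
                              optimize_shape = optimize_shape,
                              tol = tol, max_sweeps = max_sweeps),
      warning = function(w) { warns[i] <<- TRUE
        invokeRestart("muffleWarning") })
    lnl[i, ] <- fit$site_lnl
  }
  total <- as.numeric(lnl %*% patterns$weights)
  structure(list(lnl = lnl, weights = patterns$weights, total = total,
                 delta = max(total) - total, ids = ids,
                 warnings = warns, nsites = patterns$nsites),
            class = "site_lnl_matrix")
}

#' @export
print.site_lnl_matrix <- function(x, ...) {
  cat(sprintf("<site_lnl_matrix> %d hypotheses x %d patterns (best: %s)\n",
              nrow(x$lnl), ncol(x$lnl), x$ids[which.max(x$total)]))
  invisible(x)
}

# weighted RELL resample of pattern columns: returns resampled totals
# per hypothesis (one bootstrap replicate), resample size m sites
rell_totals <- function(mat, weights, m) {
  idx <- sample.int(length(weights), m, replace = TRUE,
                    prob = weights / sum(weights))
  w <- tabulate(idx, nbins = length(weights))
  as.numeric(mat %*% w)
}

#' Shimodaira-Hasegawa test by RELL resampling
#'
#' Simultaneous one-sided SH construction: RELL bootstrap of the
#' per-site log-likelihood columns, each hypothesis's resampled totals
#' centred by its own bootstrap mean; the null deviate of replicate `b`
#' is the maximum centred value across hypotheses, and the p-value of
#' hypothesis `h` is the fraction of replicates whose deviate reaches
#' the observed lnL difference `delta_h`. p-values are therefore
#' non-increasing in `delta`, the maximum-likelihood hypothesis has
#' p = 1, and the test is conservative.
#'
#' @param matrix_lnl a [per_site_lnl()] object.
#' @param n_rell RELL replicates (default 1000).
#' @return data frame `hypothesis`, `lnl`, `delta`, `p_sh` (floored at
#'   `1/n_rell`).
#' @export
sh_test <- function(matrix_lnl, n_rell = 1000) {
  stopifnot(nrow(matrix_lnl$lnl) >= 2, n_rell >= 100)
  H <- nrow(matrix_lnl$lnl)
  m <- matrix_lnl$nsites
  R <- matrix(NA_real_, H, n_rell)
  for (b in seq_len(n_rell))
    R[, b] <- rell_totals(matrix_lnl$lnl, matrix_lnl$weights, m)
  Rc <- R - rowMeans(R)                      # centre by own mean
  D <- apply(Rc, 2, max)                     # common null deviate
  p <- vapply(seq_len(H), function(h)
    mean(D >= matrix_lnl$delta[h]), 0)
  p <- pmax(p, 1 / n_rell)
  p[matrix_lnl$delta == 0] <- 1
  data.frame(hypothesis = matrix_lnl$ids, lnl = matrix_lnl$total,
             delta = matrix_lnl$delta, p_sh = p)
}

#' Approximately unbiased (AU) test by multiscale bootstrap
#'
#' For each scale `r`, RELL bootstrap with resample size `round(r * n)`;
#' the bootstrap proportion `BP_h(r)` of replicates in which hypothesis
#' `h` is best is fit as `qnorm(1 - BP) = d * sqrt(r) + c / sqrt(r)` by
#' weighted least squares over scales, and the AU p-value is
#' `1 - pnorm(d - c)`. Degenerate fits (BP identically 0 or 1) are
#' clamped and flagged.
#'
#' @param matrix_lnl a [per_site_lnl()] object.
#' @param scales bootstrap scale factors (default `seq(0.5, 1.4, 0.1)`).
#' @param n_boot replicates per scale (default 1000).
#' @return data frame `hypothesis`, `delta`, `p_au`, `degenerate`.
#' @export
au_test <- function(matrix_lnl, scales = seq(0.5, 1.4, by = 0.1),
                    n_boot = 1000) {
  stopifnot(nrow(matrix_lnl$lnl) >= 2)
  H <- nrow(matrix_lnl$lnl)
  n <- matrix_lnl$nsites
  bp <- matrix(0, H, length(scales))
  for (si in seq_along(scales)) {
    m <- max(1L, round(scales[si] * n))
    wins <- integer(H)
    for (b in seq_len(n_boot)) {
      tot <- rell_totals(matrix_lnl$lnl, matrix_lnl$weights, m)
      wins[which.max(tot)] <- wins[which.max(tot)] + 1L
    }
    bp[, si] <- wins / n_boot
  }
  p <- numeric(H); degen <- logical(H)
  for (h in seq_len(H)) {
    bph <- bp[h, ]
    if (all(bph <= 0) || all(bph >= 1)) {
      p[h] <- if (all(bph <= 0)) 0 else 1
      degen[h] <- TRUE
      next
    }
    bpc <- pmin(pmax(bph, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
    z <- qnorm(1 - bpc)
    sr <- sqrt(scales)
    w <- n_boot * dnorm(z)^2 / (bpc * (1 - bpc))   # binomial delta method
    X <- cbind(sr, 1 / sr)
    fit <- lm.wfit(X, z, w)
    d <- fit$coefficients[1]; cc <- fit$coefficients[2]
    p[h] <- 1 - pnorm(d - cc)
  }
  p <- pmin(pmax(p, 1 / n_boot), 1)
  data.frame(hypothesis = matrix_lnl$ids, delta = matrix_lnl$delta,
             p_au = p, degenerate = degen)
}

#' Write a per-site log-likelihood matrix as (gzip) TSV
#'
#' One row per hypothesis, one column per site (patterns expanded to the
#' original site grid).
#'
#' @param matrix_lnl a [per_site_lnl()] object.
#' @param path output path; written gzip-compressed when it ends in
#'   `.gz`.
#' @export
write_site_lnl <- function(matrix_lnl, path) {
  idx <- rep.int(seq_along(matrix_lnl$weights), matrix_lnl$weights)
  full <- matrix_lnl$lnl[, idx, drop = FALSE]
  rownames(full) <- matrix_lnl$ids
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(full, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Correlation between Bayes factors and likelihood differences
#'
#' OLS r-squared (p from the t transform of the correlation) between the
#' per-hypothesis average log10 Bayes factor and the lnL difference to
#' the best hypothesis from the maximum-likelihood analysis, plus the
#' paired table behind the scatter.
#'
#' @param bf_table a [run_intersection()] result.
#' @param matrix_lnl a [per_site_lnl()] result over the same hypotheses.
#' @return list with `r2`, `p`, `slope`, `table`.
#' @export
compare_bf_likelihood <- function(bf_table, matrix_lnl) {
  avg <- attr(bf_table, "average")
  ids <- matrix_lnl$ids
  if (!setequal(names(avg), ids)) stop("hypothesis sets differ")
  if (length(ids) < 3) stop("need at least 3 hypotheses")
  x <- avg[ids]
  y <- matrix_lnl$delta
  r <- cor(x, y)
  n <- length(x)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- max(2 * pt(-abs(tval), n - 2), 1e-5)
  list(r2 = r^2, p = p, slope = unname(coef(lm(y ~ x))[2]),
       table = data.frame(hypothesis = ids, avg_bf = unname(x),
                          delta_lnl = y))
}
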