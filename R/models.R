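#' Substitution models
#'
#' `aa_model()` returns an empirical amino-acid substitution model (WAG,
#' Dayhoff or BLOSUM62 exchangeabilities with their equilibrium
#' frequencies); `binary_model()` returns the two-state presence/absence
#' ("restriction") model. Rate matrices are normalized to one expected
#' substitution per unit branch length at stationarity.
#'
#' The empirical exchangeability tables are taken from the sets shipped
#' with \pkg{phangorn}.
#'
#' @param name one of `"WAG"`, `"Dayhoff"`, `"BLOSUM62"` (alias
#'   `"Blosum62"`).
#' @param freq optional length-20 equilibrium frequency override.
#' @return an object of class `subst_model`.
#' @examples
#' m <- aa_model("WAG")
#' rowSums(m$Q)        # ~0
#' sum(m$pi)           # 1
#' @export
aa_model <- function(name = c("WAG", "Dayhoff", "BLOSUM62", "Blosum62"),
                     freq = NULL) {
  name <- match.arg(name)
  key <- switch(name, WAG = "WAG", Dayhoff = "Dayhoff",
                BLOSUM62 = "Blosum62", Blosum62 = "Blosum62")
  src <- getFromNamespace(paste0(".", key), "phangorn")
  pi <- if (is.null(freq)) as.numeric(src$bf) else freq
  pi <- pi / sum(pi)
  ex <- matrix(0, 20, 20)
  ex[lower.tri(ex)] <- src$Q
  ex <- ex + t(ex)
  Q <- ex %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  new_subst_model(kind = "aa", name = key, states = AA, Q = Q, pi = pi)
}

#' @rdname aa_model
#' @param pi0,pi1 stationary frequencies of the absent (0) and present (1)
#'   states; must sum to 1.
#' @export
binary_model <- function(pi0 = 0.5, pi1 = 0.5) {
  stopifnot(pi0 > 0, pi1 > 0, abs(pi0 + pi1 - 1) < 1e-12)
  pi <- c(pi0, pi1)
  Q <- matrix(c(-pi1, pi1, pi0, -pi0), 2, 2, byrow = TRUE)
  Q <- Q / (2 * pi0 * pi1)
  new_subst_model(kind = "binary", name = "restriction",
                  states = c("0", "1"), Q = Q, pi = pi, cond_state = 0L)
}

new_subst_model <- function(kind, name, states, Q, pi, cond_state = NULL) {
  stopifnot(all(abs(rowSums(Q)) < 1e-10), abs(sum(pi) - 1) < 1e-10)
  structure(list(kind = kind, name = name, states = states, nsym =
                   length(states), Q = Q, pi = pi, cond_state = cond_state),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("<subst_model>", x$name, sprintf("(%s, %d states)\n", x$kind, x$nsym))
  invisible(x)
}

# eigen-decomposition of a reversible rate matrix via symmetrization
reversible_eigen <- function(Q, pi) {
  d <- sqrt(pi)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(U = diag(1 / d) %*% e$vectors,
       Uinv = t(e$vectors) %*% diag(d),
       lambda = e$values)
}

#' Rate-variation model
#'
#' Describes among-site rate variation (discrete gamma) and, optionally, a
#' two-class covarion process in which sites switch between an "on" class
#' (evolving at the model rate) and an "off" class (frozen), with switch
#' rates `s_on` (off to on) and `s_off` (on to off).
#'
#' @param shape gamma shape parameter (`> 0`); ignored when `ncat = 1`.
#' @param ncat number of equal-probability rate categories.
#' @param s_on,s_off covarion switch rates; both `NULL` disables covarion.
#' @param root_on_only if `TRUE`, a covarion process starts in the "on"
#'   class at the root (useful for limit checks); otherwise the hidden
#'   class is at stationarity.
#' @return an object of class `rate_model`.
#' @export
rate_model <- function(shape = 1, ncat = 1L, s_on = NULL, s_off = NULL,
                       root_on_only = FALSE) {
  stopifnot(ncat >= 1, is.null(shape) || shape > 0)
  cov <- !is.null(s_on) || !is.null(s_off)
  if (cov) stopifnot(s_on > 0, s_off > 0)
  structure(list(shape = shape, ncat = as.integer(ncat),
                 s_on = if (cov) s_on else NULL,
                 s_off = if (cov) s_off else NULL,
                 covarion = cov, root_on_only = root_on_only),
            class = "rate_model")
}

#' Discrete-gamma category rates
#'
#' Mean rate of each of `k` equal-probability quantile bins of a
#' Gamma(shape, shape) distribution; the category rates average exactly 1.
#'
#' @param shape gamma shape parameter (`> 0`).
#' @param k number of categories.
#' @return numeric vector of `k` ascending rates with mean 1.
#' @examples
#' discretize_gamma(0.5, 4)
#' @export
discretize_gamma <- function(shape, k) {
  stopifnot(shape > 0, k >= 1)
  as.numeric(cpp_gamma_rates(shape, as.integer(k)))
}

# Build the covarion expansion of a (rate-scaled) generator. States are
# ordered (all observable states "on", then all "off").
covarion_Q <- function(Qr, s_on, s_off) {
  n <- nrow(Qr)
  rbind(cbind(Qr - diag(s_off, n), diag(s_off, n)),
        cbind(diag(s_on, n), -diag(s_on, n)))
}

# Assemble everything the C++ engine needs for a model + rate combination.
# Returns U/Uinv cubes, lambda matrix, per-category weights, tip map,
# root frequencies and (for plain scalable models) the base eigenvalues.
model_engine <- function(model, rates) {
  k <- rates$ncat
  catr <- if (k == 1) 1 else discretize_gamma(rates$shape, k)
  catw <- rep(1 / k, k)
  nsym <- model$nsym
  if (!rates$covarion) {
    nstate <- nsym
    e <- reversible_eigen(model$Q, model$pi)
    U <- array(rep(e$U, k), dim = c(nstate, nstate, k))
    Uinv <- array(rep(e$Uinv, k), dim = c(nstate, nstate, k))
    lambda <- outer(e$lambda, catr)
    lambda_base <- e$lambda
    root_freq <- model$pi
    tipmap <- cbind(diag(nstate), rep(1, nstate))
  } else {
    nstate <- 2L * nsym
    p_on <- rates$s_on / (rates$s_on + rates$s_off)
    pic <- c(model$pi * p_on, model$pi * (1 - p_on))
    U <- array(0, dim = c(nstate, nstate, k))
    Uinv <- array(0, dim = c(nstate, nstate, k))
    lambda <- matrix(0, nstate, k)
    for (j in seq_len(k)) {
      Qc <- covarion_Q(model$Q * catr[j], rates$s_on, rates$s_off)
      e <- reversible_eigen(Qc, pic)
      U[, , j] <- e$U
      Uinv[, , j] <- e$Uinv
      lambda[, j] <- e$lambda
    }
    lambda_base <- numeric(0)
    root_freq <- if (isTRUE(rates$root_on_only)) c(model$pi, rep(0, nsym))
                 else pic
    tipmap <- cbind(rbind(diag(nsym), diag(nsym)), rep(1, nstate))
  }
  list(U = U, Uinv = Uinv, lambda = lambda, lambda_base = lambda_base,
       catw = catw, root_freq = root_freq, tipmap = tipmap,
       nstate = nstate, shape = if (is.null(rates$shape)) 1 else rates$shape)
}
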