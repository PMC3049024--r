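#' Search configuration for iterative profile searches
#'
#' @param evalue E-value threshold for accepting hits (default `1e-5`).
#' @param max_gap maximum tolerated per-column gap fraction before a
#'   column is removed from the working alignment (strictly-greater-than
#'   rule; default 0.5).
#' @param max_ident maximum tolerated pairwise identity before a sequence
#'   is removed as redundant (strictly-greater-than rule; default 0.95).
#' @param max_iter safety cap on search iterations (default 30).
#' @param n_decoys shuffled decoy sequences used to calibrate each
#'   profile's Gumbel null distribution (default 500).
#' @param background background amino-acid frequencies; defaults to the
#'   WAG equilibrium frequencies.
#' @param gap_open,gap_ext base gap penalties (scaled per column by the
#'   column's non-gap fraction).
#' @param pseudocount pseudocount mass added to profile columns; the
#'   pseudocount distribution is a substitution mixture of the observed
#'   column (residues one WAG "time unit" away from what was seen), so
#'   single-sequence profiles still generalize to diverged homologues.
#' @return an object of class `search_config`.
#' @export
search_config <- function(evalue = 1e-5, max_gap = 0.5, max_ident = 0.95,
                          max_iter = 30, n_decoys = 500, background = NULL,
                          gap_open = 7, gap_ext = 0.7, pseudocount = 4) {
  stopifnot(evalue > 0, max_gap > 0, max_gap <= 1, max_ident > 0,
            max_ident <= 1, max_iter >= 1, n_decoys >= 50)
  if (is.null(background)) background <- aa_model("WAG")$pi
  background <- background / sum(background)
  structure(list(evalue = evalue, max_gap = max_gap, max_ident = max_ident,
                 max_iter = max_iter, n_decoys = n_decoys,
                 background = background, gap_open = gap_open,
                 gap_ext = gap_ext, pseudocount = pseudocount),
            class = "search_config")
}

encode_seq <- function(s) {
  i <- match(seq_to_chars(s), AA) - 1L
  i[is.na(i)] <- 20L  # unknown residues score 0
  i
}

#' Bundle proteomes into a searchable database
#'
#' Flattens per-taxon sequence sets, precomputes integer encodings and a
#' fixed set of shuffled decoy sequences (real database sequences with
#' residues permuted) used to calibrate profile score distributions.
#'
#' @param proteomes named list (taxon -> named character vector of
#'   sequences), or a directory of per-taxon FASTA files (taxon = file
#'   stem).
#' @param n_decoys decoys to pre-generate.
#' @param seed seed for decoy generation.
#' @return an object of class `proteome_db`.
#' @export
make_proteome_db <- function(proteomes, n_decoys = 500, seed = 1) {
  if (is.character(proteomes) && length(proteomes) == 1 &&
      dir.exists(proteomes)) {
    files <- list.files(proteomes, pattern = "\\.(fa|fasta|faa)$",
                        full.names = TRUE)
    proteomes <- setNames(lapply(files, read_fasta),
                          sub("\\.[^.]+$", "", basename(files)))
  }
  ids <- unlist(lapply(proteomes, names), use.names = FALSE)
  if (anyDuplicated(ids)) stop("duplicate sequence IDs across proteomes")
  taxon <- rep(names(proteomes), lengths(proteomes))
  seqs <- setNames(unlist(proteomes, use.names = FALSE), ids)
  enc <- lapply(seqs, encode_seq)
  decoys <- with_seed(seed, {
    pick <- rep_len(seq_along(enc), n_decoys)
    lapply(pick, function(i) sample(enc[[i]]))
  })
  structure(list(ids = ids, taxon = setNames(taxon, ids), seqs = seqs,
                 enc = enc, decoys = decoys, n = length(ids)),
            class = "proteome_db")
}

#' @export
print.proteome_db <- function(x, ...) {
  cat(sprintf("<proteome_db> %d sequences, %d taxa\n", x$n,
              length(unique(x$taxon))))
  invisible(x)
}

#' Build a calibrated profile from a parsed alignment
#'
#' Per-column log-odds scores of pseudocounted residue frequencies
#' against the background, with per-column affine gap penalties scaled by
#' column occupancy. The null score distribution is calibrated by scoring
#' shuffled decoy sequences and fitting a Gumbel by maximum likelihood,
#' giving E-values `E = D * P(S >= s)` over a database of size `D`.
#'
#' @param aln parsed character-matrix alignment (gap-rich columns and
#'   redundant sequences already removed).
#' @param config a [search_config()].
#' @param db a [make_proteome_db()] whose decoys calibrate the profile.
#' @return an object of class `dog_profile`.
#' @export
build_profile <- function(aln, config, db) {
  stopifnot(nrow(aln) >= 1, ncol(aln) >= 1)
  L <- ncol(aln)
  bg <- config$background
  counts <- apply(aln, 2, function(col) tabulate(match(col, AA), 20))
  nobs <- colSums(counts)
  if (any(nobs == 0)) stop("alignment has an all-gap column; parse first")
  fobs <- sweep(counts, 2, pmax(nobs, 1), "/")
  # substitution-mixture pseudocounts: spread observed residues to their
  # likely substitutes before blending with the observed frequencies
  fmix <- substitution_mixture() %*% fobs
  pc <- config$pseudocount
  f <- sweep(sweep(fobs, 2, nobs, "*") + pc * fmix, 2, nobs + pc, "/")
  scores <- t(log(f / bg))               # L x 20
  scores <- cbind(scores, 0)             # unknown residue column
  occ <- 1 - colMeans(aln == "-")
  gapo <- config$gap_open * occ + 0.5
  gape <- config$gap_ext * occ + 0.1
  sc <- cpp_pssm_search(scores, gapo, gape, db$decoys)$score
  gum <- fit_gumbel(sc)
  structure(list(scores = scores, gap_open = gapo, gap_ext = gape,
                 length = L, gumbel = gum, n_decoys = length(sc),
                 decoy_scores = sc, src_hash = content_hash(aln)),
            class = "dog_profile")
}

#' @export
print.dog_profile <- function(x, ...) {
  cat(sprintf("<dog_profile> length %d, Gumbel(mu=%.2f, beta=%.2f)\n",
              x$length, x$gumbel[1], x$gumbel[2]))
  invisible(x)
}

# P(b | a) after one expected substitution per site under WAG; cached
substitution_mixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- aa_model("WAG")
      e <- reversible_eigen(m$Q, m$pi)
      P <- e$U %*% diag(exp(e$lambda * 1.0)) %*% e$Uinv
      P[P < 0] <- 0
      cache <<- t(P / rowSums(P))  # columns: observed residue a
    }
    cache
  }
})

# maximum-likelihood Gumbel fit, moment start
fit_gumbel <- function(x) {
  beta0 <- max(sd(x) * sqrt(6) / pi, 1e-3)
  mu0 <- mean(x) - 0.57721566 * beta0
  nll <- function(p) {
    beta <- exp(p[2])
    z <- (x - p[1]) / beta
    sum(z + exp(-z)) + length(x) * p[2]
  }
  fit <- optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead")
  c(mu = fit$par[1], beta = exp(fit$par[2]))
}

gumbel_upper <- function(s, mu, beta) {
  # P(S >= s), numerically safe in the far tail
  z <- (s - mu) / beta
  -expm1(-exp(-z))
}

#' Search a proteome database with a profile
#'
#' Scores every database sequence by local profile-sequence dynamic
#' programming, converts scores to E-values via the profile's Gumbel
#' calibration (`E = D * P(S >= s)`), and returns hits passing the
#' E-value threshold sorted by score (ties broken by sequence ID).
#'
#' @param profile a [build_profile()] object.
#' @param db a [make_proteome_db()] (or named list of proteomes).
#' @param config a [search_config()].
#' @return data frame with columns `seq_id`, `taxon`, `score`, `evalue`,
#'   `from`, `to` (1-based aligned span on the target).
#' @export
search_profile <- function(profile, db, config = search_config()) {
  if (!inherits(db, "proteome_db")) db <- make_proteome_db(db)
  if (db$n == 0)
    return(data.frame(seq_id = character(0), taxon = character(0),
                      score = numeric(0), evalue = numeric(0),
                      from = integer(0), to = integer(0)))
  r <- cpp_pssm_search(profile$scores, profile$gap_open, profile$gap_ext,
                       db$enc)
  ev <- db$n * gumbel_upper(r$score, profile$gumbel[1], profile$gumbel[2])
  hit <- which(ev <= config$evalue)
  out <- data.frame(seq_id = db$ids[hit], taxon = unname(db$taxon[hit]),
                    score = r$score[hit], evalue = ev[hit],
                    from = r$from[hit], to = r$to[hit])
  out[order(-out$score, out$seq_id), , drop = FALSE]
}

#' Iterative profile search from a single seed sequence
#'
#' Implements the iterate-until-fixpoint protocol: build a profile from
#' the current parsed alignment, search all proteomes, keep hits passing
#' the E-value threshold, re-align the hit set, remove gap-rich columns
#' and redundant sequences, and repeat until the hit set is identical to
#' the previous iteration's (or the iteration cap is reached).
#'
#' @param seed_id sequence ID present in `db`.
#' @param db a [make_proteome_db()].
#' @param config a [search_config()].
#' @return an object of class `dog_search`: list with `seed_id`, `ids`
#'   (final hit set, always containing the seed), `hits` (final hit
#'   table), `iterations`, `converged`, `category` and `profile`.
#' @export
iterate_search <- function(seed_id, db, config = search_config()) {
  if (!seed_id %in% db$ids) stop("seed sequence not in database: ", seed_id)
  aln <- matrix(seq_to_chars(db$seqs[[seed_id]]), 1)
  rownames(aln) <- seed_id
  prev_ids <- character(0)
  ids <- seed_id
  hits <- NULL; profile <- NULL
  it <- 0; converged <- FALSE
  while (it < config$max_iter) {
    it <- it + 1
    profile <- build_profile(aln, config, db)
    hits <- search_profile(profile, db, config)
    ids <- sort(union(seed_id, hits$seq_id))
    if (identical(ids, prev_ids)) { converged <- TRUE; break }
    prev_ids <- ids
    ord <- c(seed_id, setdiff(hits$seq_id, seed_id))
    aln <- align_sequences(db$seqs[ord])
    aln <- remove_gappy_columns(aln, config$max_gap)
    aln <- remove_redundant_sequences(aln, config$max_ident)
  }
  res <- list(seed_id = seed_id, ids = ids, hits = hits,
              iterations = it, converged = converged,
              profile = profile)
  res$category <- classify_result(res, db$taxon)
  class(res) <- "dog_search"
  res
}

#' @export
print.dog_search <- function(x, ...) {
  cat(sprintf("<dog_search> seed %s: %d hits, category %d, %s after %d iterations\n",
              x$seed_id, length(x$ids), x$category,
              if (x$converged) "converged" else "capped", x$iterations))
  invisible(x)
}

#' Classify a search result
#'
#' Category 1: no sequences beyond the seed; category 2: more than one
#' sequence but at most one per taxon; category 3: multiple sequences in
#' at least one taxon.
#'
#' @param result a [iterate_search()] result (or list with `ids`).
#' @param taxon_of named vector mapping sequence IDs to taxa.
#' @return integer 1, 2 or 3.
#' @export
classify_result <- function(result, taxon_of) {
  ids <- result$ids
  if (length(ids) <= 1) return(1L)
  tx <- taxon_of[ids]
  if (any(table(tx) > 1)) return(3L) else return(2L)
}

#' Reconcile category-2 searches into discrete orthologue groups
#'
#' A candidate group (a distinct final hit set) is accepted only when the
#' search seeded from every member recovers exactly the same set (set
#' equality of sequence IDs). Accepted groups are pairwise disjoint and
#' contain at most one sequence per taxon.
#'
#' @param results list of [iterate_search()] results (category 2).
#' @param db the [make_proteome_db()] used for the searches.
#' @return list with `dogs` (list of `dog` objects: `family_id`,
#'   `members`, `taxa`, `profile`, `alignment`) and `discarded`
#'   (data frame of rejected candidate sets with reasons).
#' @export
reconcile_dogs <- function(results, db) {
  results <- Filter(function(r) r$category == 2L, results)
  by_seed <- setNames(results, vapply(results, `[[`, "", "seed_id"))
  keysets <- unique(lapply(results, function(r) r$ids))
  dogs <- list()
  discarded <- list()
  for (ids in keysets) {
    ok <- TRUE; why <- NA_character_
    for (m in ids) {
      r <- by_seed[[m]]
      if (is.null(r)) { ok <- FALSE; why <- "member without recorded search"; break }
      if (!identical(sort(r$ids), sort(ids))) { ok <- FALSE; why <- "member search disagrees"; break }
    }
    if (ok) {
      fam <- paste0("DOG_", substr(content_hash(sort(ids)), 1, 10))
      seed <- by_seed[[ids[[1]]]]
      aln <- align_sequences(db$seqs[ids])
      dogs[[fam]] <- structure(
        list(family_id = fam, members = sort(ids),
             taxa = sort(unname(db$taxon[ids])),
             profile = seed$profile, alignment = aln), class = "dog")
    } else {
      discarded[[length(discarded) + 1]] <-
        data.frame(members = paste(sort(ids), collapse = ","), reason = why)
    }
  }
  # sanity: accepted groups are disjoint with at most one member per taxon
  all_ids <- unlist(lapply(dogs, `[[`, "members"))
  stopifnot(!anyDuplicated(all_ids))
  for (d in dogs) stopifnot(!anyDuplicated(d$taxa))
  list(dogs = dogs,
       discarded = if (length(discarded)) do.call(rbind, discarded)
                   else data.frame(members = character(0),
                                   reason = character(0)))
}

#' Run the full iterative-search protocol over a proteome set
#'
#' Seeds one iterative search from every sequence, classifies the
#' results, and reconciles category-2 searches into discrete orthologue
#' groups.
#'
#' @param proteomes a [make_proteome_db()], named list or FASTA directory.
#' @param config a [search_config()].
#' @param verbose print progress every 200 seeds.
#' @return list with `dogs`, `census` (category counts), `results` (all
#'   search results) and `discarded`.
#' @export
run_orthofind <- function(proteomes, config = search_config(),
                          verbose = FALSE) {
  db <- if (inherits(proteomes, "proteome_db")) proteomes
        else make_proteome_db(proteomes, n_decoys = config$n_decoys)
  results <- vector("list", db$n)
  for (i in seq_len(db$n)) {
    results[[i]] <- iterate_search(db$ids[i], db, config)
    if (verbose && i %% 200 == 0)
      message("  searched ", i, "/", db$n, " seeds")
  }
  cats <- vapply(results, `[[`, 1L, "category")
  rec <- reconcile_dogs(results, db)
  census <- data.frame(category = 1:3,
                       n = c(sum(cats == 1), sum(cats == 2), sum(cats == 3)))
  list(dogs = rec$dogs, census = census, results = results,
       discarded = rec$discarded, db = db)
}

#' Scan outgroup proteomes with accepted DOG profiles
#'
#' For each DOG and each outgroup genome, reports at most one homologue:
#' the highest-scoring hit passing the E-value threshold (ties broken by
#' sequence ID), mirroring best-hit selection among paralogues.
#'
#' @param dogs list of `dog` objects (from [reconcile_dogs()]).
#' @param outgroup_proteomes named list (genome -> named character vector
#'   of sequences).
#' @param config a [search_config()].
#' @return data frame with columns `family_id`, `genome`, `seq_id`,
#'   `score`, `evalue`; genomes with no passing hit are absent for that
#'   family.
#' @export
scan_outgroups <- function(dogs, outgroup_proteomes,
                           config = search_config()) {
  out <- list()
  dbs <- lapply(outgroup_proteomes, function(p)
    make_proteome_db(list(g = p), n_decoys = config$n_decoys))
  names(dbs) <- names(outgroup_proteomes)
  for (d in dogs) {
    for (g in names(dbs)) {
      hits <- search_profile(d$profile, dbs[[g]], config)
      if (nrow(hits)) {
        best <- hits[order(-hits$score, hits$seq_id)[1], ]
        out[[length(out) + 1]] <-
          data.frame(family_id = d$family_id, genome = g,
                     seq_id = best$seq_id, score = best$score,
                     evalue = best$evalue)
      }
    }
  }
  if (!length(out))
    return(data.frame(family_id = character(0), genome = character(0),
                      seq_id = character(0), score = numeric(0),
                      evalue = numeric(0)))
  do.call(rbind, out)
}
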