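# Alignment containers are plain character matrices (rows = sequences,
# rownames = sequence IDs, "-" = gap).

#' Read / write FASTA
#'
#' Thin wrappers around \pkg{seqinr} returning named uppercase character
#' strings.
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  sq <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           set.attributes = FALSE)
  toupper(unlist(sq))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 70)
  invisible(path)
}

seq_to_chars <- function(s) strsplit(s, "")[[1]]

chars_to_matrix <- function(seqlist) {
  L <- unique(lengths(seqlist))
  stopifnot(length(L) == 1)
  m <- do.call(rbind, seqlist)
  rownames(m) <- names(seqlist)
  m
}

#' Remove gap-rich alignment columns
#'
#' Drops columns whose gap fraction strictly exceeds `max_gap_fraction`
#' (a column with exactly the threshold fraction is retained). The
#' retained-to-original column index map is attached as attribute
#' `col_map`.
#'
#' @param aln character matrix alignment.
#' @param max_gap_fraction maximum tolerated gap fraction (default 0.5).
#' @return the filtered alignment with attribute `col_map`.
#' @export
remove_gappy_columns <- function(aln, max_gap_fraction = 0.5) {
  stopifnot(nrow(aln) >= 1, ncol(aln) >= 1)
  gapfrac <- colMeans(aln == "-")
  keep <- which(gapfrac <= max_gap_fraction)
  if (!length(keep)) stop("all columns exceed the gap-fraction threshold")
  out <- aln[, keep, drop = FALSE]
  attr(out, "col_map") <- keep
  out
}

# pairwise identity over mutually ungapped columns
pair_identity <- function(a, b) {
  ok <- a != "-" & b != "-"
  if (!sum(ok)) return(0)
  mean(a[ok] == b[ok])
}

#' Remove near-identical sequences from an alignment
#'
#' Greedy in input order: a sequence is dropped when its identity with
#' any earlier retained sequence strictly exceeds `max_identity`
#' (identity = matches over mutually ungapped columns).
#'
#' @param aln character matrix alignment.
#' @param max_identity identity threshold (default 0.95).
#' @return the filtered alignment.
#' @export
remove_redundant_sequences <- function(aln, max_identity = 0.95) {
  stopifnot(nrow(aln) >= 1)
  keep <- 1L
  for (i in seq_len(nrow(aln))[-1]) {
    red <- FALSE
    for (j in keep) {
      if (pair_identity(aln[i, ], aln[j, ]) > max_identity) { red <- TRUE; break }
    }
    if (!red) keep <- c(keep, i)
  }
  aln[keep, , drop = FALSE]
}

# BLOSUM62 substitution scores (half-bit units), ARNDCQEGHILKMFPSTWYV order
blosum62_matrix <- function() {
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-2,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-2, 4)
  matrix(v, 20, 20, byrow = TRUE, dimnames = list(AA, AA))
}

# shared-k-mer distance between two unaligned sequences
kmer_dist <- function(a, b, k = 3) {
  ka <- unique(substring(a, seq_len(max(nchar(a) - k + 1, 1)),
                         seq_len(max(nchar(a) - k + 1, 1)) + k - 1))
  kb <- unique(substring(b, seq_len(max(nchar(b) - k + 1, 1)),
                         seq_len(max(nchar(b) - k + 1, 1)) + k - 1))
  1 - length(intersect(ka, kb)) / max(min(length(ka), length(kb)), 1)
}

#' Progressive multiple alignment
#'
#' Greedy progressive aligner: a shared-k-mer distance matrix feeds an
#' average-linkage guide tree; profiles are merged by global affine
#' profile-profile alignment under sum-of-pairs BLOSUM62 scores. Input
#' order of equal-distance sequences is preserved, so results are
#' deterministic.
#'
#' @param seqs named character vector of (unaligned) sequences.
#' @param gap_open,gap_ext gap penalties for profile merging.
#' @return character matrix alignment (rows in input order).
#' @export
align_sequences <- function(seqs, gap_open = 10, gap_ext = 0.5) {
  n <- length(seqs)
  stopifnot(n >= 1, !is.null(names(seqs)))
  if (n == 1) {
    m <- matrix(seq_to_chars(seqs[[1]]), 1)
    rownames(m) <- names(seqs)
    return(m)
  }
  B <- blosum62_matrix()
  prof_freq <- function(m) {
    t(apply(m, 2, function(col) tabulate(match(col, AA), 20))) / nrow(m)
  }
  merge2 <- function(ma, mb) {
    FA <- prof_freq(ma); FB <- prof_freq(mb)
    S <- FA %*% B %*% t(FB)
    al <- cpp_profile_align(S, gap_open, gap_ext)
    ga <- ifelse(al$a > 0, al$a, NA)
    gb <- ifelse(al$b > 0, al$b, NA)
    out <- matrix("-", nrow(ma) + nrow(mb), length(ga))
    out[seq_len(nrow(ma)), !is.na(ga)] <- ma[, ga[!is.na(ga)], drop = FALSE]
    out[nrow(ma) + seq_len(nrow(mb)), !is.na(gb)] <-
      mb[, gb[!is.na(gb)], drop = FALSE]
    rownames(out) <- c(rownames(ma), rownames(mb))
    out
  }
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- kmer_dist(seqs[[i]], seqs[[j]])
  hc <- hclust(as.dist(d), method = "average")
  profs <- lapply(seq_len(n), function(i) {
    m <- matrix(seq_to_chars(seqs[[i]]), 1)
    rownames(m) <- names(seqs)[i]
    m
  })
  merged <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    a <- hc$merge[s, 1]; b <- hc$merge[s, 2]
    ma <- if (a < 0) profs[[-a]] else merged[[a]]
    mb <- if (b < 0) profs[[-b]] else merged[[b]]
    merged[[s]] <- merge2(ma, mb)
  }
  out <- merged[[n - 1]]
  out[match(names(seqs), rownames(out)), , drop = FALSE]
}
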