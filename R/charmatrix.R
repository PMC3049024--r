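#' Binary detection/non-detection matrix from DOG membership
#'
#' @param dogs list of `dog` objects, or a membership data frame with
#'   columns `family_id` and `taxon`.
#' @param taxa character vector: the full taxon universe (rows).
#' @return a `presence_matrix` (taxa x families, 0/1).
#' @export
build_binary_matrix <- function(dogs, taxa) {
  memb <- if (is.data.frame(dogs)) dogs else
    do.call(rbind, lapply(dogs, function(d)
      data.frame(family_id = d$family_id, taxon = d$taxa)))
  fams <- unique(memb$family_id)
  m <- matrix(0L, length(taxa), length(fams),
              dimnames = list(taxa, fams))
  m[cbind(match(memb$taxon, taxa), match(memb$family_id, fams))] <- 1L
  if (any(colSums(m) == 0)) stop("all-zero family column")
  structure(m, class = "presence_matrix")
}

#' Block-trimming configuration
#'
#' Conserved-block filter in the spirit of Gblocks: a column is
#' "conserved" when its most frequent residue reaches
#' `min_conserved_fraction` of the sequences plus one sequence and its
#' gap fraction is below 0.5. Runs of columns are split wherever more
#' than `max_contiguous_nonconserved` nonconserved columns occur in a
#' row; flanking nonconserved columns are trimmed from each block and
#' blocks shorter than `min_block_length` are dropped.
#'
#' @param min_conserved_fraction fraction of sequences the majority
#'   residue must reach (plus one sequence) for a conserved column.
#' @param min_block_length minimum retained block length.
#' @param max_contiguous_nonconserved maximum run of nonconserved
#'   columns tolerated inside a block.
#' @param occupancy_min minimum non-gap characters per column retained
#'   by [concatenate()].
#' @return an object of class `trim_config`.
#' @export
trim_config <- function(min_conserved_fraction = 0.5, min_block_length = 5,
                        max_contiguous_nonconserved = 8,
                        occupancy_min = 10) {
  stopifnot(occupancy_min >= 1)
  structure(list(min_conserved_fraction = min_conserved_fraction,
                 min_block_length = min_block_length,
                 max_contiguous_nonconserved = max_contiguous_nonconserved,
                 occupancy_min = occupancy_min), class = "trim_config")
}

#' Remove poorly aligned regions by conserved-block filtering
#'
#' @param aln character matrix alignment.
#' @param config a [trim_config()].
#' @param partition label used in error messages.
#' @return the trimmed alignment (attribute `col_map` maps retained to
#'   original columns).
#' @export
trim_blocks <- function(aln, config = trim_config(), partition = "aln") {
  stopifnot(ncol(aln) >= 1)
  n <- nrow(aln)
  need <- floor(config$min_conserved_fraction * n) + 1
  conserved <- apply(aln, 2, function(col) {
    res <- col[col != "-"]
    if (length(res) <= n / 2) return(FALSE)   # gap fraction must be < 0.5
    max(tabulate(match(res, AA), 20)) >= need
  })
  # long nonconserved runs separate candidate blocks and are removed
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sep <- !r$values & r$lengths > config$max_contiguous_nonconserved
  segment <- integer(ncol(aln))           # 0 = separator column
  seg_id <- 0; open <- FALSE
  for (k in seq_along(r$lengths)) {
    if (sep[k]) { open <- FALSE; next }
    if (!open) { seg_id <- seg_id + 1; open <- TRUE }
    segment[starts[k]:ends[k]] <- seg_id
  }
  keep <- logical(ncol(aln))
  for (b in seq_len(seg_id)) {
    idx <- which(segment == b)
    cons_idx <- idx[conserved[idx]]
    if (!length(cons_idx)) next
    blk <- min(cons_idx):max(cons_idx)    # trim nonconserved flanks
    if (length(blk) >= config$min_block_length) keep[blk] <- TRUE
  }
  if (!any(keep))
    stop("block trimming removed every column of partition ", partition)
  out <- aln[, keep, drop = FALSE]
  attr(out, "col_map") <- which(keep)
  out
}

#' Concatenate trimmed family alignments into a supermatrix
#'
#' Taxa absent from a family receive all-gap rows for that partition;
#' columns with fewer than `occupancy_min` non-gap characters are then
#' removed and the partition map is re-expressed in post-trim
#' coordinates.
#'
#' @param alignments named list of character-matrix alignments (names =
#'   family IDs).
#' @param taxa_universe full taxon set (rows of the supermatrix).
#' @param occupancy_min minimum non-gap characters per retained column.
#' @return an object of class `super_alignment`: list with `aln`
#'   (character matrix), `partitions` (data frame `family`, `start`,
#'   `end`, 1-based inclusive, zero-width when fully removed) and
#'   `dropped` (families whose columns were all removed).
#' @export
concatenate <- function(alignments, taxa_universe, occupancy_min = 10) {
  stopifnot(length(alignments) >= 1)
  rows <- list(); parts <- list(); pos <- 0
  bigcols <- list()
  for (f in names(alignments)) {
    a <- alignments[[f]]
    extra <- setdiff(rownames(a), taxa_universe)
    if (length(extra)) stop("alignment taxa outside universe: ",
                            paste(extra, collapse = ", "))
    m <- matrix("-", length(taxa_universe), ncol(a),
                dimnames = list(taxa_universe, NULL))
    m[rownames(a), ] <- a
    bigcols[[f]] <- m
  }
  big <- do.call(cbind, bigcols)
  lens <- vapply(bigcols, ncol, 0L)
  fam_of <- rep(names(alignments), lens)
  keep <- colSums(big != "-") >= occupancy_min
  aln <- big[, keep, drop = FALSE]
  fam_kept <- fam_of[keep]
  parts <- do.call(rbind, lapply(names(alignments), function(f) {
    idx <- which(fam_kept == f)
    if (!length(idx)) data.frame(family = f, start = NA_integer_,
                                 end = NA_integer_)
    else data.frame(family = f, start = min(idx), end = max(idx))
  }))
  dropped <- parts$family[is.na(parts$start)]
  structure(list(aln = aln, partitions = parts,
                 dropped = dropped, taxa = taxa_universe),
            class = "super_alignment")
}

#' @export
print.super_alignment <- function(x, ...) {
  cat(sprintf("<super_alignment> %d taxa x %d columns, %d partitions, missing %.3f\n",
              nrow(x$aln), ncol(x$aln),
              sum(!is.na(x$partitions$start)), missing_fraction(x)))
  invisible(x)
}

#' Fraction of missing (gap) cells in a supermatrix
#'
#' @param super_aln a [concatenate()] result (or character matrix).
#' @return fraction of gap cells in `[0, 1]`.
#' @export
missing_fraction <- function(super_aln) {
  a <- if (inherits(super_aln, "super_alignment")) super_aln$aln else super_aln
  mean(a == "-")
}

#' Re-filter a supermatrix at a stringent occupancy fraction
#'
#' Keeps columns whose non-gap count is at least
#' `ceiling(occupancy_fraction * n_taxa)`; used for missing-data
#' robustness checks.
#'
#' @param super_aln a `super_alignment`.
#' @param occupancy_fraction required fraction of taxa with data, in
#'   `(0, 1]`.
#' @return a filtered `super_alignment`.
#' @export
stringent_filter <- function(super_aln, occupancy_fraction) {
  stopifnot(occupancy_fraction > 0, occupancy_fraction <= 1)
  need <- ceiling(occupancy_fraction * nrow(super_aln$aln))
  keep <- colSums(super_aln$aln != "-") >= need
  if (!any(keep)) stop("stringent filter removed every column")
  fam_of <- rep(super_aln$partitions$family,
                ifelse(is.na(super_aln$partitions$start), 0,
                       super_aln$partitions$end - super_aln$partitions$start + 1))
  aln <- super_aln$aln[, keep, drop = FALSE]
  fam_kept <- fam_of[keep]
  parts <- do.call(rbind, lapply(super_aln$partitions$family, function(f) {
    idx <- which(fam_kept == f)
    if (!length(idx)) data.frame(family = f, start = NA_integer_,
                                 end = NA_integer_)
    else data.frame(family = f, start = min(idx), end = max(idx))
  }))
  structure(list(aln = aln, partitions = parts,
                 dropped = parts$family[is.na(parts$start)],
                 taxa = super_aln$taxa),
            class = "super_alignment")
}

# ---- writers / readers ----------------------------------------------------

#' Write / read a supermatrix as relaxed PHYLIP plus a partition file
#'
#' @param super_aln a `super_alignment`.
#' @param path output path for the alignment; the partition file is
#'   written alongside with extension `.partitions`.
#' @return `write_phylip`: the path, invisibly. `read_phylip`: a
#'   `super_alignment` (single partition when no partition file found).
#' @export
write_phylip <- function(super_aln, path) {
  a <- super_aln$aln
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(a), ncol(a)), con)
  writeLines(paste(rownames(a), apply(a, 1, paste, collapse = "")), con)
  pf <- paste0(path, ".partitions")
  p <- super_aln$partitions[!is.na(super_aln$partitions$start), ]
  writeLines(sprintf("AA, %s = %d-%d", p$family, p$start, p$end), pf)
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  ln <- readLines(path)
  hd <- as.integer(strsplit(trimws(ln[1]), "\\s+")[[1]])
  rows <- strsplit(trimws(ln[1 + seq_len(hd[1])]), "\\s+")
  taxa <- vapply(rows, `[[`, "", 1)
  aln <- do.call(rbind, lapply(rows, function(r) seq_to_chars(r[[2]])))
  rownames(aln) <- taxa
  stopifnot(ncol(aln) == hd[2])
  pf <- paste0(path, ".partitions")
  parts <- if (file.exists(pf)) {
    pl <- readLines(pf)
    mt <- regmatches(pl, regexec("^AA, (\\S+) = (\\d+)-(\\d+)$", pl))
    do.call(rbind, lapply(mt, function(m)
      data.frame(family = m[2], start = as.integer(m[3]),
                 end = as.integer(m[4]))))
  } else data.frame(family = "all", start = 1L, end = ncol(aln))
  structure(list(aln = aln, partitions = parts, dropped = character(0),
                 taxa = taxa), class = "super_alignment")
}

#' Write / read a binary presence matrix as NEXUS restriction data
#'
#' @param presence a `presence_matrix`.
#' @param path file path.
#' @export
write_nexus_binary <- function(presence, path) {
  m <- unclass(presence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
               "  FORMAT DATATYPE=RESTRICTION SYMBOLS=\"01\" MISSING=?;",
               "  MATRIX"), con)
  writeLines(sprintf("    %s %s", rownames(m),
                     apply(m, 1, function(r)
                       paste(ifelse(is.na(r), "?", r), collapse = ""))), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

#' @rdname write_nexus_binary
#' @export
read_nexus_binary <- function(path) {
  ln <- readLines(path)
  i0 <- grep("MATRIX", ln, ignore.case = TRUE)[1]
  iend <- grep("^\\s*;", ln)
  iend <- iend[iend > i0][1]
  rows <- strsplit(trimws(ln[(i0 + 1):(iend - 1)]), "\\s+")
  taxa <- vapply(rows, `[[`, "", 1)
  m <- do.call(rbind, lapply(rows, function(r) {
    v <- seq_to_chars(r[[2]])
    ifelse(v == "?", NA_integer_, as.integer(v))
  }))
  rownames(m) <- taxa
  colnames(m) <- sprintf("F%04d", seq_len(ncol(m)))
  structure(m, class = "presence_matrix")
}
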