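# shared small fixture: 12 taxa, 12 families, moderate divergence
orto_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- rescale_tree_depth(simulate_species_tree(12, 1, 0, seed = 301),
                               0.35)
      sp <- simulate_proteomes(tr, n_families = 12, seq_length = 80,
                               seed = 302)
      db <- make_proteome_db(sp$proteomes, seed = 303)
      cache <<- list(tree = tr, sp = sp, db = db, cfg = search_config())
    }
    cache
  }
})

# full orthofind run on the fixture, computed once
orf_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- orto_fixture()
      cache <<- run_orthofind(fx$db, fx$cfg)
    }
    cache
  }
})

test_that("gap-rich columns are removed under a strict greater-than rule", {
  aln <- rbind(c("A", "A", "A", "A"),
               c("-", "A", "C", "A"),
               c("-", "-", "C", "A"),
               c("-", "-", "C", "A"))
  rownames(aln) <- paste0("s", 1:4)
  out <- remove_gappy_columns(aln, 0.5)
  # column 1 has 75% gaps (removed); column 2 exactly 50% (retained)
  expect_equal(attr(out, "col_map"), 2:4)
  clean <- aln[, 3:4]
  expect_equal(unname(remove_gappy_columns(clean, 0.5)[, ]), unname(clean))
  # idempotent
  out2 <- remove_gappy_columns(out, 0.5)
  expect_equal(unname(out2[, ]), unname(out[, ]))
  allgap <- matrix("-", 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_error(remove_gappy_columns(allgap, 0.5), "all columns")
})

test_that("redundancy removal keeps first of a near-identical pair, strict threshold", {
  a <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  b <- a; b[1] <- "C"          # 95% identity on 20 columns
  aln <- rbind(a, a, b)
  rownames(aln) <- c("first", "dup", "border")
  out <- remove_redundant_sequences(aln, 0.95)
  expect_equal(rownames(out), c("first", "border"))  # dup dropped, 95% kept
  aln2 <- rbind(a = a, shifted = rev(a))
  expect_equal(nrow(remove_redundant_sequences(aln2, 0.95)), 2)
})

test_that("identity is computed over mutually ungapped columns only", {
  x <- c("A", "C", "-", "D")
  y <- c("A", "C", "E", "-")
  expect_equal(dogphy:::pair_identity(x, y), 1)
})

test_that("a single-sequence profile ranks its own source first", {
  fx <- orto_fixture()
  id <- fx$db$ids[5]
  aln <- matrix(dogphy:::seq_to_chars(fx$db$seqs[[id]]), 1,
                dimnames = list(id, NULL))
  pr <- build_profile(aln, fx$cfg, fx$db)
  r <- dogphy:::cpp_pssm_search(pr$scores, pr$gap_open, pr$gap_ext,
                                fx$db$enc)
  expect_equal(fx$db$ids[which.max(r$score)], id)
})

test_that("Gumbel calibration reproduces the decoy score moments", {
  fx <- orto_fixture()
  id <- fx$db$ids[1]
  aln <- matrix(dogphy:::seq_to_chars(fx$db$seqs[[id]]), 1,
                dimnames = list(id, NULL))
  pr <- build_profile(aln, fx$cfg, fx$db)
  mu <- pr$gumbel[1]; beta <- pr$gumbel[2]
  fitted_mean <- mu + 0.57721566 * beta
  expect_lt(abs(fitted_mean - mean(pr$decoy_scores)),
            3 * sd(pr$decoy_scores) / sqrt(pr$n_decoys) + 0.05)
})

test_that("duplicating an alignment row changes scores only through pseudocount weighting", {
  fx <- orto_fixture()
  ids <- fx$db$ids[1:3]
  aln <- align_sequences(fx$db$seqs[ids])
  p1 <- build_profile(aln, fx$cfg, fx$db)
  aln2 <- rbind(aln, aln[1, , drop = FALSE])
  rownames(aln2)[4] <- "dup"
  p2 <- build_profile(aln2, fx$cfg, fx$db)
  # residues actually observed keep nearly the same scores; the bound is
  # the pseudocount blend shift log((n+pc)/(n'+pc)) plus mixture effects
  seen <- t(apply(aln, 2, function(col) tabulate(match(col, AA), 20) > 0))
  expect_lt(max(abs(p1$scores[, 1:20][seen] - p2$scores[, 1:20][seen])), 0.6)
  expect_gt(cor(p1$scores[, 1:20][seen], p2$scores[, 1:20][seen]), 0.9)
})

test_that("profile search recovers its source family with tiny E-values", {
  fx <- orto_fixture()
  fam <- fx$sp$truth$family[1]
  ids <- fx$sp$truth$seq_id[fx$sp$truth$family == fam]
  aln <- align_sequences(fx$db$seqs[ids])
  pr <- build_profile(remove_redundant_sequences(
    remove_gappy_columns(aln, 0.5), 0.95), fx$cfg, fx$db)
  hits <- search_profile(pr, fx$db, fx$cfg)
  expect_true(all(ids %in% hits$seq_id))
  expect_true(all(hits$evalue[match(ids, hits$seq_id)] < 1e-10))
  expect_true(all(hits$from >= 1 & hits$to <= 80 & hits$from <= hits$to))
  # empty database
  empty <- make_proteome_db(list(g = setNames(character(0), character(0))))
  expect_equal(nrow(search_profile(pr, empty, fx$cfg)), 0)
})

test_that("E-values are calibrated: about E0 decoy hits expected at threshold E0", {
  fx <- orto_fixture()
  id <- fx$db$ids[2]
  aln <- matrix(dogphy:::seq_to_chars(fx$db$seqs[[id]]), 1,
                dimnames = list(id, NULL))
  pr <- build_profile(aln, fx$cfg, fx$db)
  # fresh decoy databases, independent of the calibration decoys
  nhit <- with_seed_local(99, {
    sapply(1:40, function(b) {
      dec <- lapply(seq_len(100), function(i)
        sample(fx$db$enc[[sample.int(fx$db$n, 1)]]))
      sc <- dogphy:::cpp_pssm_search(pr$scores, pr$gap_open, pr$gap_ext,
                                     dec)$score
      ev <- 100 * dogphy:::gumbel_upper(sc, pr$gumbel[1], pr$gumbel[2])
      sum(ev <= 1)
    })
  })
  expect_gt(mean(nhit), 0.2)
  expect_lt(mean(nhit), 3)
})

test_that("iterative search converges to the true family and respects the cap", {
  fx <- orto_fixture()
  seed_id <- fx$db$ids[10]
  r <- iterate_search(seed_id, fx$db, fx$cfg)
  fam <- fx$sp$truth$family[fx$sp$truth$seq_id == seed_id]
  expect_setequal(r$ids, fx$sp$truth$seq_id[fx$sp$truth$family == fam])
  expect_true(r$converged)
  expect_true(seed_id %in% r$ids)
  expect_equal(r$category, 2L)
  capped <- iterate_search(seed_id, fx$db, search_config(max_iter = 1))
  expect_false(capped$converged)
  expect_equal(capped$iterations, 1)
})

test_that("a family confined to one taxon yields a category-1 result", {
  tr <- rescale_tree_depth(simulate_species_tree(6, 1, 0, seed = 310), 0.35)
  pres <- matrix(0L, 6, 3, dimnames = list(tr$tip.label,
                                           sprintf("F%04d", 1:3)))
  pres[, 1] <- 1L          # normal family
  pres[1, 2] <- 1L         # singleton family
  pres[, 3] <- 1L
  sp <- simulate_proteomes(tr, presence = pres, seq_length = 80, seed = 311)
  db <- make_proteome_db(sp$proteomes, seed = 312)
  lone <- sp$truth$seq_id[sp$truth$family == "F0002"]
  r <- iterate_search(lone, db, search_config())
  expect_equal(r$category, 1L)
  expect_equal(r$ids, lone)
})

test_that("result classification follows the three-way category rule", {
  taxon_of <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C", d1 = "D", e1 = "E")
  expect_equal(classify_result(list(ids = "a1"), taxon_of), 1L)
  expect_equal(classify_result(list(ids = c("a1", "b1", "c1", "d1", "e1")),
                               taxon_of), 2L)
  expect_equal(classify_result(list(ids = c("a1", "a2", "b1", "c1", "d1")),
                               taxon_of), 3L)
})

test_that("reconciliation accepts agreeing trios and discards disagreeing ones", {
  fx <- orto_fixture()
  mk <- function(seed, ids, cat = 2L)
    structure(list(seed_id = seed, ids = sort(ids), category = cat),
              class = "dog_search")
  fam <- sort(unique(fx$sp$truth$family))[1]
  trio <- fx$sp$truth$seq_id[fx$sp$truth$family == fam][1:3]
  agree <- lapply(trio, mk, ids = trio)
  rec <- reconcile_dogs(agree, fx$db)
  expect_equal(length(rec$dogs), 1)
  expect_equal(rec$dogs[[1]]$members, sort(trio))
  disagree <- list(mk(trio[1], trio), mk(trio[2], trio),
                   mk(trio[3], c(trio, fx$db$ids[4])))
  rec2 <- reconcile_dogs(disagree, fx$db)
  expect_equal(length(rec2$dogs), 0)
  expect_gt(nrow(rec2$discarded), 0)
})

test_that("end-to-end search on paralogy-free proteomes reproduces truth exactly", {
  fx <- orto_fixture()
  orf <- orf_fixture()
  truth_sets <- lapply(split(fx$sp$truth$seq_id, fx$sp$truth$family), sort)
  dog_sets <- unname(lapply(orf$dogs, function(d) d$members))
  expect_equal(length(dog_sets), length(truth_sets))
  for (s in dog_sets)
    expect_true(any(vapply(truth_sets, identical, NA, s)))
  all_ids <- unlist(dog_sets)
  expect_false(anyDuplicated(all_ids) > 0)
})

test_that("an injected two-copy paralogous family is demoted to category 3", {
  tr <- rescale_tree_depth(simulate_species_tree(8, 1, 0, seed = 320), 0.35)
  par <- data.frame(family = "F0002", taxon = tr$tip.label[3], copies = 1)
  sp <- simulate_proteomes(tr, n_families = 4, seq_length = 80,
                           paralogs = par, paralog_divergence = 0.3,
                           seed = 321)
  db <- make_proteome_db(sp$proteomes, seed = 322)
  orf <- run_orthofind(db, search_config())
  cats <- vapply(orf$results, `[[`, 1L, "category")
  fam_of <- sp$truth$family[match(db$ids, sp$truth$seq_id)]
  expect_true(all(cats[fam_of == "F0002"] == 3L))
  expect_true(all(cats[fam_of != "F0002"] == 2L))
  fams_found <- unique(vapply(orf$dogs, function(d)
    unique(sp$truth$family[match(d$members, sp$truth$seq_id)]), ""))
  expect_false("F0002" %in% fams_found)
  expect_setequal(fams_found, c("F0001", "F0003", "F0004"))
})

test_that("outgroup scanning selects one best homologue per genome", {
  fx <- orto_fixture()
  orf <- orf_fixture()
  # outgroup genomes derived from the same families at moderate extra
  # divergence; og1 carries two paralogous copies of the first family
  m <- aa_model("WAG")
  host_tax <- fx$tree$tip.label[1]
  fams <- sort(unique(fx$sp$truth$family))
  mkseq <- function(fam, t) {
    src_id <- fx$sp$truth$seq_id[fx$sp$truth$family == fam &
                                   fx$sp$truth$taxon == host_tax]
    paste(dogphy:::mutate_sequence(
      dogphy:::seq_to_chars(fx$db$seqs[[src_id]]), m, t), collapse = "")
  }
  ogp <- with_seed_local(331, {
    og1 <- setNames(vapply(fams, mkseq, "", t = 0.3),
                    paste0("og1|", fams))
    og1["og1|extra_copy"] <- mkseq(fams[1], 0.15)
    og2 <- setNames(vapply(fams, mkseq, "", t = 0.3),
                    paste0("og2|", fams))
    list(og1 = og1, og2 = og2)
  })
  tab <- scan_outgroups(orf$dogs, ogp, fx$cfg)
  expect_true(all(table(tab$family_id, tab$genome) <= 1))
  # per-DOG detection recall over DOG x genome cells
  expect_gte(nrow(tab), 0.95 * length(orf$dogs) * 2)
  expect_true(all(tab$evalue <= fx$cfg$evalue))
  # the genome with two paralogous copies reports a single best hit
  f1 <- vapply(orf$dogs, function(d)
    unique(fx$sp$truth$family[match(d$members, fx$sp$truth$seq_id)]), "")
  dog1 <- names(f1)[f1 == fams[1]]
  cell <- tab[tab$family_id == dog1 & tab$genome == "og1", ]
  expect_equal(nrow(cell), 1)
})

test_that("outgroup scan leaves cells empty when nothing passes the threshold", {
  fx <- orto_fixture()
  orf <- orf_fixture()
  junk <- with_seed_local(340, list(
    g1 = setNames(vapply(1:5, function(i)
      paste(sample(AA, 80, replace = TRUE), collapse = ""), ""),
      paste0("junk", 1:5))))
  tab <- scan_outgroups(orf$dogs[1:3], junk, fx$cfg)
  expect_equal(nrow(tab), 0)
})
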