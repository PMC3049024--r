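#' Configuration for an end-to-end pipeline run
#'
#' One object drives [run_pipeline()]: which stages to run, the
#' synthetic-data settings, search and trimming parameters, the models
#' and MCMC settings, a single global seed (child streams are derived
#' per stage by fixed offsets), and the output directory.
#'
#' @param stages character subset of
#'   `c("simulate", "orthofind", "matrix", "tree", "intersect",
#'   "shtest", "support")`; `"all"` expands to every stage.
#' @param n_host_taxa,n_outgroup_taxa host and outgroup tree sizes.
#' @param n_families gene families to simulate.
#' @param seq_length residues per family sequence.
#' @param tree_depth mean root-to-tip depth of the host tree
#'   (substitutions/site).
#' @param intersect_sites alignment length for the intersection dataset.
#' @param stem_length outgroup stem branch length.
#' @param models substitution models for the intersection analysis.
#' @param search a [search_config()].
#' @param trim a [trim_config()].
#' @param mcmc an [mcmc_config()] for the intersection runs.
#' @param free_mcmc an [mcmc_config()] for the binary-data tree search.
#' @param n_rell SH-test RELL replicates.
#' @param seed global integer seed.
#' @param out_dir output directory (created if needed).
#' @return an object of class `run_config`.
#' @export
run_config <- function(stages = "all", n_host_taxa = 8, n_outgroup_taxa = 3,
                       n_families = 100, seq_length = 80, tree_depth = 0.35,
                       intersect_sites = 2000, stem_length = 0.2,
                       models = c("WAG", "Dayhoff"),
                       search = search_config(), trim = trim_config(),
                       mcmc = mcmc_config(n_generations = 5000,
                                          sample_interval = 10,
                                          burnin = 2000),
                       free_mcmc = mcmc_config(n_generations = 2000,
                                               sample_interval = 10,
                                               burnin = 500, n_chains = 1),
                       n_rell = 1000, seed = 1, out_dir = tempfile("dogphy")) {
  all_stages <- c("simulate", "orthofind", "matrix", "tree", "intersect",
                  "shtest", "support")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  structure(list(stages = stages, n_host_taxa = n_host_taxa,
                 n_outgroup_taxa = n_outgroup_taxa,
                 n_families = n_families, seq_length = seq_length,
                 tree_depth = tree_depth,
                 intersect_sites = intersect_sites,
                 stem_length = stem_length, models = models,
                 search = search, trim = trim, mcmc = mcmc,
                 free_mcmc = free_mcmc, n_rell = n_rell, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the pipeline end to end
#'
#' Executes the requested stages in dependency order: simulate synthetic
#' proteomes and an intersection dataset with known truth, find DOGs by
#' iterative profile search, build the binary matrix and concatenated
#' supermatrix, infer the binary-data Bayesian tree, run the
#' constrained-intersection Bayes-factor analysis, the SH/AU tests, and
#' quartet support. Every emitted file is listed, with an md5 hash, in
#' the returned manifest (also written as `manifest.tsv`).
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return a `run_manifest`: list with `config`, `files` (data frame
#'   `file`, `md5`), `timings`, `warnings` and in-memory stage `results`.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[dogphy] ", ...)
  res <- list(); timings <- c(); warns <- character(0)
  emit <- function(name) file.path(config$out_dir, name)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e)))
    timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    out
  }
  sd <- function(off) child_seed(config$seed, off)

  if ("simulate" %in% config$stages) {
    say("simulate")
    res$sim <- stage("simulate", {
      host <- rescale_tree_depth(
        simulate_species_tree(config$n_host_taxa, 1, 0, seed = sd(1)),
        config$tree_depth)
      # postorder once so edge indices agree across all stages
      host <- ape::reorder.phylo(host, "postorder")
      og <- simulate_species_tree(config$n_outgroup_taxa, 1, 0,
                                  seed = sd(2), unrooted = FALSE)
      og <- rescale_tree_depth(og, config$tree_depth / 2)
      og$tip.label <- paste0("og", seq_along(og$tip.label))
      gc <- simulate_gene_content(host, config$n_families, gain = 0.3,
                                  loss = 0.4, root_prob = 0.8,
                                  seed = sd(3))
      pr <- simulate_proteomes(host, presence = gc$presence,
                               seq_length = config$seq_length,
                               seed = sd(4))
      ie <- internal_edges(host)
      attach_edge <- ie[ceiling(length(ie) / 2)]
      inter <- simulate_intersection_dataset(
        host, og, attach_edge, stem_length = config$stem_length,
        length = config$intersect_sites, seed = sd(5))
      ape::write.tree(host, emit("host_tree.nwk"))
      ape::write.tree(og, emit("outgroup_tree.nwk"))
      for (t in names(pr$proteomes))
        write_fasta(pr$proteomes[[t]], emit(paste0("proteome_", t, ".fa")))
      write.table(pr$truth, emit("truth_families.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      list(host = host, outgroup = og, gene_content = gc, proteomes = pr,
           intersection = inter)
    })
  }

  if ("orthofind" %in% config$stages) {
    say("orthofind")
    res$orth <- stage("orthofind", {
      db <- make_proteome_db(res$sim$proteomes$proteomes,
                             n_decoys = config$search$n_decoys,
                             seed = sd(6))
      orf <- run_orthofind(db, config$search)
      memb <- do.call(rbind, lapply(orf$dogs, function(d)
        data.frame(family_id = d$family_id, taxon = d$taxa,
                   seq_id = d$members)))
      write.table(memb, emit("dog_members.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      write.table(orf$census, emit("category_census.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      dir.create(emit("dog_alignments"), showWarnings = FALSE)
      for (d in orf$dogs)
        write_fasta(setNames(apply(d$alignment, 1, paste, collapse = ""),
                             rownames(d$alignment)),
                    file.path(emit("dog_alignments"),
                              paste0(d$family_id, ".fa")))
      orf
    })
  }

  if ("matrix" %in% config$stages) {
    say("matrix")
    res$mat <- stage("matrix", {
      host <- res$sim$host
      pm <- build_binary_matrix(res$orth$dogs, host$tip.label)
      write_nexus_binary(pm, emit("presence.nex"))
      alns <- lapply(res$orth$dogs, function(d) {
        a <- d$alignment
        rownames(a) <- unname(res$orth$db$taxon[rownames(a)])
        trim_blocks(remove_gappy_columns(a, config$search$max_gap),
                    config$trim, d$family_id)
      })
      names(alns) <- vapply(res$orth$dogs, `[[`, "", "family_id")
      sup <- concatenate(alns, host$tip.label,
                         occupancy_min = min(config$trim$occupancy_min,
                                             length(host$tip.label)))
      write_phylip(sup, emit("supermatrix.phy"))
      p <- sup$partitions
      pman <- data.frame(
        family = p$family,
        retained = ifelse(is.na(p$start), 0L, p$end - p$start + 1L),
        missing_fraction = vapply(seq_len(nrow(p)), function(i) {
          if (is.na(p$start[i])) return(NA_real_)
          mean(sup$aln[, p$start[i]:p$end[i]] == "-")
        }, 0))
      write.table(pman, emit("partition_manifest.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      list(presence = pm, super = sup, alignments = alns)
    })
  }

  if ("tree" %in% config$stages) {
    say("tree (binary-data Bayesian inference)")
    res$tree <- stage("tree", {
      pat <- make_patterns(t(unclass(res$mat$presence)))
      cfg <- config$free_mcmc
      cfg$seed <- sd(7)
      tr <- mcmc_sample(pat, binary_model(), rate_model(shape = 1, ncat = 8),
                        cfg, topology = "free", sample_shape = TRUE)
      cons <- consensus_tree(tr$trees)
      ape::write.tree(cons$tree, emit("binary_consensus.nwk"))
      write_trace(tr, emit("binary_chain.p"))
      list(trace = tr, consensus = cons)
    })
  }

  if ("intersect" %in% config$stages) {
    say("intersect (", length(config$models), " models)")
    res$inter <- stage("intersect", {
      inter <- res$sim$intersection
      pat <- make_patterns(inter$alignment)
      hyp <- enumerate_attachments(res$sim$host, res$sim$outgroup,
                                   stem_length = config$stem_length)
      cfg <- config$mcmc
      cfg$seed <- sd(8)
      bft <- run_intersection(pat, hyp, models = config$models,
                              rates = rate_model(shape = 1, ncat = 4),
                              config = cfg)
      amap <- average_and_map(bft, hyp)
      write.table(cbind(bft), emit("bayes_factors.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      write.table(amap$report, emit("bf_report.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      list(hypotheses = hyp, bf_table = bft, map = amap, patterns = pat)
    })
  }

  if ("shtest" %in% config$stages) {
    say("shtest")
    res$sh <- stage("shtest", {
      sm <- per_site_lnl(res$inter$hypotheses, res$inter$patterns,
                         aa_model(config$models[1]),
                         rate_model(shape = 1, ncat = 4),
                         optimize_shape = TRUE)
      sh <- with_seed(sd(9), sh_test(sm, n_rell = config$n_rell))
      au <- with_seed(sd(10), au_test(sm, n_boot = config$n_rell))
      tab <- merge(merge(sh, au[, c("hypothesis", "p_au")], by = "hypothesis"),
                   data.frame(hypothesis = names(attr(res$inter$bf_table,
                                                      "average")),
                              avg_bf = unname(attr(res$inter$bf_table,
                                                   "average"))),
                   by = "hypothesis")
      write.table(tab, emit("topology_tests.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      write_site_lnl(sm, emit("site_lnl.tsv.gz"))
      list(matrix = sm, sh = sh, au = au, table = tab)
    })
  }

  if ("support" %in% config$stages) {
    say("support (quartets)")
    res$support <- stage("support", {
      host <- res$sim$host
      alns <- res$mat$alignments
      keep <- names(alns)[vapply(alns, nrow, 0L) >= 4]
      keep <- head(keep, 25)    # per-gene ML trees are the slow part
      gt <- per_gene_trees(alns[keep], aa_model(config$models[1]))
      qs <- quartet_support(host, gt$trees)
      write.table(cbind(qs), emit("quartet_support.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      write_support_tree(qs, emit("quartet_support.nwk"))
      list(gene_trees = gt, quartets = qs)
    })
  }

  files <- list.files(config$out_dir, full.names = TRUE, recursive = TRUE)
  manifest <- list(config = config,
                   files = data.frame(file = basename(files),
                                      md5 = unname(tools::md5sum(files))),
                   timings = timings, warnings = warns, results = res)
  class(manifest) <- "run_manifest"
  mf <- manifest$files
  write.table(mf, file.path(config$out_dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", nrow(x$files), "files in", x$config$out_dir, "\n")
  cat("stages:", paste(names(x$timings), collapse = ", "), "\n")
  invisible(x)
}

#' Strictly validate a standard-format file
#'
#' Line-oriented validators for the formats the pipeline reads and
#' writes; the first violation is reported with its line (and, where
#' sensible, column) number.
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"newick"`, `"nexus_restriction"`,
#'   `"phylip"`, `"partitions"`.
#' @return data frame of violations (zero rows when the file is valid)
#'   with columns `line`, `column`, `message`.
#' @export
validate_formats <- function(path, format) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  bad <- function(line, col, msg)
    data.frame(line = as.integer(line), column = as.integer(col),
               message = msg)
  viol <- list()
  push <- function(v) viol[[length(viol) + 1]] <<- v
  switch(format,
    fasta = {
      if (!length(ln) || !startsWith(ln[1], ">"))
        push(bad(1, 1, "first line must be a '>' header"))
      inseq <- FALSE
      for (i in seq_along(ln)) {
        l <- ln[i]
        if (startsWith(l, ">")) {
          if (nchar(l) < 2) push(bad(i, 2, "empty sequence ID"))
          inseq <- TRUE
        } else if (nzchar(l)) {
          if (!inseq) push(bad(i, 1, "sequence data before any header"))
          hit <- regexpr("[^A-Za-z*\\-\\.]", l)
          if (hit > 0) push(bad(i, hit, "invalid sequence character"))
        }
      }
    },
    newick = {
      txt <- paste(ln, collapse = "")
      depth <- 0
      for (j in seq_len(nchar(txt))) {
        ch <- substr(txt, j, j)
        if (ch == "(") depth <- depth + 1
        if (ch == ")") depth <- depth - 1
        if (depth < 0) { push(bad(1, j, "unbalanced ')'")); break }
      }
      if (depth > 0) push(bad(1, nchar(txt), "unbalanced '('"))
      if (!grepl(";\\s*$", txt)) push(bad(1, nchar(txt),
                                          "missing terminating ';'"))
    },
    nexus_restriction = {
      if (!length(ln) || toupper(trimws(ln[1])) != "#NEXUS")
        push(bad(1, 1, "missing #NEXUS header"))
      i0 <- grep("MATRIX", ln, ignore.case = TRUE)[1]
      if (is.na(i0)) push(bad(length(ln), 1, "no MATRIX block"))
      else {
        iend <- grep("^\\s*;", ln)
        iend <- iend[iend > i0][1]
        if (is.na(iend)) push(bad(length(ln), 1, "MATRIX not terminated"))
        else for (i in (i0 + 1):(iend - 1)) {
          p <- strsplit(trimws(ln[i]), "\\s+")[[1]]
          if (length(p) != 2) { push(bad(i, 1, "expect 'taxon chars'")); next }
          hit <- regexpr("[^01?]", p[2])
          if (hit > 0)
            push(bad(i, hit, paste0("taxon ", p[1],
                                    ": symbol outside {0,1,?} at character ",
                                    hit)))
        }
      }
    },
    phylip = {
      hd <- strsplit(trimws(ln[1]), "\\s+")[[1]]
      if (length(hd) != 2 || anyNA(suppressWarnings(as.integer(hd))))
        push(bad(1, 1, "header must be 'ntax nchar'"))
      else {
        nt <- as.integer(hd[1]); nc <- as.integer(hd[2])
        if (length(ln) < nt + 1) push(bad(length(ln), 1, "too few rows"))
        else for (i in 2:(nt + 1)) {
          p <- strsplit(trimws(ln[i]), "\\s+")[[1]]
          if (length(p) < 2) { push(bad(i, 1, "expect 'taxon sequence'")); next }
          if (nchar(p[2]) != nc)
            push(bad(i, nchar(p[1]) + 2,
                     sprintf("sequence length %d != %d", nchar(p[2]), nc)))
        }
      }
    },
    partitions = {
      for (i in seq_along(ln)) {
        if (!nzchar(trimws(ln[i]))) next
        if (!grepl("^\\s*\\w+,\\s*\\S+\\s*=\\s*\\d+\\s*-\\s*\\d+\\s*$", ln[i]))
          push(bad(i, 1, "expect 'TYPE, name = start-end'"))
      }
    },
    stop("unknown format name: ", format)
  )
  if (!length(viol))
    return(data.frame(line = integer(0), column = integer(0),
                      message = character(0)))
  do.call(rbind, viol)
}
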