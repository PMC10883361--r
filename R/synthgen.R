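# Synthetic multi-species proteome generator with truth tables.
#
# Emulates the statistical structure the downstream analysis assumes:
# single-copy orthologous genes evolved along a random species tree,
# per-gene x per-species dropout, redundant isoforms with read support,
# contaminant records drawn from an independent fast-evolving "food" clade,
# and lineage-specific amino-acid compositional bias.

#' Simulation configuration
#'
#' @param n_species Number of study species (>= 4).
#' @param n_genes Number of single-copy genes (>= 1).
#' @param seed Master seed; every stochastic step derives its own stream
#'   from it via [derive_seed()], so output is byte-deterministic.
#' @param missingness_rate Per gene-by-species dropout probability in
#'   `[0, 1)`.
#' @param contamination_rate Expected fraction of contaminant records added
#'   per species, relative to its native record count, in `[0, 1)`.
#' @param isoforms_per_gene Isoform copies emitted per retained gene
#'   (>= 1); copies beyond the first are truncated/perturbed duplicates.
#' @param branch_scale Mean of the i.i.d. exponential branch lengths
#'   (expected substitutions per site) of the species tree.
#' @param gene_length Ungapped length of every simulated gene (residues).
#' @param composition_bias Named list: species id -> length-20 positive
#'   multiplier vector (canonical residue order, A R N D ... V) applied to the equilibrium residue
#'   frequencies on that species' terminal branch.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 10, n_genes = 20, seed = 1,
                       missingness_rate = 0.1, contamination_rate = 0.05,
                       isoforms_per_gene = 2, branch_scale = 0.15,
                       gene_length = 300, composition_bias = list()) {
  stopifnot(n_species >= 4, n_genes >= 1,
            missingness_rate >= 0, missingness_rate < 1,
            contamination_rate >= 0, contamination_rate < 1,
            isoforms_per_gene >= 1, branch_scale > 0, gene_length >= 1)
  for (b in composition_bias)
    stopifnot(length(b) == 20L, all(b > 0))
  structure(list(n_species = as.integer(n_species),
                 n_genes = as.integer(n_genes), seed = seed,
                 missingness_rate = missingness_rate,
                 contamination_rate = contamination_rate,
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 branch_scale = branch_scale,
                 gene_length = as.integer(gene_length),
                 composition_bias = composition_bias),
            class = "sim_config")
}

#' Simulate a random binary unrooted species tree
#'
#' Topology is drawn uniformly via random leaf insertion; branch lengths are
#' i.i.d. exponential with mean `branch_scale`.
#'
#' @param n_species Number of leaves (>= 4).
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @param branch_scale Mean branch length.
#' @param labels Optional leaf labels (default `sp01`, `sp02`, ...).
#' @return An unrooted binary `phylo`.
#' @export
simulate_species_tree <- function(n_species, seed, branch_scale = 0.15,
                                  labels = NULL) {
  if (n_species < 4) stop("n_species must be >= 4")
  stopifnot(branch_scale > 0)
  if (is.null(labels)) labels <- sprintf("sp%02d", seq_len(n_species))
  stopifnot(length(labels) == n_species)
  with_seed(seed, {
    tr <- ape::rtopology(n_species, rooted = FALSE, tip.label = labels)
    tr$edge.length <- rexp(nrow(tr$edge), rate = 1 / branch_scale)
    tr
  })
}

# Equilibrium residue frequencies of the simulator (uniform over AA20).
base_frequencies <- function() setNames(rep(1 / 20, 20), AA20)

biased_frequencies <- function(bias) {
  f <- base_frequencies()
  if (!is.null(bias)) {
    stopifnot(length(bias) == 20L, all(bias > 0))
    f <- f * as.numeric(bias)
    f <- f / sum(f)
  }
  f
}

#' Evolve one ungapped gene alignment along a tree
#'
#' Sites are i.i.d.; along a branch of length `t`, each site is replaced
#' with probability `1 - exp(-t)` by a fresh draw from the branch's
#' equilibrium frequencies (an F81-style exchangeability with uniform base
#' frequencies).  Terminal branches leading to species with an entry in
#' `composition_bias` draw from the correspondingly reweighted frequencies,
#' producing lineage-specific compositional heterogeneity.
#'
#' @param tree A `phylo` with branch lengths; tip labels become row names.
#' @param length Number of sites (>= 1).
#' @param seed RNG seed.
#' @param composition_bias Named list: species -> 20-vector of positive
#'   frequency multipliers (canonical residue order, A R N D ... V).
#' @param gene_id Gene identifier for the resulting alignment.
#' @return An ungapped `gene_alignment` with one row per leaf.
#' @export
evolve_gene <- function(tree, length, seed, composition_bias = list(),
                        gene_id = "g1") {
  stopifnot(inherits(tree, "phylo"), length >= 1)
  ntip <- length(tree$tip.label)
  tr <- tree
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  with_seed(seed, {
    root <- ntip + 1L
    nnode <- ntip + tr$Nnode
    states <- matrix(NA_integer_, nrow = nnode, ncol = length)
    f0 <- base_frequencies()
    states[root, ] <- sample.int(20L, length, replace = TRUE, prob = f0)
    # preorder over edges (ape trees are stored parent-before-child from root)
    ord <- reorder(tr, "postorder")$edge  # postorder; walk reversed = preorder
    for (e in rev(seq_len(nrow(ord)))) {
      par <- ord[e, 1L]; child <- ord[e, 2L]
      elen <- tr$edge.length[which(tr$edge[, 1] == par & tr$edge[, 2] == child)[1]]
      freqs <- f0
      if (child <= ntip) {
        b <- composition_bias[[tr$tip.label[child]]]
        if (!is.null(b)) freqs <- biased_frequencies(b)
      }
      s <- states[par, ]
      hit <- runif(length) < (1 - exp(-elen))
      if (any(hit))
        s[hit] <- sample.int(20L, sum(hit), replace = TRUE, prob = freqs)
      states[child, ] <- s
    }
    seqs <- vapply(seq_len(ntip), function(i)
      paste0(AA20[states[i, ]], collapse = ""), "")
    names(seqs) <- tr$tip.label
    gene_alignment(gene_id, seqs)
  })
}

# Derive redundant isoform copies of a full-length sequence: 5-30% terminal
# truncation plus up to 2 point substitutions, so the 95% redundancy
# collapse has real work to do.
make_isoform <- function(sequence) {
  n <- nchar(sequence)
  cut <- max(1L, round(n * runif(1, 0.05, 0.30)))
  s <- substr(sequence, 1L, n - cut)
  nsub <- sample(0:2, 1L)
  if (nsub > 0 && nchar(s) > 0) {
    pos <- sample.int(nchar(s), min(nsub, nchar(s)))
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    chars[pos] <- sample(AA20, length(pos), replace = TRUE)
    s <- paste0(chars, collapse = "")
  }
  s
}

#' Assemble a full synthetic dataset with its truth table
#'
#' Runs the generative model end to end: a species tree, one ungapped
#' alignment per gene, gene-by-species dropout, redundant isoforms with
#' random read supports, and contaminant records evolved on an independent
#' "food-organism" tree at three times the branch scale and attributed to a
#' host species.  Every decision is recorded in the truth table.
#'
#' @param config A [sim_config()].
#' @return List with elements:
#'   \describe{
#'     \item{records}{`protein_records` for all emitted proteins
#'       (`truth_label` = `native`/`contaminant`).}
#'     \item{truth}{list: `presence` (gene x species logical matrix of the
#'       native dropout decisions), `species_tree` (true `phylo`),
#'       `contaminant_tree` (`phylo` the contaminants evolved on),
#'       `alignments` (list of the true ungapped `gene_alignment`s),
#'       `contaminant_alignments` (the contaminant genes across all
#'       food-clade tips, the basis for a screening database).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
assemble_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- sprintf("sp%02d", seq_len(config$n_species))
  genes <- sprintf("g%03d", seq_len(config$n_genes))
  tree <- simulate_species_tree(config$n_species,
                                derive_seed(config$seed, "species_tree"),
                                config$branch_scale, labels = sp)
  alns <- lapply(genes, function(g)
    evolve_gene(tree, config$gene_length, derive_seed(config$seed, paste0("gene:", g)),
                config$composition_bias, gene_id = g))
  names(alns) <- genes

  presence <- with_seed(derive_seed(config$seed, "missingness"),
    matrix(runif(config$n_genes * config$n_species) >= config$missingness_rate,
           nrow = config$n_genes, ncol = config$n_species,
           dimnames = list(genes, sp)))

  rec <- with_seed(derive_seed(config$seed, "isoforms"), {
    out <- vector("list", config$n_genes * config$n_species)
    k <- 0L
    for (g in genes) for (s in sp) {
      if (!presence[g, s]) next
      full <- alns[[g]]$seqs[[s]]
      supports <- round(runif(config$isoforms_per_gene, 1, 1000), 1)
      # the full-length copy always carries the highest read support, so
      # isoform selection by support is well-defined against the truth
      supports[1] <- max(supports) + 1
      seqs <- c(full, if (config$isoforms_per_gene > 1)
        vapply(seq_len(config$isoforms_per_gene - 1L),
               function(i) make_isoform(full), ""))
      k <- k + 1L
      out[[k]] <- data.frame(species_id = s, gene_id = g,
                             isoform_id = sprintf("%s.i%d", g, seq_along(seqs)),
                             sequence = seqs, read_support = supports,
                             truth_label = "native")
    }
    do.call(rbind, out[seq_len(k)])
  })

  # Contaminants: genes evolved on an independent clade at 3x branch scale,
  # then attributed to a random host species.
  ctree <- simulate_species_tree(max(4L, config$n_species),
                                 derive_seed(config$seed, "contaminant_tree"),
                                 3 * config$branch_scale,
                                 labels = sprintf("food%02d",
                                                  seq_len(max(4L, config$n_species))))
  crec <- NULL
  contaminant_alns <- list()
  if (config$contamination_rate > 0) {
    cres <- with_seed(derive_seed(config$seed, "contamination"), {
      out <- list()
      cal_all <- list()
      for (s in sp) {
        n_native <- sum(rec$species_id == s)
        n_cont <- rbinom(1L, n_native, config$contamination_rate)
        if (n_cont == 0L) next
        calns <- lapply(seq_len(n_cont), function(i)
          evolve_gene(ctree, config$gene_length,
                      sample.int(.Machine$integer.max, 1L),
                      gene_id = sprintf("cg_%s_%03d", s, i)))
        src <- sample(ctree$tip.label, n_cont, replace = TRUE)
        cal_all <- c(cal_all, calns)
        gid <- vapply(calns, `[[`, "", "gene_id")
        out[[s]] <- data.frame(species_id = s,
                               gene_id = gid,
                               isoform_id = paste0(gid, ".i1"),
                               sequence = vapply(seq_len(n_cont), function(i)
                                 calns[[i]]$seqs[[src[i]]], ""),
                               read_support = round(runif(n_cont, 1, 200), 1),
                               truth_label = "contaminant")
      }
      list(rec = if (length(out)) do.call(rbind, out) else NULL,
           alns = cal_all)
    })
    crec <- cres$rec
    contaminant_alns <- cres$alns
    names(contaminant_alns) <- vapply(contaminant_alns, `[[`, "", "gene_id")
  }

  all <- rbind(rec, crec)
  records <- protein_records(all$species_id, all$gene_id, all$isoform_id,
                             all$sequence, all$read_support, all$truth_label)
  list(records = records,
       truth = list(presence = presence, species_tree = tree,
                    contaminant_tree = ctree, alignments = alns,
                    contaminant_alignments = contaminant_alns),
       config = config)
}

#' Write a synthetic dataset to disk
#'
#' Emits one FASTA per species (header dialect of [write_fasta()]), the
#' truth-table TSV of per-record labels, and the true species tree Newick.
#'
#' @param dataset Result of [assemble_dataset()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in unique(dataset$records$species_id)) {
    p <- file.path(dir, paste0(s, ".fasta"))
    write_fasta(dataset$records[dataset$records$species_id == s, ], p)
    paths <- c(paths, p)
  }
  tt <- file.path(dir, "truth_records.tsv")
  utils::write.table(
    data.frame(protein_id = protein_ids(dataset$records),
               truth_label = dataset$records$truth_label),
    tt, sep = "\t", quote = FALSE, row.names = FALSE)
  tp <- file.path(dir, "species_tree.nwk")
  write_newick(dataset$truth$species_tree, tp)
  invisible(c(paths, tt, tp))
}
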