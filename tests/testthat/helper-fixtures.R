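# Shared fixture builders (all generated in code; no data files).

AA20 <- phylopipe:::AA20

random_records <- function(n, seed, species = c("spA", "spB")) {
  set.seed(seed)
  protein_records(
    species_id = sample(species, n, replace = TRUE),
    gene_id = sprintf("g%03d", seq_len(n)),
    isoform_id = sprintf("g%03d.i1", seq_len(n)),
    sequence = vapply(seq_len(n), function(i)
      paste0(sample(AA20, sample(30:80, 1), replace = TRUE), collapse = ""), ""),
    read_support = round(runif(n, 0, 500), 1),
    truth_label = sample(c("native", "unknown"), n, replace = TRUE))
}

# random supermatrix: `n_sp` taxa, genes of random lengths, optional gaps
random_supermatrix <- function(seed, n_sp = 4, n_genes = 3, gap_prob = 0.1,
                               states = AA20) {
  set.seed(seed)
  sp <- sprintf("t%02d", seq_len(n_sp))
  alns <- lapply(seq_len(n_genes), function(g) {
    len <- sample(5:15, 1)
    m <- matrix(sample(states, n_sp * len, replace = TRUE), nrow = n_sp)
    m[matrix(runif(n_sp * len) < gap_prob, nrow = n_sp)] <- "-"
    gene_alignment(sprintf("g%02d", g),
                   setNames(apply(m, 1, paste0, collapse = ""), sp))
  })
  concatenate(alns, roster = sp)
}

# random ortholog table over `n_sp` species and `n_og` orthogroups
random_ortholog_table <- function(seed, n_sp = 5, n_og = 8, p_present = 0.7) {
  set.seed(seed)
  sp <- sprintf("s%02d", seq_len(n_sp))
  rows <- list()
  for (og in sprintf("OG%03d", seq_len(n_og))) for (s in sp) {
    if (runif(1) < p_present)
      rows[[length(rows) + 1]] <- data.frame(
        og_id = og, species_id = s, protein_id = paste0(og, "_", s))
  }
  if (!length(rows)) return(random_ortholog_table(seed + 1, n_sp, n_og, p_present))
  ortholog_table(do.call(rbind, rows), roster = sp)
}

# random support-labelled binary tree on n tips
random_support_tree <- function(seed, n = 6) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, tip.label = sprintf("t%d", seq_len(n)))
  ntip <- length(tr$tip.label)
  lab <- rep("", tr$Nnode)
  internal <- unique(tr$edge[tr$edge[, 2] > ntip, 2])
  lab[internal - ntip] <- as.character(sample(0:100, length(internal),
                                              replace = TRUE))
  tr$node.label <- lab
  tr
}

# alignment whose 3 distinct site patterns all support the split t1t2 | t3t4
treelike_alignment <- function(reps = 50) {
  block <- c(t1 = "AAC", t2 = "AAC", t3 = "CCA", t4 = "CCA")
  gene_alignment("g1", vapply(block, strrep, "", times = reps))
}

expect_same_topology <- function(a, b) {
  expect_setequal(unname(phylopipe:::tree_splits(a)),
                  unname(phylopipe:::tree_splits(b)))
}
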