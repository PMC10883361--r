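test_that("RBH orthogroups recover simulated gene families exactly", {
  ds <- assemble_dataset(sim_config(n_species = 4, n_genes = 6, seed = 8,
                                    gene_length = 80, missingness_rate = 0,
                                    contamination_rate = 0,
                                    isoforms_per_gene = 1))
  tab <- build_orthogroups_rbh(ds$records)
  expect_equal(length(unique(tab$og_id)), 6)
  # each OG holds exactly the 4 orthologs of one true gene
  for (og in unique(tab$og_id)) {
    genes <- unique(sub("^.*\\|(g\\d+)\\|.*$", "\\1",
                        tab$protein_id[tab$og_id == og]))
    expect_equal(length(genes), 1)
  }
  # permuting species input order leaves membership invariant
  set.seed(1)
  perm <- ds$records[sample(nrow(ds$records)), ]
  tab2 <- build_orthogroups_rbh(perm)
  key <- function(t) sort(vapply(split(t$protein_id, t$og_id),
                                 function(x) paste(sort(x), collapse = ","), ""))
  expect_equal(unname(key(tab2)), unname(key(tab)))
})

test_that("a gene lost in one species yields a 2-species orthogroup", {
  ds <- assemble_dataset(sim_config(n_species = 4, n_genes = 3, seed = 4,
                                    gene_length = 80, missingness_rate = 0,
                                    contamination_rate = 0,
                                    isoforms_per_gene = 1))
  rec <- ds$records[!(ds$records$gene_id == "g001" &
                        ds$records$species_id %in% c("sp01", "sp02")), ]
  tab <- build_orthogroups_rbh(rec)
  og_sp <- table(tab$og_id[grepl("g001", tab$protein_id)])
  spanned <- unique(tab$species_id[grepl("g001", tab$protein_id)])
  expect_setequal(spanned, c("sp03", "sp04"))
})

test_that("strict completeness matches a brute-force membership scan", {
  for (seed in 1:10) {
    tab <- random_ortholog_table(seed)
    roster <- attr(tab, "roster")
    got <- select_strict_complete(tab, roster)
    # oracle: scan the incidence matrix
    oracle <- character(0)
    for (og in unique(tab$og_id)) {
      sp <- unique(tab$species_id[tab$og_id == og])
      if (all(roster %in% sp)) oracle <- c(oracle, og)
    }
    expect_setequal(got, sort(oracle))
  }
  tab <- ortholog_table(data.frame(og_id = "og1", species_id = "s1",
                                   protein_id = "p1"),
                        roster = c("s1", "s2"))
  expect_equal(length(select_strict_complete(tab)), 0)
  expect_error(select_strict_complete(tab, character(0)), "empty")
})

test_that("isoform selection prefers support, then length, then id", {
  rec <- protein_records(rep("sp", 2), rep("g1", 2), c("g1.i1", "g1.i2"),
                         c("MKV", "MKVLL"), read_support = c(10, 50))
  expect_equal(pick_isoform(rec)$isoform_id, "g1.i2")

  rec2 <- protein_records(rep("sp", 2), rep("g1", 2), c("g1.i1", "g1.i2"),
                          c(strrep("M", 120), strrep("M", 200)),
                          read_support = c(7, 7))
  expect_equal(pick_isoform(rec2)$isoform_id, "g1.i2")  # longer wins the tie

  rec3 <- protein_records(rep("sp", 2), rep("g1", 2), c("g1.i2", "g1.i1"),
                          c("MKV", "MKV"), read_support = c(7, 7))
  expect_equal(pick_isoform(rec3)$isoform_id, "g1.i1")  # smallest id last

  single <- rec[1, ]
  expect_identical(pick_isoform(single), single)
  expect_equal(nrow(select_isoforms(rbind(rec, rec2[1, ]))), 1 + 0)
})

busco_toy <- function() {
  # 3 study species; og1 complete + full variants, og2 complete but 1
  # variant short, og3 split variant group
  sp <- c("s1", "s2", "s3")
  rows <- rbind(
    expand.grid(og_id = "og1", species_id = sp, stringsAsFactors = FALSE),
    expand.grid(og_id = "og2", species_id = sp, stringsAsFactors = FALSE),
    expand.grid(og_id = "og3", species_id = sp, stringsAsFactors = FALSE))
  rows$protein_id <- paste0(rows$og_id, "_", rows$species_id)
  v1 <- data.frame(og_id = "og1", species_id = "busco",
                   protein_id = sprintf("B1_%02d", 1:10))
  v2 <- data.frame(og_id = "og2", species_id = "busco",
                   protein_id = sprintf("B2_%02d", 1:9))
  v3 <- data.frame(og_id = c(rep("og3", 6), rep("og1", 4)),
                   species_id = "busco",
                   protein_id = sprintf("B3_%02d", 1:10))
  tab <- ortholog_table(rbind(rows, v1, v2, v3), roster = c(sp, "busco"))
  variants <- data.frame(
    group_id = rep(c("B1", "B2", "B3"), times = c(10, 9, 10)),
    protein_id = c(v1$protein_id, v2$protein_id, v3$protein_id))
  list(tab = tab, variants = variants, roster = sp)
}

test_that("BUSCO co-assignment requires completeness and a full variant set", {
  toy <- busco_toy()
  res <- select_busco_ogs(toy$tab, toy$variants, toy$roster)
  expect_equal(res$selected, "og1")
  st <- setNames(res$groups$status, res$groups$group_id)
  expect_equal(unname(st["B1"]), "full")
  expect_equal(unname(st["B2"]), "deficient")
  expect_equal(unname(st["B3"]), "split")
  expect_equal(unname(res$per_og[c("og1", "og2", "og3")]), c(14L, 9L, 6L))
})

test_that("variant bookkeeping arithmetic is exact at scale", {
  s <- busco_summary(rep(10L, 978))
  expect_equal(s$total_variants, 9780)
  counts <- c(rep(10L, 766), rep(c(3L, 7L, 9L), length.out = 330))
  s2 <- busco_summary(counts)
  expect_equal(s2$n_ogs, 1096)
  expect_equal(s2$n_full, 766)
  expect_equal(s2$n_deficient, 330)
})

test_that("shared-OG matrix counts pairwise co-membership", {
  tab <- ortholog_table(data.frame(
    og_id = c("og1", "og1", "og2", "og2", "og2", "og3"),
    species_id = c("A", "B", "A", "B", "C", "C"),
    protein_id = paste0("p", 1:6)))
  m <- shared_og_matrix(tab)
  expect_equal(unname(m), matrix(c(2, 2, 1, 2, 2, 1, 1, 1, 2), 3,
                                 byrow = TRUE))
})

test_that("shared-OG matrices are symmetric and diagonal-dominant", {
  for (seed in 1:10) {
    tab <- random_ortholog_table(seed, n_sp = 6, n_og = 12)
    m <- shared_og_matrix(tab)
    expect_identical(m, t(m))
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
      expect_lte(m[i, j], min(m[i, i], m[j, j]))
  }
})

test_that("species with identical OG profiles are clustered as sisters", {
  tab <- ortholog_table(data.frame(
    og_id = rep(sprintf("og%d", 1:6), each = 2),
    species_id = c(rbind(rep("A", 6), rep("B", 6))),
    protein_id = paste0("p", 1:12)))
  tab2 <- rbind(as.data.frame(tab),
                data.frame(og_id = c("og1", "og7", "og8"),
                           species_id = "C",
                           protein_id = c("q1", "q2", "q3")),
                data.frame(og_id = c("og7", "og8", "og2"),
                           species_id = "D",
                           protein_id = c("r1", "r2", "r3")))
  tab2 <- ortholog_table(tab2)
  tr <- cluster_species(shared_og_matrix(tab2))
  expect_s3_class(tr, "phylo")
  splits <- unname(phylopipe:::tree_splits(tr))
  expect_true(any(vapply(splits, function(s)
    s %in% c("A|B", "C|D"), TRUE)))
})

test_that("zero-variance OG profiles fall back to distance 1 with warning", {
  m <- matrix(c(3L, 1L, 1L, 1L, 3L, 1L, 1L, 1L, 1L), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m["C", ] <- 1L; m[, "C"] <- 1L
  expect_warning(tr <- cluster_species(m), "zero-variance")
  expect_s3_class(tr, "phylo")
})
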