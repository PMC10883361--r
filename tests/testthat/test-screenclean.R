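test_that("ORF finder applies the length cutoff over all six frames", {
  # stops in every frame, no start codon anywhere: nothing reaches 70 aa
  junk <- paste(rep("TAATAGTGA", 17), collapse = "")
  expect_equal(find_orfs(junk), character(0))

  # ATG + 74 non-stop codons + TAA -> one 75-residue peptide
  orf <- paste0("ATG", strrep("GCT", 74), "TAA")
  peps <- find_orfs(orf)
  expect_equal(nchar(peps), 75)
  expect_equal(substr(peps, 1, 1), "M")

  # minus-strand-only ORF of 80 aa is found via reverse complement
  fwd <- paste0("ATG", strrep("AAA", 79))
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(fwd, "")[[1]]),
                                     collapse = ""))
  expect_true(any(nchar(find_orfs(rc, min_aa = 80)) == 80))

  expect_error(find_orfs("ACGTU"), "non-nucleotide")
})

test_that("frame-start ORFs are admitted only when unanchored", {
  no_m <- strrep("GCT", 80)  # 80 alanines, no methionine, no stop
  expect_equal(find_orfs(no_m, min_aa = 70), character(0))
  expect_gt(length(find_orfs(no_m, min_aa = 70, anchored = FALSE)), 0)
})

test_that("redundancy collapse keeps sub-cutoff pairs and merges identical ones", {
  twin <- protein_records(c("a", "a"), c("g1", "g2"), c("g1.i1", "g2.i1"),
                          c("MKVLWDEHR", "MKVLWDEHR"))
  expect_equal(nrow(collapse_redundant(twin)), 1)

  # 18/20 identical residues = 90% identity: both survive at 0.95
  s1 <- paste0(AA20, collapse = "")
  s2 <- paste0(c(AA20[1:18], "A", "A"), collapse = "")
  pair <- protein_records(c("a", "a"), c("g1", "g2"), c("g1.i1", "g2.i1"),
                          c(s1, s2))
  expect_equal(nrow(collapse_redundant(pair, 0.95)), 2)
  expect_equal(nrow(collapse_redundant(pair, 0.90)), 1)
})

test_that("redundancy collapse is order-independent and idempotent", {
  set.seed(42)
  base <- vapply(1:6, function(i)
    paste0(sample(AA20, 40, replace = TRUE), collapse = ""), "")
  variants <- c(base, vapply(base[1:3], function(s)
    paste0(substr(s, 1, 30)), ""))  # truncated copies join their parents
  rec <- protein_records("sp", sprintf("g%d", seq_along(variants)),
                         sprintf("g%d.i1", seq_along(variants)), variants)
  ref <- collapse_redundant(rec, 0.7)
  for (seed in 1:4) {
    set.seed(seed)
    perm <- rec[sample(nrow(rec)), ]
    out <- collapse_redundant(perm, 0.7)
    expect_setequal(protein_ids(out), protein_ids(ref))
  }
  again <- collapse_redundant(ref, 0.7)
  expect_equal(protein_ids(again), protein_ids(ref))
})

make_hit <- function(query, taxon, class, score, evalue = 1e-8) {
  data.frame(query_id = query, subject_id = paste0(taxon, "|x|x.i1"),
             subject_taxon = taxon, subject_class = class, score = score,
             evalue_like = evalue)
}

test_that("best-hit screen discards on strictly best contaminant hits only", {
  rec <- protein_records("spA", "g1", "g1.i1", "MKVLW")
  id <- protein_ids(rec)

  no_hits <- make_hit("other", "t", "reference", 1)[0, ]
  expect_equal(screen_best_hit(rec, no_hits, 1)$kept, id)

  r <- screen_best_hit(rec, rbind(make_hit(id, "diatom", "contaminant", 210),
                                  make_hit(id, "annelid", "reference", 180)),
                       1)
  expect_equal(unname(r$discarded[id]), "diatom")

  # brute force over the 2-hit outcome space: discard iff the contaminant
  # hit is strictly best
  for (sc in c(150, 200, 250)) for (sr in c(150, 200, 250)) {
    hits <- rbind(make_hit(id, "diatom", "contaminant", sc),
                  make_hit(id, "annelid", "reference", sr))
    out <- screen_best_hit(rec, hits, 1)
    expect_identical(length(out$discarded) == 1L, sc > sr,
                     label = sprintf("scores c=%d r=%d", sc, sr))
  }
  expect_error(screen_best_hit(rec, make_hit(id, "d", "contaminant", 1), -1),
               "non-negative")
})

test_that("evalue cutoff gates which hits are considered", {
  rec <- protein_records("spA", "g1", "g1.i1", "MKVLW")
  id <- protein_ids(rec)
  weak <- make_hit(id, "diatom", "contaminant", 300, evalue = 10)
  expect_equal(length(screen_best_hit(rec, weak, 1)$discarded), 0)
  expect_equal(length(screen_best_hit(rec, weak, 10)$discarded), 1)
})

test_that("control records yield a false-positive rate", {
  rec <- protein_records(c("ctrl", "ctrl", "spA"), c("g1", "g2", "g1"),
                         c("g1.i1", "g2.i1", "g1.i1"),
                         c("MKVLW", "MKVDE", "MKVHH"))
  ids <- protein_ids(rec)
  hits <- rbind(make_hit(ids[1], "diatom", "contaminant", 200),
                make_hit(ids[2], "annelid", "reference", 200))
  r <- screen_best_hit(rec, hits, 1, control_species = "ctrl")
  expect_equal(r$false_positive_rate, 0.5)
})

test_that("two-step screen composes transcript and protein rules", {
  nt <- protein_records(c("spA", "spA"), c("g1", "g2"),
                        c("g1.i1", "g2.i1"), c("ACGTACGT", "ACGTTGCA"))
  prot <- protein_records(c("spA", "spA"), c("g1", "g2"),
                          c("g1.i1", "g2.i1"), c("MKVLW", "MKVDE"))
  ids <- protein_ids(prot)
  nt_hits <- make_hit(ids[1], "diatom", "contaminant", 500)
  prot_hits <- make_hit(ids[2], "ciliate", "contaminant", 300)
  r <- two_step_screen(nt, prot, nt_hits, prot_hits, 1, 1)
  # record failing step 1 never reaches step 2: reason is parent_removed
  expect_equal(unname(r$discarded[ids[1]]), "parent_removed")
  expect_equal(unname(r$discarded[ids[2]]), "prot:ciliate")
  expect_equal(length(r$kept), 0)

  # accept-all cutoffs reduce to the single-step protein screen
  r2 <- two_step_screen(nt, prot, nt_hits[0, ], prot_hits, Inf, Inf)
  r1 <- screen_best_hit(prot, prot_hits, Inf)
  expect_setequal(r2$kept, r1$kept)
  expect_setequal(names(r2$discarded), names(r1$discarded))
})

test_that("synthetic screen recovers contaminants against the truth table", {
  ds <- assemble_dataset(sim_config(n_species = 4, n_genes = 8, seed = 11,
                                    gene_length = 120, missingness_rate = 0,
                                    contamination_rate = 0.2,
                                    isoforms_per_gene = 1))
  expect_gt(sum(ds$records$truth_label == "contaminant"), 0)
  rep <- screen_dataset(ds, 1, control_species = "sp01")
  acc <- screen_accuracy(rep, ds$records)
  expect_gte(acc$sensitivity, 0.9)
  expect_gte(acc$specificity, 0.95)
  # determinism of the screen
  rep2 <- screen_dataset(ds, 1, control_species = "sp01")
  expect_identical(sort(rep$kept), sort(rep2$kept))
})

test_that("hit tables round-trip through the 6-column TSV adapter", {
  hits <- rbind(make_hit("q1", "diatom", "contaminant", 210),
                make_hit("q2", "annelid", "reference", 180))
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(hits, f, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  back <- read_hits_tsv(f)
  expect_equal(back$score, hits$score)
  expect_equal(back$subject_class, hits$subject_class)
})
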