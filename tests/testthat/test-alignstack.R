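test_that("progressive alignment handles identity, gaps and trivial input", {
  same <- align_gene(setNames(rep("MKVLWDE", 3), c("a", "b", "c")))
  expect_equal(unique(nchar(same$seqs)), 7)
  expect_false(any(grepl("-", same$seqs, fixed = TRUE)))

  # "MKV" vs "MV": one gap column under the package scores, 3 columns total
  pair <- align_gene(c(a = "MKV", b = "MV"))
  expect_equal(pair$length, 3)
  expect_equal(sum(strsplit(pair$seqs[["b"]], "")[[1]] == "-"), 1)
  expect_equal(pair$seqs[["a"]], "MKV")

  single <- align_gene(c(only = "MKV"))
  expect_equal(single$seqs, c(only = "MKV"))
})

test_that("alignment length is bounded below by the longest input", {
  set.seed(7)
  for (i in 1:8) {
    n <- sample(2:5, 1)
    seqs <- setNames(vapply(seq_len(n), function(j)
      paste0(sample(AA20, sample(10:25, 1), replace = TRUE), collapse = ""),
      ""), sprintf("s%d", seq_len(n)))
    aln <- align_gene(seqs)
    expect_gte(aln$length, max(nchar(seqs)))
    # rows strip back to their inputs
    expect_equal(gsub("-", "", aln$seqs, fixed = TRUE)[names(seqs)], seqs)
    if (aln$length == max(nchar(seqs)) && length(unique(nchar(seqs))) == 1)
      expect_false(any(grepl("-", aln$seqs, fixed = TRUE)))
  }
})

test_that("gap trimming removes columns above the threshold", {
  clean <- gene_alignment("g", c(a = "MKV", b = "MLV", c = "MKV"))
  expect_identical(trim_gappy(clean)$seqs, clean$seqs)

  gappy <- gene_alignment("g", c(a = "M-V", b = "M-V", c = "M-V", d = "MKV"))
  tr <- trim_gappy(gappy, 0.5)  # column 2 has 75% gaps
  expect_equal(tr$length, 2)
  expect_equal(tr$seqs[["a"]], "MV")

  lost <- gene_alignment("g", c(a = "M--", b = "-KV", c = "-KV", d = "-KV"))
  tr2 <- trim_gappy(lost, 0.5)  # column 1 (75% gaps) removed: taxon a left empty
  expect_equal(attr(tr2, "fully_trimmed"), "a")
})

test_that("concatenation records partitions and fills missing blocks", {
  a <- gene_alignment("gA", c(s1 = "MKV", s2 = "MLV"))
  b <- gene_alignment("gB", c(s1 = "WWDE", s2 = "WWDD"))
  sm <- concatenate(list(b, a))  # order normalised by gene_id
  expect_equal(sm$length, 7)
  expect_equal(sm$partitions$gene_id, c("gA", "gB"))
  expect_equal(sm$partitions$start, c(1L, 4L))

  part <- concatenate(list(a, gene_alignment("gB", c(s1 = "WWDE"))),
                      roster = c("s1", "s2"))
  expect_equal(substr(part$rows[["s2"]], 4, 7), "----")
  expect_gt(matrix_stats(part)$pct_gaps_undetermined, 0)

  expect_error(concatenate(list(a, a)), "duplicate")
})

test_that("per-partition slices recover the input alignments exactly", {
  for (seed in 1:6) {
    set.seed(seed)
    sp <- sprintf("s%d", 1:4)
    alns <- lapply(1:3, function(g) {
      len <- sample(4:9, 1)
      gene_alignment(sprintf("g%d", g), setNames(vapply(sp, function(s)
        paste0(sample(c(AA20, "-"), len, replace = TRUE), collapse = ""),
        ""), sp))
    })
    sm <- concatenate(alns, roster = sp)
    for (a in alns) {
      back <- slice_partition(sm, a$gene_id)
      expect_equal(back$seqs[names(a$seqs)], a$seqs)
    }
  }
})

test_that("matrix statistics count distinct patterns and missing characters", {
  uni <- supermatrix(c(a = "AAA", b = "CCC"),
                     data.frame(gene_id = "g", start = 1, end = 3))
  expect_equal(matrix_stats(uni)$n_distinct_patterns, 1)
  expect_equal(matrix_stats(uni)$pct_gaps_undetermined, 0)

  two <- supermatrix(c(a = "AAC", b = "AAT"),
                     data.frame(gene_id = "g", start = 1, end = 3))
  expect_equal(matrix_stats(two)$n_distinct_patterns, 2)

  gap <- supermatrix(c(a = "A-X", b = "AAC"),
                     data.frame(gene_id = "g", start = 1, end = 3))
  expect_equal(matrix_stats(gap)$pct_gaps_undetermined, 100 * 2 / 6)
})

test_that("zero-gap filtering keeps exactly the gap-free columns", {
  clean <- random_supermatrix(1, gap_prob = 0)
  out <- strip_gapped_columns(clean)
  expect_identical(out$matrix$rows, clean$rows)
  expect_equal(out$pct_genes_retained, "100.0%")

  sm <- supermatrix(c(a = "ACD", b = "A-D", c = "ACD"),
                    data.frame(gene_id = "g", start = 1, end = 3))
  out2 <- strip_gapped_columns(sm)
  expect_equal(unname(out2$matrix$rows), rep("AD", 3))
  expect_equal(matrix_stats(out2$matrix)$pct_gaps_undetermined, 0)
})

test_that("gene retention percentages format to one decimal", {
  expect_equal(retention_percent(1059, 340), "32.1%")
  expect_equal(retention_percent(10, 10), "100.0%")
  expect_equal(retention_percent(3, 1), "33.3%")
})

test_that("zero-gap output always has zero missing data", {
  for (seed in 1:6) {
    sm <- random_supermatrix(seed, n_sp = 5, n_genes = 4, gap_prob = 0.15)
    out <- tryCatch(strip_gapped_columns(sm), error = function(e) NULL)
    if (is.null(out)) next  # all columns had gaps
    expect_equal(matrix_stats(out$matrix)$pct_gaps_undetermined, 0)
    expect_equal(sum(out$report$n_retained), out$matrix$length)
  }
})
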