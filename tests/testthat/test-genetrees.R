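# independent least-squares oracle over the 3 unrooted 4-taxon topologies
ls_best_quartet <- function(d) {
  taxa <- rownames(d)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  sums <- vapply(splits, function(s) {
    pair <- taxa[s]; rest <- setdiff(taxa, pair)
    d[pair[1], pair[2]] + d[rest[1], rest[2]]
  }, 0)
  splits[[which.min(sums)]]
}

test_that("neighbor joining recovers additive quartets", {
  # additive AB|CD matrix: internal branch 0.3
  taxa <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  bl <- c(A = 0.1, B = 0.2, C = 0.15, D = 0.25)
  for (i in 1:3) for (j in (i + 1):4) {
    extra <- if (length(intersect(taxa[c(i, j)], c("A", "B"))) == 1) 0.3 else 0
    d[i, j] <- d[j, i] <- bl[i] + bl[j] + extra
  }
  tr <- nj_tree(d)
  split <- unname(phylopipe:::tree_splits(tr))
  expect_true(split %in% c("A|B", "C|D"))
  # agrees with the brute-force least-squares oracle
  oracle_pair <- sort(taxa[ls_best_quartet(d)])
  expect_true(paste(oracle_pair, collapse = "|") %in%
                c(split, paste(sort(setdiff(taxa, strsplit(split, "\\|")[[1]])),
                               collapse = "|")))
})

test_that("3-taxon NJ tree length is half the distance sum", {
  d <- matrix(c(0, .2, .3, .2, 0, .25, .3, .25, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(sum(tr$edge.length), (0.2 + 0.3 + 0.25) / 2)
  bad <- d; bad[1, 2] <- 9
  expect_error(nj_tree(bad), "symmetric")
})

test_that("unanimous signal earns full bootstrap support", {
  aln <- treelike_alignment(50)
  tr <- bootstrap_supports(aln, n_reps = 50, seed = 3)
  bs <- as.numeric(tr$node.label[nzchar(tr$node.label)])
  expect_true(all(bs == 100))
  # deterministic per seed, same point topology across seeds
  tr2 <- bootstrap_supports(aln, n_reps = 50, seed = 3)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  tr3 <- bootstrap_supports(aln, n_reps = 50, seed = 4)
  expect_same_topology(tr, tr3)
  expect_error(bootstrap_supports(
    gene_alignment("g", c(a = "MK", b = "ML", c = "MK")), 10, 1), ">= 4")
})

test_that("bootstrap supports stay within [0, 100] on noisy data", {
  aln <- evolve_gene(simulate_species_tree(5, 2, 0.05), 60, 9)
  tr <- bootstrap_supports(aln, n_reps = 40, seed = 1)
  bs <- as.numeric(tr$node.label[nzchar(tr$node.label)])
  expect_true(all(bs >= 0 & bs <= 100))
})

test_that("gene statistics aggregate length, support and gaps", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1)80:0.1,c:0.1,d:0.1);")
  aln <- gene_alignment("g", c(a = "MKV", b = "MKV", c = "MKV", d = "MKV"))
  st <- gene_stats(tr, aln)
  expect_equal(st$mean_bs, 80)       # single internal branch
  expect_equal(st$tree_length, 0.5)  # 5 edges x 0.1 on an unrooted 4-leaf tree
  expect_equal(st$gap_pct, 0)

  gappy <- gene_alignment("g", c(a = "M-V", b = "MKV", c = "MKV", d = "MKV"))
  expect_equal(gene_stats(tr, gappy)$gap_pct, 100 / 12)

  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_error(gene_stats(star, aln), "internal branches")
})

test_that("quartile thresholds follow the linear-interpolation convention", {
  th <- quartile_thresholds(c(1:8, 100))
  expect_equal(th$q3, 7)
  expect_equal(th$q1, 3)
  expect_equal(th$iqr, 4)
  expect_equal(th$upper_fence, 13)
  expect_gt(100, th$upper_fence)  # 100 is an outlier

  flat <- quartile_thresholds(rep(5, 6))
  expect_equal(flat$median, 5)
  expect_equal(flat$upper_fence, 5)
  expect_error(quartile_thresholds(c(1, 2, 3)), ">= 4")
  for (seed in 1:5) {
    set.seed(seed)
    th2 <- quartile_thresholds(runif(20))
    expect_gte(th2$upper_fence, th2$q3)
  }
})

fake_stats <- function(bs, len = NULL, gap = NULL) {
  n <- length(bs)
  data.frame(gene_id = sprintf("g%d", seq_len(n)),
             tree_length = len %||% rep(1, n), mean_bs = bs,
             gap_pct = gap %||% rep(10, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("marker filters apply strict thresholds over the input distribution", {
  st <- fake_stats(c(30, 45, 60, 90))
  aa <- select_markers(st, "AA", bs_fixed = 40)
  expect_setequal(aa$ids, c("g2", "g3", "g4"))

  ab <- select_markers(st, "AB")
  expect_equal(ab$thresholds$bs, 52.5)
  expect_setequal(ab$ids, c("g3", "g4"))

  st2 <- fake_stats(c(90, 92, 95, 97),
                    len = c(1, 1, 1.2, 50),   # g4 beyond the length fence
                    gap = c(5, 8, 10, 2))
  ac <- select_markers(st2, "AC")
  expect_false("g4" %in% ac$ids)
  expect_error(select_markers(st[0, ], "AA"), "empty")
})

test_that("marker filters match brute force after distribution changes", {
  for (seed in 1:8) {
    set.seed(seed)
    st <- fake_stats(runif(12, 0, 100), len = rexp(12, 1 / 10),
                     gap = runif(12, 0, 40))
    for (rule in c("AA", "AB", "AC")) {
      got <- select_markers(st, rule)$ids
      med_bs <- unname(quantile(st$mean_bs, 0.5, type = 7))
      fence <- unname(quantile(st$tree_length, 0.75, type = 7)) +
        1.5 * unname(diff(quantile(st$tree_length, c(0.25, 0.75), type = 7)))
      gap_q3 <- unname(quantile(st$gap_pct, 0.75, type = 7))
      oracle <- switch(rule,
        AA = st$gene_id[st$mean_bs > 40],
        AB = st$gene_id[st$mean_bs > med_bs],
        AC = st$gene_id[st$tree_length < fence & st$mean_bs > med_bs &
                          st$gap_pct < gap_q3])
      expect_setequal(got, oracle)
    }
  }
})

test_that("fully-trimmed genes are excluded from the coalescent set", {
  ok <- gene_alignment("g1", c(a = "MK", b = "ML", c = "MK"))
  bad <- gene_alignment("g2", c(a = "--", b = "ML", c = "MK"))
  out <- drop_fully_trimmed(list(ok, bad))
  expect_equal(out$survivors, "g1")
  expect_equal(out$flagged, "g2")
  # oracle: brute-force row scan
  for (seed in 1:5) {
    set.seed(seed)
    alns <- lapply(1:6, function(g) {
      m <- matrix(sample(c(AA20, "-"), 12, TRUE, prob = c(rep(1, 20), 8)),
                  nrow = 3, dimnames = list(c("a", "b", "c"), NULL))
      gene_alignment(sprintf("g%d", g),
                     apply(m, 1, paste0, collapse = ""))
    })
    out <- drop_fully_trimmed(alns)
    oracle <- vapply(alns, function(a)
      any(vapply(strsplit(a$seqs, ""), function(ch) all(ch == "-"), TRUE)), TRUE)
    expect_setequal(out$flagged, sprintf("g%d", which(oracle)))
  }
})

test_that("branch contraction collapses only low-support bipartitions", {
  strong <- ape::read.tree(text = "((a,b)100:1,(c,d)100:1,e:1);")
  expect_same_topology(contract_low_support(strong, 10), strong)

  weak <- ape::read.tree(text = "((a,b)5:1,(c,d)90:1,e:1);")
  ct <- contract_low_support(weak, 10)
  expect_equal(ct$Nnode, weak$Nnode - 1L)
  expect_setequal(unname(phylopipe:::tree_splits(ct)), "c|d")
  # the removed node produced a degree-4 polytomy at the root
  expect_equal(max(table(ct$edge[, 1])), 4)
  # idempotence
  expect_identical(ape::write.tree(contract_low_support(ct, 10)),
                   ape::write.tree(ct))
  # leaves always untouched
  expect_setequal(ct$tip.label, weak$tip.label)
})

test_that("contraction removes exactly the at-threshold splits (oracle)", {
  for (seed in 1:10) {
    tr <- random_support_tree(seed, n = 7)
    ct <- contract_low_support(tr, 30)
    keys <- phylopipe:::tree_splits(tr)
    ntip <- length(tr$tip.label)
    supp <- as.numeric(tr$node.label[as.integer(names(keys)) - ntip])
    expect_setequal(unname(phylopipe:::tree_splits(ct)),
                    unname(keys[is.na(supp) | supp > 30]))
  }
})

test_that("quartet species tree maximises agreement over all topologies", {
  base <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  same <- lapply(1:5, function(i) base)
  qt <- quartet_species_tree(same)
  expect_same_topology(qt$best, base)
  expect_equal(qt$score, qt$n_quartets * 5)

  alt <- ape::read.tree(text = "((a,c),(b,d),(e,f));")
  mix <- c(lapply(1:14, function(i) base), lapply(1:6, function(i) alt))
  qt2 <- quartet_species_tree(mix)
  expect_same_topology(qt2$best, base)  # 70/30 majority wins
  expect_equal(length(qt2$co_optimal), 1)

  expect_error(quartet_species_tree(list(base, base,
    ape::read.tree(text = "((a,b),(c,d),(e,g));"))), "leaf set")
})
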