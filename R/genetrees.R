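# Gene trees with bootstrap supports, per-gene statistics, quartile-fence
# marker filters, low-support branch contraction, and an exhaustive
# quartet-agreement species tree for small taxon sets.

#' Identity-based amino-acid distance matrix
#'
#' Pairwise p-distances over shared non-gap, non-`X` sites, corrected for
#' multiple hits with the 20-state Jukes-Cantor analogue
#' `d = -(19/20) log(1 - (20/19) p)`.  p is capped just below the
#' correction's pole so distances stay finite; a pair with no shared sites
#' gets the capped maximum.
#'
#' @param alignment A `gene_alignment`.
#' @return Symmetric numeric distance matrix over the alignment's species.
#' @export
aa_distance <- function(alignment) {
  stopifnot(inherits(alignment, "gene_alignment"))
  m <- seqs_to_matrix(alignment$seqs)
  ok <- m != "-" & m != "X"
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  p_cap <- 0.94
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- ok[i, ] & ok[j, ]
    p <- if (any(shared)) mean(m[i, shared] != m[j, shared]) else p_cap
    p <- min(p, p_cap)
    d[i, j] <- d[j, i] <- -(19 / 20) * log(1 - (20 / 19) * p)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param distance_matrix Symmetric, zero-diagonal matrix, n >= 3.
#' @return An unrooted `phylo`; negative branch lengths are clamped to 0
#'   (attribute `"clamped"` set to `TRUE` when this happened).
#' @export
nj_tree <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) < 3L) stop("need >= 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    tr$edge.length[tr$edge.length < 0] <- 0
    attr(tr, "clamped") <- TRUE
  }
  tr
}

# Canonical bipartition keys of a tree's internal edges: for each internal
# edge, the sorted tip labels of the side not containing the reference tip
# (the alphabetically first label), pasted with "|".  Returns a character
# vector named by the child node of each internal edge.
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  internal_children <- tree$edge[tree$edge[, 2] > ntip, 2]
  if (length(internal_children) == 0L) return(setNames(character(0), integer(0)))
  # tips under each node via postorder accumulation
  tips_under <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_under[[i]] <- tree$tip.label[i]
  post <- reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(post)))
    tips_under[[post[e, 1]]] <- c(tips_under[[post[e, 1]]],
                                  tips_under[[post[e, 2]]])
  keys <- vapply(internal_children, function(node) {
    side <- tips_under[[node]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    paste(sort(side), collapse = "|")
  }, "")
  names(keys) <- internal_children
  # trivial "splits" (all-but-ref) can arise at the root-adjacent edge
  keys[nchar(keys) > 0]
}

#' Bootstrap supports for a neighbor-joining gene tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate is re-distanced and re-estimated, and the support of every
#' internal branch of the point-estimate tree is the percentage of
#' replicates containing the same bipartition.  Supports are stored as
#' internal node labels (rounded to integers).
#'
#' @param alignment A `gene_alignment` with >= 4 rows.
#' @param n_reps Number of replicates (>= 1; 100 by default).
#' @param seed RNG seed (deterministic output per seed).
#' @return The point-estimate `phylo` with `$node.label` supports (empty
#'   string on the root).
#' @export
bootstrap_supports <- function(alignment, n_reps = 100, seed = 1) {
  stopifnot(inherits(alignment, "gene_alignment"), n_reps >= 1)
  if (length(alignment$seqs) < 4L)
    stop("bootstrap supports need >= 4 sequences")
  point <- nj_tree(aa_distance(alignment))
  keys <- tree_splits(point)
  counts <- setNames(numeric(length(keys)), keys)
  m <- seqs_to_matrix(alignment$seqs)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_aln <- gene_alignment(alignment$gene_id,
                                matrix_to_seqs(m[, cols, drop = FALSE]))
      rep_keys <- tree_splits(nj_tree(aa_distance(rep_aln)))
      hit <- keys %in% rep_keys
      counts[hit] <- counts[hit] + 1
    }
  })
  ntip <- length(point$tip.label)
  labels <- rep("", point$Nnode)
  support <- round(100 * counts / n_reps)
  node_of <- as.integer(names(keys))
  labels[node_of - ntip] <- as.character(support)
  point$node.label <- labels
  point
}

#' Per-gene tree and alignment statistics
#'
#' The three marker-filtering axes: total tree length (sum of branch
#' lengths), mean internal-branch bootstrap support, and the alignment's
#' gap percentage.
#'
#' @param tree A support-labelled `phylo` (as from [bootstrap_supports()]).
#' @param alignment The gene's (trimmed) `gene_alignment`.
#' @return List with `gene_id`, `tree_length`, `mean_bs`, `gap_pct`.
#' @export
gene_stats <- function(tree, alignment) {
  stopifnot(inherits(tree, "phylo"), inherits(alignment, "gene_alignment"))
  if (!all(tree$tip.label %in% names(alignment$seqs)))
    stop("tree leaves must be alignment rows")
  ntip <- length(tree$tip.label)
  internal_children <- tree$edge[tree$edge[, 2] > ntip, 2]
  if (length(internal_children) == 0L)
    stop("tree has no internal branches; mean support undefined")
  bs <- suppressWarnings(as.numeric(tree$node.label[internal_children - ntip]))
  if (all(is.na(bs))) stop("no numeric supports on internal branches")
  m <- seqs_to_matrix(alignment$seqs)
  list(gene_id = alignment$gene_id,
       tree_length = sum(tree$edge.length),
       mean_bs = mean(bs, na.rm = TRUE),
       gap_pct = 100 * mean(m == "-"))
}

#' Quartile thresholds with the upper IQR fence
#'
#' Linear-interpolation ("type 7") quantiles of a numeric distribution plus
#' the conventional outlier fence `Q3 + 1.5 * IQR`.
#'
#' @param values Numeric vector with >= 4 values.
#' @return List with `median`, `q1`, `q3`, `iqr`, `upper_fence`.
#' @export
quartile_thresholds <- function(values) {
  if (length(values) < 4L) stop("need >= 4 values")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
       upper_fence = q[3] + 1.5 * (q[3] - q[1]))
}

#' Select marker genes by tree-statistic filters
#'
#' Three increasingly strict rules over the per-gene statistics, with
#' strict inequalities and thresholds computed from the full distribution
#' passed in:
#' \describe{
#'   \item{AA}{mean bootstrap support strictly above a fixed value
#'     (`bs_fixed`, default 40).}
#'   \item{AB}{mean support strictly above the support distribution's
#'     median.}
#'   \item{AC}{tree length strictly below the upper IQR fence of the
#'     length distribution, AND mean support above the support median, AND
#'     gap percentage below the gap distribution's third quartile.}
#' }
#'
#' @param stats `data.frame` with columns `gene_id`, `tree_length`,
#'   `mean_bs`, `gap_pct` (one row per gene; as from [gene_stats()] rows
#'   bound together).
#' @param rule `"AA"`, `"AB"` or `"AC"`.
#' @param bs_fixed Fixed support threshold for rule AA.
#' @return List with `ids` (selected gene ids) and `thresholds` (the values
#'   applied).
#' @export
select_markers <- function(stats, rule = c("AA", "AB", "AC"), bs_fixed = 40) {
  rule <- match.arg(rule)
  stats <- as.data.frame(stats)
  if (nrow(stats) == 0L) stop("empty stats")
  stopifnot(all(c("gene_id", "tree_length", "mean_bs", "gap_pct") %in%
                  names(stats)))
  if (rule == "AA") {
    thr <- list(bs = bs_fixed)
    keep <- stats$mean_bs > bs_fixed
  } else if (rule == "AB") {
    thr <- list(bs = unname(quantile(stats$mean_bs, 0.5, type = 7)))
    keep <- stats$mean_bs > thr$bs
  } else {
    qlen <- quartile_thresholds(stats$tree_length)
    thr <- list(length_fence = qlen$upper_fence,
                bs = unname(quantile(stats$mean_bs, 0.5, type = 7)),
                gap_q3 = unname(quantile(stats$gap_pct, 0.75, type = 7)))
    keep <- stats$tree_length < thr$length_fence &
      stats$mean_bs > thr$bs & stats$gap_pct < thr$gap_q3
  }
  list(ids = stats$gene_id[keep], thresholds = thr)
}

#' Drop genes in which any species was fully trimmed
#'
#' A gene whose trimmed alignment leaves some species with an all-gap row
#' carries no signal for that taxon and is excluded from coalescent input.
#'
#' @param alignments List of (trimmed) `gene_alignment`s.
#' @return List with `survivors` and `flagged` gene-id vectors.
#' @export
drop_fully_trimmed <- function(alignments) {
  flagged <- vapply(alignments, function(a) {
    if (a$length == 0L) return(TRUE)
    m <- seqs_to_matrix(a$seqs)
    any(rowSums(m != "-") == 0L)
  }, TRUE)
  ids <- vapply(alignments, `[[`, "", "gene_id")
  list(survivors = ids[!flagged], flagged = ids[flagged])
}

#' Contract low-support branches into polytomies
#'
#' Internal branches whose support is less than or equal to `threshold`
#' are collapsed (their lengths discarded); leaves and well-supported
#' branches are untouched.  Idempotent.
#'
#' @param tree A `phylo` with supports in `$node.label`.
#' @param threshold Support cutoff (default 10; branches with support
#'   `<= threshold` collapse).
#' @return The (possibly multifurcating) `phylo`.
#' @export
contract_low_support <- function(tree, threshold = 10) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) stop("tree has no internal supports")
  tr <- tree
  repeat {
    ntip <- length(tr$tip.label)
    child <- tr$edge[, 2]
    is_int <- child > ntip
    supp <- rep(NA_real_, length(child))
    supp[is_int] <- suppressWarnings(
      as.numeric(tr$node.label[child[is_int] - ntip]))
    drop <- which(!is.na(supp) & supp <= threshold)
    if (length(drop) == 0L) break
    e <- drop[1]
    parent <- tr$edge[e, 1]; node <- tr$edge[e, 2]
    tr$edge[tr$edge[, 1] == node, 1] <- parent
    tr$edge <- tr$edge[-e, , drop = FALSE]
    tr$edge.length <- tr$edge.length[-e]
    tr$node.label <- tr$node.label[-(node - ntip)]
    # renumber internal nodes above the removed one
    tr$edge[tr$edge > node] <- tr$edge[tr$edge > node] - 1L
    tr$Nnode <- tr$Nnode - 1L
  }
  tr
}

# Quartet split of every 4-subset of leaves under a tree: 1 = ab|cd,
# 2 = ac|bd, 3 = ad|bc (columns of `quartets`), 0 = unresolved (polytomy).
# Topological (unit-branch-length) four-point condition.
quartet_votes <- function(tree, quartets, labels) {
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  D <- cophenetic(tr)[labels, labels]
  apply(quartets, 2L, function(q) {
    s <- c(D[q[1], q[2]] + D[q[3], q[4]],
           D[q[1], q[3]] + D[q[2], q[4]],
           D[q[1], q[4]] + D[q[2], q[3]])
    lo <- which(s == min(s))
    if (length(lo) == 1L) lo else 0L
  })
}

# All unrooted binary topologies on the given labels, as nested-list trees
# rooted at a degree-3 internal node.  Deterministic order.
enumerate_topologies <- function(labels) {
  stopifnot(length(labels) >= 4L)
  grow <- function(node, tip) {
    res <- list()
    for (i in seq_along(node)) {
      child <- node[[i]]
      t2 <- node
      t2[[i]] <- list(child, tip)
      res <- c(res, list(t2))
      if (is.list(child))
        for (sub in grow(child, tip)) {
          t3 <- node
          t3[[i]] <- sub
          res <- c(res, list(t3))
        }
    }
    res
  }
  trees <- list(list(labels[1], labels[2], labels[3]))
  for (k in 4:length(labels)) {
    trees <- unlist(lapply(trees, grow, tip = labels[k]), recursive = FALSE)
  }
  to_newick <- function(node) {
    if (!is.list(node)) return(node)
    paste0("(", paste(vapply(node, to_newick, ""), collapse = ","), ")")
  }
  vapply(trees, function(tr) paste0(to_newick(tr), ";"), "")
}

#' Exhaustive quartet-agreement species tree
#'
#' A summary-coalescent stand-in for small taxon sets: every unrooted
#' binary topology on the shared leaf set is scored by the number of
#' (gene tree, quartet) pairs whose induced quartet split it matches
#' (quartets left unresolved in a gene tree — e.g. after branch
#' contraction — support no candidate), and the maximiser is returned.
#' Co-optimal topologies are all reported.
#'
#' @param gene_trees List of >= 3 `phylo` objects over one identical leaf
#'   set of size `n`.
#' @param max_exhaustive Largest `n` to attempt (default 8; beyond it the
#'   enumeration is refused).
#' @return List with `best` (first co-optimal `phylo` in enumeration
#'   order), `co_optimal` (list of all co-optimal `phylo`s), `score`
#'   (quartet agreements of the optimum) and `n_quartets`.
#' @export
quartet_species_tree <- function(gene_trees, max_exhaustive = 8) {
  stopifnot(length(gene_trees) >= 3L)
  labels <- sort(gene_trees[[1]]$tip.label)
  for (tr in gene_trees)
    if (!identical(sort(tr$tip.label), labels))
      stop("gene trees must share an identical leaf set")
  n <- length(labels)
  if (n < 4L) stop("need >= 4 taxa")
  if (n > max_exhaustive)
    stop("exhaustive search limited to ", max_exhaustive, " taxa")
  quartets <- combn(n, 4L)
  nq <- ncol(quartets)
  votes <- matrix(0, nrow = nq, ncol = 3L)
  for (tr in gene_trees) {
    v <- quartet_votes(tr, quartets, labels)
    res <- v > 0L
    votes[cbind(which(res), v[res])] <- votes[cbind(which(res), v[res])] + 1
  }
  newicks <- enumerate_topologies(labels)
  scores <- vapply(newicks, function(nwk) {
    cand <- ape::read.tree(text = nwk)
    v <- quartet_votes(cand, quartets, labels)
    sum(votes[cbind(seq_len(nq), v)])
  }, 0)
  top <- which(scores == max(scores))
  co <- lapply(newicks[top], function(nwk) ape::read.tree(text = nwk))
  list(best = co[[1]], co_optimal = co, score = max(scores), n_quartets = nq)
}
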