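# Per-gene alignment, trimming, concatenation into a partitioned
# supermatrix, matrix statistics, and the zero-gap column filter.

# 21-state substitution table for profile alignment: the package's fixed
# amino-acid scores over AA20, with a final all-zero gap state.
profile_submat <- function() {
  s <- phylopipe_submat()[AA20, AA20]
  m <- matrix(0, 21, 21, dimnames = list(c(AA20, "-"), c(AA20, "-")))
  m[1:20, 1:20] <- s
  m
}

# Column-frequency profile (21 x L) of a set of equal-length aligned rows.
profile_of <- function(seqs) {
  m <- seqs_to_matrix(seqs)
  m[m == "X"] <- "-"  # undetermined scores as neutrally as a gap
  L <- ncol(m)
  p <- matrix(0, nrow = 21L, ncol = L, dimnames = list(c(AA20, "-"), NULL))
  states <- c(AA20, "-")
  for (k in seq_along(states))
    p[k, ] <- colMeans(m == states[k])
  p
}

#' Align the sequences of one gene
#'
#' Simplified progressive alignment: pairwise global alignments give an
#' identity-based distance matrix, an average-linkage (UPGMA) guide tree
#' orders the merges, and profiles are merged by an affine-gap
#' profile-profile dynamic program over the package's fixed substitution
#' table (gap open 10, extension 1).  Deterministic throughout.
#'
#' @param records A `protein_records` data frame (rows of one gene across
#'   species) or a named character vector of ungapped sequences.
#' @param gene_id Gene id for the result (taken from `records` when absent).
#' @return A `gene_alignment`.  A single sequence is returned unchanged as a
#'   trivial alignment.
#' @export
align_gene <- function(records, gene_id = NULL) {
  if (is.data.frame(records)) {
    seqs <- setNames(records$sequence, records$species_id)
    gene_id <- gene_id %||% records$gene_id[1]
  } else {
    seqs <- records
    gene_id <- gene_id %||% "g1"
  }
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  seqs <- toupper(gsub("-", "", seqs, fixed = TRUE))
  if (any(!nzchar(seqs))) stop("empty sequence passed to align_gene")
  n <- length(seqs)
  if (n == 1L) return(gene_alignment(gene_id, seqs))

  # guide distances: 1 - identity from pairwise global alignments
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- 1 - global_identity(seqs[[i]], seqs[[j]])
  merge_order <- hclust(as.dist(d), method = "average")$merge

  sub <- profile_submat()
  nodes <- lapply(seq_len(n), function(i) seqs[i])
  merged <- vector("list", nrow(merge_order))
  fetch <- function(k) if (k < 0) nodes[[-k]] else merged[[k]]
  for (r in seq_len(nrow(merge_order))) {
    a <- fetch(merge_order[r, 1]); b <- fetch(merge_order[r, 2])
    map <- .profile_align(profile_of(a), profile_of(b), sub, 10, 1)
    expand <- function(rows, idx) {
      m <- seqs_to_matrix(rows)
      out <- matrix("-", nrow = nrow(m), ncol = ncol(map),
                    dimnames = list(rownames(m), NULL))
      out[, idx > 0] <- m[, idx[idx > 0], drop = FALSE]
      matrix_to_seqs(out)
    }
    merged[[r]] <- c(expand(a, map[1, ]), expand(b, map[2, ]))
  }
  out <- merged[[nrow(merge_order)]]
  gene_alignment(gene_id, out[names(seqs)])
}

#' Remove gap-rich alignment columns
#'
#' A plain threshold rule standing in for slope-based trimming tools:
#' columns whose gap fraction exceeds `max_gap_frac` are removed.  Species
#' whose every residue is trimmed away are flagged in the
#' `"fully_trimmed"` attribute (they drive the fully-trimmed gene
#' exclusion, see [drop_fully_trimmed()]).
#'
#' @param alignment A `gene_alignment`.
#' @param max_gap_frac Maximum tolerated per-column gap fraction in
#'   `(0, 1]` (default 0.5).
#' @return The trimmed `gene_alignment` (possibly of length 0, flagged with
#'   attribute `"empty"`), with attribute `"fully_trimmed"` listing species
#'   rows left without residues.
#' @export
trim_gappy <- function(alignment, max_gap_frac = 0.5) {
  stopifnot(inherits(alignment, "gene_alignment"),
            max_gap_frac > 0, max_gap_frac <= 1)
  m <- seqs_to_matrix(alignment$seqs)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_frac
  if (!any(keep)) {
    out <- alignment
    out$seqs <- setNames(rep("", length(alignment$seqs)),
                         names(alignment$seqs))
    out$length <- 0L
    attr(out, "empty") <- TRUE
    attr(out, "fully_trimmed") <- names(alignment$seqs)
    return(out)
  }
  m2 <- m[, keep, drop = FALSE]
  out <- gene_alignment(alignment$gene_id, matrix_to_seqs(m2))
  ft <- rownames(m2)[rowSums(m2 != "-") == 0L]
  attr(out, "fully_trimmed") <- ft
  out
}

#' Concatenate gene alignments into a supermatrix
#'
#' Genes are concatenated in lexicographic `gene_id` order; a species of
#' the roster missing from a gene contributes an all-gap block; partition
#' ranges (1-based inclusive) are recorded per gene.
#'
#' @param alignments List of `gene_alignment`s with distinct gene ids.
#' @param roster Species ids forming the matrix rows (default: union of
#'   species seen, sorted).
#' @return A `supermatrix`.
#' @export
concatenate <- function(alignments, roster = NULL) {
  stopifnot(length(alignments) >= 1L)
  gids <- vapply(alignments, `[[`, "", "gene_id")
  if (anyDuplicated(gids)) stop("duplicate gene_id: ",
                                gids[duplicated(gids)][1])
  alignments <- alignments[order(gids)]
  gids <- sort(gids)
  if (is.null(roster))
    roster <- sort(unique(unlist(lapply(alignments,
                                        function(a) names(a$seqs)))))
  blocks <- lapply(alignments, function(a) {
    extra <- setdiff(names(a$seqs), roster)
    if (length(extra)) stop("alignment species outside roster: ",
                            paste(extra, collapse = ", "))
    row <- setNames(rep(strrep("-", a$length), length(roster)), roster)
    row[names(a$seqs)] <- a$seqs
    row
  })
  lens <- vapply(alignments, `[[`, 1L, "length")
  ends <- cumsum(lens)
  rows <- setNames(do.call(paste0, lapply(blocks, `[`, roster)), roster)
  supermatrix(rows,
              data.frame(gene_id = gids,
                         start = as.integer(ends - lens + 1L),
                         end = as.integer(ends)))
}

#' Extract one gene's alignment back out of a supermatrix
#'
#' @param matrix A `supermatrix`.
#' @param gene_id Partition to slice.
#' @return A `gene_alignment` over all matrix rows.
#' @export
slice_partition <- function(matrix, gene_id) {
  p <- matrix$partitions[matrix$partitions$gene_id == gene_id, , drop = FALSE]
  if (nrow(p) != 1L) stop("unknown gene_id: ", gene_id)
  gene_alignment(gene_id, substr(matrix$rows, p$start, p$end))
}

#' Supermatrix summary statistics
#'
#' Distinct alignment patterns (unique column state vectors, residues, gaps
#' and `X` all distinguished) and the percentage of gap plus undetermined
#' (`-`, `X`) characters.
#'
#' @param matrix A `supermatrix`.
#' @return List with `n_distinct_patterns`, `pct_gaps_undetermined`,
#'   `n_positions`, `n_genes`.
#' @export
matrix_stats <- function(matrix) {
  stopifnot(inherits(matrix, "supermatrix"), matrix$length > 0)
  m <- seqs_to_matrix(matrix$rows)
  patterns <- apply(m, 2L, paste0, collapse = "")
  list(n_distinct_patterns = length(unique(patterns)),
       pct_gaps_undetermined = 100 * mean(m == "-" | m == "X"),
       n_positions = matrix$length,
       n_genes = nrow(matrix$partitions))
}

#' Remove every column containing a gap or undetermined character
#'
#' Keeps only columns with zero `-` and zero `X` across all rows — the
#' construction of a 100%-complete matrix from a strict-complete gene set.
#' The retention report counts surviving columns per gene, the genes with
#' at least one surviving column, and formats the retained-gene percentage
#' to one decimal.
#'
#' @param matrix A `supermatrix`.
#' @return List with `matrix` (the gap-free `supermatrix`, partitions
#'   restricted to surviving genes) and `report` (`data.frame` per gene of
#'   retained column counts, plus attributes; see also
#'   [retention_percent()]).  Fields `n_genes_in`, `n_genes_retained`,
#'   `pct_genes_retained` summarise the gene-level retention.
#' @export
strip_gapped_columns <- function(matrix) {
  stopifnot(inherits(matrix, "supermatrix"))
  m <- seqs_to_matrix(matrix$rows)
  keep <- colSums(m == "-" | m == "X") == 0L
  p <- matrix$partitions
  gene_of_col <- rep(p$gene_id, p$end - p$start + 1L)
  retained <- vapply(p$gene_id,
                     function(g) sum(keep[gene_of_col == g]), integer(1))
  surv <- p$gene_id[retained > 0L]
  report <- data.frame(gene_id = p$gene_id, n_columns = p$end - p$start + 1L,
                       n_retained = retained)
  if (!any(keep)) stop("no gap-free columns; matrix would be empty")
  m2 <- m[, keep, drop = FALSE]
  lens <- retained[retained > 0L]
  ends <- cumsum(lens)
  out <- supermatrix(matrix_to_seqs(m2),
                     data.frame(gene_id = surv,
                                start = as.integer(ends - lens + 1L),
                                end = as.integer(ends)),
                     alphabet = matrix$alphabet)
  list(matrix = out, report = report,
       n_genes_in = nrow(p),
       n_genes_retained = length(surv),
       pct_genes_retained = retention_percent(nrow(p), length(surv)))
}

#' Format a gene-retention percentage
#'
#' @param n_in Genes going in.
#' @param n_out Genes retained.
#' @return String like `"32.1%"` (one decimal).
#' @export
retention_percent <- function(n_in, n_out) {
  stopifnot(n_in > 0, n_out >= 0, n_out <= n_in)
  sprintf("%.1f%%", 100 * n_out / n_in)
}
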