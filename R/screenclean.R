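# Protein-set preparation: six-frame ORF extraction, redundancy collapse,
# and the two-step best-hit contamination screen with a positive-control
# false-positive estimate.

#' Find open reading frames in a nucleotide sequence
#'
#' All six reading frames are scanned.  By default an ORF is anchored at a
#' start codon and runs to the next stop codon or the end of the frame
#' (`anchored = FALSE` instead accepts stop-free stretches from the frame
#' start, the other convention common in ORF predictors).  Codons containing
#' `N` translate to `X`.
#'
#' @param nt_sequence Nucleotide string over `A,C,G,T,N`.
#' @param min_aa Minimum peptide length to report (residues; default 70).
#' @param anchored If `TRUE` (default), require an initial methionine.
#' @return Character vector of peptides (no stop symbol), longest first,
#'   ties by frame order.  Empty vector when nothing reaches `min_aa`.
#' @export
find_orfs <- function(nt_sequence, min_aa = 70, anchored = TRUE) {
  nt <- toupper(nt_sequence)
  if (grepl("[^ACGTN]", nt))
    stop("non-nucleotide characters (other than N) in sequence")
  revcomp <- function(s) chartr("ACGTN", "TGCAN",
                                paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                      collapse = ""))
  code <- Biostrings::GENETIC_CODE
  translate_frame <- function(s, off) {
    s <- substr(s, off, nchar(s))
    n_codon <- nchar(s) %/% 3L
    if (n_codon == 0L) return("")
    codons <- substring(s, 3L * (seq_len(n_codon) - 1L) + 1L,
                        3L * seq_len(n_codon))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
  }
  peps <- character(0)
  for (strand in c(nt, revcomp(nt))) for (off in 1:3) {
    segs <- strsplit(translate_frame(strand, off), "*", fixed = TRUE)[[1]]
    for (seg in segs) {
      if (anchored) {
        m <- regexpr("M", seg, fixed = TRUE)
        if (m < 0) next
        seg <- substr(seg, m, nchar(seg))
      }
      if (nchar(seg) >= min_aa) peps <- c(peps, seg)
    }
  }
  peps[order(-nchar(peps))]
}

# Global identity between two sequences: matches / alignment columns, gaps
# counted as mismatch (the redundancy-collapse metric).
global_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = phylopipe_submat(), gapOpening = 10, gapExtension = 1)
  Biostrings::nmatch(pa) / nchar(as.character(Biostrings::pattern(pa)))
}

# The fixed substitution table used by every in-repo aligner/scorer.
phylopipe_submat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Collapse redundant protein records at an identity cutoff
#'
#' Greedy longest-first clustering: records are visited in (length
#' descending, id ascending) order; a record joins the first representative
#' to which its global identity (matches / alignment columns, gaps counted
#' as mismatch) reaches `identity`, otherwise it founds a new cluster.
#' Representatives — the longest member of each cluster — are returned.
#' The visit order makes the result independent of input order, and the
#' procedure is idempotent.
#'
#' @param records A `protein_records` data frame.
#' @param identity Identity cutoff in `(0, 1]` (default 0.95).
#' @return The representative subset of `records`, in visit order.
#' @export
collapse_redundant <- function(records, identity = 0.95) {
  stopifnot(identity > 0, identity <= 1)
  if (nrow(records) == 0L) return(records)
  ids <- protein_ids(records)
  ord <- order(-nchar(records$sequence), ids)
  rec <- records[ord, , drop = FALSE]
  reps <- integer(0)
  rep_len <- integer(0)
  for (i in seq_len(nrow(rec))) {
    len_i <- nchar(rec$sequence[i])
    joined <- FALSE
    for (r in reps[len_i / rep_len >= identity]) {
      # identity <= min(len)/max(len), so shorter candidates cannot qualify
      if (global_identity(rec$sequence[i], rec$sequence[r]) >= identity) {
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, i)
      rep_len <- c(rep_len, len_i)
    }
  }
  out <- rec[reps, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' In-repo similarity search producing best-hit tables
#'
#' A desk-scale stand-in for a database search: candidate subjects sharing
#' at least one 4-mer with the query are ranked by shared 4-mer count, the
#' top `top_n` are aligned globally (affine gaps, fixed substitution table),
#' and alignment scores are reported.  `evalue_like = exp(-score / 100)` is
#' a monotone rank surrogate for an expectation value — cutoffs on it are
#' score-rank semantics, not database-size statistics.
#'
#' @param queries A `protein_records` data frame.
#' @param subjects A `protein_records` data frame of database sequences.
#' @param subject_class Named character vector mapping subject species ids to
#'   `"contaminant"`, `"reference"` or `"control"`.
#' @param k K-mer width of the prefilter (default 4).
#' @param top_n Subjects aligned per query (default 5).
#' @return `data.frame` with columns `query_id`, `subject_id`,
#'   `subject_taxon`, `subject_class`, `score`, `evalue_like`.
#' @export
search_hits <- function(queries, subjects, subject_class, k = 4, top_n = 5) {
  stopifnot(nrow(subjects) > 0,
            all(unique(subjects$species_id) %in% names(subject_class)),
            all(subject_class %in% c("contaminant", "reference", "control")))
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  }
  sub_ids <- protein_ids(subjects)
  sub_km <- lapply(subjects$sequence, kmers)
  # inverted index: k-mer -> subject row indices
  idx <- split(rep(seq_along(sub_km), lengths(sub_km)),
               unlist(sub_km, use.names = FALSE))
  q_ids <- protein_ids(queries)
  out <- vector("list", nrow(queries))
  submat <- phylopipe_submat()
  for (i in seq_len(nrow(queries))) {
    qk <- kmers(queries$sequence[i])
    shared <- table(unlist(idx[qk], use.names = FALSE))
    if (length(shared) == 0L) next
    cand <- as.integer(names(shared))
    ord <- order(-as.integer(shared), sub_ids[cand])
    cand <- cand[ord][seq_len(min(top_n, length(cand)))]
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(rep(queries$sequence[i], length(cand))),
      Biostrings::AAStringSet(subjects$sequence[cand]), type = "global",
      substitutionMatrix = submat, gapOpening = 10, gapExtension = 1,
      scoreOnly = TRUE)
    out[[i]] <- data.frame(query_id = q_ids[i], subject_id = sub_ids[cand],
                           subject_taxon = subjects$species_id[cand],
                           subject_class = unname(
                             subject_class[subjects$species_id[cand]]),
                           score = pa, evalue_like = exp(-pa / 100))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(query_id = character(0), subject_id = character(0),
                      subject_taxon = character(0), subject_class = character(0),
                      score = numeric(0), evalue_like = numeric(0))
  rownames(res) <- NULL
  res
}

#' Screen records by the best-hit taxonomy rule
#'
#' For each query, hits with `evalue_like <= evalue_cutoff` are considered.
#' A query with no qualifying hit is kept ("no evidence").  Otherwise the
#' query is discarded if and only if its strictly best-scoring hit is of
#' class `contaminant`; a score tie involving any non-contaminant subject
#' keeps the sequence (conservative, since the positive-control logic
#' penalises over-removal).
#'
#' @param records A `protein_records` data frame of queries.
#' @param hits Hit table as from [search_hits()] (or an ingested external
#'   tabular file with the same columns).
#' @param evalue_cutoff Non-negative cutoff on `evalue_like`.
#' @param control_species Species ids whose records form the positive
#'   control; the false-positive rate is the discarded fraction among them.
#' @return A `screen_report`: list with `kept` (ids), `discarded` (named
#'   character vector id -> reason, the best-hit taxon),
#'   `false_positive_rate` (`NA` if no control records).
#' @export
screen_best_hit <- function(records, hits, evalue_cutoff,
                            control_species = character(0)) {
  if (evalue_cutoff < 0) stop("evalue_cutoff must be non-negative")
  ids <- protein_ids(records)
  discarded <- character(0)
  h <- hits[hits$evalue_like <= evalue_cutoff & hits$query_id %in% ids, ,
            drop = FALSE]
  if (nrow(h) > 0) {
    for (q in unique(h$query_id)) {
      hq <- h[h$query_id == q, , drop = FALSE]
      best <- hq[hq$score == max(hq$score), , drop = FALSE]
      if (all(best$subject_class == "contaminant"))
        discarded[q] <- best$subject_taxon[1]
    }
  }
  kept <- setdiff(ids, names(discarded))
  is_control <- records$species_id %in% control_species
  fpr <- if (any(is_control))
    mean(ids[is_control] %in% names(discarded)) else NA_real_
  structure(list(kept = kept, discarded = discarded,
                 false_positive_rate = fpr),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> kept %d, discarded %d, control FPR %s\n",
              length(x$kept), length(x$discarded),
              ifelse(is.na(x$false_positive_rate), "NA",
                     sprintf("%.3f", x$false_positive_rate))))
  invisible(x)
}

#' Two-step contamination screen (nucleotide then protein)
#'
#' Step 1 removes transcripts whose best nucleotide-level hit is a
#' contaminant (at `nt_cutoff`); step 2 applies the protein-level best-hit
#' rule (at `prot_cutoff`) to peptides whose parent transcript survived.
#' Peptides are matched to parents by their `species|gene|isoform` id; a
#' peptide whose parent was removed is excluded with reason
#' `"parent_removed"`.  A peptide with no parent among `nt_records` passes
#' step 1 untouched (the transcript stage does not apply to it).
#'
#' @param nt_records Transcript-level `protein_records`-style table (ids
#'   shared with the peptides they encode).
#' @param prot_records Peptide `protein_records`.
#' @param nt_hits,prot_hits Hit tables for the two steps.
#' @param nt_cutoff,prot_cutoff Positive `evalue_like` cutoffs.
#' @param control_species Positive-control species ids (see
#'   [screen_best_hit()]).
#' @return A `screen_report` over `prot_records`, with per-step reasons
#'   (`"nt:<taxon>"`, `"parent_removed"`, `"prot:<taxon>"`) and the
#'   protein-level control false-positive rate.
#' @export
two_step_screen <- function(nt_records, prot_records, nt_hits, prot_hits,
                            nt_cutoff, prot_cutoff,
                            control_species = character(0)) {
  stopifnot(nt_cutoff > 0, prot_cutoff > 0)
  step1 <- screen_best_hit(nt_records, nt_hits, nt_cutoff)
  prot_ids <- protein_ids(prot_records)
  parent_gone <- prot_ids %in% names(step1$discarded)
  discarded <- setNames(rep("parent_removed", sum(parent_gone)),
                        prot_ids[parent_gone])
  survivors <- prot_records[!parent_gone, , drop = FALSE]
  step2 <- screen_best_hit(survivors, prot_hits, prot_cutoff)
  if (length(step2$discarded))
    discarded <- c(discarded, setNames(paste0("prot:", step2$discarded),
                                       names(step2$discarded)))
  kept <- setdiff(prot_ids, names(discarded))
  is_control <- prot_records$species_id %in% control_species
  fpr <- if (any(is_control))
    mean(prot_ids[is_control] %in% names(discarded)) else NA_real_
  structure(list(kept = kept, discarded = discarded,
                 false_positive_rate = fpr,
                 nt_report = step1),
            class = "screen_report")
}

#' Score a screen report against a synthetic truth table
#'
#' @param report A `screen_report`.
#' @param records The screened `protein_records` carrying `truth_label`.
#' @return List with `sensitivity` (contaminants removed / contaminants) and
#'   `specificity` (natives kept / natives); `NA` when a class is absent.
#' @export
screen_accuracy <- function(report, records) {
  ids <- protein_ids(records)
  removed <- ids %in% names(report$discarded)
  cont <- records$truth_label == "contaminant"
  nat <- records$truth_label == "native"
  list(sensitivity = if (any(cont)) mean(removed[cont]) else NA_real_,
       specificity = if (any(nat)) mean(!removed[nat]) else NA_real_)
}

#' Read an external tabular hit file
#'
#' Six tab-separated columns: query id, subject id, subject taxon, subject
#' class, score, evalue — the adapter for externally produced searches.
#'
#' @param path TSV file (no header).
#' @return Hit `data.frame` in the layout of [search_hits()].
#' @export
read_hits_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) != 6L) stop("hit table must have 6 columns")
  names(df) <- c("query_id", "subject_id", "subject_taxon", "subject_class",
                 "score", "evalue_like")
  df$score <- as.numeric(df$score)
  df$evalue_like <- as.numeric(df$evalue_like)
  if (!all(df$subject_class %in% c("contaminant", "reference", "control")))
    stop("subject_class must be contaminant/reference/control")
  df
}
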