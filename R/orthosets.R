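# Orthogroup construction and the marker-set selections built on it:
# reciprocal-best-hit orthogroups, strict completeness, isoform selection,
# BUSCO co-assignment, and the shared-orthogroup similarity matrix with
# species clustering.

#' Build orthogroups by reciprocal best hits
#'
#' For every ordered species pair, each protein's best-scoring hit in the
#' other proteome is found with the package's global-alignment scorer
#' ([search_hits()]); reciprocal best pairs form edges of a graph whose
#' connected components are the orthogroups.  Deterministic: score ties are
#' broken by subject id.
#'
#' @param records A `protein_records` data frame spanning >= 2 species
#'   (typically one protein per gene, after [pick_isoform()]).
#' @param top_n Candidate subjects aligned per query in the prefilter.
#' @param min_score_frac Hit-significance cutoff: a reciprocal pair is
#'   accepted only when its alignment score reaches this fraction of the
#'   smaller of the two self-alignment scores (default 0.05).  Plays the
#'   role of the E-value cutoff of database-search orthology pipelines:
#'   without it, a protein whose ortholog is missing from the partner
#'   proteome would pair with an arbitrary gene.
#' @return An `ortholog_table` whose roster is all species in `records`
#'   (species with an empty proteome draw a warning and get no assignments).
#' @export
build_orthogroups_rbh <- function(records, top_n = 10, min_score_frac = 0.05) {
  species <- sort(unique(records$species_id))
  if (length(species) < 2L) stop("need >= 2 species")
  empty <- species[!species %in% records$species_id[nzchar(records$sequence)]]
  if (length(empty))
    warning("species with empty proteome: ", paste(empty, collapse = ", "))
  ids <- protein_ids(records)
  submat <- phylopipe_submat()
  self_score <- vapply(records$sequence, function(s)
    sum(diag(submat)[match(strsplit(s, "", fixed = TRUE)[[1]],
                           rownames(submat))], na.rm = TRUE), 0)
  names(self_score) <- ids
  # best hit of every protein in every other species
  best <- list()   # query_id -> (target species -> subject_id)
  bscore <- list() # query_id -> (target species -> score)
  for (a in species) for (b in species) {
    if (a == b) next
    qa <- records[records$species_id == a, , drop = FALSE]
    sb <- records[records$species_id == b, , drop = FALSE]
    if (nrow(qa) == 0L || nrow(sb) == 0L) next
    hits <- search_hits(qa, sb, setNames("reference", b), top_n = top_n)
    if (nrow(hits) == 0L) next
    for (q in unique(hits$query_id)) {
      hq <- hits[hits$query_id == q, , drop = FALSE]
      hq <- hq[order(-hq$score, hq$subject_id), , drop = FALSE]
      best[[q]][[b]] <- hq$subject_id[1]
      bscore[[q]][[b]] <- hq$score[1]
    }
  }
  parent <- uf_new(length(ids))
  pos <- setNames(seq_along(ids), ids)
  for (q in names(best)) for (b in names(best[[q]])) {
    s <- best[[q]][[b]]
    qa <- records$species_id[pos[q]]
    if (identical(best[[s]][[qa]], q) &&
        bscore[[q]][[b]] >= min_score_frac * min(self_score[q], self_score[s]))
      parent <- uf_union(parent, pos[[q]], pos[[s]])
  }
  comp <- uf_components(parent)
  # name OGs by the smallest member id, then number in sorted order
  rep_id <- vapply(split(ids, comp), min, "")
  og_name <- setNames(sprintf("OG%06d", seq_along(sort(rep_id))), sort(rep_id))
  ortholog_table(data.frame(og_id = unname(og_name[rep_id[as.character(comp)]]),
                            species_id = records$species_id,
                            protein_id = ids),
                 roster = species)
}

#' Select orthogroups complete in every roster species
#'
#' The strict-completeness rule: an orthogroup qualifies only if every
#' species of the roster contributes at least one protein — no missing
#' genes allowed in any taxon.
#'
#' @param table An `ortholog_table`.
#' @param roster Species ids that must all be present (subset of the
#'   table's roster).
#' @return Sorted character vector of qualifying orthogroup ids.
#' @export
select_strict_complete <- function(table, roster = og_roster(table)) {
  if (length(roster) == 0L) stop("empty roster")
  if (!all(roster %in% og_roster(table)))
    stop("roster species missing from table roster")
  hit <- unique(table[table$species_id %in% roster, c("og_id", "species_id")])
  n_sp <- table(hit$og_id)
  sort(names(n_sp)[n_sp == length(roster)])
}

#' Pick one isoform per gene by read support
#'
#' The highest-read-support isoform is selected; ties go to the longest
#' sequence, remaining ties to the lexicographically smallest isoform id.
#'
#' @param records_for_gene `protein_records` rows of one gene in one
#'   species (>= 1 row).
#' @return The selected single row.
#' @export
pick_isoform <- function(records_for_gene) {
  stopifnot(nrow(records_for_gene) >= 1L)
  ord <- order(-records_for_gene$read_support,
               -nchar(records_for_gene$sequence),
               records_for_gene$isoform_id)
  records_for_gene[ord[1], , drop = FALSE]
}

#' Collapse a record table to one isoform per gene and species
#'
#' Applies [pick_isoform()] within every (species, gene) cell.
#'
#' @param records A `protein_records` data frame.
#' @return The reduced `protein_records`.
#' @export
select_isoforms <- function(records) {
  key <- paste(records$species_id, records$gene_id, sep = "\r")
  idx <- unlist(lapply(split(seq_len(nrow(records)), key), function(i) {
    i[order(-records$read_support[i], -nchar(records$sequence[i]),
            records$isoform_id[i])][1]
  }), use.names = FALSE)
  out <- records[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select orthogroups by BUSCO co-assignment
#'
#' Benchmark variant proteins (labelled groups of ancestral variants,
#' normally 10 per group) are assumed to have been clustered jointly with
#' the proteomes, so they appear in `table` like any other protein.  An
#' orthogroup is selected when (i) every roster species contributes at
#' least one protein and (ii) all members of some variant group are
#' assigned to it.  A variant group split across several orthogroups makes
#' condition (ii) unsatisfiable and is recorded as such.
#'
#' @param table An `ortholog_table` including the variant proteins.
#' @param busco_variants `data.frame` with columns `group_id`, `protein_id`
#'   listing each benchmark group's variant proteins.
#' @param roster Species that must all be present (variant pseudo-species
#'   excluded by simply not listing it).
#' @param group_size Expected variants per group (default 10).
#' @return List with `selected` (sorted og ids), `groups` (per variant
#'   group: `group_id`, `og_id` (`NA` if split or unassigned), `n_assigned`,
#'   `status` in full/deficient/split/unassigned), `per_og` (variant-protein
#'   count per orthogroup) and `summary` (counts; see [busco_summary()]).
#' @export
select_busco_ogs <- function(table, busco_variants, roster, group_size = 10) {
  stopifnot(all(c("group_id", "protein_id") %in% names(busco_variants)))
  og_of <- setNames(table$og_id, table$protein_id)
  grp <- split(busco_variants$protein_id, busco_variants$group_id)
  rows <- lapply(names(grp), function(g) {
    ogs <- unique(og_of[grp[[g]]])
    ogs <- ogs[!is.na(ogs)]
    if (length(ogs) == 0L)
      return(data.frame(group_id = g, og_id = NA_character_, n_assigned = 0L,
                        status = "unassigned"))
    if (length(ogs) > 1L)
      return(data.frame(group_id = g, og_id = NA_character_,
                        n_assigned = sum(!is.na(og_of[grp[[g]]])),
                        status = "split"))
    n <- sum(og_of[grp[[g]]] == ogs & !is.na(og_of[grp[[g]]]))
    data.frame(group_id = g, og_id = ogs, n_assigned = n,
               status = if (n >= length(grp[[g]]) && n >= group_size)
                 "full" else "deficient")
  })
  groups <- do.call(rbind, rows)
  complete <- select_strict_complete(table, roster)
  selected <- sort(unique(groups$og_id[groups$status == "full" &
                                         groups$og_id %in% complete]))
  variant_og <- og_of[busco_variants$protein_id]
  per_og <- table(variant_og[!is.na(variant_og)])
  per_og <- setNames(as.integer(per_og), names(per_og))
  list(selected = selected, groups = groups, per_og = per_og,
       summary = busco_summary(per_og, group_size,
                               total_variants = nrow(busco_variants)))
}

#' Summarise per-orthogroup benchmark-variant counts
#'
#' The bookkeeping behind a benchmark co-assignment run: how many
#' orthogroups received variant proteins, how many hold a full complement
#' (`group_size` variants), and how many are deficient.
#'
#' @param per_og Named or plain integer vector of variant-protein counts
#'   per orthogroup (only orthogroups with >= 1 variant).
#' @param group_size Full complement size (default 10).
#' @param total_variants Optional total number of variant proteins (defaults
#'   to `sum(per_og)`).
#' @return List with `n_ogs`, `n_full`, `n_deficient`, `n_over` and
#'   `total_variants`.
#' @export
busco_summary <- function(per_og, group_size = 10, total_variants = NULL) {
  per_og <- as.integer(per_og)
  list(n_ogs = length(per_og),
       n_full = sum(per_og == group_size),
       n_deficient = sum(per_og < group_size),
       n_over = sum(per_og > group_size),
       total_variants = total_variants %||% sum(per_og))
}

#' Shared-orthogroup count matrix over species pairs
#'
#' Entry (a, b) is the number of orthogroups containing both species; the
#' diagonal counts the orthogroups containing that species.
#'
#' @param table An `ortholog_table` spanning >= 2 species.
#' @return Symmetric integer matrix with the roster as dimnames.
#' @export
shared_og_matrix <- function(table) {
  roster <- og_roster(table)
  if (length(roster) < 2L) stop("need >= 2 species")
  hit <- unique(table[c("og_id", "species_id")])
  ogs <- sort(unique(hit$og_id))
  inc <- matrix(0L, nrow = length(ogs), ncol = length(roster),
                dimnames = list(ogs, roster))
  inc[cbind(match(hit$og_id, ogs), match(hit$species_id, roster))] <- 1L
  m <- crossprod(inc)
  storage.mode(m) <- "integer"
  m
}

#' Cluster species by shared-orthogroup profiles
#'
#' Distance between two species is `1 - r`, the Pearson correlation of
#' their rows of the shared-orthogroup matrix; agglomeration is complete
#' linkage.  A zero-variance profile row has undefined correlation; its
#' distances are set to 1 with a warning.
#'
#' @param matrix Output of [shared_og_matrix()].
#' @return The dendrogram as an unsupported `phylo` (cladogram).
#' @export
cluster_species <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2L,
            isTRUE(all.equal(matrix, t(matrix))))
  v <- apply(matrix, 1L, sd)
  r <- suppressWarnings(cor(t(matrix)))
  if (any(v == 0)) {
    warning("zero-variance shared-OG profile; distance set to 1 for: ",
            paste(rownames(matrix)[v == 0], collapse = ", "))
    r[v == 0, ] <- 0
    r[, v == 0] <- 0
  }
  d <- 1 - r
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "complete")
  ape::as.phylo(hc)
}
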