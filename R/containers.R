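# S3 containers shared by the pipeline stages.

#' Construct a table of protein records
#'
#' The central record type of the pipeline: one row per protein isoform,
#' carrying the species, gene and isoform identifiers, the residue sequence,
#' the RNA-seq read support of the isoform, and (for synthetic data) a truth
#' label used to score the contamination screen.
#'
#' @param species_id,gene_id,isoform_id Character vectors (recycled to a
#'   common length).
#' @param sequence Character vector of uppercase residue strings over the 20
#'   canonical amino acids plus `X` and `-`.
#' @param read_support Non-negative numeric vector; defaults to 0.
#' @param truth_label One of `"native"`, `"contaminant"`, `"unknown"` per
#'   record; defaults to `"unknown"`.
#' @return A `data.frame` of class `protein_records`.
#' @export
protein_records <- function(species_id, gene_id, isoform_id, sequence,
                            read_support = 0, truth_label = "unknown") {
  df <- data.frame(species_id = as.character(species_id),
                   gene_id = as.character(gene_id),
                   isoform_id = as.character(isoform_id),
                   sequence = toupper(as.character(sequence)),
                   read_support = as.numeric(read_support),
                   truth_label = as.character(truth_label),
                   stringsAsFactors = FALSE)
  validate_protein_records(df)
  class(df) <- c("protein_records", "data.frame")
  df
}

validate_protein_records <- function(df) {
  stopifnot(all(c("species_id", "gene_id", "isoform_id", "sequence",
                  "read_support", "truth_label") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!nzchar(df$sequence))) stop("empty sequence in protein records")
  if (any(df$read_support < 0)) stop("negative read_support")
  bad <- grepl(sprintf("[^%sX-]", paste(AA20, collapse = "")), df$sequence)
  if (any(bad))
    stop("non amino-acid characters in sequence(s): ",
         paste(head(protein_ids(df)[bad], 3), collapse = ", "))
  if (!all(df$truth_label %in% c("native", "contaminant", "unknown")))
    stop("truth_label must be native/contaminant/unknown")
  key <- paste(df$species_id, df$isoform_id)
  if (anyDuplicated(key))
    stop("duplicate (species, isoform) id: ", key[duplicated(key)][1])
  invisible(df)
}

#' Stable protein identifiers `species|gene|isoform`
#' @param records A `protein_records` data frame.
#' @return Character vector of ids, one per row.
#' @export
protein_ids <- function(records) {
  paste(records$species_id, records$gene_id, records$isoform_id, sep = "|")
}

#' Construct a single-gene alignment
#'
#' @param gene_id Gene identifier.
#' @param seqs Named character vector (names = species ids) of equal-length
#'   aligned residue strings (`-` for gaps).
#' @return An object of class `gene_alignment` with fields `gene_id`, `seqs`
#'   and `length`.
#' @export
gene_alignment <- function(gene_id, seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("duplicate species ids in alignment")
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("aligned rows differ in length")
  if (len < 1L) stop("alignment length must be >= 1")
  structure(list(gene_id = as.character(gene_id), seqs = toupper(seqs),
                 length = as.integer(len)),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s: %d sequences x %d columns\n",
              x$gene_id, length(x$seqs), x$length))
  invisible(x)
}

#' Construct a concatenated supermatrix
#'
#' @param rows Named character vector (names = species) of equal-length
#'   residue strings.
#' @param partitions `data.frame` with columns `gene_id`, `start`, `end`
#'   (1-based inclusive column ranges, in concatenation order) tiling
#'   `[1, nchar(rows[1])]` without gaps or overlap.
#' @param alphabet Free-text note on the state alphabet (`"AA"` or a
#'   recoding scheme name).
#' @return An object of class `supermatrix`.
#' @export
supermatrix <- function(rows, partitions, alphabet = "AA") {
  stopifnot(is.character(rows), length(rows) >= 1L, !is.null(names(rows)))
  len <- unique(nchar(rows))
  if (length(len) != 1L) stop("supermatrix rows differ in length")
  partitions <- as.data.frame(partitions)
  stopifnot(all(c("gene_id", "start", "end") %in% names(partitions)))
  p <- partitions[order(partitions$start), , drop = FALSE]
  if (anyDuplicated(p$gene_id)) stop("duplicate gene_id in partitions")
  if (nrow(p) > 0) {
    if (p$start[1] != 1L || p$end[nrow(p)] != len ||
        (nrow(p) > 1 && any(p$start[-1] != p$end[-nrow(p)] + 1L)) ||
        any(p$end < p$start))
      stop("partitions must tile [1, ", len, "] exactly")
  } else if (len != 0L) stop("non-empty matrix requires partitions")
  structure(list(rows = rows, partitions = partitions,
                 alphabet = alphabet, length = as.integer(len)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d gene partitions [%s]\n",
              length(x$rows), x$length, nrow(x$partitions), x$alphabet))
  invisible(x)
}

#' Construct an orthogroup table
#'
#' Long-format orthogroup membership: one row per (orthogroup, species,
#' protein) assignment, with the full species roster kept as an attribute so
#' species with no assignments are not silently dropped.
#'
#' @param assignments `data.frame` with columns `og_id`, `species_id`,
#'   `protein_id`.
#' @param roster Character vector of all species ids in the dataset; defaults
#'   to the species present in `assignments`.
#' @return A `data.frame` of class `ortholog_table` with attribute `roster`.
#' @export
ortholog_table <- function(assignments, roster = NULL) {
  df <- as.data.frame(assignments)
  stopifnot(all(c("og_id", "species_id", "protein_id") %in% names(df)))
  df <- df[c("og_id", "species_id", "protein_id")]
  df[] <- lapply(df, as.character)
  if (is.null(roster)) roster <- sort(unique(df$species_id))
  extra <- setdiff(df$species_id, roster)
  if (length(extra))
    stop("assignments mention species outside the roster: ",
         paste(head(extra, 3), collapse = ", "))
  attr(df, "roster") <- roster
  class(df) <- c("ortholog_table", "data.frame")
  df
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat(sprintf("<ortholog_table> %d orthogroups, %d proteins, %d species\n",
              length(unique(x$og_id)), nrow(x), length(attr(x, "roster"))))
  invisible(x)
}

og_roster <- function(table) attr(table, "roster")
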