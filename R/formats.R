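# External representations: FASTA (with the record-metadata header dialect),
# Newick with support labels, relaxed PHYLIP, partition files, and the
# orthogroup TSV dialect of standard orthology-inference output.

#' Read protein records from FASTA
#'
#' Headers follow the dialect `>species|gene|isoform rs=<number> src=<label>`,
#' so that read support and (for synthetic data) contamination truth labels
#' travel with the sequences.  `rs=`/`src=` are optional; a missing or
#' unparseable `rs=` defaults to 0 with a warning, a missing `src=` to
#' `"unknown"`.
#'
#' @param path FASTA file.
#' @return A `protein_records` data frame, in file order.  An empty file
#'   yields zero rows.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L)
    return(protein_records(character(0), character(0), character(0),
                           character(0), numeric(0), character(0)))
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  name <- sub("\\s.*$", "", headers)
  parts <- strsplit(name, "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("FASTA header not in species|gene|isoform form: ",
         headers[lengths(parts) != 3L][1])
  attr_str <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  rs <- rep(NA_real_, length(headers))
  m <- regmatches(attr_str, regexpr("(?<=\\brs=)\\S+", attr_str, perl = TRUE))
  rs[grepl("\\brs=", attr_str)] <- suppressWarnings(as.numeric(m))
  if (anyNA(rs)) {
    bad <- is.na(rs) & grepl("\\brs=", attr_str)
    if (any(bad))
      warning("unparseable rs= in ", sum(bad), " header(s); read_support set to 0")
    rs[is.na(rs)] <- 0
  }
  src <- rep("unknown", length(headers))
  has_src <- grepl("\\bsrc=", attr_str)
  src[has_src] <- regmatches(attr_str,
                             regexpr("(?<=\\bsrc=)\\S+", attr_str, perl = TRUE))
  protein_records(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L),
                  vapply(parts, `[`, "", 3L), as.character(set), rs, src)
}

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()]: emits the `species|gene|isoform rs= src=`
#' header dialect.  `read_fasta(write_fasta(x))` is the identity on record
#' tables.
#'
#' @param records A `protein_records` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  validate_protein_records(records)
  headers <- sprintf("%s rs=%s src=%s", protein_ids(records),
                     format(records$read_support, trim = TRUE, scientific = FALSE),
                     records$truth_label)
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a support-annotated Newick tree
#'
#' Bootstrap-style supports are expected as bare integer internal-node
#' labels (the convention consumed by tree editors that contract branches
#' by support).  Missing branch lengths default to 0.
#'
#' @param path Newick file (first tree used).
#' @return An `ape::phylo`; internal supports, when present, are in
#'   `$node.label`.
#' @export
read_newick <- function(path) {
  stopifnot(file.exists(path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_balanced_newick(txt)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in ", path)
  tr
}

# Parenthesis balance pre-check so parse errors carry a character offset.
check_balanced_newick <- function(txt) {
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' in Newick at character ", i)
    }
  }
  if (depth != 0L)
    stop("unbalanced '(' in Newick: ", depth,
         " unclosed at character ", length(chars))
  invisible(TRUE)
}

#' Write a tree to Newick
#'
#' @param tree An `ape::phylo`; `$node.label` (if any) is written as internal
#'   node labels so supports round-trip exactly.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a supermatrix as relaxed PHYLIP
#'
#' Relaxed PHYLIP: a `ntaxa nchar` header, then one `name<space>sequence`
#' line per taxon.  Taxon names must be whitespace-free.
#'
#' @param matrix A `supermatrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phylip_relaxed <- function(matrix, path) {
  stopifnot(inherits(matrix, "supermatrix"))
  nm <- names(matrix$rows)
  if (any(grepl("\\s", nm)))
    stop("species names must not contain whitespace: ",
         nm[grepl("\\s", nm)][1])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(matrix$rows), matrix$length), con)
  writeLines(paste(nm, matrix$rows), con)
  invisible(path)
}

#' Read a relaxed PHYLIP matrix
#'
#' @param path PHYLIP file written by [write_phylip_relaxed()] (sequential,
#'   one line per taxon).
#' @param partitions Optional partition table to attach (defaults to a single
#'   partition named `"all"` spanning the matrix).
#' @return A `supermatrix`.
#' @export
read_phylip_relaxed <- function(path, partitions = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr)) stop("bad PHYLIP header: ", lines[1])
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body) != hdr[1]) stop("expected ", hdr[1], " sequence lines")
  parts <- strsplit(trimws(body), "\\s+")
  rows <- setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
  if (any(nchar(rows) != hdr[2])) stop("sequence length disagrees with header")
  if (is.null(partitions))
    partitions <- data.frame(gene_id = "all", start = 1L, end = hdr[2])
  supermatrix(rows, partitions)
}

#' Write a RAxML-style partition file
#'
#' One line per gene, `MODEL, gene = start-end` with 1-based inclusive column
#' ranges in concatenation order; the ranges tile the matrix exactly.
#'
#' @param matrix A `supermatrix`.
#' @param path Output file.
#' @param model Model tag to prefix each line with (cosmetic).
#' @return `path`, invisibly.
#' @export
write_partitions <- function(matrix, path, model = "LG") {
  stopifnot(inherits(matrix, "supermatrix"), nrow(matrix$partitions) > 0)
  p <- matrix$partitions
  writeLines(sprintf("%s, %s = %d-%d", model, p$gene_id, p$start, p$end), path)
  invisible(path)
}

#' Read a RAxML-style partition file
#'
#' @param path Partition file from [write_partitions()].
#' @return `data.frame` with columns `gene_id`, `start`, `end`.
#' @export
read_partitions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^\\s*\\S+,\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)\\s*$",
                                 lines))
  if (any(lengths(m) != 4L)) stop("unparseable partition line: ",
                                  lines[lengths(m) != 4L][1])
  data.frame(gene_id = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)))
}

#' Read an orthogroup table TSV
#'
#' The dialect of standard orthogroup-inference output: first column the
#' orthogroup id, one column per species, cells holding comma-separated
#' protein ids (empty = species absent from that group).
#'
#' @param path TSV file with a header row naming the species columns.
#' @return An `ortholog_table`.
#' @export
read_orthogroup_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("orthogroup TSV needs an OG column plus species columns")
  species <- names(df)[-1]
  out <- list()
  for (s in species) {
    cells <- df[[s]]
    has <- nzchar(cells)
    if (!any(has)) next
    ids <- strsplit(cells[has], ",", fixed = TRUE)
    ids <- lapply(ids, trimws)
    out[[s]] <- data.frame(og_id = rep(df[[1]][has], lengths(ids)),
                           species_id = s,
                           protein_id = unlist(ids, use.names = FALSE))
  }
  ortholog_table(do.call(rbind, c(out, list(make.row.names = FALSE))) %||%
                   data.frame(og_id = character(0), species_id = character(0),
                              protein_id = character(0)),
                 roster = species)
}

#' Write an orthogroup table TSV
#'
#' @param table An `ortholog_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_orthogroup_tsv <- function(table, path) {
  stopifnot(inherits(table, "ortholog_table"))
  roster <- og_roster(table)
  ogs <- sort(unique(table$og_id))
  cells <- matrix("", nrow = length(ogs), ncol = length(roster),
                  dimnames = list(ogs, roster))
  key <- split(table$protein_id, list(table$og_id, table$species_id),
               drop = TRUE, sep = "\r")
  for (k in names(key)) {
    os <- strsplit(k, "\r", fixed = TRUE)[[1]]
    cells[os[1], os[2]] <- paste(sort(key[[k]]), collapse = ",")
  }
  df <- data.frame(Orthogroup = ogs, cells, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
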