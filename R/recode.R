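# Amino-acid recoding into reduced exchange-group alphabets.

# The three binning schemes, as ordered residue groups.  The first residue
# of each group is its representative output symbol.
RECODING_SCHEMES <- list(
  dayhoff6 = list(c("D", "E", "N", "Q"), c("I", "L", "M", "V"),
                  c("F", "Y", "W"), c("A", "S", "T", "G", "P"),
                  c("H", "K", "R"), "C"),
  dayhoff9 = list(c("D", "E", "H", "N", "Q"), c("I", "L", "M", "V"),
                  c("F", "Y"), c("A", "S", "T"), c("K", "R"),
                  "G", "P", "C", "W"),
  dayhoff15 = list(c("D", "E", "Q"), c("M", "L"), c("I", "V"), c("F", "Y"),
                   "G", "A", "P", "S", "T", "N", "K", "H", "R", "C", "W")
)

#' Retrieve a recoding scheme
#'
#' Available schemes: `dayhoff6` (the classical six exchange groups),
#' `dayhoff9` and `dayhoff15` (9- and 15-state refinements derived from the
#' PAM250 transition matrix).  Each is validated on load: the groups must
#' partition the 20 canonical residues exactly.
#'
#' @param name `"dayhoff6"`, `"dayhoff9"` or `"dayhoff15"`.
#' @return List with `name`, `groups` (ordered residue groups),
#'   `representatives` (first residue of each group) and `n_states`.
#' @export
recoding_scheme <- function(name = c("dayhoff6", "dayhoff9", "dayhoff15")) {
  name <- match.arg(name)
  groups <- RECODING_SCHEMES[[name]]
  all_res <- unlist(groups)
  if (anyDuplicated(all_res) || !setequal(all_res, AA20))
    stop("scheme does not partition the 20 canonical residues")  # nocov
  list(name = name, groups = groups,
       representatives = vapply(groups, `[`, "", 1L),
       n_states = length(groups))
}

# residue -> output symbol lookup, including missing-data handling
scheme_map <- function(scheme, digits = FALSE) {
  reps <- if (digits) as.character(seq_along(scheme$groups) - 1L)
          else scheme$representatives
  map <- c(setNames(rep(reps, lengths(scheme$groups)), unlist(scheme$groups)),
           "-" = "-", "X" = "?", "B" = "?", "Z" = "?", "?" = "?")
  map
}

#' Recode one residue string
#'
#' Each canonical residue maps to its group's representative (the first
#' residue listed), so the output remains a valid residue alphabet for
#' downstream tools; `digits = TRUE` instead emits 0-based state digits.
#' Gaps are preserved; `X`, `B`, `Z` and `?` become `?` (ambiguity codes
#' are treated as missing rather than resolved).  Length is preserved.
#'
#' @param seq Residue string over the 20 canonical amino acids plus
#'   `X, B, Z, -, ?`.
#' @param scheme A scheme from [recoding_scheme()] (or its name).
#' @param digits Emit digit states instead of representative residues.
#' @return The recoded string.
#' @export
recode_sequence <- function(seq, scheme, digits = FALSE) {
  if (is.character(scheme)) scheme <- recoding_scheme(scheme)
  map <- scheme_map(scheme, digits)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  out <- map[chars]
  if (anyNA(out))
    stop("unknown character '", chars[is.na(out)][1], "' at position ",
         which(is.na(out))[1])
  paste0(out, collapse = "")
}

#' Recode a supermatrix
#'
#' Row-wise [recode_sequence()]; partitions are unchanged and the alphabet
#' note is updated to the scheme name.
#'
#' @param matrix An amino-acid `supermatrix`.
#' @param scheme Scheme object or name (see [recoding_scheme()]).
#' @param digits Emit digit states (see [recode_sequence()]).
#' @return The recoded `supermatrix`.
#' @export
recode_matrix <- function(matrix, scheme, digits = FALSE) {
  stopifnot(inherits(matrix, "supermatrix"))
  if (is.character(scheme)) scheme <- recoding_scheme(scheme)
  rows <- vapply(matrix$rows, recode_sequence, "", scheme = scheme,
                 digits = digits)
  out <- matrix
  out$rows <- setNames(rows, names(matrix$rows))
  out$alphabet <- if (digits) paste0(scheme$name, "-digits") else scheme$name
  out
}
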