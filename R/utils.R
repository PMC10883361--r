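# Internal helpers shared across modules.

# Amino-acid alphabet used throughout (canonical 20, fixed order).
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Derive a stage- or gene-specific seed from a master seed
#'
#' A single pipeline seed is fanned out deterministically to independent
#' sub-seeds by a small polynomial string hash, so that any stage can be
#' rerun in isolation with the same stream it saw inside the full run.
#'
#' @param seed Master seed (integer).
#' @param tag Character label of the consumer (e.g. `"gene:g007"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483629  # largest prime < 2^31
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% m
  as.integer(h)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Split a character vector of equal-length strings into a character matrix
# (rows = sequences, columns = alignment positions).
seqs_to_matrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(character(0), 0, 0))
  n <- unique(nchar(seqs))
  if (length(n) != 1L) stop("sequences differ in length")
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), ncol = n, byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

matrix_to_seqs <- function(m) {
  if (nrow(m) == 0L) return(setNames(character(0), character(0)))
  setNames(apply(m, 1L, paste0, collapse = ""), rownames(m))
}

# Minimal union-find for connected components (RBH graphs are tiny).
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[ri] <- rj
  parent
}
uf_components <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
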