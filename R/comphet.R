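# Across-taxa compositional heterogeneity diagnostics: a chi-square-style
# per-taxon statistic, global diversity/heterogeneity summaries, and
# z-scores against a taxon-homogeneous simulated null.

# Character matrix from a supermatrix or plain matrix; missing states are
# '-', '?' and 'X'.
comphet_matrix <- function(matrix) {
  m <- if (inherits(matrix, "supermatrix")) seqs_to_matrix(matrix$rows)
       else as.matrix(matrix)
  if (nrow(m) < 2L || ncol(m) < 1L) stop("need >= 2 taxa and >= 1 column")
  m
}

is_missing_state <- function(m) m == "-" | m == "?" | m == "X"

# Per-taxon compositional statistic: sum over states of
# (f_taxon - f_global)^2 / f_global, on non-missing characters.
taxon_chisq <- function(counts, f_global) {
  f <- counts / sum(counts)
  sum((f - f_global)^2 / f_global)
}

#' Observed compositional heterogeneity statistics
#'
#' For each taxon, the squared deviation of its residue frequencies from
#' the global frequencies, `sum_s (f_taxon(s) - f_global(s))^2 / f_global(s)`,
#' computed over non-missing characters (`-`, `?`, `X` excluded).  Global
#' summaries: `div` (mean number of distinct non-missing states per
#' column), `max_het` (largest per-taxon statistic) and `mean_het` (mean of
#' the squared per-taxon statistics).
#'
#' @param matrix A `supermatrix` or character matrix (rows = taxa).
#' @return A `comphet_result`: list with `taxa` (`data.frame` of `taxon`,
#'   `observed`, `z` — `z` is `NA` until [null_zscores()] fills it) and
#'   `global` (`data.frame` of `stat`, `observed`, `z`).
#' @export
observed_stats <- function(matrix) {
  m <- comphet_matrix(matrix)
  miss <- is_missing_state(m)
  if (any(rowSums(!miss) == 0L))
    stop("taxon with zero non-missing characters: ",
         rownames(m)[rowSums(!miss) == 0L][1])
  states <- sort(unique(as.vector(m[!miss])))
  counts <- vapply(seq_len(nrow(m)), function(i)
    tabulate(match(m[i, !miss[i, ]], states), length(states)),
    integer(length(states)))
  counts <- t(matrix(counts, nrow = length(states)))
  rownames(counts) <- rownames(m)
  f_global <- colSums(counts) / sum(counts)
  obs <- apply(counts, 1L, taxon_chisq, f_global = f_global)
  div_cols <- colSums(!miss) > 0L
  div <- mean(apply(m[, div_cols, drop = FALSE], 2L, function(col)
    length(unique(col[!is_missing_state(col)]))))
  gl <- data.frame(stat = c("div", "max_het", "mean_het"),
                   observed = c(div, max(obs), mean(obs^2)),
                   z = NA_real_)
  structure(list(taxa = data.frame(taxon = rownames(m), observed = obs,
                                   z = NA_real_, row.names = NULL),
                 global = gl,
                 states = states, f_global = f_global, counts = counts,
                 missing_mask = miss, matrix_chars = m),
            class = "comphet_result")
}

#' @export
print.comphet_result <- function(x, ...) {
  cat(sprintf("<comphet_result> %d taxa, %d states; div %.3f, max_het %.4g\n",
              nrow(x$taxa), length(x$states),
              x$global$observed[x$global$stat == "div"],
              x$global$observed[x$global$stat == "max_het"]))
  invisible(x)
}

#' Z-scores against a taxon-homogeneous null
#'
#' The null preserves each taxon's non-missing character count (and, for
#' the diversity statistic, the missingness mask column by column) and
#' draws residues i.i.d. from the global frequencies, so missingness alone
#' cannot inflate a score.  Each statistic's z is
#' `(observed - null mean) / null sd`; a zero null variance yields `Inf`
#' with the matching sign.
#'
#' @param matrix A `supermatrix` or character matrix.
#' @param n_sims Number of null simulations (>= 100; default 500).
#' @param seed RNG seed (deterministic per seed).
#' @param global Also simulate the global statistics (`div` needs full
#'   matrix simulation and dominates the cost; set `FALSE` to z-score
#'   taxa only).
#' @return A `comphet_result` with `z` filled in (`taxa` gains `null_mean`
#'   and `null_sd` columns).
#' @export
null_zscores <- function(matrix, n_sims = 500, seed = 1, global = TRUE) {
  if (n_sims < 100) stop("n_sims must be >= 100")
  res <- observed_stats(matrix)
  f <- res$f_global
  live <- f > 0
  n_taxa <- nrow(res$taxa)
  with_seed(seed, {
    # per-taxon statistics from multinomial draws (taxa independent under
    # the null)
    null_stats <- matrix(NA_real_, nrow = n_taxa, ncol = n_sims)
    for (i in seq_len(n_taxa)) {
      n_i <- sum(res$counts[i, ])
      draws <- rmultinom(n_sims, n_i, f)
      null_stats[i, ] <- colSums((draws / n_i - f)^2 / f)
    }
    zs <- function(obs, sims) {
      mu <- mean(sims); s <- sd(sims)
      if (s == 0) return(sign(obs - mu) * Inf)
      (obs - mu) / s
    }
    res$taxa$null_mean <- rowMeans(null_stats)
    res$taxa$null_sd <- apply(null_stats, 1L, sd)
    res$taxa$z <- vapply(seq_len(n_taxa), function(i)
      zs(res$taxa$observed[i], null_stats[i, ]), 0)
    if (global) {
      gmax <- apply(null_stats, 2L, max)
      gmean <- colMeans(null_stats^2)
      # div needs the column structure: simulate matrices on the observed
      # missingness mask
      miss <- res$missing_mask
      div_cols <- colSums(!miss) > 0L
      n_free <- sum(!miss)
      gdiv <- vapply(seq_len(n_sims), function(s) {
        sim <- matrix("-", nrow(miss), ncol(miss))
        sim[!miss] <- sample(res$states[live], n_free, replace = TRUE,
                             prob = f[live])
        mean(apply(sim[, div_cols, drop = FALSE], 2L, function(col)
          length(unique(col[col != "-"]))))
      }, 0)
      obs_g <- res$global$observed
      res$global$null_mean <- c(mean(gdiv), mean(gmax), mean(gmean))
      res$global$null_sd <- c(sd(gdiv), sd(gmax), sd(gmean))
      res$global$z <- c(zs(obs_g[1], gdiv), zs(obs_g[2], gmax),
                        zs(obs_g[3], gmean))
    }
  })
  res
}

#' Rank and classify taxa by compositional z-score
#'
#' @param result A `comphet_result` with z-scores (see [null_zscores()]).
#' @param cutoffs Named numeric vector `c(high = ..., extreme = ...)`;
#'   a taxon is `extreme` at `z >= extreme`, `high` at `z >= high`,
#'   otherwise `low`.
#' @return `data.frame` of `taxon`, `z`, `class`, ordered by z descending.
#' @export
rank_taxa <- function(result, cutoffs = c(high = 2, extreme = 4)) {
  stopifnot(inherits(result, "comphet_result"),
            all(c("high", "extreme") %in% names(cutoffs)),
            cutoffs["high"] <= cutoffs["extreme"])
  if (all(is.na(result$taxa$z))) stop("z-scores not computed")
  df <- result$taxa[order(-result$taxa$z), c("taxon", "z")]
  df$class <- ifelse(df$z >= cutoffs["extreme"], "extreme",
                     ifelse(df$z >= cutoffs["high"], "high", "low"))
  rownames(df) <- NULL
  df
}

#' Write a compositional-heterogeneity results table
#'
#' @param ranked Output of [rank_taxa()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_comphet_tsv <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
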