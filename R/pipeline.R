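# End-to-end orchestration: simulate -> screen -> orthogroups -> matrices ->
# filters -> recode -> diagnostics -> coalescent tree, from one config, with
# a manifest recording every count and seed.

#' Pipeline configuration
#'
#' Collects the simulation settings, every stage toggle, and all the fixed
#' thresholds of the pipeline in one validated object.  The threshold
#' defaults are the pipeline's canonical constants: 70-residue minimum ORF
#' length, 95% redundancy collapse, fixed bootstrap cutoff 40 (rule AA),
#' branch contraction at support <= 10, 50% column gap tolerance.
#'
#' @param sim A [sim_config()] describing the synthetic dataset.
#' @param stages Character vector of enabled stages, a subset (in any
#'   order) of `screen`, `orthogroups`, `matrix`, `filters`, `recode`,
#'   `comphet`, `coalescent`.  Stages always execute in that fixed order.
#' @param orf_min_aa Minimum ORF length in residues (held for transcript
#'   ingestion; the synthetic flow starts from proteins).
#' @param redundancy Identity cutoff of the redundancy collapse.
#' @param evalue_cutoff `evalue_like` cutoff of the protein screen.
#' @param bs_fixed Fixed support threshold of filter rule AA.
#' @param contract_bs Support cutoff for branch contraction.
#' @param trim_gap_frac Column gap-fraction tolerance of trimming.
#' @param n_boot Bootstrap replicates per gene tree.
#' @param recode_scheme Recoding scheme name applied to the zero-gap
#'   matrix.
#' @param comphet_sims Null simulations for the heterogeneity z-scores.
#' @param comphet_cutoffs Named vector `c(high=, extreme=)` of z cutoffs.
#' @param control_species Species ids used as the screening positive
#'   control (defaults to the first simulated species).
#' @param out_dir Output directory, or `NULL` to keep results in memory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("screen", "orthogroups", "matrix",
                                       "filters", "recode", "comphet",
                                       "coalescent"),
                            orf_min_aa = 70, redundancy = 0.95,
                            evalue_cutoff = 1, bs_fixed = 40,
                            contract_bs = 10, trim_gap_frac = 0.5,
                            n_boot = 100, recode_scheme = "dayhoff6",
                            comphet_sims = 500,
                            comphet_cutoffs = c(high = 2, extreme = 4),
                            control_species = NULL, out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"),
            all(stages %in% c("screen", "orthogroups", "matrix", "filters",
                              "recode", "comphet", "coalescent")),
            orf_min_aa >= 1, redundancy > 0, redundancy <= 1,
            evalue_cutoff > 0, bs_fixed >= 0, bs_fixed <= 100,
            contract_bs >= 0, contract_bs <= 100,
            trim_gap_frac > 0, trim_gap_frac <= 1, n_boot >= 1,
            comphet_sims >= 100)
  recode_scheme <- match.arg(recode_scheme, names(RECODING_SCHEMES))
  structure(list(sim = sim, stages = stages, orf_min_aa = orf_min_aa,
                 redundancy = redundancy, evalue_cutoff = evalue_cutoff,
                 bs_fixed = bs_fixed, contract_bs = contract_bs,
                 trim_gap_frac = trim_gap_frac, n_boot = n_boot,
                 recode_scheme = recode_scheme,
                 comphet_sims = comphet_sims,
                 comphet_cutoffs = comphet_cutoffs,
                 control_species = control_species, out_dir = out_dir),
            class = "pipeline_config")
}

#' Screening database of a synthetic dataset
#'
#' Emulates a curated reference database: the native proteins of every
#' species other than the one being screened (class `reference`) plus the
#' contaminant source genes across all food-clade tips (class
#' `contaminant`).
#'
#' @param dataset Result of [assemble_dataset()].
#' @return List with `records` (`protein_records` of all subjects) and
#'   `class` (named species -> class vector for [search_hits()]).
#' @export
contaminant_reference_db <- function(dataset) {
  cal <- dataset$truth$contaminant_alignments
  crec <- NULL
  if (length(cal)) {
    crec <- do.call(rbind, lapply(cal, function(a)
      data.frame(species_id = names(a$seqs), gene_id = a$gene_id,
                 isoform_id = paste0(a$gene_id, ".ref"),
                 sequence = unname(a$seqs),
                 read_support = 0, truth_label = "unknown")))
  }
  native <- dataset$records[dataset$records$truth_label == "native", ,
                            drop = FALSE]
  native$truth_label <- "unknown"
  recs <- rbind(as.data.frame(native), crec)
  records <- protein_records(recs$species_id, recs$gene_id, recs$isoform_id,
                             recs$sequence, recs$read_support,
                             recs$truth_label)
  cls <- c(setNames(rep("reference", length(unique(native$species_id))),
                    unique(native$species_id)),
           if (!is.null(crec))
             setNames(rep("contaminant", length(unique(crec$species_id))),
                      unique(crec$species_id)))
  list(records = records, class = cls)
}

#' Screen a synthetic dataset species by species
#'
#' Runs [search_hits()] + [screen_best_hit()] for each species against the
#' dataset's reference database with that species' own proteins excluded
#' (self-hits would mask everything).
#'
#' @param dataset Result of [assemble_dataset()].
#' @param evalue_cutoff Cutoff on `evalue_like`.
#' @param control_species Species ids treated as the positive control (a
#'   stand-in for a clean genome-derived proteome; the control's own
#'   injected contaminants are therefore excluded from the false-positive
#'   denominator).
#' @return A `screen_report` over all records.
#' @export
screen_dataset <- function(dataset, evalue_cutoff = 1,
                           control_species = character(0)) {
  db <- contaminant_reference_db(dataset)
  records <- dataset$records
  kept <- character(0); discarded <- character(0)
  for (s in unique(records$species_id)) {
    queries <- records[records$species_id == s, , drop = FALSE]
    subjects <- db$records[db$records$species_id != s, , drop = FALSE]
    hits <- search_hits(queries, subjects, db$class)
    rep_s <- screen_best_hit(queries, hits, evalue_cutoff)
    kept <- c(kept, rep_s$kept)
    discarded <- c(discarded, rep_s$discarded)
  }
  ids <- protein_ids(records)
  # the positive control plays the part of a proteome known to be clean, so
  # in synthetic runs the control's injected contaminants are not part of it
  is_control <- records$species_id %in% control_species &
    records$truth_label != "contaminant"
  fpr <- if (any(is_control))
    mean(ids[is_control] %in% names(discarded)) else NA_real_
  structure(list(kept = kept, discarded = discarded,
                 false_positive_rate = fpr),
            class = "screen_report")
}

#' Run the full pipeline from one configuration
#'
#' Executes the enabled stages in fixed order on a freshly simulated
#' dataset and returns a manifest of per-stage inputs, outputs and counts
#' (the gene ledger), alongside every intermediate product.  A stage
#' failure aborts the run but the manifest accumulated so far is returned
#' in the error's `manifest` field (and written to `out_dir` when set).
#'
#' @param config A [pipeline_config()].
#' @return List with `manifest` (stage ledger; gene counts in/out at every
#'   filter), `dataset`, `screen`, `orthogroups`, `matrix` (the
#'   strict-complete supermatrix), `stats`, `gene_trees`, `marker_sets`,
#'   `gapless`, `recoded`, `comphet`, `coalescent` — entries `NULL` for
#'   disabled stages.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$sim$seed,
                   params = config[setdiff(names(config),
                                           c("sim", "out_dir"))],
                   stages = list())
  res <- list(manifest = NULL)
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  finish <- function() {
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
    }
    manifest
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(NULL)
    tryCatch(fn(), error = function(e) {
      m <- finish()
      stop(structure(class = c("pipeline_error", "error", "condition"),
                     list(message = paste0("stage '", stage, "' failed: ",
                                           conditionMessage(e)),
                          call = sys.call(-1), manifest = m)))
    })
  }

  # synth (always on: it provides the inputs)
  dataset <- assemble_dataset(config$sim)
  res$dataset <- dataset
  control <- config$control_species %||% sort(unique(dataset$records$species_id))[1]
  note("synth", n_species = config$sim$n_species,
       n_genes = config$sim$n_genes, n_records = nrow(dataset$records),
       n_contaminants = sum(dataset$records$truth_label == "contaminant"))
  records <- dataset$records

  res$screen <- run_stage("screen", function() {
    rep <- screen_dataset(dataset, config$evalue_cutoff, control)
    acc <- screen_accuracy(rep, dataset$records)
    note("screen", n_in = nrow(dataset$records), n_kept = length(rep$kept),
         n_discarded = length(rep$discarded),
         false_positive_rate = rep$false_positive_rate,
         sensitivity = acc$sensitivity, specificity = acc$specificity)
    rep
  })
  if (!is.null(res$screen))
    records <- records[protein_ids(records) %in% res$screen$kept, ,
                       drop = FALSE]

  selected <- select_isoforms(records)
  note("isoforms", n_in = nrow(records), n_out = nrow(selected))

  res$orthogroups <- run_stage("orthogroups", function() {
    tab <- build_orthogroups_rbh(selected)
    note("orthogroups", n_in = nrow(selected),
         n_ogs = length(unique(tab$og_id)),
         n_strict_complete = length(select_strict_complete(tab)))
    tab
  })

  strict <- NULL
  if (!is.null(res$orthogroups))
    strict <- select_strict_complete(res$orthogroups)

  res$matrix <- run_stage("matrix", function() {
    if (is.null(strict)) stop("matrix stage requires orthogroups")
    tab <- res$orthogroups
    alns <- lapply(strict, function(og) {
      pid <- tab$protein_id[tab$og_id == og]
      members <- selected[protein_ids(selected) %in% pid, , drop = FALSE]
      # one sequence per species: same preference order as isoform choice
      if (anyDuplicated(members$species_id)) {
        keep <- unlist(lapply(split(seq_len(nrow(members)),
                                    members$species_id), function(i)
          i[order(-members$read_support[i], -nchar(members$sequence[i]),
                  members$isoform_id[i])][1]))
        members <- members[sort(keep), , drop = FALSE]
      }
      trim_gappy(align_gene(members, gene_id = og), config$trim_gap_frac)
    })
    names(alns) <- strict
    alns <- Filter(function(a) a$length > 0L, alns)
    sm <- concatenate(unname(alns), roster = sort(unique(selected$species_id)))
    st <- matrix_stats(sm)
    note("matrix", n_ogs_in = length(strict), n_genes = st$n_genes,
         n_positions = st$n_positions,
         n_distinct_patterns = st$n_distinct_patterns,
         pct_gaps_undetermined = st$pct_gaps_undetermined)
    list(alignments = alns, supermatrix = sm, stats = st)
  })

  res$gene_trees <- run_stage("filters", function() {
    if (is.null(res$matrix)) stop("filters stage requires the matrix stage")
    alns <- res$matrix$alignments
    dropped <- drop_fully_trimmed(alns)
    surv <- alns[dropped$survivors]
    trees <- lapply(names(surv), function(g)
      bootstrap_supports(surv[[g]], config$n_boot,
                         derive_seed(config$sim$seed, paste0("boot:", g))))
    names(trees) <- names(surv)
    stats <- do.call(rbind, lapply(names(surv), function(g)
      as.data.frame(gene_stats(trees[[g]], surv[[g]]))))
    sets <- list(AA = select_markers(stats, "AA", config$bs_fixed),
                 AB = select_markers(stats, "AB"),
                 # the AC quartile fences need at least 4 genes
                 AC = if (nrow(stats) >= 4) select_markers(stats, "AC")
                      else list(ids = character(0), thresholds = NULL))
    note("filters", n_in = length(alns),
         n_fully_trimmed = length(dropped$flagged),
         n_trees = length(trees),
         n_AA = length(sets$AA$ids), n_AB = length(sets$AB$ids),
         n_AC = length(sets$AC$ids))
    list(trees = trees, stats = stats, marker_sets = sets,
         fully_trimmed = dropped$flagged)
  })
  res$marker_sets <- res$gene_trees$marker_sets

  res$gapless <- run_stage("matrix", function() {
    if (is.null(res$matrix)) return(NULL)
    sg <- strip_gapped_columns(res$matrix$supermatrix)
    note("gapless", n_genes_in = sg$n_genes_in,
         n_genes_retained = sg$n_genes_retained,
         pct_genes_retained = sg$pct_genes_retained,
         n_positions = sg$matrix$length)
    sg
  })

  res$recoded <- run_stage("recode", function() {
    if (is.null(res$gapless)) stop("recode stage requires the matrix stage")
    rc <- recode_matrix(res$gapless$matrix, config$recode_scheme)
    note("recode", scheme = config$recode_scheme,
         n_positions = rc$length,
         n_distinct_patterns = matrix_stats(rc)$n_distinct_patterns)
    rc
  })

  res$comphet <- run_stage("comphet", function() {
    if (is.null(res$matrix)) stop("comphet stage requires the matrix stage")
    ch <- null_zscores(res$matrix$supermatrix, config$comphet_sims,
                       derive_seed(config$sim$seed, "comphet"))
    ranked <- rank_taxa(ch, config$comphet_cutoffs)
    note("comphet", n_sims = config$comphet_sims,
         max_z = max(ranked$z), top_taxon = ranked$taxon[1])
    list(result = ch, ranked = ranked)
  })

  res$coalescent <- run_stage("coalescent", function() {
    if (is.null(res$gene_trees)) stop("coalescent stage requires filters")
    contracted <- lapply(res$gene_trees$trees, contract_low_support,
                         threshold = config$contract_bs)
    if (config$sim$n_species > 8) {
      note("coalescent", n_trees = length(contracted),
           species_tree = NA, note = "n_species beyond exhaustive search")
      return(list(contracted = contracted, species_tree = NULL))
    }
    qt <- quartet_species_tree(unname(contracted))
    note("coalescent", n_trees = length(contracted),
         quartet_score = qt$score,
         species_tree = ape::write.tree(qt$best))
    list(contracted = contracted, species_tree = qt)
  })

  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    write_dataset(dataset, file.path(od, "dataset"))
    if (!is.null(res$matrix)) {
      write_phylip_relaxed(res$matrix$supermatrix,
                           file.path(od, "supermatrix.phy"))
      write_partitions(res$matrix$supermatrix,
                       file.path(od, "partitions.txt"))
    }
    if (!is.null(res$orthogroups))
      write_orthogroup_tsv(res$orthogroups, file.path(od, "orthogroups.tsv"))
    if (!is.null(res$gene_trees)) {
      utils::write.table(res$gene_trees$stats,
                         file.path(od, "gene_stats.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      ape::write.tree(do.call(c, unname(res$gene_trees$trees)),
                      file.path(od, "gene_trees.nwk"))
    }
    if (!is.null(res$comphet))
      write_comphet_tsv(res$comphet$ranked, file.path(od, "comphet.tsv"))
  }
  res$manifest <- finish()
  res
}

#' Write a pipeline configuration as flat key=value text
#'
#' Scalar settings are written one per line (`key = value`); simulation
#' fields are prefixed `sim.`, composition-bias vectors are written as
#' `sim.bias.<species> = <20 comma-separated multipliers>`.
#' [read_pipeline_config()] restores an identical object (`out_dir` is
#' environment-specific and not serialised).
#'
#' @param config A [pipeline_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  kv <- c()
  add <- function(key, value) kv <<- c(kv, paste0(key, " = ", value))
  sim <- config$sim
  for (f in c("n_species", "n_genes", "seed", "missingness_rate",
              "contamination_rate", "isoforms_per_gene", "branch_scale",
              "gene_length"))
    add(paste0("sim.", f), format(sim[[f]], digits = 17))
  for (s in names(sim$composition_bias))
    add(paste0("sim.bias.", s),
        paste(format(sim$composition_bias[[s]], digits = 17),
              collapse = ","))
  add("stages", paste(config$stages, collapse = ","))
  for (f in c("orf_min_aa", "redundancy", "evalue_cutoff", "bs_fixed",
              "contract_bs", "trim_gap_frac", "n_boot", "comphet_sims"))
    add(f, format(config[[f]], digits = 17))
  add("recode_scheme", config$recode_scheme)
  add("comphet_cutoffs", paste0("high=", config$comphet_cutoffs[["high"]],
                                ",extreme=",
                                config$comphet_cutoffs[["extreme"]]))
  if (!is.null(config$control_species))
    add("control_species", paste(config$control_species, collapse = ","))
  writeLines(kv, path)
  invisible(path)
}

#' Read a pipeline configuration from flat key=value text
#'
#' @param path File written by [write_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  m <- regmatches(lines, regexec("^\\s*(\\S+)\\s*=\\s*(.*?)\\s*$", lines))
  if (any(lengths(m) != 3L))
    stop("unparseable config line: ", lines[lengths(m) != 3L][1])
  kv <- setNames(vapply(m, `[`, "", 3L), vapply(m, `[`, "", 2L))
  num <- function(k) as.numeric(kv[[k]])
  bias_keys <- grep("^sim\\.bias\\.", names(kv), value = TRUE)
  bias <- lapply(bias_keys, function(k)
    as.numeric(strsplit(kv[[k]], ",", fixed = TRUE)[[1]]))
  names(bias) <- sub("^sim\\.bias\\.", "", bias_keys)
  sim <- sim_config(n_species = num("sim.n_species"),
                    n_genes = num("sim.n_genes"), seed = num("sim.seed"),
                    missingness_rate = num("sim.missingness_rate"),
                    contamination_rate = num("sim.contamination_rate"),
                    isoforms_per_gene = num("sim.isoforms_per_gene"),
                    branch_scale = num("sim.branch_scale"),
                    gene_length = num("sim.gene_length"),
                    composition_bias = bias)
  cc <- strsplit(kv[["comphet_cutoffs"]], ",", fixed = TRUE)[[1]]
  cc <- setNames(as.numeric(sub("^.*=", "", cc)), sub("=.*$", "", cc))
  pipeline_config(sim = sim,
                  stages = strsplit(kv[["stages"]], ",", fixed = TRUE)[[1]],
                  orf_min_aa = num("orf_min_aa"),
                  redundancy = num("redundancy"),
                  evalue_cutoff = num("evalue_cutoff"),
                  bs_fixed = num("bs_fixed"),
                  contract_bs = num("contract_bs"),
                  trim_gap_frac = num("trim_gap_frac"),
                  n_boot = num("n_boot"),
                  recode_scheme = kv[["recode_scheme"]],
                  comphet_sims = num("comphet_sims"),
                  comphet_cutoffs = cc,
                  control_species = if ("control_species" %in% names(kv))
                    strsplit(kv[["control_species"]], ",", fixed = TRUE)[[1]])
  }
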