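---
title: "phylopipe: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phylopipe: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylopipe)
```

`phylopipe` packages the data-preparation side of a phylogenomic study —
from raw per-species protein sets to filtered, recoded, diagnosed
supermatrices and a coalescent-style species tree — together with a
synthetic-data generator that makes every stage testable at desk scale.
This vignette is the package's own account of the science: what each stage
assumes, which knobs matter, and where the simplifications lie.

## The pipeline and its assumptions

The pipeline mirrors the now-standard recipe for placing problematic taxa
with high-completeness datasets:

1. **Decontaminate** the protein sets (best-hit taxonomy screen, with a
   positive control estimating over-removal).
2. **Cluster** proteins into orthogroups and keep only groups present in
   *every* species (strict completeness) — the premise being that modern
   transcriptomes are complete enough that missing data need not be
   tolerated, and that gaps, not signal, drive much of the instability in
   the placement of gap-rich lineages.
3. **Align, trim, concatenate** into a partitioned supermatrix, and report
   the two matrix-level statistics that summarise its information content:
   the number of distinct alignment patterns and the percentage of gap and
   undetermined characters.
4. **Filter markers** by gene-tree statistics to raise the
   information-to-noise ratio, with increasingly strict rules (AA, AB, AC).
5. **Diagnose compositional heterogeneity** per taxon and optionally
   **recode** into Dayhoff-style reduced alphabets to suppress it.
6. **Summarise gene trees** into a species tree by quartet agreement after
   contracting unreliable branches.

The underlying assumptions are those of the field: orthology is inferable
from sequence similarity; single-copy markers dominate after strict
filtering; compositional deviation from a global equilibrium is a symptom
of model misfit rather than signal; and topological agreement across
quartets is a sensible summary of the coalescent signal in gene trees.

## Stage-by-stage notes, parameters and defaults

### ORF extraction (`find_orfs`)

All six frames are scanned; an ORF is start-codon-anchored by default
(`anchored = FALSE` accepts stop-free stretches from the frame start, the
other convention common among ORF predictors).  The default minimum length
is **70 residues** — the conventional lower cutoff for transcriptome-derived
peptides.  Codons containing `N` translate to `X`.

### Redundancy collapse (`collapse_redundant`)

Greedy longest-first clustering at a default identity of **0.95**
(matches / alignment columns, gaps counted as mismatches, via global
alignment).  Visiting records in (length descending, id ascending) order
makes the result order-independent and idempotent; representatives are the
longest cluster members.  A length-ratio prefilter skips pairs that could
not reach the cutoff.

### Contamination screen (`screen_best_hit`, `two_step_screen`)

The screening decision is the field's: *discard a peptide whose best hit is
a contaminant-class subject*.  Two numerical choices deserve note:

* **Ties keep the sequence.**  If a contaminant and a reference subject
  score equally, the peptide survives.  The positive-control logic
  penalises over-removal, so ambiguity is resolved conservatively.
* **`evalue_like` is a rank surrogate**, `exp(-score/100)`, monotone in the
  alignment score.  True expectation values are database-size statistics
  that an in-repo scorer cannot reproduce; cutoffs on `evalue_like` are
  documented as score-rank semantics.  The two-step default cutoffs are
  therefore configuration choices, not probabilities.

The in-repo search (`search_hits`) prefilters subjects by shared 4-mers and
aligns the top candidates globally with affine gaps over a fixed
substitution table (BLOSUM62 scores).  Externally produced tabular hit
files can be ingested instead (`read_hits_tsv`), preserving the module's
decision logic with real search engines.

The **positive control** plays the part of a clean, genome-derived proteome;
its discard fraction estimates the false-positive rate.  In synthetic runs
the control species' injected contaminants are excluded from that
denominator — they are not part of the (by assumption clean) control
proteome.

### Orthogroups (`build_orthogroups_rbh`)

Reciprocal best hits form a graph; connected components are orthogroups.
Two deliberate choices:

* **RBH components rather than MCL clustering**: deterministic and
  oracle-checkable at desk scale; external orthogroup TSVs remain
  ingestible for realism.
* **A hit-significance cutoff** (`min_score_frac = 0.05`): a reciprocal
  pair is accepted only if its score reaches 5% of the smaller self-score.
  Without it, a protein whose ortholog is absent from the partner proteome
  pairs with an arbitrary gene, and such spurious links chain unrelated
  orthogroups together.  The value sits in the wide empirical gap between
  non-ortholog best-hit scores (near or below zero) and genuine ortholog
  scores; it is the in-repo analogue of the E-value cutoff that real
  database searches apply.  Very divergent true orthologs could in
  principle fall under it — a knob to lower for deep datasets.

Isoform selection takes the highest read support, then the longest
sequence, then the smallest isoform id.  Within an orthogroup the pipeline
keeps one sequence per species by the same preference order.

### BUSCO-style marker selection (`select_busco_ogs`)

A benchmark group qualifies only when (i) every roster species contributes
a protein to its orthogroup and (ii) *all* of the group's variants (10 by
default) were co-assigned to that one orthogroup.  A variant group split
across orthogroups cannot satisfy (ii) and is recorded as `split` — the
treatment of split groups is this package's decision; counting them as
deficient would be the only other defensible rule.  The roster is an
explicit parameter (dropping a species to enlarge the eligible set is a
pipeline decision, not a hard-coded exclusion).

### Alignment, trimming, concatenation (`align_gene`, `trim_gappy`, `concatenate`)

The aligner is a deliberately simple progressive scheme: pairwise global
alignments give 1 − identity guide distances, UPGMA orders the merges, and
profiles are merged by an affine-gap Gotoh dynamic program (gap open 10,
extension 1, compiled in C++) over 21 states (20 residues + gap; gap
fractions score 0).  Ties in the DP prefer match, then gap-in-B, making the
output deterministic.

Trimming is a plain **gap-fraction threshold** (default 0.5): columns with
more than 50% gaps are dropped.  The slope-based heuristics of dedicated
trimming tools are *not* reproduced — a documented fidelity gap, acceptable
because trimming enters the analysis as a preprocessing black box.  A
species whose every residue is trimmed away is flagged; genes with such
rows are excluded from coalescent input (`drop_fully_trimmed`).

Concatenation orders genes lexicographically by id (determinism; nothing
in the science prefers an order), fills missing species×gene blocks with
`-`, and records 1-based inclusive partitions that provably tile the
matrix.  Internally, column indices are 0-based half-open only inside the
C++ kernel; everything user-facing is 1-based inclusive.

`matrix_stats` counts distinct column vectors with residues, gaps and `X`
all distinguished, and reports `-`/`X` jointly as "gaps and undetermined" —
`X` is grouped with gaps throughout, including the zero-gap rule.

### Gene-tree statistics and filters (`gene_stats`, `select_markers`)

Gene trees are NJ on identity distances with the 20-state Jukes–Cantor
correction `d = −(19/20)·log(1 − (20/19)p)`; p is capped at 0.94 to keep
distances finite (a pair sharing no sites gets the cap).  Negative NJ branch
lengths are clamped to zero and flagged.  Bootstrap supports are the
percentage of column-resampled replicates containing each internal
bipartition of the point tree.

Filters use **strict inequalities** (mirroring "above"/"below" wording) and
**type-7 (linear interpolation) quantiles** — the convention must be pinned
for the thresholds to be reproducible, and type 7 is R's default and the
common choice.  Thresholds are computed from whatever distribution is
passed in: whether the AB median comes from all genes or from the AA
survivors is a pipeline composition choice, deliberately left to the
caller (the package's `run_pipeline` computes each filter over the full
surviving gene set).

### Branch contraction and the quartet tree (`contract_low_support`, `quartet_species_tree`)

Internal branches with support ≤ 10 (default) collapse into polytomies;
their lengths are discarded; the operation is idempotent and never touches
leaves.  The species tree is then the unrooted topology maximising the
number of (gene tree, quartet) agreements, found by exhaustive enumeration
(refused above 8 taxa, where 10,395 topologies end the budget for
exhaustive search).  A quartet left unresolved by a polytomy votes for no
candidate.  Co-optimal topologies are all reported; `best` is the first in
the deterministic enumeration order.

### Recoding (`recode_sequence`, `recode_matrix`)

The three schemes are fixed tables validated at load (each partitions the
20 canonical residues exactly).  Output symbols are group representatives
(first residue listed), so recoded matrices remain valid residue data for
downstream tools; a digit alphabet is available by flag.  `B` and `Z` are
treated as missing (`?`) rather than resolved to D/E — the conservative
reading where the ambiguity codes' information content is below the
recoding's resolution anyway.

### Compositional heterogeneity (`observed_stats`, `null_zscores`)

The per-taxon statistic is the compositional chi-square form
`sum_s (f_taxon(s) − f_global(s))² / f_global(s)` over non-missing
characters.  Global summaries: mean distinct states per column (a
diversity analogue), the maximum per-taxon statistic, and the mean of the
squared per-taxon statistics.  These are *analogues* of the
posterior-predictive statistics reported by Bayesian packages — the
published values of those statistics are not reproduction targets, because
they depend on a fitted site-heterogeneous model this package deliberately
does not contain.  Convergence- and across-site-variance-style statistics
have no in-package analogue and are out of scope.

The null simulates residues i.i.d. from the global frequencies while
preserving each taxon's non-missing count (and, for the diversity
statistic, the missingness mask), so missingness alone cannot inflate a
z-score.  One calibration subtlety: the global frequencies are estimated
from the same data, which shrinks observed deviations relative to the
null's and biases z slightly negative, by roughly `19/(T·sqrt(38))` for T
taxa — noticeable below ~15 taxa, negligible at study scale.  The
calibration tests therefore use 25-taxon matrices.  Classification cutoffs
(`high`, `extreme`) are configuration, since any tiering of a continuous
z-score is a presentation choice.

## The synthetic generator: what it emulates, what it does not

`assemble_dataset` produces: a random binary unrooted species tree with
i.i.d. exponential branch lengths (mean `branch_scale`, default 0.15
substitutions/site — a mid-range divergence where gene trees are estimable
but not trivial); per-gene alignments evolved site-i.i.d. under an
F81-style model (replace with probability `1 − exp(−t)`, redraw from
equilibrium frequencies); per-species composition bias applied on terminal
branches (the mechanism behind across-taxa heterogeneity); gene×species
dropout; redundant isoforms (5–30% terminal truncation plus ≤2 point
substitutions — enough that the 95% collapse has real work); and
contaminants evolved on an independent tree at 3× branch scale, emulating
food-organism carry-over.  Everything derives deterministically from one
seed via a string-hash fan-out (`derive_seed`), so stages rerun in
isolation see identical streams.

Not emulated: indels (alignments are born ungapped; gaps enter only
through missingness and trimming), rate variation across sites, codon
structure, paralogy, incomplete lineage sorting, and assembly artifacts
beyond isoform redundancy.  Consequently, passing recovery tests shows the
*decision logic* is correct under the stated generative model — it does not
certify performance on real transcriptomes, where alignment error and ILS
add noise the generator does not produce.

## Problem sizes in the shipped tests

The test-suite sizes are chosen to exercise every code path while keeping
a full run around half a minute: recovery uses 6 taxa × 30 genes × 300
sites over 50 replicates (quartet tree) and 6 taxa × 30 genes at 20%
contamination (screen); calibration uses 25 taxa × 200 columns at 500 null
simulations over 50 replicates; oracle-equivalence suites run 200 random
small instances per operation.  The species-tree recovery rate hovers
around its 0.95 expectation and is seed-dependent: the failures are
replicates whose true internal branches are nearly zero, where the data
simply do not determine the topology.

## Known limitations

* The aligner, trimmer, NJ trees and quartet search are deliberate
  desk-scale stand-ins for MAFFT/TrimAL-class tools, ML gene trees and
  large-n coalescent summary methods; they share interfaces with the real
  artifacts (FASTA/Newick/PHYLIP/partition/orthogroup TSV), so swapping
  externally produced files in is supported where readers exist.
* ML/Bayesian tree inference and posterior-predictive simulation from
  fitted site-heterogeneous models are out of scope by design.
* The quartet species tree is exhaustive and thus limited to ≤ 8 taxa.
* `evalue_like` is not an expectation value; external hit tables should be
  filtered with their own tools' statistics before ingestion.
* The RBH significance cutoff (5% of self-score) may split extremely
  divergent orthologs; it is exposed as a parameter.
* The pipeline's command surface is the R API (`pipeline_config()` +
  `run_pipeline()`, config files via `write_pipeline_config()`); there is
  deliberately no shell wrapper, as the intended users drive analyses from
  R.

## A small end-to-end run

```{r, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(n_species = 6, n_genes = 12, seed = 42,
                   gene_length = 150, missingness_rate = 0.05,
                   contamination_rate = 0.1, isoforms_per_gene = 2),
  n_boot = 50, comphet_sims = 500)
res <- run_pipeline(cfg)
str(res$manifest$stages, max.level = 1)
```

The manifest's per-stage counts form a ledger (records in/out at every
filter) whose internal consistency is itself asserted by the test suite.
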