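---
title: "Methods: alignment filtration and gene tree curation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment filtration and gene tree curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phylofiltr)
```

# The problem this package models

Summary species-tree methods are statistically consistent under the
multispecies coalescent *given correct gene trees*. Short or
uninformative marker alignments violate that premise: their estimated
gene trees carry topological error (GTEE) that is indistinguishable,
from the species-tree method's point of view, from genuine coalescent
discordance (ILS). The curation strategy implemented here is to score
each marker alignment on simple statistics, sweep exclusion thresholds
over one statistic at a time, and measure whether discordance
dissipates (suggesting GTEE) or persists (suggesting biology) as the
noisier markers are removed.

# Quality-control operators and their defaults

All QC defaults live in `qc_config()` and are the screening rules of
the target-capture pipelines this package serves. They are
*procedural constants*, not tunables, and the comparison direction at
each boundary is deliberate:

| operator | rule | boundary behavior |
|---|---|---|
| `screen_reference_divergence` | drop rows with p-distance to the reference > 0.40 | exactly 0.40 is kept (strict >) |
| `qc_keep` | keep alignments with > 3 taxa and > 100 bp | 3 taxa or 100 bp fails (strict >) |
| `trim_external` | trim ends until ≥ 50% of rows carry an unambiguous base | exactly 50% stops trimming (inclusive ≥) |
| `mask_divergent_windows` | mask 100-bp windows > 40% divergent from the consensus | exactly 40% is not masked (strict >) |
| `select_reading_frame` | accept a frame only if > 90% of rows are stop-free | exactly 90% fails (strict >) |

`pdistance` is the shared divergence primitive: mismatches over
positions where *both* sequences have an unambiguous nucleotide
(`A/C/G/T`). Gaps, `N` and `?` are never compared, so the window and
reference screens measure divergence of the aligned sequence, not of
missingness. When no position is comparable the distance is undefined
(`NA`); the reference screen retains such rows but flags them
`no_overlap`, since "more than 40% divergent" cannot be asserted.

Numerical/tie-break choices that the rules above leave open:

* **Windows are non-overlapping**, left-anchored, `window_len` wide.
  A final partial window at least half a window wide is processed on
  its own; a shorter remainder is merged into the preceding window
  (so a 340-bp alignment has windows 1–100, 101–200, 201–340). This
  avoids double-masking and keeps the masked-cell count per offence
  equal to the window width.
* **Masking replaces the whole window with `N`**, including gap
  characters inside it. Both characters are missing data for every
  downstream statistic, and whole-window replacement is what makes
  the masking idempotent.
* **Consensus ties** (two bases with equal counts) resolve
  alphabetically — determinism over cleverness; ties are rare in real
  alignments.
* **Reading-frame ties** (equal row inclusion) resolve to the smaller
  offset. The stop-codon scan covers every fully unambiguous codon of
  the trimmed range; codons containing gaps or ambiguity are skipped
  rather than treated as evidence either way. The scan is
  forward-strand only: capture alignments are probe-oriented upstream
  of this step.
* The **reference row is removed** from the screened alignment: it is
  an assembly aid, not a sample, and keeping it would bias sampling
  and PIS statistics.

# Statistics and filtration

`count_pis` uses the standard parsimony-informativeness rule: a
column is informative when at least two distinct unambiguous states
each occur in at least two rows. Gap-containing columns stay in the
`prop_pis` denominator (the full alignment length), so a gappy
alignment is penalized, not excused.

`sampling_prop` divides by an explicit study roster
(`taxon_roster`), not by the union of observed taxa — "proportion of
samples" is meaningful only against the fixed study design.

`make_threshold_series` hard-codes the sweep series:

* summary-tree mode: sampling and proportion-PIS 0.05–1.00 in 0.05
  steps (20 values each; a zero threshold filters nothing and is
  excluded), PIS counts 10–100 by 10 then 200–700 by 100, lengths
  100–3,000 bp by 100 (30 values);
* concatenation mode: sampling and proportion-PIS 0.1–1.0 by 0.1,
  PIS counts {10, 30, 50, 70, 100, 200, 500, 700, 1000}, lengths
  {200, 500, 700, 1000, 1200, 1500, 1700, 2000, 2200, 2500}.

The PIS-count ranges yield 16 and 9 distinct values respectively;
they are reproduced literally rather than padded to a round count.
The filter comparator is ≥ (keep at or above), which makes threshold
0 the identity and survivor sets nested as thresholds rise — an
invariant the test suite checks on random tables.

# Supermatrix and jackknife

`concatenate_alignments` lays markers left to right, gap-fills
missing taxa with `-` (the common supermatrix convention; downstream
ML tools treat `-` and `N` alike), and emits codon-position partition
entries only for exon markers whose frame was verified by
`select_reading_frame` — codon offsets are meaningless without a
verified frame, so unverified exons fall back to per-marker
partitions with a warning. Partition schemes are validated on
construction: the expanded sites of all entries must tile the matrix
exactly once.

`gene_jackknife` draws markers sequentially without replacement per
replicate and stops at the first marker that carries the cumulative
length to ≥ `target_bp` (default 200,000 bp): replicates slightly
overshoot and are "nearly the same size". Minimality — removing the
last-selected marker drops the total below target — is a contract
checked by the tests. Replicate supermatrices are built on demand
(`materialize = TRUE`); the default returns compositions only, since
a thousand 200-kb matrices held simultaneously serve no purpose.

# Tree metrics

Gene trees are treated as **unrooted**; monophyly of a clade is
membership of the bipartition `members | rest` among the tree's
splits, evaluated on the taxa actually present. Trees with fewer than
two members or two non-members present are *not evaluable* and are
excluded from denominators — monophyly is undefined there, and
counting such trees as failures would conflate missingness with
discordance. The report carries `n_evaluable` so either denominator
can be reconstructed.

Support handling follows the IQ-Tree ultrafast-bootstrap convention:
an internal-node label that is a plain integer is bootstrap support
in [0, 100]; anything else (e.g. an SH-aLRT fraction `0.95`) is
preserved but ignored by support-aware operations. Unlabeled edges
are support-*unknown*: `collapse_low_support` never contracts them
(absence of evidence is not low support) and `clade_support` never
counts them as strong. Collapsing contracts edges with support
strictly below the threshold (default 10), discards their lengths,
and is idempotent.

A caveat inherited from Newick semantics: a binary-*rooted* input
tree places the same unrooted split on two root-adjacent edges. On
unrooting, the label nearer the root is dropped. IQ-Tree emits
unrooted (trifurcating-root) trees, where every internal edge has
exactly one label, so this is only reachable with hand-made inputs.

`gene_concordance` implements gCF with the ≥2/≥2 decisiveness rule: a
gene tree counts for a species-tree branch `P|Q` only when it has at
least two leaves from each side; it is concordant when, restricted to
the shared leaves, one of its splits induces `P|Q`. gCF is reported
as a percentage, `NA` when no tree is decisive. Site concordance
factors are out of scope (they require site resampling inside the
likelihood software).

`ols_support_regression` is plain OLS (`stats::lm`) with the
two-sided t-test on the slope, for regressing clade monophyly or
strong-support proportions on parent branch lengths.

# Downstream configuration files

`write_bpp` emits the A01 ("species tree estimation") configuration:
`speciestree = 1`, `speciesdelimitation = 0`, `burnin = 10000`,
`sampfreq = 2`, `nsample = 100000`, `nloci` = number of serialized
alignments, and `gamma(3, 0.004)` priors on both theta and tau. Keys
the run design does not pin down (`cleandata`, `finetune`, `print`,
`seed`) are written explicitly with the BPP-documented defaults so
the generated file is auditable rather than implicit. Each sample is
its own population by default (`Imap` identity), with labels in the
`name^individual` convention. The starting species tree is a ladder
over the populations unless a guide tree is supplied — A01 resamples
the topology, so the start matters only for mixing.

`write_svdq_nexus` writes the DATA block, charsets from the partition
scheme, and a PAUP block with `evalq=all` and
`bootstrap=multilocus nreps=1000`. `prepare_astral_input` collapses
branches below 10% support and writes one Newick per line.

All writers are deterministic (fixed ordering, no timestamps);
byte-identity under repeated calls is tested.

# The synthetic generator: what it emulates and what it does not

`generate_study` produces the world the filtration experiment
assumes:

* **Marker lengths** are log-uniform on [100, 5000] bp — a
  right-skewed distribution with a median of a few hundred bp,
  matching the regime of capture data sets where most markers are
  short and a tail is long.
* **Gene tree error** is phenomenological: each gene tree is the
  species tree after `K ~ Poisson(c · ref_len / length)` random NNI
  moves (`ref_len` 1000 bp). This plants exactly the GTEE-versus-
  length relationship the filtration argument needs, with `c` as the
  single error dial, and keeps the experiment seconds-scale. It does
  *not* emulate the estimation process itself — no branch-length
  error, no support-value noise beyond the discordant-edge rule
  (concordant edges get support 100, discordant edges a uniform
  integer in 0–70), no model misspecification.
* **No coalescent process** is included by default, so all
  discordance is "error" and filtration should reconcile it — that
  is the point of the positive control. The
  `length_independent = TRUE` mode draws `K ~ Poisson(c)` regardless
  of length, emulating ILS-like discordance that length filtration
  cannot remove, for the negative contrast.
* **Sequences** evolve under Jukes-Cantor (via `phangorn::simSeq`)
  along the gene tree: uniform base frequencies, no rate
  heterogeneity, no indels — alignments are simulated as aligned.
  Branch lengths are exponential with mean 0.05 substitutions/site,
  a typical shallow-radiation scale.
* **Occupancy**: each taxon drops out of each marker independently
  with probability 0.1 (capture data sets are mostly complete), with
  a floor of four retained leaves so every gene tree stays
  informative.
* Default study size: 26 taxa (a subfamily-scale sample), 200
  markers.

A green end-to-end test therefore establishes that the *pipeline
logic* behaves as designed under its own assumptions — it does not
validate the filtration strategy against real estimation error,
alignment error, or genuine ILS, which require sequence-level tree
estimation outside this package's scope.

# Known limitations

* Interleaved Phylip and NEXUS sequence input are not parsed (FASTA
  and relaxed sequential Phylip are).
* `clade_frequencies` keys bipartitions by their literal taxon sides;
  across trees with *different* leaf sets, conceptually identical
  splits observed at different taxon subsets are tallied as separate
  rows (each with the restriction-based denominator). With equal leaf
  sets — the jackknife use case — the tally is exact.
* Codon partitioning trusts `select_reading_frame`; frames inferred
  elsewhere must be set on the alignment explicitly.
* The OLS p-value assumes independent observations; clade-level
  points from a single tree set are not independent, so treat it as a
  descriptive screen, as in the workflows this package supports.
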