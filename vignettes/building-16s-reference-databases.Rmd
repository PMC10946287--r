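---
title: "Building and benchmarking curated 16S rRNA reference databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and benchmarking curated 16S rRNA reference databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refdbkit)
```

## The problem

Amplicon-based microbiome profiling assigns taxonomy to 16S rRNA reads by
matching them against a reference database of sequences paired with
seven-rank lineages (`k__Kingdom; p__Phylum; ...; s__Species`). Public
references disagree with each other: they use different nomenclatures for
the same organism, carry unannotated or misannotated entries, and cover
different clades. refdbkit implements a reproducible pipeline for building
a single, curated, taxonomy-unified reference from several sources, cutting
it down to the hypervariable region a study actually sequenced, and
measuring — with in-silico mock communities — how well a classifier using
such a reference recovers known community compositions.

A reference database is represented throughout as a plain data frame with
columns `id`, `sequence`, `taxonomy`, `source`, serialised as a FASTA +
two-column TSV pair so the artifacts drop directly into the wider amplicon
tool ecosystem.

## Curation

`curate_database()` applies, in order:

1. **Kingdom filter** — only Bacteria and Archaea are kept by default;
   Eukaryota and Viruses entries are dropped.
2. **Unknown-label filter** — an entry is dropped when its species label is
   empty or any rank label contains one of the configured patterns
   (`uncultured`, `unidentified`, `candidate` by default), matched as
   case-insensitive literal substrings. The defaults are literal on
   purpose: `candidate` does *not* match `Candidatus_...`; users who want
   that behaviour add `candidatus` to the pattern list. A grammar inferred
   beyond the printed patterns would silently change what is removed.
3. **Rank-sparsity filter** — entries annotated only at the kingdom and
   species ranks (e.g. `k__Bacteria; ...; s__bacterium_Te63R`) carry too
   little structure to support rank-level classification and are dropped.
   This rule involves a judgment call about rare, poorly characterised
   isolates, so it is applied unconditionally but can be switched off
   (`drop_rank_sparse = FALSE`).
4. **Cross-kingdom filter** — a species whose canonical record in the
   synonym map belongs to a disallowed kingdom (a plant filed under a
   Bacteria lineage, say) is removed. Species absent from the map cannot
   be judged and pass.
5. **Synonym unification** — every rank label present in the synonym map
   is replaced by its canonical (NCBI-convention) name. Unmapped labels
   pass through unchanged but are observable in the report, so
   source-specific names remain visible rather than being silently
   normalised away.

Unification runs last so that removals are judged on the original labels.
The report satisfies `input == output + removals` exactly on every run, and
curation is idempotent: curating a curated database changes nothing.

The synonym map is a four-column table (name, canonical, taxid, kingdom)
that the user supplies, typically exported from the NCBI taxonomy; the
package deliberately performs no live taxonomy queries so that runs are
reproducible and offline.

## Merging

`merge_pair(reference, candidate)` integrates one database into another.
For each candidate entry, in input order: if its full seven-rank taxonomy
string is new, the entry is added; if the taxonomy is already present, the
candidate sequence is compared with every sequence held under that exact
taxonomy, and the entry is skipped only when it is identical to or a
contiguous substring of one of them. Three semantic choices deserve
mention:

* **Taxonomy identity is exact string equality** after unification; this is
  why curation must precede merging, and why `merge_pair()` refuses
  entries with empty taxonomy.
* **The merged set grows**: a candidate accepted earlier takes part in the
  duplicate test for later candidates. This keeps the output free of
  within-candidate duplicates and matches the left-fold use in
  `merge_chain()`.
* **Containment is one-directional**: a reference sequence contained in a
  longer candidate does not block the addition. The longer variant enters
  the database; nothing is ever removed from the reference side. Sequence
  comparison is forward-strand only, which assumes the sources are
  consistently oriented — true for the curated 16S references this is
  aimed at.

`merge_chain()` folds an ordered list of databases through `merge_pair()`.
Order matters and is part of the design: earlier databases act as
references and keep priority, so sources should be listed from most to
least trusted. The report gives per-source entry counts and percentages of
the final database.

## Region extraction and dereplication

`extract_region()` finds the forward primer on the forward strand and the
reverse complement of the reverse primer downstream of it, and returns the
insert strictly between them — primers excluded, because classifier
training and read matching operate on primer-trimmed amplicons. If the
forward strand has no site pair, the reverse complement of the record is
searched. Matching is IUPAC-aware (`matchPattern(fixed = FALSE)` from
Biostrings) with a default of **zero mismatches** per primer; exactness
keeps extraction deterministic, and the tolerance is a per-primer-pair
knob for users who want degenerate-site slack. Leftmost hits win, a fixed
tie-break. Inserts outside the pair's length bounds are treated as absent,
which guards against spurious distal primer hits.

Primer pairs for V4 (515F/806R), V1–V3 (27F/534R), V3–V4 (341F/805R) and
V3–V5 (357F/926R) ship as conventional defaults with length bounds that
bracket the typical insert sizes; they are ordinary `primer_pair()`
objects and a YAML config overrides them per protocol.

`dereplicate()` removes exact `(sequence, taxonomy)` duplicates only.
Identical sequences with *different* taxonomies are deliberately retained:
they are precisely the input the clustering stage must resolve.

## Clustering and the clustered-nomenclature grammar

Cutting full-length references down to a short region makes distinct
organisms collapse onto identical subsequences. `cluster_database()`
groups sequences at a 100% identity threshold — greedy longest-first, each
sequence joining the first representative that contains it exactly, the
semantics popularised by CD-HIT — and merges the member taxonomies into
one label per rank:

* kingdom–genus: distinct names, sorted alphabetically
  (case-insensitively, original case kept), joined with `-`;
* species: names in `Genus_epithet` form are grouped by genus; within a
  group the alphabetically first full name is kept and later members
  contribute only their epithet (`-`-joined); groups are `:`-joined.
  `expand_clustered_name()` inverts this grammar exactly;
* a rank that would list more than `max_names` (default 10) distinct names
  becomes `Unknown` — a long enumeration stops being informative.

So three Lactobacillaceae lineages sharing one V4 sequence merge into

```
g__Lactobacillus-Limosilactobacillus;
s__Lactobacillus_crispatus:Limosilactobacillus_fermentum-oris
```

Alphabetical ordering is a determinism choice — any stable order would
carry the same information. The `max_names` threshold counts distinct
post-unification names, per rank independently; for species it counts full
names rather than genus groups, the stricter and simpler reading.
Representative choice is the longest sequence, ties broken by sequence
then id, so repeated runs are byte-identical.

## Mock communities and simulated classifiers

`generate_fixture_database()` and `build_mock_community()` make the whole
pipeline testable without downloading any external reference.
A mock community draws `n_taxa` species (one member sequence each) and
gives each of its samples — five by default, matching common mock designs
— its own abundance profile:

* `uniform`: normalised uniform draws, an even community;
* `lognormal` (meanlog 0, sdlog 1, normalised): the skewed,
  few-dominants-many-rares shape typical of gut communities.

The exact abundance law matters little for the metrics because abundances
enter only as weights; what matters is having both an even and a skewed
option. `simulate_assignment()` is a perturbed oracle standing in for a
real classifier: each sequence keeps its true taxonomy with probability
`1 − error_rate − unassigned_rate`, receives a uniformly drawn wrong
database taxonomy with probability `error_rate`, and is left unassigned
otherwise. All randomness flows through explicit integer seeds; identical
seeds give identical artifacts, which the tests assert.

What the generator does **not** emulate: sequencing error profiles,
chimeras, denoising artifacts, classifier-specific confusion structure
(real misassignments are biased toward near neighbours, not uniform), and
the phylogenetic clustering of real taxon names. Green tests therefore
demonstrate that the construction and scoring machinery is correct, not
that any particular classifier will reach a given score on real data.

## Evaluation

`evaluate_dataset()` unifies both the expected and the assigned
taxonomies, then scores each of the seven ranks:

* **Matching.** Two labels match when they are identical or, for
  clustered labels, when one name is included in the other — implemented
  symmetrically as a non-empty intersection of the two labels' name sets
  (the label itself plus its expansion). `Unknown` expands to the empty
  set and therefore matches only itself.
* **Confusion counts.** For every taxon in the union of expected and
  assigned labels at a rank, each sequence is tallied TP/FP/FN/TN
  depending on which side(s) the taxon matches, so
  `TP + FP + FN + TN = number of sequences` for every taxon. Restricting
  the taxon universe to that union (rather than the whole database) keeps
  TN counts interpretable. Tallies are per sequence; abundance enters
  only afterwards, as weights.
* **Metrics.** Accuracy `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)`,
  recall `TP/(TP+FN)`, and F1 as the harmonic mean of precision and
  recall — the standard definition. A `0/0` ratio is reported as 0 and
  flagged, so a fully missed rare taxon drags the weighted mean down
  instead of disappearing from it.
* **Weighted means.** Per-taxon scores are averaged with the sample's
  expected relative abundances as weights
  (`s̄ = Σ aᵢ sᵢ / Σ aᵢ`); taxa that appear only on the assigned side get
  weight 0.
* **Bray–Curtis.** Per sample and rank, the distance between expected and
  assigned compositions over the union of labels (vegan's
  implementation), with unassigned mass kept under its own `Unassigned`
  label rather than discarded — an unassigned half of the community
  should look different from a perfectly assigned one.

Because all samples of a community share the same sequence set, confusion
counts are computed once per rank and only the weights vary per sample.
`summarize_configurations()` then averages metrics per configuration and
rank and flags the best mean F1, the comparison used to choose classifier
parameters. Significance testing between configurations is left to the
user on the emitted tidy tables.

## Numerical and testing choices

Degenerate inputs are given explicit semantics rather than errors wherever
a value makes sense: extraction returns "absent", an empty database
curates to an empty database, a lookup miss returns `NA`. Composition
tables must sum to 1 within `1e-9` per sample. All tie-breaks (clustering
representatives, primer hits, name ordering) are fixed so every stage is
deterministic; `run_pipeline()` re-run on the same config produces
byte-identical artifacts, including a JSON manifest with per-stage entry
accounting.

The test suite checks the algorithmic core against independent
brute-force oracles (plain-loop merge re-derivation, double-loop confusion
tallies, an explicit IUPAC table, all-pairs containment) on randomised
instances: merge equivalence on 200+ random database pairs of up to 100
entries, confusion equivalence on 100+ random 20-sequence tables, and
losslessness of every serialisation and of the compress/expand label
grammar on 1000 random cases. Error-rate recovery is checked at 2000
sequences, where a 20% misassignment rate must be recovered within three
binomial standard errors. These sizes keep the full suite under a minute
while leaving the statistical assertions sharp; all larger inputs are
generated in code at run time.

## Known limitations

* Merging trusts unification: two lineages that differ by an unmapped
  synonym are treated as distinct taxa, so an incomplete synonym table
  inflates the merged database rather than corrupting it.
* Forward-strand-only sequence comparison during merging; mixed-orientation
  sources must be oriented beforehand (region extraction, by contrast, is
  strand-aware).
* 100%-identity clustering only; no approximate duplicate detection.
* The simulated classifier's uniform error model is a calibration device,
  not a model of real classifier confusion.
* Species labels containing `-` or `:` would collide with the clustered
  nomenclature grammar; inputs are expected to use underscore-form names.
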