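---
title: "Marker-gene profiling of long metagenomic reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-gene profiling of long metagenomic reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerprof)
```

## The estimation problem

Taxonomic profilers that bin whole reads report *sequence* abundance — the
fraction of bases assigned to each taxon — which conflates cell counts with
genome sizes. markerprof instead targets *taxonomic* abundance, the fraction
of cells, by exploiting universal single-copy ribosomal protein genes
(RPGs): because every genome carries exactly one copy of each marker, the
sequencing coverage of a marker gene is an unbiased estimate of the number
of genome copies in the library, regardless of genome size.

The pipeline has two stages. First, long reads are searched against a marker
*protein* database (frame-shift-aware blastx-style alignment; e-value
cutoff 1e-15, subject cover at least 75%), and marker coverage is turned
into genome copies. Second, the marker-containing reads are aligned against
a *nucleotide* database of 10 kb marker-flanking windows, and an EM
algorithm resolves reads that align nearly equally well to several species.

## Genome copies from marker coverage

For every marker protein (subject) sequence we build the positional
coverage vector over its amino-acid positions and take a **trimmed mean**:
positions in the leftmost and rightmost 25% of the sequence are discarded
and the mean is taken over the central half, positions
`floor(0.25 L) + 1 … ceiling(0.75 L)`. The trim is positional, by
coordinate, not an order statistic over coverage values: any hit that
covers at least 75% of the subject necessarily spans the whole central
window, so with the 75% subject-cover floor the trimmed mean is *exactly*
the number of mapped hits. This identity is asserted by a property test on
randomised hit sets and is the reason the positional reading was chosen.

Marker coverage is the sum of the trimmed means of its constituent subject
sequences, and the total genome-copy estimate of a domain is the plain
average over its eight-gene marker set, with absent markers contributing
zero:

```{r copies}
total_genome_copies(c(l2 = 1))   # one marker-containing read
```

A species supported by a single read therefore receives 1/8 = 0.125
copies — the detection floor of an eight-marker design. Bacteria and
archaea are estimated over their own eight-gene sets and summed for the
prokaryotic total. The marker labels shipped as defaults are ordinary RPG
short names; only the *size* of the set enters any formula, and the set is
an argument everywhere it is used.

## Hit filtering

Raw protein hits pass three filters shared by profiling and database
construction:

* **Greedy overlap culling** (per query): hits sorted by e-value
  ascending are kept iff their query-range overlap with every already-kept
  hit is below 25% of the shorter range. E-value ties are broken by higher
  bit score then input order — the published rule is silent on ties and a
  total order keeps results reproducible. Overlap is computed on closed
  1-based nucleotide intervals as `max(0, min(b,d) - max(a,c) + 1)`.
* **Boundary filtering** (database path): hits whose distance from either
  contig end is less than the subject length are discarded. The subject
  length is amino acids; distances are nucleotides, so the length is
  converted by a factor of three. Distance is measured from the nearer hit
  endpoint (`query_start - 1` on the left, `contig_len - query_end` on the
  right); the endpoint convention was chosen over the hit centre because it
  is the conservative reading — any partial overlap of the would-be window
  with the contig boundary is excluded.
* **Best hit per marker** (database path): at most one hit per marker per
  contig, by highest identity, ties by lower e-value then input order.

## EM reassignment

Marker-containing reads are aligned to the window database with all
near-best secondary alignments retained. For each read–species pair only
the best alignment survives (sorted by alignment score AS, local-best score
MS, then gap-compressed identity ID). An alignment is *valid* if any of

* `AS > 0.99 · max AS` over the read's species,
* `MS > 0.99 · max MS`,
* `ID > 0.999 · max ID`

holds (strict inequalities, as published). Valid cells define the binary
read–species matrix `x` with `n` reads and `k` candidate species — `k`
counts only species with at least one valid alignment, since the uniform
initialisation `θ_j = 1/k` is only meaningful over actual candidates.

The EM then iterates

* E-step: `z_ij = x_ij θ_j / Σ_j x_ij θ_j`
* M-step: `θ_j = Σ_i z_ij / n`

until the L1 change of θ falls below `eps = 1e-5` or `t_max = 100`
iterations pass (both exposed as arguments). The observed-data
log-likelihood `Σ_i log Σ_j x_ij θ_j` is recorded per iteration and is
non-decreasing, which the tests assert numerically. Abundances below 1e-12
are clamped to zero and θ renormalised — pure numeric hygiene; such species
hold less than one trillionth of a read of posterior mass.

```{r em}
aln <- nucleotide_alignments(
  c("r1", "r2", "r3", "r4", "r4"), "w",
  c("A", "A", "B", "A", "B"), AS = 1000, MS = 1000, ID = 0.99)
fit <- em_iterate(build_read_species_matrix(aln))
coef(fit)   # the {A},{A},{B},{A,B} instance: fixed point (2/3, 1/3)
```

After convergence each read is hard-assigned to `argmax_j z_ij`. Ties are
broken by a deterministic chain: well-defined species over placeholder
binomials (an `"... sp."` label loses to a proper species at equal
evidence), then AS, MS, ID, then the lexicographic species label. The
published rule names the ingredients of this tie-break but not their
order; the chain above makes it a total order.

Finally, per-species copies are apportioned from the coverage total by
hard-assigned read counts, `copies_j = total · n_j / n` — with one read per
marker per copy this is `n_j / 8`. Apportioning by read counts rather than
by per-marker coverage shares was an open choice; read counts were chosen
because they remain defined when a species' reads concentrate on few
markers, and the two agree whenever reads spread evenly.

## Database construction and marker screening

Reference windows are the 5,000 bp flanks of each filtered hit's centre
(`floor((query_start + query_end)/2)`, window `[centre-5000, centre+5000)`
in 0-based half-open coordinates), clipped — not shifted — at contig ends:
shifting would bias flank composition toward contig interiors. Exact
duplicate windows within a (species, marker) group are removed.

The marker-screening statistics mirror how the eight-gene sets were
derived: **universality** (fraction of assemblies containing the gene),
**deviance** (|mean copy − 1|, the mean over *all* assemblies of the
subset, zeros included — the convention that makes a gene absent from many
genomes register deviance even when present copies are single),
**F0.5-score** of the annotation model (`1.25pr/(0.25p + r)`), and the
**mean relative genomic distance** between gene pairs on circular genomes,
`min(|p−q|, L−|p−q|)/L`, minimised over copies and averaged over
assemblies containing both genes — bounded by 0.5, the antipodal maximum.
Genes passing universality > 0.99, deviance < 0.01 and F0.5 > 0.99 in
every subset are clustered by single linkage at distance cutoff 0.05
(strict `<`, an unstated convention chosen here) and one representative per
cluster is kept, ranked by universality, then deviance, then F0.5, then
label. Clusters are computed directly as connected components of the
`d < cutoff` graph, which is what a single-linkage dendrogram cut below
that height yields; the test suite cross-checks against
`hclust(method = "single")`.

## Evaluation metrics

Profiles are compared with the x/y ratio (estimated over expected total
copies) and Pearson correlation across samples; species sets with
precision, recall, and F1 = `2pr/(p + r)` (the harmonic mean — one printed
variant of the formula omits the factor 2, which would halve every F1
uniformly without changing any ranking; the standard form is implemented);
and four dissimilarities on renormalised abundances after dropping
unclassified entries: Manhattan, Euclidean, Bray–Curtis
(`Σ|p−q| / Σ(p+q)`), and the Jensen–Shannon *distance* (square root of the
base-2 JS divergence, hence in [0, 1]). Bray–Curtis is cross-checked
against `vegan::vegdist` in the tests; the JS distance is computed directly
because no installed package exposes the base-2 distance form.

The genome-size database used to correct read-binning profilers assigns
every internal taxid the unweighted mean size of its descendant leaf
genomes (plasmids counted single-copy), and species missing from the
database walk up to the lowest sized ancestor.

## The synthetic generator

`sample_community()` draws taxonomic abundances from a log-normal
distribution with μ = 0, σ = 1 — the stated simulation condition — and
normalises them; genome lengths are uniform on 2–8 Mb, a typical
prokaryotic span (the precise length distribution only matters for the
taxonomic-to-sequence conversion, which is tested separately). Genome
copies are the abundances scaled to a total (default 100).

`simulate_marker_alignments()` emits alignment-level records directly:
each species contributes `round(copies × reads_per_copy)` reads spread
uniformly over the eight markers, each backed by one protein hit at 80%
subject cover and one nucleotide alignment at AS = MS = 1000, ID = 0.99.
At the default `reads_per_copy = 8` — one read per marker per genome
copy — the coverage estimate reproduces the planted copies up to the 1/8
rounding granularity. A configurable fraction of reads also receives a
near-tied alignment to an ambiguity-graph neighbour, with multiplicative
score offsets that can be placed on either side of the 0.99/0.999 validity
thresholds, so both the accept and reject branches are exercised.

What the generator deliberately does **not** emulate: sequencing errors and
quality scores, chimeras, within-species strain variation, reads spanning
two markers, and non-uniform read placement along genomes. Passing tests
therefore demonstrate the correctness of the post-alignment arithmetic and
the EM machinery under controlled ambiguity — not robustness to aligner
noise, which enters upstream of this package's inputs.

Problem sizes in the test suite were chosen to pin the statistics without
waste: the parameter-recovery check runs one 32-species community with at
least 200 reads per species and 20% ambiguity (about 10^5 reads), the
culling oracle replays 10,000 random instances of up to 8 hits, and the
trimmed-mean identity 1,000 random hit sets.

## Known limitations

* The detection floor of 0.125 copies means rare taxa below roughly one
  marker read are invisible; more markers would lower the floor but RPGs
  cluster on the genome, capping the usable set at about eight per domain.
* Multi-copy marker outliers (genomes carrying duplicated RPGs) inflate
  copy estimates proportionally.
* EM resolves ambiguity by community-wide abundance, so systematically
  shared windows between close relatives shift mass toward the more
  abundant relative; the hard assignment sharpens this further.
* Copy apportioning assumes reads are exchangeable across markers within a
  species.
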