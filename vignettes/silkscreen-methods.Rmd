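---
title: "Screening proteomes for silk-like structural proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening proteomes for silk-like structural proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkscreen)
library(data.table)
```

## The problem

Silk proteins of tube-building animals — silkworm and caddisworm fibroins,
spider spidroins, and the silks of tube-dwelling crustaceans — share a
characteristic architecture: they are long, dominated by short tandem
repeat units (GA/GAGAGS, serine-rich SXSX, GPX, cysteine-rich), and carry
short conserved non-repetitive termini. Because such proteins rarely have
close homologs in general-purpose databases, a silk proteome cannot be
annotated by similarity alone. `silkscreen` implements the screening logic
used in silk multiomics studies: candidate silk genes are the proteins in
a silk-material proteome that are

1. **novel** — no local-alignment hit against a known-protein database at
   E-value below `1e-15`;
2. **well supported** — at least two distinct tryptic peptides identified;
3. **consistently detected** — the coefficient of variation of their
   normalised intensities across replicates is below 1; and
4. **repetitive** — tandem repeats cover at least 10% of the sequence.

Survivors are clustered into families by pairwise sequence identity,
super-grouped by conserved N-terminal homology (capturing paralogous silk
genes with divergent repeats), ranked by iBAQ abundance, classified by
repeat motif, screened for cross-species conservation by translated
search, and characterised by Kyte–Doolittle hydropathy.

## Quantification model

Peptide evidence is a table of feature areas: the integrated LC–MS signal
of one identified peptide ion in one replicate. Per replicate,

$$\mathrm{iBAQ}_r(P) \;=\; \frac{\sum_{\text{peptides } q \in P} \text{area}_r(q)}
{\#\{\text{theoretical peptides of } P\}},$$

where the theoretical peptides are the distinct fully tryptic peptides
(cleavage after K/R except before P) of observable length 6–30 residues.
Distinctness matters for repetitive proteins, whose repeat regions emit
the same linker peptide many times but are reported once by
identification software. iBAQ is linear in areas and inverse in the
theoretical count, which the tests assert directly.

The replicate-consistency statistic reads "normalised standard deviation"
as the coefficient of variation of total-intensity-normalised iBAQ:
each replicate's iBAQ vector is divided by its replicate total, and
`consistency_z = sd/mean` across replicates. This makes the statistic
invariant to per-replicate loading differences — the property that
motivates normalising in the first place — and gives an `Inf` sentinel to
proteins with zero mean. Whether the statistic should be computed on iBAQ
or raw intensity is not canonical; we compute it on iBAQ, and the
normalisation is a plain column-total division rather than anything
heavier (median-of-ratios etc.) because the screen only thresholds at
CV < 1, far from where the normalisation flavour matters.

The assembly-level contamination filter keeps transcripts with TPM ≥ 1
and assembler ID rank ≤ 30,000; both cutoffs are arguments. The ID rank
falls back to FASTA record order because numeric assembler ID suffixes
are assembler-specific.

## Tandem-repeat detection

The detector is a seed-and-extend scan of the period-*p* self-match
profile, for every period in 1–60 (covering the unit lengths seen in real
silks, from (GA)n dimers to 12-residue linker motifs):

* positions `i` with `s[i] == s[i+p]` form the match profile; maximal runs
  of length ≥ min(p, 3) are seeds;
* each seed is extended outwards **one unit copy at a time**; a new copy is
  accepted only while its per-column divergence from the seed's consensus
  is at most `max_divergence` (default 0.3), plus a final partial copy of
  exactly matching columns;
* overlapping calls across periods are resolved greedily by residues
  covered (ties: smaller period, then smaller start); later calls are
  trimmed to uncovered residues, so the reported disjoint regions tile
  exactly the union of all accepted calls, and `repeat_fraction` is the
  covered fraction of the sequence.

Anchoring extension to the unit consensus, rather than to a global
mismatch budget, is the design decision that keeps non-repetitive flanks
out of repeat regions: a long perfect repeat otherwise accumulates enough
mismatch budget to swallow tens of flanking residues. With consensus
anchoring, a flanking block must itself look like a unit copy to be
absorbed, and the package tests assert that appending repeat-free flanks
never increases the covered residue count.

For perfect repeats (`max_divergence = 0`) the regions are exactly the
maximal self-match runs, and the acceptance suite proves coverage equal to
a brute-force oracle over **every** string of length ≤ 12 on a two-letter
alphabet. Two consequences of these semantics are worth knowing: a doubled
residue is a legitimate two-copy period-1 repeat, so random sequences have
a baseline repeat fraction of a few percent at `min_copies = 2`; and the
10% screen threshold counts total disjoint coverage across all repeat
families, not just the dominant one. Consensus extraction is column-wise
majority with ties broken by the earliest copy; motif classification is
rule-based (G+A ≥ 0.6 with GA alternation → silkworm-fibroin-like;
S ≥ 0.3 with SX alternation → caddisworm-fibroin-like; period-3 G?X with
G anchored and P present → collagen-like; C ≥ 0.2 → KAP-like), with all
thresholds exposed.

## Similarity search and E-values

The search engine is a full affine-gap Smith–Waterman (BLOSUM62, gap open
11, extend 1, a length-L gap costing `open + L·extend`), written as a
small C++ kernel with fully deterministic tie-breaks (best cell at the
smallest row/column; diagonal preferred in traceback). Desk-scale
databases make exact search affordable; there is no heuristic seeding in
the alignment itself. An exact k-mer prefilter (shared 5-mers) skips
subjects that cannot align: any hit passing an E < 1e-15 cut needs on the
order of forty well-matching aligned residues and therefore shares many
exact 5-mers with the query, so the prefilter does not change decisions
at that cut (asserted in tests against the unfiltered search); it can be
disabled with `prefilter_k = 0`.

Significance uses Karlin–Altschul statistics, `E = K·m·n·exp(−λS)`, with
the conventional ungapped BLOSUM62 constants (λ = 0.3176, K = 0.134) as
configurable defaults. E-values from gapped scores under ungapped
constants are approximations; the screen only uses them as a fixed,
monotone threshold rule, and no cross-database E-value is treated as
reproducible. **No low-complexity masking is applied anywhere** — silk
repeats are precisely the low-complexity signal the screen is after.

The conservation screen is TBlastN-style: each family representative is
searched against all six-frame translations of each species' transcripts
(stop codons as `*`, N-containing codons as `X`); a family is conserved in
a species when its best hit beats the E-value cut, and the reported
expression is the maximum TPM among transcripts with a qualifying hit. A
protein-vs-protein (BlastP-style) route over user-supplied protein
databases is available through the same `protein_search()` engine; the
conservation gate itself is the translated search, since transcript
assemblies are the only cross-species substrate the pipeline assumes.

## The synthetic study

`simulate_silk_study()` generates the conditions the screen assumes, with
ground truth attached:

* **Six silk families** built from motif grammars — one GA/GAGAGS
  silkworm-fibroin-type (with GPG-style and `SGRVQQTYTSSF`-style linkers),
  three serine-rich SXSX paralogs sharing an 80-residue N-terminal flank
  (pairwise ~2% flank divergence) but with distinct X-residue repertoires,
  one GPX collagen-type, and one CC-rich KAP-type. Unit copies are
  point-mutated at 2% per residue. Family lengths run ~650–1450 residues,
  in the size range typical of silk structural proteins. Each family is
  expanded into near-full-length isoforms (C-terminal truncation to
  95–100% plus 0.3% substitutions), 21 isoform transcripts in all.
* **500 globular decoys** (i.i.d. uniform-composition sequences, 120–600
  residues) and 10 flagged contaminants. Decoys plus contaminants form the
  known-protein database, so every non-silk protein fails the novelty
  criterion by self-match while planted silks, which resemble nothing in
  the database, pass it. Contaminant abundances are log-normal around a
  high mean, emulating abundant shared-environment proteins; their
  distribution is a free parameter of the generator.
* **Replicate evidence**: each observable peptide of each protein is
  detected per replicate with probability 0.9 (five replicates), and
  detected areas are log-normal around the planted protein abundance with
  CV 0.3, mean exactly the abundance — so the noiseless limit
  (`detection_prob = 1, intensity_cv = 0`) reproduces planted abundances
  exactly, and planted abundance rank is recovered. Planted abundances
  make the GA-rich family the most abundant (1000 vs 300–50 for the
  others, decoys log-normal around 5), mirroring the abundance structure
  of a real silk proteome. Peptide-to-peptide ionisation differences are
  deliberately not modelled: the screen consumes protein-level sums, and a
  per-peptide factor would only blur the planted rank without exercising
  any additional code path.
* **Eight species' transcriptomes**: where the presence matrix plants an
  ortholog, the species carries a back-translated (fixed one-codon-per-
  residue table), divergence-mutated copy of the family's N-terminal
  portion — the 80-residue flank plus a 60-residue repeat stub — among 40
  random decoy transcripts; TPM derives from simulated counts and sums to
  10^6. Truncating planted orthologs to the N-terminal portion emulates
  repeat-collapsed short-read assemblies (full-length silk transcripts
  typically require long reads) and makes conservation detection
  flank-driven, with a second, deliberate effect: cross-class repeat
  similarity (two G-rich classes align weakly but positively over long
  spans, and the reverse-complement frames of a GA-rich coding sequence
  are forced by the genetic code to read as proline/alanine repeats) stays
  below the E-value cut, keeping planted presence exactly recoverable.
  Back-translation picks between two synonymous codons per residue by a
  positional hash — deterministic, but leaving reverse frames aperiodic —
  and the translated search aligns within stop-free frame segments, as
  translated searches do.
* **Class-level presence**: the three serine-rich paralogs share one
  presence column. Their shared flank and similar repeats make them
  mutually alignable far above any sensible cut, so paralog-level
  presence is unidentifiable by E-thresholded search; conservation truth
  is therefore planted (and reported) at the class level, the same
  granularity at which such screens group paralogous silk genes. The
  default pattern has the collagen-like and KAP-like families conserved in
  every species including the outgroup-like last species (the signature of
  mucus contaminants rather than silk proper), the GA-rich family
  restricted to one species block, and the serine-rich class extending
  into a second block.

One master seed fans out to per-component child seeds through a fixed
congruential mix (`child_seed()`), so any stage can be re-run in
isolation and the whole study is byte-reproducible.

What the generator does **not** emulate — and what green tests therefore
do not show about real data: peptide-level FDR and identification error,
per-peptide ionisation efficiency, shared peptides between paralogs,
codon usage and transcript assembly artefacts beyond simple truncation,
and homologs of intermediate divergence in the known database (real
novelty calls are only as good as the database).

## Clustering and grouping choices

Family clustering is single-linkage over pairwise alignment identity
(matches ÷ alignment length, Needleman–Wunsch with end gaps by default;
a local-identity mode is provided since the identity denominator is a
genuinely open choice), at a default threshold of 0.90 — isoforms of one
gene share long exact stretches, unrelated silk families do not.
N-terminal grouping compares the first 100 residues of cluster
representatives at a 0.5 identity threshold: shared-flank paralogs score
~0.85 there, unrelated termini ~0.2–0.35, so the threshold sits in a wide
margin. Both merges are single-linkage, hence transitive and independent
of input order; representatives are the longest members with
lexicographic tie-breaks. The peptide-support criterion defaults to ≥ 2
distinct peptides (the "one peptide support is excluded" reading), with
`min_peptides` exposed.

## Hydropathy

Kyte–Doolittle profiles are sliding unweighted means over the N-terminal
1,000 residues (span configurable) with no partial windows at the ends;
window width defaults to 9, the common server convention, since no single
width is canonical. Ambiguous residues (`X`, `*`) are excluded from
window means with a reduced denominator. GRAVY is the mean scale value
over the analysed span. The package's synthetic serine- and glycine-rich
silks score well below hydrophobic controls, the qualitative contrast
expected of silks spun in water.

## Problem sizes and numerical conventions

Default test and acceptance runs use the study defaults: 21 silk isoform
transcripts in 6 families among 500 decoys, 5 replicates, 8 species with
~46 transcripts each; the planted-recovery property is checked across ten
independent study seeds and the conservation round trip at divergence 0
and 0.05. Exhaustive oracles run over every two-letter string of length
≤ 12 (repeat coverage) and every three-letter protein pair of length ≤ 3
plus sampled pairs to length 8 (alignment scores).

Coordinates are 0-based half-open internally and in returned tables;
1-based only where serialised formats demand it. Ties are always broken
deterministically (documented per function). Degenerate inputs fail loud:
empty databases, single replicates, all-zero compositions and counts are
errors or warnings, not silent zeros.

## Known limitations

* E-values use ungapped Karlin–Altschul constants with gapped scores;
  they are decision thresholds, not calibrated probabilities.
* The repeat detector resolves overlapping periods greedily; nested or
  higher-order repeat architectures are reported as their strongest
  single-period decomposition.
* Conservation is gated on the translated search only, and at class
  granularity for paralogs sharing conserved termini (see above).
* The distinct-peptide count collapses modified forms and charge states;
  quantification does not model missing-value imputation (a missing
  detection contributes zero, the conservative reading of "consistent
  detection").
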