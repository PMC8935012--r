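---
title: "Detecting and modeling compensatory frameshifting mutation pairs"
author: "pcfm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modeling compensatory frameshifting mutation pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcfm)
```

## The problem

A frameshifting indel — an insertion or deletion whose length is not a
multiple of 3 — rewrites the protein downstream of it and usually introduces
premature stop codons. A second indel nearby can compensate: when the two
lengths sum to a multiple of 3, the reading frame downstream of the second
indel is restored, and only the *spanned region* between the indels is
translated in a shifted frame. Such pairs (pCFMs) can fix in evolution and
inject radically novel amino-acid sequence into a protein. This package
detects candidate pairs in gapped alignments of orthologous CDS on a species
phylogeny, characterizes where they sit and how conserved their context is,
scores their effect on the protein, and computes how many such genes a simple
population-genetic model predicts.

## Detection procedure and its assumptions

Detection runs in three steps on each gene alignment.

**1. Indel reconstruction.** Maximal runs of alignment columns sharing an
identical, nonempty gap-carrier set form *gap blocks*. Each block is a binary
presence/absence character on the tree; we seek the minimum-change
reconstruction. For one binary character on a rooted tree, a single-change
explanation exists iff the carriers or their complement form a clade, and the
Fitch root state is ambiguous iff *both* do (which happens exactly when the
carriers are one half of the root bipartition). We accept a block only when a
unique single-change reconstruction exists: gap gained below the edge is a
deletion inherited by the carriers; gap ancestral with bases gained below the
edge is an insertion inherited by the non-carriers. Multi-change
(homoplastic) blocks and root-ambiguous blocks are counted and discarded.
Discarding polarity ties, rather than resolving them toward the more common
deletion, avoids circularity if one later measures the deletion bias. The
test suite verifies exact agreement with an exhaustive enumeration of all
ancestral state assignments on trees of 4–6 leaves over every carrier subset.

**2. Sequence quality.** A row is considered a likely functional gene copy
when its ungapped sequence starts with ATG, ends with TAA/TAG/TGA, has length
divisible by 3, and has no internal in-frame stop. Quality filtering is
applied *after* indel reconstruction, so lower-quality rows still inform the
phylogenetic placement of shared gaps, but *before* pairing.

**3. Pairing and filters.** Within each quality-passing species, events of
length not divisible by 3 are collected. Exactly two such events form a
candidate pair, kept when their signed net length (insertions positive)
is divisible by 3; species with more than two frame-disrupting events are
excluded as untrustworthy, and identical pairs found via several species are
merged with the union carrier set. The low-confidence filter then keeps pairs
of short indels (each 1–2 nt, combined ≤ 4 nt — i.e. 1+2 same-kind, 1+1 or
2+2 opposite-kind) placed on the same edge; short indels are less likely to
be assembly or alignment artifacts, and same-edge placement means the
uncompensated intermediate was never observed. The high-confidence filter
additionally requires inheritance by at least two species, since coincident
artifacts in independently assembled genomes should be rare.

Alignments with fewer than four usable species are rejected. At least one
non-carrier row is required to anchor ancestral coordinates.

## Coordinates and degenerate inputs

All alignment columns and CDS positions are 1-based and inclusive, matching
R conventions and the TSV outputs. The relative position of a pair is
`P = p1 / (L − (p2 − p1))`, with `p1` the ungapped ancestral position before
the 5′ indel, `p2` the position through the 3′ indel's end, and `L` the
reference CDS length, measured on a non-carrier row; `P` is clamped to
`[0, 1]` only against floating-point rounding, and a pair spanning the whole
CDS (denominator 0) is an error rather than a value.

## Scoring the protein effect

The spanned region, extended to codon boundaries, is translated in the
ancestral and the shifted frame. Stops arising inside the shifted frame are
kept in place as `*` rather than truncating the peptide, so positional
pairing with the unshifted translation is preserved; distance metrics treat
`*`, `X` (from N-containing codons) and `-` identically as the maximum
distance. When the two peptides differ in length (net −3 or +3 templates),
the shorter is padded with gaps at its 3′ end.

Two metrics are used. The **mean Miyata distance** averages pairwise
amino-acid distances in the Miyata (1979) physicochemical scale; the matrix
is computed from Grantham polarity and volume, normalized so the published
scale is reproduced (maximum 5.13 at glycine–tryptophan, which is also the
gap/stop penalty) and frozen at two decimals. The **hydropathy difference**
is the absolute difference in mean Kyte–Doolittle index over scoreable
residues, ranging 0–9 (poly-Ile vs poly-Arg).

An observed effect is ranked against an empirical null: the same pair shape
(kinds, lengths, spacer) is planted at a position drawn uniformly among the
valid placements of a gene drawn uniformly from a control pool, and the
spanned region scored the same way; 10,000 draws by default. The percentile
p-value is `(1 + #{draws ≤ observed}) / (n_draws + 1)`, so it is never 0 and
is uniform under the null — the suite checks KS uniformity of 1,000
such p-values at α = 0.01. Placements exclude the start and stop codons but
deliberately do *not* exclude placements creating premature stops in the
shifted frame: the observed pairs are scored with the same convention, and
excluding them would bias the null toward smaller distances. Inserted bases
are uniform over A/C/G/T; deletion-only templates are deterministic.
Per-gene p-values are combined by a one-sample KS test against Uniform(0,1),
with per-gene family-wise calls at the Bonferroni level α/k.

## Ancestral states and the quartet

For a same-edge pair, nucleotide states at the edge's two endpoints are
reconstructed by parsimony over five states (four bases and the gap), with a
bottom-up Fitch pass and a top-down refinement; remaining ambiguity is broken
toward the parent's state (no spurious substitutions), then alphabetically
with the gap last. If more than half the spanned sites stay ambiguous the
reconstruction is refused. Maximum-likelihood reconstruction would be the
natural alternative; parsimony is used to stay self-contained, and at the low
divergences where pairs are detectable the two coincide on the vast majority
of sites.

Four region states are built: ancestral `A` (parent, ancestral frame),
derived `E` (child, shifted frame), `A_mut` (same-branch substitutions
applied to `A`, ancestral frame) and `A_fr` (the pair applied without
substitutions, shifted frame). Both intermediates are omitted when no
same-branch substitution falls in the region. When substitutions are
synonymous in one frame but not the other, the intermediate that becomes
protein-identical to its neighboring endpoint is omitted — it does not exist
as a distinct protein state. Distances among the defined states support two
hypotheses: substitutions after the pair compensate it when
`d(A, E) < d(A, A_fr)`; substitutions before it make it permissible when
`d(A_mut, E) < d(A, A_fr)`. Per-carrier-leaf distances to `A` flag
compensation on descendant branches when a leaf is closer to `A` than `E`
is.

## Conservation context

Per-site Shannon entropy `H = −Σ p_i ln p_i` is computed over amino-acid
frequencies excluding gaps (0 for constant columns, ln 20 for a 20-way
uniform column); all-gap columns are undefined and skipped inside windows.
The spanned region's mean score is ranked against all same-length windows of
its gene, ties counting as ≤, so a constant profile yields percentile 1.
External phastCons-style tracks and codon-model log-likelihood pairs are
consumed from TSV; only the LRT arithmetic (`2ΔlnL`, chi-square, 1 df for the
one extra dN/dS ratio) is computed here. Gene age is the root-to-MRCA
distance of the functional species, in branch-length or branch-count mode.
Matched controls are detectability-verified: a candidate control must carry
no detected pair itself, and must yield the planted case template back
through the full detection pipeline before it is accepted.

## The expected-frequency model

Two tightly linked mutations are each deleterious (selection `s` against the
single mutant, as against a heterozygous loss of function of a nonessential
gene) but neutral in combination. The first frameshifting mutation arises
with per-gene per-generation probability `m1 = 1 − (1 − p1)^L` (evaluated
via `expm1`/`log1p` for numerical stability at `p1·L ≪ 1`) and segregates at
mutation–selection balance frequency `m1/s`; compensated haplotypes then
arise — and, compensation being exact, fix — at rate `m1·m2/s`, with
`m2 = 1 − (1 − p2)^l` over the compensation window `l`. Over `T` generations
the per-gene probability is `P = T · Σ m1·m2 / s`, summed over the
compensating type pairs (1-nt insertion ↔ {2-nt insertion, 1-nt deletion},
and symmetrically — the only combinations of lengths ≤ 2 whose total is
divisible by 3). The expected count is `n_genes · P` with a 95% CI half-width
`1.96 · sqrt(n_genes · P (1 − P))` from the normal approximation to the
binomial.

Defaults, per clade preset: mutation rate μ = 1e-8 (vertebrates) or 4.9e-9
(insects) per nt per generation; indel-type rates 0.020μ, 0.010μ, 0.042μ,
0.015μ for ins1, ins2, del1, del2; s = 0.005 / 0.0015; mean gene length
L = 1897 / 1204 nt; l = 100 nt (all observed spanned regions are shorter);
T = 176,536,337 / 403,272,889 generations; 21,208 / 15,283 genes. `T` is
treated as a generation count, the only reading under which `T·m1·m2/s` is
dimensionless. Headline probabilities are reported at one significant
figure and counts at the nearest integer; the simultaneous-occurrence
scenario (`s = 1`, lethal intermediate) rescales the *rounded* probability
by the lineage's `s` — the convention under which both clades' printed
values follow consistently — with the unrounded value reported alongside.

## The simulator: what it does and does not emulate

`simulate_genes()` roots a random stop-free CDS per gene, evolves it down
the tree under a single-parameter equal-rates substitution process, plants
the scenario's indels, and emits the truth table in final-alignment
coordinates. Gap columns are introduced globally when planting insertions,
so the emitted alignment *is* the true alignment — no aligner is simulated,
and alignment error, sequencing error and assembly artifacts (the real-world
motivation for the filter cascade) are deliberately out of scope. A simple
substitution model suffices because detection operates purely on gap
structure. Substitutions never touch the terminal codons and are rejected
when they would create an in-frame stop in the reference frame — purifying
selection against nonsense — so planted histories remain recoverable;
positions of planted pairs are additionally resampled until every carrier
row passes quality control. Planted pair positions avoid the first and last
two codons and carrier edges avoid the root bipartition (whose polarity is
inherently ambiguous). Consequently, passing truth-recovery tests
demonstrates correctness of the detection logic, not robustness to
misalignment or assembly noise.

Scenario controls plant each failure mode the filters must reject: a lone
frameshifting indel (carrier pseudogenized by the mod-3 criterion), three
1-nt deletions (net in-frame but over the two-event limit), a compensating
pair on two nested edges (rejected by same-edge placement), and a 4+2-nt
deletion pair (over the length bound).

`make_control_pool()` draws quality-passing CDS with log-normal lengths
(σ_log = 0.45, a realistic spread for CDS length distributions) around the
preset mean (1897 / 1204 nt).

## Problem sizes and reproducibility

The test suite exercises detection on 100 simulated genes over a 20-leaf
tree (40 planted pairs, 60 negative controls), frame restoration on 1,000
random in-silico applications, null calibration with 10,000 null draws and
1,000 observations, and positional uniformity with 200 planted placements —
sizes chosen so each property is tested at meaningful resolution while the
whole suite stays fast. Every stochastic component takes an explicit integer
seed; the pipeline fans a single run seed out to fixed per-stage child
seeds, so any stage can be rerun independently and identical configurations
produce byte-identical outputs.

## Known limitations

- Gap blocks interrupted by a single mismatching column are not merged, and
  overlapping gap patterns in different species subsets are treated as
  independent events; a sequencing gap bridging two blocks can therefore
  split one biological event in two.
- Pairs spanning more than the compensation window, or whose carriers sit at
  the root bipartition, are undetectable by construction.
- The spacer between indels is counted on the derived (carrier) sequence;
  the ancestral count is emitted alongside, as published per-gene tables are
  ambiguous about which convention they use.
- The popgen model ignores back-mutation, interference, and any fitness
  difference of the compensated state; its `T` aggregates lineage-specific
  generation times into one number.
- Ancestral-state parsimony underestimates multiple hits on long branches;
  quartet analyses should be restricted to recent, well-sampled pairs.
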