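---
title: "Methods: pan-genome gene-family analysis with panfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome gene-family analysis with panfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panfam)
```

# Scope

`panfam` analyses one gene family across a pan-genome of related diploid
genomes. It was built around the kind of study in which a family such as
the plant lipid transfer proteins (LTPs, Pfam domains PF14368/PF00234) is
identified in nine diploid *Gossypium* genomes and then characterised by
presence/absence variation (PAV), selection pressure (Ka/Ks), structural
variant (SV) impact, promoter cis-element content and spatiotemporal
expression. The real genomes are not desk-scale inputs, so the package
ships a seeded simulator that emits every file format the pipeline reads,
with ground truth, and the test suite judges the methods against that
known world plus independent oracles.

# Family identification

Candidate genes arrive as HMMER3 `domtblout` hits of the family's profile
models. Per gene, hits with independent E-value strictly below `e_max`
(default 1e-5) are kept and the best hit is the one with the largest
*model-side* coverage, `(hmm_to - hmm_from + 1) / model_len`. A gene is
**typical** when coverage strictly exceeds 0.90; **atypical** when
coverage lies in (0.80, 0.90], or when coverage passes the typical bar
but the protein is shorter than 90% of the median typical protein length.
Genes at or below 0.80 are dropped.

Design choices the source description left open:

* *Coverage side.* "Alignment coverage" is computed over the HMM model
  length because the typical/atypical tiering is about domain
  completeness; `coverage_side = "target"` switches to query-side
  coverage.
* *Length-rule anchor.* The reference length is the per-genome **median**
  typical protein length (robust to outliers), falling back to the
  cross-genome median when a genome has no typical member. The
  provisional typical set (coverage rule only) defines the median; short
  members are then demoted.
* *Tie-breaking* when both family domains hit one gene: larger coverage,
  then smaller E-value, then lexicographic accession.
* External database cross-validation is out of computational scope; the
  `validated` argument accepts an allow-list and intersects.

All boundaries are strict as stated: coverage must *exceed* 0.90,
E-values must be strictly *below* 1e-5. The acceptance tests probe genes
sitting exactly on 0.90, 0.80 and 1e-5.

# PAV classification

With `n` genomes, occupancy `n` is **core**, occupancy 1 is **specific**
and anything in `[2, n-1]` is **variable**; this is the only reading under
which core genes appear in all genomes and "exclusive" genes in one. Two
pooled summaries are emitted because a plain per-gene share cannot
reproduce occurrence-style percentages: `gene_share_pct` (class counts
over gene count) and `pooled_pct` (occurrence-weighted: class occurrences
summed over genomes, divided by total occurrences). Presence by default
counts typical *or* atypical members; `typical_only = TRUE` restricts it.

# Ka/Ks by Nei–Gojobori (1986)

The counting method is implemented from first principles rather than
wrapping an external calculator:

1. **Sites.** For each codon, each of the 9 single-nucleotide mutations is
   classified against the standard genetic code; mutations to stop codons
   count as nonsynonymous. `s` is the synonymous count over 3, `n = 3 - s`;
   `S` and `N` are the means of the two sequences' sums, so
   `S + N = 3 × codons` exactly.
2. **Differences.** Codon pairs differing at 2–3 positions average
   `(sd, nd)` over all orderings of the differing positions, excluding
   pathways through stop codons (when none is stop-free the stop-passing
   pathways are used and the pair flagged).
3. **Rates.** `pS = Sd/S`, `pN = Nd/N` receive the Jukes–Cantor
   correction `d = -(3/4) ln(1 - (4/3) p)`; `omega = Ka/Ks`.

Numerical conventions: `Ks = 0` makes omega **undefined** (NA), never 0
or infinity — treating it as infinite would manufacture positive
selection. Proportions at or above 0.75 flag saturation and void the
rates. Codon columns containing ambiguous bases or stops are dropped
pairwise. Per family, omegas over all genome pairs form the reported
distribution; the headline positive-selection share uses the mode of a
0.1-wide histogram (lowest bin wins ties), and undefined omegas never
enter a denominator. Families present in fewer than two genomes have no
pair and are excluded.

The simulator's companion operation `evolve_cds_pair()` realises a true
omega by acceptance thinning: synonymous proposals accepted with
probability `min(1, 1/omega)`, nonsynonymous with `min(1, omega)`.
Because proposals are uniform over sites, the expected realised
`(Nd/N)/(Sd/S)` equals omega; rejecting stop-creating proposals biases
this slightly, which the acceptance band absorbs. The acceptance suite
regresses estimated against true omega over {0.2, 0.5, 1, 2, 2.5} at
10-kb CDS and 5% divergence (50 seeds each) and requires a slope in
[0.8, 1.2].

# SV region annotation

Each gene's territory is the 2-kb flank on both sides plus its internal
anatomy: `exon` means *coding* exon (UTRs are their own categories),
`intron` is gene body minus exons, and `splice` is the 2 nt of intron at
each exon–intron junction (configurable; introns of width ≤ 4 are splice
throughout). One region per (SV, gene) pair is assigned with precedence

```
splice > utr5 > utr3 > exon > intron > upstream > downstream
```

so that the seven counts always partition the overlap total; the rare,
specific features outrank the broad ones — a splice category could never
be populated if intron or exon outranked it. Zero-length anchors (INS and
TRA breakpoints) hit an interval exactly when the anchor point lies inside
the half-open interval. A TRA row's start and end are treated as its two
breakpoints, tested in coordinate order, counting once per gene. SVs
touching several genes contribute one record per gene, and the distinct
gene count is reported separately, so both readings of a pair-vs-SV
census are available.

# Expression analyses

All statistics run on `log2(RPKM + 1)`; pattern detection runs on raw
RPKM. The detection threshold (`expressed_min = 1` RPKM in at least one
sample of a tissue) is a package default — the source analysis never
states one — and is echoed into the provenance JSON. Categories are
ovule-only, root-only, both, none, and every gene gets exactly one.

The SV–expression association splits samples by whether their genome
carries an SV overlapping the gene; groups smaller than 2 samples exclude
the gene. The significance flag is exactly the published joint rule
`|r| > 0.3` and Pearson `p < 0.05`; Welch t and Wilcoxon rank-sum
p-values are reported alongside (both appear in the source methods), and
a Benjamini–Hochberg column is provided for users but never drives the
flag, matching the stated rule.

Co-expression edges between transcription factors and expressed
(category ≠ none) family genes use Pearson correlation with
`|r| >= 0.8` and `p < 0.05`; the 0.8 cutoff is a package default since
only the method, not the threshold, is stated.

# The synthetic world

`sim_config()` fixes the stated world; its defaults are not tuned to test
outcomes:

* 9 genomes, 107 families split 45/43/19 core/variable/specific
  (largest-remainder rounding), the published family size and class
  counts.
* Pairwise CDS divergence 5%; ~20% of families draw omega from
  U(1.5, 2.6) (positive selection), the rest from U(0.1, 0.6), mirroring
  the reported "about 20%" positive fraction.
* SV placement weights proportional to the published region breakdown
  (1004 upstream / 731 intron / 669 downstream / 260 exon / 51 utr3 /
  21 utr5 / 4 splice) plus a far-intergenic class; five SV types with a
  deletion-heavy mix. 300 SVs by default (a desk-scale stand-in for the
  published 2,740; counts scale, the partition property does not).
* Expression grid: root at −4/−2 DPA, ovule at 0/4/8 DPA — the visible
  timepoints of the emulated study. Expressed samples draw RPKM from
  LogNormal(meanlog 3, sdlog 0.6) (~20 RPKM, a realistic magnitude the
  source never states); silent samples from U(0, 0.3), below the 1-RPKM
  threshold. Pattern fractions default to 35/25/20/20
  ovule-only/root-only/both/none.
* Planted TFs are affine-noise copies of their target's realised log
  profile, so the planted Pearson correlation is `rho` (exactly 1 at
  `rho = 1`; the positivity shift is affine and preserves r).
* Promoters are the 2000 bp 5' of each gene; 3 catalog elements are
  planted per promoter at non-overlapping positions, IUPAC degeneracies
  concretised at random.
* Protein lengths: normal families 110–130 codons; ~10% "short" families
  (60–85 codons) exist to exercise the atypical length rule, and the
  ground-truth status applies the same definition the classifier states,
  written independently in the generator.

What the simulator does **not** emulate — and therefore what a green test
does not establish: indels and recombination within CDS (pairwise
substitution only), phylogenetic structure among the nine genomes
(divergence is star-like), SVs that actually rearrange the assembly
(tables only, as in the source data), read-level expression noise or
library-size effects (RPKM matrices are drawn directly), and the real
PlantCARE element universe (the bundled 29-element catalog is a
documented stand-in; counts against the real catalog are explicitly not
reproduced).

Determinism: every simulation stage seeds the RNG from `config$seed`
plus a fixed small offset per stage, so fixtures are byte-identical for
identical configs, and the pipeline is a pure function of
(inputs, config, seed).

# Calibration and power choices

The null calibration test (200 replicates at `sv_effect_delta = 0`)
bounds the association rule's fire rate at 7%: with 45 samples the
binding constraint is `P(|r| > 0.3) ≈ 4.5%`, and the band allows
Monte-Carlo error. The sensitivity test plants `delta = 2` log2 units on
uniformly expressed genes: the implied point-biserial correlation is
about 0.75 at 45 samples, giving theoretical power near 1 for the
`|r| > 0.3` rule, against a required sensitivity of 0.85.

# Known limitations

* NG86 is the canonical, fully specifiable baseline; maximum-likelihood
  codon models and model averaging are out of scope, so absolute omega
  magnitudes from other calculators will differ.
* The GFF3 reader supports the gene/mRNA/exon/CDS/UTR subset the
  analysis needs (longest-CDS transcript per gene), not arbitrary GFF3.
* Promoters anchor at the gene start, not a transcription start site,
  because the emulated extraction is relative to the gene.
* With genomes containing paralogous family copies, the PAV matrix
  collapses family presence to a boolean; copy number is not modelled.
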