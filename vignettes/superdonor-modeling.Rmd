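---
title: "Modeling HLA class I superdonors: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling HLA class I superdonors: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superhla)
```

This vignette documents the statistical models, conventions and design
decisions behind `superhla`, in the spirit of a methods section: what each
component assumes, which knobs matter, and what the synthetic-data tests do
and do not demonstrate about real registries.

## Nomenclature and resolution

Alleles are WHO-style names `locus*f1:f2:f3:f4` with an optional expression
suffix. All aggregation happens at a configurable *field resolution* `k`
(default 3, the resolution of modern sequencing-based registries): field 1
is the allele group, field 2 the protein, field 3 synonymous coding
variation, field 4 non-coding variation. Two conventions are fixed
package-wide:

* call pairs are **unordered** — registry columns `A_1`/`A_2` carry no phase
  information, and no statistic in the package depends on slot order;
* suffixed alleles (e.g. a null `N` allele) compare as **distinct** from
  their unsuffixed namesakes, since expression status is exactly what
  matters for compatibility. The suffix is dropped on truncation to fewer
  fields because a truncated name no longer identifies the suffixed
  sequence.

Homozygosity is name equality at resolution `k`. Registries are typically
typed on exons 2–3; whether two alleles identical there also agree outside
the typed region is not observable from the registry, so third-field name
equality *is* the package's operational definition of coding-sequence
homozygosity.

## Homozygosity accounting

Per-gene, per-pair and triple homozygote counts use *at-least* semantics
(a triple homozygote contributes to every pair and gene count), matching how
proportional Euler diagrams are drawn. Union and exclusive counts follow by
inclusion–exclusion:

$$|A \cup B \cup C| = \sum_g n_g - \sum_{gh} n_{gh} + n_{ABC}, \qquad
n_{\text{exactly 2}} = \sum_{gh} n_{gh} - 3\,n_{ABC}.$$

The constructor validates containment (`triple ≤ pair ≤ gene ≤ n`), so
derived quantities are non-negative whenever the inputs are coherent.
Haplotypes are only tallied for triple homozygotes, the one class of
individuals whose three-gene haplotype needs no phasing; statistical (EM)
phasing of heterozygotes is deliberately out of scope.

## Hardy–Weinberg testing

Allele frequencies are estimated by direct call counting (not maximum
likelihood under HWE), expected genotype counts are $np_i^2$ and
$2np_ip_j$, and the statistic is the usual
$\sum (O-E)^2/E$ over genotype classes. Two procedural choices are worth
making explicit:

* **Low-count filtering.** Classes observed fewer than `min_count = 5`
  times are excluded from the sum — the χ² approximation is unreliable for
  sparse classes. Expected counts are *not* re-normalized afterwards and
  the degrees of freedom keep the closed form $n(n+1)/2 - n$ for $n$
  observed alleles (the number of genotype classes minus the number of
  estimated allele frequencies). When filtering actually removes classes,
  the df no longer matches the number of summed terms; rather than silently
  absorbing that approximation, the result sets `filtered_df_mismatch` and
  the print method states it. With `min_count = 0` the statistic reduces to
  the textbook multi-allele test (verified against an independent
  brute-force implementation in the test suite).
* **Calibration.** The test is exactly calibrated when no class is
  filtered. The acceptance suite verifies type-I error at $\alpha = 0.05$
  over 500 null registries of 500 individuals drawn from a three-allele
  pool chosen so all six genotype classes have expected counts ≥ 20 —
  i.e. under conditions where the df formula is exact. On real class I data
  (dozens of alleles, thousands of rare genotypes) the filtered statistic
  is an approximation by construction, and p-values should be read
  qualitatively.

No multiple-testing correction is applied across genes; results report df,
retained-class counts and the caveat flag so users can judge.

## Cross-population comparison

Published tables give per-gene allele frequencies, not genotypes, so
cross-population geometry is computed on **Monte Carlo reconstructions**:
each simulated individual draws two alleles i.i.d. per gene. This ignores
between-gene linkage by necessity — frequency tables contain no linkage
information — and the vignette's coverage caveat below follows from that.
Frequency regression is ordinary least squares over the union of alleles
(absent alleles imputed 0), on the values as given: a table that was
rescaled or truncated is regressed raw, not silently renormalized.

One-hot encoding marks allele *carriage* (1 if the individual carries ≥ 1
copy): homozygosity is not recoverable from the presence/absence encoding,
which is the conventional choice for population-structure PCA; a dosage
mode (0/1/2) is available where that matters. PCA mean-centers columns but
does not scale them to unit variance — presence/absence columns are already
on a common scale, and variance scaling would inflate rare-allele columns.
Centroids are per-population means in PC space; distances are Euclidean
there, with an optional normalization that pins a chosen pair at 1.00 for
relative reporting. Default simulated cohort size is the registry's own
size (3,496), since the source publications do not state one.

## The compatibility model

The matching rule is **host-versus-graft, donor→recipient**: donor $D$
matches recipient $R$ under configuration $(G, k)$ iff

$$\forall g \in G:\; \text{alleles}_k(D, g) \subseteq \text{alleles}_k(R, g),$$

i.e. the recipient's CD8 T cells see no foreign class I allele on the
graft. This is the only direction under which homozygous donors are
systematically advantaged and under which knocking out a gene relaxes the
rule — the mechanism that makes the HLA-C-retained (HLA-A/HLA-B double
knockout) configuration gain coverage. The rule is reflexive, not
symmetric, and monotone: shrinking the retained set never loses a match
(asserted property-style in the tests). Graft-versus-host direction is
available as an option but unused by default. Self-pairs count as matches
by default (donor panels are drawn from the recipient cohort);
`exclude_self = TRUE` changes that.

Coverage curves accumulate donors in a seeded random order; the ordering
shapes only the displayed curve, never the endpoint. Random-subset
baselines draw panels without replacement and report the per-replicate
coverage distribution.

The expected number of triple homozygotes under linkage equilibrium is
simulated (independent-locus HWE draws from measured per-gene frequencies,
default 1,000 replicates — the replicate count is not prescribed anywhere,
so a value giving a stable ±sd is used) and cross-checked against the
closed form $n \prod_g \sum_i p_{g,i}^2$.

## The guide-design cascade

SpCas9 sites are 20-nt protospacers followed by an NGG PAM (NAG is not
counted; the activity model presumes NGG), found on both strands; minus
strand sites are reported in plus-strand coordinates. The scoring context
is the published 30-mer convention — 4 nt upstream, protospacer, PAM, 3 nt
downstream — and sites too close to a sequence end to have full context are
dropped and counted separately rather than scored on padded sequence.

Coordinates are 0-based half-open internally, 1-based in written outputs.
The blunt cut falls between protospacer positions 17 and 18 (3 bp 5′ of
the PAM). **Region membership is decided by the cut position**, not by
protospacer overlap, because the frameshift position governs knockout; a
guide whose protospacer straddles an exon boundary but cuts in the intron
is not an exonic guide here. This is a documented divergence risk against
pipelines that use overlap. The cascade flags nest by construction:
`in_gene_body ⊇ in_exon ⊇ in_ectodomain ⊇ high_activity`, with the
ectodomain boundary at the first nucleotide of the codon of the first
transmembrane residue (transmembrane spans are *inputs*, keyed per allele
or per locus, with an explicit signal-peptide offset when given on the
mature protein — transmembrane prediction itself is out of scope).

Rule Set 1 scoring is a logistic model over position-specific single- and
di-nucleotide indicators plus a GC-count term (|GC − 10| over the
protospacer, with separate low/high coefficients). The coefficient table
(Doench et al. 2014, doi:10.1038/nbt.3026) ships as a CSV asset whose md5
is pinned in code; the scorer refuses a modified file. Scores are purely
sequence-determined — relocating a site without changing its 30-mer cannot
change its score. The "inactive quartile" seen in score distributions is
reported descriptively only; the selection filter is the fixed 0.5
threshold. Uniqueness across alleles is keyed on the protospacer+PAM
string; flags are OR-combined across occurrences and the retained
representative carries the maximum score (the same 23-mer can sit in
different 30-mer contexts in different alleles). HLA-C sparing removes any
candidate whose 23-mer occurs verbatim, on either strand, in any supplied
HLA-C sequence — a within-panel exclusion, not a genome-wide off-target
scan.

## Synthetic data: what it emulates, and what it does not

`sample_registry()` draws individuals from a haplotype pool with a single
autozygosity parameter `F`: with probability `F` one haplotype is drawn and
duplicated (a forced triple homozygote), otherwise two i.i.d. haplotypes.
Modeling the excess at the whole-haplotype level was chosen because one
parameter then reproduces precisely the observable of interest — triple
homozygotes exceeding independent-locus expectation — and gives the HWE
stage a controllable true positive. The method-of-moments recovery
$\hat F = (h_{obs} - h_0)/(1 - h_0)$ with $h_0 = \sum_k w_k^2$ is exact in
expectation and is verified to within 3 standard errors at
$F \in \{0, 0.1, 0.3\}$, $n = 5{,}000$.

The default `demo_pool()` is the fixture cohort's 15 haplotypes plus 25
invented ones under Zipf-like weights. It is *illustrative*: its
homozygosity mass $h_0 \approx 0.09$ is an order of magnitude above a real
registry's triple-homozygote fraction (~1.5%), so synthetic coverage
numbers (e.g. ~98% by the synthetic registry's own triple homozygotes) are
not comparable to published registry figures — they demonstrate mechanism
(coverage ordering, knockout gains), not magnitude. Likewise the pool/`F`
model has no linkage-disequilibrium structure beyond haplotype identity and
no mutation or recombination, so passing tests show correctness of the
computations, not realism of the demography.

Toy genes default to class I scale — 8 exons, a 1,101-nt CDS, the
transmembrane helix encoded in exon 5 — with substitution variants placed
in exons. All generators are seed-deterministic down to emitted file bytes.

## Numerical and procedural conventions

* Frequencies are kept as integer counts until the final division, so a
  frequency table sums to 1 exactly up to one float division.
* Tie-breaks in tallies and tables: descending count, then nomenclature
  order (numeric within fields, suffixed after unsuffixed).
* Degenerate inputs are first-class: empty retained-gene sets (universal
  donor), single-allele frequency tables, rank-deficient PCA input
  (zero-variance warning, distances 0), cohorts of size 0 or 1.
* Every stochastic routine takes an explicit seed; simulation sizes used by
  the test and acceptance runs (500 calibration replicates at n = 500;
  n = 5,000 for recovery; 1,000 replicates for the homozygote expectation;
  100 random kilobase sequences for the site-extraction oracle) were chosen
  as the smallest sizes at which the relevant standard errors are a small
  fraction of the tested effect.

## Known limitations

* HLA class II, G/P-group collapsing, allele-ambiguity codes and
  registry-search algorithms are out of scope.
* The compatibility rule models CD8-mediated host-versus-graft recognition
  only — no KIR/NK ligand logic, no anti-HLA antibody modeling.
* The HWE procedure reproduces the filtered-χ²-with-closed-form-df
  convention described above; it is an approximation whenever rare
  genotype classes exist, and flagged as such.
* Unique-site counts on real HLA alleles depend on the allele-database
  release used for input sequences; the cascade recomputes them for
  whatever FASTA panel is supplied rather than shipping any release.
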