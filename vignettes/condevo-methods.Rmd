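---
title: "Methods and design of condevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of condevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condevo)
```

`condevo` implements the computational core of a comparative study of
condensin complex evolution: calling subunit presence or absence from
genome sequence, screening for compensatory duplications, mapping loss
events onto a species tree, and testing for positive selection. This
vignette explains each model and procedure, its assumptions, the
parameters that matter, and the design choices made where the design
was genuinely open. Every empirical claim here is one the package's own
tests or acceptance script computes.

## Presence/absence calling: the tiered protocol

Homology-based absence calling is asymmetric: a hit demonstrates
presence, but a missed search may reflect divergence, assembly gaps, or
a bad bait rather than a true loss. The protocol therefore escalates
baits through up to three tiers — canonical distant sequences first
(tier 1), an annotated within-order sequence next (tier 2), and the
closest relative's sequence last (tier 3) — and calls a gene absent
only when every tier fails.

Hits are classified from their E-values and aligned-region structure:

* **strong** — best E ≤ 1e-10 *and* at least two distinct aligned
  regions (HSPs) on the same subject. Real eukaryotic genes split into
  multiple HSPs because introns interrupt the alignment, so requiring
  two regions is a cheap structural plausibility check. Strong hits
  establish presence without further validation.
* **weak** — best E in (1e-10, 0.05], or any E-value carried by a
  single region. Weak hits must pass reciprocal validation: the
  candidate locus is extracted and searched against an annotated
  reference gene set of a related species; presence is accepted only if
  the expected subunit is the best match (ties on E broken by total
  aligned score). A weak hit that fails validation does *not* stop the
  cascade — escalation exists precisely because early searches can be
  inconclusive.
* **none** — nothing at E ≤ 0.05.

Two interpretation choices are worth stating. "Multiple regions" means
≥ 2 HSPs of the same bait against the same subject contig, the natural
reading of a contrast with "only a single region". And the E ≤ 1e-10
threshold is applied to the best HSP of a subject rather than per-HSP;
the alternative would only matter for hits whose second-best HSP
straddles the threshold, and the classification consumes the best HSP's
E-value anyway.

### The built-in search engine

The package includes a desk-scale translated (six-frame) and nucleotide
local-alignment engine so the protocol runs without external binaries.
It reproduces the *semantics* of an E-value-driven search, not the
numbers of any particular tool: Smith–Waterman local alignment
(`Biostrings::pairwiseAlignment`), greedy masking of each found subject
segment to recover up to 4 distinct regions per frame, and
Karlin–Altschul statistics E = K·m·n·e^(−λS) with m the query length
and n the total searched length (all six translated frames, or both
nucleotide strands).

Protein scoring uses BLOSUM62 with gap open 11 / extend 1 and the
gapped constants λ = 0.267, K = 0.041; nucleotide scoring uses
match +2 / mismatch −3, open 5 / extend 2 with λ = 0.625, K = 0.41. The
gapped protein constants were chosen over the ungapped pair
(λ = 0.318, K = 0.13) after a null calibration — 100 random
200-residue-query vs. 600-nt-subject searches — in which the gapped
constants produced a spurious E ≤ 0.05 hit in 1/100 seeds versus 3/100
for the ungapped pair; both satisfy the ≥ 95% hit-free requirement the
package tests enforce, but the gapped constants are the statistically
appropriate ones for gapped scores. The engine's default reporting
cutoff is E ≤ 0.05, the protocol's own "no hit" boundary, so
sub-significant junk regions cannot inflate the region count that the
strong/weak classification relies on.

E-values scale with the database searched. This matters for reciprocal
validation: the candidate extracted from a weak hit is a short
sequence, and re-aligning it against the very bait family that produced
it will reproduce the original chance similarity at a deceptively small
per-pair E. Validation therefore judges E-values at an effective
database size (`db_size`, default 2e6 residues — the scale of an
annotated insect gene set, which the reference stands in for). At that
scale a marginal chance score sits at E ≈ 8 and is rejected, while a
genuine subunit match remains below 1e-30. Chance similarity scores are
around 50; genuine matches within the protocol's useful divergence
range score above 300, so the decision is not knife-edge.

### What the synthetic benchmark shows — and does not

`simulate_genomes` implants back-translated, divergence-laddered coding
sequences into random-background contigs, splitting each gene into two
exons separated by an intron whose length is deliberately not a
multiple of 3 (successive exons then fall in different reading frames,
as real introns almost always arrange). With the built-in engine and
150-residue families, tier-1 baits classify implants as strong up to
~50% residue divergence, weak around 60–70%, and miss them at 80% —
which is where tier-3 close-relative baits take over. The 20-genome
benchmark (divergences ≤ 35%, i.e. within the detectable band) is
screened at 100% accuracy, and escalation fixtures resolve at the
expected tier.

The generator emulates ortholog divergence, deletions, decoy paralogs,
exact-repeat artifacts, and intron structure. It does not emulate
repeat families, low-complexity sequence, fragmented assemblies, GC
heterogeneity, or codon-usage bias (back-translation uses a fixed
table). Passing the benchmark therefore demonstrates the protocol logic
and engine statistics, not robustness to the full messiness of real
assemblies.

## Duplication screening

Candidate duplicates come from searching a gene against its own genome.
Each aligned region is treated as a separate candidate locus (the
self-locus and a tandem copy often share a contig). The pipeline order
is fixed: keep regions with E strictly below 0.001; drop the query's
own locus, identified by coordinate overlap with its annotated span
(without this every screen would trivially report a "duplicate");
remove likely artifacts — any region longer than 200 nt at more than
98% identity, both inequalities strict, with identity computed over
aligned columns excluding gaps and ambiguous positions (near-identical
long repeats are more plausibly assembly duplicates than old
duplications); finally, validate survivors reciprocally against a close
relative's annotated genes unless already annotated as a family
paralog. The artifact filter is idempotent, and the tests pin the
boundary behavior (200 nt at 98% identity is retained; 250 nt at 99% is
not).

## Dollo parsimony loss mapping

Binary presence/absence states evolve under Dollo parsimony: the gene
is gained at most once (at the root), so along any root-to-tip path the
state may only flip present → absent. The minimal reconstruction has a
closed form: a node is present exactly when its subtree contains a tip
known to carry the gene, and every edge from a present parent to an
absent child whose subtree contains a known-absent tip is one
independent loss. This minimal labeling is unique, making the procedure
deterministic; the test suite proves equivalence against exhaustive
enumeration of all internal labelings on hundreds of random trees.

Choices: when *every* tip lacks the gene the reconstruction depends on
the prior — with `assume_ancestral_present = TRUE` (the default,
appropriate when outgroup evidence says the ancestor had the complex)
the gene is charged one loss on the root edge; otherwise it is simply
ancestrally absent. Unknown tips are unconstrained: they adopt whatever
state avoids an event (in practice the parent's state) and are flagged
in the output. Polytomies are allowed, a loss on a polytomy edge
counting once.

One property the package deliberately does *not* claim: flipping an
absent tip to present can **increase** the minimal loss count, because
a present tip inside a formerly absent clade splits that clade's single
ancestral loss into several deeper ones. (Enumeration confirms this on
small trees.) The bounded direction — such a flip never removes more
than one loss — is asserted in the tests.

## The unpolarized McDonald–Kreitman test

Per codon site of an ingroup alignment plus outgroup: segregating
changes (each distinct minor allele against the major allele; ties for
the major broken lexicographically, which keeps the tabulation
invariant to haplotype order) count toward polymorphism (pN/pS), and a
site whose ingroup allele set excludes the outgroup consensus codon
additionally contributes a fixed change (major vs. outgroup consensus)
to divergence (dN/dS). The test is unpolarized — no third species
assigns ancestral states — so sites where a multi-sequence outgroup
itself segregates without a major allele cannot be classified and are
skipped. Codon columns containing gaps, ambiguity codes or stop codons
in any sequence are skipped entirely; all skips are tallied in a QC
report.

Codons differing at k positions are classified by enumerating all k!
single-step pathways, discarding those passing through a stop codon,
and averaging the per-step synonymous/nonsynonymous labels over the
remaining pathways (weights summing to k). Fractional weights are
summed across sites and rounded half-up only in the final table; raw
weights are always reported alongside. This pathway averaging is
conventional, and it is isolated in one function so its effect can be
probed.

The adaptive proportion is α = 1 − (dS·pN)/(dN·pS), one minus the
neutrality index; it is undefined when dN or pS is zero and may be
negative when nonsynonymous polymorphism is in excess (slightly
deleterious variants segregating). No low-frequency polymorphism filter
is applied — the estimator is the plain contingency form, and users
wanting asymptotic-α-style corrections should apply them downstream.

Significance comes from Fisher's exact test on [[dN, dS], [pN, pS]].
The package default is the **two-sided** exact test: on the bundled
published count table the two-sided convention reproduces the printed
p-values (e.g. 9.56e-11 for Cap-D3) where the one-sided test does not,
and the tests pin the implementation to an independent hypergeometric
enumeration oracle. Both one-sided tails remain available. Two rows of
that published table are documented anomalies — one row's α/p duplicate
another row's values and a second row's printed α does not follow from
its own printed counts — and the test suite asserts these as expected
mismatches rather than skipping them.

### MK generator and calibration

`simulate_mk_alignment` places at most one event per codon site on a
glycine background whose single-step neighbors are cleanly synonymous
(third position) or nonsynonymous (first position): synonymous and
nonsynonymous polymorphisms at rate θ/2 each, synonymous and neutral
nonsynonymous fixed differences at rate d/2 each, and adaptive
nonsynonymous fixations at rate (d/2)·a/(1−a), which makes the expected
adaptive fraction of amino-acid fixations equal a. Sites are
independent (no linkage or coalescent structure — a stated non-goal),
and true counts are returned exactly. Defaults — 20 ingroup haplotypes,
2000 codons, θ = 0.28, d = 0.10 — yield expected counts (pS ≈ pN ≈ 280,
dS ≈ 100) of the magnitude seen in real fly polymorphism tables, large
enough that the ratio estimator's Jensen bias stays well inside the
±0.05 recovery tolerance the acceptance tests demand at
a ∈ {0, 0.3, 0.8} over 200 replicates.

## Site-model likelihood-ratio tests

Model optimization itself (e.g. with codeml) is out of scope; the
package consumes maximized log-likelihoods of the nested neutral (beta)
and positive-selection (beta + ω > 1 class) codon site models and
computes 2·(lnL_sel − lnL_neut), clipped at zero when the selection
model scores lower, against the upper tail of χ² with 2 degrees of
freedom (the conventional df for this pair; configurable). The tail is
verified against numerical integration to 1e-10. The Bonferroni helper
reproduces the dozen-subunit screening threshold 0.05/12 = 0.00417 (3
significant figures for display); because reasonable people disagree on
whether distinct subunits of one complex are multiple tests of one
hypothesis, the uncorrected mode is equally supported and neither is
asserted as correct.

## Pairing proportions and probe windows

Paired-nucleus proportions use the Wilson score interval — the score
test inverted in closed form — which behaves sensibly at the extreme
proportions pairing data produce (many species pair < 10% of nuclei).
The tests check the closed form against bisection of the score test and
verify 93–97% empirical coverage at nominal 95% for p ∈ {0.05, 0.285,
0.8}, n = 200, over 10,000 simulations. When a species was scored with
two probes, the table reports the absolute difference of the two
proportions: similar values indicate genome-representative rather than
locus-specific pairing behavior.

FISH target selection maximizes the number of oligo starts in a
fixed-width window (default 300 kb). With a constant denominator,
maximum density is maximum count, and a window achieving the maximum
can always be anchored at an oligo position, so a two-pointer sweep
over anchored candidates is exact; ties break to the smallest start for
determinism. A tiled (non-overlapping grid) mode is exposed behind a
flag for users who prefer disjoint windows. Equivalence with exhaustive
enumeration is tested on 500 random instances.

## Reproducibility machinery

All generators draw from named substreams derived from one root seed,
so adding a generator never perturbs existing fixtures, and outputs are
byte-identical across runs. `run_pipeline` validates its YAML
configuration fully before any stage runs, records input checksums,
timings and outputs in a manifest, and on rerun skips stages whose
inputs are unchanged. Problem sizes used by the test suite — e.g. 200
random trees for the Dollo oracle, 200 replicates per adaptive
fraction, a 20-genome screening benchmark with 150-residue families —
were chosen to give stable statistical verdicts at interactive
runtimes.

## Known limitations

* The built-in engine is desk-scale: quadratic alignment, no X-drop
  heuristics, approximate E-values. For genome-scale screens, run a
  dedicated search tool and ingest its tabular output.
* Absence calls inherit all caveats of homology search; the package
  quantifies protocol behavior on synthetic data but cannot rule out
  false negatives in heterochromatic or unassembled regions of real
  genomes.
* The MK module implements the unpolarized two-species test only; no
  polarized variant, no frequency filtering.
* Dollo parsimony reports minimal loss counts; it never overcounts a
  true Dollo history (tested), but real histories with more events than
  the minimum are indistinguishable from it.
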