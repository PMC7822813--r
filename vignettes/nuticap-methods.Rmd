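---
title: "Models and methods in nuticap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nuticap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuticap)
```

# Scope

`nuticap` implements the computational side of targeted high-resolution
chromosome conformation capture (Capture-C style 3C): in-silico digestion and
capture-probe design, decomposition of chimeric sequencing reads into
restriction slices, admixture-based quantification of inter-nuclear ligation
noise, a closed-form model of co-targeting enrichment bias, cis-normalised
profile construction, distance-decay interaction calling with marginal
posterior probabilities of contact (MPPC), regulatory-organisation summaries,
and a fully seeded read simulator used to validate the whole chain end to
end. Wet-lab steps, alignment to real genomes, HMM chromatin-state training
and differential expression are out of scope; externally produced alignments,
state labels and expression tables enter as plain tables.

# Digestion and coordinates

All coordinates are 0-based half-open internally, with the BED dialect on
disk. Digestion places a blunt cut immediately 5' of every motif occurrence
(the `^GATC` chemistry of DpnII), so every fragment except the first of a
chromosome begins with the motif, and the fragment set is an exact partition
of the genome: fragment lengths sum to chromosome length and concatenating
fragment sequences reproduces the input. Runs of `N` are not special-cased;
they simply contain no motif. The same convention is applied to read
sequences by `split_at_motif()`, which is what makes a ligation junction
(`...viewpoint | GATC reporter...`) separate into the two constituent slices.

The 16-fold complexity argument for 4-bp versus 6-bp cutters
(`complexity_fold()`) uses a uniform-base genome model: a k-bp site every
4^k bases.

# Inter-nuclear noise from species admixture

In a 1:1 two-species mix, a ligation joining DNA from two different nuclei is
visible as an inter-species chimera half the time (in general with
probability 2 p_A p_B). The mixing model is inverted by
`implied_internuclear()`: an observed chimera rate c implies an inter-nuclear
rate c / (2 p_A p_B). A 10--15% chimera rate at a 1:1 mix therefore implies
that 20--30% of reporters arise from ligation between nuclei. Confidence
intervals are Wilson score intervals, which remain stable at small counts;
the inversion is linear so the interval divides through. Mixture proportions
default to the cell-mix proportions; unequal ligatable-DNA content between
the species (e.g. different genome sizes or digestibility) is not corrected
by default -- the proportions are simply parameters, so a weighted value can
be passed instead.

# Co-targeting enrichment bias

A ligation product carries two restriction fragments; if probes target both,
either probe can pull the product down. Per capture round the retention is
the inclusion-exclusion probability

$$p = e_i + e_j - e_i e_j,$$

and double capture is modelled as two independent identical rounds, i.e.
$p^r$. The bias factor against an untargeted partner is
$\left((e_i + e_j - e_i e_j)/e_i\right)^r$: 1 when the partner is untargeted
or the viewpoint captures perfectly, and growing as the viewpoint's own
efficiency falls. Over a 5%--100% efficiency grid at single capture the
factor spans exactly 1- to 20-fold; the 5% grid floor is a toolkit constant
(bias is unbounded as $e_i \to 0$, and efficiencies below 5% are not worth
designing for). Because the bias is variable and fragment-specific, the
toolkit masks co-targeted fragments (`mask_cotargeted()`, setting them
missing rather than zero so they leave both the numerator and denominator of
any normalisation) instead of attempting correction. `cotarget_skew()`
provides the empirical diagnostic: the relative excess of a co-targeted
fragment's counts over the mean of its two immediate neighbours.

# Reporter extraction

Reads are split at the motif, slices are placed, classified and assembled
into reporter events:

* **capture** -- slice overlaps a target fragment; the viewpoint is the one
  whose target was hit, and reads hitting targets of two different
  viewpoints are ambiguous and dropped (counted, never silently).
* **exclusion** -- slice lies strictly closer than the exclusion radius
  (default 1000 bp; radius 0 disables the zone) to a target fragment without
  overlapping it. This removes undigested and re-ligated proximal material.
  The radius is a design choice, not a published constant.
* **reporter** -- everything else placed; **unmapped** otherwise.

PCR duplicates are collapsed on a key built from the sorted coordinates of
*all* placed slices plus the sonication ends (the outermost coordinates of
the molecule). Keying on the full slice set plus breakpoints is the stricter
of the plausible conventions: two independent molecules joining the same
fragment pair almost surely shear differently and are retained, while true
PCR copies are identical everywhere. Deduplication keeps first occurrences
and is idempotent.

The built-in placer is deliberately minimal: exact seed-and-verify matching
with unique 20-mer seeds, intended only for the simulator's rejection-sampled
genomes. Real data should be aligned externally and supplied as a placement
table (`read_id`, `slice_idx`, `chrom`, `start`, `end`, `strand`).

Capture enrichment is reported as observed over uniform expectation: the
on-target read fraction divided by `n_target / n_total` fragments. With
97.70% on-target sequencing against a single fragment of the ~6.4 million in
a 4-bp digest of the mouse genome this reproduces the ~6.3-million-fold
figure quoted for titrated double capture.

# Profiles

Counts are normalised to reporters per 100,000 cis reporters (masked
fragments excluded from both sides of the division), proportionally assigned
to 250-bp bins (each fragment contributes in proportion to its overlap with
the bin, conserving total mass exactly), and smoothed with an 11-bin moving
mean. The description "each bin ±2.5 kb (11 bins total)" is internally
inconsistent at 250-bp bins (±2.5 kb would be 21 bins); the literal 11-bin
window is the default here and the width is configurable. Edge bins average
over the available neighbours rather than NA-padding, so tracks have no
missing leading or trailing values.

# Interaction calling

Contact frequency decays with distance. The expectation is fit per
log-spaced distance bin (default 16 bins spanning 2.5 kb -- 1 Mb, the span
within which targeted 3C interactions concentrate; fragments outside the
span are not called) as a 10% trimmed mean, then forced monotone
non-increasing by pooled-adjacent-violators (`stats::isoreg` on the negated
values). Empty bins inherit the nearest fitted value.

Residuals (observed minus expected) are then z-normalised to mean 0 / SD 1
*within each distance bin* (population SD), which damps overcalling in
sparse distance strata. Bins with fewer than 5 fragments are merged with
their nearest occupied neighbour first; a bin with zero spread yields zero
residuals with a warning. The centring/scaling step is exactly idempotent.

Calling uses a spike-and-slab model on the z-scores:

$$z_j = \gamma_j \beta_j + \epsilon_j,\qquad \epsilon_j \sim N(0,1),\quad
\gamma_j \sim \mathrm{Bernoulli}(\pi),\quad \beta_j \sim N(\mu_\beta,
\sigma_\beta^2)$$

fit by Gibbs sampling; the MPPC of fragment j is the posterior mean of
$\gamma_j$, and fragments with MPPC >= 0.01 are significant, with directly
adjacent significant fragments merged into runs. Defaults: $\pi = 0.01$,
slab $N(3, 2^2)$ -- a positive slab mean encodes that contacts are
enrichments, and ties break toward no call. The sampler is per-fragment
independent by default; an optional exponential spatial coupling
$\omega = \exp(-\lambda\,|\Delta d|)$ on the prior log-odds of neighbours is
provided but off by default. This is intentionally simpler than a full
joint reversible-jump treatment with spatial peak kernels: the per-distance-
bin residual normalisation is the methodological delta implemented here, and
for a single observation the sampler's MPPC agrees with the analytic
two-component posterior (checked in the tests to Monte-Carlo accuracy). A
seed is mandatory everywhere randomness enters; identical seeds give
identical output.

# Regulatory organisation

Significant prey fragments are intersected with open-chromatin element
annotations (8 classes: strong/weak enhancer, strong/weak promoter,
promoter-CTCF, two CTCF classes, background) using a >= 1 bp overlap rule
(configurable); one pair per (viewpoint, element) is kept at the maximum
MPPC. On top of the pairs:

* `hub_size()` -- distinct interacting promoter elements per viewpoint.
* `enhancer_summary()` -- distinct interacting enhancers per promoter with
  the 0/1/2/3/>=4 grouping.
* `directionality()` -- upstream/downstream is defined in gene orientation
  (coordinate sign flipped for minus-strand promoters). Promoters qualify
  with >= 2 distinct enhancers; an enhancer midpoint exactly on the TSS is
  excluded with a counter. A promoter is unidirectional when all enhancers
  fall on one side; among bidirectional promoters with >= 4 enhancers the
  imbalance flag marks at least two more enhancers on one side. The
  construction is exactly mirror-symmetric under simultaneous strand flip
  and coordinate reflection (property-tested).
* `class_enrichment()` -- observed class-overlap fraction of prey divided by
  the mean over seeded random placements of the same number and sizes of
  intervals within the same chromosome.
* `metaprofile()` -- coverage averaged over intervals, anchored at interval
  edges with the body length-normalised to a common grid by linear
  interpolation, flanks at base resolution, minus-strand intervals flipped.
* `expression_grouping()` -- group means and inclusive >= 4-fold change
  flags between two named stages; the grouped tables are emitted for
  standard tests (Mann-Whitney, Kruskal-Wallis, ...) rather than
  re-implementing them.

Promoter-promoter interactions remain countable after co-target masking
because calls at fragments *adjacent* to a masked target still overlap the
promoter's element interval.

# The simulator

`simulate_library()` draws, per viewpoint: with probability `rho` an
inter-nuclear partner (species from the mixture, then a uniform fragment of
that species -- maximum-entropy noise, matching the observation that such
events mostly surface as trans signal); otherwise an intra-nuclear ligation,
trans with the background rate and cis with probability proportional to
$(|d| + d_0)^{-\alpha}$ times any spike-in fold. Defaults $\alpha = 1$,
$d_0 = 1000$ bp give a typical 3C decay shape over the 2.5 kb -- 1 Mb span;
only the span is quoted in the source experiments, so the decay law itself
is a modelling choice, fixed once. Genomes are uniform-base with rejection
until all 20-mers are unique, so exact placement is unambiguous; chromosome
name spaces are species-prefixed and disjoint. Each retained event becomes a
molecule: a sonication-trimmed suffix of the viewpoint fragment ligated to a
trimmed prefix of the reporter fragment, with exactly one motif copy at the
junction; PCR duplicates are verbatim copies at the configured rate, and
paired-end emission trims both molecule ends at the configured read length.
Chromosome-first fragments (no leading motif) and fragments shorter than the
minimum sonication piece (30 bp, above the 20-mer placement seed) are never
drawn as partners: they cannot produce a canonical junction or a placeable
slice.

What the simulator does *not* emulate: sequencing errors and quality
realism, mappability structure, the inflated sub-4-kb proximal signal of
disrupted nuclei (the inter-nuclear fraction is a single noise budget), or
unequal ligatable content between species. Passing round-trip and recovery
tests therefore demonstrates correctness of the computational chain on
clean, placement-unambiguous data -- not robustness to alignment artefacts
in real genomes.

# Problem sizes and test design

The test suite validates on deliberately small instances chosen to keep the
statistical properties meaningful: 30--100 kb chromosomes (a few hundred
fragments), 2,000--10,000 events per viewpoint for round-trip and spike-in
recovery, 20,000 events for the admixture closure (binomial SE on the
implied rate ~0.5%), 10^5 draws for Monte-Carlo checks of the capture model
(3 SE agreement), and 2,000 null z-scores for sampler calibration.
Stochastic assertions use 3-sigma bounds so that a fixed seed does not sit
in the rejection region of a nominally valid run.

# Known limitations

* The bias model treats capture rounds as independent and identical;
  saturation or probe depletion between rounds is not modelled.
* The spike-and-slab caller does not share information across fragments by
  default; broad gentle enrichments spanning many fragments are better
  served by enabling the spatial coupling.
* The built-in exact placer is not an aligner: real-genome data must arrive
  pre-aligned.
* TSS-to-fragment assignment supports both a point rule and a promoter
  window rule (`tss_to_fragments()`); the point rule is the default, and
  designs that intend probes at both fragment ends of a promoter window
  should use the window rule explicitly.
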