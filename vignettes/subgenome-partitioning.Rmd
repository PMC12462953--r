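---
title: "Divergence-based subgenome partitioning: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence-based subgenome partitioning: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyphase)
```

## The problem and the model

An allotetraploid genome carries two subgenomes inherited from two diverged
progenitor species. When neither progenitor has a sequenced (or extant)
diploid descendant, subgenome assignment by direct progenitor comparison is
impossible, and transposon-based phasing fails when the two subgenomes have
similar repeat content. `polyphase` implements a third route that needs only
a related diploid reference species: because the two progenitor lineages
accumulated mutations at different rates (different divergence times from
the common ancestor, or asymmetric post-polyploidization degeneration), the
two members of each homoeologous chromosome pair sit at measurably
different sequence distances from *any* related reference. Within each
pair, the member with the smaller distance is closer to the ancestral state
and is assigned to one subgenome; the more diverged member to the other.
The labels are arbitrary; the method cannot tell which subgenome is
maternal and which paternal.

Distances are Mash distances: each chromosome is reduced to the set of its
canonical k-mers, the Jaccard index *j* between two chromosomes' sets is
estimated from bottom-s MinHash sketches, and

$$D = -\frac{1}{k}\,\ln\frac{2j}{1+j},$$

which under a Poisson model of random site mutation estimates per-base
divergence. `D` is capped at 1 when no hashes are shared (the logarithm is
undefined at `j = 0`); such records are flagged.

## Parameters that matter

* **`k` (default 21).** Matches the 21-mer convention of the k-mer analyses
  this workflow accompanies. `k` must be odd so no k-mer equals its own
  reverse complement; even `k` would make canonical counting ambiguous for
  palindromes. Larger `k` increases specificity but loses sensitivity at
  high divergence (at `D` ≈ 0.15 and `k` = 21 only ~4% of k-mers survive
  unmutated).
* **`s` (default 5000).** The bottom-sketch size. The standard error of the
  Jaccard estimate scales as `sqrt(j(1-j)/s)`; at `s` = 5000 the resulting
  distance noise (roughly 2–3% of `D` in the regimes exercised here) is an
  order of magnitude below typical between-subgenome gaps. `s = Inf`
  ("exact mode") retains every hash and reproduces the exhaustive-sketch
  regime in which the estimate equals the brute-force Jaccard index
  exactly — equivalent to choosing a sketch size far above any
  chromosome's distinct k-mer count.
* **Hashing.** A seeded splitmix64 mix of the 2-bit k-mer encoding; the top
  53 bits are kept so hash values are exactly representable as R doubles
  and sketches are portable across platforms. The hash function and seed
  are recorded in the sketch JSON; interoperability with other tools' exact
  hash values is deliberately not promised.
* **Case policy.** Soft-masked (lowercase) bases are folded to uppercase by
  default; hard-masked (`N`) windows are always dropped. This mirrors the
  design of masked-versus-unmasked robustness checks: masking removes
  k-mers but does not move the surviving ones.
* **`tau` (default 0.05).** A homoeolog pair is flagged ambiguous when its
  *relative* gap `(d_high - d_low) / mean(d_low, d_high)` falls below
  `tau`. The gap is relative rather than absolute so one threshold works
  across reference species at very different phylogenetic distances: an
  absolute gap of 0.005 is decisive at `D` ≈ 0.03 and meaningless at
  `D` ≈ 0.2. The default separates cleanly: simulated asymmetric presets
  give relative gaps around 0.6, while equal-rate controls concentrate
  below 0.05. Pairs are still labeled when ambiguous; the flag, not the
  label, carries the uncertainty.
* **`copies_per_ref` (default 2).** Tetraploid pairing. Higher ploidies are
  accepted by the greedy assignment core but the two-member pair table and
  the partition rule target the tetraploid case.

## Pairing and the decision rule

Homology between polyploid and reference chromosomes is inferred from the
distance matrix itself by a global greedy pass: all (reference, query)
records ascending by distance, binding each query chromosome to the first
reference with a free slot. On block-structured matrices — which is what
divergence-asymmetric tetraploids produce — the greedy optimum coincides
with the exhaustive minimum-total-distance pairing (verified against an
enumeration oracle in the tests). Users with externally derived homology
(e.g. from collinearity analysis, the workflow the distance method was
validated against) can impose it with a pairs file; distances are then filled from the
matrix, and labels always follow the distances, never the file's column
order. Ties on equal distance
are broken lexicographically so results are independent of input order.
Unbound chromosomes (fusions, count mismatches) are reported, never
silently dropped.

Assignment is per-pair and independent — exactly what per-chromosome
divergence bar plots encode — so one aberrant pair cannot cascade into
neighboring assignments. The summary's verdict is `"indeterminate"` when
more than half of the pairs are ambiguous; this operationalizes the known
failure mode on genomes whose subgenomes carry indistinguishable
divergence (autopolyploid-like histories), where no threshold-free method
of this family can succeed. The 50% convention is this package's, chosen
so that a majority of confidently separated pairs is required before the
genome is called partitioned. With several reference species, per-reference
partitions are combined by majority vote (`consensus_partition()`), which
is the recommended way to resolve borderline cases.

## The read-based ploidy module

Heterozygous k-mer pairs — two canonical k-mers differing at exactly one
position, both above a depth cutoff — are found by per-position wildcard
bucketing over *both* orientations of every k-mer, so strand
canonicalization cannot hide a pair (an implementation subtlety: a SNP can
flip which strand is lexicographically smaller). K-mers participating in
more than one pair are discarded to suppress repeat-family artifacts. Each
isolated SNP contributes about `k` pairs, one per overlapping window.

The depth cutoff defaults to the first local minimum of the
moving-average-smoothed k-mer depth histogram (the valley between the
sequencing-error peak and the first genomic peak); error-free histograms
with no leading peak yield a cutoff of 1, and strictly decreasing
histograms raise an error asking for an explicit cutoff (the conventional
value for deep short-read data, 20, is available as a flag).

Each pair is summarized by `(covA, covB)`, coverages of its two members
with `covA >= covB`; the minor fraction `covB/(covA+covB)` lies in
`(0, 0.5]`. The minor-fraction convention (rather than an arbitrary
member's fraction) makes genotype-class centers unique. Genotype classes
`(m, b)` — total allele multiplicity and minor copy number: AB = (2,1),
AAB = (3,1), AABB = (4,2), AAAB = (4,1), … — predict coverages
`((m-b)c, bc)` where `c` is the haploid (1n) k-mer coverage.

**Coverage estimation.** `c` is fit by grid search, modelling each pair's
`(covA, covB)` as an ordered pair of independent Poisson counts under a
mixture over genotype classes, with mixture weights profiled out by EM at
every candidate `c`. Per-pair log-likelihood is floored (at −15) for
robustness to stray repeat-derived pairs, and the grid is capped at the
99th percentile of pair totals so a handful of high-coverage repeat pairs
cannot stretch it. A naive nearest-center squared-distance fit is
degenerate here: halving `c` doubles the density of predicted centers and
always reduces the distance, so the likelihood — in which a cloud
shattered across several narrow Poisson components pays an entropy
penalty through the mixture weights — is what makes `c` identifiable.
One ambiguity is fundamental: data whose every occupied class has a
double-multiplicity counterpart (e.g. a pure balanced smudge) fit `c` and
`c/2` essentially identically (the halved interpretation can gain a few
10⁻⁴ nat/pair by mopping Poisson tails with its extra classes, far below
the ≥0.2 nat/pair separating genuinely different coverages). Candidate
optima within 0.01 nat/pair are therefore treated as tied and resolved
toward the largest coverage, i.e. the smallest-multiplicity, most
parsimonious genotype interpretation: a lone smudge at `(2c, 0.5)` is
read as AB, not AABB. Real tetraploid data escape the tie because residual
within-subgenome heterozygosity populates an AB smudge at `2c` alongside
the dominant AABB smudge at `4c`, pinning `c`. Estimation hypothesizes
classes up to multiplicity 4 by default (`max_ploidy = 4`); classification
afterwards uses the full class set (default 8).

**Classification.** Pairs are assigned to the maximum-posterior class
under the fitted mixture (EM weights as priors). Posterior rather than
flat maximum-likelihood assignment matters in the tails: with flat priors
a minor neighboring class (e.g. AAABB next to AABB) soaks up the sampling
tail of a dominant class; the fitted weights suppress this. The summary
reports class proportions and the modal genotype — the quantity whose
AABB-majority signature distinguishes an allotetraploid read set from a
diploid one.

The estimated `c` is k-mer-space coverage, as is conventional for this
kind of analysis. The read simulator reports the corresponding expectation
`cov * (read_len - k + 1)/read_len * (1 - e)^k` as metadata, and that — not
the nominal per-base depth — is the ground truth the tests compare against.

## The synthetic-data generator

`make_allotetraploid()` emulates the scenario the partition method is built
for: an ancestral genome (default 10 chromosomes × 200 kb, GC 0.40,
fish-like composition at desk scale), three independent branches — a
reference lineage (default rate 0.05 substitutions/site) and progenitors B
(0.02) and C (0.08) — and fusion of B and C into a tetraploid whose
chromosome names are shuffled so the truth is not encoded in labels. The
branch-rate asymmetry, not its absolute scale, is what the method reads;
the defaults place distances in the neighborhood suggested by synonymous
substitution rate peaks of real tetraploid loaches (intra-genome ~0.28,
inter-species ~0.4) while keeping every test fast. Substitutions follow a
uniform (Jukes–Cantor-like) base exchange without transition bias — rate
asymmetry is the only signal the method needs — and rates are applied once
per branch without multiple-hit bookkeeping, a negligible bias below
0.1 substitutions/site. Indels are geometric (mean 3 bp) at a light
default rate; repeats are a single monomer copied with 2% per-copy
mutation to a target genomic fraction, with every insertion recorded as a
0-based half-open BED interval so hard-masking can be tested. Reads are
uniform single-end with per-base substitution errors. Everything is
deterministic per seed, with RNG state restored afterwards.

What the generator does *not* emulate: realistic transposon family
dynamics, homoeologous exchange, chromosomal rearrangement (off by
default, matching the karyotype conservation of the clade that motivated
the method), GC-biased coverage, indel sequencing errors, and paired-end
structure. Passing tests therefore demonstrate correctness of the
method's logic under its stated model — divergence-rate asymmetry readable
through k-mer sketches — not robustness to every artifact of real
assemblies; the masked/unmasked invariance check probes the repeat
sensitivity that is this method's most common practical concern.

## Numerical choices and degenerate inputs

* Exhaustive sketches (`s = Inf`) equal brute-force Jaccard to machine
  precision; this is tested, not assumed.
* `j = 0` → distance capped at 1.0 and flagged `capped`.
* Equal-distance pairing ties and equal-distance partition ties break
  lexicographically by chromosome name; partition ties are additionally
  flagged ambiguous.
* Chromosomes yielding no valid k-mers (all-N, shorter than `k`) are
  excluded from matrices with a warning; an entirely invalid genome is an
  error.
* Characters outside the IUPAC alphabet are hard errors naming the
  offending position; IUPAC ambiguity codes are treated like `N` (window
  skipped).
* `k` is limited to 31 so the 2-bit encoding fits one 64-bit word.
* Coverage estimation requires at least 5 pairs (50+ recommended); the
  EM grid is thinned deterministically to at most 5000 pairs, far above
  what the fit needs.

## Problem sizes used by the checks

The bundled tests and the acceptance script run entirely on simulated
data at sizes chosen to finish comfortably on a laptop core: 200 kb
chromosomes (10 per genome, 20 seeds for the partition recovery and
negative control, 10 for masking invariance), 1 Mb sequences for rate
recovery (rates 0.01/0.02/0.05), and 500 kb genomes at 15× per copy for
the read-based module. The acceptance script scales the seed counts down
further (5–10 replicates per property) and reports every quantity it
computes as JSON.

## Known limitations

* The method reads *relative* divergence; it cannot partition subgenomes
  with indistinguishable histories (the equal-rate control returns
  `indeterminate` by design), and near-equal distances against one
  reference should be re-tested against additional reference species.
* Mash distance sees k-mer content only: homoeologous exchanges, segmental
  allopolyploidy, and large structural events blur the per-chromosome
  signal and are invisible to it.
* Results depend on `k` and `s`; the defaults are sensible for
  chromosome-scale comparisons at the divergences tested, but extreme
  divergence (where `(1-D)^k` underflows the sketch) needs smaller `k`.
* A pure balanced smudge cannot reveal its multiplicity (the `c` vs `c/2`
  tie above); the reported tie rule makes the choice explicit rather than
  hiding it.
* The maternal/paternal identity of subgenomes is out of reach by
  construction.
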