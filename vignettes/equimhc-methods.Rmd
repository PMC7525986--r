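---
title: "Models and methods behind equimhc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind equimhc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(equimhc)
```

## Scope and scientific setting

`equimhc` analyses the second exon of MHC class II *DRB* and *DQB* genes
in equids. Exon 2 encodes the beta1 domain that forms the antigen binding
site (ABS) of class II molecules, and is the classical unit for studying
balancing selection at the MHC: high polymorphism, an excess of
nonsynonymous substitution at ABS codons, and trans-species allele
sharing are its expected signatures. The package implements the full
desk-side analysis chain: gene presence/absence from per-base coverage,
allele calling from tagged amplicon reads, alignment diversity indices
and allele sharing, codon-based selection tests (global and site-wise
with a two-method consensus), and a single-breakpoint recombination
screen. Seeded simulators generate inputs with the statistical structure
each stage assumes, so the whole chain is testable without external
data.

## Data containers

A `codon_alignment` is a tibble (one row per sequence: `id`, `species`,
`locus`, `sequence`, `has_stop`) with alignment-level attributes. On
construction, sequences are upper-cased, `frame_offset` leading bases
and any trailing partial codon are trimmed, and internal stop codons are
flagged. Stop-flagged sequences (pseudogene-like variants) stay in the
alignment for diversity counts but are excluded from all rate and
selection computations. The default `frame_offset` is
`exon2_length %% 3`, which for the 269-bp DQB and 260-bp DRB amplicons
yields the 89- and 86-codon reading frames of the beta1 domain. DRB
amplicons are 260 bp because the nested reverse primer sits on the
exon-intron boundary, so nine 3'-terminal exon nucleotides are never
sequenced.

Coordinates are 0-based half-open internally (BED-style arithmetic);
every human-readable report is 1-based. IUPAC ambiguity codes other than
N are rejected outright because codon counting is undefined for them.
Trees are `ape::phylo` objects throughout.

## Presence/absence from coverage

The statistic is the fraction of a gene's positions covered by at least
one read. A gene is called absent when this fraction is strictly below
the threshold (default 0.10, i.e. at least 90% zero-covered bases). The
strict inequality means a gene at exactly 10% is called present. Reports
print integer percentages; the rounding convention is round-half-up.
Depth of 1 counts as covered regardless of mapping quality - any MQ
filtering belongs upstream, in whatever produced the depth table.
Duplicate depth rows for one position are resolved by the maximum, which
is deterministic and conservative for presence calling. The statistic
cannot distinguish "missing from the genome" from "undetected by the
sequencing protocol"; both interpretations remain open, as for any
coverage-based call.

## Allele calling

Amplicon reads are demultiplexed by exact MID prefix match (tags must be
mutually non-prefix), sorted to loci by primer identity at a 0.90
cutoff, primer-trimmed allowing two mismatches per primer, and clustered
at 0.99 identity. Identity is ungapped end-to-end (matches over the
longer length): reads are same-length amplicons and the logic under test
is identity clustering, not gapped alignment - which is also why the
read simulator introduces substitutions only, no indels. Clustering is
greedy over a canonical ordering (length descending, then lexicographic,
then read ID), assigning each read to the best-scoring existing centroid
at or above the cutoff; this makes results independent of input order.
Cluster consensus is the per-column majority; ties are resolved by base
order A < C < G < T with a warning, because downstream codon analysis
needs unambiguous bases.

A consensus sequence becomes an allelic haplotype only under the
two-independent-source rule: at least two distinct PCR runs, or one PCR
plus one of a Sanger trace, a clone, or a genome-derived haplotype. No
minimum cluster size is imposed beyond that rule. Validated alleles are
named `<SpeciesCode>-<Locus>*<serial>` (e.g. `Eqca-DQB1*0001`), with the
four-letter species code formed from two letters of genus and epithet
and serials assigned in first-seen order within species and locus; the
emitted table is the authoritative name mapping, since serial numbering
is otherwise arbitrary.

## Diversity indices and allele sharing

Variable nucleotide positions (VNP) count columns with at least two
distinct bases; parsimony-informative positions (PIP) require at least
two distinct bases each in at least two sequences, so PIP <= VNP always.
Two gap policies are supported: complete deletion (columns containing
any gap or N are dropped entirely; the default, mirroring the common
default of desktop phylogenetics suites) and pairwise deletion (gaps
ignored within each column or pair). The choice is an attribute of the
alignment, so one decision governs distances, diversity and rate
computations consistently.

Trans-species sharing reports identical nucleotide sequences observed in
two or more species within a locus. Sequences identical between two
loci of the same species are reported separately as inter-locus
identity - a possible footprint of concerted evolution or shared
primer capture, not of trans-species polymorphism.

## Pairwise rates and the global Z-test

Synonymous/nonsynonymous counting follows the Nei-Gojobori (1986)
pathway method. Site counts use the universal code with changes to stop
codons excluded from the mutational target set: at each codon position
the synonymous fraction is taken over the non-stop single-base changes,
so S + N = 3 per codon. Differences between codons are averaged over all
orderings of the differing positions; orderings passing through a stop
codon are excluded, with a documented fallback to all orderings in the
rare case that every ordering hits a stop. Proportions are corrected
with the one-parameter (Jukes-Cantor) formula
`d = -(3/4) ln(1 - (4/3) p)`; a proportion at or above 0.75 leaves the
rate undefined and the pair flagged as saturated.

The global test averages dN and dS over all sequence pairs and tests
dN = dS against the one-tailed alternative dN > dS (positive selection).
The variance of the mean difference is estimated by bootstrap over codon
sites (default 1000 replicates, seeded); the bootstrap is chosen over a
delta-method variance because it is assumption-light and is the usual
configuration of the desktop suites that popularised this test.
Degenerate inputs - no variation, or zero bootstrap standard error -
return p = 1 by convention rather than NaN.

## Site-wise selection and the consensus rule

Two in-package methods feed the consensus:

* **Counting (SLAC-style).** Ancestral codons are reconstructed per site
  by Fitch parsimony over the 61 sense codons (ties broken
  deterministically to the first codon in T/C/A/G order, and logged by
  construction). Codon changes along branches are decomposed into
  synonymous/nonsynonymous fractions by the same pathway averaging as
  the pairwise counter. The observed nonsynonymous count is compared
  with its neutral expectation (the site's nonsynonymous site fraction)
  by a binomial tail; fractional counts use the regularised
  incomplete-beta extension of the binomial tail.
* **Likelihood (FEL-style).** Per site, a two-rate MG94xJC model
  (synonymous rate alpha, nonsynonymous rate beta, uniform codon
  frequencies) is maximised on the fixed tree and compared with the
  one-rate null beta = alpha by a 1-df likelihood-ratio test. The
  generator is symmetric under uniform frequencies, so transition
  probabilities come from a symmetric eigendecomposition; the
  optimisation profiles the overall rate within an outer search over
  omega = beta/alpha, reusing one eigendecomposition per omega.
  Invariant sites short-circuit to alpha = beta = 0, p = 1.

A codon is consensus-positive (or -negative) iff at least two methods
call it so at their thresholds. The per-method site threshold defaults
to p <= 0.1, conventional for these site tests and configurable.
Externally computed site tables (Bayesian or episodic-model tools) can
be supplied as extra columns of the same consensus; they are not
re-implemented here. When the recombination scan declares a breakpoint,
site methods run per partition with independent per-partition trees and
the tables are concatenated with original codon numbering.

The SAAS reports cross-tabulate observed amino acid substitutions
(relative to the per-site majority residue) with ABS membership and
consensus-selected status, and - when an external predictor table is
supplied - compute the "deleterious by both tools" intersection. ABS
positions are a required configuration input; the bundled example list
derives from the classical human class II beta1 peptide-contact
residues and is exactly that, an example.

## Phylogenetics engine

Distances are Jukes-Cantor-corrected mismatch proportions under the
alignment's gap policy, with saturated pairs capped at 5.0
substitutions/site (a logged sentinel that keeps neighbor-joining
defined). Trees are standard NJ (`ape::nj`) with negative branch lengths
clamped to zero and the deficit moved to an adjacent branch. Bootstrap
support resamples columns with replacement (seeded) and scores
bipartitions of the point-estimate tree. Branch lengths are optimised by
maximum likelihood under JC69 (delegated to `phangorn::optim.pml`); the
per-site JC69 pruning likelihood is implemented in-package because the
recombination criterion needs per-site log-likelihood vectors, and is
cross-checked against the independent phangorn implementation in the
tests. JC69 is deliberately the only likelihood model: the screen needs
a likelihood, not a model-selection study; a kappa extension is noted as
future work.

## Single-breakpoint recombination screen

The full alignment is fitted with one NJ topology and ML branch lengths;
each candidate breakpoint (codon boundaries only, so partitions stay in
frame; interior margin of `min_partition = 10` codons) is fitted with
two independent per-partition trees, re-estimating the NJ topology per
partition. Fits are compared by the small-sample AIC,
`cAIC = -2 lnL + 2k + 2k(k+1)/(n-k-1)`, with k counting branch lengths
plus one bookkeeping parameter per tree topology and n the number of
nucleotide sites; the two-partition fit sums both trees' parameters over
the same n. Recombination is declared iff the best two-partition cAIC
undercuts the single-tree cAIC (delta cAIC < 0), with no secondary
significance test - the information criterion is the decision rule.
This NJ-plus-JC69 scan is a desk-scale surrogate for genetic-algorithm
breakpoint searches: it trades topology-search breadth for speed and
determinism, which is the right trade for 60-90-codon exon alignments.

## Simulators: what they emulate, and what they do not

The codon simulator evolves sites independently under an MG94xHKY-style
process over the 61 sense codons: single-nucleotide exchanges,
transitions scaled by kappa (default 2), nonsynonymous exchanges scaled
by the site class's omega, uniform codon frequencies by default. Rates
are normalised so one branch-length unit is one expected substitution
per codon under neutrality; classes with omega > 1 evolve
proportionally faster, as selection should. The read simulator decorates
alleles with MID + forward primer and reverse-complemented reverse
primer and applies i.i.d. substitution errors. The depth simulator draws
Poisson coverage with optional dropout for present genes and constructs
absent genes with >= 90% zero positions. A fixed 12-tip "equid-like"
topology (caballine clade versus ass and zebra clades) ships for
demonstrations; it is a fixture, not a claim about the true tree.

Real data differ in ways these generators do not model: indels and PCR
chimeras in amplicons, quality-score structure, ancient-DNA damage,
base-compositional bias in coverage, non-uniform codon frequencies, and
rate variation beyond the two-class omega structure. Passing tests
therefore demonstrate correctness of the statistics under their own
assumptions and sensible operating characteristics - not that every
biological complication is handled.

## Calibration experiments and problem sizes

The test-suite experiments fix their conditions as follows, chosen once
as the package's own study design:

* **Z-test calibration and power**: 20-tip star phylogeny, terminal
  branches 0.1 substitutions/codon (mean pairwise divergence about
  6-7% per nucleotide site, in the range of interspecific MHC exon-2
  comparisons), kappa = 1 (matching the counting method's
  no-transition-bias assumption, the correct generating model for
  type-I calibration), 90 codons, 200 null and 100 selected replicates,
  300 bootstrap replicates per test. With kappa > 1 the NG86-based test
  becomes conservative; that bias is a property of the method, not of
  this implementation, and is deliberately kept out of the calibration.
* **Site-method recovery**: the 12-tip demo topology scaled x4,
  60 codons with 18 codons at omega = 5 against a background of
  omega = 0.3, 50 replicates; enrichment is scored as a
  Haldane-corrected odds ratio over the consensus-positive calls.
* **Breakpoint recovery**: 8 taxa, 90 codons, conflicting topologies
  obtained by relabelling tips of one random tree (total length 3
  substitutions/codon), breakpoint at codon 45, candidate grid step 3
  with local refinement; 50 recombinant and 100 single-topology
  replicates.
* **Allele pipeline**: 2-6 alleles at >= 3 pairwise differences,
  error rate 0.003/base, 20 copies per allele per run, two runs,
  20 seeds.

These sizes keep the default suite deep but desk-scale; the simulations
are the quantities the acceptance script recomputes, and no empirical
number is stated here that the tests do not themselves compute.

## Numerical choices and degenerate inputs

* JC rate undefined at p >= 0.75: flagged, never silently truncated;
  distances capped at 5.0 only for tree building.
* Z-test with zero bootstrap SE: p = 1.
* FEL underflow guarded by per-node rescaling; alt-model log-likelihood
  floored at the null's so LRT >= 0.
* Fitch ties, consensus-base ties and locus-assignment ties all break
  deterministically (first codon in T/C/A/G order; A < C < G < T; first
  locus in configuration order) so reruns are byte-identical.
* Single-sequence alignments report NA - never 0 - for undefined
  indices.

## Known limitations

Codon-model extensions (kappa in the likelihood engine, non-uniform
codon frequencies in FEL), multiple-breakpoint scans, chimera detection
and quality-aware denoising are out of scope. The global Z-test inherits
NG86's conservativeness under transition bias. Bootstrap supports on
very short partitions are noisy, and the cAIC screen's power drops when
partition-specific signal is weak - both visible in the simulation
experiments above.
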