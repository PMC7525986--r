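# equimhc

Diversity and selection analysis of MHC class II **DRB**/**DQB** exon 2
sequences in the horse family (*Equidae*).

The second exon of class II beta-chain genes encodes the beta1 domain
that forms the antigen binding site (ABS). Balancing, pathogen-driven
selection leaves three classical signatures there: high allelic
polymorphism, an excess of nonsynonymous over synonymous substitution
(dN/dS = omega > 1), and trans-species sharing of alleles. `equimhc`
implements the full desk-side analysis chain used to detect them:

* **Presence/absence** of genes from per-base coverage: the
  non-zero-coverage fraction (share of positions with depth >= 1), with
  absence called strictly below 10%.
* **Allele calling** from MID-tagged amplicon reads: exact-prefix
  demultiplexing, primer sorting at 90% identity, primer trimming,
  greedy 0.99-identity clustering with majority consensus, and the
  two-independent-source validation rule with Klein-style naming
  (`Eqca-DQB1*0001`).
* **Diversity**: variable (VNP) and parsimony-informative (PIP)
  nucleotide positions under complete- or pairwise-deletion gap
  policies, plus trans-species allele sharing.
* **Selection**: Nei–Gojobori pathway counting with Jukes–Cantor
  correction, `d = -(3/4) ln(1 - (4/3) p)`; a codon-based Z-test of
  dN = dS against dN > dS with bootstrap variance over codon sites; and
  two site-wise methods — parsimony-based counting (SLAC-style) and a
  per-site two-rate likelihood (FEL-style, MG94xJC) — combined by the
  rule that a codon counts as selected only when at least two methods
  agree. Reports annotate ABS membership and selected amino acid sites
  (SAAS), and can intersect external deleteriousness predictions.
* **Recombination**: a single-breakpoint scan comparing one tree
  against two per-partition trees by the small-sample AIC
  (`cAIC = -2 lnL + 2k + 2k(k+1)/(n-k-1)`), declaring a breakpoint iff
  delta cAIC < 0.
* **Simulators** for codon alignments with site-class-specific omega
  (MG94xHKY-style), recombinant alignments with a known breakpoint,
  decorated amplicon reads, and depth tracks — so every stage is
  exercisable and testable without downloads.

Everything is tidyverse-native: alignments, reads, depth tables and all
reports are tibbles; fitted objects have `tidy()`/`glance()` methods and
`autoplot()` visualisations; `run_pipeline()` drives the whole chain
from a YAML configuration with seeded, byte-identical reruns.

## Worked example

Simulate an exon-2-like alignment on a 12-tip equid-like tree in which
18 of 60 codons evolve under strong positive selection (omega = 5)
against a purifying background (omega = 0.3), then test for selection:

```r
library(equimhc)

tree  <- demo_equid_tree(scale = 4)
model <- site_class_model(
  class_of_codon = rep(c("abs", "background"), c(18, 42)),
  omega_by_class = c(background = 0.3, abs = 5), kappa = 1
)
aln <- simulate_codon_alignment(tree, model, n_codons = 60, seed = 11)

tidy(global_z_test(aln, n_boot = 1000, seed = 1))
#> # A tibble: 1 × 5
#>   term    estimate statistic std.error p.value
#>   <chr>      <dbl>     <dbl>     <dbl>   <dbl>
#> 1 dN - dS  -0.0692    -0.918    0.0754   0.821

cons <- site_selection(aln, config = locus_config("DQB1", 269, abs_codons = 1:18))
dplyr::filter(cons, consensus == "positive")
#> # A tibble: 3 × 7
#>   codon class_slac class_fel n_positive n_negative consensus is_abs
#>   <int> <chr>      <chr>          <dbl>      <dbl> <chr>     <lgl>
#> 1     1 positive   positive           2          0 positive  TRUE
#> 2    14 positive   positive           2          0 positive  TRUE
#> 3    15 positive   positive           2          0 positive  TRUE
```

The global average is dominated by the purifying background (negative
dN − dS, p = 0.82: no alignment-wide positive selection), while the
site-wise consensus pinpoints individual codons under strong positive
selection — all inside the simulated ABS. This is exactly the pattern
expected at real MHC loci, where selection concentrates on
peptide-contact residues.

A recombinant alignment spliced at codon 30 from two conflicting
topologies is recovered by the breakpoint scan:

```r
rec  <- make_recombinant(left, right, breakpoint = 30)  # see ?make_recombinant
sbp_scan(rec, grid_step = 3)
#> Single-breakpoint recombination scan (cAIC)
#>   single tree cAIC = 2481.28; best two-partition cAIC = 2123.18 at codon 30
#>   delta cAIC = -358.10 -> recombination declared (breakpoint 30)
```

The end-to-end pipeline runs from a YAML configuration; a fully
simulated demonstration data set ships with the package:

```r
cfg <- demo_pipeline(tempfile("demo"), seed = 5)
res <- run_pipeline(cfg)
res$truth_summary
#> # A tibble: 2 × 3
#>   stage        n n_correct
#>   <chr>    <int>     <int>
#> 1 presence     6         6
#> 2 alleles      4         4
```

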