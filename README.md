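# orthodiverge

Cross-species transcriptome divergence of orthologous coding sequences.

Given two transcriptome assemblies (e.g. two whitefly species with no
reference genome), `orthodiverge` answers the classical molecular-evolution
questions about them:

* which transcripts are **one-to-one orthologs** — reciprocal best hits
  from similarity-search tables, with a minimum match length of 200 bp and
  disambiguation by a shared reference-protein accession (e-value ≤ 1e-5);
* how **diverged** their coding sequences are at sites under different
  constraint — per-site degeneracy classes (nd, 2d, 3d, 4d) and CpG
  context over codon-aware alignments, aggregated into a region × context
  divergence table;
* what **selection** acted on them — synonymous and nonsynonymous rates
  per pair by Nei–Gojobori counting (NG86) and the Yang–Nielsen
  approximate method (YN00): S, N, Sd, Nd, Ka, Ks, ω = Ka/Ks, κ;
* which orthologs are **differentially expressed** between the species —
  TMM normalisation, an exact conditional negative-binomial test, BH
  adjustment, calls at |log2FC| > 1 and FDR < 0.05;
* which **pathways** concentrate divergent or differentially expressed
  genes — upper-tail hypergeometric over-representation with BH
  adjustment, plus per-pathway identity/ω summaries.

Every stage is validated against a built-in generative model:
`simulate_study()` evolves orthologous CDS pairs under a GY94-style codon
model (parameters κ, ω, path length t, CpG transition multiplier),
wraps them in transcripts with UTRs, fabricates consistent hit tables
with planted confounders, simulates negative-binomial counts with known
fold changes, and plants an enriched pathway — together with a truth
manifest, so recovery is checkable end to end with no external data.

## Worked example

Simulate a 30-pair study in which 8 pairs are planted to fail one filter
each, then run the full pipeline:

```r
library(orthodiverge)

sim <- simulate_study(sim_params(n_pairs = 30, seed = 42),
                      confounders = c(short_match = 2, ambig_ref = 2,
                                      short_cds = 2, internal_stop = 2),
                      out_dir = "study")
res <- run_pipeline("study", out_dir = "results")

table(keep = res$orthologs$keep, reason = res$orthologs$reason)
#>        reason
#> keep       ambiguous_reference cds_length internal_stop
#>   FALSE  0                   2          2             2
#>   TRUE  22                   0          0             0
```

22 of 30 pairs survive: the 2 short-match plants never form a reciprocal
pair (the 200 bp filter), and the other 6 are dropped with the expected
reasons. The divergence table shows the signature of purifying selection
and CpG hypermutability baked into the generator:

```r
res$divergence
#>   region context loci compared_kb se_pct_diff mean_pct_diff pct_cpg pct_gc
#> 1    CDS     All   22      12.210      0.2721        13.047    14.8   49.4
#> 2    CDS  No CpG   22      10.400      0.2839        10.292    14.8   49.4
#> 3    CDS     CpG   22       1.810      0.7913        28.871    14.8   49.4
#> 4     nd     All   22       7.736      0.0948         1.267    13.2   51.8
#> 5     nd  No CpG   22       6.718      0.1038         0.981    13.2   51.8
#> 6     nd     CpG   22       1.018      0.4695         3.146    13.2   51.8
#> 7     4d     All   22       2.021      0.9613        43.817    22.3   43.4
#> 8     4d  No CpG   22       1.570      1.1687        34.587    22.3   43.4
#> 9     4d     CpG   22       0.451      1.7755        75.819    22.3   43.4
```

Fourfold-degenerate sites have diverged ~35× more than nondegenerate
sites (43.8% vs 1.3%), and CpG-context sites ~2.8× more than non-CpG
sites within the CDS — the generator's ω = 0.02 and CpG multiplier 4 at
work. The rate estimates recover the generative parameters:

```r
str(res$kaks$summary)
#> List of 8
#>  $ n_pairs    : int 22
#>  $ n_estimable: int 22
#>  $ n_saturated: int 0
#>  $ n_undefined: int 0
#>  $ mean_ks    : num 0.694
#>  $ median_ks  : num 0.682
#>  $ mean_ka    : num 0.0141
#>  $ mean_omega : num 0.0207

res$de$counts
#> A_over B_over     ns
#>      2      3     17
```

Mean ω ≈ 0.021 against a generative ω = 0.02, and 5 of the 22 retained
orthologs are called differentially expressed (25% of genes carry a true
|log2FC| = 2 by default; the weaker ones fall below the strict
thresholds at two replicates). Result tables (`orthologs.tsv`,
`divergence_table.tsv`, `kaks.tsv`, `de.tsv`, enrichment tables and
per-pathway summaries) are written to `results/`.

A thin command-line wrapper over the same functions is included:

```sh
Rscript inst/scripts/orthodiverge.R simulate --out study --seed 42
Rscript inst/scripts/orthodiverge.R all --in study --out results
```

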