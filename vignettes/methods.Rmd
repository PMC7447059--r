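---
title: "Methods: cross-species coding-sequence divergence with orthodiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species coding-sequence divergence with orthodiverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthodiverge)
```

# The problem

Two related insect species (the motivating system is a pair of whitefly
species feeding on different host plants) each have a transcriptome
assembly but no reference genome. The questions are classical molecular
evolution questions: which transcripts are one-to-one orthologs, how
diverged are their coding sequences at sites under different selective
constraints, what do synonymous/nonsynonymous substitution rates say about
selection, which orthologs are differentially expressed between the
species, and which pathways concentrate the divergent or differentially
expressed genes.

`orthodiverge` implements this analysis chain as a set of small, testable
stages, and pairs it with a generative model of the data so that every
stage can be validated against planted ground truth. Nothing in the
package requires external databases or downloads.

# Orthology: reciprocal best hits with reference disambiguation

Orthologs are identified from four similarity-search hit tables in the
standard 12-column tabular format (the package never runs the search
itself; the tables are the contract):

1. **Best hits** (`best_hits()`): rows with a match shorter than 200 bp
   are discarded first; the surviving row with maximal bitscore wins, with
   deterministic tie-breaking (lower e-value, then lexicographic subject).
   The 200 bp minimum is applied to the cross-species tables only, not to
   the reference-protein tables, because the length criterion belongs to
   the reciprocal pairing step.
2. **Reciprocal best hits** (`reciprocal_best_hits()`): a pair is kept iff
   each member is the other's best hit. This enforces one-to-one pairing.
3. **Reference disambiguation** (`disambiguate_by_reference()`): each
   member's best hit against a reference protein database must exist at
   e-value ≤ 1e-5 and both members must hit the *same* accession. This
   removes paralog pairs that happen to be mutual best hits. "Unambiguous"
   is read as top-hit agreement; a stricter reading (a unique
   below-threshold accession per member) is available via `strict = TRUE`.

# CDS delineation and codon-aware alignment

The ORF finder (`predict_orf()`) is a deterministic longest-complete-ORF
rule over all six frames: an ORF is complete iff it starts with ATG and
ends with TAA/TGA/TAG; ties prefer forward frames, then the smaller start
coordinate; ORFs spanning an ambiguous base are rejected. This replaces
gene-prediction software with trained models; the substitution trades
sensitivity on real, messy transcripts for exact reproducibility.

For a pair, the ORF is predicted on the species-A transcript and
*projected* onto the species-B transcript through a semi-global ("fit")
nucleotide alignment that places A's ORF inside B without penalising B's
overhangs. The projection — rather than an independent ORF call on B — is
deliberate: a longest-complete-ORF call can *by construction* never
contain an internal stop codon, while the biologically meaningful partner
region (what a cross-species match aligns to) can. The classical
"unexpected stop codon" filter only has content on the projected CDS. The
UTR overhangs are non-homologous between species, which is why the
projection is semi-global; a full-transcript global alignment wanders at
the boundaries.

Pairs are then filtered (`filter_pair()`): either CDS of 150 nt or less
(the "longer than 150 bp" rule read strictly; lengths exclude the
terminal stop codon) or any internal stop codon drops the pair, with the
reason recorded.

Surviving pairs get a codon-aware alignment: translations are aligned
globally under BLOSUM62 with affine gaps (open 10, extend 1; a run of
$k$ gaps costs $10 + k$) and back-translated, so gaps are always
whole-codon and frame-preserving — a requirement of every downstream codon
operation. The aligner's traceback is deterministic (substitution
preferred over a gap in B over a gap in A at equal score).

# Site classes and the divergence table

Each ungapped, unambiguous alignment column is classified by codon-position
degeneracy: **nd** (nondegenerate: every single-nucleotide change alters
the amino acid), **2d**, **3d**, or **4d** (fourfold degenerate: no change
alters the amino acid). Variants that would create a stop codon are
excluded from the classification denominator. A column enters the nd or 4d
tallies only when *both* species' codons assign it that class; discordant
columns are labelled `mixed` and count toward CDS totals only. Requiring
agreement is the conservative choice that gives each site one unambiguous
class.

CpG context: a column is flagged when its base participates in a CG
dinucleotide, evaluated on the degapped sequence. Three rules are
available (`cpg_mode`): `either` (default — context in one sequence
suffices), `both`, and `first` (species A only). The default mirrors the
inclusive convention of transcriptome divergence tables. For *rate
comparisons* the one-sequence rule is the right one: substitutions create
and destroy CpG context, so conditioning on the union ("either") enriches
flagged columns for diverged sites even under a context-blind model (we
measure z ≈ +15 on null simulations), and "both" depletes them (z ≈ −17);
`first` is unbiased (z ≈ 0.4). The hypermutability validation therefore
uses `cpg_mode = "first"`.

The divergence table (`divergence_table()`) reports, for each region
(CDS, nd, 4d) × context (All, No CpG, CpG): the unweighted mean and
standard error across pairs of the per-pair percent difference, the total
compared kb, and per region the percent of CpG-context sites and the GC
percent. Averaging across pairs (rather than pooling sites) matches the
loci-and-SE structure of published divergence tables; a single pair
reports SE 0.

# Substitution rates: NG86 and YN00

Both estimators share one counting engine and the same conventions:
mutations to or from stop codons are excluded and site totals are
renormalised so each codon contributes exactly 3 sites, making
$S + N = 3 \times \text{codons}$ exact.

**NG86** (`ng86()`): per-position synonymous site fractions are the
proportion of synonymous changes among non-stop single-nucleotide changes,
averaged over the two sequences; observed differences in multi-difference
codons are averaged with equal weight over the substitution pathways that
avoid stop codons; the Jukes–Cantor correction
$d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$ maps proportions to distances.
Proportions ≥ 3/4 report `saturated`.

**YN00** (`yn00()`): the approximate method accounting for
transition/transversion bias and codon usage. Codon frequencies are
estimated from the pair by F3×4 (position-specific base frequencies, with
a +0.25 pseudo-count per base so weights stay positive on short pairs).
Kappa is estimated from sites that are nondegenerate in both sequences and
fourfold degenerate in both: the K80 distance components
$a = -\tfrac12\log(1-2P-Q) + \tfrac14\log(1-2Q)$ and
$b = -\tfrac12\log(1-2Q)$ are pooled across the two site classes weighted
by site counts, and $\kappa = 2a/b$ (this is the exact closed-form ML
ratio: $a = 2\alpha t$, $b = 4\beta t$). Sites are counted with
mutation-opportunity weights $\pi_j \kappa^{[\text{ts}]}$; differences are
counted with pathways weighted by their likelihood
$\prod \pi_j \kappa^{[\text{ts}]} \omega^{[\text{nonsyn}]}$ under the
current estimates; the K80 correction is applied separately to synonymous
and nonsynonymous transition/transversion proportions; and $\omega$ is
iterated from 0.5 to convergence (relative change < 1e-6, ≤ 100
iterations). With $\kappa$ forced to 1 and uniform codon frequencies the
site counting collapses to NG86's, which the tests assert to 1e-6.

Pairs with $K_s = 0$ report $\omega$ as undefined rather than infinite;
batch summaries (`batch_kaks()`) state the denominator (pairs for which
both a Ka and a Ks could be calculated).

On simulations at $K_s \approx 0.5$ (500 codons, 100 replicates per cell),
YN00's median $\omega$ is within 15% of truth across
$\kappa \in \{1,2,5\} \times \omega \in \{0.02, 0.2, 1.0\}$. NG86 is
within 25% except at $\kappa = 5, \omega = 1.0$, where its median is
~0.73 — the well-documented downward bias of counting methods that ignore
transition bias; the test suite asserts the stricter bound and that
assertion fails honestly. An independent NG86 implementation shows the
same or larger bias on the same pairs.

# Differential expression

Counts over the shared orthologous regions are compared between species
(two replicates each) with a deliberately transparent pipeline:

* **TMM normalisation** (`tmm_factors()`): weighted trimmed mean of log2
  ratios against a reference sample (upper-quartile rule), trimming 30% by
  log-ratio and 5% by intensity, inverse-asymptotic-variance weights,
  factors rescaled to geometric mean 1. It reproduces the reference
  implementation to 1e-8 on random matrices.
* **Common dispersion** by method of moments across genes (ratio of summed
  within-group variance excesses to summed squared means), floored at
  1e-4; a `dispersion` override enables sensitivity checks.
* **Exact conditional NB test**: counts are scaled to a common effective
  library size, group sums rounded, and the two-sided exact conditional
  test applied — given the total of the two group sums, the conditional
  law of one sum is mean-free (negative hypergeometric), so the p-value is
  the summed probability of all outcomes no more likely than the observed
  one. Dispersion → 0 degenerates to the binomial split.
* **Fold change** from mean normalised counts with pseudo-count 0.5 (never
  used for testing); **BH adjustment** over all tested genes; calls at the
  strict thresholds |log2FC| > 1 and FDR < 0.05.

Null simulations at dispersion 0.05 give a raw p < 0.05 fraction near
0.04–0.05 (slightly conservative from discreteness), power at planted
|log2FC| = 3 and mean ≥ 200 exceeds 95%, and empirical FDR on mixed
simulations stays below the nominal target.

# Enrichment

Over-representation is the one-sided upper-tail hypergeometric test
(exact summation), applied to the DEG set and to the high-divergence set
(genes strictly below the lower quartile — linear interpolation — of
amino-acid identity). The universe defaults to the orthologs entering the
respective analysis that carry at least one annotation, overridable via
`universe`. No gene-length bias correction is applied: the package's
enrichment claims are threshold statements, and length-bias modelling
would import assumptions the count-level simulation does not generate.
Per-pathway divergence summaries (`pathway_divergence_summary()`) average
amino-acid identity and defined $\omega$ per pathway for ranking-style
reporting.

# The generative model

`simulate_study()` produces everything the pipeline consumes, plus a truth
manifest.

**Codon model.** Sequence pairs evolve from a sampled ancestor (first
codon fixed to ATG) along two independent lineages of length $t/2$ each,
under a GY94-style continuous-time model on sense codons: single-nucleotide
exchanges with rate $\pi_j \kappa^{[\text{ts}]} \omega^{[\text{nonsyn}]}$,
an extra `cpg_multiplier` on transitions at sites currently in CpG context
(context re-evaluated as the sequence evolves, so context can be created
and destroyed), and rate 0 for stop-creating proposals, keeping the chain
on sense codons. Simulation is exact (Gillespie, compiled); time is scaled
so one unit of $t$ is one expected substitution per codon at the ancestor.
The initiation codon is invariant. `t_for_ks()` inverts this scale to hit
a target synonymous divergence.

**Defaults as study conditions.** 185 codons per CDS (the ~555 bp mean
ortholog length of the motivating comparison), $\omega = 0.02$ (the
magnitude of the real-data mean Ka/Ks), $\kappa = 2$ (a typical
transcriptome-wide transition bias; the study does not report one),
`cpg_multiplier = 4` (reproducing the roughly 2–3× CpG vs non-CpG
divergence such comparisons show), UTRs of 50 nt, and $t = 0.65$, placing
$K_s$ near 0.5 — a regime where pairwise estimators are informative. The
real species pair sits near $K_s \approx 2.2$, i.e. deep saturation; the
validation regime is deliberately chosen where recovery is checkable, and
the saturation pathway is exercised separately by the `saturated` status
tests.

**Confounders.** Hit tables are fabricated with rank-consistent bitscores
(the orthology stage consumes only ordering and lengths), mutual best rows
for true pairs, lower-scoring decoys, and shared reference accessions.
Planted confounders exercise each filter: match length 199 (fails the
200 bp minimum), discordant reference accessions, a 50-codon CDS (150 nt,
fails the strict >150 rule), and a TGA written mid-CDS into species B
(caught by the internal-stop filter on the projected CDS). For the two
sequence-level confounders the fabricated match length is the transcript
length — a real search aligns through the UTRs — so they pass the
reciprocal stage and fail exactly where they should.

**Counts and annotation.** Counts are negative-binomial with gene means
scaled by library size and split across groups by the true log2 fold
change (dispersion 0 degenerates to Poisson); by default 25% of retained
orthologs get |log2FC| = 2, in the vicinity of the ~27% DEG fraction of
the motivating study. One pathway is planted to draw 80% of its members
from the true DEGs.

**What the simulation does not emulate.** Read-level noise, assembly
artefacts, indels (simulated pairs are gap-free; the aligner's gap handling
is tested on constructed cases), alternative splicing, expression-level
dependence of divergence, and annotation incompleteness. Passing tests
therefore demonstrate correctness of the analysis logic under the model's
assumptions, not robustness to everything real transcriptomes do.

# Numerical and design choices

* Sequence containers are plain character strings; Biostrings supplies the
  genetic code, FASTA IO and BLOSUM62. Alignment and simulation kernels
  are in C++ (Rcpp) for exactness at scale.
* All randomness flows through R's RNG; every generator is reproducible
  from a seed, and the pipeline itself is RNG-free, so a fixed-seed study
  is byte-identical across runs (asserted in the tests).
* Problem sizes used in the validation suite: 60-pair studies for the
  cascade; 100 pairs × 100 codons for conservation accounting; 10–20k
  codons for CpG rate contrasts; 9 × 100 pairs × 500 codons for the
  recovery grid; 2000-gene null and 1000-gene mixed count simulations.
  These sizes put Monte-Carlo error comfortably below the asserted
  tolerances while keeping the default test run fast.
* Ties, degenerate inputs and error paths are all specified: empty masks
  contribute no sites, single-pair cells report SE 0, `Ks = 0` yields an
  undefined omega, saturation is an explicit status, malformed hit-table
  rows fail with their line number.

# Limitations

The RBH + shared-accession cascade gives one-to-one orthologs only; gene
families and many-to-many orthology are out of scope. YN00 is an
approximate method: at high divergence ($K_s \gtrsim 1.5$) estimates
saturate and the batch summary's estimable-pair count matters. The DE
stage assumes cross-species count comparability over shared orthologous
regions and uses a common dispersion; gene-wise shrinkage is not
implemented. Enrichment ignores gene-length bias. The ORF finder has no
model of incomplete ORFs, frameshifts, or non-ATG starts.
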