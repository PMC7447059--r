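# Shared helpers: lightweight constructors and small simulated fixtures.

codon_aln <- function(a, b) {
  structure(list(a = a, b = b), class = "codon_alignment")
}

# simulate one diverged pair and return its (gap-free) codon alignment
sim_aln <- function(n_codons, kappa = 2, omega = 0.2, t = 0.5,
                    cpg_multiplier = 1) {
  p <- sim_params(n_codons = n_codons, kappa = kappa, omega = omega,
                  t = t, cpg_multiplier = cpg_multiplier)
  pr <- evolve_pair(sample_ancestral_cds(n_codons), p)
  codon_aln(pr$cds_a, pr$cds_b)
}

# memoised small study fixture shared by pipeline-level tests
.fixture_env <- new.env()
small_study <- function() {
  if (is.null(.fixture_env$sim)) {
    dir <- file.path(tempdir(), "orthodiverge-small-study")
    .fixture_env$sim <- simulate_study(
      sim_params(n_pairs = 20L, seed = 7L),
      confounders = c(short_match = 2L, ambig_ref = 2L, short_cds = 2L,
                      internal_stop = 2L),
      out_dir = dir)
    .fixture_env$dir <- dir
  }
  list(sim = .fixture_env$sim, dir = .fixture_env$dir)
}
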