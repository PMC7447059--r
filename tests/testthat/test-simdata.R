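# The synthetic-data generator: ancestral sampling, codon-model evolution,
# transcript assembly, hit-table fabrication and count simulation.

test_that("ancestral CDS sampling forces ATG, avoids stops, is seed-stable", {
  expect_identical(sample_ancestral_cds(1), "ATG")
  set.seed(7)
  a <- sample_ancestral_cds(50)
  set.seed(7)
  b <- sample_ancestral_cds(50)
  expect_identical(a, b)
  expect_equal(nchar(a), 150L)
  for (i in 1:20) {
    cds <- sample_ancestral_cds(40)
    expect_false(any(orthodiverge:::is_stop_codon(
      orthodiverge:::split_codons(cds))))
  }
  expect_error(sample_ancestral_cds(10, codon_freqs = numeric(61)),
               "positive mass")
})

test_that("sampled codon frequencies match the target distribution", {
  set.seed(42)
  n <- 10000L
  cds <- sample_ancestral_cds(n)
  cods <- orthodiverge:::split_codons(cds)[-1]  # first codon is forced
  sc <- orthodiverge:::sense_codons()
  obs <- table(factor(cods, levels = sc))
  # joint goodness of fit plus a per-bin bound adjusted for the 61
  # simultaneous comparisons (a plain 3 SE bound on the maximum of 61
  # z-scores would reject a correct sampler ~15% of the time)
  expect_gt(stats::chisq.test(obs)$p.value, 1e-3)
  p <- 1 / length(sc)
  se <- sqrt((n - 1) * p * (1 - p))
  z <- (as.numeric(obs) - (n - 1) * p) / se
  expect_lt(max(abs(z)), 4)
})

test_that("zero path length leaves both lineages identical to the ancestor", {
  p <- sim_params(n_codons = 30, t = 0)
  anc <- sample_ancestral_cds(30)
  pr <- evolve_pair(anc, p)
  expect_identical(pr$cds_a, anc)
  expect_identical(pr$cds_b, anc)
})

test_that("omega = 0 produces no amino-acid differences", {
  set.seed(11)
  p <- sim_params(n_codons = 300, omega = 0, t = 1, cpg_multiplier = 1)
  anc <- sample_ancestral_cds(300)
  pr <- evolve_pair(anc, p)
  expect_false(identical(pr$cds_a, pr$cds_b))  # synonymous changes did occur
  expect_identical(orthodiverge:::translate_cds(pr$cds_a),
                   orthodiverge:::translate_cds(pr$cds_b))
})

test_that("uniform exchange model yields 1:2 transition:transversion ratio", {
  set.seed(5)
  p <- sim_params(n_codons = 8000, kappa = 1, omega = 1, cpg_multiplier = 1,
                  t = 0.12)
  anc <- sample_ancestral_cds(8000)
  pr <- evolve_pair(anc, p)
  a <- strsplit(pr$cds_a, "")[[1]]
  b <- strsplit(pr$cds_b, "")[[1]]
  d <- which(a != b)
  ts <- sum(orthodiverge:::is_transition(a[d], b[d]))
  n <- length(d)
  p_ts <- 1 / 3
  z <- (ts - n * p_ts) / sqrt(n * p_ts * (1 - p_ts))
  expect_lt(abs(z), 3)
})

test_that("no simulated CDS ever contains an internal stop codon", {
  set.seed(3)
  for (i in 1:10) {
    p <- sim_params(n_codons = 100, omega = 1, t = 2)
    pr <- evolve_pair(sample_ancestral_cds(100), p)
    for (s in c(pr$cds_a, pr$cds_b))
      expect_false(any(orthodiverge:::is_stop_codon(
        orthodiverge:::split_codons(s))))
  }
})

test_that("amino-acid divergence increases monotonically with omega", {
  frac_aa_diff <- function(omega, seed) {
    set.seed(seed)
    p <- sim_params(n_codons = 2000, omega = omega, t = 0.6,
                    cpg_multiplier = 1)
    pr <- evolve_pair(sample_ancestral_cds(2000), p)
    pa <- strsplit(orthodiverge:::translate_cds(pr$cds_a), "")[[1]]
    pb <- strsplit(orthodiverge:::translate_cds(pr$cds_b), "")[[1]]
    mean(pa != pb)
  }
  f <- vapply(c(0.02, 0.2, 1.0), frac_aa_diff, numeric(1), seed = 9)
  expect_true(f[1] < f[2] && f[2] < f[3])
})

test_that("CpG hypermutability shows up at CpG-context sites only when on", {
  div_by_context <- function(mult, seed) {
    set.seed(seed)
    p <- sim_params(n_codons = 10000, omega = 1, t = 0.25,
                    cpg_multiplier = mult)
    pr <- evolve_pair(sample_ancestral_cds(10000), p)
    # the one-sequence context rule is the unbiased one here: "either"
    # conditions on contexts that substitutions themselves create
    cpg <- classify_cpg(pr$cds_a, pr$cds_b, mode = "first")
    a <- strsplit(pr$cds_a, "")[[1]]
    b <- strsplit(pr$cds_b, "")[[1]]
    mm <- a != b
    list(p_cpg = mean(mm[cpg]), n_cpg = sum(cpg),
         p_non = mean(mm[!cpg]), n_non = sum(!cpg))
  }
  z_stat <- function(d) {
    pool <- (d$p_cpg * d$n_cpg + d$p_non * d$n_non) / (d$n_cpg + d$n_non)
    (d$p_cpg - d$p_non) /
      sqrt(pool * (1 - pool) * (1 / d$n_cpg + 1 / d$n_non))
  }
  expect_lt(abs(z_stat(div_by_context(1, 21))), 3)
  expect_gt(z_stat(div_by_context(4, 22)), 3)
})

test_that("transcript assembly plants a recoverable unique longest ORF", {
  set.seed(2)
  cds <- sample_ancestral_cds(100)
  tx <- make_transcript(cds, 0, 0)
  expect_identical(tx$seq, paste0(cds, tx$stop))
  tx2 <- make_transcript(cds, 50, 40)
  orf <- predict_orf(tx2$seq)
  expect_true(orf$found)
  expect_equal(orf$start, 50)
  expect_equal(orf$end, 50 + nchar(cds) + 3)
  parts <- delineate_utrs(tx2$seq, orf)
  expect_equal(nchar(parts$utr5), 50)
  expect_equal(nchar(parts$utr3), 40)
  set.seed(77)
  t1 <- make_transcript(cds, 30, 30)
  set.seed(77)
  t2 <- make_transcript(cds, 30, 30)
  expect_identical(t1, t2)
})

test_that("fabricated hit tables round-trip through the ortholog cascade", {
  set.seed(13)
  p <- sim_params(n_pairs = 8, n_codons = 100)
  tx_a <- tx_b <- character(0)
  for (i in 1:8) {
    pr <- evolve_pair(sample_ancestral_cds(100), p)
    tx_a[sprintf("a%02d", i)] <- make_transcript(pr$cds_a, 20, 20)$seq
    tx_b[sprintf("b%02d", i)] <- make_transcript(pr$cds_b, 20, 20)$seq
  }
  pairs <- data.frame(pair_id = sprintf("p%02d", 1:8),
                      id_A = names(tx_a), id_B = names(tx_b),
                      match_len = 303L,
                      plant = c(rep("clean", 6), "short_match", "ambig_ref"))
  ht <- make_hit_tables(tx_a, tx_b, pairs, n_decoys = 0L)
  orth <- find_orthologs(ht$ab, ht$ba, ht$aref, ht$bref)
  expect_setequal(orth$id_A[orth$retained], pairs$id_A[pairs$plant == "clean"])
  expect_false("a07" %in% orth$id_A)               # short match never pairs
  expect_true("a08" %in% orth$id_A[!orth$retained]) # ambiguous reference
  bad <- pairs
  bad$id_A[1] <- "missing"
  expect_error(make_hit_tables(tx_a, tx_b, bad), "unknown transcript")
})

test_that("count simulation is seed-stable and validates its inputs", {
  set.seed(1)
  m1 <- simulate_counts(50, log2fc = 1, dispersion = 0.1)
  set.seed(1)
  m2 <- simulate_counts(50, log2fc = 1, dispersion = 0.1)
  expect_identical(m1, m2)
  expect_true(all(m1 >= 0))
  expect_error(simulate_counts(10, dispersion = -1), "dispersion")
  expect_error(simulate_counts(10, lib_sizes = c(0, 1, 1, 1)), "positive")
  expect_error(simulate_counts(10, log2fc = Inf), "finite")
  expect_error(simulate_counts(10, base_means = rep(-5, 10)), "negative mean")
})
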