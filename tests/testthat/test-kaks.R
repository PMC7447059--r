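# NG86 and YN00 substitution-rate estimation.

test_that("identical sequences give zero rates and undefined omega", {
  aln <- codon_aln("ATGGCTAAA", "ATGGCTAAA")
  for (f in list(ng86, yn00)) {
    r <- f(aln)
    expect_equal(r$Ka, 0)
    expect_equal(r$Ks, 0)
    expect_true(is.na(r$omega))
    expect_equal(r$status, "ok")
  }
})

test_that("NG86 site fractions follow stop-excluded counting", {
  # TTA: position 1 contributes 1/3 (CTA Leu), position 3 contributes 1/3
  # (TTG Leu), position 2 contributes 0 after excluding TAA/TGA stops
  r <- ng86(codon_aln("TTA", "TTA"))
  expect_equal(r$S, 2 / 3, tolerance = 1e-12)
  expect_equal(r$N, 3 - 2 / 3, tolerance = 1e-12)
})

test_that("a single fourfold difference is purely synonymous", {
  r <- ng86(codon_aln("GGG", "GGA"))
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ka, 0)
  # padded with identical codons the synonymous proportion leaves the
  # saturation domain and Ks becomes positive
  pad <- paste(rep("AAA", 10), collapse = "")
  r2 <- ng86(codon_aln(paste0(pad, "GGG"), paste0(pad, "GGA")))
  expect_equal(r2$Sd, 1)
  expect_equal(r2$Nd, 0)
  expect_equal(r2$Ka, 0)
  expect_gt(r2$Ks, 0)
})

test_that("site counts satisfy S + N = 3 x codons and swap symmetry", {
  set.seed(61)
  for (rep in 1:5) {
    aln <- sim_aln(100, t = 0.8)
    swap <- codon_aln(aln$b, aln$a)
    for (f in list(ng86, yn00)) {
      r <- f(aln)
      n_cod <- nchar(aln$a) / 3
      expect_equal(r$S + r$N, 3 * n_cod, tolerance = 1e-6)
      r2 <- f(swap)
      expect_equal(r2$Ka, r$Ka, tolerance = 1e-9)
      expect_equal(r2$Ks, r$Ks, tolerance = 1e-9)
      expect_equal(r2$S, r$S, tolerance = 1e-9)
    }
  }
})

test_that("YN00 collapses to NG86 site counts at kappa 1, uniform usage", {
  sc <- orthodiverge:::sense_codons()
  unif <- setNames(rep(1 / 61, 61), sc)
  set.seed(67)
  for (rep in 1:5) {
    aln <- sim_aln(80, t = 0.6)
    y <- yn00(aln, kappa = 1, codon_freqs = unif)
    n <- ng86(aln)
    expect_equal(y$S, n$S, tolerance = 1e-6)
    expect_equal(y$N, n$N, tolerance = 1e-6)
  }
})

test_that("K80 kappa estimation validates input and recovers the truth", {
  expect_error(estimate_kappa_k80(0, 0), "no divergence")
  expect_error(estimate_kappa_k80(0.5, 0.3), "saturated")

  # simulate aligned site pairs under K80 with kappa = 5
  k80_pq <- function(at, bt) {
    e1 <- exp(-8 * bt)
    e2 <- exp(-4 * (at + bt))
    c(P = 0.25 + 0.25 * e1 - 0.5 * e2, Q = 0.5 * (1 - e1))
  }
  kappa_true <- 5
  bt <- 0.03
  at <- kappa_true * bt
  pq <- k80_pq(at, bt)
  set.seed(71)
  n <- 1e5
  kind <- sample(c("ts", "tv", "same"), n, replace = TRUE,
                 prob = c(pq["P"], pq["Q"], 1 - pq["P"] - pq["Q"]))
  Pobs <- mean(kind == "ts")
  Qobs <- mean(kind == "tv")
  expect_gt(estimate_kappa_k80(Pobs, Qobs), 4.5)
  expect_lt(estimate_kappa_k80(Pobs, Qobs), 5.5)

  # closed form equals the inversion of the forward K80 map (at, bt) ->
  # (P, Q): bt follows from Q alone and at from the pooled-difference
  # equation; optimisation of the squared residual confirms it coarsely
  set.seed(73)
  for (rep in 1:20) {
    P <- runif(1, 0.01, 0.25)
    Q <- runif(1, 0.01, 0.25)
    bt <- -log(1 - 2 * Q) / 8
    at <- -log(1 - 2 * P - Q) / 4 - bt
    expect_equal(estimate_kappa_k80(P, Q), at / bt, tolerance = 1e-9)
    obj <- function(par) sum((k80_pq(par[1], par[2]) - c(P, Q))^2)
    fit <- optim(c(at, bt) * 1.3, obj, method = "L-BFGS-B",
                 lower = c(1e-8, 1e-8), control = list(factr = 1e2))
    expect_equal(fit$par[1] / fit$par[2], at / bt, tolerance = 5e-3)
  }
})

test_that("estimated Ks increases with simulated divergence time", {
  mean_ks <- function(t, seed) {
    set.seed(seed)
    ks <- replicate(100, {
      aln <- sim_aln(300, kappa = 2, omega = 0.2, t = t)
      yn00(aln)$Ks
    })
    mean(ks, na.rm = TRUE)
  }
  m <- vapply(c(0.2, 0.5, 0.9), mean_ks, numeric(1), seed = 79)
  expect_true(m[1] < m[2] && m[2] < m[3])
})

test_that("batch estimation summarises and flags saturated pairs", {
  same <- codon_aln("ATGGCTAAACTT", "ATGGCTAAACTT")
  res0 <- batch_kaks(list(p1 = same, p2 = same), method = "ng86")
  expect_equal(res0$summary$mean_ks, 0)
  expect_true(is.na(res0$summary$mean_omega))

  # all-synonymous saturation: every codon differs at a fourfold site
  sat <- codon_aln(paste(rep("GGG", 100), collapse = ""),
                   paste(rep("GGA", 100), collapse = ""))
  set.seed(83)
  ok1 <- sim_aln(100, t = 0.4)
  mix <- batch_kaks(list(a = ok1, b = sat), method = "ng86")
  expect_equal(mix$summary$n_pairs, 2)
  expect_equal(mix$summary$n_estimable, 1)
  expect_equal(mix$summary$n_saturated, 1)
  expect_equal(mix$table$status[mix$table$pair_id == "b"], "saturated")
})
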