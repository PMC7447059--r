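# Differential expression between the two species over shared orthologous
# regions: TMM library normalisation, a common method-of-moments
# negative-binomial dispersion, an exact conditional test on group sums,
# and Benjamini-Hochberg adjustment. Counts are assumed comparable across
# species because they are taken over the same orthologous regions; no
# further length correction is applied.

#' TMM normalisation factors
#'
#' Weighted trimmed mean of M-values: per sample, log2 count ratios against
#' a reference sample are trimmed by log-ratio (`trim_logratio` each side)
#' and by absolute intensity (`trim_abs` each side) over genes positive in
#' both samples, averaged with inverse asymptotic-variance weights, and the
#' resulting factors are rescaled to geometric mean 1. The reference sample
#' is the column whose upper-quartile count fraction is closest to the mean
#' of upper quartiles.
#'
#' @param counts non-negative integer matrix, genes x samples (>= 2
#'   columns).
#' @param trim_logratio two-sided trim fraction on log ratios.
#' @param trim_abs two-sided trim fraction on average log intensity.
#' @return named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_logratio = 0.3, trim_abs = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("at least two samples required")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with all-zero counts")
  f75 <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(j) {
    if (j == ref) return(1)
    obs <- counts[, j]
    rf <- counts[, ref]
    keep <- obs > 0 & rf > 0
    obs <- obs[keep]
    rf <- rf[keep]
    if (length(obs) == 0L) return(1)
    lo <- lib[j]
    lr <- lib[ref]
    M <- log2((obs / lo) / (rf / lr))
    A <- 0.5 * log2((obs / lo) * (rf / lr))
    # asymptotic variance of M; genes are weighted by its inverse
    v <- (lo - obs) / (lo * obs) + (lr - rf) / (lr * rf)
    fin <- is.finite(M) & is.finite(A) & A > -1e10
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    n <- length(M)
    if (n == 0L || max(abs(M)) < 1e-6) return(1)
    loL <- floor(n * trim_logratio) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * trim_abs) + 1
    hiS <- n + 1 - loS
    keep2 <- rank(M) >= loL & rank(M) <= hiL &
      rank(A) >= loS & rank(A) <= hiS
    f <- sum(M[keep2] / v[keep2]) / sum(1 / v[keep2])
    if (!is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper around the standard step-up procedure (monotonicity
#' enforced, capped at 1, stable for ties).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# Two-sided exact conditional NB test: given the total s of two group sums
# (each the sum of 2 NB samples with common dispersion phi), the
# conditional distribution of one group sum is free of the mean; the
# p-value sums the probabilities of all outcomes no more likely than the
# observed one.
.exact_nb_test <- function(ya, yb, phi) {
  s <- ya + yb
  if (s == 0L) return(1)
  k <- 0:s
  lp <- if (phi < 1e-8) {
    stats::dbinom(k, s, 0.5, log = TRUE)
  } else {
    stats::dnbinom(k, size = 2 / phi, mu = s / 2, log = TRUE) +
      stats::dnbinom(s - k, size = 2 / phi, mu = s / 2, log = TRUE)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[ya + 1L]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Exact negative-binomial differential expression test
#'
#' Counts are scaled to a common effective library size (TMM-normalised),
#' a common dispersion is estimated across genes by method of moments
#' (floored at 1e-4), and each gene's rounded group sums are compared with
#' a two-sided exact conditional negative-binomial test. Fold changes are
#' computed from mean normalised counts with a pseudo-count of 0.5 (used
#' for the fold change only, never for testing); p-values are BH-adjusted
#' over all tested genes.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param groups group label per column (two levels, >= 2 replicates
#'   each); the first factor level (or alphabetically first label) is the
#'   "A" (numerator) group, so results do not depend on column order.
#' @param dispersion common NB dispersion, or `"auto"` to estimate.
#' @return data.frame with `gene`, `log2fc` (A over B), `pvalue`, `fdr`.
#' @export
de_test <- function(counts, groups, dispersion = "auto") {
  counts <- as.matrix(counts)
  lev <- if (is.factor(groups)) levels(groups) else sort(unique(groups))
  groups <- as.character(groups)
  if (length(lev) != 2L) stop("exactly two groups required")
  ia <- which(groups == lev[1])
  ib <- which(groups == lev[2])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("at least two replicates per group required")
  f <- tmm_factors(counts)
  eff <- colSums(counts) * f
  common <- exp(mean(log(eff)))
  norm <- sweep(counts, 2, common / eff, "*")
  if (identical(dispersion, "auto")) {
    va <- apply(norm[, ia, drop = FALSE], 1, stats::var)
    vb <- apply(norm[, ib, drop = FALSE], 1, stats::var)
    ma <- rowMeans(norm[, ia, drop = FALSE])
    mb <- rowMeans(norm[, ib, drop = FALSE])
    num <- (va + vb) / 2 - (ma + mb) / 2
    den <- (ma^2 + mb^2) / 2
    use <- den > 0
    phi <- max(1e-4, sum(num[use]) / sum(den[use]))
  } else {
    if (!is.numeric(dispersion) || dispersion < 0)
      stop("dispersion must be 'auto' or a non-negative number")
    phi <- dispersion
  }
  ya <- round(rowSums(norm[, ia, drop = FALSE]))
  yb <- round(rowSums(norm[, ib, drop = FALSE]))
  p <- vapply(seq_len(nrow(counts)),
              function(g) .exact_nb_test(ya[g], yb[g], phi), numeric(1))
  lfc <- log2((rowMeans(norm[, ia, drop = FALSE]) + 0.5) /
                (rowMeans(norm[, ib, drop = FALSE]) + 0.5))
  genes <- rownames(counts)
  if (is.null(genes)) genes <- sprintf("gene_%04d", seq_len(nrow(counts)))
  out <- data.frame(gene = genes, log2fc = unname(lfc), pvalue = p,
                    fdr = bh_adjust(p), stringsAsFactors = FALSE)
  attr(out, "dispersion") <- phi
  rownames(out) <- NULL
  out
}

#' Call differentially expressed genes at threshold
#'
#' A gene is over-expressed in A iff `log2fc > lfc_min` and
#' `fdr < fdr_max` (both strict), in B iff `log2fc < -lfc_min` and
#' `fdr < fdr_max`; otherwise not significant.
#'
#' @param de_table output of [de_test()].
#' @param lfc_min absolute log2 fold-change threshold (exclusive).
#' @param fdr_max FDR threshold (exclusive).
#' @return list with `table` (the input plus a `call` column in
#'   `A_over`/`B_over`/`ns`) and `counts` per call.
#' @export
call_deg <- function(de_table, lfc_min = 1, fdr_max = 0.05) {
  call <- rep("ns", nrow(de_table))
  call[de_table$log2fc > lfc_min & de_table$fdr < fdr_max] <- "A_over"
  call[de_table$log2fc < -lfc_min & de_table$fdr < fdr_max] <- "B_over"
  de_table$call <- call
  list(table = de_table,
       counts = c(A_over = sum(call == "A_over"),
                  B_over = sum(call == "B_over"),
                  ns = sum(call == "ns")))
}
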