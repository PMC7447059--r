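# Synonymous / nonsynonymous substitution rates per ortholog pair.
#
# Two estimators share one counting engine:
#   * ng86 -- Nei-Gojobori counting: unit mutation weights, unweighted
#     averaging over substitution pathways that avoid stop codons, and a
#     Jukes-Cantor multiple-hit correction.
#   * yn00 -- the Yang-Nielsen approximate method: F3x4 codon frequencies
#     estimated from the pair, kappa estimated from two-parameter-corrected
#     transition/transversion proportions at nondegenerate and fourfold
#     degenerate sites, mutation-opportunity-weighted site counting,
#     likelihood-weighted pathway counting, iterative omega updates and a
#     K80-style distance correction applied separately to synonymous and
#     nonsynonymous changes.
#
# Conventions: mutations to or from stop codons are excluded from site and
# difference counting and each codon contributes exactly 3 sites, so
# S + N = 3 * (compared codons) holds exactly for both methods.

# ---- pathway structure over all ordered sense-codon pairs (cached) -------

# For every ordered pair of distinct sense codons, enumerate the orderings
# of its nucleotide differences; pathways passing through a stop codon are
# dropped (unless that would remove every pathway, in which case all are
# kept -- the standard counting convention degenerates gracefully).
.path_structure <- function() {
  if (!is.null(.gc_env$paths)) return(.gc_env$paths)
  sc <- sense_codons()
  code <- .genetic_code()
  perms <- list(`1` = matrix(1L, 1, 1),
                `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                            c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  pair_key <- character(0)
  path_pair <- integer(0)
  step_path <- integer(0)
  step_target <- character(0)
  step_ts <- logical(0)
  step_syn <- logical(0)
  n_pair <- 0L
  n_path <- 0L
  chars <- strsplit(sc, "", fixed = TRUE)
  names(chars) <- sc
  for (c1 in sc) for (c2 in sc) {
    if (c1 == c2) next
    d <- which(chars[[c1]] != chars[[c2]])
    k <- length(d)
    n_pair <- n_pair + 1L
    pair_key[n_pair] <- paste0(c1, c2)
    pp <- perms[[as.character(k)]]
    cand <- list()
    for (r in seq_len(nrow(pp))) {
      cur <- chars[[c1]]
      steps <- vector("list", k)
      blocked <- FALSE
      for (s in seq_len(k)) {
        p <- d[pp[r, s]]
        prev_cod <- paste(cur, collapse = "")
        cur[p] <- chars[[c2]][p]
        tgt <- paste(cur, collapse = "")
        if (unname(code[tgt]) == "*") blocked <- TRUE
        steps[[s]] <- c(target = tgt,
                        ts = unname(is_transition(chars[[c1]][p],
                                                  chars[[c2]][p])),
                        syn = unname(code[prev_cod] == code[tgt]))
      }
      cand[[r]] <- list(steps = steps, blocked = blocked)
    }
    use <- Filter(function(x) !x$blocked, cand)
    if (length(use) == 0L) use <- cand
    for (path in use) {
      n_path <- n_path + 1L
      path_pair[n_path] <- n_pair
      for (st in path$steps) {
        step_path <- c(step_path, n_path)
        step_target <- c(step_target, st[["target"]])
        step_ts <- c(step_ts, as.logical(st[["ts"]]))
        step_syn <- c(step_syn, as.logical(st[["syn"]]))
      }
    }
  }
  .gc_env$paths <- list(
    pair_key = pair_key, path_pair = path_pair,
    step_path = step_path, step_target = step_target,
    step_ts = step_ts, step_syn = step_syn)
  .gc_env$paths
}

# Expected (syn, nonsyn) x (transition, transversion) difference counts for
# observed codon-pair tallies, averaging over substitution pathways with
# weight proportional to prod(pi_target * kappa^[ts] * omega^[nonsyn]).
# `obs` is a named count vector keyed by paste0(codon_a, codon_b).
.count_diffs <- function(obs, kappa, omega, pi) {
  ps <- .path_structure()
  w_step <- pmax(pi[ps$step_target], 1e-300) *
    ifelse(ps$step_ts, kappa, 1) * ifelse(ps$step_syn, 1, omega)
  logw <- rowsum(log(w_step), ps$step_path)
  path_w <- exp(logw[, 1])
  pair_of_path <- ps$path_pair
  tot_w <- rowsum(path_w, pair_of_path)[, 1]
  norm_w <- path_w / tot_w[pair_of_path]
  contrib <- cbind(syn_ts = ps$step_syn & ps$step_ts,
                   syn_tv = ps$step_syn & !ps$step_ts,
                   non_ts = !ps$step_syn & ps$step_ts,
                   non_tv = !ps$step_syn & !ps$step_ts)
  path_counts <- rowsum(contrib + 0, ps$step_path)
  pair_counts <- rowsum(path_counts * norm_w, pair_of_path)
  rownames(pair_counts) <- ps$pair_key
  idx <- match(names(obs), ps$pair_key)
  if (anyNA(idx)) stop("unknown codon pair in observations")
  colSums(pair_counts[idx, , drop = FALSE] * as.numeric(obs))
}

# Synonymous site count per codon with mutation-opportunity weights
# pi_target * kappa^[ts]; stop targets excluded; each position contributes
# exactly one site, so N per codon is 3 minus this.
.syn_sites_per_codon <- function(kappa, pi) {
  mt <- .mut_table()
  w <- ifelse(mt$stop, 0, pmax(pi[mt$target], 1e-300) * ifelse(mt$ts, kappa, 1))
  key <- paste(mt$codon, mt$pos)
  tot <- tapply(w, key, sum)
  syn <- tapply(w * mt$syn, key, sum)
  frac <- ifelse(tot > 0, syn / tot, 0)
  cod <- sub(" .*", "", names(tot))
  tapply(frac, cod, sum)
}

# codon columns of an alignment where both rows carry sense codons
.sense_codon_pairs <- function(aln) {
  n_cod <- nchar(aln$a) %/% 3L
  ca <- substring(aln$a, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  cb <- substring(aln$b, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  sc <- sense_codons()
  ok <- ca %in% sc & cb %in% sc
  list(a = ca[ok], b = cb[ok])
}

.kaks_record <- function(method, S = NA_real_, N = NA_real_, Sd = NA_real_,
                         Nd = NA_real_, Ka = NA_real_, Ks = NA_real_,
                         omega = NA_real_, kappa = NA_real_,
                         status = "undefined") {
  list(method = method, S = S, N = N, Sd = Sd, Nd = Nd, Ka = Ka, Ks = Ks,
       omega = omega, kappa = kappa, status = status)
}

#' Nei-Gojobori (1986) Ka/Ks estimate for a codon alignment
#'
#' Counts synonymous and nonsynonymous sites per codon as the fraction of
#' synonymous changes among the non-stop single-nucleotide changes at each
#' position (averaged over the two sequences), counts differences by
#' unweighted averaging over the substitution pathways of multi-difference
#' codons that avoid stop codons, and applies the Jukes-Cantor correction
#' `d = -(3/4) log(1 - (4/3) p)` to the per-site proportions. Proportions
#' of 3/4 or more are reported as `"saturated"`.
#'
#' @param aln a `codon_alignment`; columns with gaps, ambiguous bases or
#'   stop codons are excluded.
#' @return a Ka/Ks record: list with `S`, `N`, `Sd`, `Nd`, `Ka`, `Ks`,
#'   `omega`, `kappa` (`NA` for this method), `status`.
#' @export
ng86 <- function(aln) {
  cp <- .sense_codon_pairs(aln)
  n_cod <- length(cp$a)
  if (n_cod == 0L) return(.kaks_record("NG86"))
  sc <- sense_codons()
  pi_unif <- stats::setNames(rep(1 / length(sc), length(sc)), sc)
  spc <- .syn_sites_per_codon(1, pi_unif)
  S <- (sum(spc[cp$a]) + sum(spc[cp$b])) / 2
  N <- 3 * n_cod - S
  diff <- cp$a != cp$b
  if (!any(diff)) {
    return(.kaks_record("NG86", S, N, 0, 0, Ka = 0, Ks = 0,
                        omega = NA_real_, status = "ok"))
  }
  obs <- table(paste0(cp$a[diff], cp$b[diff]))
  cnt <- .count_diffs(obs, kappa = 1, omega = 1, pi = pi_unif)
  Sd <- cnt[["syn_ts"]] + cnt[["syn_tv"]]
  Nd <- cnt[["non_ts"]] + cnt[["non_tv"]]
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(pS)
  Ka <- jc(pN)
  status <- if (is.na(Ks) || is.na(Ka)) "saturated" else "ok"
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  .kaks_record("NG86", S, N, Sd, Nd, Ka, Ks, omega, NA_real_, status)
}

#' Kimura two-parameter transition/transversion rate ratio
#'
#' Closed-form maximum-likelihood estimate of kappa from observed
#' proportions of transitions (`P`) and transversions (`Q`): with
#' `a = -(1/2) log(1 - 2P - Q) + (1/4) log(1 - 2Q)` (the transition
#' distance component) and `b = -(1/2) log(1 - 2Q)` (the transversion
#' component), `kappa = 2 a / b`.
#'
#' @param P proportion of sites differing by a transition.
#' @param Q proportion of sites differing by a transversion.
#' @return kappa, the transition/transversion rate ratio.
#' @export
estimate_kappa_k80 <- function(P, Q) {
  if (P < 0 || Q < 0) stop("P and Q must be non-negative")
  if (P == 0 && Q == 0) stop("no divergence: kappa is not estimable")
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop("saturated: K80 correction domain violated")
  a <- -0.5 * log(1 - 2 * P - Q) + 0.25 * log(1 - 2 * Q)
  b <- -0.5 * log(1 - 2 * Q)
  if (b <= 0) stop("no transversions observed: kappa is not estimable")
  2 * a / b
}

# F3x4 codon frequencies of an aligned pair (position-specific base
# frequencies over both sequences, mass renormalised over sense codons)
.f3x4 <- function(cp) {
  cods <- c(cp$a, cp$b)
  m <- matrix(unlist(strsplit(cods, "", fixed = TRUE)), ncol = 3, byrow = TRUE)
  pos_freq <- lapply(1:3, function(p) {
    f <- table(factor(m[, p], levels = BASES))
    f <- as.numeric(f) + 0.25  # light smoothing keeps all weights positive
    stats::setNames(f / sum(f), BASES)
  })
  sc <- sense_codons()
  ch <- strsplit(sc, "", fixed = TRUE)
  pi <- vapply(ch, function(x)
    pos_freq[[1]][x[1]] * pos_freq[[2]][x[2]] * pos_freq[[3]][x[3]],
    numeric(1))
  stats::setNames(pi / sum(pi), sc)
}

# kappa from nd/4d site classes of the pair, per the YN00 recipe: pool the
# K80 distance components of the two site classes before taking the ratio.
.yn00_kappa <- function(cp) {
  degen <- .degeneracy_table()
  ch_a <- matrix(unlist(strsplit(cp$a, "", fixed = TRUE)), ncol = 3,
                 byrow = TRUE)
  ch_b <- matrix(unlist(strsplit(cp$b, "", fixed = TRUE)), ncol = 3,
                 byrow = TRUE)
  ia <- match(cp$a, rownames(degen))
  ib <- match(cp$b, rownames(degen))
  acc <- c(`nd` = 0, `4d` = 0)  # site totals
  P <- Q <- c(`nd` = 0, `4d` = 0)
  for (p in 1:3) {
    cls_a <- degen[ia, p]
    cls_b <- degen[ib, p]
    for (cl in c("nd", "4d")) {
      sel <- cls_a == cl & cls_b == cl
      if (!any(sel)) next
      ba <- ch_a[sel, p]
      bb <- ch_b[sel, p]
      ts <- sum(ba != bb & is_transition(ba, bb))
      tv <- sum(ba != bb) - ts
      acc[cl] <- acc[cl] + sum(sel)
      P[cl] <- P[cl] + ts
      Q[cl] <- Q[cl] + tv
    }
  }
  if (sum(acc) == 0) return(NA_real_)
  comp <- function(cl) {
    if (acc[cl] == 0) return(c(a = NA_real_, b = NA_real_))
    p <- unname(P[cl] / acc[cl])
    q <- unname(Q[cl] / acc[cl])
    if (1 - 2 * p - q <= 0 || 1 - 2 * q <= 0)
      return(c(a = NA_real_, b = NA_real_))
    c(a = -0.5 * log(1 - 2 * p - q) + 0.25 * log(1 - 2 * q),
      b = -0.5 * log(1 - 2 * q))
  }
  c0 <- comp("nd")
  c4 <- comp("4d")
  w0 <- acc["nd"]
  w4 <- acc["4d"]
  if (anyNA(c4)) { c4 <- c(a = 0, b = 0); w4 <- 0 }
  if (anyNA(c0)) { c0 <- c(a = 0, b = 0); w0 <- 0 }
  if (w0 + w4 == 0) return(NA_real_)
  A <- (w0 * c0["a"] + w4 * c4["a"]) / (w0 + w4)
  B <- (w0 * c0["b"] + w4 * c4["b"]) / (w0 + w4)
  if (!is.finite(A) || !is.finite(B) || B <= 0) return(NA_real_)
  unname(2 * A / B)
}

#' Yang-Nielsen (2000) approximate Ka/Ks estimate for a codon alignment
#'
#' Estimates F3x4 codon frequencies and kappa from the pair itself, counts
#' sites with mutation-opportunity weighting (`pi_target * kappa^[ts]`),
#' counts differences by averaging over substitution pathways weighted by
#' their likelihood under the current kappa and omega, applies the K80
#' two-parameter correction separately to synonymous and nonsynonymous
#' transition/transversion proportions, and iterates the omega update to
#' convergence (relative change below `tol`, at most `max_iter` rounds;
#' started at omega = 0.5).
#'
#' @param aln a `codon_alignment`.
#' @param tol relative-change convergence tolerance for omega.
#' @param max_iter maximum number of omega updates.
#' @param kappa optional fixed kappa, bypassing the nd/4d estimate (used
#'   for sensitivity checks; with `kappa = 1` and uniform `codon_freqs`
#'   the site counting collapses to NG86's).
#' @param codon_freqs optional fixed codon frequencies over the 61 sense
#'   codons, bypassing the F3x4 estimate.
#' @return a Ka/Ks record as in [ng86()], with the estimated `kappa` and
#'   `status` in `"ok"`, `"saturated"`, `"not_converged"` or
#'   `"undefined"`.
#' @export
yn00 <- function(aln, tol = 1e-6, max_iter = 100L, kappa = NULL,
                 codon_freqs = NULL) {
  cp <- .sense_codon_pairs(aln)
  n_cod <- length(cp$a)
  if (n_cod == 0L) return(.kaks_record("YN00"))
  pi <- if (is.null(codon_freqs)) .f3x4(cp) else codon_freqs[sense_codons()]
  if (is.null(kappa)) {
    kappa <- .yn00_kappa(cp)
    if (is.na(kappa)) kappa <- 1
    kappa <- min(max(kappa, 0.01), 99)
  }
  spc <- .syn_sites_per_codon(kappa, pi)
  S <- (sum(spc[cp$a]) + sum(spc[cp$b])) / 2
  N <- 3 * n_cod - S
  diff <- cp$a != cp$b
  if (!any(diff)) {
    return(.kaks_record("YN00", S, N, 0, 0, Ka = 0, Ks = 0,
                        omega = NA_real_, kappa = kappa, status = "ok"))
  }
  obs <- table(paste0(cp$a[diff], cp$b[diff]))
  k80 <- function(p, q) {
    if (1 - 2 * p - q <= 0 || 1 - 2 * q <= 0) return(NA_real_)
    -0.5 * log(1 - 2 * p - q) - 0.25 * log(1 - 2 * q)
  }
  omega <- 0.5
  status <- "not_converged"
  Ka <- Ks <- NA_real_
  Sd <- Nd <- NA_real_
  for (it in seq_len(max_iter)) {
    cnt <- .count_diffs(obs, kappa = kappa, omega = omega, pi = pi)
    Sd <- cnt[["syn_ts"]] + cnt[["syn_tv"]]
    Nd <- cnt[["non_ts"]] + cnt[["non_tv"]]
    Ks <- k80(cnt[["syn_ts"]] / S, cnt[["syn_tv"]] / S)
    Ka <- k80(cnt[["non_ts"]] / N, cnt[["non_tv"]] / N)
    if (is.na(Ks) || is.na(Ka)) { status <- "saturated"; break }
    if (Ks <= 0) { status <- "ok"; omega <- NA_real_; break }
    new_omega <- max(Ka / Ks, 1e-9)
    if (abs(new_omega - omega) / omega < tol) {
      omega <- new_omega
      status <- "ok"
      break
    }
    omega <- new_omega
  }
  if (status == "ok" && (is.na(Ks) || Ks == 0)) omega <- NA_real_
  .kaks_record("YN00", S, N, Sd, Nd, Ka, Ks,
               if (status %in% c("ok", "not_converged")) omega else NA_real_,
               kappa, status)
}

#' Batch Ka/Ks estimation and summary
#'
#' Applies [yn00()] or [ng86()] to every pair and summarises the pairs for
#' which both a Ka and a Ks could be calculated.
#'
#' @param alignments named list of `codon_alignment` objects.
#' @param method `"yn00"` or `"ng86"`.
#' @return list with `table` (one row per pair: S, N, Sd, Nd, Ka, Ks,
#'   omega, kappa, status) and `summary` (pair counts, mean/median Ks,
#'   mean Ka, mean omega over pairs with a defined omega).
#' @export
batch_kaks <- function(alignments, method = c("yn00", "ng86")) {
  method <- match.arg(method)
  f <- if (method == "yn00") yn00 else ng86
  ids <- names(alignments)
  if (is.null(ids)) ids <- sprintf("pair_%04d", seq_along(alignments))
  rows <- lapply(alignments, function(aln) {
    r <- f(aln)
    data.frame(method = r$method, S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
               Ka = r$Ka, Ks = r$Ks, omega = r$omega, kappa = r$kappa,
               status = r$status, stringsAsFactors = FALSE)
  })
  tab <- cbind(data.frame(pair_id = ids, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(tab) <- NULL
  est <- !is.na(tab$Ka) & !is.na(tab$Ks)
  defined_omega <- est & !is.na(tab$omega)
  summary <- list(
    n_pairs = nrow(tab),
    n_estimable = sum(est),
    n_saturated = sum(tab$status == "saturated"),
    n_undefined = sum(tab$status == "undefined"),
    mean_ks = if (any(est)) mean(tab$Ks[est]) else NA_real_,
    median_ks = if (any(est)) stats::median(tab$Ks[est]) else NA_real_,
    mean_ka = if (any(est)) mean(tab$Ka[est]) else NA_real_,
    mean_omega = if (any(defined_omega)) mean(tab$omega[defined_omega])
                 else NA_real_)
  list(table = tab, summary = summary)
}
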