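# Site-class divergence accounting: every ungapped, unambiguous column of
# a codon alignment gets a degeneracy class (nd / 2d / 3d / 4d, or "mixed"
# when the two species' codons disagree) and a CpG-context flag, and
# per-pair percent differences are aggregated into a divergence table over
# regions (CDS, nd, 4d) and contexts (All, No CpG, CpG).

.aln_chars <- function(aln) {
  list(a = strsplit(aln$a, "", fixed = TRUE)[[1]],
       b = strsplit(aln$b, "", fixed = TRUE)[[1]])
}

#' Per-column CpG-context flags of an aligned sequence pair
#'
#' A column is in CpG context iff its base participates in a C immediately
#' followed by a G. The dinucleotide is evaluated on the degapped sequence
#' (gaps do not interrupt a CpG), and both members of the CG are flagged.
#' `mode` decides which sequences are consulted: `"either"` (the default;
#' context in one sequence suffices), `"both"` (required in both), or
#' `"first"` (sequence A alone). Because substitutions create and destroy
#' CpG context, the `"either"` rule enriches flagged columns for diverged
#' sites and `"both"` depletes them; `"first"` conditions on a single
#' sequence and is free of that selection effect, which matters when
#' comparing CpG and non-CpG substitution rates.
#'
#' @param aligned_a,aligned_b equal-length gapped nucleotide strings.
#' @param mode `"either"`, `"both"` or `"first"`.
#' @return logical vector, one flag per alignment column.
#' @examples
#' classify_cpg("ACGT", "AAAT") # F T T F: context in one sequence suffices
#' @export
classify_cpg <- function(aligned_a, aligned_b,
                         mode = c("either", "both", "first")) {
  mode <- match.arg(mode)
  one <- function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    flags <- logical(length(ch))
    idx <- which(ch != "-")
    x <- ch[idx]
    if (length(x) >= 2L) {
      cg <- x[-length(x)] == "C" & x[-1] == "G"
      f <- logical(length(x))
      f[which(cg)] <- TRUE
      f[which(cg) + 1L] <- TRUE
      flags[idx] <- f
    }
    flags
  }
  fa <- one(aligned_a)
  fb <- one(aligned_b)
  if (length(fa) != length(fb)) stop("aligned strings differ in length")
  switch(mode, either = fa | fb, both = fa & fb, first = fa)
}

#' Classify every column of a codon alignment
#'
#' Columns where either row has a gap or an ambiguous base, or where either
#' codon is a stop, are excluded from classification. A classified column's
#' degeneracy class is the shared class of the two codons at that position
#' ([classify_degeneracy()]); when the two codons assign different classes
#' the column is labelled `"mixed"` (it still counts as CDS but enters no
#' nd/4d tally).
#'
#' @param aln a `codon_alignment`.
#' @param cpg_mode CpG context rule, see [classify_cpg()].
#' @return data.frame with one row per column: `classified`, `class`,
#'   `cpg`, `mismatch`.
#' @export
site_class_map <- function(aln, cpg_mode = "either") {
  ch <- .aln_chars(aln)
  L <- length(ch$a)
  if (L != length(ch$b)) stop("alignment rows differ in length")
  if (L %% 3L != 0L) stop("codon alignment length must be a multiple of 3")
  n_cod <- L %/% 3L
  cods_a <- substring(aln$a, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  cods_b <- substring(aln$b, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  sc <- sense_codons()
  ok_cod <- cods_a %in% sc & cods_b %in% sc
  degen <- .degeneracy_table()
  cls <- matrix(NA_character_, nrow = n_cod, ncol = 3L)
  ia <- match(cods_a[ok_cod], rownames(degen))
  ib <- match(cods_b[ok_cod], rownames(degen))
  for (p in 1:3) {
    ca <- degen[ia, p]
    cb <- degen[ib, p]
    cls[ok_cod, p] <- ifelse(ca == cb, ca, "mixed")
  }
  class_col <- as.vector(t(cls))
  classified <- rep(ok_cod, each = 3L)
  data.frame(classified = classified, class = class_col,
             cpg = classify_cpg(aln$a, aln$b, mode = cpg_mode),
             mismatch = ch$a != ch$b,
             stringsAsFactors = FALSE)
}

#' Percent difference over a masked set of aligned sites
#'
#' @param aln a `codon_alignment`.
#' @param mask logical vector over alignment columns selecting the sites to
#'   compare; `NULL` selects all classified columns.
#' @param cpg_mode CpG context rule, see [classify_cpg()].
#' @return list with `pct_diff` (100 x mismatched/total masked columns; `NA`
#'   when the mask is empty) and `n_sites`.
#' @export
pairwise_divergence <- function(aln, mask = NULL, cpg_mode = "either") {
  map <- site_class_map(aln, cpg_mode)
  if (is.null(mask)) mask <- map$classified
  if (length(mask) != nrow(map)) stop("mask length must equal column count")
  n <- sum(mask)
  if (n == 0L) return(list(pct_diff = NA_real_, n_sites = 0L))
  list(pct_diff = 100 * sum(map$mismatch[mask]) / n, n_sites = n)
}

#' Divergence table over regions and CpG contexts
#'
#' For each region (whole CDS, nd sites, 4d sites) and context (All,
#' No CpG, CpG): the unweighted mean and standard error, across pairs with
#' at least one site in the cell, of the per-pair percent difference, and
#' the total compared length in kb. Per region the table also reports the
#' number of contributing pairs (loci), the percent of sites in CpG
#' context and the GC percent over both sequences.
#'
#' @param alignments list of `codon_alignment` objects.
#' @param cpg_mode CpG context rule, see [classify_cpg()].
#' @return data.frame with columns `region`, `context`, `loci`,
#'   `mean_pct_diff`, `se_pct_diff`, `compared_kb`, `pct_cpg`, `pct_gc`.
#' @export
divergence_table <- function(alignments, cpg_mode = "either") {
  if (length(alignments) == 0L) stop("at least one pair required")
  regions <- c("CDS", "nd", "4d")
  contexts <- c("All", "No CpG", "CpG")
  stats_ <- list()
  gc_chars <- tot_chars <- stats::setNames(numeric(3), regions)
  for (aln in alignments) {
    map <- site_class_map(aln, cpg_mode)
    ch <- .aln_chars(aln)
    for (r in regions) {
      rmask <- if (r == "CDS") map$classified
      else map$classified & !is.na(map$class) & map$class == r
      gc_chars[r] <- gc_chars[r] +
        sum(ch$a[rmask] %in% c("G", "C")) + sum(ch$b[rmask] %in% c("G", "C"))
      tot_chars[r] <- tot_chars[r] + 2 * sum(rmask)
      for (cx in contexts) {
        m <- switch(cx, All = rmask, `No CpG` = rmask & !map$cpg,
                    CpG = rmask & map$cpg)
        n <- sum(m)
        if (n == 0L) next
        key <- paste(r, cx, sep = "|")
        stats_[[key]] <- rbind(stats_[[key]],
                               c(pct = 100 * sum(map$mismatch[m]) / n,
                                 n = n))
      }
    }
  }
  out <- expand.grid(context = contexts, region = regions,
                     stringsAsFactors = FALSE)[, 2:1]
  out$loci <- 0L
  out$mean_pct_diff <- out$se_pct_diff <- out$compared_kb <- NA_real_
  for (i in seq_len(nrow(out))) {
    key <- paste(out$region[i], out$context[i], sep = "|")
    s <- stats_[[key]]
    if (is.null(s)) { out$compared_kb[i] <- 0; next }
    out$loci[i] <- nrow(s)
    out$mean_pct_diff[i] <- mean(s[, "pct"])
    out$se_pct_diff[i] <- if (nrow(s) > 1)
      stats::sd(s[, "pct"]) / sqrt(nrow(s)) else 0
    out$compared_kb[i] <- sum(s[, "n"]) / 1000
  }
  # region-level composition: %CpG = CpG kb / All kb, %GC over both rows
  for (r in regions) {
    all_kb <- out$compared_kb[out$region == r & out$context == "All"]
    cpg_kb <- out$compared_kb[out$region == r & out$context == "CpG"]
    out[out$region == r, "pct_cpg"] <-
      if (isTRUE(all_kb > 0)) 100 * cpg_kb / all_kb else NA_real_
    out[out$region == r, "pct_gc"] <-
      if (tot_chars[r] > 0) 100 * gc_chars[r] / tot_chars[r] else NA_real_
  }
  out
}

#' Nucleotide and amino-acid identity of an aligned pair
#'
#' Nucleotide identity is computed over ungapped columns; amino-acid
#' identity over aligned residue pairs (gap columns excluded).
#'
#' @param aln a `codon_alignment`.
#' @return named numeric vector with `nt` and `aa` identity percentages.
#' @export
sequence_identity <- function(aln) {
  ch <- .aln_chars(aln)
  ungapped <- ch$a != "-" & ch$b != "-"
  nt <- 100 * sum(ch$a[ungapped] == ch$b[ungapped]) / sum(ungapped)
  n_cod <- nchar(aln$a) %/% 3L
  cods_a <- substring(aln$a, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  cods_b <- substring(aln$b, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  res_ok <- cods_a != "---" & cods_b != "---"
  aa_a <- codon_aa(cods_a[res_ok])
  aa_b <- codon_aa(cods_b[res_ok])
  aa_a[is.na(aa_a)] <- "X"
  aa_b[is.na(aa_b)] <- "X"
  aa <- 100 * sum(aa_a == aa_b) / sum(res_ok)
  c(nt = nt, aa = aa)
}
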