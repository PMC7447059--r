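# CDS prediction and codon-aware pairwise alignment. The ORF finder is a
# deterministic longest-complete-ORF rule over all six frames (ATG start,
# TAA/TGA/TAG end). For an ortholog pair, the CDS is predicted on species A
# and projected onto species B through a global nucleotide alignment of the
# two transcripts, mirroring a design where coding regions are annotated on
# one assembly and transferred to the partner via the pairwise match; the
# projected partner CDS can therefore legitimately contain unexpected stop
# codons, which the pair filter rejects. Codon alignments are built by
# aligning translations under BLOSUM62 and back-translating, so gaps are
# always whole-codon and frame-preserving.

#' Predict the best open reading frame of a transcript
#'
#' Scans all six frames (three forward, three on the reverse complement)
#' for complete ORFs -- an ATG followed in frame by a TAA/TGA/TAG stop with
#' no internal stop -- and returns the longest. Ties prefer forward-strand
#' ORFs, then smaller start coordinate. ORFs spanning an N are rejected.
#'
#' @param transcript nucleotide string over A/C/G/T/N.
#' @return list with `found` (logical); when found: `strand` (`"+"`/`"-"`),
#'   `start`, `end` (0-based half-open coordinates on the chosen
#'   orientation), and `cds` (the ORF sequence including its stop codon).
#' @examples
#' predict_orf("AAATGGCTTAAGG") # start 2, end 11, CDS "ATGGCTTAA"
#' @export
predict_orf <- function(transcript) {
  transcript <- toupper(transcript)
  if (grepl("[^ACGTN]", transcript)) stop("sequence must be over A/C/G/T/N")
  cand <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") transcript else revcomp(transcript)
    L <- nchar(s)
    for (f in 0:2) {
      n_cod <- (L - f) %/% 3L
      if (n_cod < 2L) next
      starts <- f + 3L * (seq_len(n_cod) - 1L) + 1L
      cods <- substring(s, starts, starts + 2L)
      aa <- codon_aa(cods)
      aa[is.na(aa)] <- "X"  # codons containing N
      atg <- which(cods == "ATG")
      stp <- which(aa == "*")
      if (length(atg) == 0L || length(stp) == 0L) next
      # first in-frame stop at or after each ATG
      nxt <- stp[findInterval(atg - 0.5, stp) + 1L]
      ok <- !is.na(nxt)
      for (k in which(ok)) {
        a0 <- f + 3L * (atg[k] - 1L)          # 0-based start
        e0 <- f + 3L * nxt[k]                 # 0-based end (past stop)
        span <- substr(s, a0 + 1L, e0)
        if (grepl("N", span, fixed = TRUE)) next
        cand[[length(cand) + 1L]] <-
          list(strand = strand, start = a0, end = e0, cds = span)
      }
    }
  }
  if (length(cand) == 0L) return(list(found = FALSE))
  len <- vapply(cand, function(x) x$end - x$start, integer(1))
  fwd <- vapply(cand, function(x) x$strand == "+", logical(1))
  st <- vapply(cand, function(x) x$start, integer(1))
  ord <- order(-len, !fwd, st)
  best <- cand[[ord[1]]]
  c(list(found = TRUE, complete = TRUE), best)
}

#' Split a transcript into UTRs and CDS around a predicted ORF
#'
#' Orients the transcript to the ORF's strand and cuts it at the ORF
#' boundaries. The concatenation `utr5 + cds + utr3` reconstructs the
#' oriented transcript exactly; `cds` includes the terminal stop codon.
#'
#' @param transcript nucleotide string.
#' @param orf an ORF call from [predict_orf()] with `found = TRUE`.
#' @return list with `utr5`, `cds`, `utr3`.
#' @export
delineate_utrs <- function(transcript, orf) {
  if (!isTRUE(orf$found)) stop("no ORF to delineate around")
  s <- if (orf$strand == "-") revcomp(transcript) else toupper(transcript)
  list(utr5 = substr(s, 1L, orf$start),
       cds = substr(s, orf$start + 1L, orf$end),
       utr3 = substr(s, orf$end + 1L, nchar(s)))
}

.blosum62 <- function() {
  if (is.null(.gc_env$blosum)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .gc_env$blosum <- e$BLOSUM62
  }
  .gc_env$blosum
}

#' Optimal global protein alignment under BLOSUM62 with affine gaps
#'
#' Needleman-Wunsch with gap cost `gap_open + k * gap_extend` for a run of
#' k gaps (defaults 10 and 1) and a deterministic traceback preferring
#' substitution over a gap in the second sequence over a gap in the first.
#'
#' @param prot_a,prot_b amino-acid strings (one-letter code; `X` allowed).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return list with gapped strings `a` and `b` and the alignment `score`.
#' @export
align_proteins <- function(prot_a, prot_b, gap_open = 10, gap_extend = 1) {
  if (nchar(prot_a) == 0L || nchar(prot_b) == 0L)
    stop("empty protein sequence")
  bl <- .blosum62()
  enc <- function(p) {
    i <- match(strsplit(p, "", fixed = TRUE)[[1]], rownames(bl)) - 1L
    if (anyNA(i)) stop("unknown amino-acid code in: ", p)
    i
  }
  a <- enc(prot_a)
  b <- enc(prot_b)
  res <- .nw_align_cpp(a, b, bl + 0.0, gap_open, gap_extend)
  gapped <- function(chars, idx) {
    out <- rep("-", length(idx))
    out[idx >= 0] <- chars[idx[idx >= 0] + 1L]
    paste(out, collapse = "")
  }
  list(a = gapped(strsplit(prot_a, "", fixed = TRUE)[[1]], res$a),
       b = gapped(strsplit(prot_b, "", fixed = TRUE)[[1]], res$b),
       score = res$score)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned residue becomes its source codon; each residue gap becomes
#' `---`, so gaps are whole-codon and frame-preserving and degapping either
#' row returns the input CDS exactly.
#'
#' @param protein_aln alignment from [align_proteins()].
#' @param cds_a,cds_b the coding sequences (terminal stop excluded) whose
#'   translations were aligned.
#' @return object of class `codon_alignment`: list with gapped nucleotide
#'   strings `a` and `b`.
#' @export
backtranslate_alignment <- function(protein_aln, cds_a, cds_b) {
  row <- function(aln_str, cds) {
    res <- strsplit(aln_str, "", fixed = TRUE)[[1]]
    cods <- split_codons(cds)
    aa <- codon_aa(cods)
    aa[is.na(aa)] <- "X"
    if (paste(res[res != "-"], collapse = "") != paste(aa, collapse = ""))
      stop("protein alignment row is not the translation of its CDS")
    out <- character(length(res))
    out[res == "-"] <- "---"
    out[res != "-"] <- cods
    paste(out, collapse = "")
  }
  structure(list(a = row(protein_aln$a, cds_a),
                 b = row(protein_aln$b, cds_b)),
            class = "codon_alignment")
}

#' Apply the CDS-length and internal-stop filters to an ortholog pair
#'
#' A pair is dropped when either coding sequence is 150 nt or shorter
#' ("longer than 150 bp" read strictly: at least 151 nt, i.e. 51 codons),
#' or when either coding sequence contains a stop codon before the
#' terminal position.
#'
#' @param pair list with `cds_a` and `cds_b`, the two coding sequences with
#'   the terminal stop codon excluded.
#' @param min_cds length threshold in nucleotides (dropped unless longer).
#' @return list with `keep` (logical) and `reason` (`""`, `"cds_length"` or
#'   `"internal_stop"`).
#' @export
filter_pair <- function(pair, min_cds = 150L) {
  la <- nchar(pair$cds_a)
  lb <- nchar(pair$cds_b)
  if (la <= min_cds || lb <= min_cds)
    return(list(keep = FALSE, reason = "cds_length"))
  has_stop <- function(cds) any(is_stop_codon(split_codons(cds)), na.rm = TRUE)
  if (has_stop(pair$cds_a) || has_stop(pair$cds_b))
    return(list(keep = FALSE, reason = "internal_stop"))
  list(keep = TRUE, reason = "")
}

# nucleotide scoring matrix for transcript-level projection (A C G T N)
.nt_matrix <- function() {
  m <- matrix(-3, 5, 5, dimnames = list(c(BASES, "N"), c(BASES, "N")))
  diag(m) <- 2
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

.encode_nt <- function(seq) {
  i <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]],
             c(BASES, "N")) - 1L
  if (anyNA(i)) stop("sequence contains characters outside ACGTN")
  i
}

# Project the [start, end) interval of sequence a onto sequence b by
# fitting that interval inside b with a semi-global alignment (b's
# overhangs -- e.g. non-homologous UTRs -- are free). Returns NULL unless
# the projection is contiguous and of identical length (no indels within
# the interval).
.project_interval <- function(seq_a, seq_b, start, end) {
  q <- substr(seq_a, start + 1L, end)
  res <- .nw_align_cpp(.encode_nt(q), .encode_nt(seq_b),
                       .nt_matrix(), 10, 4, fit = TRUE)
  sel <- res$a >= 0 & res$b >= 0
  bpos <- res$b[sel]
  if (length(bpos) != end - start) return(NULL)
  if (max(bpos) - min(bpos) + 1L != end - start) return(NULL)
  c(min(bpos), max(bpos) + 1L)
}

#' Delineate, filter and align the CDS of candidate ortholog pairs
#'
#' For each pair: predicts the ORF on the species-A transcript, projects
#' its coordinates onto the species-B transcript through a global
#' nucleotide alignment (falling back to B's own predicted ORF when the
#' projection is broken by indels), applies [filter_pair()], and builds a
#' codon-aware alignment of the surviving coding sequences via
#' [align_proteins()] and [backtranslate_alignment()].
#'
#' @param pairs data.frame with `id_A`, `id_B` and optionally `pair_id`.
#' @param seqs_a,seqs_b named character vectors of transcripts.
#' @param min_cds CDS length threshold, see [filter_pair()].
#' @return list with `pairs` (metadata: CDS coordinates, UTR lengths, keep
#'   flag, drop reason) and `alignments` (named list of `codon_alignment`
#'   objects for the kept pairs).
#' @export
process_pairs <- function(pairs, seqs_a, seqs_b, min_cds = 150L) {
  n <- nrow(pairs)
  ids <- if (!is.null(pairs$pair_id)) pairs$pair_id else pairs$id_A
  meta <- data.frame(pair_id = ids, id_A = pairs$id_A, id_B = pairs$id_B,
                     cds_start_a = NA_integer_, cds_end_a = NA_integer_,
                     utr5_a = NA_integer_, utr3_a = NA_integer_,
                     cds_len_a = NA_integer_, cds_len_b = NA_integer_,
                     keep = FALSE, reason = "", stringsAsFactors = FALSE)
  alns <- list()
  for (i in seq_len(n)) {
    a <- seqs_a[[pairs$id_A[i]]]
    b <- seqs_b[[pairs$id_B[i]]]
    if (is.null(a) || is.null(b)) stop("pair references unknown transcript")
    orf_a <- predict_orf(a)
    if (!orf_a$found) { meta$reason[i] <- "no_orf"; next }
    a_or <- if (orf_a$strand == "-") revcomp(a) else toupper(a)
    parts <- delineate_utrs(a, orf_a)
    meta$cds_start_a[i] <- orf_a$start
    meta$cds_end_a[i] <- orf_a$end
    meta$utr5_a[i] <- nchar(parts$utr5)
    meta$utr3_a[i] <- nchar(parts$utr3)
    orf_b <- predict_orf(b)
    # project A's ORF onto B, trying both orientations of B
    b_or <- toupper(b)
    proj <- .project_interval(a_or, b_or, orf_a$start, orf_a$end)
    if (is.null(proj)) {
      b_or <- revcomp(b)
      proj <- .project_interval(a_or, b_or, orf_a$start, orf_a$end)
    }
    if (!is.null(proj)) {
      cds_b_full <- substr(b_or, proj[1] + 1L, proj[2])
    } else if (orf_b$found) {
      cds_b_full <- orf_b$cds
    } else {
      meta$reason[i] <- "no_orf"
      next
    }
    core_a <- substr(orf_a$cds, 1L, nchar(orf_a$cds) - 3L)
    core_b <- substr(cds_b_full, 1L, nchar(cds_b_full) - 3L)
    meta$cds_len_a[i] <- nchar(core_a)
    meta$cds_len_b[i] <- nchar(core_b)
    verdict <- filter_pair(list(cds_a = core_a, cds_b = core_b), min_cds)
    meta$keep[i] <- verdict$keep
    meta$reason[i] <- verdict$reason
    if (!verdict$keep) next
    paln <- align_proteins(translate_cds(core_a), translate_cds(core_b))
    alns[[ids[i]]] <- backtranslate_alignment(paln, core_a, core_b)
  }
  list(pairs = meta, alignments = alns)
}
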