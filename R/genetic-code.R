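# Codon-level machinery shared by the simulator, site classification and
# Ka/Ks estimation. The standard nuclear genetic code (translation table 1)
# is used throughout; it is taken from Biostrings::GENETIC_CODE.

BASES <- c("A", "C", "G", "T")

#' @noRd
.gc_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.gc_env$code)) {
    code <- Biostrings::GENETIC_CODE
    # reorder lexicographically (A,C,G,T per position; Biostrings uses TCAG)
    .gc_env$code <- code[sort(names(code))]
  }
  .gc_env$code
}

#' All 64 codons in lexicographic order
#' @noRd
all_codons <- function() names(.genetic_code())

#' The 61 sense codons in lexicographic order
#' @noRd
sense_codons <- function() {
  code <- .genetic_code()
  names(code)[code != "*"]
}

#' Amino acid (one letter, "*" for stop) encoded by each codon
#' @noRd
codon_aa <- function(codons) unname(.genetic_code()[codons])

is_stop_codon <- function(codons) codon_aa(codons) == "*"

#' Split a nucleotide string into codons
#' @noRd
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3: ", n)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a CDS (no terminal stop required); returns one-letter string,
#' with codons containing ambiguous bases rendered as "X"
#' @noRd
translate_cds <- function(seq) {
  aa <- codon_aa(split_codons(toupper(seq)))
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Transition (purine<->purine or pyrimidine<->pyrimidine) indicator
#' @noRd
is_transition <- function(from, to) {
  pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  from != to & pur[from] == pur[to]
}

revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  paste(rev(unname(comp[chars])), collapse = "")
}

#' Classify a codon position by degeneracy
#'
#' Counts, among the three single-nucleotide variants at the given position,
#' how many encode the same amino acid as the input codon. Variants creating
#' stop codons are excluded from the denominator. A position where no
#' possible change is synonymous is nondegenerate (`"nd"`); a position where
#' all three variants are non-stop and synonymous is fourfold degenerate
#' (`"4d"`); one or two synonymous variants give `"2d"` and `"3d"`.
#'
#' @param codon a sense codon (3-letter string over ACGT).
#' @param position codon position, 1, 2 or 3.
#' @return one of `"nd"`, `"2d"`, `"3d"`, `"4d"`.
#' @examples
#' classify_degeneracy("GGG", 3) # "4d": GGA/GGC/GGT all glycine
#' classify_degeneracy("GGG", 1) # "nd": AGG/CGG arginine, TGG tryptophan
#' @export
classify_degeneracy <- function(codon, position) {
  codon <- toupper(codon)
  if (!codon %in% sense_codons())
    stop("not a sense codon: ", codon)
  if (!position %in% 1:3) stop("position must be 1, 2 or 3")
  aa <- codon_aa(codon)
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  alts <- setdiff(BASES, chars[position])
  variants <- vapply(alts, function(b) {
    v <- chars; v[position] <- b; paste(v, collapse = "")
  }, character(1))
  v_aa <- codon_aa(variants)
  nonstop <- v_aa != "*"
  n_syn <- sum(v_aa[nonstop] == aa)
  if (n_syn == 0L) return("nd")
  if (n_syn == 3L && all(nonstop)) return("4d")
  if (n_syn == 1L) return("2d")
  if (n_syn == 2L) return("3d")
  # n_syn == 3 impossible here without all(nonstop); treat as 3d-like
  "3d"
}

# Precomputed degeneracy class for every sense codon x position, used by the
# vectorised site classifier.
.degeneracy_table <- function() {
  if (is.null(.gc_env$degen)) {
    sc <- sense_codons()
    tab <- matrix(NA_character_, nrow = length(sc), ncol = 3,
                  dimnames = list(sc, NULL))
    for (cod in sc) for (p in 1:3) tab[cod, p] <- classify_degeneracy(cod, p)
    .gc_env$degen <- tab
  }
  .gc_env$degen
}

# Integer encodings used at the C++ boundary: bases 0..3 in A,C,G,T order;
# codons 0..63 as 16*b1 + 4*b2 + b3; amino acids as integers with stop = -1.
.encode_seq <- function(seq) {
  m <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES) - 1L
  if (anyNA(m)) stop("sequence contains characters outside ACGT")
  m
}

.decode_seq <- function(int_seq) paste(BASES[int_seq + 1L], collapse = "")

.codon_int <- function(codons) {
  # integer 0..63 for codon strings
  m <- matrix(match(unlist(strsplit(codons, "", fixed = TRUE)), BASES) - 1L,
              ncol = 3, byrow = TRUE)
  m[, 1] * 16L + m[, 2] * 4L + m[, 3]
}

# Enumeration of all single-nucleotide mutations of all sense codons:
# one row per (codon, position, alternative base), with transition,
# synonymous and stop-target flags. Shared by the simulator's time
# calibration and the Ka/Ks site/difference counting.
.mut_table <- function() {
  if (is.null(.gc_env$mut)) {
    sc <- sense_codons()
    rows <- vector("list", length(sc) * 9L)
    k <- 0L
    for (cod in sc) {
      chars <- strsplit(cod, "", fixed = TRUE)[[1]]
      aa <- codon_aa(cod)
      for (p in 1:3) for (b in setdiff(BASES, chars[p])) {
        v <- chars; v[p] <- b
        tgt <- paste(v, collapse = "")
        taa <- codon_aa(tgt)
        k <- k + 1L
        rows[[k]] <- data.frame(codon = cod, pos = p, target = tgt,
                                ts = unname(is_transition(chars[p], b)),
                                syn = taa == aa, stop = taa == "*",
                                stringsAsFactors = FALSE)
      }
    }
    .gc_env$mut <- do.call(rbind, rows)
  }
  .gc_env$mut
}

# aa index (0-based over sorted unique aas) per codon int 0..63, stop = -1
.aa_int64 <- function() {
  if (is.null(.gc_env$aa64)) {
    cods <- all_codons()
    aa <- codon_aa(cods)
    lev <- sort(unique(aa[aa != "*"]))
    v <- integer(64)
    v[.codon_int(cods) + 1L] <- ifelse(aa == "*", -1L, match(aa, lev) - 1L)
    .gc_env$aa64 <- v
  }
  .gc_env$aa64
}
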