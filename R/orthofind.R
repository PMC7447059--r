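# Ortholog identification from reciprocal similarity-search hit tables:
# best hits with a minimum match length, reciprocal-best-hit pairing, and
# disambiguation by a shared reference-protein accession. The stage never
# runs a search itself; 12-column tabular hit files are the contract.

.HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")
.HIT_NUMERIC <- setdiff(.HIT_COLS, c("qseqid", "sseqid"))

#' Read a 12-column tabular hit file
#'
#' Parses the standard tabular similarity-search format (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore).
#' Malformed rows are reported with their line numbers.
#'
#' @param path path to a tab-separated hit file.
#' @return data.frame with one row per hit and the 12 standard columns.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 10)),
      .HIT_COLS))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad))
    stop(sprintf("line %d: expected 12 tab-separated columns, got %d",
                 bad[1], nf[bad[1]]))
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE,
              dimnames = list(NULL, .HIT_COLS))
  out <- data.frame(m, stringsAsFactors = FALSE)
  for (col in .HIT_NUMERIC) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("line %d: non-numeric value '%s' in column %s",
                   bad, out[[col]][bad], col))
    }
    out[[col]] <- v
  }
  for (col in c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send"))
    out[[col]] <- as.integer(out[[col]])
  out
}

#' Write a hit table in the 12-column tabular format
#'
#' Inverse of [read_hit_table()].
#'
#' @param hits data.frame with the 12 standard columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(.HIT_COLS %in% names(hits)))
  utils::write.table(hits[, .HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Best hit per query after a minimum match length filter
#'
#' Rows shorter than `min_match_len` are discarded first; among the
#' survivors, each query's best row is the one with maximal bitscore, ties
#' broken by lower e-value, then by lexicographically smaller subject id,
#' so the result is deterministic regardless of input row order.
#'
#' @param hits hit data.frame (as from [read_hit_table()]).
#' @param min_match_len minimum alignment length in nucleotides.
#' @return named character vector mapping query id to best subject id.
#' @export
best_hits <- function(hits, min_match_len = 200L) {
  if (min_match_len < 1L) stop("min_match_len must be >= 1")
  hits <- hits[hits$length >= min_match_len, , drop = FALSE]
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  first <- !duplicated(hits$qseqid)
  stats::setNames(hits$sseqid[first], hits$qseqid[first])
}

#' Reciprocal best hits
#'
#' Keeps a pair (a, b) iff a's best hit is b and b's best hit is a.
#'
#' @param fwd_map,rev_map named maps from [best_hits()] (A->B and B->A).
#' @return data.frame with columns `id_A`, `id_B`, sorted by `id_A`.
#' @export
reciprocal_best_hits <- function(fwd_map, rev_map) {
  a <- names(fwd_map)
  b <- unname(fwd_map)
  keep <- !is.na(rev_map[b]) & rev_map[b] == a
  keep[is.na(keep)] <- FALSE
  out <- data.frame(id_A = a[keep], id_B = b[keep], stringsAsFactors = FALSE)
  out[order(out$id_A), , drop = FALSE]
}

#' Disambiguate candidate pairs by a shared reference-protein hit
#'
#' For each member of a pair, its best reference hit (same ranking rule as
#' [best_hits()], no length filter) must exist with e-value at most
#' `evalue_max`; the pair is retained iff both best reference accessions
#' are identical. With `strict = TRUE` a member additionally fails when it
#' has hits below the threshold to more than one distinct accession.
#'
#' @param pairs data.frame with `id_A`, `id_B`.
#' @param ref_hits_a,ref_hits_b hit tables of each species against the
#'   reference protein database.
#' @param evalue_max maximum e-value of the best reference hit.
#' @param strict require a unique below-threshold accession per member.
#' @return `pairs` with columns `reference_accession`, `retained` and
#'   `reason` (`""` when retained).
#' @export
disambiguate_by_reference <- function(pairs, ref_hits_a, ref_hits_b,
                                      evalue_max = 1e-5, strict = FALSE) {
  best_ref <- function(hits) {
    if (nrow(hits) == 0L)
      return(data.frame(q = character(0), s = character(0), e = numeric(0)))
    ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid,
                 method = "radix")
    hits <- hits[ord, , drop = FALSE]
    first <- !duplicated(hits$qseqid)
    data.frame(q = hits$qseqid[first], s = hits$sseqid[first],
               e = hits$evalue[first], stringsAsFactors = FALSE)
  }
  ra <- best_ref(ref_hits_a)
  rb <- best_ref(ref_hits_b)
  ia <- match(pairs$id_A, ra$q)
  ib <- match(pairs$id_B, rb$q)
  acc_a <- ra$s[ia]
  acc_b <- rb$s[ib]
  ok_a <- !is.na(ia) & ra$e[ia] <= evalue_max
  ok_b <- !is.na(ib) & rb$e[ib] <= evalue_max
  ok_a[is.na(ok_a)] <- FALSE
  ok_b[is.na(ok_b)] <- FALSE
  same <- ok_a & ok_b & acc_a == acc_b
  same[is.na(same)] <- FALSE
  if (strict) {
    n_acc <- function(hits, ids) {
      sub <- hits[hits$evalue <= evalue_max & hits$qseqid %in% ids, ,
                  drop = FALSE]
      tapply(sub$sseqid, sub$qseqid, function(x) length(unique(x)))
    }
    na_ <- n_acc(ref_hits_a, pairs$id_A)
    nb_ <- n_acc(ref_hits_b, pairs$id_B)
    uniq <- !is.na(na_[pairs$id_A]) & na_[pairs$id_A] == 1L &
      !is.na(nb_[pairs$id_B]) & nb_[pairs$id_B] == 1L
    uniq[is.na(uniq)] <- FALSE
    same <- same & uniq
  }
  pairs$reference_accession <- ifelse(same, acc_a, NA_character_)
  pairs$retained <- same
  pairs$reason <- ifelse(same, "",
                         ifelse(!ok_a | !ok_b, "weak_reference",
                                "ambiguous_reference"))
  pairs
}

#' Full ortholog identification cascade
#'
#' Chains [best_hits()] on both directions (with the match-length minimum
#' applied to the cross-species hits only), [reciprocal_best_hits()], and
#' [disambiguate_by_reference()].
#'
#' @param hits_ab,hits_ba cross-species hit tables (A->B, B->A).
#' @param ref_hits_a,ref_hits_b reference-protein hit tables.
#' @param min_match_len minimum cross-species match length (nucleotides).
#' @param evalue_max maximum reference-hit e-value.
#' @param strict see [disambiguate_by_reference()].
#' @return data.frame of reciprocal-best-hit pairs with
#'   `reference_accession`, `retained`, `reason`.
#' @export
find_orthologs <- function(hits_ab, hits_ba, ref_hits_a, ref_hits_b,
                           min_match_len = 200L, evalue_max = 1e-5,
                           strict = FALSE) {
  fwd <- best_hits(hits_ab, min_match_len)
  rev <- best_hits(hits_ba, min_match_len)
  rbh <- reciprocal_best_hits(fwd, rev)
  disambiguate_by_reference(rbh, ref_hits_a, ref_hits_b,
                            evalue_max = evalue_max, strict = strict)
}
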