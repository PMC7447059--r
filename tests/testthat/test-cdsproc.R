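# ORF prediction, UTR delineation, protein alignment and back-translation.

test_that("ORF finder recovers hand-checkable ORFs", {
  orf <- predict_orf("AAATGGCTTAAGG")
  expect_true(orf$found)
  expect_equal(orf$start, 2)
  expect_equal(orf$end, 11)
  expect_equal(orf$cds, "ATGGCTTAA")
  expect_equal(orf$strand, "+")

  # two complete ORFs: 30 nt and 300 nt; the longest wins
  set.seed(4)
  short <- paste0("ATG", paste(rep("GCT", 8), collapse = ""), "TAA")
  long <- paste0("ATG", paste(rep("GAA", 98), collapse = ""), "TGA")
  tx <- paste0("TT", short, "CC", long, "AA")
  orf2 <- predict_orf(tx)
  expect_equal(orf2$end - orf2$start, 300)
  expect_equal(orf2$cds, long)

  expect_false(predict_orf("ACGTACGTACGT")$found)
  # an N inside the only ORF disqualifies it
  expect_false(predict_orf("ATGGNCTAA")$found)
  # reverse-strand ORF is found and reported on the reverse orientation
  rc <- orthodiverge:::revcomp("AAATGGCTTAAGG")
  orf3 <- predict_orf(rc)
  expect_equal(orf3$strand, "-")
  expect_equal(orf3$cds, "ATGGCTTAA")
})

test_that("ORF finder matches an exhaustive six-frame scan oracle", {
  oracle_orf <- function(seq) {
    best <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else orthodiverge:::revcomp(seq)
      n <- nchar(s)
      for (start in 0:(n - 6)) {
        if (substr(s, start + 1, start + 3) != "ATG") next
        end <- NA
        pos <- start
        ok <- TRUE
        while (pos + 3 <= n) {
          cod <- substr(s, pos + 1, pos + 3)
          if (grepl("N", cod)) { ok <- FALSE; break }
          if (cod %in% c("TAA", "TGA", "TAG") && pos > start) {
            end <- pos + 3
            break
          }
          pos <- pos + 3
        }
        if (!ok || is.na(end)) next
        len <- end - start
        better <- is.null(best) || len > best$len ||
          (len == best$len && strand == "+" && best$strand == "-") ||
          (len == best$len && strand == best$strand && start < best$start)
        if (better) best <- list(len = len, strand = strand, start = start,
                                 end = end)
      }
    }
    best
  }
  set.seed(23)
  for (rep in 1:15) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
    want <- oracle_orf(seq)
    got <- predict_orf(seq)
    if (is.null(want)) {
      expect_false(got$found)
    } else {
      expect_true(got$found)
      expect_equal(got$strand, want$strand)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("UTR delineation reconstructs the transcript exactly", {
  cds <- "ATGGCTTAA"
  orf <- predict_orf(cds)
  parts <- delineate_utrs(cds, orf)
  expect_equal(parts$utr5, "")
  expect_equal(parts$utr3, "")
  expect_equal(parts$cds, cds)
  set.seed(8)
  for (rep in 1:20) {
    body <- sample_ancestral_cds(60)
    tx <- make_transcript(body, sample(0:60, 1), sample(0:60, 1))
    orf <- predict_orf(tx$seq)
    parts <- delineate_utrs(tx$seq, orf)
    expect_identical(paste0(parts$utr5, parts$cds, parts$utr3), tx$seq)
  }
})

# exhaustive alignment scorer under the same scoring model: gap run of
# length k costs open + k * extend
enumerate_best_score <- function(a, b, open = 10, extend = 1) {
  bl <- orthodiverge:::.blosum62()
  rec <- function(i, j, state) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- rec(i - 1, j - 1, "M") +
        bl[substr(a, i, i), substr(b, j, j)]
      best <- max(best, s)
    }
    if (i > 0) {
      s <- rec(i - 1, j, "X") - extend - if (state == "X") 0 else open
      best <- max(best, s)
    }
    if (j > 0) {
      s <- rec(i, j - 1, "Y") - extend - if (state == "Y") 0 else open
      best <- max(best, s)
    }
    best
  }
  rec(nchar(a), nchar(b), "M")
}

test_that("protein alignment is optimal, deterministic and symmetric", {
  id <- align_proteins("MKVLA", "MKVLA")
  expect_false(grepl("-", id$a) || grepl("-", id$b))
  bl <- orthodiverge:::.blosum62()
  expect_equal(align_proteins("A", "A")$score, bl["A", "A"])
  expect_equal(align_proteins("A", "A")$score, 4)

  res <- align_proteins("MKV", "MV")
  expect_equal(res$score, enumerate_best_score("MKV", "MV"))
  expect_equal(nchar(res$a), 3)
  expect_equal(lengths(regmatches(res$b, gregexpr("-", res$b))), 1)

  set.seed(19)
  aas <- setdiff(rownames(orthodiverge:::.blosum62()), c("*", "B", "Z", "X"))
  for (rep in 1:10) {
    pa <- paste(sample(aas, sample(2:4, 1), replace = TRUE), collapse = "")
    pb <- paste(sample(aas, sample(2:4, 1), replace = TRUE), collapse = "")
    expect_equal(align_proteins(pa, pb)$score, enumerate_best_score(pa, pb))
    expect_equal(align_proteins(pa, pb)$score, align_proteins(pb, pa)$score)
  }
})

test_that("back-translation yields whole-codon gaps and degaps exactly", {
  # gap-free alignment: codon alignment is the two CDS verbatim
  cds1 <- "ATGAAAGTT"  # MKV
  cds2 <- "ATGAAGGTA"  # MKV
  aln <- backtranslate_alignment(align_proteins("MKV", "MKV"), cds1, cds2)
  expect_equal(aln$a, cds1)
  expect_equal(aln$b, cds2)

  # one residue gap becomes one --- codon column
  cds3 <- "ATGGTT"  # MV
  aln2 <- backtranslate_alignment(align_proteins("MKV", "MV"), cds1, cds3)
  expect_equal(nchar(aln2$a), 9)
  expect_true(grepl("---", aln2$b, fixed = TRUE))
  degap <- function(s) gsub("-", "", s, fixed = TRUE)
  expect_equal(degap(aln2$a), cds1)
  expect_equal(degap(aln2$b), cds3)

  expect_error(backtranslate_alignment(align_proteins("MKV", "MV"),
                                       cds1, "ATGAAA"),
               "not the translation")

  # degap round-trip on simulated diverged pairs
  set.seed(29)
  for (rep in 1:10) {
    p <- sim_params(n_codons = 60, t = 0.8)
    pr <- evolve_pair(sample_ancestral_cds(60), p)
    paln <- align_proteins(orthodiverge:::translate_cds(pr$cds_a),
                           orthodiverge:::translate_cds(pr$cds_b))
    aln <- backtranslate_alignment(paln, pr$cds_a, pr$cds_b)
    expect_equal(degap(aln$a), pr$cds_a)
    expect_equal(degap(aln$b), pr$cds_b)
    expect_equal(nchar(aln$a) %% 3, 0)
  }
})

test_that("pair filters drop short and stop-containing CDS with reasons", {
  mk <- function(n) substr(sample_ancestral_cds(n), 1, n * 3)
  set.seed(41)
  short <- list(cds_a = mk(50), cds_b = mk(100))   # 150 nt is not > 150
  expect_equal(filter_pair(short), list(keep = FALSE, reason = "cds_length"))
  a <- mk(150)
  b <- mk(150)
  substr(b, 301, 303) <- "TGA"
  expect_equal(filter_pair(list(cds_a = a, cds_b = b)),
               list(keep = FALSE, reason = "internal_stop"))
  clean <- list(cds_a = mk(150), cds_b = mk(150))
  expect_equal(filter_pair(clean), list(keep = TRUE, reason = ""))
})
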