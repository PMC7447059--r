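# Hit-table parsing and the reciprocal-best-hit ortholog cascade.

make_hits <- function(q, s, len = 300L, bits = 100, evalue = 1e-20) {
  data.frame(qseqid = q, sseqid = s, pident = 95, length = len,
             mismatch = 1L, gapopen = 0L, qstart = 1L, qend = len,
             sstart = 1L, send = len, evalue = evalue, bitscore = bits,
             stringsAsFactors = FALSE)
}

test_that("hit tables parse, serialise and report malformed rows by line", {
  empty <- tempfile()
  file.create(empty)
  expect_equal(nrow(read_hit_table(empty)), 0)

  h <- make_hits(c("q1", "q1", "q2"), c("s1", "s2", "s1"),
                 bits = c(100, 90, 80))
  path <- tempfile()
  write_hit_table(h, path)
  h2 <- read_hit_table(path)
  expect_equal(nrow(h2), 3)
  expect_equal(h2$bitscore, c(100, 90, 80))
  expect_equal(h2$qseqid, h$qseqid)

  bad <- tempfile()
  writeLines(c(paste(rep("x", 12), collapse = "\t"),
               paste(rep("x", 11), collapse = "\t")), bad)
  expect_error(read_hit_table(bad), "line 2.*11")
  bad2 <- tempfile()
  row <- c("q", "s", "95", "300", "1", "0", "1", "300", "1", "300",
           "not_a_number", "100")
  writeLines(paste(row, collapse = "\t"), bad2)
  expect_error(read_hit_table(bad2), "line 1.*evalue")
  expect_error(read_hit_table(tempfile()), "no such file")
})

test_that("best hits rank by bitscore with the match-length filter first", {
  h <- make_hits(c("q1", "q1"), c("s_lo", "s_hi"), bits = c(90, 100))
  expect_equal(unname(best_hits(h, 1)["q1"]), "s_hi")
  short <- make_hits("q1", "s1", len = 199L)
  expect_false("q1" %in% names(best_hits(short, 200)))
  expect_true("q1" %in% names(best_hits(short, 199)))
})

test_that("best hits agree with an exhaustive scan oracle", {
  oracle_best <- function(hits, min_len) {
    out <- character(0)
    for (q in sort(unique(hits$qseqid))) {
      rows <- hits[hits$qseqid == q & hits$length >= min_len, , drop = FALSE]
      if (nrow(rows) == 0) next
      best <- NULL
      for (i in seq_len(nrow(rows))) {
        r <- rows[i, ]
        if (is.null(best) || r$bitscore > best$bitscore ||
            (r$bitscore == best$bitscore && r$evalue < best$evalue) ||
            (r$bitscore == best$bitscore && r$evalue == best$evalue &&
             r$sseqid < best$sseqid)) best <- r
      }
      out[q] <- best$sseqid
    }
    out
  }
  set.seed(31)
  for (rep in 1:20) {
    h <- make_hits(q = sample(paste0("q", 1:5), 20, replace = TRUE),
                   s = sample(paste0("s", 1:6), 20, replace = TRUE),
                   len = sample(c(150L, 250L, 400L), 20, replace = TRUE),
                   bits = sample(50:60, 20, replace = TRUE),
                   evalue = sample(c(1e-30, 1e-20, 1e-10), 20, replace = TRUE))
    got <- best_hits(h, 200)
    want <- oracle_best(h, 200)
    expect_identical(got[sort(names(got))], want[sort(names(want))])
  }
})

test_that("reciprocal best hits keep only mutual pairs", {
  expect_equal(reciprocal_best_hits(c(a = "b"), c(b = "a")),
               data.frame(id_A = "a", id_B = "b"))
  expect_equal(nrow(reciprocal_best_hits(c(a = "b"), c(b = "c"))), 0)
  # random bipartite maps against quadratic enumeration
  set.seed(17)
  for (rep in 1:20) {
    fwd <- setNames(sample(paste0("b", 1:6), 6, replace = TRUE),
                    paste0("a", 1:6))
    rev <- setNames(sample(paste0("a", 1:6), 6, replace = TRUE),
                    paste0("b", 1:6))
    want <- data.frame(id_A = character(0), id_B = character(0))
    for (a in names(fwd)) for (b in names(rev))
      if (fwd[[a]] == b && rev[[b]] == a)
        want <- rbind(want, data.frame(id_A = a, id_B = b))
    want <- want[order(want$id_A), , drop = FALSE]
    got <- reciprocal_best_hits(fwd, rev)
    rownames(want) <- rownames(got) <- NULL
    expect_equal(got, want)
  }
})

test_that("reference disambiguation retains only same-accession pairs", {
  pairs <- data.frame(id_A = c("a1", "a2", "a3"),
                      id_B = c("b1", "b2", "b3"),
                      stringsAsFactors = FALSE)
  ra <- make_hits(c("a1", "a2", "a3"), c("P1", "P2", "P3"),
                  evalue = c(1e-20, 1e-20, 1e-4))
  rb <- make_hits(c("b1", "b2", "b3"), c("P1", "PX", "P3"),
                  evalue = c(1e-20, 1e-20, 1e-20))
  out <- disambiguate_by_reference(pairs, ra, rb)
  expect_true(out$retained[1])
  expect_equal(out$reference_accession[1], "P1")
  expect_false(out$retained[2])  # accessions differ
  expect_equal(out$reason[2], "ambiguous_reference")
  expect_false(out$retained[3])  # best reference e-value above 1e-5
  expect_equal(out$reason[3], "weak_reference")
})

test_that("the cascade is order-independent and pairs ids uniquely", {
  fx <- small_study()
  ht <- fx$sim$hits
  base <- find_orthologs(ht$ab, ht$ba, ht$aref, ht$bref)
  set.seed(99)
  shuf <- function(df) df[sample(nrow(df)), , drop = FALSE]
  perm <- find_orthologs(shuf(ht$ab), shuf(ht$ba), shuf(ht$aref),
                         shuf(ht$bref))
  rownames(base) <- rownames(perm) <- NULL
  expect_equal(perm, base)
  acc <- base[base$retained, ]
  expect_false(any(duplicated(acc$id_A)))
  expect_false(any(duplicated(acc$id_B)))
})
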