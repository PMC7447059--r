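# Synthetic-data generator: orthologous CDS pairs diverged under a
# GY94-style codon model with CpG hypermutability, transcripts with UTRs,
# fabricated reciprocal hit tables, negative-binomial count matrices and
# pathway annotations with planted enrichment -- plus a ground-truth
# manifest, so every downstream stage can be validated without external
# data. All randomness goes through R's global RNG; top-level generators
# take an explicit seed.

#' Simulation parameters for orthologous CDS pair generation
#'
#' Bundles the generative parameters of the codon substitution model and of
#' the transcript layout. `kappa` and `omega` are the generative
#' counterparts of the transition/transversion ratio and the Ka/Ks ratio
#' estimated downstream; `t` is the total expected number of substitutions
#' per codon along the whole path between the two species (split equally
#' between the two lineages); `cpg_multiplier` multiplies the rate of
#' transitions at sites currently in CpG context.
#'
#' Defaults describe a whitefly-like cross-species comparison: CDS of 185
#' codons (the study-scale mean ortholog length of ~555 bp), strong
#' purifying selection (`omega = 0.02`, the magnitude of the real-data mean
#' Ka/Ks), moderate transition bias (`kappa = 2`), CpG hypermutability
#' (`cpg_multiplier = 4`, reproducing the elevated CpG-site divergence seen
#' in such comparisons), and a path length `t = 0.65` placing synonymous
#' divergence near Ks ~ 0.5, where pairwise estimators are informative.
#'
#' @param n_pairs number of ortholog pairs to simulate.
#' @param n_codons codons per CDS (excluding the terminal stop).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (> 0).
#' @param t expected substitutions per codon along the whole pair path (> 0).
#' @param cpg_multiplier extra rate multiplier for transitions at CpG-context
#'   sites (>= 1).
#' @param utr5_len,utr3_len UTR lengths in nucleotides (>= 0).
#' @param codon_freqs named distribution over the 61 sense codons (sums to
#'   1); `NULL` for uniform.
#' @param seed integer seed used by [simulate_study()].
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_pairs = 60L, n_codons = 185L, kappa = 2, omega = 0.02,
                       t = 0.65, cpg_multiplier = 4, utr5_len = 50L,
                       utr3_len = 50L, codon_freqs = NULL, seed = 1L) {
  sc <- sense_codons()
  if (is.null(codon_freqs)) {
    codon_freqs <- stats::setNames(rep(1 / length(sc), length(sc)), sc)
  }
  if (is.null(names(codon_freqs)) || !setequal(names(codon_freqs), sc))
    stop("codon_freqs must be named by the 61 sense codons")
  codon_freqs <- codon_freqs[sc]
  if (any(codon_freqs < 0) || abs(sum(codon_freqs) - 1) > 1e-9)
    stop("codon_freqs must be non-negative and sum to 1")
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("kappa must be a single positive number")
  # omega = 0 (no amino-acid changes) and t = 0 (no divergence) are valid
  # degenerate settings, useful for model checks
  for (nm in c("omega", "t")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop(nm, " must be a single non-negative number")
  }
  if (cpg_multiplier < 1) stop("cpg_multiplier must be >= 1")
  if (n_codons < 1) stop("n_codons must be >= 1")
  if (utr5_len < 0 || utr3_len < 0) stop("UTR lengths must be >= 0")
  structure(list(n_pairs = as.integer(n_pairs),
                 n_codons = as.integer(n_codons),
                 kappa = kappa, omega = omega, t = t,
                 cpg_multiplier = cpg_multiplier,
                 utr5_len = as.integer(utr5_len),
                 utr3_len = as.integer(utr3_len),
                 codon_freqs = codon_freqs, seed = as.integer(seed)),
            class = "sim_params")
}

# pi over codon ints 0..63, zero mass on stops
.pi64 <- function(codon_freqs) {
  v <- numeric(64)
  v[.codon_int(names(codon_freqs)) + 1L] <- codon_freqs
  v
}

#' Sample an ancestral coding sequence
#'
#' Draws `n_codons` sense codons i.i.d. from `codon_freqs`, with the first
#' codon forced to ATG. The result contains no stop codon at any codon
#' position.
#'
#' @param n_codons number of codons (>= 1).
#' @param codon_freqs distribution over the 61 sense codons; `NULL` for
#'   uniform.
#' @return a nucleotide string of length `3 * n_codons`.
#' @export
sample_ancestral_cds <- function(n_codons, codon_freqs = NULL) {
  sc <- sense_codons()
  if (n_codons < 1) stop("n_codons must be >= 1")
  if (is.null(codon_freqs))
    codon_freqs <- stats::setNames(rep(1 / length(sc), length(sc)), sc)
  codon_freqs <- codon_freqs[sc]
  if (anyNA(codon_freqs) || any(codon_freqs < 0) || sum(codon_freqs) <= 0)
    stop("codon_freqs must be a non-negative vector with positive mass over sense codons")
  body <- if (n_codons > 1L)
    sample(sc, n_codons - 1L, replace = TRUE, prob = codon_freqs)
  else character(0)
  paste(c("ATG", body), collapse = "")
}

#' Evolve an ancestral CDS into a pair of diverged orthologs
#'
#' Simulates two independent lineages from a common ancestor, each for
#' `t/2` expected substitutions per codon, under a GY94-style
#' continuous-time codon model with single-nucleotide exchanges: proposal
#' rate to codon j is `pi_j * kappa^[transition] * omega^[amino-acid
#' change]`, with an extra `cpg_multiplier` on transitions at sites
#' currently in CpG context (context is re-evaluated on the evolving
#' sequence). Proposals creating stop codons get rate zero, so the process
#' is a proper CTMC on sense codons and the outputs never contain internal
#' stops. The initiation codon is held invariant so every simulated CDS
#' keeps its ATG start. Simulation is exact (Gillespie); the time scale is
#' normalised so one unit of `t` is one expected substitution per codon at
#' the ancestor.
#'
#' @param ancestor a sense-codon nucleotide string (no stops).
#' @param params a [sim_params()] object.
#' @return list with elements `cds_a` and `cds_b`, same length as
#'   `ancestor`.
#' @export
evolve_pair <- function(ancestor, params) {
  stopifnot(inherits(params, "sim_params"))
  cods <- split_codons(ancestor)
  if (any(is_stop_codon(cods))) stop("ancestor contains a stop codon")
  s0 <- .encode_seq(ancestor)
  pi64 <- .pi64(params$codon_freqs)
  aa64 <- .aa_int64()
  a <- .evolve_lineage_cpp(s0, params$t / 2, params$kappa, params$omega,
                           params$cpg_multiplier, pi64, aa64)
  b <- .evolve_lineage_cpp(s0, params$t / 2, params$kappa, params$omega,
                           params$cpg_multiplier, pi64, aa64)
  list(cds_a = .decode_seq(a), cds_b = .decode_seq(b))
}

.STOPS <- c("TAA", "TGA", "TAG")

.random_utr <- function(len) {
  if (len == 0L) return("")
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

#' Wrap a CDS in a transcript with random UTRs
#'
#' Appends a random stop codon to the CDS and flanks it with random UTRs.
#' UTRs are re-drawn until the planted ORF is the unique longest complete
#' ORF of the transcript (checked with [predict_orf()]), so downstream ORF
#' prediction recovers the planted coordinates exactly.
#'
#' @param cds complete CDS (starts with ATG, no internal stop, no terminal
#'   stop -- one is appended here).
#' @param utr5_len,utr3_len UTR lengths in nucleotides.
#' @param check_orf verify (and if needed re-draw) that the planted ORF is
#'   recovered by [predict_orf()]; disable when deliberately planting a
#'   defective CDS.
#' @param max_tries re-draw budget before giving up.
#' @return list with `seq` (the transcript), `cds_start`, `cds_end` (0-based
#'   half-open coordinates of the ORF including its stop codon) and `stop`
#'   (the stop codon used).
#' @export
make_transcript <- function(cds, utr5_len, utr3_len, check_orf = TRUE,
                            max_tries = 100L) {
  cods <- split_codons(cds)
  if (cods[1] != "ATG") stop("cds must start with ATG")
  if (check_orf && any(is_stop_codon(cods)))
    stop("cds must not contain a stop codon")
  stop_codon <- sample(.STOPS, 1L)
  orf <- paste0(cds, stop_codon)
  for (i in seq_len(max_tries)) {
    tx <- paste0(.random_utr(utr5_len), orf, .random_utr(utr3_len))
    if (!check_orf)
      return(list(seq = tx, cds_start = utr5_len,
                  cds_end = utr5_len + nchar(orf), stop = stop_codon))
    call <- predict_orf(tx)
    if (call$found && call$strand == "+" && call$start == utr5_len &&
        call$end == utr5_len + nchar(orf))
      return(list(seq = tx, cds_start = utr5_len,
                  cds_end = utr5_len + nchar(orf), stop = stop_codon))
  }
  stop("could not place UTRs without outranking the planted ORF")
}

#' Fabricate reciprocal and reference hit tables for known pairs
#'
#' Emits the four similarity-search tables the orthology stage consumes
#' (A->B, B->A, A->reference, B->reference) in 12-column tabular format.
#' True pairs get mutually best rows; decoy rows against other subjects get
#' strictly lower bitscores; both members of a true pair point to the same
#' fabricated reference-protein accession, except for planted confounders.
#' Bitscores are fabricated rank-consistent numbers, not alignment scores:
#' the orthology stage consumes only their ordering and the match lengths.
#'
#' Planted confounders, driven by `pairs$plant`:
#' `"short_match"` rows get match length 199 (failing a 200 bp minimum);
#' `"ambig_ref"` pairs have their two members point to different reference
#' accessions.
#'
#' @param transcripts_a,transcripts_b named character vectors of transcript
#'   sequences (names are the ids the tables reference).
#' @param pairs data.frame with columns `pair_id`, `id_A`, `id_B`,
#'   `match_len` and optionally `plant` (default `"clean"`).
#' @param n_decoys decoy rows per true pair and direction.
#' @return list of four data.frames (`ab`, `ba`, `aref`, `bref`) in hit
#'   table layout, plus `accession` mapping pair_id to the shared reference
#'   accession.
#' @export
make_hit_tables <- function(transcripts_a, transcripts_b, pairs,
                            n_decoys = 2L) {
  if (!all(pairs$id_A %in% names(transcripts_a)))
    stop("pairs reference unknown transcript ids in species A")
  if (!all(pairs$id_B %in% names(transcripts_b)))
    stop("pairs reference unknown transcript ids in species B")
  if (is.null(pairs$plant)) pairs$plant <- "clean"
  n <- nrow(pairs)

  hit_row <- function(q, s, len, bits, evalue = 1e-50) {
    data.frame(qseqid = q, sseqid = s, pident = 98.5, length = len,
               mismatch = as.integer(round(len * 0.015)), gapopen = 0L,
               qstart = 1L, qend = len, sstart = 1L, send = len,
               evalue = evalue, bitscore = bits,
               stringsAsFactors = FALSE)
  }

  top_bits <- 500 + rev(seq_len(n))  # rank-consistent, all distinct
  len <- ifelse(pairs$plant == "short_match", 199L, as.integer(pairs$match_len))

  ab <- do.call(rbind, lapply(seq_len(n), function(i)
    hit_row(pairs$id_A[i], pairs$id_B[i], len[i], top_bits[i])))
  ba <- do.call(rbind, lapply(seq_len(n), function(i)
    hit_row(pairs$id_B[i], pairs$id_A[i], len[i], top_bits[i])))

  decoy_rows <- function(queries, subjects, partner) {
    out <- list()
    for (i in seq_along(queries)) {
      others <- setdiff(subjects, partner[i])
      if (length(others) == 0L || n_decoys == 0L) next
      pick <- sample(others, min(n_decoys, length(others)))
      for (s in pick) {
        out[[length(out) + 1L]] <-
          hit_row(queries[i], s, sample(150:400, 1L),
                  bits = round(top_bits[i] * stats::runif(1, 0.3, 0.8), 1),
                  evalue = 1e-10)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  ab <- rbind(ab, decoy_rows(pairs$id_A, pairs$id_B, pairs$id_B))
  ba <- rbind(ba, decoy_rows(pairs$id_B, pairs$id_A, pairs$id_A))

  acc <- sprintf("Q%05d", seq_len(n))
  acc_b <- ifelse(pairs$plant == "ambig_ref", sprintf("Q%05dX", seq_len(n)), acc)
  ref_bits <- 300 + rev(seq_len(n))
  aref <- do.call(rbind, lapply(seq_len(n), function(i)
    hit_row(pairs$id_A[i], acc[i], 150L, ref_bits[i], evalue = 1e-30)))
  bref <- do.call(rbind, lapply(seq_len(n), function(i)
    hit_row(pairs$id_B[i], acc_b[i], 150L, ref_bits[i], evalue = 1e-30)))
  # secondary, lower-scoring reference hits exercise the ranking rule
  sec <- sample(n)
  aref <- rbind(aref, do.call(rbind, lapply(seq_len(n), function(i)
    hit_row(pairs$id_A[i], sprintf("Q9%04dS", sec[i]), 120L,
            round(ref_bits[i] * 0.6, 1), evalue = 1e-8))))

  shuffle <- function(df) df[sample(nrow(df)), , drop = FALSE]
  list(ab = shuffle(ab), ba = shuffle(ba), aref = shuffle(aref),
       bref = shuffle(bref),
       accession = stats::setNames(acc, pairs$pair_id))
}

#' Simulate a two-group negative-binomial count matrix
#'
#' Draws counts for two species with two replicates each. Gene means are
#' scaled by library size and split across groups by the per-gene log2 fold
#' change (species A gets `+log2fc/2`, species B `-log2fc/2`).
#' `dispersion = 0` degenerates to Poisson sampling.
#'
#' @param n_genes number of genes.
#' @param log2fc per-gene true log2 fold change (A over B); recycled.
#' @param dispersion common negative-binomial dispersion (>= 0).
#' @param lib_sizes library sizes for the four samples (A_1, A_2, B_1, B_2).
#' @param base_means per-gene expected counts at the average library size;
#'   `NULL` draws them log-normally (meanlog log(200), sdlog 1).
#' @return integer matrix genes x 4 with a `true_log2fc` attribute.
#' @export
simulate_counts <- function(n_genes, log2fc = 0, dispersion = 0.05,
                            lib_sizes = rep(1e6, 4), base_means = NULL) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (any(lib_sizes <= 0)) stop("lib_sizes must be positive")
  if (length(lib_sizes) != 4L) stop("exactly 2 samples per group expected")
  log2fc <- rep_len(log2fc, n_genes)
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  if (is.null(base_means))
    base_means <- stats::rlnorm(n_genes, meanlog = log(200), sdlog = 1)
  if (any(base_means < 0)) stop("negative mean")
  sign <- c(1, 1, -1, -1)
  mu <- outer(base_means, lib_sizes / mean(lib_sizes)) *
    2^(outer(log2fc / 2, sign))
  draw <- if (dispersion == 0)
    function(m) stats::rpois(length(m), m)
  else
    function(m) stats::rnbinom(length(m), size = 1 / dispersion, mu = m)
  counts <- matrix(draw(mu), nrow = n_genes,
                   dimnames = list(sprintf("gene_%04d", seq_len(n_genes)),
                                   c("A_1", "A_2", "B_1", "B_2")))
  storage.mode(counts) <- "integer"
  attr(counts, "true_log2fc") <- stats::setNames(log2fc, rownames(counts))
  counts
}

#' Simulate a flat pathway annotation with optional planted gene sets
#'
#' Assigns genes to pathways at random; a planted pathway draws a stated
#' fraction of its members from a supplied signal set (e.g. true DEGs), so
#' over-representation tests have a known positive.
#'
#' @param gene_ids universe of gene ids.
#' @param n_pathways number of pathways.
#' @param genes_per_pathway genes sampled into each pathway.
#' @param planted optional list of `pathway_id = character vector of signal
#'   genes`; 80% of that pathway's members come from the signal set.
#' @return data.frame with columns `gene_id`, `pathway_id`, `pathway_name`,
#'   `category`.
#' @export
simulate_annotation <- function(gene_ids, n_pathways = 12L,
                                genes_per_pathway = 12L, planted = NULL) {
  cats <- c("metabolism", "genetic information processing",
            "environmental information processing", "cellular processes",
            "organismal systems")
  ids <- sprintf("path%03d", seq_len(n_pathways))
  rows <- lapply(seq_len(n_pathways), function(i) {
    k <- min(genes_per_pathway, length(gene_ids))
    if (!is.null(planted) && ids[i] %in% names(planted)) {
      signal <- intersect(planted[[ids[i]]], gene_ids)
      n_sig <- min(length(signal), round(0.8 * k))
      members <- c(sample(signal, n_sig),
                   sample(setdiff(gene_ids, signal), k - n_sig))
    } else {
      members <- sample(gene_ids, k)
    }
    data.frame(gene_id = members, pathway_id = ids[i],
               pathway_name = sprintf("Pathway %03d", i),
               category = cats[(i - 1L) %% length(cats) + 1L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a complete two-species study with ground truth
#'
#' Generates everything the pipeline consumes: transcript FASTA sets for
#' two species, four hit tables, an ortholog count matrix, a pathway
#' annotation, and a truth manifest. Confounder pairs are planted to
#' exercise each filter of the ortholog cascade:
#' \describe{
#'   \item{short_match}{hit rows of length 199, failing the 200 bp minimum.}
#'   \item{ambig_ref}{members mapping to different reference accessions.}
#'   \item{short_cds}{a 50-codon CDS (150 nt), failing the > 150 nt rule.}
#'   \item{internal_stop}{a TGA planted mid-CDS in species B.}
#' }
#' For short_cds and internal_stop plants the fabricated match length is
#' the full transcript length (a real search would align through the UTRs),
#' so these pairs pass the reciprocal-hit stage and are rejected by the CDS
#' filters, each with its own recorded reason.
#'
#' Differential expression and enrichment truth: a fraction `frac_de` of
#' retained orthologs get a true log2 fold change of `+/- lfc_de`, and one
#' pathway is planted to be enriched in those genes.
#'
#' @param params a [sim_params()] object; `params$seed` seeds the run.
#' @param confounders named counts of planted confounder pairs (out of
#'   `params$n_pairs`).
#' @param frac_de fraction of retained genes with a true fold change.
#' @param lfc_de absolute true log2 fold change of those genes.
#' @param dispersion negative-binomial dispersion of the counts.
#' @param lib_sizes library sizes for the four samples.
#' @param n_pathways,genes_per_pathway annotation shape.
#' @param out_dir if non-NULL, write all inputs there via [write_study()].
#' @return list of class `ortho_sim` with transcripts, hit tables, counts,
#'   annotation and a `truth` manifest.
#' @export
simulate_study <- function(params = sim_params(),
                           confounders = c(short_match = 5L, ambig_ref = 5L,
                                           short_cds = 5L, internal_stop = 5L),
                           frac_de = 0.25, lfc_de = 2, dispersion = 0.05,
                           lib_sizes = rep(1e6, 4), n_pathways = 12L,
                           genes_per_pathway = 12L, out_dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_pairs
  if (sum(confounders) > n) stop("more confounders than pairs")
  plant <- rep("clean", n)
  if (sum(confounders) > 0) {
    slots <- sample(n, sum(confounders))
    plant[slots] <- rep(names(confounders), confounders)
  }

  pair_id <- sprintf("pair_%04d", seq_len(n))
  id_a <- sprintf("trA_%04d", seq_len(n))
  id_b <- sprintf("trB_%04d", seq_len(n))
  tx_a <- stats::setNames(character(n), id_a)
  tx_b <- stats::setNames(character(n), id_b)
  cds_a <- cds_b <- stats::setNames(character(n), pair_id)
  match_len <- integer(n)

  for (i in seq_len(n)) {
    nc <- if (plant[i] == "short_cds") 50L else params$n_codons
    anc <- sample_ancestral_cds(nc, params$codon_freqs)
    pr <- evolve_pair(anc, params)
    ca <- pr$cds_a
    cb <- pr$cds_b
    if (plant[i] == "internal_stop") {
      k <- max(2L, nc %/% 2L)  # never the ATG
      substr(cb, 3L * (k - 1L) + 1L, 3L * k) <- "TGA"
    }
    ta <- make_transcript(ca, params$utr5_len, params$utr3_len)
    tb <- make_transcript(cb, params$utr5_len, params$utr3_len,
                          check_orf = plant[i] != "internal_stop")
    tx_a[i] <- ta$seq
    tx_b[i] <- tb$seq
    cds_a[i] <- ca
    cds_b[i] <- cb
    match_len[i] <- if (plant[i] %in% c("short_cds", "internal_stop"))
      nchar(ta$seq) else 3L * nc + 3L
  }

  pairs <- data.frame(pair_id = pair_id, id_A = id_a, id_B = id_b,
                      match_len = match_len, plant = plant,
                      stringsAsFactors = FALSE)
  hits <- make_hit_tables(tx_a, tx_b, pairs)

  # count/annotation gene ids are the species-A transcript ids of the
  # retained pairs, the key the pipeline joins on
  kept <- id_a[plant == "clean"]
  n_de <- round(frac_de * length(kept))
  lfc <- stats::setNames(rep(0, length(kept)), kept)
  de_genes <- character(0)
  if (n_de > 0) {
    de_genes <- sample(kept, n_de)
    lfc[de_genes] <- lfc_de * sample(c(-1, 1), n_de, replace = TRUE)
  }
  counts <- simulate_counts(length(kept), log2fc = unname(lfc),
                            dispersion = dispersion, lib_sizes = lib_sizes)
  rownames(counts) <- kept
  attr(counts, "true_log2fc") <- lfc

  planted_path <- if (length(de_genes) >= 3) list(path001 = de_genes) else NULL
  annotation <- simulate_annotation(kept, n_pathways = n_pathways,
                                    genes_per_pathway = genes_per_pathway,
                                    planted = planted_path)

  truth <- list(
    pairs = data.frame(pairs,
                       true_kappa = params$kappa, true_omega = params$omega,
                       true_t = params$t,
                       expected_kept = plant == "clean",
                       stringsAsFactors = FALSE),
    genes = data.frame(gene_id = kept, true_log2fc = unname(lfc),
                       stringsAsFactors = FALSE),
    pathways = data.frame(
      pathway_id = unique(annotation$pathway_id),
      planted_enriched = unique(annotation$pathway_id) %in%
        names(planted_path),
      stringsAsFactors = FALSE))

  sim <- structure(list(params = params, transcripts_a = tx_a,
                        transcripts_b = tx_b, cds_a = cds_a, cds_b = cds_b,
                        hits = hits[c("ab", "ba", "aref", "bref")],
                        counts = counts, groups = c("A", "A", "B", "B"),
                        annotation = annotation, truth = truth),
                   class = "ortho_sim")
  if (!is.null(out_dir)) write_study(sim, out_dir)
  sim
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Produces two FASTA files, four tab-separated hit tables, a counts TSV, a
#' group map, an annotation TSV and the truth manifest.
#'
#' @param sim an `ortho_sim` object from [simulate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  stopifnot(inherits(sim, "ortho_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- function(x, path) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  }
  fa(sim$transcripts_a, file.path(dir, "species_A.fasta"))
  fa(sim$transcripts_b, file.path(dir, "species_B.fasta"))
  write_hit_table(sim$hits$ab, file.path(dir, "hits_AB.tsv"))
  write_hit_table(sim$hits$ba, file.path(dir, "hits_BA.tsv"))
  write_hit_table(sim$hits$aref, file.path(dir, "hits_Aref.tsv"))
  write_hit_table(sim$hits$bref, file.path(dir, "hits_Bref.tsv"))
  tsv <- function(df, path, rn = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
  tsv(data.frame(gene_id = rownames(sim$counts), sim$counts,
                 check.names = FALSE), file.path(dir, "counts.tsv"))
  tsv(data.frame(sample = colnames(sim$counts), group = sim$groups),
      file.path(dir, "groups.tsv"))
  tsv(sim$annotation, file.path(dir, "annotation.tsv"))
  tsv(sim$truth$pairs, file.path(dir, "truth_pairs.tsv"))
  tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  tsv(sim$truth$pathways, file.path(dir, "truth_pathways.tsv"))
  invisible(dir)
}

#' Path length giving a target synonymous divergence
#'
#' Inverts the simulator's time scale: given model parameters, returns the
#' `t` (expected substitutions per codon over the whole path) at which the
#' expected synonymous divergence per synonymous site equals `target_ks`.
#' Synonymous sites are counted with mutation-opportunity weighting
#' (transition bias and codon frequencies), evaluated at the equilibrium
#' codon distribution; CpG acceleration is ignored here, so with
#' `cpg_multiplier > 1` realised Ks runs slightly above target.
#'
#' @param params a [sim_params()] object.
#' @param target_ks desired expected synonymous substitutions per
#'   synonymous site.
#' @return a single positive number usable as `t`.
#' @export
t_for_ks <- function(params, target_ks = 0.5) {
  stopifnot(inherits(params, "sim_params"))
  mt <- .mut_table()
  pi_codon <- params$codon_freqs[mt$codon]
  w <- ifelse(mt$stop, 0,
              params$codon_freqs[mt$target] *
                ifelse(mt$ts, params$kappa, 1) *
                ifelse(mt$syn, 1, params$omega))
  rate_total <- sum(pi_codon * w)
  rate_syn <- sum(pi_codon * w * mt$syn)
  s_pc <- .site_count_s(params$codon_freqs, params$kappa,
                        params$codon_freqs)
  target_ks * s_pc / (rate_syn / rate_total)
}

# Expected synonymous sites per codon under codon distribution `freqs`,
# with mutation-opportunity weights kappa^[ts] * pi_target.
.site_count_s <- function(freqs, kappa, pi) {
  mt <- .mut_table()
  w <- ifelse(mt$stop, 0, pi[mt$target] * ifelse(mt$ts, kappa, 1))
  key <- paste(mt$codon, mt$pos)
  tot <- tapply(w, key, sum)
  syn <- tapply(w * mt$syn, key, sum)
  frac <- ifelse(tot > 0, syn / tot, 0)
  cod <- sub(" .*", "", names(tot))
  s_per_codon <- tapply(frac, cod, sum)
  sum(freqs[names(s_per_codon)] * s_per_codon)
}
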