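# End-to-end pipeline: orthology cascade -> CDS delineation and filters ->
# codon alignments -> divergence table, identities, Ka/Ks -> differential
# expression -> enrichment. Every stage is deterministic given its inputs;
# running the pipeline twice on the same input directory produces
# byte-identical outputs. Genes are keyed throughout by the species-A
# transcript id of the ortholog pair.

.read_fasta_chr <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*", "", names(x)))
}

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Run the full cross-species divergence pipeline on an input directory
#'
#' Expects the file layout written by [write_study()]: `species_A.fasta`,
#' `species_B.fasta`, hit tables `hits_AB.tsv`, `hits_BA.tsv`,
#' `hits_Aref.tsv`, `hits_Bref.tsv`, plus `counts.tsv`, `groups.tsv` and
#' `annotation.tsv`. Writes result tables to `out_dir` (orthologs with
#' per-pair filter outcomes, divergence table, identities, Ka/Ks,
#' differential expression, enrichment, per-pathway summary) and returns
#' the corresponding objects.
#'
#' @param input_dir directory with the pipeline inputs.
#' @param out_dir directory for result TSVs; `NULL` skips writing.
#' @param min_match_len minimum cross-species match length (nt).
#' @param evalue_max maximum reference-protein e-value.
#' @param min_cds CDS length threshold (kept only if longer).
#' @param kaks_method `"yn00"` or `"ng86"`.
#' @param lfc_min,fdr_max differential-expression thresholds.
#' @param divergence_quantile identity quantile defining the
#'   high-divergence set.
#' @param cpg_mode CpG context rule for the divergence table, see
#'   [classify_cpg()].
#' @return list with `orthologs`, `cds`, `alignments`, `divergence`,
#'   `identity`, `kaks`, `de`, `deg_enrichment`, `highdiv_enrichment`,
#'   `pathway_summary`, `high_divergence`.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL, min_match_len = 200L,
                         evalue_max = 1e-5, min_cds = 150L,
                         kaks_method = "yn00", lfc_min = 1, fdr_max = 0.05,
                         divergence_quantile = 0.25, cpg_mode = "either") {
  p <- function(f) file.path(input_dir, f)
  seqs_a <- .read_fasta_chr(p("species_A.fasta"))
  seqs_b <- .read_fasta_chr(p("species_B.fasta"))
  orth <- find_orthologs(read_hit_table(p("hits_AB.tsv")),
                         read_hit_table(p("hits_BA.tsv")),
                         read_hit_table(p("hits_Aref.tsv")),
                         read_hit_table(p("hits_Bref.tsv")),
                         min_match_len = min_match_len,
                         evalue_max = evalue_max)
  accepted <- orth[orth$retained, , drop = FALSE]
  proc <- process_pairs(data.frame(pair_id = accepted$id_A,
                                   id_A = accepted$id_A,
                                   id_B = accepted$id_B,
                                   stringsAsFactors = FALSE),
                        seqs_a, seqs_b, min_cds = min_cds)
  cds_info <- proc$pairs[, c("id_A", "cds_len_a", "cds_len_b", "keep",
                             "reason")]
  names(cds_info)[names(cds_info) == "reason"] <- "cds_reason"
  orthologs <- merge(orth, cds_info, by = "id_A", all.x = TRUE, sort = TRUE)
  orthologs$keep[is.na(orthologs$keep)] <- FALSE
  orthologs$reason <- ifelse(!orthologs$retained, orthologs$reason,
                             ifelse(is.na(orthologs$cds_reason), "",
                                    orthologs$cds_reason))
  orthologs$cds_reason <- NULL
  alns <- proc$alignments
  div <- divergence_table(alns, cpg_mode = cpg_mode)
  ident <- t(vapply(alns, sequence_identity, numeric(2)))
  identity <- data.frame(gene = rownames(ident),
                         nt_identity = ident[, "nt"],
                         aa_identity = ident[, "aa"],
                         stringsAsFactors = FALSE)
  rownames(identity) <- NULL
  kk <- batch_kaks(alns, method = kaks_method)

  counts_df <- .read_tsv(p("counts.tsv"))
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df[[1]]
  groups_df <- .read_tsv(p("groups.tsv"))
  groups <- groups_df$group[match(colnames(counts), groups_df$sample)]
  counts <- counts[rownames(counts) %in% names(alns), , drop = FALSE]
  de <- call_deg(de_test(counts, groups), lfc_min = lfc_min,
                 fdr_max = fdr_max)

  annotation <- .read_tsv(p("annotation.tsv"))
  deg_enr <- pathway_deg_enrichment(de$table, annotation)
  aa_ident <- stats::setNames(identity$aa_identity, identity$gene)
  hd <- high_divergence_set(aa_ident, divergence_quantile)
  hd_enr <- gene_set_enrichment(hd$genes, names(aa_ident), annotation)
  path_sum <- pathway_divergence_summary(aa_ident, kk$table, annotation)

  res <- list(orthologs = orthologs, cds = proc$pairs, alignments = alns,
              divergence = div, identity = identity, kaks = kk,
              de = de, deg_enrichment = deg_enr,
              highdiv_enrichment = hd_enr, pathway_summary = path_sum,
              high_divergence = hd)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(out_dir, f)
    .write_tsv(orthologs, o("orthologs.tsv"))
    .write_tsv(div, o("divergence_table.tsv"))
    .write_tsv(identity, o("identity.tsv"))
    .write_tsv(kk$table, o("kaks.tsv"))
    .write_tsv(data.frame(statistic = names(kk$summary),
                          value = unlist(lapply(kk$summary, format,
                                                digits = 10))),
               o("kaks_summary.tsv"))
    .write_tsv(de$table, o("de.tsv"))
    .write_tsv(deg_enr, o("enrichment_deg.tsv"))
    .write_tsv(hd_enr, o("enrichment_highdiv.tsv"))
    .write_tsv(path_sum, o("pathway_summary.tsv"))
    .write_tsv(data.frame(gene = hd$genes,
                          threshold = rep(hd$threshold,
                                          length(hd$genes))),
               o("high_divergence.tsv"))
  }
  res
}
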