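# Gene-set over-representation in pathway annotations, and per-pathway
# aggregation of divergence statistics. The over-representation test is
# the one-sided upper-tail hypergeometric test.

#' High-divergence gene set by amino-acid identity quantile
#'
#' The threshold is the stated quantile (linear interpolation) of
#' amino-acid identity across all orthologs; the set contains the genes
#' strictly below it.
#'
#' @param aa_identities named numeric vector of percent amino-acid
#'   identities (names are gene ids).
#' @param quantile quantile defining the threshold (default: lower
#'   quartile).
#' @return list with `genes` (character vector) and `threshold`.
#' @export
high_divergence_set <- function(aa_identities, quantile = 0.25) {
  if (length(aa_identities) < 4L) stop("at least 4 genes required")
  thr <- unname(stats::quantile(aa_identities, quantile, type = 7))
  list(genes = names(aa_identities)[aa_identities < thr], threshold = thr)
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of observing at least the actual overlap between `set` and
#' `pathway_genes` when `pathway_genes` are drawn without replacement from
#' `universe`; computed by exact summation of the hypergeometric mass.
#'
#' @param set,pathway_genes,universe character vectors;
#'   `set` and `pathway_genes` must be subsets of `universe`.
#' @return the p-value.
#' @export
hypergeom_overrep <- function(set, pathway_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  set <- unique(set)
  pathway_genes <- unique(pathway_genes)
  if (!all(set %in% universe) || !all(pathway_genes %in% universe))
    stop("set and pathway_genes must be subsets of the universe")
  k <- length(intersect(set, pathway_genes))
  K <- length(set)
  n <- length(pathway_genes)
  N <- length(universe)
  sum(stats::dhyper(k:min(K, n), K, N - K, n))
}

#' Pathway over-representation of differentially expressed genes
#'
#' One row per pathway with at least one annotated gene in the universe:
#' the overlap of the DEG set with the pathway, its upper-tail
#' hypergeometric p-value, and the BH adjustment across all tested
#' pathways. The universe defaults to all tested genes carrying at least
#' one annotation.
#'
#' @param de_calls table from [call_deg()] (or any data.frame with `gene`
#'   and `call` columns).
#' @param annotation data.frame with `gene_id` and `pathway_id` (extra
#'   columns such as `pathway_name` are carried through).
#' @param universe optional character vector overriding the default
#'   universe.
#' @return data.frame with `pathway_id`, `n_set`, `n_pathway`, `pvalue`,
#'   `fdr`, ordered by p-value.
#' @export
pathway_deg_enrichment <- function(de_calls, annotation, universe = NULL) {
  tab <- if (is.list(de_calls) && !is.data.frame(de_calls)) de_calls$table
  else de_calls
  deg <- tab$gene[tab$call != "ns"]
  gene_set_enrichment(deg, tab$gene, annotation, universe)
}

#' Pathway over-representation of an arbitrary gene set
#'
#' Workhorse behind [pathway_deg_enrichment()]; also used for
#' high-divergence gene sets.
#'
#' @param set character vector of genes of interest.
#' @param tested character vector of all genes entering the analysis.
#' @param annotation data.frame with `gene_id`, `pathway_id`.
#' @param universe optional override; default: tested genes with >= 1
#'   annotation.
#' @return data.frame with `pathway_id`, `pathway_name` (if present),
#'   `n_set`, `n_pathway`, `pvalue`, `fdr`, ordered by p-value.
#' @export
gene_set_enrichment <- function(set, tested, annotation, universe = NULL) {
  if (is.null(universe))
    universe <- intersect(unique(tested), unique(annotation$gene_id))
  universe <- unique(universe)
  set <- intersect(unique(set), universe)
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  paths <- unique(ann$pathway_id)
  rows <- lapply(paths, function(pw) {
    pg <- unique(ann$gene_id[ann$pathway_id == pw])
    data.frame(pathway_id = pw,
               n_set = length(intersect(set, pg)),
               n_pathway = length(pg),
               pvalue = hypergeom_overrep(set, pg, universe),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(pathway_id = character(0),
                                      n_set = integer(0),
                                      n_pathway = integer(0),
                                      pvalue = numeric(0), fdr = numeric(0)))
  if (!is.null(annotation$pathway_name)) {
    nm <- annotation$pathway_name[match(out$pathway_id,
                                        annotation$pathway_id)]
    out <- cbind(out[1], pathway_name = nm, out[-1])
  }
  out$fdr <- bh_adjust(out$pvalue)
  out[order(out$pvalue, out$pathway_id), , drop = FALSE]
}

#' Per-pathway divergence summary
#'
#' Aggregates amino-acid identity and Ka/Ks per pathway (and per category
#' when the annotation carries one): gene count, mean amino-acid identity,
#' and mean omega over genes with a defined omega.
#'
#' @param aa_identities named numeric vector (percent identity per gene).
#' @param kaks_table per-pair table from [batch_kaks()] (columns `pair_id`
#'   and `omega`); may be `NULL`.
#' @param annotation data.frame with `gene_id`, `pathway_id` and optional
#'   `pathway_name`, `category`.
#' @return data.frame with one row per pathway: `n_genes`,
#'   `mean_aa_identity`, `mean_omega` (`NA` when no omega is defined),
#'   ordered by increasing mean identity (most divergent first).
#' @export
pathway_divergence_summary <- function(aa_identities, kaks_table,
                                       annotation) {
  ann <- annotation[annotation$gene_id %in% names(aa_identities), ,
                    drop = FALSE]
  omega <- if (!is.null(kaks_table))
    stats::setNames(kaks_table$omega, kaks_table$pair_id)
  else stats::setNames(numeric(0), character(0))
  paths <- unique(ann$pathway_id)
  rows <- lapply(paths, function(pw) {
    genes <- unique(ann$gene_id[ann$pathway_id == pw])
    om <- omega[genes]
    om <- om[!is.na(om)]
    data.frame(pathway_id = pw,
               pathway_name = if (!is.null(ann$pathway_name))
                 ann$pathway_name[match(pw, ann$pathway_id)] else pw,
               category = if (!is.null(ann$category))
                 ann$category[match(pw, ann$pathway_id)] else NA_character_,
               n_genes = length(genes),
               mean_aa_identity = mean(aa_identities[genes]),
               mean_omega = if (length(om)) mean(om) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mean_aa_identity), , drop = FALSE]
}
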