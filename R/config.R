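#' Analysis configuration
#'
#' Central record of every tunable threshold used across the pipeline, with
#' defaults matching the study design this package operationalises:
#' differential calls at FDR 0.1, pseudobulk DE additionally at
#' |log2FC| >= 0.2, an expression filter at mean count > 100 within a
#' condition, peak-to-gene annotation windows of 20 kb upstream / 10 kb
#' downstream of the TSS, enhancer probability > 0.8, motif co-occurrence at
#' a 50-bp gap against 1,000 background subsamples, 100 random control motif
#' sets for footprint envelopes, preranked GSEA with 1,000 permutations and
#' 300-gene signature sets (FDR < 0.05, |log2FC| > 2), single-cell QC at
#' >= 1,200 detected genes, 7,000 highly variable genes, 50 principal
#' components, and 15-nearest-neighbour projection.
#'
#' @param da_fdr FDR threshold for differential accessibility classes.
#' @param de_fdr FDR threshold for pseudobulk differential expression.
#' @param de_min_abs_lfc Minimum |log2FC| for a pseudobulk DE call.
#' @param expr_filter_mean Mean-count filter: keep a feature if its mean
#'   count exceeds this in at least one group level (strict).
#' @param annot_upstream,annot_downstream TSS window, in gene orientation.
#' @param enhancer_prob_min Enhancer probability cutoff (strict `>`).
#' @param cooc_gap Maximum nearest-edge gap (bp) for motif co-occurrence.
#' @param cooc_n_bg Number of background peak subsamples for the z-score.
#' @param ctcf_n_sets Number of random control-motif sets for the footprint
#'   envelope.
#' @param gsea_n_perm Gene-label permutations for GSEA significance.
#' @param sig_set_size Signature gene-set size cap.
#' @param sig_fdr,sig_min_abs_lfc Signature candidate thresholds.
#' @param qc_min_genes Minimum detected genes per cell.
#' @param n_hvg Number of highly variable genes.
#' @param n_pcs Number of principal components.
#' @param proj_k Neighbours used for query-to-reference projection.
#' @param knn_graph_k Reference-graph neighbour count, recorded for
#'   provenance only (graph clustering is performed outside this package).
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(da_fdr = 0.1,
                            de_fdr = 0.1,
                            de_min_abs_lfc = 0.2,
                            expr_filter_mean = 100,
                            annot_upstream = 20000L,
                            annot_downstream = 10000L,
                            enhancer_prob_min = 0.8,
                            cooc_gap = 50L,
                            cooc_n_bg = 1000L,
                            ctcf_n_sets = 100L,
                            gsea_n_perm = 1000L,
                            sig_set_size = 300L,
                            sig_fdr = 0.05,
                            sig_min_abs_lfc = 2,
                            qc_min_genes = 1200L,
                            n_hvg = 7000L,
                            n_pcs = 50L,
                            proj_k = 15L,
                            knn_graph_k = 8L) {
  cfg <- list(
    da_fdr = da_fdr, de_fdr = de_fdr, de_min_abs_lfc = de_min_abs_lfc,
    expr_filter_mean = expr_filter_mean,
    annot_upstream = as.integer(annot_upstream),
    annot_downstream = as.integer(annot_downstream),
    enhancer_prob_min = enhancer_prob_min,
    cooc_gap = as.integer(cooc_gap), cooc_n_bg = as.integer(cooc_n_bg),
    ctcf_n_sets = as.integer(ctcf_n_sets),
    gsea_n_perm = as.integer(gsea_n_perm),
    sig_set_size = as.integer(sig_set_size),
    sig_fdr = sig_fdr, sig_min_abs_lfc = sig_min_abs_lfc,
    qc_min_genes = as.integer(qc_min_genes),
    n_hvg = as.integer(n_hvg), n_pcs = as.integer(n_pcs),
    proj_k = as.integer(proj_k), knn_graph_k = as.integer(knn_graph_k)
  )
  stopifnot(
    cfg$da_fdr > 0, cfg$da_fdr < 1, cfg$de_fdr > 0, cfg$de_fdr < 1,
    cfg$de_min_abs_lfc >= 0, cfg$expr_filter_mean >= 0,
    cfg$annot_upstream >= 0, cfg$annot_downstream >= 0,
    cfg$enhancer_prob_min >= 0, cfg$enhancer_prob_min <= 1,
    cfg$cooc_gap >= 0, cfg$cooc_n_bg >= 1, cfg$ctcf_n_sets >= 1,
    cfg$gsea_n_perm >= 1, cfg$sig_set_size >= 1,
    cfg$sig_fdr > 0, cfg$sig_fdr < 1, cfg$sig_min_abs_lfc >= 0,
    cfg$qc_min_genes >= 0, cfg$n_hvg >= 1, cfg$n_pcs >= 1, cfg$proj_k >= 1
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' @method print analysis_config
#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
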