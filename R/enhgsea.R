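#' Filter peaks by enhancer probability
#'
#' Keeps peaks whose enhancer probability strictly exceeds the threshold
#' (`> 0.8` by default). Probabilities come from the `enh_prob` metadata
#' column (BED score / 1000 on disk).
#'
#' @param peaks A [peak_set()] with an `enh_prob` column.
#' @param min_prob Probability threshold (strict).
#' @return Filtered `peak_set`.
#' @export
enhancer_filter <- function(peaks, min_prob = 0.8) {
  prob <- S4Vectors::mcols(peaks$ranges)$enh_prob
  if (is.null(prob) || anyNA(prob))
    stopf("peaks lack enhancer probabilities")
  keep <- prob > min_prob
  peak_set(peaks$ranges[keep],
           if (!is.null(peaks$seqs)) peaks$seqs[keep])
}

#' Build a gene-level ranked list from peak differential results
#'
#' Rank value per peak: `log2FC * (-log10 FDR)` (FDR floored at 1e-300
#' before the log). Unannotated peaks are dropped. Each gene keeps the peak
#' with the largest |log2FC| (signed-maximum selection available via
#' `dedup = "signed"`); ranks are sorted descending, ties broken by gene id
#' for determinism.
#'
#' @param da A `differential_result` on peaks (columns `feature`, `log2fc`,
#'   `fdr`).
#' @param annotation Peak-to-gene map from [annotate_peaks()] (`peak`,
#'   `gene`).
#' @param dedup `"abs"` (default: keep the peak of maximal |log2FC| per
#'   gene) or `"signed"` (maximal signed log2FC).
#' @return Data frame of class `"ranked_list"` (`gene`, `rank`), sorted
#'   descending by rank.
#' @export
build_ranked_list <- function(da, annotation, dedup = c("abs", "signed")) {
  dedup <- match.arg(dedup)
  gene <- annotation$gene[match(da$feature, annotation$peak)]
  keep <- !is.na(gene)
  df <- data.frame(gene = gene[keep], log2fc = da$log2fc[keep],
                   fdr = pmax(da$fdr[keep], 1e-300))
  df$rank <- df$log2fc * (-log10(df$fdr))
  key <- if (dedup == "abs") abs(df$log2fc) else df$log2fc
  ord <- order(df$gene, -key)
  df <- df[ord, ][!duplicated(df$gene[ord]), ]
  df <- df[order(-df$rank, df$gene), c("gene", "rank")]
  rownames(df) <- NULL
  class(df) <- c("ranked_list", "data.frame")
  attr(df, "dedup") <- dedup
  df
}

#' Build signature gene sets from a reference differential comparison
#'
#' Candidates pass FDR < `sig_fdr` and log2FC > `sig_min_abs_lfc` (up-in-A
#' set) or < `-sig_min_abs_lfc` (up-in-B set); both strict, so a fold
#' change of exactly 2 is excluded. Each set keeps up to `size` candidates
#' of smallest FDR, ties broken by larger |log2FC| then gene id.
#'
#' @param reference_de A `differential_result` oriented A vs B (positive
#'   log2FC = higher in A), with `feature` read as gene ids.
#' @param size Set size cap (default 300).
#' @param sig_fdr FDR threshold (default 0.05).
#' @param sig_min_abs_lfc Fold-change threshold (default 2).
#' @param names Names for the two sets.
#' @return Named list of two character vectors (gene ids).
#' @export
build_signature_sets <- function(reference_de, size = 300, sig_fdr = 0.05,
                                 sig_min_abs_lfc = 2,
                                 names = c("up_in_A", "up_in_B")) {
  pick <- function(dir) {
    cand <- reference_de[!is.na(reference_de$fdr) &
                           reference_de$fdr < sig_fdr &
                           dir * reference_de$log2fc > sig_min_abs_lfc, ]
    if (nrow(cand) < 10)
      warnf("only %d signature candidates in one direction", nrow(cand))
    cand <- cand[order(cand$fdr, -abs(cand$log2fc), cand$feature), ]
    utils::head(cand$feature, size)
  }
  stats::setNames(list(pick(1), pick(-1)), names)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic preranked GSEA running sum: walking down the ranked list, set
#' members increment by `|rank|^p / sum_set |rank|^p` and non-members
#' decrement by `1 / (N - |set|)`; the enrichment score is the
#' maximum-magnitude deviation from zero (signed).
#'
#' @param ranked A [build_ranked_list()] result (or data frame `gene`,
#'   `rank`, sorted descending).
#' @param set Character vector of gene ids.
#' @param p Weight exponent (default 1; `p = 0` gives the unweighted KS).
#' @return List: `es`, `running` (length-N running sum), `hit_idx`,
#'   `leading_edge` (genes up to the extremum, on the extremum's side).
#' @export
enrichment_score <- function(ranked, set, p = 1) {
  N <- nrow(ranked)
  inset <- ranked$gene %in% set
  n_hit <- sum(inset)
  if (n_hit == 0) stopf("no overlap between ranked list and gene set")
  wt <- abs(ranked$rank)^p
  inc <- numeric(N)
  denom_hit <- sum(wt[inset])
  inc[inset] <- if (denom_hit > 0) wt[inset] / denom_hit else 1 / n_hit
  if (N > n_hit) inc[!inset] <- -1 / (N - n_hit)
  running <- cumsum(inc)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  le <- if (es >= 0) ranked$gene[seq_len(i_max)][inset[seq_len(i_max)]]
  else ranked$gene[seq(i_max + 1, N)][inset[seq(i_max + 1, N)]]
  list(es = es, running = running, hit_idx = which(inset),
       leading_edge = le)
}

#' Permutation significance for a preranked enrichment score
#'
#' Null enrichment scores from `n_perm` random gene-label sets of the same
#' effective size. Significance compares magnitudes over the whole null
#' ensemble: p = (1 + #\{|ES_null| >= |ES|\}) / (n_perm + 1), so the
#' attainable minimum is 1/(n_perm+1) and null sets give uniform p. NES
#' normalises the observed ES by the mean |ES_null| of the matching sign
#' (standard sign-matched convention).
#'
#' @param ranked A ranked list (see [enrichment_score()]).
#' @param set Character vector of gene ids.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param p Weight exponent.
#' @return List of class `"enrichment_result"`: `es`, `nes`, `p`,
#'   `running`, `leading_edge`, `n_perm`, `seed`, `null_es`.
#' @export
permutation_pvalue <- function(ranked, set, n_perm = 1000, seed = 1L,
                               p = 1) {
  obs <- enrichment_score(ranked, set, p)
  n_eff <- sum(ranked$gene %in% set)
  null_es <- withr::with_seed(derive_seed(seed, 13L), {
    vapply(seq_len(n_perm), function(r) {
      rs <- ranked$gene[sample.int(nrow(ranked), n_eff)]
      enrichment_score(ranked, rs, p)$es
    }, 0)
  })
  pval <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
  matched <- null_es[sign(null_es) == sign(obs$es)]
  if (length(matched) < 2) {
    warnf("degenerate permutation null (no sign-matched scores)")
    nes <- NA_real_
  } else {
    nes <- obs$es / mean(abs(matched))
  }
  if (stats::sd(null_es) == 0) warnf("degenerate permutation null")
  structure(list(es = obs$es, nes = nes, p = pval, running = obs$running,
                 leading_edge = obs$leading_edge, n_perm = n_perm,
                 seed = seed, null_es = null_es),
            class = "enrichment_result")
}

#' @method print enrichment_result
#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: ES=%.3f NES=%.3f p=%.4g (n_perm=%d)\n",
              x$es, x$nes, x$p, x$n_perm))
  invisible(x)
}
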