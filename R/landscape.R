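#' QC filter on detected genes per cell
#'
#' Keeps cells with at least `min_genes` detected genes (count > 0); cells
#' detecting fewer ("< 1,200 detected genes" in the default configuration)
#' are excluded.
#'
#' @param counts Genes x cells count matrix.
#' @param min_genes Minimum detected genes.
#' @return Named logical mask over cells.
#' @export
qc_filter <- function(counts, min_genes = 1200) {
  det <- Matrix::colSums(counts > 0)
  stats::setNames(det >= min_genes, colnames(counts))
}

#' Assign cell sex from sex-marker expression
#'
#' Cells expressing the female marker (Xist-like) but no Y-linked gene are
#' female; cells expressing at least one Y-linked gene but not the female
#' marker are male; cells expressing both are excluded as suspected
#' doublets; cells expressing neither are excluded as undetermined.
#' "Expressed" means value > 0.
#'
#' @param expr Genes x cells expression matrix (raw or log-normalised).
#' @param female_marker Female marker gene name.
#' @param y_genes Character vector of Y-linked gene names.
#' @return Factor per cell with levels female, male, excluded_doublet,
#'   excluded_undetermined.
#' @export
assign_sex <- function(expr, female_marker = "Xist",
                       y_genes = c("Ddx3y", "Eif2s3y", "Uty")) {
  miss <- setdiff(c(female_marker, y_genes), rownames(expr))
  if (length(miss)) stopf("marker genes missing from matrix: %s",
                          paste(miss, collapse = ", "))
  f <- as.numeric(expr[female_marker, ]) > 0
  y <- Matrix::colSums(expr[y_genes, , drop = FALSE] > 0) > 0
  lab <- rep("excluded_undetermined", ncol(expr))
  lab[f & !y] <- "female"
  lab[!f & y] <- "male"
  lab[f & y] <- "excluded_doublet"
  factor(stats::setNames(lab, colnames(expr)),
         levels = c("female", "male", "excluded_doublet",
                    "excluded_undetermined"))
}

#' Log-normalise, select highly variable genes, and compute PCs
#'
#' Per-cell counts are scaled to the median total count and log1p
#' transformed. Highly variable genes are chosen by within-bin normalised
#' dispersion (variance/mean of the log-normalised values, z-scored within
#' 20 mean-expression bins), honouring an exclusion list (by default the
#' perturbed gene, sex markers and cell-cycle genes are excluded in the
#' study design this emulates). PCs are computed on the standardised HVG
#' submatrix; the gene rotation matrix is returned for projection.
#'
#' @param counts Genes x cells count matrix.
#' @param n_hvg Number of highly variable genes.
#' @param n_pcs Number of principal components.
#' @param exclude Gene names barred from the HVG list.
#' @return List: `lognorm` (genes x cells), `hvg`, `pcs` (cells x n_pcs),
#'   `rotation` (hvg x n_pcs), `center`, `scale` (per-HVG standardisation
#'   moments), `sdev`.
#' @export
lognormalize_and_reduce <- function(counts, n_hvg = 7000, n_pcs = 50,
                                    exclude = character()) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  if (any(tot == 0)) stopf("cell with zero total count")
  target <- stats::median(tot)
  lognorm <- log1p(sweep(counts, 2, tot, "/") * target)

  mu <- rowMeans(lognorm)
  v <- apply(lognorm, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(mu, breaks = unique(stats::quantile(mu, seq(0, 1, 0.05))),
              include.lowest = TRUE)
  zdisp <- stats::ave(disp, bins, FUN = function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  })
  eligible <- setdiff(rownames(counts), exclude)
  n_hvg_eff <- min(n_hvg, length(eligible))
  if (n_hvg_eff < n_hvg) warnf("n_hvg capped at %d genes", n_hvg_eff)
  ord <- order(-zdisp)
  hvg <- rownames(counts)[ord]
  hvg <- hvg[hvg %in% eligible][seq_len(n_hvg_eff)]

  sub <- t(lognorm[hvg, , drop = FALSE]) # cells x hvg
  ctr <- colMeans(sub)
  scl <- apply(sub, 2, stats::sd)
  scl[scl == 0] <- 1
  std <- sweep(sweep(sub, 2, ctr), 2, scl, "/")
  n_pcs_eff <- min(n_pcs, ncol(std), nrow(std) - 1L)
  pca <- stats::prcomp(std, center = FALSE, scale. = FALSE,
                       rank. = n_pcs_eff)
  pcs <- pca$x
  rownames(pcs) <- colnames(counts)
  list(lognorm = lognorm, hvg = hvg, pcs = pcs,
       rotation = pca$rotation, center = ctr, scale = scl,
       sdev = pca$sdev)
}

#' Expression-bin-matched gene score (cell-cycle style)
#'
#' Score per cell = mean log-normalised expression over the gene set minus
#' the mean over control genes drawn, per set gene, from the same
#' mean-expression bin (default 25 bins, 50 controls per gene, seeded) —
#' the standard binned-control scoring used for cell-cycle phase scores.
#'
#' @param lognorm Genes x cells log-normalised matrix.
#' @param genes Gene set to score.
#' @param n_bins Number of mean-expression bins.
#' @param n_ctrl Control genes sampled per set gene.
#' @param seed Integer seed.
#' @return Numeric score per cell.
#' @export
cell_cycle_score <- function(lognorm, genes, n_bins = 25, n_ctrl = 50,
                             seed = 1L) {
  genes <- intersect(genes, rownames(lognorm))
  if (length(genes) < 2) warnf("gene set has fewer than 2 members present")
  if (!length(genes)) stopf("no set gene present in matrix")
  mu <- rowMeans(lognorm)
  br <- unique(stats::quantile(mu, seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(mu, breaks = br, include.lowest = TRUE)
  nonset <- setdiff(rownames(lognorm), genes)
  ctrl <- withr::with_seed(derive_seed(seed, 17L), {
    unlist(lapply(genes, function(g) {
      pool <- rownames(lognorm)[bins == bins[match(g, rownames(lognorm))]]
      pool <- intersect(pool, nonset)
      if (!length(pool)) pool <- nonset # bin exhausted by the set itself
      sample(pool, min(n_ctrl, length(pool)), replace = FALSE)
    }))
  })
  set_mean <- colMeans(lognorm[genes, , drop = FALSE])
  ctrl_mean <- colMeans(lognorm[unique(ctrl), , drop = FALSE])
  set_mean - ctrl_mean
}

#' Direction-of-transition (DoT) score on a reference landscape
#'
#' For each reference cell c, the raw score is
#' `sum_g delta_g * (x_cg - xbar_origin_g)` over the differential genes g,
#' with `delta_g` the perturbation log2 fold change, `x` log-normalised
#' expression, and `xbar_origin` the mean over the origin cells (so the
#' origin mean score is 0 by construction). Positive scores mark cell
#' states the perturbation shifts toward; negative, away from. Per-cell
#' z-scores are computed against `n_null` seeded draws in which the
#' weights are reassigned to random genes from matched expression bins.
#'
#' @param lognorm Genes x cells log-normalised reference matrix.
#' @param weights Named numeric vector: log2 fold changes keyed by gene.
#' @param origin_cells Character vector (or logical/integer index) of
#'   origin cells.
#' @param n_null Size of the matched-gene null ensemble.
#' @param seed Integer seed.
#' @param n_bins Expression bins for null gene matching.
#' @return List of class `"dot_result"`: `raw`, `z`, `weights_used`,
#'   `origin_cells`, `n_null`, `seed`.
#' @export
dot_score <- function(lognorm, weights, origin_cells, n_null = 100,
                      seed = 1L, n_bins = 25) {
  genes <- intersect(names(weights), rownames(lognorm))
  if (!length(genes)) stopf("no differential gene present in landscape")
  if (!length(origin_cells)) stopf("origin cell set is empty")
  wt <- weights[genes]
  X <- lognorm[genes, , drop = FALSE]
  origin_mean <- rowMeans(X[, origin_cells, drop = FALSE])
  centered <- X - origin_mean
  raw <- as.numeric(crossprod(centered, wt))
  names(raw) <- colnames(lognorm)

  mu <- rowMeans(lognorm)
  br <- unique(stats::quantile(mu, seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(mu, breaks = br, include.lowest = TRUE)
  null_mat <- withr::with_seed(derive_seed(seed, 19L), {
    W <- matrix(0, nrow(lognorm), n_null,
                dimnames = list(rownames(lognorm), NULL))
    for (r in seq_len(n_null)) {
      for (g in genes) {
        pool <- rownames(lognorm)[bins == bins[match(g, rownames(lognorm))]]
        pick <- pool[sample.int(length(pool), 1)]
        W[pick, r] <- W[pick, r] + wt[[g]]
      }
    }
    W
  })
  origin_full <- rowMeans(lognorm[, origin_cells, drop = FALSE])
  null_scores <- crossprod(lognorm - origin_full, null_mat) # cells x n_null
  nm <- rowMeans(null_scores)
  nsd <- apply(null_scores, 1, stats::sd)
  z <- ifelse(nsd > 0, (raw - nm) / nsd, 0)
  structure(list(raw = raw, z = stats::setNames(z, names(raw)),
                 weights_used = wt, origin_cells = origin_cells,
                 n_null = n_null, seed = seed),
            class = "dot_result")
}

#' @method print dot_result
#' @export
print.dot_result <- function(x, ...) {
  cat(sprintf("dot_result: %d cells, %d weighted genes, n_null=%d\n",
              length(x$raw), length(x$weights_used), x$n_null))
  invisible(x)
}

#' Project query cells onto a reference landscape
#'
#' Query expression is standardised per gene to the reference HVG moments
#' (this replaces an iterative batch-correction step; acceptance of the
#' projection is neighbour recovery, not coordinate identity), multiplied
#' by the reference PCA rotation, and matched to the k nearest reference
#' cells in PC space (Euclidean). Corrected-PC and 2-D embedding
#' coordinates are predicted as the (by default unweighted) mean of the
#' neighbours' coordinates.
#'
#' @param reference List with `lognorm`, `hvg`, `rotation`, `center`,
#'   `scale`, `pcs` (from [lognormalize_and_reduce()]) plus `corrected`
#'   (cells x PCs) and `embedding` (cells x 2) coordinate matrices.
#'   The query is first aligned by a single global location-scale map to
#'   the reference's pooled expression moments, then standardised per gene
#'   to the reference mean/SD.
#' @param query_lognorm Genes x cells log-normalised query matrix.
#' @param k Number of neighbours.
#' @param weighted Use inverse-distance weighting of neighbours.
#' @param min_overlap Minimum fraction of reference HVGs present in the
#'   query.
#' @return List: `pcs`, `corrected`, `embedding` (query coordinates),
#'   `neighbors` (cells x k reference ids), `distances`.
#' @export
project_cells <- function(reference, query_lognorm, k = 15,
                          weighted = FALSE, min_overlap = 0.5) {
  shared <- intersect(reference$hvg, rownames(query_lognorm))
  if (length(shared) < min_overlap * length(reference$hvg)) {
    miss <- setdiff(reference$hvg, rownames(query_lognorm))
    stopf("query covers only %d/%d reference HVGs (first missing: %s)",
          length(shared), length(reference$hvg),
          paste(utils::head(miss, 5), collapse = ", "))
  }
  idx <- match(shared, reference$hvg)
  Q <- t(query_lognorm[shared, , drop = FALSE]) # cells x genes
  # Two-step alignment standing in for iterative batch correction:
  # (1) one global location-scale map matches the query's overall
  # expression moments (pooled over genes and cells) to the reference's,
  # cancelling platform-wide affine distortions without touching the
  # between-gene signal a homogeneous query carries; (2) per-gene
  # standardisation to the reference moments places the query in the
  # standardised space the reference PCs were computed in.
  Rsub <- as.numeric(reference$lognorm[shared, , drop = FALSE])
  ref_pool_m <- mean(Rsub); ref_pool_s <- stats::sd(Rsub)
  q_pool_m <- mean(Q); q_pool_s <- stats::sd(as.numeric(Q))
  if (q_pool_s > 0)
    Q <- (Q - q_pool_m) / q_pool_s * ref_pool_s + ref_pool_m
  Qstd <- sweep(sweep(Q, 2, reference$center[idx]), 2,
                reference$scale[idx], "/")
  pcs <- Qstd %*% reference$rotation[idx, , drop = FALSE]

  ref_pcs <- reference$pcs
  d2 <- outer(rowSums(pcs^2), rowSums(ref_pcs^2), "+") -
    2 * pcs %*% t(ref_pcs)
  d2[d2 < 0] <- 0
  ord <- apply(d2, 1, function(row) order(row)[seq_len(k)])
  nn <- t(matrix(ord, nrow = k))
  nd <- t(matrix(vapply(seq_len(nrow(nn)), function(i)
    sqrt(d2[i, nn[i, ]]), numeric(k)), nrow = k))

  predict_coords <- function(coords) {
    t(vapply(seq_len(nrow(nn)), function(i) {
      M <- coords[nn[i, ], , drop = FALSE]
      if (weighted) {
        w <- 1 / pmax(nd[i, ], 1e-12)
        colSums(M * w) / sum(w)
      } else colMeans(M)
    }, numeric(ncol(coords))))
  }
  ref_ids <- rownames(ref_pcs)
  list(pcs = pcs,
       corrected = predict_coords(reference$corrected),
       embedding = predict_coords(reference$embedding),
       neighbors = matrix(ref_ids[nn], nrow(nn), k),
       distances = nd)
}
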