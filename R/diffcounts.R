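#' Count matrix with sample metadata
#'
#' The shared container for accessibility (peaks x samples) and pseudobulk
#' expression (genes x samples) counts. Metadata must contain a `sample`
#' column matching the count columns and a two-level `group` factor; `sex`
#' and `batch` columns are optional covariates.
#'
#' @param counts Non-negative integer matrix, features x samples, with
#'   dimnames.
#' @param meta Data frame of per-sample metadata.
#' @return An object of class `"count_set"`.
#' @export
count_set <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts need feature and sample dimnames")
  if (anyNA(counts)) stopf("counts contain missing values")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (!all(c("sample", "group") %in% names(meta)))
    stopf("meta needs `sample` and `group` columns")
  if (!identical(as.character(meta$sample), colnames(counts)))
    stopf("meta sample order must match count columns")
  meta$group <- factor(meta$group)
  structure(list(counts = counts, meta = meta), class = "count_set")
}

#' @method print count_set
#' @export
print.count_set <- function(x, ...) {
  cat(sprintf("count_set: %d features x %d samples (groups: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(levels(x$meta$group), collapse = ", ")))
  invisible(x)
}

#' Median-of-ratios library size factors
#'
#' Size factor per sample = median across features of the ratio of the
#' sample's count to the feature's geometric mean, computed over features
#' with all-positive counts. Falls back to total-count factors (scaled to
#' geometric mean 1) when no feature has a defined geometric mean.
#'
#' @param counts Feature x sample count matrix.
#' @return Numeric vector of size factors (geometric mean 1).
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts <= 0) == 0
  if (any(pos)) {
    logc <- log(counts[pos, , drop = FALSE])
    ref <- rowMeans(logc)
    sf <- exp(apply(logc - ref, 2, stats::median))
  } else {
    tot <- colSums(counts)
    if (any(tot == 0)) stopf("sample with zero total count")
    sf <- tot / exp(mean(log(tot)))
  }
  sf / exp(mean(log(sf)))
}

#' Expression filter on within-group mean counts
#'
#' Keeps a feature iff its mean raw count within at least one group level
#' strictly exceeds the threshold (the "mean count > 100 in any condition"
#' rule; the inequality is strict, so a mean of exactly 100 drops).
#'
#' @param cs A [count_set()].
#' @param threshold Mean-count threshold (default from [analysis_config()]).
#' @param group Optional grouping factor (default `meta$group`).
#' @return Named logical vector over features.
#' @export
filter_expressed <- function(cs, threshold = 100, group = NULL) {
  group <- group %||% cs$meta$group
  gm <- vapply(levels(factor(group)), function(g)
    rowMeans(cs$counts[, group == g, drop = FALSE]), numeric(nrow(cs$counts)))
  mask <- apply(gm > threshold, 1, any)
  if (!any(mask)) warnf("expression filter removed every feature")
  stats::setNames(mask, rownames(cs$counts))
}

#' Per-feature negative-binomial dispersion estimates
#'
#' Method-of-moments dispersions on size-factor-normalised, group-centred
#' counts, shrunk toward a mean-dispersion trend with an empirical-Bayes
#' weight `prior_df / (prior_df + residual_df)`. Features with zero
#' variance are pinned to the floor.
#'
#' @param cs A [count_set()].
#' @param group Grouping factor used for centring (default `meta$group`).
#' @param prior_df Prior degrees of freedom for shrinkage toward the trend.
#' @param phi_floor Dispersion floor.
#' @param sf Optional precomputed size factors.
#' @return List with `phi` (shrunk, floored), `phi_raw`, `trend`,
#'   `resid_df`, `prior_df`.
#' @export
estimate_dispersion <- function(cs, group = NULL, prior_df = 6,
                                phi_floor = 1e-4, sf = NULL) {
  group <- factor(group %||% cs$meta$group)
  n <- ncol(cs$counts)
  if (n < 2) stopf("dispersion estimation needs >= 2 samples")
  if (all(tabulate(group) <= 1))
    stopf("no replication in any group: dispersion cannot be estimated; provide replicates")
  sf <- sf %||% size_factors(cs$counts)
  y <- sweep(cs$counts, 2, sf, "/")
  fit <- matrix(0, nrow(y), n)
  for (g in levels(group)) {
    j <- group == g
    fit[, j] <- rowMeans(y[, j, drop = FALSE])
  }
  resid_df <- n - nlevels(group)
  if (resid_df < 1) stopf("no residual degrees of freedom")
  v <- rowSums((y - fit)^2) / resid_df
  m <- rowMeans(y)
  ok <- m > 0
  phi_raw <- rep(NA_real_, nrow(y))
  phi_raw[ok] <- (v[ok] - m[ok]) / m[ok]^2

  trend <- rep(phi_floor, nrow(y))
  if (sum(ok) >= 20) {
    lo <- stats::lowess(log(m[ok]), phi_raw[ok], f = 0.5)
    trend[ok] <- pmax(phi_floor,
                      stats::approx(lo$x, lo$y, xout = log(m[ok]),
                                    rule = 2)$y)
  }
  w <- prior_df / (prior_df + resid_df)
  phi <- pmax(phi_floor, (1 - w) * phi_raw + w * trend)
  phi[!ok | is.na(phi)] <- phi_floor
  phi[ok & v == 0] <- phi_floor
  list(phi = stats::setNames(phi, rownames(y)), phi_raw = phi_raw,
       trend = trend, resid_df = resid_df, prior_df = prior_df)
}

# Vectorised IRLS for per-feature NB GLMs with a shared design matrix.
# Y: features x samples; X: samples x p; offset: length-n log offsets;
# phi: per-feature dispersion. Returns coefficients and the standard error
# of the requested coefficient.
nb_glm_wald <- function(Y, X, offset, phi, coef_idx, max_iter = 30,
                        tol = 1e-10) {
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  XX <- matrix(0, n, p * p)
  for (j in seq_len(p)) for (k in seq_len(p))
    XX[, (j - 1) * p + k] <- X[, j] * X[, k]
  off <- matrix(offset, G, n, byrow = TRUE)
  mu <- pmax(Y, 0.5)
  eta <- log(mu) - off
  beta <- matrix(0, G, p)
  for (iter in seq_len(max_iter)) {
    mu <- exp(pmin(pmax(eta + off, -30), 30))
    W <- mu / (1 + phi * mu)
    Z <- eta + (Y - mu) / mu
    A <- W %*% XX          # G x p^2, rows are XtWX in column-major order
    B <- (W * Z) %*% X     # G x p
    beta_new <- solve_batch(A, B, p)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- tcrossprod(beta, X)
    if (delta < tol) break
  }
  mu <- exp(pmin(pmax(eta + off, -30), 30))
  W <- mu / (1 + phi * mu)
  A <- W %*% XX
  se <- sqrt(vapply(seq_len(G), function(g) {
    Ai <- matrix(A[g, ], p, p)
    d <- tryCatch(solve(Ai)[coef_idx, coef_idx], error = function(e) NA_real_)
    max(d, 0)
  }, 0))
  list(beta = beta, se = se, iter = iter)
}

# Solve G small pxp systems stored row-wise; closed form for p<=2.
solve_batch <- function(A, B, p) {
  G <- nrow(A)
  if (p == 1L) return(B / A)
  if (p == 2L) {
    a <- A[, 1]; b <- A[, 3]; c <- A[, 2]; d <- A[, 4]
    det <- a * d - b * c
    cbind((d * B[, 1] - b * B[, 2]) / det,
          (a * B[, 2] - c * B[, 1]) / det)
  } else {
    t(vapply(seq_len(G), function(g)
      solve(matrix(A[g, ], p, p), B[g, ]), numeric(p)))
  }
}

#' Negative-binomial differential test on a count matrix
#'
#' Fits a per-feature NB log-linear model with log-size-factor offsets and
#' trended, empirically shrunk method-of-moments dispersions, then tests
#' the group coefficient with a moderated Wald t-test (degrees of freedom =
#' residual + prior). The log2 fold change is oriented second-level vs
#' first-level of the group factor (KO - WT in the default design). Classes
#' are assigned at the supplied FDR (and, for pseudobulk use, a minimum
#' absolute log2FC).
#'
#' @param cs A [count_set()] (already expression-filtered as appropriate).
#' @param design One-sided formula over metadata columns; the first term
#'   must be `group` (e.g. `~ group` or `~ group + sex + batch`).
#' @param fdr FDR threshold for class assignment.
#' @param min_abs_lfc Minimum |log2FC| for a non-`ns` class (0 for DA).
#' @param prior_df Dispersion-shrinkage prior degrees of freedom.
#' @param phi_floor Dispersion floor.
#' @return A `data.frame` of class `"differential_result"` with columns
#'   `feature`, `base_mean`, `log2fc`, `p`, `fdr`, `dispersion`, `class`.
#' @export
test_differential <- function(cs, design = ~group, fdr = 0.1,
                              min_abs_lfc = 0, prior_df = 6,
                              phi_floor = 1e-4) {
  meta <- cs$meta
  tf <- stats::terms(design)
  vars <- attr(tf, "term.labels")
  if (!"group" %in% vars) stopf("design must include `group`")
  # drop covariates that are constant in this matrix
  keep <- vars[vapply(vars, function(v)
    nlevels(factor(meta[[v]])) > 1, TRUE)]
  X <- stats::model.matrix(stats::reformulate(keep), meta)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stopf("rank-deficient design: factors %s are confounded",
          paste(keep, collapse = " + "))
  }
  coef_idx <- grep("^group", colnames(X))[1]
  if (is.na(coef_idx)) stopf("no group coefficient in design")

  sf <- size_factors(cs$counts)
  disp <- estimate_dispersion(cs, prior_df = prior_df, phi_floor = phi_floor,
                              sf = sf)
  fitres <- nb_glm_wald(cs$counts, X, log(sf), disp$phi, coef_idx)
  lfc <- fitres$beta[, coef_idx] / log(2)
  stat <- fitres$beta[, coef_idx] / fitres$se
  df <- disp$resid_df + disp$prior_df
  p <- 2 * stats::pt(-abs(stat), df = df)
  q <- bh_adjust(p)
  cls <- rep("ns", nrow(cs$counts))
  sig <- !is.na(q) & q < fdr & abs(lfc) >= min_abs_lfc
  cls[sig & lfc < 0] <- "reduced"
  cls[sig & lfc > 0] <- "gained"
  res <- data.frame(
    feature = rownames(cs$counts),
    base_mean = rowMeans(sweep(cs$counts, 2, sf, "/")),
    log2fc = lfc, p = p, fdr = q,
    dispersion = disp$phi,
    class = cls,
    row.names = NULL
  )
  class(res) <- c("differential_result", "data.frame")
  attr(res, "design") <- paste(deparse(design), collapse = "")
  attr(res, "fdr_threshold") <- fdr
  attr(res, "min_abs_lfc") <- min_abs_lfc
  res
}

#' Annotate peaks to the nearest gene TSS window
#'
#' Each peak is assigned to the gene whose TSS-anchored window (20 kb
#' upstream to 10 kb downstream by default, in gene orientation) contains
#' the peak centre. Among multiple containing windows the gene with the
#' smallest centre-to-TSS distance wins; remaining ties break
#' lexicographically by gene id. Peaks contained by no window stay
#' unannotated (`NA`).
#'
#' @param peaks A [peak_set()].
#' @param genes Data frame with columns `gene`, `chrom`, `tss` (1-based
#'   position), `strand` (`"+"`/`"-"`).
#' @param upstream,downstream Window extent in gene orientation (bp).
#' @return Data frame `peak`, `gene`, `distance` (centre to TSS; `NA` when
#'   unannotated), in peak order.
#' @export
annotate_peaks <- function(peaks, genes, upstream = 20000,
                           downstream = 10000) {
  if (!all(c("gene", "chrom", "tss", "strand") %in% names(genes)))
    stopf("gene table needs gene/chrom/tss/strand columns")
  gr <- peaks$ranges
  center <- GenomicRanges::start(gr) +
    floor((GenomicRanges::width(gr) - 1) / 2)
  cgr <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(center, width = 1))
  plus <- genes$strand == "+"
  win_start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  win_end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  wgr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(pmax(win_start, 1), win_end))
  hits <- GenomicRanges::findOverlaps(cgr, wgr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  out <- data.frame(peak = peak_names(peaks), gene = NA_character_,
                    distance = NA_real_)
  if (length(qh)) {
    d <- abs(center[qh] - genes$tss[sh])
    ord <- order(qh, d, genes$gene[sh])
    first <- !duplicated(qh[ord])
    out$gene[qh[ord][first]] <- genes$gene[sh[ord][first]]
    out$distance[qh[ord][first]] <- d[ord][first]
  }
  out
}

#' Pseudobulk aggregation of single-cell counts
#'
#' Sums raw counts over the cells of each (cluster, sample) pair, producing
#' one [count_set()] per cluster. Clusters in which either group level has
#' fewer than `min_reps` contributing samples are skipped, with the reason
#' recorded in the `skipped` attribute.
#'
#' @param counts Genes x cells count matrix (base or sparse).
#' @param clusters Per-cell cluster labels.
#' @param samples Per-cell sample-of-origin labels.
#' @param sample_meta Data frame keyed by `sample` with `group` and optional
#'   `sex`, `batch` columns.
#' @param min_reps Minimum samples per group level within a cluster.
#' @return Named list of `count_set` (one per retained cluster), with a
#'   `skipped` attribute naming dropped clusters.
#' @export
pseudobulk <- function(counts, clusters, samples, sample_meta,
                       min_reps = 2L) {
  if (ncol(counts) != length(clusters) || ncol(counts) != length(samples))
    stopf("clusters/samples must match count columns")
  clusters <- as.character(clusters)
  samples <- as.character(samples)
  out <- list(); skipped <- character()
  for (cl in sort(unique(clusters))) {
    in_cl <- clusters == cl
    sam <- sort(unique(samples[in_cl]))
    agg <- vapply(sam, function(s) {
      j <- in_cl & samples == s
      as.numeric(Matrix::rowSums(counts[, j, drop = FALSE]))
    }, numeric(nrow(counts)))
    rownames(agg) <- rownames(counts)
    meta <- sample_meta[match(sam, sample_meta$sample), , drop = FALSE]
    reps <- table(factor(meta$group))
    if (any(reps < min_reps)) {
      skipped <- c(skipped, sprintf(
        "cluster %s: insufficient replication (%s)", cl,
        paste(sprintf("%s=%d", names(reps), reps), collapse = ", ")))
      next
    }
    out[[cl]] <- count_set(agg, meta)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write a differential result as TSV with a provenance header
#'
#' @param res A `differential_result`.
#' @param path Output TSV path.
#' @param seed Optional seed recorded in the header.
#' @export
write_differential_tsv <- function(res, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# primingkit differential result | design=%s fdr=%s min_abs_lfc=%s seed=%s",
                     attr(res, "design"), attr(res, "fdr_threshold"),
                     attr(res, "min_abs_lfc"), seed), con)
  utils::write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential result TSV
#' @param path TSV written by [write_differential_tsv()].
#' @export
read_differential_tsv <- function(path) {
  res <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  class(res) <- c("differential_result", "data.frame")
  res
}
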