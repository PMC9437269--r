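# Per-gene x per-cell expected expression rates for the synthetic
# landscape. Shared by gen_landscape() and gen_query_cells() so query
# cells are drawn from exactly the reference generative model.
landscape_rates <- function(gene_params, cell_cluster, lineage, sex,
                            genotype, marker_lfc, shift_lfc, shift_cluster) {
  G <- nrow(gene_params); n <- length(cell_cluster)
  logr <- matrix(rep(gene_params$base_log2, n), G, n)
  for (g in which(gene_params$type == "marker")) {
    home <- gene_params$cluster[g]
    logr[g, cell_cluster == home] <- logr[g, cell_cluster == home] + marker_lfc
  }
  grad <- which(gene_params$type == "gradient")
  if (length(grad))
    logr[grad, ] <- logr[grad, ] +
      outer(gene_params$grad_slope[grad], lineage)
  if (!is.null(shift_cluster)) {
    sel <- which(gene_params$shifted)
    ko <- genotype == "KO" & cell_cluster == shift_cluster
    logr[sel, ko] <- logr[sel, ko] + shift_lfc
  }
  rate <- 2^logr
  fem <- which(gene_params$type == "female_marker")
  ym <- which(gene_params$type == "y_marker")
  rate[fem, sex != "female"] <- 0
  rate[ym, sex != "male"] <- 0
  dimnames(rate) <- list(gene_params$gene, names(cell_cluster))
  rate
}

#' Generate a clustered synthetic single-cell landscape
#'
#' Cells are placed on a branched two-dimensional manifold: the origin
#' cluster sits at the root and the remaining clusters at the tips of
#' radiating branches; each cell's lineage coordinate is its distance from
#' the root. Genes comprise cluster markers (log2-elevated in their home
#' cluster), smooth lineage-gradient genes, sex markers (one Xist-like
#' female marker expressed only in female cells, Y-linked markers only in
#' male cells; a configured doublet fraction expresses both — marker
#' detection is guaranteed in the designated cells so labels are
#' definitional), and background genes, a subset of which carries a planted
#' genotype (KO vs WT) log2 shift restricted to one cluster. Counts are
#' negative-binomial with per-cell library sizes; the returned bundle
#' includes log-normalised expression, HVGs, a PCA rotation, PC
#' coordinates (also stored as the "corrected" coordinates, since no batch
#' effect correction is applied to synthetic data) and the true 2-D
#' manifold coordinates as the embedding.
#'
#' @param config A [generator_config()].
#' @param seed Optional seed override.
#' @param n_hvg,n_pcs Landscape reduction size (defaults scale to the
#'   synthetic gene count).
#' @return List with `landscape` (fields `counts`, `lognorm`, `hvg`,
#'   `rotation`, `center`, `scale`, `pcs`, `corrected`, `embedding`,
#'   `meta`) and `truth` (per-cell ground truth, gene parameters, marker
#'   and shifted gene lists, cluster centres).
#' @export
gen_landscape <- function(config, seed = NULL,
                          n_hvg = min(500L, config$n_genes),
                          n_pcs = 20L) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_clusters < 3) stopf("need >= 3 clusters")
  if (is.null(seed)) seed <- derive_seed(config$seed, 404L)
  withr::with_seed(seed, {
    K <- config$n_clusters
    n <- config$n_cells
    cells <- sprintf("cell_%05d", seq_len(n))

    # mice: half WT / half KO, alternating sex, batches round-robin
    mice <- sprintf("mouse_%02d", seq_len(config$n_mice))
    # genotype blocks, sex alternating, batches in pairs: keeps group, sex
    # and batch mutually non-collinear so covariate designs stay full rank
    m_geno <- rep(c("WT", "KO"), each = ceiling(config$n_mice / 2),
                  length.out = config$n_mice)
    m_sex <- rep(c("female", "male"), length.out = config$n_mice)
    m_batch <- rep(rep(seq_len(config$n_batches), each = 2),
                   length.out = config$n_mice)

    cell_mouse <- sample(seq_len(config$n_mice), n, replace = TRUE)
    cluster <- sample(seq_len(K), n, replace = TRUE)
    names(cluster) <- cells
    sex <- m_sex[cell_mouse]
    genotype <- m_geno[cell_mouse]
    batch <- m_batch[cell_mouse]

    if (config$doublet_frac > 0) {
      dbl <- sample(c(TRUE, FALSE), n, replace = TRUE,
                    prob = c(config$doublet_frac, 1 - config$doublet_frac))
    } else dbl <- rep(FALSE, n)

    # branched manifold: origin at the root, others at branch tips
    angles <- seq(0, 2 * pi, length.out = K)[-K]
    centers <- matrix(0, K, 2)
    others <- setdiff(seq_len(K), config$origin_cluster)
    centers[others, ] <- 3 * cbind(cos(angles[seq_along(others)]),
                                   sin(angles[seq_along(others)]))
    latent <- centers[cluster, ] + matrix(stats::rnorm(2 * n, 0, 0.45), n, 2)
    rownames(latent) <- cells
    lineage <- sqrt(rowSums(latent^2))

    # gene catalogue
    mk <- expand.grid(i = seq_len(config$n_markers_per_cluster),
                      cluster = seq_len(K))
    gene_params <- rbind(
      data.frame(gene = sprintf("Mk%d_%d", mk$cluster, mk$i),
                 type = "marker", cluster = mk$cluster,
                 base_log2 = log2(3), grad_slope = 0),
      data.frame(gene = sprintf("Grad_%03d", seq_len(config$n_gradient_genes)),
                 type = "gradient", cluster = NA,
                 base_log2 = log2(3),
                 grad_slope = rep(c(0.5, -0.5),
                                  length.out = config$n_gradient_genes)),
      data.frame(gene = config$female_marker, type = "female_marker",
                 cluster = NA, base_log2 = log2(5), grad_slope = 0),
      data.frame(gene = config$y_genes, type = "y_marker", cluster = NA,
                 base_log2 = log2(5), grad_slope = 0)
    )
    n_bg <- config$n_genes - nrow(gene_params)
    gene_params <- rbind(gene_params, data.frame(
      gene = sprintf("Gene_%04d", seq_len(n_bg)), type = "background",
      cluster = NA,
      base_log2 = stats::runif(n_bg, log2(1), log2(10)), grad_slope = 0))
    gene_params$shifted <- FALSE
    shift_genes <- character()
    if (!is.null(config$shift_cluster) && config$shift_n_genes > 0 &&
        config$shift_lfc != 0) {
      # the genotype shift targets the shift cluster's own marker genes
      # first (so the perturbation points toward that cell state), then
      # fills up with random background genes
      mki <- which(gene_params$type == "marker" &
                     gene_params$cluster == config$shift_cluster)
      bgi <- which(gene_params$type == "background")
      n_extra <- max(0L, config$shift_n_genes - length(mki))
      sel <- c(mki[seq_len(min(length(mki), config$shift_n_genes))],
               sample(bgi, min(n_extra, length(bgi))))
      gene_params$shifted[sel] <- TRUE
      shift_genes <- gene_params$gene[sel]
    }

    sex_eff <- ifelse(dbl, "doublet", sex)
    rate <- landscape_rates(gene_params, cluster, lineage,
                            ifelse(dbl, "female", sex), genotype,
                            config$marker_lfc, config$shift_lfc,
                            config$shift_cluster)
    # doublets express both marker classes
    if (any(dbl)) {
      ym <- gene_params$type == "y_marker"
      rate[ym, dbl] <- 2^gene_params$base_log2[ym]
    }

    counts <- sample_landscape_counts(rate, config)
    counts <- guarantee_sex_markers(counts, gene_params,
                                    ifelse(dbl, "doublet", sex))

    red <- lognormalize_and_reduce(
      counts, n_hvg = n_hvg, n_pcs = n_pcs,
      exclude = c(config$female_marker, config$y_genes))

    meta <- data.frame(cell = cells, cluster = cluster,
                       sex = ifelse(dbl, "doublet", sex),
                       genotype = factor(genotype, levels = c("WT", "KO")),
                       batch = batch,
                       mouse = mice[cell_mouse], lineage = lineage)
    landscape <- c(red[c("lognorm", "hvg", "rotation", "center",
                         "scale", "pcs")],
                   list(counts = counts, corrected = red$pcs,
                        embedding = latent, meta = meta))
    truth <- list(
      cell_truth = meta,
      gene_params = gene_params,
      markers = split(gene_params$gene[gene_params$type == "marker"],
                      gene_params$cluster[gene_params$type == "marker"]),
      shift_genes = shift_genes,
      shift = list(cluster = config$shift_cluster,
                   lfc = config$shift_lfc),
      cluster_centers = centers,
      seed = seed
    )
    list(landscape = landscape, truth = truth)
  })
}

# NB counts with per-cell library sizes from the configured range.
sample_landscape_counts <- function(rate, config) {
  n <- ncol(rate)
  lib <- stats::runif(n, config$lib_size_range[1], config$lib_size_range[2])
  p <- sweep(rate, 2, colSums(rate), "/")
  mu <- sweep(p, 2, lib, "*")
  phi <- config$cell_dispersion
  counts <- if (phi < 1e-8) {
    matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / phi),
           nrow(mu), ncol(mu))
  }
  dimnames(counts) <- dimnames(rate)
  counts
}

# Sex-marker detection is definitional in the generator: the designated
# marker is guaranteed detected (count >= 1) in the cells that carry it.
guarantee_sex_markers <- function(counts, gene_params, sex) {
  fem <- gene_params$gene[gene_params$type == "female_marker"]
  ym <- gene_params$gene[gene_params$type == "y_marker"]
  fcells <- sex %in% c("female", "doublet")
  mcells <- sex %in% c("male", "doublet")
  counts[fem, fcells] <- pmax(counts[fem, fcells], 1)
  counts[ym[1], mcells] <- pmax(counts[ym[1], mcells], 1)
  counts
}

#' Generate query cells from one cluster of a synthetic landscape
#'
#' Draws new cells from the same generative model as [gen_landscape()],
#' restricted to the given cluster, and returns their log-normalised
#' expression — the natural input for [project_cells()].
#'
#' @param sim Output of [gen_landscape()].
#' @param config The same [generator_config()].
#' @param cluster Cluster index to sample from.
#' @param n_query Number of query cells.
#' @param seed Integer seed.
#' @return List: `counts`, `lognorm` (genes x cells), `cluster`.
#' @export
gen_query_cells <- function(sim, config, cluster, n_query = 200,
                            seed = 1L) {
  withr::with_seed(derive_seed(seed, 23L), {
    centers <- sim$truth$cluster_centers
    latent <- centers[rep(cluster, n_query), , drop = FALSE] +
      matrix(stats::rnorm(2 * n_query, 0, 0.45), n_query, 2)
    lineage <- sqrt(rowSums(latent^2))
    cl <- stats::setNames(rep(cluster, n_query),
                          sprintf("query_%04d", seq_len(n_query)))
    sex <- rep(c("female", "male"), length.out = n_query)
    rate <- landscape_rates(sim$truth$gene_params, cl, lineage, sex,
                            rep("WT", n_query), config$marker_lfc,
                            config$shift_lfc, NULL)
    counts <- sample_landscape_counts(rate, config)
    tot <- colSums(counts)
    tot[tot == 0] <- 1
    target <- stats::median(colSums(sim$landscape$counts))
    lognorm <- log1p(sweep(counts, 2, tot, "/") * target)
    list(counts = counts, lognorm = lognorm, cluster = cluster)
  })
}

#' Convert a landscape bundle to a SingleCellExperiment
#'
#' @param landscape A landscape list (from [gen_landscape()] or
#'   [read_landscape_bundle()]).
#' @return A [SingleCellExperiment::SingleCellExperiment] with `counts` and
#'   `logcounts` assays, PCA / corrected / embedding reduced dims, and the
#'   metadata as `colData`.
#' @export
landscape_to_sce <- function(landscape) {
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = landscape$counts,
                  logcounts = landscape$lognorm),
    colData = S4Vectors::DataFrame(landscape$meta,
                                   row.names = landscape$meta$cell))
  SingleCellExperiment::reducedDims(sce) <- list(
    PCA = landscape$pcs, CORRECTED = landscape$corrected,
    EMBEDDING = landscape$embedding)
  S4Vectors::metadata(sce)$hvg <- landscape$hvg
  S4Vectors::metadata(sce)$rotation <- landscape$rotation
  sce
}

#' Write a landscape bundle as a plain-text directory
#'
#' Sparse counts go to `matrix.mtx` with `genes.tsv` / `cells.tsv` axis
#' files; metadata, rotation, PC / corrected / embedding coordinates and
#' the HVG list are TSV. Log-normalised expression is recomputed on read.
#'
#' @param landscape A landscape list.
#' @param dir Output directory (created).
#' @export
write_landscape_bundle <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(landscape$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(landscape$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(landscape$counts), file.path(dir, "cells.tsv"))
  utils::write.table(landscape$meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wr <- function(m, f) utils::write.table(
    data.frame(id = rownames(m), m, check.names = FALSE), file.path(dir, f),
    sep = "\t", quote = FALSE, row.names = FALSE)
  wr(landscape$rotation, "rotation.tsv")
  wr(landscape$pcs, "pcs.tsv")
  wr(landscape$corrected, "corrected.tsv")
  wr(landscape$embedding, "embedding.tsv")
  utils::write.table(
    data.frame(gene = names(landscape$center), center = landscape$center,
               scale = landscape$scale),
    file.path(dir, "hvg_moments.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Read a landscape bundle directory
#' @param dir Directory written by [write_landscape_bundle()].
#' @return A landscape list (see [gen_landscape()]).
#' @export
read_landscape_bundle <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "cells.tsv"))
  meta <- utils::read.table(file.path(dir, "metadata.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  rd <- function(f) {
    d <- utils::read.table(file.path(dir, f), header = TRUE, sep = "\t",
                           check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    m
  }
  mom <- utils::read.table(file.path(dir, "hvg_moments.tsv"), header = TRUE,
                           sep = "\t")
  tot <- colSums(counts)
  lognorm <- log1p(sweep(counts, 2, tot, "/") * stats::median(tot))
  list(counts = counts, lognorm = lognorm,
       hvg = mom$gene,
       rotation = rd("rotation.tsv"), pcs = rd("pcs.tsv"),
       corrected = rd("corrected.tsv"), embedding = rd("embedding.tsv"),
       center = stats::setNames(mom$center, mom$gene),
       scale = stats::setNames(mom$scale, mom$gene),
       meta = meta)
}
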