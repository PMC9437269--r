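test_that("expression filter applies the strict within-group mean rule", {
  counts <- rbind(
    kept = c(150, 150, 2, 2),       # mean 150 in one group
    zero = c(0, 0, 0, 0),           # all-zero: dropped
    boundary = c(100, 100, 100, 100) # exactly 100: dropped (strict >)
  )
  colnames(counts) <- paste0("s", 1:4)
  cs <- toy_count_set(counts, c("WT", "WT", "KO", "KO"))
  mask <- filter_expressed(cs, threshold = 100)
  expect_identical(unname(mask), c(TRUE, FALSE, FALSE))
  expect_warning(filter_expressed(cs, threshold = 1e6), "every feature")
})

test_that("bh_adjust matches hand computation and the textbook step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_warning(q <- bh_adjust(c(0.01, NA, 0.5)), "NA")
  expect_true(is.na(q[2]))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  withr::with_seed(99, {
    for (i in 1:50) {
      p <- runif(sample(3:40, 1))
      expect_equal(bh_adjust(p), bh_textbook(p))
    }
  })
})

test_that("dispersion estimates hit the floor on Poisson data and recover NB truth", {
  cfg <- generator_config(seed = 2, n_features = 2000, n_da = 0,
                          nb_dispersion_range = c(0, 0),
                          depth_range = c(1, 1))
  g <- gen_counts(cfg)
  d <- estimate_dispersion(g$counts)
  expect_lte(median(d$phi), 2e-4)

  # constant feature pinned to the floor
  counts <- matrix(5L, 3, 6, dimnames = list(paste0("f", 1:3),
                                             paste0("s", 1:6)))
  counts[2, ] <- c(3L, 9L, 4L, 8L, 2L, 10L)
  cs <- toy_count_set(counts, rep(c("WT", "KO"), each = 3))
  dc <- estimate_dispersion(cs)
  expect_equal(unname(dc$phi[1]), 1e-4)

  # phi = 0.2 recovered within a factor of two at n = 20 per group
  cfg2 <- generator_config(seed = 4, n_features = 1000, n_da = 0,
                           nb_dispersion_range = c(0.2, 0.2),
                           n_per_group = c(WT = 20L, KO = 20L))
  g2 <- gen_counts(cfg2)
  d2 <- estimate_dispersion(g2$counts)
  expect_gte(median(d2$phi), 0.1)
  expect_lte(median(d2$phi), 0.4)
})

test_that("differential test is antisymmetric and order-invariant", {
  cfg <- generator_config(seed = 8, n_features = 400, n_da = 40)
  g <- gen_counts(cfg)
  res <- test_differential(g$counts, ~group)

  # swapping the group labels negates every log2FC, p unchanged
  sw <- g$counts
  sw$meta$group <- factor(ifelse(sw$meta$group == "WT", "KO", "WT"),
                          levels = c("WT", "KO"))
  res_sw <- test_differential(sw, ~group)
  expect_equal(res_sw$log2fc, -res$log2fc, tolerance = 1e-6)
  expect_equal(res_sw$p, res$p, tolerance = 1e-6)

  # permuting sample order leaves every statistic unchanged
  perm <- sample(ncol(g$counts$counts))
  cs_p <- count_set(g$counts$counts[, perm],
                    g$counts$meta[perm, , drop = FALSE])
  res_p <- test_differential(cs_p, ~group)
  expect_equal(res_p$log2fc, res$log2fc, tolerance = 1e-10)
  expect_equal(res_p$p, res$p, tolerance = 1e-10)
})

test_that("differential test agrees with an independent NB GLM route", {
  skip_if_not_installed("edgeR")
  cfg <- generator_config(seed = 5, n_features = 500, n_da = 50,
                          da_lfc = c(-2, 2),
                          nb_dispersion_range = c(0.1, 0.1))
  g <- gen_counts(cfg)
  res <- test_differential(g$counts, ~group)
  y <- edgeR::DGEList(g$counts$counts, group = g$counts$meta$group)
  y <- edgeR::calcNormFactors(y)
  design <- stats::model.matrix(~group, g$counts$meta)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  qt <- edgeR::glmQLFTest(fit, coef = 2)
  expect_gt(cor(res$log2fc, qt$table$logFC), 0.995)
  expect_gt(cor(-log10(res$p), -log10(qt$table$PValue)), 0.9)
  # the two routes call the same planted features at FDR 0.1
  mine <- res$feature[res$fdr < 0.1]
  theirs <- rownames(qt$table)[stats::p.adjust(qt$table$PValue, "BH") < 0.1]
  expect_gt(length(intersect(mine, theirs)) /
              length(union(mine, theirs)), 0.8)
})

test_that("rank-deficient designs are rejected with the factors named", {
  counts <- matrix(rpois(40, 50), 5, 8,
                   dimnames = list(paste0("f", 1:5), paste0("s", 1:8)))
  meta <- data.frame(sample = paste0("s", 1:8),
                     group = factor(rep(c("WT", "KO"), each = 4),
                                    levels = c("WT", "KO")),
                     sex = rep(c("F", "M"), each = 4)) # confounded with group
  cs <- count_set(counts, meta)
  expect_error(test_differential(cs, ~ group + sex), "confounded")
})

test_that("peak annotation matches an exhaustive window search", {
  # hand-checked cases
  genes <- data.frame(gene = c("gA", "gB", "gC"),
                      chrom = "chrT",
                      tss = c(50000L, 120000L, 200000L),
                      strand = c("+", "-", "+"))
  mk_peak <- function(centers) {
    gr <- GenomicRanges::GRanges("chrT",
                                 IRanges::IRanges(centers - 100, width = 201),
                                 name = sprintf("pk%02d", seq_along(centers)))
    peak_set(gr)
  }
  # 5 kb upstream of + strand TSS: inside the 20-kb window
  ann <- annotate_peaks(mk_peak(45000L), genes)
  expect_equal(ann$gene, "gA")
  # 25 kb upstream: outside
  ann2 <- annotate_peaks(mk_peak(25000L), genes)
  expect_true(is.na(ann2$gene))
  # 5 kb *downstream* of a minus-strand gene = tss - 5000
  ann3 <- annotate_peaks(mk_peak(115000L), genes)
  expect_equal(ann3$gene, "gB")

  # brute-force oracle on a random mixed-strand configuration
  withr::with_seed(31, {
    genes_r <- data.frame(gene = paste0("g", 1:3), chrom = "chrT",
                          tss = sort(sample(1e5:4e5, 3)),
                          strand = sample(c("+", "-"), 3, replace = TRUE))
    centers <- sample(8e4:42e4, 10)
    pk <- mk_peak(centers)
    ann_r <- annotate_peaks(pk, genes_r)
    for (i in seq_len(10)) {
      best <- NA_character_; bestd <- Inf
      for (j in 1:3) {
        lo <- if (genes_r$strand[j] == "+") genes_r$tss[j] - 20000 else
          genes_r$tss[j] - 10000
        hi <- if (genes_r$strand[j] == "+") genes_r$tss[j] + 10000 else
          genes_r$tss[j] + 20000
        d <- abs(centers[i] - genes_r$tss[j])
        if (centers[i] >= lo && centers[i] <= hi &&
            (d < bestd || (d == bestd && genes_r$gene[j] < best))) {
          best <- genes_r$gene[j]; bestd <- d
        }
      }
      expect_identical(ann_r$gene[i], best)
    }
  })
})

test_that("pseudobulk aggregation is exact, linear, and replication-guarded", {
  withr::with_seed(12, {
    counts <- matrix(rpois(60, 10), 6, 10,
                     dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  })
  clusters <- rep(c("1", "2"), each = 5)
  samples <- rep(c("mA", "mB", "mC", "mD", "mE"), 2)
  sm <- data.frame(sample = c("mA", "mB", "mC", "mD", "mE"),
                   group = factor(c("WT", "WT", "KO", "KO", "KO"),
                                  levels = c("WT", "KO")))
  pb <- pseudobulk(counts, clusters, samples, sm)
  # one cell per (cluster, sample): pseudobulk equals the cell's counts
  expect_equal(unname(pb[["1"]]$counts[, "mA"]), unname(counts[, 1]))
  # duplicating every cell doubles the pseudobulk exactly
  pb2 <- pseudobulk(cbind(counts, counts), rep(clusters, 2),
                    rep(samples, 2), sm)
  expect_equal(pb2[["1"]]$counts, pb[["1"]]$counts * 2)
  # a cluster with one sample per group is skipped with a reason
  pb3 <- pseudobulk(counts[, 1:3, drop = FALSE], rep("1", 3),
                    c("mA", "mA", "mC"), sm)
  expect_length(pb3, 0)
  expect_match(attr(pb3, "skipped"), "insufficient replication")
})

test_that("differential results round-trip through TSV", {
  cfg <- generator_config(seed = 6, n_features = 50, n_da = 5)
  g <- gen_counts(cfg)
  res <- test_differential(g$counts, ~group)
  f <- tempfile(fileext = ".tsv")
  write_differential_tsv(res, f, seed = 6)
  back <- read_differential_tsv(f)
  expect_equal(back$log2fc, res$log2fc, tolerance = 1e-6)
  expect_identical(back$class, res$class)
})
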