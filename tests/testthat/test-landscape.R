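test_that("QC filter applies the strict detected-genes rule", {
  n_genes <- 1500
  counts <- matrix(0L, n_genes, 3,
                   dimnames = list(sprintf("g%04d", 1:n_genes),
                                   c("c1199", "c1200", "cEmpty")))
  counts[1:1199, 1] <- 1L
  counts[1:1200, 2] <- 1L
  mask <- qc_filter(counts, min_genes = 1200)
  expect_identical(unname(mask), c(FALSE, TRUE, FALSE))
  # toy matrix equals a manual detected-gene count
  withr::with_seed(31, toy <- matrix(rbinom(50, 1, 0.4), 10, 5,
                                     dimnames = list(paste0("g", 1:10),
                                                     paste0("c", 1:5))))
  expect_identical(unname(qc_filter(toy, 3)),
                   unname(colSums(toy > 0) >= 3))
})

test_that("sex assignment partitions cells exhaustively by the marker rules", {
  expr <- matrix(0, 4, 4,
                 dimnames = list(c("Xist", "Ddx3y", "Eif2s3y", "Uty"),
                                 c("f", "m", "dbl", "und")))
  expr["Xist", "f"] <- 2.1
  expr["Ddx3y", "m"] <- 1.5
  expr["Xist", "dbl"] <- 1.0; expr["Uty", "dbl"] <- 0.5
  lab <- assign_sex(expr)
  expect_identical(as.character(lab),
                   c("female", "male", "excluded_doublet",
                     "excluded_undetermined"))
  expect_false(anyNA(lab)) # the four labels are exhaustive
  expect_error(assign_sex(expr[1:2, ]), "missing")

  # generated landscape with doublet fraction 0: 100% agreement with truth
  sh <- shared_landscape()
  lab_gen <- assign_sex(sh$sim$landscape$counts)
  expect_identical(as.character(lab_gen), sh$sim$landscape$meta$sex)
})

test_that("log-normalisation is scaling-invariant and honours HVG exclusions", {
  withr::with_seed(33, {
    base <- rpois(200, 20)
    counts <- cbind(c1 = base, c2 = base * 3L,
                    c3 = rpois(200, 20), c4 = rpois(200, 30))
    rownames(counts) <- sprintf("g%03d", 1:200)
  })
  red <- lognormalize_and_reduce(counts, n_hvg = 50, n_pcs = 2)
  # proportional count vectors give identical log-normalised profiles
  expect_equal(red$lognorm[, "c1"], red$lognorm[, "c2"])
  # an excluded gene never enters the HVG list even if most variable
  excl <- red$hvg[1]
  red2 <- lognormalize_and_reduce(counts, n_hvg = 50, n_pcs = 2,
                                  exclude = excl)
  expect_false(excl %in% red2$hvg)
  expect_warning(lognormalize_and_reduce(counts, n_hvg = 500, n_pcs = 2),
                 "capped")
})

test_that("rank-3 expression structure is captured by the first 3 PCs", {
  # three archetype profiles with equal totals; each cell copies one
  withr::with_seed(34, {
    arch <- matrix(rpois(3 * 120, 30), 120, 3)
    arch <- sweep(arch, 2, colSums(arch), function(a, b) round(a / b * 3000))
    cells <- arch[, sample(1:3, 90, replace = TRUE)]
    dimnames(cells) <- list(sprintf("g%03d", 1:120), sprintf("c%02d", 1:90))
  })
  red <- lognormalize_and_reduce(cells, n_hvg = 100, n_pcs = 10)
  varfrac <- cumsum(red$sdev^2) / sum(red$sdev^2)
  expect_gt(varfrac[3], 0.99)
  rot <- red$rotation
  expect_equal(crossprod(rot), diag(ncol(rot)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("binned-control gene scores are null-centred and shift-sensitive", {
  withr::with_seed(35, {
    lognorm <- matrix(abs(rnorm(400 * 500, 1, 0.5)), 400, 500,
                      dimnames = list(sprintf("g%03d", 1:400),
                                      sprintf("c%03d", 1:500)))
  })
  set <- sprintf("g%03d", seq(5, 95, by = 10))
  s0 <- cell_cycle_score(lognorm, set, seed = 36)
  expect_lt(abs(mean(s0)), 0.05)
  expect_true(all(is.finite(s0)))
  # +1 shift in a subpopulation scores ~ 1 there
  sub <- 1:100
  shifted <- lognorm
  shifted[set, sub] <- shifted[set, sub] + 1
  s1 <- cell_cycle_score(shifted, set, seed = 36)
  expect_equal(mean(s1[sub]) - mean(s0[sub]), 1, tolerance = 0.05)
})

test_that("DoT scores are centred, linear, and sign-antisymmetric", {
  sh <- shared_landscape()
  land <- sh$sim$landscape
  origin <- land$meta$cell[land$meta$cluster == sh$cfg$origin_cluster]
  genes <- rownames(land$lognorm)[1:30]
  withr::with_seed(37, {
    w1 <- setNames(rnorm(30), genes)
    w2 <- setNames(rnorm(30), genes)
  })
  d1 <- dot_score(land$lognorm, w1, origin, n_null = 5, seed = 1)
  d2 <- dot_score(land$lognorm, w2, origin, n_null = 5, seed = 1)
  d12 <- dot_score(land$lognorm, 2 * w1 + 3 * w2, origin, n_null = 5,
                   seed = 1)
  # linearity in the weights, to machine precision
  expect_equal(d12$raw, 2 * d1$raw + 3 * d2$raw, tolerance = 1e-10)
  # origin mean is zero by construction
  expect_equal(mean(d1$raw[origin]), 0, tolerance = 1e-10)
  # sign flip negates raw scores exactly
  dn <- dot_score(land$lognorm, -w1, origin, n_null = 5, seed = 1)
  expect_equal(dn$raw, -d1$raw, tolerance = 1e-10)
  # zero weights: raw = 0 everywhere
  d0 <- dot_score(land$lognorm, setNames(numeric(30), genes), origin,
                  n_null = 5, seed = 1)
  expect_true(all(d0$raw == 0))
  expect_error(dot_score(land$lognorm, c(absent = 1), origin), "no differential")
})

test_that("marker-weighted DoT peaks in the marked cluster", {
  sh <- shared_landscape()
  land <- sh$sim$landscape
  origin <- land$meta$cell[land$meta$cluster == sh$cfg$origin_cluster]
  target <- 4L
  wm <- setNames(rep(1, length(sh$sim$truth$markers[[as.character(target)]])),
                 sh$sim$truth$markers[[as.character(target)]])
  dm <- dot_score(land$lognorm, wm, origin, n_null = 100, seed = 38)
  mz <- tapply(dm$z[land$meta$cell], land$meta$cluster, mean)
  expect_equal(as.integer(names(which.max(mz))), target)
  expect_gt(max(mz), 2)
})

test_that("projection recovers reference coordinates and cluster labels", {
  sh <- shared_landscape()
  land <- sh$sim$landscape
  # self-projection, k = 1: every cell is its own neighbour, coordinates exact
  p1 <- project_cells(land, land$lognorm[land$hvg, ], k = 1)
  expect_identical(as.character(p1$neighbors[, 1]), land$meta$cell)
  expect_equal(unname(p1$corrected), unname(land$corrected),
               tolerance = 1e-8)
  expect_equal(unname(p1$embedding), unname(land$embedding),
               tolerance = 1e-8)
  # per-gene affine distortion (gain 2, offset 5) is removed exactly
  pd <- project_cells(land, land$lognorm[land$hvg, ] * 2 + 5, k = 1)
  expect_identical(as.character(pd$neighbors[, 1]), land$meta$cell)
  expect_equal(unname(pd$embedding), unname(land$embedding),
               tolerance = 1e-8)
  # predictions lie in the convex hull of the neighbours, dimension-wise
  q <- gen_query_cells(sh$sim, sh$cfg, cluster = 2, n_query = 50, seed = 39)
  pq <- project_cells(land, q$lognorm, k = 15)
  for (i in c(1, 25, 50)) {
    nb <- land$embedding[pq$neighbors[i, ], , drop = FALSE]
    expect_true(all(pq$embedding[i, ] >= apply(nb, 2, min) - 1e-9))
    expect_true(all(pq$embedding[i, ] <= apply(nb, 2, max) + 1e-9))
  }
  # cluster-restricted queries land among same-cluster neighbours
  lab <- matrix(land$meta$cluster[match(pq$neighbors, land$meta$cell)],
                nrow(pq$neighbors))
  maj <- apply(lab, 1, function(r) as.integer(names(which.max(table(r)))))
  expect_gte(mean(maj == 2), 0.9)
  # insufficient gene overlap is rejected
  expect_error(project_cells(land, q$lognorm[1:5, ], k = 5), "HVGs")
})

test_that("landscape bundles round-trip through the text directory format", {
  sh <- shared_landscape()
  land <- sh$sim$landscape
  dir <- tempfile("bundle_")
  write_landscape_bundle(land, dir)
  back <- read_landscape_bundle(dir)
  expect_equal(back$counts, land$counts, ignore_attr = TRUE)
  expect_equal(back$lognorm, land$lognorm, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(back$rotation), unname(land$rotation),
               tolerance = 1e-9)
  expect_identical(back$hvg, land$hvg)
  expect_equal(back$meta$cluster, land$meta$cluster)
  # SCE conversion carries assays and reduced dims
  sce <- landscape_to_sce(land)
  expect_s4_class(sce, "SingleCellExperiment")
  expect_equal(dim(sce), dim(land$counts))
  expect_identical(
    SingleCellExperiment::reducedDimNames(sce),
    c("PCA", "CORRECTED", "EMBEDDING"))
})
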