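test_that("scanning finds consensus and reverse-complement plants exactly", {
  motif <- motif_model("M1", ppm_from_consensus("TTGACA", 0.9))
  cons <- motif_consensus(motif)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cons, "")[[1]]),
                                     collapse = ""))
  pk <- toy_peaks(c(cons,                                  # exact consensus
                    paste0("GGGGGGG", rc, "GGGGGGG")))     # rc at offset 7
  hits <- scan_motifs(pk, motif)
  h1 <- hits[hits$peak == "tp_01", ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$offset, 0)
  expect_equal(h1$strand, "+")
  expect_equal(h1$score, motif$max_score)
  h2 <- hits[hits$peak == "tp_02", ]
  expect_equal(h2$offset, 7)
  expect_equal(h2$strand, "-")

  # shorter-than-motif sequence: zero hits, no error
  short <- toy_peaks("ACG")
  expect_equal(nrow(scan_motifs(short, motif)), 0)
})

test_that("scanning equals exhaustive per-position rescoring", {
  motif <- motif_model("M2", ppm_from_consensus("TGASTCA", 0.8))
  withr::with_seed(77, {
    seqs <- vapply(1:50, function(i)
      paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
            collapse = ""), "")
  })
  pk <- toy_peaks(seqs)
  thr <- 0.25 * motif$max_score # permissive
  hits <- scan_motifs(pk, motif, threshold = thr)
  for (i in seq_along(seqs)) {
    naive <- naive_scan(seqs[i], motif, thr)
    mine <- hits[hits$peak == sprintf("tp_%02d", i), ]
    mine <- mine[order(mine$offset, mine$strand), ]
    if (is.null(naive)) {
      expect_equal(nrow(mine), 0)
    } else {
      naive <- naive[order(naive$offset, naive$strand), ]
      expect_equal(mine$offset, naive$offset)
      expect_equal(mine$strand, naive$strand)
      expect_equal(mine$score, naive$score, tolerance = 1e-9)
    }
  }
})

test_that("strand mirror: scanning the reverse-complemented peaks mirrors hits", {
  motif <- motif_model("M3", ppm_from_consensus("TTGCGCAA", 0.85))
  withr::with_seed(13, {
    seqs <- vapply(1:20, function(i)
      paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
            collapse = ""), "")
  })
  pk <- toy_peaks(seqs)
  hits <- scan_motifs(pk, motif, threshold = 0.3 * motif$max_score)
  rc_seqs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  pk_rc <- toy_peaks(rc_seqs)
  hits_rc <- scan_motifs(pk_rc, motif, threshold = 0.3 * motif$max_score)
  L <- motif_length(motif)
  mirrored <- data.frame(
    peak = hits$peak,
    offset = 150 - L - hits$offset,
    strand = ifelse(hits$strand == "+", "-", "+"))
  key <- function(d) sort(paste(d$peak, d$offset, d$strand))
  expect_identical(key(hits_rc[, c("peak", "offset", "strand")]),
                   key(mirrored))
})

test_that("motif enrichment matches the hypergeometric closed form", {
  # construct peak sets giving the 2x2 table (8/2 target, 2/8 control)
  motif <- motif_model("M4", ppm_from_consensus("TTTTCCCC", 0.95))
  cons <- motif_consensus(motif)
  bg <- strrep("AG", 50)
  with_hit <- paste0(bg, cons, bg)
  without <- paste0(bg, bg)
  target <- toy_peaks(c(rep(with_hit, 8), rep(without, 2)))
  control <- toy_peaks(c(rep(with_hit, 2), rep(without, 8)))
  enr <- motif_enrichment(target, control, motif)
  expect_equal(enr$odds_ratio, 16)
  p_hyper <- sum(stats::dhyper(8:10, 10, 10, 10))
  expect_equal(enr$p, p_hyper, tolerance = 1e-12)

  # identical target and control: OR 1, p >= 0.5
  enr2 <- motif_enrichment(target, target, motif)
  expect_equal(enr2$odds_ratio, 1)
  expect_gte(enr2$p, 0.5)

  # planted contrast: p < 1e-6
  withr::with_seed(41, {
    rand_seq <- function() paste(sample(c("A", "C", "G", "T"), 120,
                                        replace = TRUE), collapse = "")
    tseqs <- vapply(1:200, function(i)
      if (i <= 100) paste0(substr(rand_seq(), 1, 50), cons,
                           substr(rand_seq(), 1, 50)) else rand_seq(), "")
    cseqs <- vapply(1:200, function(i)
      if (i <= 10) paste0(substr(rand_seq(), 1, 50), cons,
                          substr(rand_seq(), 1, 50)) else rand_seq(), "")
  })
  enr3 <- motif_enrichment(toy_peaks(tseqs), toy_peaks(cseqs), motif)
  expect_lt(enr3$p, 1e-6)
})

test_that("co-occurrence counting follows the 50-bp edge-gap rule", {
  ha <- data.frame(peak = "p1", offset = 10L, strand = "+", score = 1,
                   motif = "A")
  hb30 <- data.frame(peak = "p1", offset = 50L, strand = "+", score = 1,
                     motif = "B")
  hb70 <- data.frame(peak = "p1", offset = 90L, strand = "+", score = 1,
                     motif = "B")
  # [10,20) vs [50,60): gap 30 <= 50 -> 1
  expect_equal(count_cooccurrences(ha, hb30, 10, 10, 50), 1)
  # [10,20) vs [90,100): gap 70 -> 0
  expect_equal(count_cooccurrences(ha, hb70, 10, 10, 50), 0)
  # overlapping occurrences have distance 0
  hb_ov <- data.frame(peak = "p1", offset = 15L, strand = "+", score = 1,
                      motif = "B")
  expect_equal(count_cooccurrences(ha, hb_ov, 10, 10, 0), 1)
})

test_that("co-occurrence counts equal O(n^2) brute force on random configurations", {
  for (trial in 1:100) {
    ha <- random_hits(20, 0.8, "A", seed = 1000 + trial)
    hb <- random_hits(20, 0.8, "B", seed = 2000 + trial)
    expect_equal(count_cooccurrences(ha, hb, 10, 12, 50),
                 brute_cooc(ha, hb, 10, 12, 50))
    # symmetry in (A, B)
    expect_equal(count_cooccurrences(hb, ha, 12, 10, 50),
                 count_cooccurrences(ha, hb, 10, 12, 50))
    # invariance to hit ordering
    perm <- sample(nrow(ha))
    expect_equal(count_cooccurrences(ha[perm, ], hb, 10, 12, 50),
                 count_cooccurrences(ha, hb, 10, 12, 50))
  }
  # self-pair case: unordered distinct pairs once
  ha <- random_hits(10, 1.5, "A", seed = 5)
  expect_equal(count_cooccurrences(ha, ha, 10, 10, 50),
               brute_cooc(ha, ha, 10, 10, 50, same = TRUE))
})

test_that("z-score conventions: degenerate universe gives z = 0 with warning", {
  ha <- random_hits(30, 1, "A", seed = 3)
  hb <- random_hits(30, 1, "B", seed = 4)
  universe <- sprintf("p%04d", 1:30)
  expect_warning(
    res <- cooccurrence_zscore(ha, hb, universe, universe, 10, 10,
                               n_bg = 50, seed = 1),
    "universe equals target")
  expect_equal(res$z, 0)
  expect_equal(res$n_bg, 50)
  expect_error(cooccurrence_zscore(ha, hb, c(universe, "zz"), universe,
                                   10, 10), "subset")
})

test_that("planted co-occurrence stands out and the z-score is resampling-stable", {
  # universe: 1000 peaks with 2% baseline pairs; target 150 peaks with 40%
  withr::with_seed(61, {
    n_u <- 1000
    ids <- sprintf("p%04d", seq_len(n_u))
    target <- sample(ids, 150)
    pair_frac <- ifelse(ids %in% target, 0.4, 0.02)
    has_pair <- runif(n_u) < pair_frac
    ha <- data.frame(peak = ids, offset = 30L, strand = "+", score = 1,
                     motif = "A")
    hb <- data.frame(peak = ids[has_pair], offset = 55L, strand = "+",
                     score = 1, motif = "B")
  })
  z1 <- cooccurrence_zscore(ha, hb, target, ids, 10, 10, max_gap = 50,
                            n_bg = 1000, seed = 7)
  expect_gt(z1$z, 5)
  z4 <- cooccurrence_zscore(ha, hb, target, ids, 10, 10, max_gap = 50,
                            n_bg = 4000, seed = 7)
  expect_lt(abs(z1$z - z4$z), 0.2 * abs(z1$z) + 0.5)
  # peak relabelling leaves z unchanged
  relab <- setNames(sprintf("q%04d", seq_len(n_u)), ids)
  ha2 <- transform(ha, peak = relab[peak])
  hb2 <- transform(hb, peak = relab[peak])
  z2 <- cooccurrence_zscore(ha2, hb2, unname(relab[target]),
                            unname(relab[ids]), 10, 10, max_gap = 50,
                            n_bg = 1000, seed = 7)
  expect_equal(z2$z, z1$z)
})
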