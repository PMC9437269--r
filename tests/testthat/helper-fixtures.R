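# Shared fixtures, built in code at test time.

# A tiny peak set with hand-chosen sequences.
toy_peaks <- function(seqs, chrom = "chrT", gap = 1000L) {
  lens <- nchar(seqs)
  ids <- sprintf("tp_%02d", seq_along(seqs))
  starts <- cumsum(c(1L, head(lens, -1) + gap))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, width = lens),
                               name = ids, enh_prob = rep(0.9, length(seqs)))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  peak_set(gr, dna)
}

# Random hit tables over a synthetic peak universe (homogeneous rates).
random_hits <- function(n_peaks, lambda, motif, peak_len = 300, seed = 1) {
  withr::with_seed(seed, {
    n <- stats::rpois(n_peaks, lambda)
    data.frame(peak = rep(sprintf("p%04d", seq_len(n_peaks)), n),
               offset = sample.int(peak_len - 10, sum(n), replace = TRUE) - 1L,
               strand = "+", score = 10, motif = motif)
  })
}

# Independent O(n^2) brute-force co-occurrence counter (the oracle).
brute_cooc <- function(hits_a, hits_b, len_a, len_b, max_gap,
                       same = FALSE) {
  total <- 0L
  for (i in seq_len(nrow(hits_a))) {
    for (j in seq_len(nrow(hits_b))) {
      if (hits_a$peak[i] != hits_b$peak[j]) next
      if (same && i >= j) next
      a1 <- hits_a$offset[i]; a2 <- a1 + len_a
      b1 <- hits_b$offset[j]; b2 <- b1 + len_b
      gap <- max(b1 - a2, a1 - b2, 0)
      if (gap <= max_gap) total <- total + 1L
    }
  }
  total
}

# Textbook Benjamini-Hochberg step-up (the oracle for bh_adjust).
bh_textbook <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

# Naive per-position PWM rescoring (the oracle for scan_motifs).
naive_scan <- function(seq, motif, threshold) {
  bases <- c("A", "C", "G", "T")
  sc <- function(s, lo) {
    ch <- strsplit(s, "")[[1]]
    sum(vapply(seq_along(ch), function(l) {
      i <- match(ch[l], bases)
      if (is.na(i)) 0 else lo[i, l]
    }, 0))
  }
  L <- ncol(motif$ppm)
  lo_r <- motif_revcomp(motif)$log_odds
  out <- NULL
  for (pos in seq_len(nchar(seq) - L + 1)) {
    sub <- substr(seq, pos, pos + L - 1)
    for (strand in c("+", "-")) {
      s <- sc(sub, if (strand == "+") motif$log_odds else lo_r)
      if (s >= threshold)
        out <- rbind(out, data.frame(offset = pos - 1L, strand = strand,
                                     score = s))
    }
  }
  out
}

# Small count_set built by hand.
toy_count_set <- function(counts, groups) {
  meta <- data.frame(sample = colnames(counts),
                     group = factor(groups, levels = unique(groups)))
  count_set(counts, meta)
}

# Cached small landscape shared across test files (generation ~3 s).
shared_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(seed = 3, n_cells = 1200, n_genes = 600,
                              n_clusters = 5)
      cache <<- list(cfg = cfg, sim = gen_landscape(cfg))
    }
    cache
  }
})
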