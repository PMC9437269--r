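# Encode an uppercase ACGTN sequence as integers 1..4 (NA for N).
encode_seq <- function(s) {
  match(strsplit(toupper(s), "")[[1]], DNA_BASES)
}

# Score every start position of an encoded sequence against a log-odds
# matrix; N (NA) contributes 0 (background behaviour).
score_positions <- function(enc, lo) {
  L <- ncol(lo); P <- length(enc) - L + 1L
  if (P < 1L) return(numeric(0))
  score <- numeric(P)
  for (l in seq_len(L)) {
    v <- lo[, l][enc[seq(l, l + P - 1L)]]
    v[is.na(v)] <- 0
    score <- score + v
  }
  score
}

#' Scan peak sequences with a position weight matrix
#'
#' Scores every position of every peak sequence on both strands with the
#' motif's log-odds matrix and emits positions reaching the threshold.
#' Reverse-strand hits are reported in forward-frame coordinates (the
#' offset of the leftmost base of the occurrence). `N` bases score as
#' background (zero log-odds contribution).
#'
#' @param peaks A [peak_set()] with sequences.
#' @param motif A [motif_model()].
#' @param threshold Absolute log-odds threshold; default
#'   `threshold_frac * max_score` of the motif.
#' @return Data frame `peak`, `offset` (0-based within peak), `strand`,
#'   `score`, `motif`.
#' @export
scan_motifs <- function(peaks, motif, threshold = NULL) {
  if (is.null(peaks$seqs)) stopf("peak set carries no sequences")
  threshold <- threshold %||% (motif$threshold_frac * motif$max_score)
  if (threshold > motif$max_score)
    stopf("threshold %.2f exceeds maximal achievable score %.2f",
          threshold, motif$max_score)
  lo_f <- motif$log_odds
  lo_r <- motif_revcomp(motif)$log_odds
  seqs <- as.character(peaks$seqs)
  ids <- peak_names(peaks)
  res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    enc <- encode_seq(seqs[[i]])
    sf <- score_positions(enc, lo_f)
    sr <- score_positions(enc, lo_r)
    hf <- which(sf >= threshold); hr <- which(sr >= threshold)
    if (length(hf) || length(hr)) {
      res[[i]] <- data.frame(
        peak = ids[i],
        offset = c(hf, hr) - 1L,
        strand = rep(c("+", "-"), c(length(hf), length(hr))),
        score = c(sf[hf], sr[hr]),
        motif = motif$name)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(peak = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      motif = character())
  rownames(out) <- NULL
  out
}

#' Motif enrichment of a target peak set against a control set
#'
#' Builds the 2x2 table of peaks with / without at least one motif hit in
#' the target vs control set and reports the sample odds ratio together
#' with the one-sided (enrichment) Fisher exact p-value. The control may be
#' the reciprocal differential peak set or a dinucleotide-free shuffle of
#' the target sequences.
#'
#' @param target,control [peak_set()] objects with sequences; or, when
#'   `control = "shuffle"`, the control is built by per-sequence
#'   mononucleotide shuffling of the target (seeded).
#' @param motif A [motif_model()].
#' @param threshold Scanning threshold (shared by both sets).
#' @param seed Seed for the shuffle control.
#' @return List: `odds_ratio`, `p`, `table` (2x2 counts).
#' @export
motif_enrichment <- function(target, control, motif, threshold = NULL,
                             seed = 1L) {
  if (identical(control, "shuffle")) {
    control <- withr::with_seed(seed, {
      sh <- vapply(as.character(target$seqs), function(s)
        paste(sample(strsplit(s, "")[[1]]), collapse = ""), "")
      ids <- paste0(peak_names(target), "_shuf")
      gr <- target$ranges
      S4Vectors::mcols(gr)$name <- ids
      dna <- Biostrings::DNAStringSet(sh); names(dna) <- ids
      peak_set(gr, dna)
    })
  }
  if (length(control) == 0L || length(control$ranges) == 0L)
    stopf("control peak set is empty")
  hit_t <- unique(scan_motifs(target, motif, threshold)$peak)
  hit_c <- unique(scan_motifs(control, motif, threshold)$peak)
  tab <- matrix(c(length(hit_t), length(target) - length(hit_t),
                  length(hit_c), length(control) - length(hit_c)),
                2, 2, dimnames = list(c("hit", "no_hit"),
                                      c("target", "control")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  a <- tab[1, 1]; b <- tab[2, 1]; c <- tab[1, 2]; d <- tab[2, 2]
  or <- (a * d) / (b * c)
  list(odds_ratio = or, p = ft$p.value, table = tab,
       conditional_or = unname(ft$estimate))
}

#' Count motif-pair co-occurrences within peaks
#'
#' Counts pairs (one hit of A, one hit of B) lying in the same peak whose
#' distance does not exceed `max_gap`. Distance is the gap between nearest
#' edges (0 when the occurrences overlap); `anchor = "center"` switches to
#' centre-to-centre distance. All qualifying pairs are counted
#' (multiplicity); `per_peak = TRUE` counts each peak at most once. When
#' the two hit tables describe the same motif, each unordered pair of
#' distinct hits is counted once.
#'
#' @param hits_a,hits_b Hit tables from [scan_motifs()] (need `peak`,
#'   `offset`, `motif` columns).
#' @param len_a,len_b Motif lengths in bp (taken from hit width context).
#' @param max_gap Maximum separation in bp.
#' @param anchor `"edge"` (nearest-edge gap) or `"center"`.
#' @param per_peak Count each peak at most once instead of all pairs.
#' @return Integer co-occurrence count.
#' @export
count_cooccurrences <- function(hits_a, hits_b, len_a, len_b, max_gap = 50,
                                anchor = c("edge", "center"),
                                per_peak = FALSE) {
  anchor <- match.arg(anchor)
  same <- nrow(hits_a) == nrow(hits_b) &&
    length(unique(c(hits_a$motif, hits_b$motif))) == 1L &&
    identical(hits_a$offset, hits_b$offset) &&
    identical(hits_a$peak, hits_b$peak)
  common <- intersect(unique(hits_a$peak), unique(hits_b$peak))
  total <- 0L
  for (pk in common) {
    oa <- hits_a$offset[hits_a$peak == pk]
    ob <- hits_b$offset[hits_b$peak == pk]
    d <- pair_distance(oa, ob, len_a, len_b, anchor)
    ok <- d <= max_gap
    if (same) {
      # unordered distinct pairs, counted once
      ok <- ok & outer(seq_along(oa), seq_along(ob), "<")
    }
    cnt <- sum(ok)
    total <- total + if (per_peak) as.integer(cnt > 0) else cnt
  }
  total
}

# Pairwise distances between occurrence sets (matrix |a| x |b|).
pair_distance <- function(oa, ob, len_a, len_b, anchor) {
  if (anchor == "center") {
    abs(outer(oa + (len_a - 1) / 2, ob + (len_b - 1) / 2, "-"))
  } else {
    # nearest-edge gap of [oa, oa+len_a) vs [ob, ob+len_b), 0 if overlapping
    gap_ab <- outer(oa, ob, function(x, y) y - (x + len_a)) # b right of a
    gap_ba <- outer(oa, ob, function(x, y) x - (y + len_b)) # a right of b
    pmax(gap_ab, gap_ba, 0)
  }
}

#' Motif-pair co-occurrence z-score against background peak subsamples
#'
#' Observed co-occurrence count in a target peak subset, compared with the
#' counts in `n_bg` equally sized random subsamples (without replacement)
#' of a peak universe. z = (observed - mean) / SD over background counts
#' (sample SD); when the background SD is 0 the z-score is 0 by convention
#' (with a warning when the universe equals the target so every subsample
#' is the target itself).
#'
#' @param hits_a,hits_b Hit tables over the universe (from [scan_motifs()]).
#' @param target_peaks Character vector of target peak ids (subset of
#'   universe).
#' @param universe_peaks Character vector of universe peak ids.
#' @param len_a,len_b Motif lengths (bp).
#' @param max_gap Maximum separation (bp).
#' @param n_bg Number of background subsamples.
#' @param seed Integer seed; replicate r uses a derived stream so results
#'   are reproducible regardless of evaluation order.
#' @param anchor,per_peak Passed to [count_cooccurrences()].
#' @return A list of class `"cooc_result"`: `pair`, `observed`, `bg_mean`,
#'   `bg_sd`, `z`, `n_bg`, `seed`, `background` (full count vector).
#' @export
cooccurrence_zscore <- function(hits_a, hits_b, target_peaks, universe_peaks,
                                len_a, len_b, max_gap = 50, n_bg = 1000,
                                seed = 1L, anchor = "edge",
                                per_peak = FALSE) {
  if (!all(target_peaks %in% universe_peaks))
    stopf("target peaks must be a subset of the universe")
  if (length(universe_peaks) < length(target_peaks))
    stopf("universe smaller than target")
  # Per-peak pair counts over the universe: a subset's count is the sum of
  # the per-peak counts of its members (pairs are within-peak only).
  per_counts <- stats::setNames(numeric(length(universe_peaks)),
                                universe_peaks)
  involved <- intersect(unique(c(hits_a$peak, hits_b$peak)), universe_peaks)
  for (pk in involved) {
    per_counts[pk] <- count_cooccurrences(
      hits_a[hits_a$peak == pk, , drop = FALSE],
      hits_b[hits_b$peak == pk, , drop = FALSE],
      len_a, len_b, max_gap, anchor, per_peak)
  }
  observed <- sum(per_counts[target_peaks])
  m <- length(target_peaks)
  bg <- withr::with_seed(derive_seed(seed, 7L), {
    vapply(seq_len(n_bg), function(r)
      sum(per_counts[sample.int(length(universe_peaks), m)]), 0)
  })
  bg_sd <- stats::sd(bg)
  if (length(universe_peaks) == length(target_peaks))
    warnf("universe equals target: every background subsample is the target")
  z <- if (is.na(bg_sd) || bg_sd == 0) 0 else (observed - mean(bg)) / bg_sd
  structure(list(pair = c(hits_a$motif[1] %||% NA, hits_b$motif[1] %||% NA),
                 observed = observed, bg_mean = mean(bg), bg_sd = bg_sd,
                 z = z, n_bg = n_bg, seed = seed, background = bg),
            class = "cooc_result")
}

#' @method print cooc_result
#' @export
print.cooc_result <- function(x, ...) {
  cat(sprintf("cooc_result %s-%s: obs=%g bg=%.2f+/-%.2f z=%.2f (n_bg=%d)\n",
              x$pair[1], x$pair[2], x$observed, x$bg_mean, x$bg_sd, x$z,
              x$n_bg))
  invisible(x)
}
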