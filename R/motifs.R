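DNA_BASES <- c("A", "C", "G", "T")

#' Construct a motif model
#'
#' A motif model couples a position probability matrix (PPM) with the
#' background nucleotide frequencies and a scanning threshold. Log-odds
#' scores are computed as `log2(ppm / background)` after pseudocount
#' regularisation; `N` bases score zero (background behaviour).
#'
#' @param name Motif name (e.g. `"EBF1"`).
#' @param ppm Numeric matrix, 4 rows (A, C, G, T) by motif length; columns
#'   need not sum exactly to 1 before pseudocounting.
#' @param background Length-4 background frequencies (must sum to 1).
#' @param pseudocount Added to each probability before renormalising.
#' @param threshold_frac Default scanning threshold, as a fraction of the
#'   motif's maximal achievable log-odds score.
#' @return An object of class `"motif_model"`.
#' @export
motif_model <- function(name, ppm, background = rep(0.25, 4),
                        pseudocount = 0.01, threshold_frac = 0.8) {
  ppm <- as.matrix(ppm)
  if (nrow(ppm) != 4L) stopf("`ppm` must have 4 rows (A, C, G, T)")
  if (any(ppm < 0)) stopf("`ppm` entries must be non-negative")
  if (abs(sum(background) - 1) > 1e-8) stopf("background must sum to 1")
  ppm <- sweep(ppm + pseudocount, 2, colSums(ppm + pseudocount), "/")
  dimnames(ppm) <- list(DNA_BASES, NULL)
  lo <- log2(sweep(ppm, 1, background, "/"))
  structure(
    list(name = name, ppm = ppm, background = background,
         log_odds = lo, max_score = sum(apply(lo, 2, max)),
         min_score = sum(apply(lo, 2, min)),
         threshold_frac = threshold_frac),
    class = "motif_model"
  )
}

#' @method print motif_model
#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model '%s': length %d, max log-odds %.2f, consensus %s\n",
              x$name, ncol(x$ppm), x$max_score, motif_consensus(x)))
  invisible(x)
}

#' Motif length (bp)
#' @param motif A `motif_model`.
#' @export
motif_length <- function(motif) ncol(motif$ppm)

#' Consensus sequence (most probable base per column)
#' @param motif A `motif_model`.
#' @export
motif_consensus <- function(motif) {
  paste(DNA_BASES[apply(motif$ppm, 2, which.max)], collapse = "")
}

#' Reverse-complement a motif model
#' @param motif A `motif_model`.
#' @export
motif_revcomp <- function(motif) {
  ppm <- motif$ppm[4:1, rev(seq_len(ncol(motif$ppm))), drop = FALSE]
  motif_model(motif$name, ppm, background = motif$background[4:1],
              pseudocount = 0, threshold_frac = motif$threshold_frac)
}

# Build a sharply-peaked PPM from a consensus string; 'N' means uniform.
ppm_from_consensus <- function(consensus, strength = 0.85) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  ppm <- vapply(letters, function(b) {
    if (b == "N") return(rep(0.25, 4))
    p <- rep((1 - strength) / 3, 4)
    p[match(b, DNA_BASES)] <- strength
    p
  }, numeric(4))
  dimnames(ppm) <- list(DNA_BASES, NULL)
  ppm
}

#' Built-in synthetic motif library
#'
#' Three synthetic position weight matrices emulating the motif classes of
#' interest in progenitor accessibility analysis: an EBF1-like palindromic
#' motif, a C/EBP-like bZIP motif and a long CTCF-like zinc-finger motif
#' (the usual randomised control motif for footprint envelopes). These are
#' synthetic models built from consensus strings, not database PWMs.
#'
#' @param strength Probability mass on the consensus base at each position.
#' @return Named list of `motif_model` objects.
#' @export
default_motif_library <- function(strength = 0.85) {
  cons <- c(
    EBF1 = "TCCCNNGGGA",
    CEBPA = "TTGCGCAA",
    CTCF = "CCACCAGGGGGCGC"
  )
  lapply(stats::setNames(names(cons), names(cons)), function(nm) {
    motif_model(nm, ppm_from_consensus(cons[[nm]], strength))
  })
}

#' Write motifs in MEME-minimal format
#'
#' @param motifs A list of `motif_model` objects.
#' @param path Output file.
#' @export
write_meme <- function(motifs, path) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  bg <- motifs[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, bg), collapse = " "),
               ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(m$ppm)), con)
    apply(m$ppm, 2, function(col)
      writeLines(paste(sprintf("%.6f", col), collapse = " "), con))
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a MEME-minimal file
#'
#' Parses the minimal MEME motif text format (header, background line,
#' `MOTIF`/`letter-probability matrix` blocks). Only the fields this
#' package uses are interpreted.
#'
#' @param path MEME-minimal motif file.
#' @param threshold_frac Scanning threshold fraction applied to each motif.
#' @return Named list of `motif_model` objects.
#' @export
read_meme <- function(path, threshold_frac = 0.8) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(toks[seq(2, 8, by = 2)])
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stopf("no MOTIF blocks in %s", path)
  motifs <- lapply(starts, function(i) {
    name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    hdr <- i + grep("letter-probability matrix", lines[seq(i + 1, length(lines))])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[seq(hdr + 1, hdr + w)]
    ppm <- t(vapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:4]), numeric(4)))
    motif_model(name, t(ppm), background = bg, pseudocount = 0,
                threshold_frac = threshold_frac)
  })
  stats::setNames(motifs, vapply(motifs, `[[`, "", "name"))
}
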