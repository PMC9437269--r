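#' Peak set container
#'
#' Couples genomic peak intervals (a [GenomicRanges::GRanges] with `name`
#' and optional `enh_prob` metadata columns) with optional per-peak DNA
#' sequences (a [Biostrings::DNAStringSet] named by peak id). Coordinates
#' follow the BED convention externally (0-based half-open) and the
#' GRanges convention (1-based closed) in memory; readers and writers
#' convert.
#'
#' @param ranges A `GRanges` with a `name` metadata column (unique ids).
#' @param seqs Optional `DNAStringSet` named by peak id, one per peak.
#' @return An object of class `"peak_set"`.
#' @export
peak_set <- function(ranges, seqs = NULL) {
  if (!methods::is(ranges, "GRanges")) stopf("`ranges` must be a GRanges")
  nm <- S4Vectors::mcols(ranges)$name
  if (is.null(nm) || anyDuplicated(nm))
    stopf("peak ranges need a unique `name` metadata column")
  if (!is.null(seqs)) {
    if (!methods::is(seqs, "DNAStringSet")) stopf("`seqs` must be a DNAStringSet")
    if (!setequal(names(seqs), nm)) stopf("sequence names must match peak names")
    seqs <- seqs[nm]
    if (!all(Biostrings::width(seqs) == GenomicRanges::width(ranges)))
      stopf("sequence widths must equal peak widths")
  }
  structure(list(ranges = ranges, seqs = seqs), class = "peak_set")
}

#' @method print peak_set
#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks%s%s\n", length(x$ranges),
              if (!is.null(x$seqs)) ", with sequences" else "",
              if (!is.null(S4Vectors::mcols(x$ranges)$enh_prob))
                ", with enhancer probabilities" else ""))
  invisible(x)
}

#' @export
length.peak_set <- function(x) length(x$ranges)

#' Peak ids of a peak set
#' @param peaks A `peak_set`.
#' @export
peak_names <- function(peaks) S4Vectors::mcols(peaks$ranges)$name

#' Subset a peak set by peak id
#' @param peaks A `peak_set`.
#' @param ids Character vector of peak ids to retain (order preserved).
#' @export
subset_peaks <- function(peaks, ids) {
  idx <- match(ids, peak_names(peaks))
  if (anyNA(idx)) stopf("unknown peak ids: %s",
                        paste(utils::head(ids[is.na(idx)], 3), collapse = ", "))
  peak_set(peaks$ranges[idx], if (!is.null(peaks$seqs)) peaks$seqs[idx])
}

#' Write peaks as BED6
#'
#' The BED score column stores the enhancer probability scaled by 1,000
#' (0 when absent); strand is `.` for peaks.
#'
#' @param peaks A `peak_set`.
#' @param path Output BED file.
#' @export
write_peaks_bed <- function(peaks, path) {
  gr <- peaks$ranges
  prob <- S4Vectors::mcols(gr)$enh_prob
  score <- if (is.null(prob)) rep(0L, length(gr)) else as.integer(round(prob * 1000))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = S4Vectors::mcols(gr)$name,
    score = score,
    strand = "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 peak file
#'
#' @param path BED file (as written by [write_peaks_bed()]).
#' @param seqs_fasta Optional FASTA of peak sequences keyed by peak id.
#' @return A `peak_set`; BED scores are decoded into `enh_prob`.
#' @export
read_peaks_bed <- function(path, seqs_fasta = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  S4Vectors::mcols(gr)$enh_prob <- S4Vectors::mcols(gr)$score / 1000
  S4Vectors::mcols(gr)$score <- NULL
  seqs <- if (!is.null(seqs_fasta)) Biostrings::readDNAStringSet(seqs_fasta)
  if (!is.null(seqs)) names(seqs) <- sub("\\s.*$", "", names(seqs))
  peak_set(gr, seqs)
}

#' Write peak sequences as FASTA
#' @param peaks A `peak_set` with sequences.
#' @param path Output FASTA file.
#' @export
write_peaks_fasta <- function(peaks, path) {
  if (is.null(peaks$seqs)) stopf("peak set carries no sequences")
  Biostrings::writeXStringSet(peaks$seqs, path)
  invisible(path)
}

#' Write a per-base cut-site track as bedGraph
#'
#' @param track Named list of per-base numeric vectors (one per peak, in
#'   peak-local full-length coordinates) as produced by [gen_cut_track()].
#' @param peaks The `peak_set` the track is defined on.
#' @param path Output bedGraph (1-bp bins, zero bins omitted).
#' @export
write_track_bedgraph <- function(track, peaks, path) {
  gr <- peaks$ranges
  idx <- match(names(track), S4Vectors::mcols(gr)$name)
  rows <- lapply(seq_along(track), function(i) {
    v <- track[[i]]
    keep <- v != 0
    if (!any(keep)) return(NULL)
    pos <- which(keep)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[idx[i]],
               start = GenomicRanges::start(gr)[idx[i]] - 2L + pos,
               end = GenomicRanges::start(gr)[idx[i]] - 1L + pos,
               value = v[keep])
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph cut track into per-peak vectors
#'
#' @param path bedGraph file.
#' @param peaks The `peak_set` defining the peak-local frames.
#' @return Named list of per-base vectors, one per peak (length = width).
#' @export
read_track_bedgraph <- function(path, peaks) {
  bg <- rtracklayer::import(path, format = "bedGraph")
  gr <- peaks$ranges
  track <- lapply(seq_along(gr), function(i) numeric(GenomicRanges::width(gr)[i]))
  names(track) <- S4Vectors::mcols(gr)$name
  hits <- GenomicRanges::findOverlaps(bg, gr)
  for (h in seq_along(hits)) {
    q <- S4Vectors::queryHits(hits)[h]; s <- S4Vectors::subjectHits(hits)[h]
    off <- GenomicRanges::start(bg)[q] - GenomicRanges::start(gr)[s] + 1L
    len <- GenomicRanges::width(bg)[q]
    track[[s]][seq(off, off + len - 1L)] <- S4Vectors::mcols(bg)$score[q]
  }
  track
}
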