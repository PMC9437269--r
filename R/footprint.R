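#' Aggregate Tn5 cut counts around motif-centred windows
#'
#' Extracts a window of +/- `w` bp around each site centre from the
#' per-peak cut track and averages per base over sites. Minus-strand
#' windows are reversed before averaging so the profile is motif-oriented.
#' Sites whose window leaves the peak are dropped (count reported).
#'
#' @param track Named list of per-base cut vectors (one per peak), e.g.
#'   from [gen_cut_track()] or [read_track_bedgraph()].
#' @param sites Data frame with columns `peak`, `center` (0-based offset of
#'   the window centre within the peak) and `strand`.
#' @param w Window half-width (bp); the profile has `2w + 1` bases.
#' @return A list of class `"cut_profile"`: `profile` (length `2w+1` mean
#'   cut counts), `n_sites`, `n_dropped`, `w`.
#' @export
aggregate_cuts <- function(track, sites, w = 100) {
  stopifnot(all(c("peak", "center", "strand") %in% names(sites)))
  acc <- numeric(2 * w + 1)
  used <- 0L; dropped <- 0L
  for (i in seq_len(nrow(sites))) {
    v <- track[[sites$peak[i]]]
    if (is.null(v)) { dropped <- dropped + 1L; next }
    c1 <- sites$center[i] + 1L # 1-based centre
    lo <- c1 - w; hi <- c1 + w
    if (lo < 1L || hi > length(v)) { dropped <- dropped + 1L; next }
    win <- v[lo:hi]
    if (identical(sites$strand[i], "-")) win <- rev(win)
    acc <- acc + win
    used <- used + 1L
  }
  if (used == 0L) stopf("no usable sites (all %d dropped)", dropped)
  structure(list(profile = acc / used, n_sites = used,
                 n_dropped = dropped, w = w),
            class = "cut_profile")
}

#' @method print cut_profile
#' @export
print.cut_profile <- function(x, ...) {
  cat(sprintf("cut_profile: w=%d, %d sites (%d dropped), mean signal %.3f\n",
              x$w, x$n_sites, x$n_dropped, mean(x$profile)))
  invisible(x)
}

#' Randomised control-motif aggregation envelope
#'
#' Draws `n_sets` random sets of `set_size` control-motif sites (without
#' replacement within a set), aggregates each, and summarises the ensemble
#' by the per-base median and SD — the randomised-control band against
#' which a candidate footprint profile is judged.
#'
#' @param track Per-peak cut track.
#' @param control_sites Data frame of control-motif sites (`peak`, `center`,
#'   `strand`), typically CTCF-motif hits across the peak universe.
#' @param n_sets Number of random sets.
#' @param set_size Sites per set.
#' @param w Window half-width (bp).
#' @param seed Integer seed.
#' @return List of class `"control_envelope"`: `median`, `sd` (per-base),
#'   `profiles` (`n_sets` x `2w+1`), `n_sets`, `set_size`, `w`, `seed`.
#' @export
control_envelope <- function(track, control_sites, n_sets = 100,
                             set_size = 200, w = 100, seed = 1L) {
  if (nrow(control_sites) < set_size)
    stopf("only %d control sites for set_size %d; reduce set_size",
          nrow(control_sites), set_size)
  profs <- withr::with_seed(derive_seed(seed, 11L), {
    t(vapply(seq_len(n_sets), function(r) {
      idx <- sample.int(nrow(control_sites), set_size)
      aggregate_cuts(track, control_sites[idx, , drop = FALSE], w)$profile
    }, numeric(2 * w + 1)))
  })
  structure(list(median = apply(profs, 2, stats::median),
                 sd = if (n_sets > 1) apply(profs, 2, stats::sd) else
                   numeric(2 * w + 1),
                 profiles = profs, n_sets = n_sets, set_size = set_size,
                 w = w, seed = seed),
            class = "control_envelope")
}

#' Scalar footprint depth of an aggregation profile
#'
#' depth = mean over the flank bases minus mean over the core bases, where
#' the flanks are the intervals `[w/2, w]` on each side of the centre and
#' the core is `[-core_halfwidth, +core_halfwidth]`. Positive depth means
#' central protection (a footprint); negative depth means central
#' enrichment.
#'
#' @param profile A `cut_profile` (or bare numeric profile of odd length).
#' @param core_halfwidth Core half-width in bp (must be < `w`).
#' @return Numeric depth.
#' @export
footprint_depth <- function(profile, core_halfwidth = 10) {
  p <- if (inherits(profile, "cut_profile")) profile$profile else profile
  w <- (length(p) - 1L) %/% 2L
  if (core_halfwidth >= w) stopf("core_halfwidth must be < w (%d)", w)
  center <- w + 1L
  core <- p[(center - core_halfwidth):(center + core_halfwidth)]
  fl <- c(p[(center - w):(center - ceiling(w / 2))],
          p[(center + ceiling(w / 2)):(center + w)])
  mean(fl) - mean(core)
}

#' Footprint depth of an envelope's member profiles
#'
#' Convenience: applies [footprint_depth()] to every control profile of a
#' [control_envelope()], giving the null depth distribution.
#'
#' @param env A `control_envelope`.
#' @param core_halfwidth Core half-width (bp).
#' @return Numeric vector of depths, one per control set.
#' @export
envelope_depths <- function(env, core_halfwidth = 10) {
  apply(env$profiles, 1, footprint_depth, core_halfwidth = core_halfwidth)
}
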