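#' Synthetic-data generator configuration
#'
#' One seeded configuration object drives every generator in the package.
#' Defaults describe the study conditions the generators emulate: a
#' peak universe of 2,000 regulatory elements of 300-600 bp with motif
#' instances planted from the built-in library; negative-binomial count
#' matrices with 4 replicates per genotype (accessibility) and moderate
#' biological dispersion; Tn5 cut tracks with footprint-shaped depletion at
#' bound motifs; and a clustered single-cell landscape (2,000 cells, 1,000
#' genes, 5 clusters on a branched manifold) with sex markers, batch labels
#' and a planted per-cluster genotype shift.
#'
#' @param seed Integer master seed; every generator derives its own stream.
#' @param n_peaks,peak_len_range,bg_freqs Peak universe geometry and i.i.d.
#'   background nucleotide frequencies (must sum to 1).
#' @param motifs Motif library (named list of [motif_model()]).
#' @param plant_fidelity Fidelity of planted instances: 1 plants the
#'   consensus (max-scoring occurrence), values below 1 sample each base
#'   from the PPM.
#' @param planted_site_frac Named numeric: fraction of peaks receiving a
#'   planted instance of each named motif.
#' @param planted_pairs Data frame with columns `a`, `b`, `fraction`,
#'   `gap_min`, `gap_max`: motif pairs planted in a fraction of peaks at a
#'   nearest-edge gap drawn uniformly from `[gap_min, gap_max]` bp.
#' @param enh_prob_planted,enh_prob_background Uniform ranges from which
#'   enhancer probabilities are drawn for peaks with / without planted sites.
#' @param n_features,n_per_group Count-matrix dimensions; `n_per_group` is a
#'   named integer vector (two group levels).
#' @param nb_mean_range Log-uniform range of baseline negative-binomial means.
#' @param nb_dispersion_range Uniform range of per-feature NB dispersions.
#' @param n_da,da_lfc Number of planted differential features and the
#'   signed log2 fold-change grid they are drawn from.
#' @param sex_effect,batch_effect SDs of per-feature additive log2 effects.
#' @param depth_range Uniform range of per-sample sequencing-depth factors.
#' @param cut_rate Background Tn5 cut rate (expected cuts per base).
#' @param footprint_depth Fractional depletion of the cut rate over the
#'   motif core at bound sites (0 = no footprint).
#' @param footprint_ramp Linear ramp width (bp) from full depletion back to
#'   background on each side of the core.
#' @param footprint_frac Fraction of planted motif sites carrying a footprint.
#' @param footprint_motifs Names of the motifs whose planted sites are
#'   bound (carry cut depletion); control motifs (e.g. CTCF) stay unbound.
#' @param n_cells,n_genes,n_clusters,origin_cluster Landscape geometry.
#' @param n_markers_per_cluster,marker_lfc Cluster-marker genes and their
#'   log2 elevation in the home cluster.
#' @param n_gradient_genes Genes whose expression follows the lineage
#'   coordinate smoothly.
#' @param female_marker,y_genes Sex-marker gene names (one female marker,
#'   three Y-linked markers by default).
#' @param doublet_frac Fraction of cells expressing both sex-marker classes.
#' @param n_mice,n_batches Biological replicates (split evenly between
#'   genotypes) and batches.
#' @param shift_cluster,shift_n_genes,shift_lfc Planted genotype effect:
#'   cluster index whose cells carry a log2 shift on a random gene subset
#'   (`NULL` cluster disables the plant; default last cluster).
#' @param cell_dispersion NB dispersion of single-cell counts.
#' @param lib_size_range Uniform range of per-cell expected library sizes.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L,
                             n_peaks = 2000L,
                             peak_len_range = c(300L, 600L),
                             bg_freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             motifs = default_motif_library(),
                             plant_fidelity = 1,
                             planted_site_frac = c(EBF1 = 0.2),
                             planted_pairs = data.frame(
                               a = "EBF1", b = "CEBPA", fraction = 0.05,
                               gap_min = 0L, gap_max = 50L),
                             enh_prob_planted = c(0.85, 1),
                             enh_prob_background = c(0, 1),
                             n_features = 5000L,
                             n_per_group = c(WT = 4L, KO = 4L),
                             nb_mean_range = c(20, 500),
                             nb_dispersion_range = c(0.05, 0.2),
                             n_da = 200L,
                             da_lfc = c(-2, 2),
                             sex_effect = 0,
                             batch_effect = 0,
                             depth_range = c(0.7, 1.3),
                             cut_rate = 0.5,
                             footprint_depth = 0.8,
                             footprint_ramp = 10L,
                             footprint_frac = 1,
                             footprint_motifs = "EBF1",
                             n_cells = 2000L,
                             n_genes = 1000L,
                             n_clusters = 5L,
                             origin_cluster = 1L,
                             n_markers_per_cluster = 10L,
                             marker_lfc = 2,
                             n_gradient_genes = 50L,
                             female_marker = "Xist",
                             y_genes = c("Ddx3y", "Eif2s3y", "Uty"),
                             doublet_frac = 0,
                             n_mice = 8L,
                             n_batches = 2L,
                             shift_cluster = n_clusters,
                             shift_n_genes = 50L,
                             shift_lfc = 1,
                             cell_dispersion = 0.1,
                             lib_size_range = c(2000, 6000)) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$bg_freqs) - 1) > 1e-8) stopf("bg_freqs must sum to 1")
  if (!length(cfg$motifs)) stopf("motif library must be non-empty")
  if (any(cfg$n_per_group != round(cfg$n_per_group)))
    stopf("sample sizes must be integers")
  if (length(cfg$n_per_group) != 2L || is.null(names(cfg$n_per_group)))
    stopf("n_per_group must be a named vector with two group levels")
  if (any(cfg$n_per_group < 0) || cfg$n_peaks < 0 || cfg$n_features < 0 ||
      cfg$n_cells < 0) stopf("all counts must be non-negative")
  max_mot <- max(vapply(cfg$motifs, motif_length, 0L))
  max_gap <- if (nrow(cfg$planted_pairs)) max(cfg$planted_pairs$gap_max) else 0L
  if (cfg$peak_len_range[1] < 2 * max_mot + max_gap)
    stopf("peak length (%d) too short for motif + gap placement (need >= %d)",
          cfg$peak_len_range[1], 2 * max_mot + max_gap)
  if (cfg$n_clusters < 3L) stopf("landscape needs >= 3 clusters")
  if (cfg$n_genes < cfg$n_clusters * cfg$n_markers_per_cluster +
      cfg$n_gradient_genes + 1L + length(cfg$y_genes))
    stopf("fewer genes than markers requested")
  if (cfg$footprint_depth < 0 || cfg$footprint_depth > 1)
    stopf("footprint_depth must lie in [0, 1]")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "generator_config"
  cfg
}

# Concrete motif instance: the consensus at fidelity 1 (every planted
# occurrence attains the maximal score, so recovery is exact at any
# threshold), otherwise sampled base-by-base from the PPM.
sample_motif_instance <- function(motif, fidelity = 1) {
  if (fidelity >= 1) return(motif_consensus(motif))
  paste(apply(motif$ppm, 2, function(p) sample(DNA_BASES, 1, prob = p)),
        collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x)
           paste(rev(strsplit(x, "")[[1]]), collapse = ""), ""))
}

#' Generate a synthetic peak universe with planted motif instances
#'
#' Peaks receive i.i.d. background sequence; a configured fraction carries a
#' planted instance of each single motif, and a further fraction carries an
#' A-B motif pair at a nearest-edge gap drawn from the configured range.
#' Planted instances are sampled from the motif's probability matrix and
#' written into the sequence at a recorded offset and strand.
#'
#' @param config A [generator_config()].
#' @return A list with elements `peaks` (a [peak_set()]) and `truth`
#'   (planted site, pair and footprint records).
#' @export
gen_peaks <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(derive_seed(config$seed, 101L), {
    n <- config$n_peaks
    ids <- sprintf("peak_%05d", seq_len(n))
    lens <- sample(seq(config$peak_len_range[1], config$peak_len_range[2]),
                   n, replace = TRUE)
    starts <- cumsum(c(1L, utils::head(lens, -1) + 1000L))
    seqs <- vapply(lens, function(L)
      paste(sample(DNA_BASES, L, replace = TRUE, prob = config$bg_freqs),
            collapse = ""), "")

    sites <- list(); pairs <- list()
    used <- rep(FALSE, n)

    plant <- function(seqs, peak_i, motif, offset, strand) {
      inst <- sample_motif_instance(motif, config$plant_fidelity)
      if (strand == "-") inst <- revcomp_chr(inst)
      substr(seqs[peak_i], offset + 1L, offset + nchar(inst)) <- inst
      seqs
    }

    # Pair plants first so pair peaks stay distinct from single plants.
    if (nrow(config$planted_pairs)) {
      for (r in seq_len(nrow(config$planted_pairs))) {
        pr <- config$planted_pairs[r, ]
        ma <- config$motifs[[pr$a]]; mb <- config$motifs[[pr$b]]
        if (is.null(ma) || is.null(mb)) stopf("pair motif not in library")
        n_pair <- round(pr$fraction * n)
        if (!n_pair) next
        cand <- which(!used)
        sel <- cand[sample.int(length(cand), n_pair)]
        used[sel] <- TRUE
        for (i in sel) {
          gap <- sample(seq(pr$gap_min, pr$gap_max), 1)
          la <- motif_length(ma); lb <- motif_length(mb)
          span <- la + gap + lb
          off_a <- sample.int(lens[i] - span + 1L, 1) - 1L
          off_b <- off_a + la + gap
          st <- sample(c("+", "-"), 2, replace = TRUE)
          seqs <- plant(seqs, i, ma, off_a, st[1])
          seqs <- plant(seqs, i, mb, off_b, st[2])
          sites[[length(sites) + 1L]] <- data.frame(
            peak = ids[i], motif = c(ma$name, mb$name),
            offset = c(off_a, off_b), strand = st)
          pairs[[length(pairs) + 1L]] <- data.frame(
            a = ma$name, b = mb$name, peak = ids[i], gap = gap)
        }
      }
    }

    if (length(config$planted_site_frac)) {
      for (mn in names(config$planted_site_frac)) {
        mo <- config$motifs[[mn]]
        if (is.null(mo)) stopf("motif '%s' not in library", mn)
        n_single <- round(config$planted_site_frac[[mn]] * n)
        if (!n_single) next
        cand <- which(!used)
        if (length(cand) < n_single) stopf("not enough unused peaks to plant")
        sel <- cand[sample.int(length(cand), n_single)]
        used[sel] <- TRUE
        L <- motif_length(mo)
        for (i in sel) {
          off <- sample.int(lens[i] - L + 1L, 1) - 1L
          st <- sample(c("+", "-"), 1)
          seqs <- plant(seqs, i, mo, off, st)
          sites[[length(sites) + 1L]] <- data.frame(
            peak = ids[i], motif = mo$name, offset = off, strand = st)
        }
      }
    }

    site_df <- if (length(sites)) do.call(rbind, sites) else
      data.frame(peak = character(), motif = character(),
                 offset = integer(), strand = character())
    pair_df <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(a = character(), b = character(),
                 peak = character(), gap = integer())

    has_plant <- ids %in% site_df$peak
    prob <- numeric(n)
    prob[has_plant] <- stats::runif(sum(has_plant),
                                    config$enh_prob_planted[1],
                                    config$enh_prob_planted[2])
    prob[!has_plant] <- stats::runif(sum(!has_plant),
                                     config$enh_prob_background[1],
                                     config$enh_prob_background[2])

    fp <- site_df[site_df$motif %in% config$footprint_motifs, , drop = FALSE]
    fp <- fp[seq_len(nrow(fp)) %in%
               sample(seq_len(nrow(fp)),
                      round(config$footprint_frac * nrow(fp))), ,
             drop = FALSE]

    gr <- GenomicRanges::GRanges(
      "chrS", IRanges::IRanges(start = starts, width = lens),
      name = ids, enh_prob = prob)
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- ids

    list(
      peaks = peak_set(gr, dna),
      truth = list(planted_motif_sites = site_df,
                   planted_cooccurring_pairs = pair_df,
                   planted_footprint_sites = fp,
                   seed = config$seed)
    )
  })
}

#' Generate a negative-binomial count matrix with planted group effects
#'
#' Feature-wise NB counts for a two-group design. Planted features differ
#' between groups by a recorded log2 fold change (second group level
#' relative to the first); optional per-feature additive sex and batch
#' effects act on the log2 scale. Per-sample depth factors are drawn from
#' U(0.7, 1.3) so library-size normalisation is exercised downstream.
#'
#' @param config A [generator_config()].
#' @param feature_ids Optional feature id vector (default `feat_#####`).
#' @param planted Optional data frame (`feature`, `lfc`) fixing the planted
#'   effects; by default `n_da` features are drawn with effects from the
#'   `da_lfc` grid.
#' @param seed Optional seed override (defaults to the config stream).
#' @return A list with `counts` (a [count_set()]) and `truth`
#'   (`planted_da_features` data frame).
#' @export
gen_counts <- function(config, feature_ids = NULL, planted = NULL,
                       seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) seed <- derive_seed(config$seed, 202L)
  withr::with_seed(seed, {
    groups <- names(config$n_per_group)
    n_s <- sum(config$n_per_group)
    if (any(config$n_per_group < 2)) stopf("need >= 2 samples per group")
    ids <- feature_ids %||% sprintf("feat_%05d", seq_len(config$n_features))
    G <- length(ids)
    meta <- data.frame(
      sample = sprintf("%s_rep%d",
                       rep(groups, config$n_per_group),
                       unlist(lapply(config$n_per_group, seq_len))),
      group = factor(rep(groups, config$n_per_group), levels = groups),
      sex = factor(rep_len(c("F", "M"), n_s)),
      batch = factor(rep_len(seq_len(config$n_batches), n_s))
    )

    base_mean <- exp(stats::runif(G, log(config$nb_mean_range[1]),
                                  log(config$nb_mean_range[2])))
    phi <- stats::runif(G, config$nb_dispersion_range[1],
                        config$nb_dispersion_range[2])

    lfc <- stats::setNames(numeric(G), ids)
    if (is.null(planted)) {
      n_da <- min(config$n_da, G)
      if (n_da > 0) {
        sel <- sample.int(G, n_da)
        lfc[sel] <- sample(config$da_lfc, n_da, replace = TRUE)
      }
    } else {
      lfc[planted$feature] <- planted$lfc
    }

    sex_eff <- if (config$sex_effect > 0)
      stats::rnorm(G, 0, config$sex_effect) else numeric(G)
    batch_eff <- if (config$batch_effect > 0)
      stats::rnorm(G, 0, config$batch_effect) else numeric(G)

    depth <- stats::runif(n_s, config$depth_range[1], config$depth_range[2])
    is_g2 <- as.integer(meta$group == groups[2])
    is_m <- as.integer(meta$sex == "M")
    is_b2 <- as.integer(meta$batch != levels(meta$batch)[1])

    logmu <- log2(base_mean) + outer(lfc, is_g2)
    if (config$sex_effect > 0) logmu <- logmu + outer(sex_eff, is_m)
    if (config$batch_effect > 0) logmu <- logmu + outer(batch_eff, is_b2)
    mu <- 2^logmu * rep(depth, each = G)

    counts <- matrix(0L, G, n_s, dimnames = list(ids, meta$sample))
    pois <- phi < 1e-8
    if (any(pois))
      counts[pois, ] <- stats::rpois(sum(pois) * n_s, mu[pois, ])
    if (any(!pois))
      counts[!pois, ] <- stats::rnbinom(sum(!pois) * n_s,
                                        mu = mu[!pois, ],
                                        size = 1 / phi[!pois])

    truth <- data.frame(feature = ids, lfc = lfc,
                        base_mean = base_mean, dispersion = phi)
    list(counts = count_set(counts, meta),
         truth = list(planted_da_features =
                        truth[truth$lfc != 0, c("feature", "lfc")],
                      feature_params = truth, seed = seed))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Depletion multiplier profile over a peak for one footprint site.
footprint_multiplier <- function(len, offset, motif_len, depth, ramp) {
  m <- rep(1, len)
  core <- seq(offset + 1L, offset + motif_len)
  core <- core[core >= 1 & core <= len]
  m[core] <- pmin(m[core], 1 - depth)
  if (ramp > 0) {
    for (k in seq_len(ramp)) {
      frac <- 1 - depth * (1 - k / (ramp + 1))
      for (pos in c(offset + 1L - k, offset + motif_len + k)) {
        if (pos >= 1 && pos <= len) m[pos] <- pmin(m[pos], frac)
      }
    }
  }
  m
}

#' Generate per-base Tn5 cut-count tracks
#'
#' Background cuts are Poisson-uniform within each peak. In the `"bound"`
#' condition, the expected cut rate at planted footprint sites is multiplied
#' by a trapezoidal depletion profile: full depletion of `footprint_depth`
#' over the motif core, with a linear ramp back to background over
#' `footprint_ramp` bp on each side. The `"unbound"` condition ignores the
#' planted sites (background only), emulating the knockout contrast.
#'
#' @param peaks A [peak_set()] (from [gen_peaks()]).
#' @param truth Truth record from [gen_peaks()] (for footprint site list).
#' @param config A [generator_config()].
#' @param condition `"bound"` or `"unbound"`.
#' @param seed Optional seed override.
#' @return Named list of per-base cut-count vectors, one per peak.
#' @export
gen_cut_track <- function(peaks, truth, config,
                          condition = c("bound", "unbound"), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  condition <- match.arg(condition)
  if (is.null(seed))
    seed <- derive_seed(config$seed, if (condition == "bound") 303L else 304L)
  lens <- GenomicRanges::width(peaks$ranges)
  ids <- peak_names(peaks)
  fp <- truth$planted_footprint_sites
  withr::with_seed(seed, {
    track <- lapply(seq_along(ids), function(i) {
      rate <- rep(config$cut_rate, lens[i])
      if (condition == "bound" && nrow(fp)) {
        here <- fp[fp$peak == ids[i], , drop = FALSE]
        for (r in seq_len(nrow(here))) {
          ml <- motif_length(config$motifs[[here$motif[r]]])
          rate <- rate * footprint_multiplier(
            lens[i], here$offset[r], ml,
            config$footprint_depth, config$footprint_ramp)
        }
      }
      if (config$cut_rate == 0) numeric(lens[i]) else stats::rpois(lens[i], rate)
    })
    names(track) <- ids
    track
  })
}
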