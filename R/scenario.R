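#' Default end-to-end scenario recipe
#'
#' The "ebf1-like" study scenario: peaks carrying a planted lymphoid-factor
#' motif (with a fraction also carrying a partner bZIP motif within 50 bp)
#' lose accessibility in the knockout; those peaks are enhancers annotated
#' to lymphoid signature genes and carry Tn5 footprints only in the
#' wild-type condition; a disjoint set of myeloid-gene enhancer peaks gains
#' accessibility; and the single-cell landscape carries a knockout
#' expression shift in its myeloid-most cluster.
#'
#' @param seed Master seed.
#' @return A nested list understood by [run_scenario()].
#' @export
default_recipe <- function(seed = 1L) {
  list(
    name = "ebf1-like",
    seed = as.integer(seed),
    generator = list(
      n_peaks = 2000L, peak_len_range = c(300L, 500L),
      planted_site_frac = c(EBF1 = 0.15, CTCF = 0.3),
      planted_pairs = data.frame(a = "EBF1", b = "CEBPA", fraction = 0.05,
                                 gap_min = 0L, gap_max = 50L),
      n_per_group = c(WT = 4L, KO = 4L),
      nb_mean_range = c(30, 300), nb_dispersion_range = c(0.05, 0.15),
      cut_rate = 0.5, footprint_depth = 0.8,
      n_cells = 2000L, n_genes = 1000L, n_clusters = 5L,
      origin_cluster = 1L, shift_cluster = 5L, shift_n_genes = 50L,
      shift_lfc = 1
    ),
    analysis = list(),
    da_lfc = -2,        # accessibility log2FC planted at motif-bearing peaks
    gained_lfc = 2,     # accessibility log2FC of the myeloid gained peaks
    n_gained = 150L,
    signature_lfc = 3   # reference CLP-vs-GMP expression contrast
  )
}

#' Run the full seeded scenario end to end
#'
#' Chains simulate -> differential accessibility -> motif enrichment and
#' co-occurrence -> footprint aggregation -> enhancer-anchored GSEA ->
#' landscape pseudobulk DE and DoT scoring on one seeded synthetic dataset,
#' writes every intermediate in its standard text format, and emits a
#' markdown report plus a JSON manifest with content hashes and per-stage
#' record counts. The recovery summary flags whether each planted finding
#' was detected.
#'
#' @param recipe A recipe list (see [default_recipe()]) or the path to a
#'   YAML file containing one.
#' @param out_dir Output directory.
#' @param seed Optional master-seed override.
#' @return Invisibly, a list with `manifest`, `recovery`, and the major
#'   stage results.
#' @export
run_scenario <- function(recipe = default_recipe(), out_dir = tempfile("scenario_"),
                         seed = NULL) {
  if (is.character(recipe)) recipe <- read_recipe(recipe)
  if (!is.null(seed)) recipe$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  acfg <- do.call(analysis_config, recipe$analysis %||% list())
  gen_args <- recipe$generator %||% list()
  gen_args$seed <- recipe$seed
  cfg <- do.call(generator_config, gen_args)
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- sprintf(...)
    message(sprintf("[%s] %s", stage, log[[stage]]))
  }

  ## -- simulate ----------------------------------------------------------
  pk <- gen_peaks(cfg)
  peaks <- pk$peaks
  motif_peaks <- unique(pk$truth$planted_motif_sites$peak[
    pk$truth$planted_motif_sites$motif == "EBF1"])
  other <- setdiff(peak_names(peaks), pk$truth$planted_motif_sites$peak)
  gained_peaks <- withr::with_seed(derive_seed(cfg$seed, 31L),
                                   sample(other, recipe$n_gained))
  # gained myeloid peaks are enhancers too
  pr <- S4Vectors::mcols(peaks$ranges)
  sel <- pr$name %in% gained_peaks
  pr$enh_prob[sel] <- withr::with_seed(
    derive_seed(cfg$seed, 32L), stats::runif(sum(sel), 0.85, 1))
  S4Vectors::mcols(peaks$ranges) <- pr
  planted_da <- rbind(
    data.frame(feature = motif_peaks, lfc = recipe$da_lfc),
    data.frame(feature = gained_peaks, lfc = recipe$gained_lfc))
  cfg_counts <- cfg
  cfg_counts$n_features <- length(peaks)
  cnt <- gen_counts(cfg_counts, feature_ids = peak_names(peaks),
                    planted = planted_da)
  note("simulate", "%d peaks (%d motif-bearing reduced, %d gained), %d x %d counts",
       length(peaks), length(motif_peaks), length(gained_peaks),
       nrow(cnt$counts$counts), ncol(cnt$counts$counts))
  write_peaks_bed(peaks, file.path(out_dir, "peaks.bed"))
  write_peaks_fasta(peaks, file.path(out_dir, "peaks.fa"))
  write_meme(cfg$motifs, file.path(out_dir, "motifs.meme"))
  utils::write.table(
    data.frame(feature = rownames(cnt$counts$counts), cnt$counts$counts,
               check.names = FALSE),
    file.path(out_dir, "atac_counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  ## -- differential accessibility ---------------------------------------
  da <- test_differential(cnt$counts, ~group, fdr = acfg$da_fdr)
  reduced <- da$feature[da$class == "reduced"]
  gained <- da$feature[da$class == "gained"]
  note("da", "%d reduced, %d gained at FDR<%g", length(reduced),
       length(gained), acfg$da_fdr)
  write_differential_tsv(da, file.path(out_dir, "da_results.tsv"),
                         seed = recipe$seed)

  ## -- motif enrichment & co-occurrence ---------------------------------
  if (length(reduced)) {
    target <- subset_peaks(peaks, reduced)
    control <- subset_peaks(peaks, setdiff(peak_names(peaks), reduced))
    enr <- motif_enrichment(target, control, cfg$motifs$EBF1)
  } else {
    enr <- list(odds_ratio = NA_real_, p = NA_real_, table = NULL)
  }
  hits_a <- scan_motifs(peaks, cfg$motifs$EBF1)
  hits_b <- scan_motifs(peaks, cfg$motifs$CEBPA)
  cooc <- cooccurrence_zscore(
    hits_a, hits_b, target_peaks = reduced,
    universe_peaks = peak_names(peaks),
    len_a = motif_length(cfg$motifs$EBF1),
    len_b = motif_length(cfg$motifs$CEBPA),
    max_gap = acfg$cooc_gap, n_bg = acfg$cooc_n_bg,
    seed = derive_seed(recipe$seed, 41L))
  note("cooc", "motif OR=%.1f (p=%.3g); pair z=%.2f (obs=%d, bg=%.1f)",
       enr$odds_ratio, enr$p, cooc$z, cooc$observed, cooc$bg_mean)
  utils::write.table(
    data.frame(pair = paste(cooc$pair, collapse = "-"),
               observed = cooc$observed, bg_mean = cooc$bg_mean,
               bg_sd = cooc$bg_sd, z = cooc$z, n_bg = cooc$n_bg),
    file.path(out_dir, "cooccurrence.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  ## -- footprints --------------------------------------------------------
  wt_track <- gen_cut_track(peaks, pk$truth, cfg, "bound")
  ko_track <- gen_cut_track(peaks, pk$truth, cfg, "unbound")
  fp_sites <- pk$truth$planted_footprint_sites
  if (any(fp_sites$peak %in% reduced))
    fp_sites <- fp_sites[fp_sites$peak %in% reduced, , drop = FALSE]
  ml <- motif_length(cfg$motifs$EBF1)
  sites <- data.frame(peak = fp_sites$peak,
                      center = fp_sites$offset + ml %/% 2,
                      strand = fp_sites$strand)
  w <- 100L
  prof_wt <- aggregate_cuts(wt_track, sites, w)
  prof_ko <- aggregate_cuts(ko_track, sites, w)
  ctcf_hits <- scan_motifs(peaks, cfg$motifs$CTCF)
  ctcf_sites <- data.frame(
    peak = ctcf_hits$peak,
    center = ctcf_hits$offset + motif_length(cfg$motifs$CTCF) %/% 2,
    strand = ctcf_hits$strand)
  env <- control_envelope(wt_track, ctcf_sites, n_sets = acfg$ctcf_n_sets,
                          set_size = min(200L, nrow(ctcf_sites)), w = w,
                          seed = derive_seed(recipe$seed, 42L))
  depth_wt <- footprint_depth(prof_wt, core_halfwidth = ml %/% 2)
  depth_ko <- footprint_depth(prof_ko, core_halfwidth = ml %/% 2)
  null_depths <- envelope_depths(env, core_halfwidth = ml %/% 2)
  depth_hi <- mean(null_depths) + 2 * stats::sd(null_depths)
  note("footprint", "depth WT=%.3f KO=%.3f (control %.3f +/- %.3f)",
       depth_wt, depth_ko, mean(null_depths), stats::sd(null_depths))
  utils::write.table(
    data.frame(pos = -w:w, wt = prof_wt$profile, ko = prof_ko$profile,
               control_median = env$median, control_sd = env$sd),
    file.path(out_dir, "footprint_profiles.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  write_track_bedgraph(wt_track[unique(fp_sites$peak)], peaks,
                       file.path(out_dir, "cuts_wt_footprint_peaks.bedgraph"))

  ## -- enhancer GSEA -----------------------------------------------------
  genes <- scenario_gene_table(peaks, motif_peaks, gained_peaks)
  annot <- annotate_peaks(peaks, genes, acfg$annot_upstream,
                          acfg$annot_downstream)
  enh <- enhancer_filter(peaks, acfg$enhancer_prob_min)
  da_enh <- da[da$feature %in% peak_names(enh), ]
  ranked <- build_ranked_list(da_enh, annot)
  ref_de <- scenario_reference_de(genes, recipe, cfg)
  sets <- build_signature_sets(ref_de, size = acfg$sig_set_size,
                               sig_fdr = acfg$sig_fdr,
                               sig_min_abs_lfc = acfg$sig_min_abs_lfc,
                               names = c("CLP_like", "GMP_like"))
  gsea <- lapply(sets, function(s)
    permutation_pvalue(ranked, s, n_perm = acfg$gsea_n_perm,
                       seed = derive_seed(recipe$seed, 43L)))
  note("gsea", "CLP ES=%.2f p=%.3g | GMP ES=%.2f p=%.3g",
       gsea$CLP_like$es, gsea$CLP_like$p, gsea$GMP_like$es, gsea$GMP_like$p)
  utils::write.table(
    data.frame(set = names(gsea),
               es = vapply(gsea, `[[`, 0, "es"),
               nes = vapply(gsea, `[[`, 0, "nes"),
               p = vapply(gsea, `[[`, 0, "p")),
    file.path(out_dir, "gsea_results.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  ## -- landscape ---------------------------------------------------------
  ls_sim <- gen_landscape(cfg)
  land <- ls_sim$landscape
  pb <- pseudobulk(land$counts, land$meta$cluster, land$meta$mouse,
                   unique(land$meta[c("mouse", "genotype", "sex", "batch")] |>
                            stats::setNames(c("sample", "group", "sex", "batch"))))
  shift_cl <- as.character(cfg$shift_cluster)
  pb_de <- NULL; shift_recall <- NA_real_
  if (shift_cl %in% names(pb)) {
    keep <- filter_expressed(pb[[shift_cl]], threshold = 20)
    cs <- pb[[shift_cl]]
    cs$counts <- cs$counts[keep, , drop = FALSE]
    pb_de <- test_differential(cs, ~ group + sex + batch,
                               fdr = acfg$de_fdr,
                               min_abs_lfc = acfg$de_min_abs_lfc)
    found <- pb_de$feature[pb_de$class == "gained"]
    shift_recall <- mean(ls_sim$truth$shift_genes %in% found)
  }
  if (is.null(pb_de))
    stopf("landscape stage failed: pseudobulk cluster %s lacks replication",
          shift_cl)
  de_genes <- pb_de$feature[pb_de$class != "ns"]
  origin <- land$meta$cell[land$meta$cluster == cfg$origin_cluster]
  dot <- NULL; mean_z <- NA
  if (length(de_genes)) {
    wts <- stats::setNames(pb_de$log2fc[pb_de$class != "ns"], de_genes)
    dot <- dot_score(land$lognorm, wts, origin,
                     seed = derive_seed(recipe$seed, 44L))
    mean_z <- tapply(dot$z[land$meta$cell], land$meta$cluster, mean)
  }
  note("landscape", "pseudobulk shift recall=%.2f (%d DE genes); max DoT z in cluster %s",
       shift_recall, length(de_genes),
       if (length(de_genes)) names(which.max(mean_z)) else "<none>")
  write_landscape_bundle(land, file.path(out_dir, "landscape"))
  if (!is.null(dot))
    utils::write.table(
      data.frame(cell = names(dot$raw), raw = dot$raw, z = dot$z,
                 cluster = land$meta$cluster),
      file.path(out_dir, "dot_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)

  ## -- recovery summary & report ----------------------------------------
  recovery <- list(
    reduced_peaks_motif_enriched = is.finite(enr$p) && enr$p < 0.05 &&
      enr$odds_ratio > 1,
    cooccurrence_z_gt_5 = cooc$z > 5,
    wt_specific_footprint = depth_wt > depth_hi && depth_ko <= depth_hi,
    signature_enrichment =
      gsea$CLP_like$es < 0 && gsea$CLP_like$p < 0.05 &&
      gsea$GMP_like$es > 0 && gsea$GMP_like$p < 0.05 &&
      !is.na(shift_recall) && shift_recall >= 0.8
  )
  manifest <- list(
    tool = "primingkit", version = as.character(utils::packageVersion("primingkit")),
    recipe_name = recipe$name %||% "custom", seed = recipe$seed,
    analysis_config = unclass(acfg),
    stage_log = log,
    recovery = recovery,
    outputs = as.list(file_md5(list.files(out_dir, full.names = TRUE,
                                          recursive = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_scenario_report(file.path(out_dir, "report.md"), manifest, da, enr,
                        cooc, depth_wt, depth_ko, null_depths, gsea,
                        shift_recall, mean_z)
  invisible(list(manifest = manifest, recovery = recovery, da = da,
                 enrichment = enr, cooc = cooc,
                 footprint = list(wt = depth_wt, ko = depth_ko,
                                  null = null_depths, envelope = env),
                 gsea = gsea, pseudobulk_de = pb_de, dot = dot,
                 mean_dot_z = mean_z, out_dir = out_dir))
}

# Synthetic gene catalogue: one gene per peak, TSS at the peak centre, so
# annotation is unambiguous; motif-bearing peaks get lymphoid gene ids and
# gained peaks myeloid gene ids.
scenario_gene_table <- function(peaks, motif_peaks, gained_peaks) {
  gr <- peaks$ranges
  nm <- peak_names(peaks)
  gene <- sprintf("G_%04d", seq_along(nm))
  gene[nm %in% motif_peaks] <- sprintf("Lym_%04d", which(nm %in% motif_peaks))
  gene[nm %in% gained_peaks] <- sprintf("Mye_%04d", which(nm %in% gained_peaks))
  data.frame(
    gene = gene,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = GenomicRanges::start(gr) + floor((GenomicRanges::width(gr) - 1) / 2),
    strand = rep(c("+", "-"), length.out = length(gr)))
}

# Reference two-population expression contrast (CLP-like vs GMP-like):
# lymphoid genes strongly up in population A, myeloid genes in B.
scenario_reference_de <- function(genes, recipe, cfg) {
  cfg_ref <- cfg
  cfg_ref$n_features <- nrow(genes)
  planted <- data.frame(
    feature = genes$gene[grepl("^(Lym|Mye)_", genes$gene)])
  planted$lfc <- ifelse(grepl("^Lym_", planted$feature),
                        recipe$signature_lfc, -recipe$signature_lfc)
  ref <- gen_counts(cfg_ref, feature_ids = genes$gene, planted = planted,
                    seed = derive_seed(cfg$seed, 51L))
  test_differential(ref$counts, ~group, fdr = 0.05)
}

write_scenario_report <- function(path, manifest, da, enr, cooc, depth_wt,
                                  depth_ko, null_depths, gsea, shift_recall,
                                  mean_z) {
  rec <- manifest$recovery
  lines <- c(
    sprintf("# primingkit scenario report: %s (seed %d)",
            manifest$recipe_name, manifest$seed),
    "",
    "## Differential accessibility",
    sprintf("- %d reduced / %d gained peaks at FDR < %g",
            sum(da$class == "reduced"), sum(da$class == "gained"),
            manifest$analysis_config$da_fdr),
    "",
    "## Motif analysis (reduced peaks vs reciprocal control)",
    sprintf("- enrichment odds ratio %.1f, one-sided Fisher p = %.3g",
            enr$odds_ratio, enr$p),
    sprintf("- pair co-occurrence z = %.2f (observed %d vs background %.1f +/- %.1f, %d subsamples)",
            cooc$z, cooc$observed, cooc$bg_mean, cooc$bg_sd, cooc$n_bg),
    "",
    "## Footprint contrast",
    sprintf("- depth WT = %.3f, KO = %.3f; randomized-control depths %.3f +/- %.3f",
            depth_wt, depth_ko, mean(null_depths), stats::sd(null_depths)),
    "",
    "## Enhancer-anchored GSEA",
    sprintf("- CLP-like set: ES = %.2f, NES = %.2f, p = %.3g",
            gsea$CLP_like$es, gsea$CLP_like$nes, gsea$CLP_like$p),
    sprintf("- GMP-like set: ES = %.2f, NES = %.2f, p = %.3g",
            gsea$GMP_like$es, gsea$GMP_like$nes, gsea$GMP_like$p),
    "",
    "## Landscape",
    sprintf("- pseudobulk shift-gene recall: %.2f", shift_recall),
    sprintf("- mean DoT z by cluster: %s",
            paste(sprintf("%s=%.2f", names(mean_z), mean_z), collapse = ", ")),
    "",
    "## Planted-finding recovery",
    sprintf("- [%s] reduced peaks enriched for the planted motif",
            if (rec$reduced_peaks_motif_enriched) "x" else " "),
    sprintf("- [%s] motif-pair co-occurrence z > 5",
            if (rec$cooccurrence_z_gt_5) "x" else " "),
    sprintf("- [%s] WT-specific footprint outside the control envelope",
            if (rec$wt_specific_footprint) "x" else " "),
    sprintf("- [%s] lymphoid signature on the WT side, myeloid on the KO side, with pseudobulk shift recovery",
            if (rec$signature_enrichment) "x" else " ")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a scenario recipe as YAML
#'
#' Named vectors and the planted-pair table are converted to YAML maps so
#' the file round-trips through [read_recipe()].
#'
#' @param recipe A recipe list.
#' @param path Output YAML file.
#' @export
write_recipe <- function(recipe, path) {
  g <- recipe$generator
  if (!is.null(g$planted_site_frac))
    g$planted_site_frac <- as.list(g$planted_site_frac)
  if (!is.null(g$n_per_group)) g$n_per_group <- as.list(g$n_per_group)
  if (!is.null(g$planted_pairs)) g$planted_pairs <- as.list(g$planted_pairs)
  recipe$generator <- g
  yaml::write_yaml(recipe, path)
  invisible(path)
}

#' Read a scenario recipe from YAML
#' @param path YAML recipe file.
#' @export
read_recipe <- function(path) {
  rec <- yaml::read_yaml(path)
  if (!is.null(rec$generator$planted_pairs))
    rec$generator$planted_pairs <-
      as.data.frame(lapply(rec$generator$planted_pairs, unlist))
  if (!is.null(rec$generator$planted_site_frac))
    rec$generator$planted_site_frac <- unlist(rec$generator$planted_site_frac)
  if (!is.null(rec$generator$n_per_group))
    rec$generator$n_per_group <- unlist(rec$generator$n_per_group)
  rec
}
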