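# End-to-end orchestration of the sex-stratified analysis: metric
# computation per subject, per-stratum harmonization, group statistics,
# expression processing, PLS association, clinical prediction, and
# provenance. Every stage's outputs are written before the next begins.

#' Screened multi-site cohort counts
#'
#' The screened ABIDE study cohort used as the reference cohort structure:
#' per-site male case/control counts and the overall totals by sex and
#' diagnosis. These counts are inputs to manifest arithmetic checks and to
#' scaling decisions in the generator.
#'
#' @return List with `male_by_site` (data.frame: site, group, n) and
#'   `totals` (named integer vector: male_asd, male_hc, female_asd,
#'   female_hc, total).
#' @export
abide_screened_counts <- function() {
  male_by_site <- data.frame(
    site = rep(c("PITT", "YALE", "SDSU", "NYU_I", "EMC", "CALTECH"), each = 2),
    group = rep(c("ASD", "HC"), 6),
    n = c(16L, 18L, 16L, 17L, 21L, 19L, 62L, 73L, 12L, 12L, 12L, 14L),
    stringsAsFactors = FALSE)
  totals <- c(male_asd = 139L, male_hc = 153L, female_asd = 34L,
              female_hc = 46L, total = 372L)
  list(male_by_site = male_by_site, totals = totals)
}

#' Site-balance QC of a manifest
#'
#' Chi-square screen of the sex-by-site contingency (are the sexes
#' distributed comparably across sites?). Reported, not enforced.
#'
#' @param manifest Subject manifest.
#' @return List with `table` and `p_value`.
#' @export
manifest_qc <- function(manifest) {
  tab <- table(manifest$sex, manifest$site)
  p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                error = function(e) NA_real_)
  list(table = tab, p_value = p)
}

#' Per-subject functional-activity metric, full preprocessing chain
#'
#' Applies the enforced stage order to one run: linear detrend, ALFF on
#' the unfiltered series, ideal band-pass, nuisance regression (6 motion
#' parameters + global mean + optional extra regressors), spline
#' scrubbing of high-FD frames, then ReHo or DC, z-scoring and Gaussian
#' smoothing.
#'
#' @param run A `bold_run`.
#' @param metric "ALFF", "ReHo" or "DC".
#' @param band Band edges in Hz.
#' @param dc_threshold Correlation threshold for DC.
#' @param fd_threshold Scrubbing threshold in mm.
#' @param fwhm,voxel_size Smoothing parameters (mm).
#' @param extra_regressors Optional t x k matrix (tissue stand-ins).
#' @return A z-scored, smoothed `metric_volume`.
#' @export
subject_metric <- function(run, metric = c("ALFF", "ReHo", "DC"),
                           band = c(0.01, 0.1), dc_threshold = 0.25,
                           fd_threshold = 0.5, fwhm = 8, voxel_size = 3,
                           extra_regressors = NULL) {
  metric <- match.arg(metric)
  run <- detrend_linear(run)
  if (metric == "ALFF") {
    vol <- alff(run, band[1], band[2])
  } else {
    run <- bandpass(run, band[1], band[2])
    gm <- rowMeans(run_matrix(run))
    reg <- cbind(run$motion, global_mean = gm)
    colnames(reg) <- c(paste0("motion", 1:6), "global_mean")
    if (!is.null(extra_regressors)) reg <- cbind(reg, extra_regressors)
    run <- regress_nuisance(run, reg)
    fd <- frame_displacement(run$motion, threshold = fd_threshold)
    run <- scrub_interpolate(run, fd)
    vol <- if (metric == "ReHo") reho(run)
           else degree_centrality(run, r_threshold = dc_threshold)
  }
  smooth_gaussian(zscore_volume(vol), fwhm = fwhm, voxel_size = voxel_size)
}

#' Build the subject x voxel metric matrix of a cohort
#'
#' @param bundle A `cohort_bundle`.
#' @param metric,... Passed to [subject_metric()].
#' @return An unharmonized `cohort_matrix` over in-mask voxels, plus the
#'   per-subject `metric_volume`s as attribute "volumes".
#' @export
cohort_metric_matrix <- function(bundle, metric = "ALFF", ...) {
  mask <- bundle$parcellation$mask
  vox <- which(mask)
  vols <- lapply(bundle$runs, subject_metric, metric = metric, ...)
  m <- t(vapply(vols, function(v) v$values[vox], numeric(length(vox))))
  rownames(m) <- bundle$manifest$subject_id
  cm <- cohort_matrix(m, bundle$manifest, feature_index = vox)
  attr(cm, "volumes") <- vols
  cm
}

subset_cohort_matrix <- function(cm, rows) {
  cohort_matrix(cm$values[rows, , drop = FALSE],
                cm$table[rows, , drop = FALSE],
                feature_index = cm$feature_index,
                harmonized = cm$harmonized)
}

#' Pipeline configuration
#'
#' Collects the analysis constants: the 0.01-0.1 Hz band, the DC
#' correlation threshold 0.25, the 0.5 mm scrubbing threshold, 8 mm
#' smoothing, cluster extent > 20 voxels, permutation/bootstrap counts and
#' the top-gene fraction 0.05.
#'
#' @param out_dir Output directory.
#' @param cohort Generator settings from [cohort_config()].
#' @param truth A [ground_truth()].
#' @param metrics Metrics to analyze.
#' @param sexes Strata to analyze.
#' @param band,dc_threshold,fd_threshold,fwhm,voxel_size Metric constants.
#' @param alpha,min_cluster Significance gate (FDR level, cluster extent).
#' @param n_genes,probes_per_gene,n_donors Expression generator sizes.
#' @param n_components,n_perm,n_boot,top_fraction PLS settings.
#' @param n_perm_svr SVR label permutations.
#' @param seed Master seed.
#' @return Config list.
#' @export
pipeline_config <- function(out_dir = tempfile("imgtx"),
                            cohort = cohort_config(), truth = NULL,
                            metrics = c("ALFF", "ReHo", "DC"),
                            sexes = c("M", "F"), band = c(0.01, 0.1),
                            dc_threshold = 0.25, fd_threshold = 0.5,
                            fwhm = 8, voxel_size = 3, alpha = 0.05,
                            min_cluster = 21L, n_genes = 200L,
                            probes_per_gene = 2L, n_donors = 6L,
                            n_components = 5L, n_perm = 1000L,
                            n_boot = 200L, top_fraction = 0.05,
                            n_perm_svr = 200L, seed = 1L) {
  if (!(band[1] > 0 && band[1] < band[2])) imgtx_stop("need 0 < low < high")
  if (top_fraction <= 0 || top_fraction > 0.5)
    imgtx_stop("`top_fraction` must lie in (0, 0.5]")
  cfg <- as.list(environment())
  cfg$truth <- truth %||% ground_truth(seed = seed)
  cfg
}

# Tiny FNV-1a hash over a JSON rendering of the config, for provenance.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full sex-stratified imaging-transcriptomics pipeline
#'
#' Generates (or accepts) a synthetic cohort, computes the requested
#' metrics for every subject, and per sex stratum: harmonizes sites with
#' ComBat (age and diagnosis protected), computes the case-control t-map
#' with FDR and cluster-extent control, summarizes the t-map over
#' left-hemisphere parcels, processes the synthetic probe table into an
#' expression matrix, fits the PLS association with permutation and
#' bootstrap inference, and runs clinical SVR / diagnostic SVC
#' prediction. All artifacts are written under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param bundle Optional pre-generated `cohort_bundle` (else generated
#'   from `config$cohort` and `config$truth`).
#' @return Invisible list of per-stratum, per-metric results plus paths.
#' @export
run_pipeline <- function(config = pipeline_config(), bundle = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      imgtx_stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e))))
  }
  bundle <- bundle %||% stage("simulate",
                              generate_cohort(config$cohort, config$truth))
  parc <- bundle$parcellation
  dim3 <- dim(parc$labels)
  write_manifest(bundle$manifest, file.path(config$out_dir, "manifest.tsv"))
  write_volume(parc$labels, file.path(config$out_dir, "parcellation.nii.gz"),
               config$voxel_size, integer = TRUE)
  qc <- manifest_qc(bundle$manifest)

  # probe table and expression matrix (shared across strata)
  expr <- stage("expression", {
    pt <- generate_probe_table(parc, n_genes = config$n_genes,
                               probes_per_gene = config$probes_per_gene,
                               n_donors = config$n_donors,
                               truth = config$truth)
    kept <- filter_probes(pt$probes)
    sel <- select_probe_per_gene(kept, pt$reference)
    em <- aggregate_to_parcels(sel, parc, hemisphere = "left")
    utils::write.table(
      data.frame(parcel = em$parcels, em$values, check.names = FALSE),
      file.path(config$out_dir, "expression.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(matrix = em, probe_table = pt)
  })

  results <- list()
  for (metric in config$metrics) {
    cm_all <- stage(paste0("metrics_", metric),
                    cohort_metric_matrix(bundle, metric = metric,
                                         band = config$band,
                                         dc_threshold = config$dc_threshold,
                                         fd_threshold = config$fd_threshold,
                                         fwhm = config$fwhm,
                                         voxel_size = config$voxel_size))
    vols <- attr(cm_all, "volumes")
    regional <- t(vapply(vols, function(v)
      regional_summary(v, parc), numeric(parc$n_parcels)))
    colnames(regional) <- as.character(seq_len(parc$n_parcels))
    clin <- generate_clinical_scores(bundle$manifest, regional, config$truth)

    for (sx in config$sexes) {
      key <- paste(sx, metric, sep = "_")
      rows <- which(bundle$manifest$sex == sx)
      cm <- subset_cohort_matrix(cm_all, rows)
      cm <- stage(paste0("harmonize_", key), combat(cm))
      tm <- stage(paste0("tmap_", key), two_sample_tmap(cm))
      cl <- significant_clusters(tm, dim3, alpha = config$alpha,
                                 min_size = config$min_cluster)
      prefix <- file.path(config$out_dir, key)
      write_volume(cl$t_volume, paste0(prefix, "_t.nii.gz"), config$voxel_size)
      write_volume(features_to_volume(tm$q_fdr, tm$feature_index, dim3, fill = 1),
                   paste0(prefix, "_q.nii.gz"), config$voxel_size)
      utils::write.table(cl$clusters, paste0(prefix, "_clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)

      feat <- regional_summary(cl$t_volume, parc, hemisphere = "left")
      utils::write.table(data.frame(parcel = names(feat), t_mean = feat),
                         paste0(prefix, "_feature.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)

      pls_out <- stage(paste0("pls_", key), {
        em <- expr$matrix
        keep <- intersect(as.character(em$parcels), names(feat)[!is.na(feat)])
        xm <- em$values[keep, , drop = FALSE]
        yv <- feat[keep]
        ncomp <- min(config$n_components, length(keep) - 1L)
        fit <- pls_fit(xm, yv, n_components = ncomp)
        pt <- permutation_test_variance(xm, yv, n_components = ncomp,
                                        n_perm = config$n_perm,
                                        seed = config$seed)
        # rank genes on the most significant component (ties: larger
        # explained variance); all components' p values are reported
        sig <- which(pt$p_perm == min(pt$p_perm))
        ksel <- sig[which.max(fit$explained_variance_y[sig])]
        gw <- bootstrap_gene_weights(xm, yv, component_k = ksel,
                                     n_boot = config$n_boot,
                                     seed = config$seed,
                                     top_fraction = config$top_fraction)
        wmap <- weighted_expression_map(fit$x, fit$x_weights[, ksel], parc)
        st <- spatial_similarity_test(wmap$map[keep], yv,
                                      n_perm = config$n_perm,
                                      seed = config$seed)
        jsonlite::write_json(
          list(explained_variance = fit$explained_variance_y,
               p_perm = pt$p_perm, component = ksel,
               spatial_r = st$r, p_spatial = st$p_spatial),
          paste0(prefix, "_pls.json"), auto_unbox = TRUE, digits = NA)
        utils::write.table(gw, paste0(prefix, "_genes.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        write_volume(wmap$volume, paste0(prefix, "_weighted_expression.nii.gz"),
                     config$voxel_size)
        list(fit = fit, perm = pt, genes = gw, component = ksel,
             spatial = st)
      })

      pred_out <- stage(paste0("predict_", key), {
        sig_parcels <- names(feat)[!is.na(feat)]
        # prediction features: regional means over parcels overlapping
        # retained clusters (fall back to all left parcels if none)
        hit <- unique(parc$labels[cl$labels > 0])
        hit <- as.character(hit[hit > 0])
        if (!length(hit)) hit <- sig_parcels
        fx <- regional[rows, hit, drop = FALSE]
        asd <- clin$group[rows] == "ASD"
        svr <- NULL
        sc <- clin$ADOS_TOTAL[rows]
        if (sum(!is.na(sc)) >= 10L)
          svr <- svr_loocv(fx[asd, , drop = FALSE], sc[asd],
                           clin$age[rows][asd], n_perm = config$n_perm_svr,
                           seed = config$seed)
        svc <- svc_cv10(fx, clin$group[rows], seed = config$seed)
        jsonlite::write_json(
          list(svr = if (!is.null(svr))
                 list(rmse = svr$rmse, mean = svr$mean_observed,
                      p_perm = svr$p_perm, n = svr$n_used),
               svc = list(acc = svc$acc, auc = svc$auc)),
          paste0(prefix, "_prediction.json"), auto_unbox = TRUE, digits = NA)
        list(svr = svr, svc = svc)
      })

      results[[key]] <- list(tmap = tm, clusters = cl$clusters,
                             feature = feat, pls = pls_out, pred = pred_out)
    }
  }
  prov <- list(package_version = as.character(utils::packageVersion("imgtx")),
               r_version = R.version.string, seed = config$seed,
               config_hash = config_hash(config),
               site_balance_p = qc$p_value,
               timestamp = "deterministic-output")
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, expression = expr, bundle = bundle,
                 out_dir = config$out_dir, qc = qc))
}
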