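# Synthetic multi-site cohort generator. Emulates the structure of a
# multi-site resting-state fMRI consortium release plus a donor-based
# microarray expression atlas, with known ground truth (site effects,
# group-effect regions, expression-coupled genes, clinical coupling) so
# that every downstream stage of the pipeline can be tested for parameter
# recovery without any external download.

#' Ground truth for a synthetic cohort
#'
#' Collects the injected effects a synthetic bundle carries, so tests can
#' check that downstream stages recover them.
#'
#' @param site_shift Named numeric: additive site offset (signal units),
#'   one per site.
#' @param site_scale Named numeric: multiplicative site factor (> 0).
#' @param effect_regions Integer parcel ids carrying the group effect.
#' @param effect_size Standardized mean difference (Cohen's d) of the
#'   low-frequency oscillation amplitude between groups in those regions.
#' @param coupled_genes Integer indices of genes whose regional expression
#'   tracks the effect map.
#' @param coupling_r Target Pearson correlation between coupled-gene
#'   expression and the effect map, in [-1, 1].
#' @param clinical_beta Clinical-score units per unit of regional metric.
#' @param seed Integer seed; the single RNG stream for the whole bundle is
#'   derived from it (cohort: seed, probe table: seed + 1, clinical
#'   scores: seed + 2).
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(site_shift = NULL, site_scale = NULL,
                         effect_regions = c(3L, 8L, 15L), effect_size = 1.5,
                         coupled_genes = 1:10, coupling_r = 0.9,
                         clinical_beta = 5, seed = 1L) {
  if (!is.null(site_scale) && any(site_scale <= 0))
    imgtx_stop("`site_scale` must be strictly positive")
  if (abs(coupling_r) > 1) imgtx_stop("`coupling_r` must be in [-1, 1]")
  if (seed >= 2^31 - 10) imgtx_stop("`seed` too large for 32-bit substreams")
  structure(list(site_shift = site_shift, site_scale = site_scale,
                 effect_regions = as.integer(effect_regions),
                 effect_size = effect_size,
                 coupled_genes = as.integer(coupled_genes),
                 coupling_r = coupling_r, clinical_beta = clinical_beta,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Ellipsoidal brain-like mask filling most of the grid.
ellipsoid_mask <- function(grid_shape) {
  d <- grid_shape
  ctr <- (d + 1) / 2
  ax <- pmax(d / 2 - 0.5, 1)
  x <- slice.index(array(0, d), 1); y <- slice.index(array(0, d), 2)
  z <- slice.index(array(0, d), 3)
  ((x - ctr[1]) / ax[1])^2 + ((y - ctr[2]) / ax[2])^2 +
    ((z - ctr[3]) / ax[3])^2 <= 1
}

#' Generate a contiguous random parcellation of an ellipsoidal mask
#'
#' Parcels are grown from random seed voxels by multi-source breadth-first
#' expansion under 6-connectivity, so each parcel is spatially contiguous
#' and every in-mask voxel carries exactly one label in 1..n_parcels.
#' Parcels are tagged left/right by the x-coordinate of their centroid
#' relative to the grid midline.
#'
#' @param grid_shape Three positive integers.
#' @param n_parcels Number of parcels; must not exceed the in-mask voxel
#'   count.
#' @param seed Integer RNG seed.
#' @return Object of class `parcellation` with fields `labels` (3D
#'   integer array, 0 outside the mask), `mask`, `n_parcels`, `hemisphere`
#'   (named "L"/"R" per parcel).
#' @export
generate_parcellation <- function(grid_shape, n_parcels, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L), n_parcels >= 1L)
  mask <- ellipsoid_mask(grid_shape)
  vox <- which(mask)
  if (n_parcels > length(vox))
    imgtx_stop(sprintf("n_parcels (%d) exceeds in-mask voxels (%d)",
                       n_parcels, length(vox)))
  labels <- with_seed(seed, {
    lab <- array(0L, grid_shape)
    seeds <- sample(vox, n_parcels)
    lab[seeds] <- seq_len(n_parcels)
    frontier <- seeds
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    strides <- c(1L, grid_shape[1], grid_shape[1] * grid_shape[2])
    coords <- arrayInd(vox, grid_shape)
    rownames(coords) <- as.character(vox)
    while (length(frontier)) {
      nxt <- integer(0)
      # shuffle so parcel growth order does not systematically favor ids
      frontier <- frontier[sample.int(length(frontier))]
      for (v in frontier) {
        ci <- arrayInd(v, grid_shape)[1, ]
        for (k in seq_len(6)) {
          nb <- ci + offs[k, ]
          if (any(nb < 1L) || any(nb > grid_shape)) next
          fi <- 1L + sum((nb - 1L) * strides)
          if (mask[fi] && lab[fi] == 0L) {
            lab[fi] <- lab[v]
            nxt <- c(nxt, fi)
          }
        }
      }
      frontier <- nxt
    }
    lab
  })
  mid <- (grid_shape[1] + 1) / 2
  xs <- slice.index(labels, 1)
  cx <- tapply(xs[labels > 0], labels[labels > 0], mean)
  hemi <- ifelse(cx[as.character(seq_len(n_parcels))] < mid, "L", "R")
  names(hemi) <- as.character(seq_len(n_parcels))
  structure(list(labels = labels, mask = mask, n_parcels = as.integer(n_parcels),
                 hemisphere = hemi),
            class = "parcellation")
}

#' Default generator settings for a synthetic cohort
#'
#' Defaults emulate a six-site consortium with a male-heavier case group,
#' on a 12x12x12 grid (ellipsoidal mask, ~650 voxels) with 150 frames at
#' TR = 2 s, so the 0.01-0.1 Hz band holds 28 DFT bins.
#'
#' @param sites Site names.
#' @param n_per_site Named counts per site cell: male ASD, male HC,
#'   female ASD, female HC.
#' @param grid_shape,n_parcels,t_len,tr Grid, parcel count, frames, TR (s).
#' @param noise_sd Baseline white-noise sd (signal units).
#' @param osc_freq Frequency (Hz) of the low-frequency oscillation.
#' @param amp_base,amp_sd Mean and between-subject sd of the oscillation
#'   amplitude; the group effect shifts the amplitude by
#'   `effect_size * amp_sd` in the effect regions.
#' @param reho_weight Weight of the parcel-shared band-limited signal
#'   (local-coherence ground truth).
#' @param hub_fraction,hub_weight Fraction of in-mask voxels designated as
#'   correlation hubs and the weight of the shared network signal they
#'   (and a third of all voxels, at one-third weight) receive.
#' @param n_spikes Motion spike frames per subject (FD > 0.5 mm each).
#' @param age_range Uniform age range (years).
#' @return A list of generator settings.
#' @export
cohort_config <- function(sites = c("PITT", "YALE", "SDSU", "NYU", "EMC", "CALTECH"),
                          n_per_site = c(M_ASD = 4L, M_HC = 4L, F_ASD = 2L, F_HC = 3L),
                          grid_shape = c(12L, 12L, 12L), n_parcels = 40L,
                          t_len = 150L, tr = 2, noise_sd = 1, osc_freq = 0.05,
                          amp_base = 1, amp_sd = 0.3, reho_weight = 0.6,
                          hub_fraction = 0.05, hub_weight = 1.2,
                          n_spikes = 2L, age_range = c(8, 30)) {
  list(sites = sites, n_per_site = n_per_site, grid_shape = as.integer(grid_shape),
       n_parcels = as.integer(n_parcels), t_len = as.integer(t_len), tr = tr,
       noise_sd = noise_sd, osc_freq = osc_freq, amp_base = amp_base,
       amp_sd = amp_sd, reho_weight = reho_weight, hub_fraction = hub_fraction,
       hub_weight = hub_weight, n_spikes = as.integer(n_spikes),
       age_range = age_range)
}

#' Generate a multi-site synthetic BOLD cohort with known ground truth
#'
#' Each subject's BOLD signal is built as baseline Gaussian noise plus a
#' low-frequency sinusoid whose amplitude carries the group effect in the
#' designated effect regions, plus a parcel-shared band-limited signal
#' (local coherence), plus a network signal concentrating correlations on
#' designated hub voxels. Site location/scale effects are applied to the
#' BOLD signal itself, so harmonization is exercised end to end. Motion
#' traces are smooth random walks with injected spike frames whose frame
#' displacement exceeds 0.5 mm.
#'
#' @param config Generator settings from [cohort_config()].
#' @param truth A [ground_truth()]; site effect vectors default to a fixed
#'   spread over the configured sites when not supplied.
#' @return Object of class `cohort_bundle`: `runs` (list of `bold_run`),
#'   `manifest` (data.frame), `parcellation`, `truth`.
#' @export
generate_cohort <- function(config = cohort_config(), truth = ground_truth()) {
  if (length(config$sites) < 2L) imgtx_stop("config must list at least 2 sites")
  if (config$t_len < 64L)
    imgtx_stop("t_len < 64: too few frames to resolve the 0.01-0.1 Hz band")
  if (config$tr <= 0) imgtx_stop("tr must be positive")
  ns <- length(config$sites)
  shift <- truth$site_shift %||%
    stats::setNames(seq(-2, 3, length.out = ns), config$sites)
  scale <- truth$site_scale %||%
    stats::setNames(seq(0.8, 1.6, length.out = ns), config$sites)
  if (any(scale <= 0)) imgtx_stop("site scale factors must be positive")
  truth$site_shift <- shift; truth$site_scale <- scale

  parc <- generate_parcellation(config$grid_shape, config$n_parcels,
                                seed = truth$seed)
  if (!all(truth$effect_regions %in% seq_len(parc$n_parcels)))
    imgtx_stop("effect_regions must be a subset of parcel ids")
  mask <- parc$mask
  vox <- which(mask)
  nv <- length(vox)
  nt <- config$t_len
  lab_v <- parc$labels[vox]
  effect_vox <- lab_v %in% truth$effect_regions

  cells <- expand.grid(sex = c("M", "F"), group = c("ASD", "HC"),
                       stringsAsFactors = FALSE)
  out <- with_seed(truth$seed, {
    # hub layout and per-parcel coherence signals are cohort-level
    hubs <- sample.int(nv, max(1L, round(config$hub_fraction * nv)))
    listeners <- sample.int(nv, round(nv / 3))
    tt <- seq_len(nt)
    runs <- list(); rows <- list(); si <- 0L
    for (site in config$sites) {
      for (ci in seq_len(nrow(cells))) {
        cell <- paste(cells$sex[ci], cells$group[ci], sep = "_")
        n_cell <- config$n_per_site[[cell]]
        if (is.null(n_cell) || n_cell == 0) next
        for (k in seq_len(n_cell)) {
          si <- si + 1L
          sid <- sprintf("sub%03d", si)
          age <- stats::runif(1, config$age_range[1], config$age_range[2])
          # amplitude field: base + subject jitter + group effect in regions
          amp <- rep(config$amp_base + stats::rnorm(1, 0, config$amp_sd), nv)
          if (cells$group[ci] == "ASD")
            amp[effect_vox] <- amp[effect_vox] +
              truth$effect_size * config$amp_sd
          phase <- stats::runif(1, 0, 2 * pi)
          osc <- sin(2 * pi * config$osc_freq * config$tr * tt + phase)
          x <- matrix(stats::rnorm(nt * nv, 0, config$noise_sd), nt, nv)
          x <- x + outer(osc, amp)
          # parcel-shared band-limited coherence signal
          fco <- stats::runif(parc$n_parcels, 0.02, 0.09)
          pph <- stats::runif(parc$n_parcels, 0, 2 * pi)
          pc <- sapply(seq_len(parc$n_parcels),
                       function(p) sin(2 * pi * fco[p] * config$tr * tt + pph[p]))
          x <- x + config$reho_weight * pc[, lab_v]
          # network signal: hubs strongly, a third of voxels weakly
          net <- stats::rnorm(nt)
          x[, hubs] <- x[, hubs] + config$hub_weight * net
          x[, listeners] <- x[, listeners] + (config$hub_weight / 3) * net
          # site location/scale on the BOLD signal itself
          x <- shift[[site]] + scale[[site]] * x
          # motion: smooth drift + injected spikes
          mot <- apply(matrix(stats::rnorm(nt * 6, 0,
                                           rep(c(0.01, 2e-4), each = 3 * nt)),
                              nt, 6), 2, cumsum)
          if (config$n_spikes > 0) {
            sp <- sample(3:(nt - 2), config$n_spikes)
            mot[sp, 1] <- mot[sp, 1] + 0.8
          }
          dat <- array(0, c(config$grid_shape, nt))
          nvox3 <- prod(config$grid_shape)
          dat[rep(vox, nt) + nvox3 * rep(tt - 1L, each = nv)] <- as.vector(t(x))
          run <- bold_run(dat, tr = config$tr, mask = mask, motion = mot,
                          subject_id = sid)
          runs[[sid]] <- run
          rows[[sid]] <- data.frame(
            subject_id = sid, site = site, sex = cells$sex[ci],
            group = cells$group[ci], age = age,
            mean_fd = mean(frame_displacement(mot)$fd),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(runs = runs, manifest = do.call(rbind, rows), hubs = hubs)
  })
  rownames(out$manifest) <- NULL
  structure(list(runs = out$runs, manifest = out$manifest,
                 parcellation = parc, truth = truth,
                 hub_voxels = vox[out$hubs]),
            class = "cohort_bundle")
}

#' Generate a donor-structured probe-level expression table
#'
#' Builds probe-level microarray-style data over the left-hemisphere
#' parcels of a parcellation: per-gene regional profiles (coupled genes
#' correlate with the supplied effect map at `truth$coupling_r`), multiple
#' probes per gene of which one designated probe matches an RNA-seq
#' reference best, a fixed fraction of redundant probes corrupted with
#' invalid gene ids, and a fixed fraction marked below background in more
#' than half of their samples.
#'
#' @param parcellation A `parcellation`.
#' @param n_genes Number of genes.
#' @param probes_per_gene Integer (same for every gene) or integer vector
#'   of length `n_genes`.
#' @param n_donors Number of donors; each donor samples a random ~80% of
#'   the left-hemisphere parcels.
#' @param truth A [ground_truth()] (uses `coupled_genes`, `coupling_r`,
#'   `seed + 1`).
#' @param effect_map Numeric vector indexed by left-hemisphere parcel ids
#'   (names = parcel ids) that coupled genes should track.
#' @param fraction_invalid Fraction of probes given an invalid (missing)
#'   gene id; applied to redundant probes only, so every gene keeps a
#'   valid probe.
#' @param fraction_background Fraction of probes marked above background
#'   in fewer than half of their samples (again redundant probes only).
#' @param probe_regional_sd Regional distortion sd of non-designated
#'   probes (drives the RNA-seq probe selection).
#' @param sample_noise_sd Per-sample measurement noise sd.
#' @return List with `probes` (data.frame: probe_id, gene_id, donor_id,
#'   sample_id, parcel_label, intensity, above_background), `reference`
#'   (data.frame: gene_id, parcel_label, expression), `profiles` (parcel x
#'   gene matrix of true regional profiles), `designated` (named character:
#'   best probe per gene), `gene_ids`.
#' @export
generate_probe_table <- function(parcellation, n_genes = 200L,
                                 probes_per_gene = 2L, n_donors = 6L,
                                 truth = ground_truth(), effect_map = NULL,
                                 fraction_invalid = 0.05,
                                 fraction_background = 0.2,
                                 probe_regional_sd = 0.8,
                                 sample_noise_sd = 0.1) {
  left <- as.integer(names(parcellation$hemisphere)[parcellation$hemisphere == "L"])
  if (length(left) < 3L) imgtx_stop("parcellation has fewer than 3 left parcels")
  if (is.null(effect_map)) {
    effect_map <- stats::setNames(rep(0, length(left)), left)
    effect_map[as.character(intersect(truth$effect_regions, left))] <- 1
  }
  if (!all(as.character(left) %in% names(effect_map)))
    imgtx_stop("effect_map must be indexed by every left-hemisphere parcel id")
  effect_map <- effect_map[as.character(left)]
  ppg <- if (length(probes_per_gene) == 1L) rep(as.integer(probes_per_gene), n_genes)
         else as.integer(probes_per_gene)
  stopifnot(length(ppg) == n_genes, all(ppg >= 1L))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  np <- length(left)

  with_seed(truth$seed + 1L, {
    # true regional profiles; coupled genes track the effect map
    prof <- matrix(stats::rnorm(np * n_genes), np, n_genes,
                   dimnames = list(as.character(left), gene_ids))
    em <- if (stats::sd(effect_map) > 0) as.numeric(scale(effect_map))
          else effect_map
    r <- truth$coupling_r
    for (g in truth$coupled_genes)
      if (g >= 1 && g <= n_genes)
        prof[, g] <- r * em + sqrt(max(0, 1 - r^2)) * stats::rnorm(np)

    probe_gene <- rep(seq_len(n_genes), ppg)
    n_probes <- length(probe_gene)
    probe_id <- sprintf("p%05d", seq_len(n_probes))
    designated <- probe_id[!duplicated(probe_gene)]
    names(designated) <- gene_ids
    redundant <- setdiff(seq_len(n_probes), which(!duplicated(probe_gene)))
    n_inv <- round(fraction_invalid * n_probes)
    n_bg <- round(fraction_background * n_probes)
    if (n_inv + n_bg > length(redundant))
      imgtx_stop("invalid + background fractions exceed redundant probe count")
    corrupt <- sample(redundant, n_inv + n_bg)
    invalid_set <- corrupt[seq_len(n_inv)]
    background_set <- setdiff(corrupt, invalid_set)
    # fixed regional distortion of non-designated probes
    distort <- matrix(0, np, n_probes)
    distort[, redundant] <- stats::rnorm(np * length(redundant), 0, probe_regional_sd)

    # donor sampling design: each donor covers ~80% of left parcels
    cover <- lapply(seq_len(n_donors), function(d)
      sort(sample(np, max(3L, round(0.8 * np)))))
    donor_eff <- stats::rnorm(n_donors, 0, 0.2)
    sample_rows <- do.call(rbind, lapply(seq_len(n_donors), function(d)
      data.frame(donor_id = sprintf("d%02d", d), parcel_idx = cover[[d]])))
    sample_rows$sample_id <- sprintf("s%04d", seq_len(nrow(sample_rows)))
    n_samp <- nrow(sample_rows)

    rows <- vector("list", n_probes)
    for (i in seq_len(n_probes)) {
      g <- probe_gene[i]
      base <- prof[sample_rows$parcel_idx, g] + distort[sample_rows$parcel_idx, i] +
        donor_eff[match(sample_rows$donor_id, sprintf("d%02d", seq_len(n_donors)))] +
        stats::rnorm(n_samp, 0, sample_noise_sd)
      rate <- if (i %in% background_set) 0.3 else 0.95
      n_above <- round(rate * n_samp)
      above <- rep(FALSE, n_samp)
      above[sample.int(n_samp, n_above)] <- TRUE
      rows[[i]] <- data.frame(
        probe_id = probe_id[i],
        gene_id = if (i %in% invalid_set) NA_character_ else gene_ids[g],
        donor_id = sample_rows$donor_id, sample_id = sample_rows$sample_id,
        parcel_label = left[sample_rows$parcel_idx],
        intensity = base, above_background = above,
        stringsAsFactors = FALSE)
    }
    probes <- do.call(rbind, rows)
    rownames(probes) <- NULL
    reference <- data.frame(
      gene_id = rep(gene_ids, each = np),
      parcel_label = rep(left, n_genes),
      expression = as.vector(prof), stringsAsFactors = FALSE)
    list(probes = probes, reference = reference, profiles = prof,
         designated = designated, gene_ids = gene_ids,
         invalid_probes = probe_id[invalid_set],
         background_probes = probe_id[background_set])
  })
}

#' Generate clinical scores coupled to regional functional activity
#'
#' Each score is `clinical_beta` times the subject's mean metric over the
#' effect regions, plus a linear age term, plus Gaussian noise. Scores are
#' produced for ASD rows only; control rows are left missing, as in
#' instruments administered to cases alone.
#'
#' @param manifest Subject manifest (data.frame with `subject_id`, `group`,
#'   `age`), one row per subject.
#' @param regional_metrics subjects x parcels matrix aligned with the
#'   manifest rows (column names = parcel ids).
#' @param truth A [ground_truth()] (uses `clinical_beta`, `effect_regions`,
#'   `seed + 2`).
#' @param score_names Names of the score columns to generate.
#' @param noise_sd Gaussian noise sd (score units).
#' @param beta_age Score units per year of age.
#' @return The manifest with the score columns appended.
#' @export
generate_clinical_scores <- function(manifest, regional_metrics,
                                     truth = ground_truth(),
                                     score_names = c("ADOS_TOTAL", "ADI_R_RRB"),
                                     noise_sd = 1, beta_age = 0.05) {
  stopifnot(nrow(manifest) == nrow(regional_metrics))
  cols <- intersect(as.character(truth$effect_regions), colnames(regional_metrics))
  if (!length(cols)) imgtx_stop("no effect-region columns in `regional_metrics`")
  base <- rowMeans(regional_metrics[, cols, drop = FALSE])
  with_seed(truth$seed + 2L, {
    for (nm in score_names) {
      sc <- truth$clinical_beta * base + beta_age * manifest$age +
        stats::rnorm(nrow(manifest), 0, noise_sd)
      sc[manifest$group != "ASD"] <- NA_real_
      manifest[[nm]] <- sc
    }
    manifest
  })
}
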