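# Synthetic cohort generator: determinism, parcellation geometry,
# injected site/group/coupling effects, probe-table construction counts.

small_cfg <- function(...) {
  cohort_config(sites = c("A", "B"),
                n_per_site = c(M_ASD = 3L, M_HC = 3L, F_ASD = 0L, F_HC = 0L),
                grid_shape = c(10L, 10L, 10L), n_parcels = 12L, t_len = 80L,
                ...)
}
small_truth <- function(...) {
  ground_truth(effect_regions = c(2L, 5L, 9L), coupled_genes = 1:5, seed = 7L,
               ...)
}

test_that("parcellation covers the mask with contiguous hemisphere-tagged parcels", {
  parc <- generate_parcellation(c(12, 12, 12), 40, seed = 7)
  lab <- parc$labels
  expect_true(all(lab[parc$mask] >= 1 & lab[parc$mask] <= 40))
  expect_true(all(lab[!parc$mask] == 0))
  expect_setequal(unique(lab[parc$mask]), 1:40)    # all parcels non-empty
  # contiguity: each parcel is one connected component (26-connectivity)
  for (p in sample(40, 8)) {
    comp <- imgtx:::label_components(lab == p, connectivity = 26)
    expect_equal(max(comp), 1L)
  }
  expect_setequal(unique(parc$hemisphere), c("L", "R"))
  # degenerate single parcel equals the mask
  one <- generate_parcellation(c(8, 8, 8), 1, seed = 1)
  expect_true(all((one$labels == 1) == one$mask))
  expect_error(generate_parcellation(c(8, 8, 8), 10000, seed = 1),
               "exceeds in-mask")
})

test_that("identical config and seed reproduce the cohort bundle exactly", {
  b1 <- generate_cohort(small_cfg(), small_truth())
  b2 <- generate_cohort(small_cfg(), small_truth())
  expect_identical(b1$runs[[1]]$data, b2$runs[[1]]$data)
  expect_identical(b1$manifest, b2$manifest)
  expect_identical(b1$parcellation$labels, b2$parcellation$labels)
  pt1 <- generate_probe_table(b1$parcellation, n_genes = 30, truth = small_truth())
  pt2 <- generate_probe_table(b2$parcellation, n_genes = 30, truth = small_truth())
  expect_identical(pt1$probes, pt2$probes)
})

test_that("generator rejects configurations it cannot honor", {
  cfg <- small_cfg(); cfg$t_len <- 40L
  expect_error(generate_cohort(cfg, small_truth()), "64")
  cfg2 <- small_cfg(); cfg2$sites <- "A"
  expect_error(generate_cohort(cfg2, small_truth()), "2 sites")
  expect_error(ground_truth(site_scale = c(A = -1)), "positive")
  tr <- small_truth(); tr$effect_regions <- 99L
  expect_error(generate_cohort(small_cfg(), tr), "subset")
})

test_that("site shift and scale show up in pre-harmonization metric moments", {
  tr <- small_truth(site_shift = c(A = 0, B = 5), site_scale = c(A = 1, B = 2))
  b <- generate_cohort(small_cfg(), tr)
  msk <- b$parcellation$mask
  submeans <- vapply(b$runs, function(r) mean(r$data[msk]), numeric(1))
  subsd <- vapply(b$runs, function(r) sd(as.vector(run_matrix(r))), numeric(1))
  a_rows <- b$manifest$site == "A"
  expect_equal(mean(submeans[!a_rows]) - mean(submeans[a_rows]), 5,
               tolerance = 0.5)
  expect_equal(mean(subsd[!a_rows]) / mean(subsd[a_rows]), 2, tolerance = 0.2)
})

test_that("injected motion spikes exceed the scrubbing threshold", {
  b <- generate_cohort(small_cfg(), small_truth())
  flagged <- vapply(b$runs, function(r)
    sum(frame_displacement(r$motion)$flagged), numeric(1))
  expect_true(all(flagged >= 2))   # each injected jump flags >= 1 frame
})

test_that("amplitude effect in effect regions tracks the requested Cohen's d", {
  # with d = 0 groups are exchangeable; with d = 1.5 the ALFF gap over
  # effect-region voxels approximates d in amplitude units
  cfg <- cohort_config(sites = c("A", "B"),
                       n_per_site = c(M_ASD = 10L, M_HC = 10L, F_ASD = 0L, F_HC = 0L),
                       grid_shape = c(10L, 10L, 10L), n_parcels = 12L, t_len = 96L)
  tr <- small_truth(site_shift = c(A = 0, B = 0), site_scale = c(A = 1, B = 1))
  b <- generate_cohort(cfg, tr)
  vox <- which(b$parcellation$labels %in% tr$effect_regions)
  av <- t(vapply(b$runs, function(r) {
    r <- detrend_linear(r); alff(r)$values[vox]
  }, numeric(length(vox))))
  asd <- b$manifest$group == "ASD"
  d <- (colMeans(av[asd, ]) - colMeans(av[!asd, ])) /
    sqrt((apply(av[asd, ], 2, var) + apply(av[!asd, ], 2, var)) / 2)
  expect_gt(mean(d), 0.8)   # strong positive standardized effect
})

test_that("probe table honors exact corruption counts and coupling", {
  parc <- generate_parcellation(c(12, 12, 12), 40, seed = 3)
  tr <- ground_truth(effect_regions = c(3L, 8L, 15L), coupled_genes = 1:10,
                     coupling_r = 0.9, seed = 11)
  pt <- generate_probe_table(parc, n_genes = 100, probes_per_gene = 2,
                             n_donors = 6, truth = tr,
                             fraction_invalid = 0.1)
  expect_equal(length(pt$invalid_probes), 20L)     # exactly 10% of 200
  expect_true(all(is.na(pt$probes$gene_id[pt$probes$probe_id %in% pt$invalid_probes])))
  # single probe per gene: probe selection is the identity
  pt1 <- generate_probe_table(parc, n_genes = 20, probes_per_gene = 1,
                              truth = tr, fraction_invalid = 0,
                              fraction_background = 0)
  kept <- filter_probes(pt1$probes)
  sel <- select_probe_per_gene(kept, pt1$reference)
  expect_setequal(unique(sel$probe_id), unique(pt1$probes$probe_id))
  # coupled genes correlate with the effect map at the requested level
  left <- names(parc$hemisphere)[parc$hemisphere == "L"]
  em <- setNames(rep(0, length(left)), left)
  em[as.character(intersect(tr$effect_regions, as.integer(left)))] <- 1
  if (sd(em) > 0) {
    cors <- vapply(tr$coupled_genes, function(g)
      cor(pt$profiles[, g], em[rownames(pt$profiles)]), numeric(1))
    expect_equal(mean(cors), 0.9, tolerance = 0.1)
  }
})

test_that("clinical scores follow the linear model and stay ASD-only", {
  b <- generate_cohort(small_cfg(), small_truth())
  reg <- matrix(rnorm(nrow(b$manifest) * 12), ncol = 12,
                dimnames = list(NULL, as.character(1:12)))
  tr <- small_truth()
  clin <- generate_clinical_scores(b$manifest, reg, tr, noise_sd = 0)
  expect_true(all(is.na(clin$ADOS_TOTAL[clin$group == "HC"])))
  asd <- clin$group == "ASD"
  base <- rowMeans(reg[, as.character(tr$effect_regions)])
  expect_equal(clin$ADOS_TOTAL[asd],
               (tr$clinical_beta * base + 0.05 * clin$age)[asd],
               tolerance = 1e-10)
  clin2 <- generate_clinical_scores(b$manifest, reg, tr, noise_sd = 0)
  expect_identical(clin, clin2)   # seeded determinism
})
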