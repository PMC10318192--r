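# Preprocessing stages and the three functional-activity metrics, each
# checked against closed forms or independent brute-force oracles.

simple_run <- function(m, tr = 2, steps = c("detrend", "bandpass")) {
  # t x V matrix packed into a (V,1,1) grid
  v <- ncol(m)
  dat <- array(0, c(v, 1, 1, nrow(m)))
  dat[, 1, 1, ] <- t(m)
  run <- bold_run(dat, tr = tr, mask = array(TRUE, c(v, 1, 1)))
  attr(run, "steps") <- steps
  run
}

test_that("frame displacement matches the translation + 50 mm rotation formula", {
  mot <- matrix(0, 5, 6)
  expect_equal(frame_displacement(mot)$fd, rep(0, 5))
  mot2 <- matrix(0, 3, 6)
  mot2[2, 1:3] <- 0.1
  mot2[2, 4:6] <- 0.001
  fd <- frame_displacement(mot2)
  expect_equal(fd$fd[2], 0.45)          # 3*0.1 + 50*3*0.001
  expect_equal(fd$fd[1], 0)
  # a single 0.6 mm jump flags exactly the frames whose delta exceeds 0.5
  mot3 <- matrix(0, 6, 6); mot3[4, 1] <- 0.6
  fd3 <- frame_displacement(mot3, threshold = 0.5)
  expect_equal(which(fd3$flagged), c(4L, 5L))  # jump up then back down
  expect_error(frame_displacement(matrix(c(NA, rep(0, 11)), 2, 6)), "finite")
})

test_that("spline scrubbing reproduces cubics and clamps at the support edge", {
  tt <- 1:30
  cub <- 0.01 * tt^3 - 0.2 * tt^2 + tt + 3
  m <- cbind(cub, cub)
  run <- simple_run(m)
  fd <- structure(list(fd = rep(0, 30), threshold = 0.5,
                       flagged = rep(FALSE, 30)), class = "fd_series")
  expect_identical(scrub_interpolate(run, fd)$data, run$data)
  fd$flagged[15] <- TRUE
  out <- scrub_interpolate(run, fd)
  expect_equal(out$data[1, 1, 1, 15], cub[15], tolerance = 1e-8)
  expect_equal(out$data[1, 1, 1, -15], run$data[1, 1, 1, -15])
  # flagged first frame: nearest-support value
  fd2 <- fd; fd2$flagged[] <- FALSE; fd2$flagged[1] <- TRUE
  out2 <- scrub_interpolate(run, fd2)
  expect_equal(out2$data[1, 1, 1, 1], cub[2])
  # too few support frames
  fd3 <- fd; fd3$flagged <- rep(TRUE, 30); fd3$flagged[1:3] <- FALSE
  expect_error(scrub_interpolate(run, fd3), class = "imgtx_unrecoverable_run")
})

test_that("linear detrending removes lines exactly and leaves residuals orthogonal", {
  tt <- 1:50
  line <- 2 + 0.3 * tt
  sine <- sin(2 * pi * tt / 10)
  set.seed(3)
  noise <- rnorm(50)
  run <- simple_run(cbind(line, line + sine, noise), steps = character())
  out <- detrend_linear(run)
  m <- run_matrix(out)
  expect_equal(max(abs(m[, 1])), 0, tolerance = 1e-8)
  # sine recovered up to its own projection on [1, t]
  pr <- lm(sine ~ tt)$residuals
  expect_equal(m[, 2], unname(pr), tolerance = 1e-8)
  expect_lt(abs(sum(m[, 3] * tt)), 1e-8)
  expect_lt(abs(sum(m[, 3])), 1e-8)
  expect_error(detrend_linear(simple_run(matrix(1:2, 2, 1), steps = character())),
               "3 frames")
})

test_that("nuisance regression equals lm residuals and reports collinear columns", {
  set.seed(4)
  tt <- 60
  reg <- cbind(a = rnorm(tt), b = rnorm(tt))
  y <- cbind(rnorm(tt), reg[, 1] * 2 + 1)
  run <- simple_run(y, steps = c("detrend", "bandpass"))
  out <- run_matrix(regress_nuisance(run, reg))
  expect_equal(out[, 1], unname(lm(y[, 1] ~ reg)$residuals), tolerance = 1e-8)
  expect_equal(max(abs(out[, 2])), 0, tolerance = 1e-8)   # voxel equal to regressor
  # intercept only: mean centering
  cen <- run_matrix(regress_nuisance(run, matrix(numeric(0), tt, 0)))
  expect_equal(cen[, 1], unname(y[, 1] - mean(y[, 1])), tolerance = 1e-10)
  dup <- cbind(a = reg[, 1], b = reg[, 1])
  expect_error(regress_nuisance(run, dup), "collinear")
})

test_that("ideal band-pass keeps in-band tones, kills out-of-band and DC", {
  tt <- 1:200; tr <- 2
  f_in <- 0.05; f_out <- 0.2
  s_in <- sin(2 * pi * f_in * tr * tt)
  s_out <- sin(2 * pi * f_out * tr * tt)
  run <- simple_run(cbind(s_in, s_out, rep(3, 200)), tr = tr,
                    steps = "detrend")
  out <- run_matrix(bandpass(run))
  expect_equal(sd(out[, 1]), sd(s_in), tolerance = 0.01)
  expect_lt(sqrt(mean(out[, 2]^2)), 0.01 * sqrt(mean(s_out^2)))
  expect_equal(max(abs(out[, 3])), 0, tolerance = 1e-10)
  expect_error(bandpass(run, 0.01, 0.3), "Nyquist")
})

test_that("ALFF equals amplitude / n_band_bins for a pure in-band tone", {
  t_len <- 200; tr <- 2
  # bin 12 -> f = 12/400 = 0.03 Hz, inside the band
  amp <- 1.7
  s <- amp * sin(2 * pi * 12 * (0:(t_len - 1)) / t_len)
  run <- simple_run(cbind(s, rep(0, t_len)), tr = tr, steps = "detrend")
  vol <- alff(run)
  f <- (1:(t_len / 2)) / (t_len * tr)
  n_bins <- sum(f >= 0.01 & f <= 0.1)
  expect_equal(vol$values[1, 1, 1], amp / n_bins, tolerance = 0.01)
  expect_equal(vol$values[2, 1, 1], 0)
  short <- simple_run(cbind(rnorm(10)), tr = 0.1, steps = "detrend")
  expect_error(alff(short), "no DFT bin")
})

test_that("ALFF/ReHo/DC match independent brute-force oracles on random runs", {
  for (seed in 1:6) {
    run <- make_test_run(n_mask = 30L, t_len = 80L, seed = seed)
    run_a <- run; attr(run_a, "steps") <- "detrend"
    a <- alff(run_a)$values
    ora <- array(0, dim(run$mask))
    m <- run_matrix(run)
    vox <- which(run$mask)
    for (i in seq_along(vox))
      ora[vox[i]] <- oracle_alff_series(m[, i], run$tr, 0.01, 0.1)
    expect_equal(a, ora, tolerance = 1e-10)
    expect_equal(reho(run)$values, oracle_reho(run), tolerance = 1e-10)
    expect_equal(degree_centrality(run)$values, oracle_dc(run),
                 tolerance = 1e-10)
  }
})

test_that("ReHo analytic cases: perfect concordance, anti-monotone pair, ties", {
  # 27 identical series in a full 3x3x3 mask -> W = 1 at the center
  s <- rnorm(40)
  dat <- array(rep(s, each = 27), c(3, 3, 3, 40))
  run <- bold_run(dat, tr = 2)
  attr(run, "steps") <- c("detrend", "bandpass")
  expect_equal(reho(run)$values[2, 2, 2], 1, tolerance = 1e-12)
  # two exactly anti-monotone series -> W = 0
  m2 <- cbind(1:20, 20:1)
  expect_equal(oracle_kendall_w(m2), 0)
  dat2 <- array(0, c(2, 1, 1, 20)); dat2[1, 1, 1, ] <- 1:20; dat2[2, 1, 1, ] <- 20:1
  run2 <- bold_run(dat2, tr = 2)
  attr(run2, "steps") <- c("detrend", "bandpass")
  expect_equal(max(abs(reho(run2)$values)), 0, tolerance = 1e-12)
  # tied values handled by midranks, identical to the direct formula
  set.seed(9)
  run3 <- make_test_run(n_mask = 15L, t_len = 40L, seed = 11)
  m3 <- run_matrix(run3)
  m3 <- round(m3, 1)   # force ties
  run3 <- imgtx:::run_with_matrix(run3, m3)
  expect_equal(reho(run3)$values, oracle_reho(run3), tolerance = 1e-12)
})

test_that("DC on constructed correlations averages only suprathreshold neighbors", {
  # one-factor structure r_jk = r_1j * r_1k keeps the matrix PSD
  r1 <- c(1, 0.9, 0.3, 0.1, -0.5)
  r <- outer(r1, r1); diag(r) <- 1
  m <- make_series_with_cor(r, t_len = 60, seed = 2)
  expect_equal(cor(m)[1, 2:5], c(0.9, 0.3, 0.1, -0.5), tolerance = 1e-10)
  dat <- array(0, c(5, 1, 1, 60)); dat[, 1, 1, ] <- t(m)
  run <- bold_run(dat, tr = 2)
  attr(run, "steps") <- c("detrend", "bandpass")
  dc <- degree_centrality(run)$values
  expect_equal(dc[1, 1, 1], mean(c(0.9, 0.3)), tolerance = 1e-10)
  # one shared series everywhere -> DC = 1
  dat2 <- array(rep(rnorm(50), each = 8), c(2, 2, 2, 50))
  run2 <- bold_run(dat2, tr = 2)
  attr(run2, "steps") <- c("detrend", "bandpass")
  expect_equal(unname(degree_centrality(run2)$values[1, 1, 1]), 1,
               tolerance = 1e-12)
})

test_that("metric maps transform correctly under per-series rescaling", {
  run <- make_test_run(n_mask = 25L, t_len = 60L, seed = 21)
  m <- run_matrix(run)
  run2 <- imgtx:::run_with_matrix(run, 3.5 * m + 2)
  run_a1 <- run; attr(run_a1, "steps") <- "detrend"
  run_a2 <- run2; attr(run_a2, "steps") <- "detrend"
  # ReHo and DC invariant under positive affine maps; ALFF scales linearly
  expect_equal(reho(run2)$values, reho(run)$values, tolerance = 1e-10)
  expect_equal(degree_centrality(run2)$values, degree_centrality(run)$values,
               tolerance = 1e-10)
  a1 <- alff(run_a1)$values; a2 <- alff(run_a2)$values
  vox <- which(run$mask)
  # the additive constant only moves DC (excluded from the band)
  expect_equal(a2[vox], 3.5 * a1[vox], tolerance = 1e-8)
})

test_that("z-scoring and mask-renormalized smoothing behave as documented", {
  run <- make_test_run(n_mask = 30L, seed = 31, steps = "detrend")
  vol <- alff(run)
  z <- zscore_volume(vol)
  expect_equal(mean(z$values[z$mask]), 0, tolerance = 1e-10)
  expect_equal(sd(z$values[z$mask]), 1, tolerance = 1e-10)
  const <- vol; const$values[const$mask] <- 2
  expect_error(zscore_volume(const), "constant")
  # mass conservation: smoothing a delta keeps total in-mask mass 1
  delta <- vol; delta$values[] <- 0
  delta$values[which(delta$mask)[5]] <- 1
  sm <- smooth_gaussian(delta, fwhm = 8, voxel_size = 3)
  expect_gt(sum(sm$values[sm$mask] > 0), 1)   # mass spread out
  # constant map is a fixed point of mask-renormalized smoothing
  const2 <- vol; const2$values[const2$mask] <- 3.3
  smc <- smooth_gaussian(const2)
  expect_equal(smc$values[smc$mask], rep(3.3, sum(smc$mask)), tolerance = 1e-8)
})

test_that("stage-order contract warns on out-of-order metric calls", {
  run <- make_test_run(seed = 41, steps = character())
  expect_warning(alff(run), "detrend")
  run2 <- make_test_run(seed = 41, steps = c("detrend", "bandpass"))
  expect_warning(alff(run2), "before")
  expect_warning(reho(make_test_run(seed = 41, steps = "detrend")), "bandpass")
})
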