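# Voxelwise functional-activity metrics and the temporal preprocessing
# stages that feed them. All operations work on a `bold_run`: a masked 4D
# time series with repetition time and motion parameters. The enforced
# stage order mirrors standard resting-state practice: linear detrend ->
# ALFF (on unfiltered data) -> band-pass -> nuisance regression / motion
# scrubbing -> ReHo / degree centrality -> z-score -> spatial smoothing.

#' Construct a BOLD run
#'
#' Bundles a 4D BOLD array with its repetition time, analysis mask and
#' 6-parameter rigid-body motion trace.
#'
#' @param data 4D numeric array (x, y, z, t), arbitrary signal units.
#' @param tr Repetition time in seconds (> 0).
#' @param mask 3D logical array; defaults to all voxels in-mask. Values
#'   outside the mask are ignored by every metric.
#' @param motion t x 6 numeric matrix: three translations (mm) followed by
#'   three rotations (radians). Defaults to zero motion.
#' @param subject_id Subject identifier string.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr, mask = NULL, motion = NULL,
                     subject_id = "subject") {
  if (length(dim(data)) != 4L)
    imgtx_stop("`data` must be a 4D array (x, y, z, t)")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    imgtx_stop("`tr` must be a single positive number (seconds)")
  nt <- dim(data)[4L]
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  if (!identical(dim(mask), dim(data)[1:3]))
    imgtx_stop("`mask` dimensions must match the spatial grid of `data`")
  mask <- array(as.logical(mask), dim(mask))
  if (is.null(motion)) motion <- matrix(0, nt, 6L)
  motion <- as.matrix(motion)
  if (nrow(motion) != nt || ncol(motion) != 6L)
    imgtx_stop(sprintf("`motion` must be a %d x 6 matrix", nt))
  vox <- run_matrix_idx(mask)
  if (any(!is.finite(data[vox$flat4(nt)])))
    imgtx_stop("`data` contains non-finite values inside the mask")
  structure(list(data = data, tr = tr, mask = mask, motion = motion,
                 subject_id = subject_id),
            steps = character(), class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %s: %dx%dx%d grid, %d frames, TR=%gs, %d in-mask voxels\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  steps <- attr(x, "steps")
  if (length(steps)) cat("  steps applied:", paste(steps, collapse = " -> "), "\n")
  invisible(x)
}

# In-mask voxel bookkeeping: linear indices into the 3D grid, plus a
# closure producing the 4D flat indices for all frames.
run_matrix_idx <- function(mask) {
  idx3 <- which(mask)
  nvox3 <- prod(dim(mask))
  list(idx3 = idx3,
       flat4 = function(nt) rep(idx3, nt) + nvox3 * rep(seq_len(nt) - 1L, each = length(idx3)))
}

#' Extract the in-mask time-by-voxel matrix of a run
#' @param run A `bold_run`.
#' @return t x V numeric matrix, V = number of in-mask voxels in column
#'   order of `which(mask)`.
#' @export
run_matrix <- function(run) {
  vox <- run_matrix_idx(run$mask)
  nt <- dim(run$data)[4L]
  matrix(run$data[vox$flat4(nt)], nrow = nt, ncol = length(vox$idx3), byrow = TRUE)
}

# Write a t x V matrix back into a run, preserving out-of-mask values.
run_with_matrix <- function(run, m, step = NULL) {
  vox <- run_matrix_idx(run$mask)
  nt <- dim(run$data)[4L]
  run$data[vox$flat4(nt)] <- as.vector(t(m))
  if (!is.null(step)) attr(run, "steps") <- c(attr(run, "steps"), step)
  run
}

run_steps <- function(run) attr(run, "steps") %||% character()

# Contract check on the pipeline stage order; violations warn, they do not
# stop, so exploratory use off the beaten path stays possible.
check_step_order <- function(run, op, requires = character(), forbids = character()) {
  steps <- run_steps(run)
  miss <- setdiff(requires, steps)
  if (length(miss))
    warning(sprintf("%s() expects earlier stage(s) %s; applied so far: %s",
                    op, paste(miss, collapse = ", "),
                    if (length(steps)) paste(steps, collapse = " -> ") else "none"),
            call. = FALSE)
  bad <- intersect(forbids, steps)
  if (length(bad))
    warning(sprintf("%s() should run before stage(s) %s", op,
                    paste(bad, collapse = ", ")), call. = FALSE)
  invisible(NULL)
}

#' Construct a metric volume
#'
#' @param metric One of "ALFF", "ReHo", "DC".
#' @param values 3D numeric array, zero outside the mask.
#' @param mask 3D logical array.
#' @param z_scored Has the in-mask distribution been z-transformed?
#' @param smoothed_fwhm Gaussian FWHM in mm if smoothed, else `NULL`.
#' @param subject_id Subject identifier.
#' @return Object of class `metric_volume`.
#' @export
metric_volume <- function(metric, values, mask, z_scored = FALSE,
                          smoothed_fwhm = NULL, subject_id = "subject") {
  stopifnot(identical(dim(values), dim(mask)))
  values[!mask] <- 0
  structure(list(metric = metric, values = values, mask = mask,
                 z_scored = z_scored, smoothed_fwhm = smoothed_fwhm,
                 subject_id = subject_id),
            class = "metric_volume")
}

#' @export
print.metric_volume <- function(x, ...) {
  cat(sprintf("<metric_volume> %s (%s): %s grid, %d in-mask voxels%s%s\n",
              x$metric, x$subject_id, paste(dim(x$values), collapse = "x"),
              sum(x$mask), if (x$z_scored) ", z-scored" else "",
              if (!is.null(x$smoothed_fwhm))
                sprintf(", smoothed %g mm" , x$smoothed_fwhm) else ""))
  invisible(x)
}

#' Power-style frame displacement from rigid-body motion parameters
#'
#' FD at frame t (t >= 2) is the sum of absolute backward differences of
#' the three translations plus `head_radius` times the sum of absolute
#' rotation differences (small-angle arc length on a sphere of that
#' radius). The first frame has FD 0 by convention.
#'
#' @param motion t x 6 matrix: translations (mm) then rotations (radians).
#' @param head_radius Sphere radius in mm used to convert rotations to
#'   displacements; 50 mm is the common convention.
#' @param threshold Flagging threshold in mm; frames with FD strictly above
#'   it are marked for scrubbing.
#' @return Object of class `fd_series` with fields `fd`, `threshold`,
#'   `flagged`.
#' @export
frame_displacement <- function(motion, head_radius = 50, threshold = 0.5) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) imgtx_stop("`motion` must have 6 columns")
  if (any(!is.finite(motion))) imgtx_stop("`motion` contains non-finite values")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               head_radius * rowSums(d[, 4:6, drop = FALSE]))
  structure(list(fd = fd, threshold = threshold, flagged = fd > threshold),
            class = "fd_series")
}

#' Scrub high-motion frames by natural cubic-spline interpolation
#'
#' Frames flagged in `fd` are replaced, per voxel, by a natural cubic
#' spline fitted through the unflagged frames. Flagged frames outside the
#' support of the unflagged frames (a flagged first or last frame) take
#' the value of the nearest unflagged frame rather than extrapolating the
#' spline.
#'
#' @param run A `bold_run`.
#' @param fd An `fd_series` for the same run.
#' @return The scrubbed `bold_run`.
#' @export
scrub_interpolate <- function(run, fd) {
  stopifnot(inherits(run, "bold_run"), inherits(fd, "fd_series"))
  nt <- dim(run$data)[4L]
  if (length(fd$fd) != nt) imgtx_stop("`fd` length does not match run frames")
  flagged <- fd$flagged
  if (!any(flagged)) {
    attr(run, "steps") <- c(run_steps(run), "scrub")
    return(run)
  }
  keep <- which(!flagged)
  if (length(keep) < 4L)
    imgtx_stop("fewer than 4 unflagged frames: run is unrecoverable",
               class = "imgtx_unrecoverable_run")
  bad <- which(flagged)
  # clamp out-of-support frames to the nearest retained frame
  eval_at <- pmin(pmax(bad, min(keep)), max(keep))
  m <- run_matrix(run)
  for (v in seq_len(ncol(m))) {
    sf <- stats::splinefun(keep, m[keep, v], method = "natural")
    m[bad, v] <- sf(eval_at)
  }
  run_with_matrix(run, m, step = "scrub")
}

#' Remove the per-voxel linear trend
#'
#' Least-squares removal of an intercept and linear term in frame index;
#' residuals are orthogonal to both.
#'
#' @param run A `bold_run` with at least 3 frames.
#' @return Detrended `bold_run`.
#' @export
detrend_linear <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  nt <- dim(run$data)[4L]
  if (nt < 3L) imgtx_stop("detrending needs at least 3 frames")
  m <- run_matrix(run)
  x <- cbind(1, seq_len(nt))
  m <- m - x %*% solve(crossprod(x), crossprod(x, m))
  run_with_matrix(run, m, step = "detrend")
}

#' Regress nuisance signals from a run
#'
#' Voxelwise OLS residualization against the supplied regressors plus an
#' intercept (motion parameters, global mean, tissue signals, ...).
#'
#' @param run A `bold_run`.
#' @param regressors t x k numeric matrix; column names are used in rank
#'   diagnostics.
#' @return Residualized `bold_run`.
#' @export
regress_nuisance <- function(run, regressors) {
  stopifnot(inherits(run, "bold_run"))
  regressors <- as.matrix(regressors)
  nt <- dim(run$data)[4L]
  if (nrow(regressors) != nt) imgtx_stop("regressor rows must equal run frames")
  if (ncol(regressors) >= nt) imgtx_stop("more regressors than frames")
  if (any(!is.finite(regressors))) imgtx_stop("regressors contain non-finite values")
  x <- cbind(intercept = 1, regressors)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    nm <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
    bad <- nm[qx$pivot[(qx$rank + 1L):ncol(x)]]
    imgtx_stop(sprintf("nuisance design is rank deficient; collinear column(s): %s",
                       paste(bad, collapse = ", ")))
  }
  m <- run_matrix(run)
  m <- m - x %*% solve(crossprod(x), crossprod(x, m))
  run_with_matrix(run, m, step = "nuisance")
}

# DFT bin frequencies for a length-nt series sampled every tr seconds.
dft_freqs <- function(nt, tr) {
  j <- seq_len(nt) - 1L
  pmin(j, nt - j) / (nt * tr)
}

#' Ideal band-pass filter in the DFT domain
#'
#' Fourier coefficients with frequency inside `[low, high]` are retained
#' exactly; all others, including the DC component, are zeroed. Exact band
#' edges and zero phase distortion by construction.
#'
#' @param run A `bold_run`.
#' @param low,high Band edges in Hz; `high` must be below Nyquist
#'   (1 / (2 tr)).
#' @return Filtered `bold_run`.
#' @export
bandpass <- function(run, low = 0.01, high = 0.1) {
  stopifnot(inherits(run, "bold_run"))
  if (!(low < high)) imgtx_stop("`low` must be below `high`")
  nyq <- 1 / (2 * run$tr)
  if (high >= nyq)
    imgtx_stop(sprintf("`high` (%g Hz) must be below Nyquist (%g Hz)", high, nyq))
  check_step_order(run, "bandpass", requires = "detrend")
  m <- run_matrix(run)
  nt <- nrow(m)
  f <- dft_freqs(nt, run$tr)
  keep <- f >= low & f <= high
  fm <- stats::mvfft(m)
  fm[!keep, ] <- 0
  m <- Re(stats::mvfft(fm, inverse = TRUE)) / nt
  run_with_matrix(run, m, step = "bandpass")
}

#' Amplitude of low-frequency fluctuation (ALFF)
#'
#' Per voxel, the mean of the single-sided DFT amplitude spectrum over the
#' bins with frequency in `[low, high]`. Computed on detrended but
#' unfiltered data, upstream of the band-pass stage, so the in-band signal
#' is measured intact. The mean (rather than the sum) over in-band bins
#' makes the raw value independent of run length.
#'
#' @param run A detrended `bold_run`.
#' @param low,high Band edges in Hz.
#' @return A `metric_volume` of metric "ALFF".
#' @export
alff <- function(run, low = 0.01, high = 0.1) {
  stopifnot(inherits(run, "bold_run"))
  check_step_order(run, "alff", requires = "detrend", forbids = "bandpass")
  m <- run_matrix(run)
  nt <- nrow(m)
  j <- seq_len(floor(nt / 2))            # positive-frequency bins
  f <- j / (nt * run$tr)
  band <- which(f >= low & f <= high)
  if (!length(band))
    imgtx_stop(sprintf("no DFT bin inside [%g, %g] Hz at T=%d, TR=%g",
                       low, high, nt, run$tr))
  fm <- stats::mvfft(m)
  scale <- ifelse(j[band] == nt / 2, 1, 2)   # no doubling at Nyquist
  amp <- (scale / nt) * Mod(fm[1L + j[band], , drop = FALSE])
  vals <- array(0, dim(run$mask))
  vals[run$mask] <- colMeans(amp)
  metric_volume("ALFF", vals, run$mask, subject_id = run$subject_id)
}

# Neighborhood offset tables: 7 = faces, 19 = faces + edges, 27 = full cube.
neighborhood_offsets <- function(neighborhood) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(neighborhood),
                 "7"  = d <= 1,
                 "19" = d <= 2,
                 "27" = rep(TRUE, nrow(g)),
                 imgtx_stop("`neighborhood` must be 7, 19 or 27"))
  as.matrix(g[keep, , drop = FALSE])
}

# Shift a 3D array by an integer offset, zero-filling the vacated border.
shift3d <- function(a, off) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) { dst[[k]] <- (1 + o):d[k]; src[[k]] <- 1:(d[k] - o) }
    else        { dst[[k]] <- 1:(d[k] + o); src[[k]] <- (1 - o):d[k] }
    if (abs(o) >= d[k]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Regional homogeneity (ReHo): Kendall's coefficient of concordance
#'
#' For each in-mask voxel, Kendall's W over the ranked time series of the
#' voxel and its in-mask neighbors (26-neighborhood by default):
#' \deqn{W = 12 \sum_t (R_t - \bar R)^2 / (K^2 (n^3 - n))}
#' where R_t is the rank sum across the K series at frame t and n the
#' number of frames. Ties take midranks; no tie correction is applied to
#' the denominator. At mask edges the neighborhood shrinks to the
#' available in-mask voxels, with K adjusted accordingly.
#'
#' @param run A band-passed `bold_run` with at least 3 frames.
#' @param neighborhood Cluster size including the center: 7, 19 or 27.
#' @return A `metric_volume` of metric "ReHo".
#' @export
reho <- function(run, neighborhood = 27) {
  stopifnot(inherits(run, "bold_run"))
  nt <- dim(run$data)[4L]
  if (nt < 3L) imgtx_stop("ReHo needs at least 3 frames")
  check_step_order(run, "reho", requires = "bandpass")
  offs <- neighborhood_offsets(neighborhood)
  m <- run_matrix(run)                      # t x V
  ranks <- apply(m, 2L, rank)               # midranks per voxel series
  d3 <- dim(run$mask)
  maskind <- array(0, d3); maskind[run$mask] <- 1
  # rank arrays per frame stacked as a 4D array for shifting
  rk4 <- array(0, c(d3, nt))
  vox <- which(run$mask)
  nvox3 <- prod(d3)
  rk4[rep(vox, nt) + nvox3 * rep(seq_len(nt) - 1L, each = length(vox))] <-
    as.vector(t(ranks))
  rsum <- array(0, c(d3, nt))
  kcount <- array(0, d3)
  for (i in seq_len(nrow(offs))) {
    off <- offs[i, ]
    kcount <- kcount + shift3d(maskind, off)
    for (t in seq_len(nt)) {
      slice <- array(rk4[, , , t, drop = FALSE], d3)
      rsum[, , , t] <- array(rsum[, , , t, drop = FALSE], d3) + shift3d(slice, off)
    }
  }
  rs <- matrix(rsum[rep(vox, nt) + nvox3 * rep(seq_len(nt) - 1L, each = length(vox))],
               nrow = length(vox))          # V x t rank sums
  k <- kcount[vox]
  s <- rowSums((rs - rowMeans(rs))^2)
  w <- 12 * s / (k^2 * (nt^3 - nt))
  vals <- array(0, d3)
  vals[vox] <- w
  metric_volume("ReHo", vals, run$mask, subject_id = run$subject_id)
}

#' Voxelwise degree centrality (DC)
#'
#' For each in-mask voxel, the mean Pearson correlation with every other
#' in-mask voxel whose correlation exceeds `r_threshold` (strictly). A
#' voxel with no suprathreshold neighbor gets DC 0. Zero-variance voxels
#' have all their correlations defined as 0 and are excluded as neighbors.
#'
#' @param run A band-passed `bold_run` with >= 2 in-mask voxels.
#' @param r_threshold Correlation threshold; neighbors must exceed it.
#' @param binarize If `TRUE`, report the proportion of suprathreshold
#'   neighbors instead of their mean correlation.
#' @return A `metric_volume` of metric "DC".
#' @export
degree_centrality <- function(run, r_threshold = 0.25, binarize = FALSE) {
  stopifnot(inherits(run, "bold_run"))
  check_step_order(run, "degree_centrality", requires = "bandpass")
  m <- run_matrix(run)
  nv <- ncol(m)
  if (nv < 2L) imgtx_stop("degree centrality needs at least 2 in-mask voxels")
  sds <- apply(m, 2L, stats::sd)
  ok <- sds > 0
  cc <- matrix(0, nv, nv)
  if (sum(ok) >= 2L) cc[ok, ok] <- stats::cor(m[, ok, drop = FALSE])
  diag(cc) <- NA                           # exclude self
  pass <- !is.na(cc) & cc > r_threshold
  npass <- rowSums(pass)
  dc <- if (binarize) npass / (nv - 1L)
        else ifelse(npass > 0, rowSums(cc * pass, na.rm = TRUE) / pmax(npass, 1L), 0)
  dc[npass == 0] <- 0
  vals <- array(0, dim(run$mask))
  vals[run$mask] <- dc
  metric_volume("DC", vals, run$mask, subject_id = run$subject_id)
}

#' Z-transform a metric volume over its mask
#'
#' @param vol A `metric_volume`.
#' @return The z-scored `metric_volume` (in-mask mean 0, sd 1).
#' @export
zscore_volume <- function(vol) {
  stopifnot(inherits(vol, "metric_volume"))
  x <- vol$values[vol$mask]
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    imgtx_stop("cannot z-score a constant map")
  vol$values[vol$mask] <- (x - mean(x)) / s
  vol$z_scored <- TRUE
  vol
}

#' Mask-renormalized Gaussian smoothing
#'
#' Convolves the in-mask values with an isotropic Gaussian kernel of the
#' given FWHM, restricting the kernel support to the mask and renormalizing
#' the weights so that mass is conserved (no bleeding of zeros across the
#' mask edge). Kernel sigma in voxels is fwhm / (2 sqrt(2 ln 2) * voxel_size).
#'
#' @param vol A `metric_volume`.
#' @param fwhm Full width at half maximum in mm.
#' @param voxel_size Isotropic voxel edge in mm.
#' @return Smoothed `metric_volume`.
#' @export
smooth_gaussian <- function(vol, fwhm = 8, voxel_size = 3) {
  stopifnot(inherits(vol, "metric_volume"))
  if (voxel_size <= 0) imgtx_stop("`voxel_size` must be positive")
  if (!any(vol$mask)) imgtx_stop("empty mask")
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  r <- max(1L, ceiling(3 * sigma))
  ax <- -r:r
  g <- expand.grid(dx = ax, dy = ax, dz = ax)
  w <- exp(-(g$dx^2 + g$dy^2 + g$dz^2) / (2 * sigma^2))
  maskind <- array(0, dim(vol$mask)); maskind[vol$mask] <- 1
  v0 <- vol$values * maskind
  num <- array(0, dim(vol$mask)); den <- array(0, dim(vol$mask))
  for (i in seq_len(nrow(g))) {
    off <- c(g$dx[i], g$dy[i], g$dz[i])
    num <- num + w[i] * shift3d(v0, off)
    den <- den + w[i] * shift3d(maskind, off)
  }
  out <- array(0, dim(vol$mask))
  out[vol$mask] <- num[vol$mask] / den[vol$mask]
  vol$values <- out
  vol$smoothed_fwhm <- fwhm
  vol
}
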