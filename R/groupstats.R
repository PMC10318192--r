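# Voxelwise two-sample group comparison within a sex stratum, with
# Benjamini-Hochberg FDR control and cluster-extent filtering of the
# significant voxels, plus parcel-level summarization of maps.

#' Feature-wise pooled-variance two-sample t-map
#'
#' For every feature, Student's two-sample t statistic (pooled variance,
#' df = n1 + n2 - 2) contrasting the two groups, with two-sided p values
#' and BH-adjusted q values. Features with zero pooled variance get t = 0
#' with a warning.
#'
#' @param matrix A harmonized `cohort_matrix`.
#' @param group_col Manifest column holding the two-level grouping.
#' @param positive Level whose larger mean yields positive t (cases).
#' @return Object of class `tstat_map`: `t`, `dof`, `p`, `q_fdr`,
#'   `feature_index`, group sizes.
#' @export
two_sample_tmap <- function(matrix, group_col = "group", positive = "ASD") {
  stopifnot(inherits(matrix, "cohort_matrix"))
  if (!matrix$harmonized)
    warning("t-map computed on an unharmonized matrix", call. = FALSE)
  g <- matrix$table[[group_col]]
  lv <- unique(g)
  if (length(lv) != 2L) imgtx_stop("grouping must have exactly 2 levels")
  a <- g == positive
  n1 <- sum(a); n2 <- sum(!a)
  if (n1 < 2L || n2 < 2L) imgtx_stop("both groups need at least 2 subjects")
  x <- matrix$values
  m1 <- colMeans(x[a, , drop = FALSE]); m2 <- colMeans(x[!a, , drop = FALSE])
  v1 <- apply(x[a, , drop = FALSE], 2, stats::var)
  v2 <- apply(x[!a, , drop = FALSE], 2, stats::var)
  dof <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dof
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (m1 - m2) / se
  if (any(se == 0)) {
    warning(sprintf("%d feature(s) with zero pooled variance; t set to 0",
                    sum(se == 0)), call. = FALSE)
    tval[se == 0] <- 0
  }
  p <- 2 * stats::pt(abs(tval), dof, lower.tail = FALSE)
  structure(list(t = tval, dof = dof, p = p, q_fdr = fdr_bh(p),
                 feature_index = matrix$feature_index, n1 = n1, n2 = n2),
            class = "tstat_map")
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()] with method "BH").
#'
#' @param p Numeric vector of p values in [0, 1].
#' @return Adjusted q values.
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) imgtx_stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# 26-connectivity (or 6/18) offsets excluding the center.
connectivity_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  d <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d <= 2, "26" = rep(TRUE, nrow(g)),
                 imgtx_stop("`connectivity` must be 6, 18 or 26"))
  as.matrix(g[keep, , drop = FALSE])
}

# Label connected components of a 3D logical array by breadth-first search.
label_components <- function(mask3d, connectivity = 26) {
  d <- dim(mask3d)
  offs <- connectivity_offsets(connectivity)
  lab <- array(0L, d)
  nxt <- 0L
  strides <- c(1L, d[1], d[1] * d[2])
  todo <- which(mask3d)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    lab[start] <- nxt
    queue <- start
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      ci <- arrayInd(v, d)[1, ]
      for (k in seq_len(nrow(offs))) {
        nb <- ci + offs[k, ]
        if (any(nb < 1L) || any(nb > d)) next
        fi <- 1L + sum((nb - 1L) * strides)
        if (mask3d[fi] && lab[fi] == 0L) {
          lab[fi] <- nxt
          queue <- c(queue, fi)
        }
      }
    }
  }
  lab
}

#' Cluster-extent filtering of a significance mask
#'
#' Labels connected components of the significant-voxel mask
#' (26-connectivity by default) and retains components of at least
#' `min_size` voxels — with the default 21, clusters must exceed 20
#' voxels. Each retained cluster is reported with its size, peak statistic
#' and peak coordinate when a statistic volume is supplied.
#'
#' @param sig_mask 3D logical array of significant voxels.
#' @param min_size Minimum retained component size in voxels.
#' @param connectivity 6, 18 or 26.
#' @param stat Optional 3D numeric array (e.g. the t map) for peak
#'   reporting; peaks maximize `abs(stat)`.
#' @return List with `labels` (3D integer array, relabeled 1..k over
#'   retained clusters) and `clusters` (data.frame: label, size, peak
#'   x/y/z, peak_stat).
#' @export
cluster_filter <- function(sig_mask, min_size = 21L, connectivity = 26,
                           stat = NULL) {
  stopifnot(is.logical(sig_mask) || all(sig_mask %in% c(0, 1)))
  sig_mask <- array(as.logical(sig_mask), dim(sig_mask))
  lab <- label_components(sig_mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  out_lab <- array(0L, dim(sig_mask))
  rows <- list()
  for (i in seq_along(keep)) {
    sel <- lab == keep[i]
    out_lab[sel] <- i
    vi <- which(sel)
    if (!is.null(stat)) {
      pk <- vi[which.max(abs(stat[vi]))]
      pc <- arrayInd(pk, dim(sig_mask))[1, ]
      pstat <- stat[pk]
    } else { pc <- c(NA, NA, NA); pstat <- NA_real_ }
    rows[[i]] <- data.frame(label = i, size = sizes[keep[i]],
                            peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
                            peak_stat = pstat)
  }
  clusters <- if (length(rows)) do.call(rbind, rows)
              else data.frame(label = integer(), size = integer(),
                              peak_x = integer(), peak_y = integer(),
                              peak_z = integer(), peak_stat = numeric())
  list(labels = out_lab, clusters = clusters)
}

#' Map a feature-wise statistic vector back to the 3D grid
#'
#' @param values Feature-wise numeric vector.
#' @param feature_index Linear voxel indices of the features.
#' @param dim3 Grid dimensions.
#' @param fill Value outside the features.
#' @return 3D numeric array.
#' @export
features_to_volume <- function(values, feature_index, dim3, fill = 0) {
  vol <- array(fill, dim3)
  vol[as.integer(feature_index)] <- values
  vol
}

#' Significant clusters of a t-map
#'
#' Applies the significance gate (BH q below `alpha`) and then the
#' cluster-extent filter, in that order.
#'
#' @param tmap A `tstat_map` over voxel features.
#' @param dim3 Grid dimensions.
#' @param alpha FDR level.
#' @param min_size,connectivity Passed to [cluster_filter()].
#' @param sign "both", "increase" (t > 0) or "decrease" (t < 0).
#' @return As [cluster_filter()], plus the t volume under `t_volume`.
#' @export
significant_clusters <- function(tmap, dim3, alpha = 0.05, min_size = 21L,
                                 connectivity = 26, sign = "both") {
  stopifnot(inherits(tmap, "tstat_map"))
  sig <- tmap$q_fdr < alpha
  if (sign == "increase") sig <- sig & tmap$t > 0
  if (sign == "decrease") sig <- sig & tmap$t < 0
  tvol <- features_to_volume(tmap$t, tmap$feature_index, dim3)
  svol <- features_to_volume(as.numeric(sig), tmap$feature_index, dim3)
  res <- cluster_filter(array(svol > 0, dim3), min_size, connectivity, stat = tvol)
  res$t_volume <- tvol
  res
}

#' Parcel-wise means of a 3D map
#'
#' @param values 3D numeric array (or `metric_volume`).
#' @param parcellation A `parcellation` aligned to the same grid.
#' @param hemisphere "all", "left" or "right" parcel subset.
#' @return Named numeric vector of per-parcel in-mask means; parcels with
#'   no in-mask voxels are `NA` with a warning.
#' @export
regional_summary <- function(values, parcellation, hemisphere = "all") {
  if (inherits(values, "metric_volume")) values <- values$values
  stopifnot(identical(dim(values), dim(parcellation$labels)))
  ids <- seq_len(parcellation$n_parcels)
  if (hemisphere != "all") {
    want <- if (hemisphere == "left") "L" else "R"
    ids <- ids[parcellation$hemisphere[as.character(ids)] == want]
  }
  lab <- parcellation$labels
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  m <- tapply(values[lab > 0], lab[lab > 0], mean)
  hit <- intersect(names(m), names(out))
  out[hit] <- m[hit]
  if (anyNA(out))
    warning(sprintf("%d empty parcel(s) returned as NA", sum(is.na(out))),
            call. = FALSE)
  out
}
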