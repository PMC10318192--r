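# Partial least squares regression linking parcel-level gene expression
# (predictors, genes >> parcels) to a parcel-level functional difference
# map (response), with permutation tests of per-component explained
# variance, a spatial-similarity permutation test, bootstrap gene-weight
# Z-scores, top-fraction gene selection, and weighted expression maps.

# Minimal univariate-response NIPALS with deflation; no input checks.
# Returns per-component x-weights (for the deflated X of that step),
# scores, x-loadings, y-loadings and incremental explained variance of y.
pls_core <- function(x, y, k) {
  n <- nrow(x); p <- ncol(x)
  w <- matrix(0, p, k); tt <- matrix(0, n, k)
  pl <- matrix(0, p, k); cl <- numeric(k)
  ssy <- sum(y^2)
  xk <- x; yk <- y
  evar <- numeric(k)
  for (j in seq_len(k)) {
    wj <- crossprod(xk, yk)
    nw <- sqrt(sum(wj^2))
    if (nw < .Machine$double.eps) { w[, j] <- 0; next }
    wj <- wj / nw
    tj <- xk %*% wj
    tt2 <- sum(tj^2)
    if (tt2 < .Machine$double.eps) { w[, j] <- wj; next }
    pj <- crossprod(xk, tj) / tt2
    cj <- sum(yk * tj) / tt2
    xk <- xk - tcrossprod(tj, pj)
    yk <- yk - cj * tj
    w[, j] <- wj; tt[, j] <- tj; pl[, j] <- pj; cl[j] <- cj
    evar[j] <- cj^2 * tt2 / ssy
  }
  list(weights = w, scores = tt, x_loadings = pl, y_loadings = cl,
       explained_variance_y = evar)
}

as_pls_x <- function(x) {
  if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
}

#' Fit a PLS regression of a regional feature map on gene expression
#'
#' Univariate-response NIPALS PLS: components maximize the covariance
#' between X-scores and the response, with standard deflation. Predictors
#' and response are centered and scaled internally unless already flagged
#' standardized. Explained variance per component is the incremental
#' fraction of var(y) captured.
#'
#' @param x Parcels x genes matrix or `expression_matrix`.
#' @param y Parcel-level response vector aligned on the same parcel order.
#' @param n_components Number of components, at most min(parcels - 1, genes).
#' @param scale. Standardize x columns and y before fitting.
#' @return Object of class `pls_result`: `n_components`, `x_weights`,
#'   `region_scores`, `x_loadings`, `y_loadings`, `explained_variance_y`,
#'   plus the standardized inputs used.
#' @export
pls_fit <- function(x, y, n_components = 5L, scale. = TRUE) {
  xm <- as_pls_x(x)
  y <- as.numeric(y)
  if (nrow(xm) != length(y)) imgtx_stop("x rows and y length must agree")
  if (stats::sd(y) == 0) imgtx_stop("constant response: nothing to explain")
  n_components <- as.integer(n_components)
  kmax <- min(nrow(xm) - 1L, ncol(xm))
  if (n_components < 1L || n_components > kmax)
    imgtx_stop(sprintf("n_components must be in 1..%d", kmax))
  if (scale.) {
    sds <- apply(xm, 2, stats::sd)
    if (any(sds == 0)) imgtx_stop("constant predictor column(s); drop them first")
    xm <- scale(xm); y <- as.numeric(scale(y))
  }
  fit <- pls_core(xm, y, n_components)
  structure(list(n_components = n_components,
                 x_weights = fit$weights, region_scores = fit$scores,
                 x_loadings = fit$x_loadings, y_loadings = fit$y_loadings,
                 explained_variance_y = fit$explained_variance_y,
                 x = xm, y = y,
                 gene_ids = colnames(xm) %||% paste0("gene", seq_len(ncol(xm)))),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> %d component(s), %d parcels x %d genes\n",
              x$n_components, nrow(x$region_scores), nrow(x$x_weights)))
  cat("  explained variance of y:",
      paste(sprintf("%.3f", x$explained_variance_y), collapse = ", "), "\n")
  invisible(x)
}

#' Permutation test of PLS explained variance per component
#'
#' Refits the PLS under `n_perm` null reorderings of the response and
#' reports, per component, the add-one permutation p value
#' p = (1 + #\{permuted evar >= observed\}) / (n_perm + 1). The null
#' generator is either a plain row permutation or a
#' spatial-autocorrelation-preserving surrogate (variogram-matched
#' Gaussian field rank-remapped to the observed values; requires parcel
#' coordinates).
#'
#' @param x,y,n_components,scale. As in [pls_fit()].
#' @param n_perm Number of permutations (>= 100 recommended, >= 1 required).
#' @param null "permute" or "spatial".
#' @param coords Parcels x 3 coordinate matrix (required for "spatial").
#' @param seed RNG seed.
#' @return List with `p_perm` (per component), `observed` explained
#'   variance, `n_perm`, `null`.
#' @export
permutation_test_variance <- function(x, y, n_components = 5L, n_perm = 10000L,
                                      null = c("permute", "spatial"),
                                      coords = NULL, seed = 1L, scale. = TRUE) {
  null <- match.arg(null)
  if (n_perm < 1L) imgtx_stop("n_perm must be at least 1")
  xm <- as_pls_x(x)
  y <- as.numeric(y)
  if (scale.) { xm <- scale(xm); y <- as.numeric(scale(y)) }
  obs <- pls_core(xm, y, n_components)$explained_variance_y
  if (null == "spatial" && is.null(coords))
    imgtx_stop("spatial null requires parcel `coords`")
  exceed <- numeric(n_components)
  with_seed(seed, {
    surr <- if (null == "spatial")
      spatial_surrogates(y, coords, n_perm) else NULL
    for (i in seq_len(n_perm)) {
      yp <- if (null == "permute") y[sample.int(length(y))] else surr[, i]
      ev <- pls_core(xm, yp, n_components)$explained_variance_y
      exceed <- exceed + (ev >= obs)
    }
  })
  list(p_perm = (1 + exceed) / (n_perm + 1), observed = obs,
       n_perm = n_perm, null = null)
}

#' Variogram-matched spatial surrogate maps
#'
#' Fits an exponential variogram to the map over the given coordinates,
#' draws Gaussian fields with the implied covariance, and rank-remaps each
#' field to the observed values, so surrogates preserve both the marginal
#' distribution and (approximately) the spatial autocorrelation.
#'
#' @param y Map values.
#' @param coords n x 3 coordinates.
#' @param n Number of surrogates.
#' @return length(y) x n matrix of surrogate maps.
#' @export
spatial_surrogates <- function(y, coords, n) {
  coords <- as.matrix(coords)
  dmat <- as.matrix(stats::dist(coords))
  v <- stats::var(y)
  # empirical semivariogram and a grid fit of the exponential range
  dv <- dmat[upper.tri(dmat)]
  gv <- 0.5 * outer(y, y, "-")[upper.tri(dmat)]^2
  ranges <- seq(max(dv) / 20, max(dv), length.out = 25)
  sse <- vapply(ranges, function(r) sum((gv - v * (1 - exp(-dv / r)))^2),
                numeric(1))
  r0 <- ranges[which.min(sse)]
  cv <- v * exp(-dmat / r0)
  ch <- chol(cv + diag(1e-8 * v, nrow(cv)))
  z <- t(ch) %*% matrix(stats::rnorm(length(y) * n), length(y), n)
  ys <- sort(y)
  apply(z, 2, function(col) ys[rank(col, ties.method = "first")])
}

#' Spatial-similarity permutation test between two parcel maps
#'
#' Observed Pearson correlation between the weighted expression map and
#' the functional feature map, against a null of permuted weighted-map
#' values; two-sided on |r|.
#'
#' @param weighted_map,feature_map Numeric vectors on the same parcel set.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return List with `r`, `p_spatial`, `n_perm`.
#' @export
spatial_similarity_test <- function(weighted_map, feature_map,
                                    n_perm = 10000L, seed = 1L) {
  if (length(weighted_map) != length(feature_map))
    imgtx_stop("maps must share the parcel set")
  if (stats::sd(weighted_map) == 0 || stats::sd(feature_map) == 0)
    imgtx_stop("constant map")
  r_obs <- stats::cor(weighted_map, feature_map)
  exceed <- with_seed(seed, {
    e <- 0L
    for (i in seq_len(n_perm)) {
      rp <- stats::cor(weighted_map[sample.int(length(weighted_map))], feature_map)
      if (abs(rp) >= abs(r_obs)) e <- e + 1L
    }
    e
  })
  list(r = r_obs, p_spatial = (1 + exceed) / (n_perm + 1), n_perm = n_perm)
}

#' Bootstrap Z-scores for PLS gene weights
#'
#' Resamples parcels with replacement, refits the PLS per replicate, and
#' sign-aligns each replicate's component-`component_k` weight vector to
#' the original (flipping when their correlation is negative, since PLS
#' components carry an arbitrary sign). The bootstrap standard error of
#' each gene's weight gives Z = weight / SE, and genes are ranked by Z.
#'
#' @param x,y As in [pls_fit()].
#' @param component_k Component whose weights are ranked.
#' @param n_boot Bootstrap replicates; below 100 draws a warning.
#' @param seed RNG seed.
#' @param top_fraction Fraction per tail for `selected_top` flags.
#' @param scale. Standardize inputs.
#' @return Object of class `gene_weight_table`: data.frame with
#'   `gene_id`, `weight`, `boot_se`, `z`, `rank` (descending Z),
#'   `selected_top` (either tail), `tail` ("positive", "negative" or "").
#' @export
bootstrap_gene_weights <- function(x, y, component_k = 1L, n_boot = 1000L,
                                   seed = 1L, top_fraction = 0.05,
                                   scale. = TRUE) {
  if (n_boot < 100L)
    warning("fewer than 100 bootstrap replicates: SE estimates will be noisy",
            call. = FALSE)
  xm <- as_pls_x(x)
  gene_ids <- colnames(xm) %||% paste0("gene", seq_len(ncol(xm)))
  y <- as.numeric(y)
  if (scale.) { xm <- scale(xm); y <- as.numeric(scale(y)) }
  n <- nrow(xm)
  w0 <- pls_core(xm, y, component_k)$weights[, component_k]
  boot <- matrix(NA_real_, length(w0), n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) > 2L) break    # degenerate resample: redraw
      }
      xb <- xm[idx, , drop = FALSE]; yb <- y[idx]
      sds <- apply(xb, 2, stats::sd)
      if (any(sds == 0) || stats::sd(yb) == 0) next   # column stays NA
      wb <- pls_core(scale(xb), as.numeric(scale(yb)),
                     component_k)$weights[, component_k]
      if (sum(wb * w0) < 0) wb <- -wb          # sign alignment
      boot[, b] <- wb
    }
  })
  se <- apply(boot, 1, stats::sd, na.rm = TRUE)
  z <- w0 / se
  ord <- order(z, decreasing = TRUE)
  rk <- integer(length(z)); rk[ord] <- seq_along(z)
  tab <- data.frame(gene_id = gene_ids, weight = w0, boot_se = se, z = z,
                    rank = rk, stringsAsFactors = FALSE)
  sel <- select_top_genes(tab, fraction = top_fraction)
  tab$tail <- ifelse(tab$gene_id %in% sel$positive, "positive",
                     ifelse(tab$gene_id %in% sel$negative, "negative", ""))
  tab$selected_top <- tab$tail != ""
  class(tab) <- c("gene_weight_table", "data.frame")
  tab
}

#' Select top-ranked genes from a gene-weight table
#'
#' Returns the top `fraction` of genes by Z in each tail:
#' ceiling(fraction * n) genes with the largest Z (positive tail) and the
#' same number with the smallest Z (negative tail), plus the merged list.
#'
#' @param table A `gene_weight_table` (or data.frame with `gene_id`, `z`).
#' @param fraction Per-tail fraction, in (0, 0.5].
#' @return List with `positive`, `negative`, `merged` gene-id vectors and
#'   `n_per_tail`.
#' @export
select_top_genes <- function(table, fraction = 0.05) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5)
    imgtx_stop("`fraction` must lie in (0, 0.5]")
  n <- nrow(table)
  k <- ceiling(fraction * n)
  ord <- order(table$z, decreasing = TRUE)
  pos <- table$gene_id[ord[seq_len(k)]]
  neg <- table$gene_id[rev(ord)[seq_len(k)]]
  list(positive = pos, negative = neg, merged = union(pos, neg), n_per_tail = k)
}

#' Weighted gene-expression map from PLS weights
#'
#' Per parcel, the inner product of the standardized expression row with
#' the gene weight vector; optionally projected to voxels through a
#' parcellation for visualization.
#'
#' @param x Parcels x genes matrix or `expression_matrix` (standardized).
#' @param weights Gene weight vector.
#' @param parcellation Optional `parcellation` for the voxel projection;
#'   parcel names of the map must be parcel ids.
#' @return Named parcel-level score vector; if a parcellation is given, a
#'   list with `map` and `volume`.
#' @export
weighted_expression_map <- function(x, weights, parcellation = NULL) {
  xm <- as_pls_x(x)
  if (ncol(xm) != length(weights)) imgtx_stop("one weight per gene required")
  sc <- as.numeric(xm %*% weights)
  names(sc) <- rownames(xm) %||% seq_len(nrow(xm))
  if (is.null(parcellation)) return(sc)
  vol <- array(0, dim(parcellation$labels))
  for (p in names(sc)) vol[parcellation$labels == as.integer(p)] <- sc[[p]]
  list(map = sc, volume = vol)
}
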