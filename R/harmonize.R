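# Multi-site harmonization of subject x feature metric matrices by
# empirical-Bayes location/scale adjustment (ComBat), protecting specified
# biological covariates, plus a site-leakage audit that checks whether site
# is still decodable from the harmonized features.

#' Construct a cohort matrix
#'
#' @param values subjects x features numeric matrix.
#' @param table Subject manifest data.frame; must contain `subject_id`,
#'   `site`, `group`, `sex`, `age`, one row per matrix row.
#' @param feature_index Optional feature identifiers (voxel linear indices
#'   or parcel ids); defaults to column names or 1..p.
#' @param harmonized Has site adjustment been applied?
#' @return Object of class `cohort_matrix`.
#' @export
cohort_matrix <- function(values, table, feature_index = NULL,
                          harmonized = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(table))
    imgtx_stop("matrix rows must match manifest rows")
  if (any(!is.finite(values))) imgtx_stop("matrix contains non-finite values")
  need <- c("subject_id", "site", "group", "sex", "age")
  miss <- setdiff(need, names(table))
  if (length(miss))
    imgtx_stop(paste("manifest is missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(table$subject_id))
    imgtx_stop("manifest contains duplicate subject_id values")
  if (any(table$age <= 0)) imgtx_stop("ages must be positive")
  feature_index <- feature_index %||% colnames(values) %||% seq_len(ncol(values))
  structure(list(values = values, table = table,
                 feature_index = feature_index, harmonized = harmonized),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d subjects x %d features, %d site(s)%s\n",
              nrow(x$values), ncol(x$values), length(unique(x$table$site)),
              if (x$harmonized) ", harmonized" else ""))
  invisible(x)
}

# Parametric EB hyperpriors for the batch scale parameters (inverse gamma
# via method of moments), as in standard ComBat.
eb_aprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
eb_bprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }

# Iterative joint posterior-mode solution for one batch's location (gamma)
# and scale (delta^2) under the parametric priors.
eb_solve <- function(z, g_hat, d_hat, g_bar, t2, a, b,
                     conv = 1e-6, max_iter = 100L) {
  n <- rowSums(!is.na(z))
  g_old <- g_hat; d_old <- d_hat
  for (i in seq_len(max_iter)) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- rowSums((z - g_new)^2, na.rm = TRUE)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old), abs(d_new - d_old))
    g_old <- g_new; d_old <- d_new
    if (change < conv) break
  }
  list(gamma_star = g_old, delta_star = d_old)
}

#' ComBat harmonization of a cohort matrix
#'
#' Standard parametric empirical-Bayes batch adjustment: feature-wise OLS
#' on covariates plus batch indicators, standardization by pooled residual
#' scale, EB shrinkage of per-batch location (normal prior) and scale
#' (inverse-gamma prior) toward their across-feature means, then removal
#' of the shrunken batch effects and restoration of the covariate fit.
#' Covariate effects (by default age and diagnosis) are preserved.
#'
#' @param matrix A `cohort_matrix`.
#' @param batch Manifest column naming the batch variable (default site).
#' @param covariates Manifest columns protected during adjustment.
#'   Numeric columns enter as-is; character/factor columns are expanded to
#'   treatment-coded indicators.
#' @param eb Use empirical-Bayes shrinkage (TRUE) or per-batch estimates.
#' @param conv,max_iter EB iteration stopping rule.
#' @return The harmonized `cohort_matrix` (`harmonized = TRUE`). Features
#'   with zero variance within some batch are left unadjusted with a
#'   warning.
#' @export
combat <- function(matrix, batch = "site", covariates = c("age", "group"),
                   eb = TRUE, conv = 1e-6, max_iter = 100L) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  tab <- matrix$table
  b <- factor(tab[[batch]])
  nb <- nlevels(b)
  if (nb < 2L) {
    matrix$harmonized <- TRUE
    return(matrix)
  }
  if (any(table(b) < 2L)) imgtx_stop("every batch needs at least 2 subjects")
  y <- t(matrix$values)                       # features x subjects
  n <- ncol(y)
  bm <- stats::model.matrix(~ b - 1)          # batch indicators
  cm <- NULL
  if (length(covariates)) {
    cl <- lapply(covariates, function(v) {
      x <- tab[[v]]
      if (is.numeric(x)) stats::setNames(data.frame(x), v)
      else as.data.frame(stats::model.matrix(~ factor(x))[, -1, drop = FALSE])
    })
    cm <- as.matrix(do.call(cbind, cl))
    colnames(cm) <- unlist(lapply(seq_along(covariates), function(i)
      paste0(covariates[i], seq_len(ncol(as.matrix(cl[[i]]))))))
  }
  design <- cbind(bm, cm)
  if (qr(design)$rank < ncol(design)) {
    # find which covariate is confounded with batch
    bad <- covariates[vapply(covariates, function(v) {
      qr(cbind(bm, if (is.numeric(tab[[v]])) tab[[v]]
               else stats::model.matrix(~ factor(tab[[v]]))[, -1, drop = FALSE]
               ))$rank < nb + (if (is.numeric(tab[[v]])) 1L
                               else nlevels(factor(tab[[v]])) - 1L)
    }, logical(1))]
    imgtx_stop(sprintf(
      "design is confounded: covariate(s) %s are collinear with batch '%s'",
      paste(if (length(bad)) bad else "(batch levels)", collapse = ", "), batch))
  }
  n_batch <- as.vector(table(b))
  beta <- solve(crossprod(design), crossprod(design, t(y)))   # coef x features
  grand_mean <- crossprod(n_batch / n, beta[seq_len(nb), , drop = FALSE])
  var_pooled <- rowSums((y - t(design %*% beta))^2) / n
  zero_var <- var_pooled <= .Machine$double.eps * 100
  if (any(zero_var))
    warning(sprintf("%d feature(s) with (near) zero pooled variance left unadjusted",
                    sum(zero_var)), call. = FALSE)
  keep <- which(!zero_var)
  stand_mean <- t(rep(1, n) %*% grand_mean)[keep, , drop = FALSE]
  if (!is.null(cm))
    stand_mean <- stand_mean +
      t(cm %*% beta[(nb + 1):ncol(design), keep, drop = FALSE])
  sp <- sqrt(var_pooled[keep])
  z <- (y[keep, , drop = FALSE] - stand_mean) / sp

  adj <- y
  zadj <- z
  for (i in seq_len(nb)) {
    sel <- b == levels(b)[i]
    zi <- z[, sel, drop = FALSE]
    g_hat <- rowMeans(zi)
    d_hat <- apply(zi, 1, stats::var)
    if (eb && length(g_hat) >= 2L) {
      sol <- eb_solve(zi, g_hat, d_hat,
                      g_bar = mean(g_hat), t2 = stats::var(g_hat),
                      a = eb_aprior(d_hat), b = eb_bprior(d_hat),
                      conv = conv, max_iter = max_iter)
      g_star <- sol$gamma_star; d_star <- sol$delta_star
    } else {
      g_star <- g_hat; d_star <- d_hat
    }
    zadj[, sel] <- (zi - g_star) / sqrt(pmax(d_star, .Machine$double.eps))
  }
  adj[keep, ] <- zadj * sp + stand_mean
  matrix$values <- t(adj)
  matrix$harmonized <- TRUE
  matrix
}

#' Audit residual site information after harmonization
#'
#' Fits a cross-validated linear SVM predicting site from the features and
#' compares its accuracy with chance (the largest site's share). If the
#' accuracy exceeds chance by more than `margin`, site information has
#' leaked through harmonization and the report is flagged.
#'
#' @param matrix A `cohort_matrix`.
#' @param n_folds Cross-validation folds.
#' @param margin Allowed accuracy excess over chance before flagging.
#' @param seed RNG seed for fold assignment.
#' @return List with `accuracy`, `chance`, `flagged`, `applicable`.
#' @export
site_leakage_audit <- function(matrix, n_folds = 5L, margin = 0.1, seed = 1L) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  site <- factor(matrix$table$site)
  if (nlevels(site) < 2L)
    return(list(accuracy = NA_real_, chance = 1, flagged = FALSE,
                applicable = FALSE))
  x <- matrix$values
  with_seed(seed, {
    folds <- make_stratified_folds(site, n_folds)
    pred <- factor(rep(NA_character_, length(site)), levels = levels(site))
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      fit <- e1071::svm(x[tr, , drop = FALSE], site[tr], kernel = "linear",
                        cost = 1, scale = FALSE)
      pred[!tr] <- stats::predict(fit, x[!tr, , drop = FALSE])
    }
    acc <- mean(pred == site)
    chance <- max(table(site)) / length(site)
    list(accuracy = acc, chance = chance,
         flagged = acc > chance + margin, applicable = TRUE)
  })
}

# Stratified fold labels: classes distributed as evenly as possible.
make_stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (lv in levels(factor(y))) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}
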