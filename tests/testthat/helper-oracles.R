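# Independent brute-force oracles. Deliberately share no code with the
# package implementations: explicit trigonometric sums for the DFT,
# per-pair cor() loops, direct rank-sum formulas, graph components for
# cluster labeling, lm()/t.test() for the regressions.

# single-sided amplitude-spectrum ALFF for one voxel series
oracle_alff_series <- function(x, tr, low, high) {
  n <- length(x)
  js <- seq_len(floor(n / 2))
  amps <- vapply(js, function(j) {
    th <- 2 * pi * j * (0:(n - 1)) / n
    re <- sum(x * cos(th)); im <- -sum(x * sin(th))
    mod <- sqrt(re^2 + im^2)
    if (j == n / 2) mod / n else 2 * mod / n
  }, numeric(1))
  f <- js / (n * tr)
  mean(amps[f >= low & f <= high])
}

# Kendall's W from a t x K matrix of series (midranks, no tie correction)
oracle_kendall_w <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  r <- apply(mat, 2, rank)
  rs <- rowSums(r)
  12 * sum((rs - mean(rs))^2) / (k^2 * (n^3 - n))
}

# ReHo map by explicit neighbor gathering per voxel
oracle_reho <- function(run, neighborhood = 27) {
  m <- run_matrix(run)
  vox <- which(run$mask)
  d <- dim(run$mask)
  co <- arrayInd(vox, d)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  manh <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[switch(as.character(neighborhood), "7" = manh <= 1,
                      "19" = manh <= 2, "27" = rep(TRUE, 27)), ]
  out <- array(0, d)
  for (i in seq_along(vox)) {
    cols <- integer(0)
    for (o in seq_len(nrow(offs))) {
      nb <- co[i, ] + c(offs$dx[o], offs$dy[o], offs$dz[o])
      if (any(nb < 1) || any(nb > d)) next
      j <- which(co[, 1] == nb[1] & co[, 2] == nb[2] & co[, 3] == nb[3])
      if (length(j)) cols <- c(cols, j)
    }
    out[vox[i]] <- oracle_kendall_w(m[, cols, drop = FALSE])
  }
  out
}

# DC map by explicit pairwise cor() loop
oracle_dc <- function(run, thr = 0.25) {
  m <- run_matrix(run)
  nv <- ncol(m)
  sds <- apply(m, 2, sd)
  out <- numeric(nv)
  for (v in seq_len(nv)) {
    rs <- numeric(0)
    for (u in seq_len(nv)) {
      if (u == v) next
      r <- if (sds[u] == 0 || sds[v] == 0) 0 else cor(m[, v], m[, u])
      if (r > thr) rs <- c(rs, r)
    }
    out[v] <- if (length(rs)) mean(rs) else 0
  }
  vol <- array(0, dim(run$mask)); vol[run$mask] <- out
  vol
}

# connected components via igraph on a Chebyshev-adjacency graph
oracle_components <- function(mask3d) {
  vox <- which(mask3d)
  if (!length(vox)) return(array(0L, dim(mask3d)))
  co <- arrayInd(vox, dim(mask3d))
  n <- length(vox)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    adj[i, j] <- max(abs(co[i, ] - co[j, ])) <= 1
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- array(0L, dim(mask3d)); out[vox] <- comp
  out
}

# independently coded covariance-deflation PLS (explained variance via
# residual sums of squares, loadings via per-column projections)
oracle_pls <- function(x, y, k) {
  x <- scale(x); y <- as.numeric(scale(y))
  ss0 <- sum(y^2)
  w <- matrix(0, ncol(x), k); evar <- numeric(k)
  for (j in seq_len(k)) {
    cv <- vapply(seq_len(ncol(x)), function(i) sum(x[, i] * y), numeric(1))
    wj <- cv / sqrt(sum(cv^2))
    tj <- as.numeric(x %*% wj)
    ss_before <- sum(y^2)
    pj <- vapply(seq_len(ncol(x)), function(i)
      sum(x[, i] * tj) / sum(tj^2), numeric(1))
    cj <- sum(y * tj) / sum(tj^2)
    x <- x - outer(tj, pj)
    y <- y - cj * tj
    w[, j] <- wj
    evar[j] <- (ss_before - sum(y^2)) / ss0
  }
  list(weights = w, explained_variance_y = evar)
}

# t x k series with an exact target sample correlation matrix: orthonormal
# basis recombined through the Cholesky factor
make_series_with_cor <- function(target_r, t_len, seed = 1) {
  set.seed(seed)
  k <- nrow(target_r)
  raw <- matrix(rnorm(t_len * k), t_len, k)
  raw <- scale(raw, scale = FALSE)
  q <- qr.Q(qr(raw))
  m <- q %*% chol(target_r)
  scale(m)  # unit sd; correlations unchanged
}

# small random masked run for oracle-equivalence sweeps
make_test_run <- function(grid = c(8L, 8L, 8L), t_len = 120L, tr = 2,
                          n_mask = 40L, seed = 1L, steps = c("detrend", "bandpass")) {
  set.seed(seed)
  mask <- array(FALSE, grid)
  # contiguous-ish random mask: random walk growth from the center
  ctr <- matrix(ceiling(grid / 2), 1)
  cells <- ctr
  while (nrow(cells) < n_mask) {
    base <- cells[sample.int(nrow(cells), 1), ]
    step <- sample(c(-1, 1), 1)
    axis <- sample(3, 1)
    nb <- base; nb[axis] <- nb[axis] + step
    if (any(nb < 1) || any(nb > grid)) next
    cells <- unique(rbind(cells, nb))
  }
  mask[cells] <- TRUE
  dat <- array(0, c(grid, t_len))
  nv3 <- prod(grid)
  vox <- which(mask)
  dat[rep(vox, t_len) + nv3 * rep(0:(t_len - 1), each = length(vox))] <-
    rnorm(length(vox) * t_len)
  run <- bold_run(dat, tr = tr, mask = mask)
  attr(run, "steps") <- steps   # mark stages as applied for order contract
  run
}
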