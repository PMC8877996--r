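# Independent brute-force oracles and small fixture builders used across the
# test files. The oracles deliberately use naive loop/queue implementations
# so they share no code path with the package internals.

# Single-slice volume/mask builders -----------------------------------------

slice_volume <- function(m, spacing = c(1, 1, 1)) {
  image_volume(array(m, c(1, nrow(m), ncol(m))), spacing)
}

slice_mask <- function(m, spacing = c(1, 1, 1)) {
  binary_mask(array(m, c(1, nrow(m), ncol(m))), spacing)
}

full_roi <- function(x) binary_mask(array(TRUE, dim(x$data)), x$spacing)

# Region-growth oracles ------------------------------------------------------

neighbor_offsets_2d <- function(connectivity) {
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  offs
}

# Connected component (within the thresholded-difference set relative to the
# original seed) containing the seed: plain queue-based flood fill.
oracle_region_seed <- function(I, seed_rc, a, threshold, connectivity = 4) {
  eligible <- (1 - abs(I - I[seed_rc[1], seed_rc[2]]) / a) >= threshold
  eligible[seed_rc[1], seed_rc[2]] <- TRUE
  offs <- neighbor_offsets_2d(connectivity)
  acc <- matrix(FALSE, nrow(I), ncol(I))
  queue <- list(seed_rc)
  acc[seed_rc[1], seed_rc[2]] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (o in offs) {
      q <- p + o
      if (q[1] < 1 || q[1] > nrow(I) || q[2] < 1 || q[2] > ncol(I)) next
      if (acc[q[1], q[2]] || !eligible[q[1], q[2]]) next
      acc[q[1], q[2]] <- TRUE
      queue[[length(queue) + 1]] <- q
    }
  }
  acc
}

# Chain-affinity growth with an explicit frontier; `order` switches between
# queue (BFS) and stack (DFS) processing to probe order invariance.
oracle_region_chain <- function(I, seed_rc, a, threshold, connectivity = 4,
                                order = c("bfs", "dfs"), allowed = NULL) {
  order <- match.arg(order)
  offs <- neighbor_offsets_2d(connectivity)
  acc <- matrix(FALSE, nrow(I), ncol(I))
  acc[seed_rc[1], seed_rc[2]] <- TRUE
  frontier <- list(seed_rc)
  while (length(frontier)) {
    k <- if (order == "bfs") 1 else length(frontier)
    p <- frontier[[k]]; frontier <- frontier[-k]
    for (o in offs) {
      q <- p + o
      if (q[1] < 1 || q[1] > nrow(I) || q[2] < 1 || q[2] > ncol(I)) next
      if (acc[q[1], q[2]]) next
      if (!is.null(allowed) && !allowed[q[1], q[2]]) next
      if ((1 - abs(I[q[1], q[2]] - I[p[1], p[2]]) / a) >= threshold) {
        acc[q[1], q[2]] <- TRUE
        frontier[[length(frontier) + 1]] <- q
      }
    }
  }
  acc
}

# Morphology oracle -----------------------------------------------------------

# Closing by definition on the (conceptually unbounded) integer plane:
# dilation computed over a padded coordinate range, then erosion evaluated
# at the original grid points. Plain double loops.
oracle_closing <- function(m, radius) {
  r <- as.integer(floor(radius))
  if (r <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  offs <- which(outer((-r:r)^2, (-r:r)^2, "+") <= radius^2, arr.ind = TRUE) -
    (r + 1)
  D <- matrix(FALSE, nr + 2 * r, nc + 2 * r)  # rows/cols shifted by +r
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!m[i, j]) next
    for (k in seq_len(nrow(offs)))
      D[i + offs[k, 1] + r, j + offs[k, 2] + r] <- TRUE
  }
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ok <- TRUE
    for (k in seq_len(nrow(offs))) {
      if (!D[i + offs[k, 1] + r, j + offs[k, 2] + r]) { ok <- FALSE; break }
    }
    out[i, j] <- ok
  }
  out
}

# ICC oracle ------------------------------------------------------------------

# Mean squares via stats::aov on the long-format table, independent of the
# package's direct-sum computation.
oracle_icc <- function(ref, cand, type = "agreement") {
  n <- length(ref)
  df <- data.frame(y = c(ref, cand),
                   subject = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  if (type == "agreement")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
}

# Random image builders -------------------------------------------------------

# i.i.d. uniform-intensity image (for oracle-equivalence sweeps).
random_image <- function(nr = 32, nc = 32) matrix(stats::runif(nr * nc), nr, nc)

# Small piecewise-smooth 3D "phantom" with a bright blob on a textured
# background, for inverse-edit tests.
random_blob_volume <- function(nz = 3, nr = 24, nc = 24, sigma = 0.02) {
  arr <- array(0.3 + stats::rnorm(nz * nr * nc, 0, sigma), c(nz, nr, nc))
  ctr <- c(sample(seq_len(nz), 1),
           sample(5:(nr - 4), 1), sample(5:(nc - 4), 1))
  rad <- stats::runif(1, 2, 4)
  for (z in seq_len(nz)) for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if ((z - ctr[1])^2 + (i - ctr[2])^2 + (j - ctr[3])^2 <= rad^2)
      arr[z, i, j] <- 0.85 + stats::rnorm(1, 0, sigma)
  }
  list(volume = image_volume(pmin(pmax(arr, 0), 1)), center = ctr)
}
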