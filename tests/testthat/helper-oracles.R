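# Independent reference implementations used as oracles. Deliberately naive
# (plain loops, no shared code with the package internals).

# Flood-fill 26-connected labeling of a logical 3D array.
naive_cc_labels <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  next_lab <- 0L
  for (k0 in seq_len(d[3])) for (j0 in seq_len(d[2])) for (i0 in seq_len(d[1])) {
    if (!mask[i0, j0, k0] || labels[i0, j0, k0] != 0L) next
    next_lab <- next_lab + 1L
    queue <- list(c(i0, j0, k0))
    labels[i0, j0, k0] <- next_lab
    while (length(queue) > 0) {
      v <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        p <- v + c(di, dj, dk)
        if (any(p < 1) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] && labels[p[1], p[2], p[3]] == 0L) {
          labels[p[1], p[2], p[3]] <- next_lab
          queue[[length(queue) + 1L]] <- p
        }
      }
    }
  }
  labels
}

# Partition of voxel linear indices by component, order-independent form.
label_partition <- function(labels) {
  nz <- which(labels != 0L)
  parts <- split(nz, labels[nz])
  unname(parts[order(vapply(parts, min, numeric(1)))])
}

# Literal implementation of the noise-threshold rule: bin-width-1 histogram,
# background peak = max of lower occupied half excluding I = 0, then walk up
# tracking the running minimum until a bin doubles it (or any occupied bin
# after an empty one); the threshold is the running-minimum bin.
naive_noise_threshold <- function(data) {
  h <- integer(max(data) + 1L)
  for (x in as.vector(data)) h[x + 1L] <- h[x + 1L] + 1L
  occ <- which(h > 0L) - 1L
  if (length(occ) < 2L) stop("degenerate")
  lo <- min(occ); hi <- max(occ)
  cand <- occ[occ >= max(1L, lo) & occ <= lo + (hi - lo) / 2]
  peak <- if (!length(cand)) lo else cand[which.max(h[cand + 1L])]
  run_min <- Inf; valley <- NA_integer_
  for (i in seq(peak + 1L, hi)) {
    ci <- h[i + 1L]
    if (ci < run_min) { run_min <- ci; valley <- i }
    else if (ci > 0 && ci >= 2 * run_min) return(valley)
  }
  stop("no separation")
}

# Brute-force constellation matcher: all 4-subsets, all label permutations.
naive_match <- function(coms, template, tol_max = 10) {
  tmpl <- fidseg::template_distances(template)
  pairs <- utils::combn(4, 2)
  tmpl_pair <- apply(pairs, 2, function(p)
    sqrt(sum((template$points[p[1], ] - template$points[p[2], ])^2)))
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  subsets <- utils::combn(nrow(coms), 4)
  for (tol in seq_len(tol_max)) {
    best <- NULL
    for (s in seq_len(ncol(subsets))) {
      pts <- coms[subsets[, s], , drop = FALSE]
      d6 <- sort(as.vector(dist(pts)), decreasing = TRUE)
      if (!all(abs(d6 - tmpl) <= tol)) next
      for (r in seq_len(nrow(perms))) {
        q <- pts[unlist(perms[r, ]), , drop = FALSE]
        dq <- apply(pairs, 2, function(p) sqrt(sum((q[p[1], ] - q[p[2], ])^2)))
        rms <- sqrt(mean((dq - tmpl_pair)^2))
        if (is.null(best) || rms < best$rms)
          best <- list(rms = rms, idx = subsets[, s][unlist(perms[r, ])],
                       tol = tol)
      }
    }
    if (!is.null(best)) return(best)
  }
  NULL
}

# Rigid-fit oracle: derivative-free search over unit quaternions — a coarse
# global random sample followed by shrinking local perturbation grids around
# the incumbent. Independent of the SVD solution it checks.
quaternion_grid_rms <- function(P, Q, seed = 99) {
  set.seed(seed)
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  quat_to_mat <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3, 3)
  }
  rms_of <- function(q) sqrt(mean(rowSums((Q0 - P0 %*% quat_to_mat(q))^2)))
  best_q <- c(1, 0, 0, 0)
  best <- rms_of(best_q)
  for (i in 1:3000) {
    q <- stats::rnorm(4)
    r <- rms_of(q)
    if (r < best) { best <- r; best_q <- q / sqrt(sum(q^2)) }
  }
  for (scale in c(0.2, 0.06, 0.02, 0.006, 0.002, 6e-4, 2e-4)) {
    for (i in 1:1500) {
      q <- best_q + stats::rnorm(4, sd = scale)
      r <- rms_of(q)
      if (r < best) { best <- r; best_q <- q / sqrt(sum(q^2)) }
    }
  }
  best
}
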