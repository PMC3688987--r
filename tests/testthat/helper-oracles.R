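# Independent oracles used across tests. These deliberately avoid the code
# paths they check: plain loops, closed forms and brute-force enumeration.

# small default simulation for tests: 8x8x4 grid, narrow blobs
tiny_truth <- function(n_subjects = 10, d_true = 3, seed = 1, ...) {
  simulation_truth(n_subjects = n_subjects, grid_dims = c(8, 8, 4),
                   d_true = d_true, blob_fwhm = 2, seed = seed, ...)
}

# pairwise Pearson correlation by explicit loops
cor_loop <- function(x) {
  d <- ncol(x)
  out <- diag(d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
    out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  out
}

# partial correlation of columns i and j given all others, via regression
# residuals
pcor_residual <- function(x, i, j) {
  others <- setdiff(seq_len(ncol(x)), c(i, j))
  if (length(others) == 0) return(cor(x[, i], x[, j]))
  ri <- stats::lm.fit(cbind(1, x[, others, drop = FALSE]), x[, i])$residuals
  rj <- stats::lm.fit(cbind(1, x[, others, drop = FALSE]), x[, j])$residuals
  cor(ri, rj)
}

# Benjamini-Hochberg step-up by exhaustive scan over all k
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kmax <- 0
  for (k in seq_len(m)) if (ps[k] <= k / m * q) kmax <- k
  reject <- logical(m)
  if (kmax > 0) reject[ord[seq_len(kmax)]] <- TRUE
  reject
}

# brute-force TFCE: explicit threshold loop with BFS 26-connected clustering
neighbours_26 <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  coords <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  lapply(seq_len(nrow(coords)), function(i) {
    xx <- coords$x[i] + offs$dx; yy <- coords$y[i] + offs$dy
    zz <- coords$z[i] + offs$dz
    ok <- xx >= 1 & xx <= nx & yy >= 1 & yy <= ny & zz >= 1 & zz <= nz
    (zz[ok] - 1) * nx * ny + (yy[ok] - 1) * nx + xx[ok]
  })
}

cluster_sizes_at <- function(supra, nbrs) {
  lab <- integer(length(supra))
  cur <- 0
  for (s in which(supra)) {
    if (lab[s] > 0) next
    cur <- cur + 1
    queue <- s; lab[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nbrs[[v]]) if (supra[w] && lab[w] == 0) {
        lab[w] <- cur; queue <- c(queue, w)
      }
    }
  }
  lab
}

tfce_brute <- function(stat, dims, E, H, dh, nbrs = neighbours_26(dims)) {
  s <- pmax(as.numeric(stat), 0)
  out <- numeric(length(s))
  if (max(s) <= 0) return(out)
  hs <- seq(dh, max(s) + 1e-12, by = dh)
  hs <- hs[hs <= max(s)]
  for (h in hs) {
    lab <- cluster_sizes_at(s >= h, nbrs)
    sizes <- tabulate(lab)
    idx <- lab > 0
    out[idx] <- out[idx] + sizes[lab[idx]]^E * h^H * dh
  }
  out
}
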