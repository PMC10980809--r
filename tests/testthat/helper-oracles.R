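# Independent brute-force oracles used across the suite.
# These deliberately reimplement the definitions with naive loops so the
# vectorised/compiled implementations are checked against something simpler.

# O(N^2) time-averaged MSD by explicit double loop over sample pairs
msd_brute <- function(pos, dt, max_lag_fraction = 0.5) {
  N <- nrow(pos)
  K <- max(1L, floor(max_lag_fraction * (N - 1)))
  vals <- numeric(K)
  for (k in seq_len(K)) {
    acc <- 0
    for (t in 1:(N - k)) acc <- acc + sum((pos[t + k, ] - pos[t, ])^2)
    vals[k] <- acc / (N - k)
  }
  list(lags = dt * seq_len(K), values = vals)
}

# flood-fill component labeling by queue, plain R
flood_fill_brute <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, dim = d)
  cur <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] == 0 || lab[i, j, k] != 0) next
    cur <- cur + 1L
    queue <- matrix(c(i, j, k), ncol = 3)
    lab[i, j, k] <- cur
    while (nrow(queue)) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (m in seq_len(nrow(offs))) {
        w <- v + offs[m, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] != 0 && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- cur
          queue <- rbind(queue, w)
        }
      }
    }
  }
  lab
}

connectivity_brute <- function(mask, connectivity = 26) {
  lab <- flood_fill_brute(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  100 * max(sizes) / sum(sizes)
}

# triple-loop internal face counting with anisotropic face areas
interfacial_area_brute <- function(labels, voxel_size = c(1, 1, 1)) {
  d <- dim(labels)
  fa <- c(voxel_size[2] * voxel_size[3],
          voxel_size[1] * voxel_size[3],
          voxel_size[1] * voxel_size[2])
  sa <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (i < d[1] && labels[i, j, k] != labels[i + 1, j, k]) sa <- sa + fa[1]
    if (j < d[2] && labels[i, j, k] != labels[i, j + 1, k]) sa <- sa + fa[2]
    if (k < d[3] && labels[i, j, k] != labels[i, j, k + 1]) sa <- sa + fa[3]
  }
  sa / (prod(d) * prod(voxel_size))
}

# sort-based percentile with linear interpolation between order statistics
percentile_brute <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# IQR outlier rule via the same percentile oracle
iqr_keep_brute <- function(x) {
  q1 <- percentile_brute(x, 0.25)
  q3 <- percentile_brute(x, 0.75)
  iqr <- q3 - q1
  x >= q1 - 1.5 * iqr & x <= q3 + 1.5 * iqr
}

# Hertz forward model, written independently of the package internals
hertz_brute <- function(depth, E, R, nu = 0.49) {
  4 / 3 * E / (1 - nu^2) * sqrt(R) * depth^1.5
}

# small helpers for constructing tracks
make_track_df <- function(ids, times, xyz) {
  df <- data.frame(track_id = ids, t_h = times,
                   x_um = xyz[, 1], y_um = xyz[, 2])
  if (ncol(xyz) == 3) df$z_um <- xyz[, 3]
  df
}

straight_track <- function(id = "s", n = 10, step = c(2, 0), dt = 1, dim = 2) {
  pos <- outer(0:(n - 1), step)
  if (dim == 3) pos <- cbind(pos, 0)
  track(id, dt * (0:(n - 1)), pos)
}

random_track <- function(id = "r", n = 20, dt = 1, dim = 2) {
  track(id, dt * (0:(n - 1)),
        apply(matrix(rnorm(n * dim), n, dim), 2, cumsum))
}
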