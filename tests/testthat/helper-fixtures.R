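# Shared fixtures and independent oracles, all generated in code.

small_geometry <- function(n_projections = 5L, detector = c(32L, 48L),
                           pitch = 1) {
  acquisition_geometry(n_projections = n_projections, arc_deg = 15,
                       detector_shape = detector, pixel_pitch = pitch,
                       source_to_detector = 700,
                       source_to_rotation_center = 660)
}

# Smooth "breast-like" test image: a few Gaussian blobs.
blob_image <- function(nr = 128L, nc = 128L, n_blobs = 6L, seed = 4L) {
  set.seed(seed)
  img <- matrix(0, nr, nc)
  for (i in seq_len(n_blobs)) {
    cx <- runif(1, 0.15 * nr, 0.85 * nr)
    cy <- runif(1, 0.15 * nc, 0.85 * nc)
    s <- runif(1, 8, 20)
    img <- img + runif(1, 0.2, 0.6) *
      outer(seq_len(nr), seq_len(nc),
            function(r, c) exp(-((r - cx)^2 + (c - cy)^2) / (2 * s^2)))
  }
  img
}

# Pool of blob patches with additive Gaussian noise (trainer fixtures).
blob_pool <- function(n, size = 32L, noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  arr <- array(0, c(size, size, n))
  for (i in seq_len(n)) {
    cx <- runif(1, 0.25 * size, 0.75 * size)
    cy <- runif(1, 0.25 * size, 0.75 * size)
    s <- runif(1, size / 10, size / 4)
    g <- outer(seq_len(size), seq_len(size),
               function(r, c) exp(-((r - cx)^2 + (c - cy)^2) / (2 * s^2)))
    arr[, , i] <- 0.3 + 0.5 * g + rnorm(size * size, sd = noise_sd)
  }
  arr
}

# Mock network whose forward pass is the identity (exercises tiling/blending
# machinery independently of any trained weights).
identity_network <- function() {
  e <- new.env()
  e$forward <- function(x) x
  class(e) <- "dbt_network"
  e
}

# Oracle: count connected components of a 3-D logical mask by BFS
# (6-connectivity).
count_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  ncomp <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      k <- (cur - 1L) %/% (d[1] * d[2])
      rem <- (cur - 1L) %% (d[1] * d[2])
      j <- rem %/% d[1]; i <- rem %% d[1]
      for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                       c(0,0,1), c(0,0,-1))) {
        ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
        if (ii < 0 || ii >= d[1] || jj < 0 || jj >= d[2] ||
            kk < 0 || kk >= d[3]) next
        nb <- 1L + ii + d[1] * (jj + d[2] * kk)
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- ncomp
          queue <- c(queue, nb)
        }
      }
    }
  }
  ncomp
}

# Oracle: 8-neighbourhood co-occurrence counts by exhaustive pair
# enumeration on a quantised integer image.
glcm_oracle <- function(q, levels) {
  counts <- matrix(0, levels, levels)
  d <- dim(q)
  offsets <- list(c(0,1), c(0,-1), c(1,0), c(-1,0),
                  c(1,1), c(1,-1), c(-1,1), c(-1,-1))
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) for (o in offsets) {
    r2 <- r + o[1]; c2 <- c + o[2]
    if (r2 < 1 || r2 > d[1] || c2 < 1 || c2 > d[2]) next
    counts[q[r, c], q[r2, c2]] <- counts[q[r, c], q[r2, c2]] + 1
  }
  counts <- (counts + t(counts)) / 2
  counts / sum(counts)
}

# Oracle: ramp filtering of one line by an explicit DFT matrix product,
# with the same edge-replication padding convention as the implementation.
ramlak_line_oracle <- function(line, pitch = 1) {
  n <- length(line)
  N <- 2^ceiling(log2(2 * n))
  pl <- (N - n) %/% 2
  padded <- c(rep(line[1], pl), line, rep(line[n], N - n - pl))
  W <- exp(-2i * pi * outer(0:(N - 1), 0:(N - 1)) / N)
  freqs <- c(seq(0, N / 2), seq(-N / 2 + 1, -1)) / (N * pitch)
  spec <- (W %*% padded) * abs(freqs)
  out <- Re(Conj(W) %*% spec) / N
  out[pl + seq_len(n)]
}
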