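# Independent brute-force oracles, deliberately written as plain loops so they
# share no code path with the package implementations they check.

# exhaustive scan of the threshold error term over every integer tau
oracle_threshold <- function(r, h) {
  stopifnot(length(r) == length(h))
  n <- length(r)          # support f = 0 .. n-1
  best_tau <- NA_integer_
  best_eps <- Inf
  for (tau in 0:n) {
    eps <- 0
    f <- 0
    while (f <= tau - 1) {
      eps <- eps + (r[f + 1] - h[f + 1])
      f <- f + 1
    }
    f <- tau
    while (f <= n - 1) {
      eps <- eps + r[f + 1]
      f <- f + 1
    }
    if (eps < best_eps - 1e-12) {
      best_eps <- eps
      best_tau <- tau
    }
  }
  best_tau
}

# literal Minkowski dilation: c = a + b over all pairs
oracle_dilate <- function(mask, offsets) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  ons <- which(mask != 0, arr.ind = TRUE)
  for (i in seq_len(nrow(ons))) {
    for (j in seq_len(nrow(offsets))) {
      r <- ons[i, 1] + offsets[j, 1]
      c <- ons[i, 2] + offsets[j, 2]
      if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask)) {
        out[r, c] <- 1L
      }
    }
  }
  out
}

# literal erosion: keep c iff the translated element lies entirely in the mask
oracle_erode <- function(mask, offsets) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      ok <- TRUE
      for (j in seq_len(nrow(offsets))) {
        rr <- r + offsets[j, 1]
        cc <- c + offsets[j, 2]
        if (rr < 1 || rr > nrow(mask) || cc < 1 || cc > ncol(mask) ||
            mask[rr, cc] == 0) {
          ok <- FALSE
          break
        }
      }
      if (ok) out[r, c] <- 1L
    }
  }
  out
}

# queue-based flood fill labelling
oracle_components <- function(mask, connectivity = 8) {
  nb <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  }
  lab <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (mask[r, c] != 0 && lab[r, c] == 0L) {
        k <- k + 1L
        queue <- list(c(r, c))
        lab[r, c] <- k
        while (length(queue)) {
          p <- queue[[1]]
          queue <- queue[-1]
          for (d in nb) {
            rr <- p[1] + d[1]
            cc <- p[2] + d[2]
            if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
                mask[rr, cc] != 0 && lab[rr, cc] == 0L) {
              lab[rr, cc] <- k
              queue[[length(queue) + 1]] <- c(rr, cc)
            }
          }
        }
      }
    }
  }
  lab
}

# plain-loop evaluation of the fuzzy within-cluster sum of squares
oracle_fcm_objective <- function(x, centers, u, m) {
  J <- 0
  for (i in seq_along(centers)) {
    for (k in seq_along(x)) {
      J <- J + u[i, k]^m * abs(x[k] - centers[i])^2
    }
  }
  J
}

# flood fill at an absolute intensity threshold (for region-grow fixtures
# whose foreground is homogeneous): all bright pixels 4-connected to the seed
# inside the box
oracle_bright_component <- function(slice, seed, bbox, level) {
  mask <- matrix(0L, nrow(slice), ncol(slice))
  sub <- matrix(0L, nrow(slice), ncol(slice))
  sub[bbox[1]:bbox[3], bbox[2]:bbox[4]] <- 1L
  bright <- (slice >= level) * sub
  lab <- oracle_components(bright, 4)
  if (lab[seed[1], seed[2]] == 0L) return(mask)
  mask[lab == lab[seed[1], seed[2]]] <- 1L
  mask
}

# small tube-and-lungs raster used by several airway tests
make_tube_fixture <- function(nr = 60, nc = 80, tube_level = 100) {
  slice <- matrix(0, nr, nc)
  tube_rows <- 5:40
  tube_cols <- 37:44
  slice[tube_rows, tube_cols] <- tube_level
  slice[15:55, 8:28] <- 80    # left "lung"
  slice[15:55, 52:72] <- 80   # right "lung"
  list(slice = slice, tube_rows = tube_rows, tube_cols = tube_cols,
       tube_mask = {
         m <- matrix(0L, nr, nc)
         m[tube_rows, tube_cols] <- 1L
         m
       })
}
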